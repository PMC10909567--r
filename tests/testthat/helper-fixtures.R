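# Shared fixture builders. Everything is generated in code at test time;
# no data files are read.

# A tiny hand-built colony observation table with valid invariants.
tiny_obs <- function() {
  data.frame(
    colony_id = c("A1", "A2", "A3"),
    region = "AT", site = "p1", taxon = "Acropora",
    strategy = "competitive", year_t = 2016L,
    size_t = c(10, 40, 200),
    survived = c(TRUE, TRUE, FALSE),
    size_t1 = c(14, NA, NA),
    fragmented = c(FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  ) |> (\(d) {
    d$remnant_sizes <- list(numeric(0), c(12, 5), numeric(0))
    d
  })()
}

# Random strictly positive square matrix; strictly positive entries make
# the matrix primitive by construction.
random_primitive_matrix <- function(m, scale = 1) {
  matrix(stats::runif(m * m, min = 0.01, max = 1), m, m) * scale
}

# Deterministic fixture kernels built straight from generative presets
# (no simulation noise).
fixture_kernel <- function(name = "AT.competitive", m = 200) {
  pr <- assemblage_presets()[[name]]
  build_kernel(vital_rates_from_params(pr), m = m)
}

# Dense-grid oracle for the Kreiss bounds: 10^5 log-spaced probes of
# r - 1 in [1e-6, 1e3] plus local refinement around the best grid point.
# Uses the eigendecomposition to evaluate all probes in vectorized form;
# the implementation under test instead runs multistart scalar
# optimization, so search strategy and evaluation route both differ.
kreiss_grid_oracle <- function(K, n_grid = 1e5) {
  lambda <- max(Mod(eigen(K, only.values = TRUE)$values))
  A <- K / lambda
  e <- eigen(A)
  V <- e$vectors
  Vinv <- solve(V)
  cV <- colSums(V)
  d <- e$values
  r <- 1 + exp(seq(log(1e-6), log(1e3), length.out = n_grid))
  up <- numeric(n_grid)
  lo <- numeric(n_grid)
  chunk <- 20000L
  for (start in seq(1, n_grid, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_grid)
    M <- 1 / outer(r[idx], d, "-")          # |idx| x m complex
    CS <- Re(sweep(M, 2, cV, "*") %*% Vinv) # colsums of the resolvent
    up[idx] <- (r[idx] - 1) * apply(CS, 1, max)
    lo[idx] <- (r[idx] - 1) * apply(CS, 1, min)
  }
  cs_at <- function(rr) Re(drop(t(Vinv) %*% (cV / (rr - d))))
  refine <- function(i_best, f, maximize) {
    lo_i <- max(1L, i_best - 1L)
    hi_i <- min(n_grid, i_best + 1L)
    o <- stats::optimize(f, c(r[lo_i], r[hi_i]), maximum = maximize,
                         tol = 1e-12)
    if (maximize) o$objective else o$objective
  }
  f_up <- function(rr) (rr - 1) * max(cs_at(rr))
  f_lo <- function(rr) (rr - 1) * min(cs_at(rr))
  list(upper = max(max(up), refine(which.max(up), f_up, TRUE)),
       lower = min(min(lo), refine(which.min(lo), f_lo, FALSE)))
}
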