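#' Log-size domain of an assemblage
#'
#' Computes the kernel's size domain from observed colony sizes: raw bounds
#' at 0.9 x the minimum and 1.1 x the maximum observed size (a multiplicative
#' 10% buffer avoiding accidental exclusion of observed states), then
#' log-transformed.
#'
#' @param obs Colony-observation data frame; sizes at t and t+1 and remnant
#'   sizes all count as observed.
#' @param extra_sizes Optional further raw sizes (e.g. recruit sizes).
#' @return Named numeric `c(L, U)` on the log scale.
#' @export
size_domain <- function(obs, extra_sizes = NULL) {
  sizes <- c(obs$size_t, obs$size_t1[!is.na(obs$size_t1)],
             unlist(obs$remnant_sizes), extra_sizes)
  sizes <- sizes[!is.na(sizes)]
  if (length(unique(sizes)) < 2) {
    stop("at least 2 distinct observed sizes are required for a size domain")
  }
  if (min(sizes) <= 0) stop("non-positive observed size")
  c(L = log(0.9 * min(sizes)), U = log(1.1 * max(sizes)))
}

# Discretize a Gaussian transition density into an m x m column-stochastic
# matrix on mesh x: midpoint-rule densities times cell width, probability
# mass escaping [L, U] binned into the nearest boundary cell, and a final
# column normalization absorbing the residual quadrature error so every
# column sums to exactly 1.
gaussian_columns <- function(x, mu, sd, L, U, h) {
  m <- length(x)
  if (length(sd) == 1) sd <- rep(sd, m)
  SD <- matrix(sd, m, m, byrow = TRUE)
  MU <- matrix(mu, m, m, byrow = TRUE)
  G <- stats::dnorm(matrix(x, m, m), MU, SD) * h
  G[1, ] <- G[1, ] + stats::pnorm(L, mu, sd)
  G[m, ] <- G[m, ] + stats::pnorm(U, mu, sd, lower.tail = FALSE)
  cs <- colSums(G)
  cs[cs == 0] <- 1
  sweep(G, 2, cs, "/")
}

# Discretize the recruit log-size density on the mesh, renormalized to sum 1.
recruit_column <- function(x, mean, sd, L, U, h) {
  v <- stats::dnorm(x, mean, sd) * h
  v[1] <- v[1] + stats::pnorm(L, mean, sd)
  v[length(v)] <- v[length(v)] + stats::pnorm(U, mean, sd,
                                              lower.tail = FALSE)
  v / sum(v)
}

#' Build the discretized projection kernel
#'
#' Assembles the survival-growth-fragmentation kernel
#' `P(z', z) = (1 - kappa(z)) sigma(z) gamma(z' | z)
#'            + kappa(z) kappa_b(z) kappa_z0(z' | z)`
#' and the reproduction kernel `F(z', z) = phi(z) phi_s C0(z')`, and
#' discretizes both by the midpoint rule on an m-point mesh over the
#' log-size domain (entry (i, j) is the kernel at the cell midpoints times
#' the cell width). Growth and remnant-size densities are column-normalized
#' with boundary-mass binning so no survival mass is evicted at the domain
#' edges. Remnant production can push column masses of P above 1 (one parent
#' producing several remnants); this is intentional and not clamped.
#'
#' The fragmentation term carries no survival factor by default, matching
#' the structure of the governing kernel; `sigma_on_fragmentation = TRUE`
#' multiplies it by sigma(z) for sensitivity analysis.
#'
#' @param rates A `vital_rates` object.
#' @param m Mesh size (default 200, minimum 10).
#' @param sigma_on_fragmentation Multiply the fragmentation term by
#'   survival (default FALSE).
#' @param phi Optional settlement probability overriding the fitted pooled
#'   value (used when resampling varies settlement within observed limits).
#' @param check_growth_rate If TRUE (default), error when the spectral
#'   radius of P reaches 1, which would leave the net reproductive rate
#'   undefined downstream.
#' @return An object of class `ipm_kernel` with elements `L`, `U`, `m`, `h`,
#'   `mesh`, `P`, `F`, `K` (= P + F), `sigma`, `kappa`, `phi`.
#' @export
build_kernel <- function(rates, m = 200, sigma_on_fragmentation = FALSE,
                         phi = NULL, check_growth_rate = TRUE) {
  stopifnot(inherits(rates, "vital_rates"), m >= 10)
  L <- log(0.9 * rates$size_range[1])
  U <- log(1.1 * rates$size_range[2])
  h <- (U - L) / m
  x <- L + (seq_len(m) - 0.5) * h
  sigma <- survival_prob(rates, x)
  kappa <- fragmentation_prob(rates, x)
  G <- gaussian_columns(x, growth_mean(rates, x), growth_sd(rates, x),
                        L, U, h)
  P <- sweep(G, 2, (1 - kappa) * sigma, "*")
  if (any(kappa > 0)) {
    rs <- rates$remnant_size
    if (isTRUE(rs$empirical)) {
      R <- gaussian_columns(x, rep(rs$mean, m), rs$sigma, L, U, h)
    } else {
      R <- gaussian_columns(x, poly_eval(rs$coefficients, x), rs$sigma,
                            L, U, h)
    }
    kb <- remnant_count_mean(rates, x)
    w <- kappa * kb
    if (sigma_on_fragmentation) w <- w * sigma
    P <- P + sweep(R, 2, w, "*")
  }
  phi_s <- if (is.null(phi)) rates$settlement$pooled else phi
  C0 <- recruit_column(x, rates$recruit_size$mean, rates$recruit_size$sd,
                       L, U, h)
  Fm <- outer(C0, fecundity_mean(rates, x) * phi_s)
  if (any(P < 0) || any(Fm < 0)) stop("internal error: negative kernel entry")
  if (check_growth_rate) {
    rhoP <- max(Mod(eigen(P, only.values = TRUE)$values))
    if (rhoP >= 1) {
      stop("spectral radius of the survival kernel P is ",
           format(rhoP, digits = 5),
           " (>= 1); the net reproductive rate is undefined")
    }
  }
  structure(list(L = L, U = U, m = m, h = h, mesh = x,
                 P = P, F = Fm, K = P + Fm,
                 sigma = sigma, kappa = kappa, phi = phi_s),
            class = "ipm_kernel")
}

#' @export
print.ipm_kernel <- function(x, ...) {
  cat("Discretized IPM kernel: ", x$m, "x", x$m,
      " cells on log-size domain [", format(x$L, digits = 4), ", ",
      format(x$U, digits = 4), "], h = ", format(x$h, digits = 4), "\n",
      sep = "")
  lam <- max(Mod(eigen(x$K, only.values = TRUE)$values))
  cat("  asymptotic growth rate lambda =", format(lam, digits = 6), "\n")
  invisible(x)
}

#' Project a size distribution through the kernel
#'
#' Repeated matrix-vector products `n(t+1) = K n(t)`.
#'
#' @param kernel An `ipm_kernel` or a plain projection matrix.
#' @param n0 Non-negative density vector of length m.
#' @param t Number of steps (t = 0 returns the input unchanged).
#' @return A list with `densities` (m x (t+1) matrix, column s+1 is step s)
#'   and `total` (population sizes per step).
#' @export
project <- function(kernel, n0, t) {
  K <- if (inherits(kernel, "ipm_kernel")) kernel$K else kernel
  stopifnot(length(n0) == nrow(K), t >= 0)
  if (any(n0 < 0)) stop("negative entry in the initial density vector")
  out <- matrix(NA_real_, nrow(K), t + 1)
  out[, 1] <- n0
  n <- n0
  if (t > 0) for (s in seq_len(t)) {
    n <- drop(K %*% n)
    out[, s + 1] <- n
  }
  list(densities = out, total = colSums(out))
}

#' Export or import a kernel as a plain-text dump
#'
#' The file holds a YAML metadata block (domain, mesh size, cell width,
#' settlement) followed by whitespace-delimited `P` and `F` matrix blocks.
#'
#' @param kernel An `ipm_kernel`.
#' @param path Output file path.
#' @return `path` ([write_kernel()]) or the restored `ipm_kernel`
#'   ([read_kernel()]).
#' @export
write_kernel <- function(kernel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- list(L = kernel$L, U = kernel$U, m = kernel$m, h = kernel$h,
               phi = kernel$phi)
  writeLines("#meta", con)
  writeLines(yaml::as.yaml(meta), con)
  fmt <- function(M) {
    apply(M, 1, function(row) paste(sprintf("%.17g", row), collapse = " "))
  }
  writeLines("#P", con)
  writeLines(fmt(kernel$P), con)
  writeLines("#F", con)
  writeLines(fmt(kernel$F), con)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  lines <- readLines(path)
  ip <- which(lines == "#P")
  iff <- which(lines == "#F")
  meta <- yaml::yaml.load(paste(lines[2:(ip - 1)], collapse = "\n"))
  parse_block <- function(block) {
    do.call(rbind, lapply(block, function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    }))
  }
  P <- parse_block(lines[(ip + 1):(iff - 1)])
  Fm <- parse_block(lines[(iff + 1):length(lines)])
  h <- meta$h
  x <- meta$L + (seq_len(meta$m) - 0.5) * h
  structure(list(L = meta$L, U = meta$U, m = meta$m, h = h, mesh = x,
                 P = P, F = Fm, K = P + Fm, sigma = NULL, kappa = NULL,
                 phi = meta$phi),
            class = "ipm_kernel")
}
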