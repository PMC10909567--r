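test_that("growth rate and damping ratio match closed forms and the
           eigendecomposition oracle", {
  expect_equal(asymptotic_growth(diag(c(0.5, 0.2))), 0.5)
  A <- matrix(c(0, 0.5, 2, 0), 2, 2)
  expect_warning(lam <- asymptotic_growth(A), NA)  # irreducible, no warning
  expect_equal(lam, 1.0)
  rho <- damping_ratio(A)
  expect_equal(as.numeric(rho), 1.0)
  expect_equal(attr(rho, "flag"), "imprimitive")

  expect_equal(as.numeric(damping_ratio(diag(c(0.8, 0.4)))), 2.0)

  set.seed(1)
  M <- random_primitive_matrix(50)
  ev <- sort(Mod(eigen(M, only.values = TRUE)$values), decreasing = TRUE)
  expect_equal(as.numeric(damping_ratio(M)), ev[1] / ev[2],
               tolerance = 1e-10)

  # dominant eigenvalue agrees with power iteration on a 200 x 200 matrix
  set.seed(2)
  K <- random_primitive_matrix(200)
  v <- rep(1, 200)
  for (i in 1:2000) {
    v <- drop(K %*% v)
    v <- v / sum(v)
  }
  lam_power <- sum(K %*% v)
  expect_equal(asymptotic_growth(K), lam_power, tolerance = 1e-10)
})

test_that("scalar kernels give the closed-form R0 and generation time", {
  gt <- generation_time(matrix(0.5), matrix(0.6))
  expect_equal(gt$R0, 1.2)
  expect_equal(gt$lambda, 1.1)
  expect_equal(gt$generation_time, log(1.2) / log(1.1))

  gt0 <- generation_time(matrix(0.5), matrix(0))
  expect_equal(gt0$R0, 0)
  expect_equal(gt0$flag, "zero_R0")
  expect_true(is.na(gt0$generation_time))

  expect_error(generation_time(matrix(1.2), matrix(0.1)), ">= 1")
})

test_that("R0 matches an individual-based lifetime-offspring simulation", {
  pr <- assemblage_presets()[["AT.stress_tolerant"]]
  p2 <- generative_params(survival = pr$survival, growth = pr$growth,
                          growth_sd = pr$growth_sd,
                          fragmentation = c(-1e6, 0, 0),
                          fecundity = pr$fecundity,
                          settlement = pr$settlement,
                          init_size_mean = pr$init_size_mean)
  k <- build_kernel(vital_rates_from_params(p2), m = 60)
  R0_matrix <- generation_time(k$P, k$F)$R0
  # Monte Carlo: the reproduction kernel is rank one (all offspring recruit
  # into the C0 size distribution), so R0 is the mean lifetime expected
  # offspring of an individual recruited from C0. Simulate individual lives
  # through the column-stochastic survival kernel, accumulating the
  # per-step expected offspring of the occupied size class.
  set.seed(7)
  m <- k$m
  surv <- colSums(k$P)
  trans <- sweep(k$P, 2, pmax(surv, 1e-300), "/")
  fper <- colSums(k$F)
  C0 <- k$F[, 1] / sum(k$F[, 1])
  n_ind <- 200000
  states <- sample.int(m, n_ind, replace = TRUE, prob = C0)
  offspring <- numeric(n_ind)
  alive <- rep(TRUE, n_ind)
  for (t in 1:1500) {
    idx <- which(alive)
    if (length(idx) == 0) break
    offspring[idx] <- offspring[idx] + fper[states[idx]]
    die <- runif(length(idx)) > surv[states[idx]]
    alive[idx[die]] <- FALSE
    idx <- which(alive)
    if (length(idx) == 0) break
    st <- states[idx]
    for (s in unique(st)) {  # grouped categorical sampling per size class
      sel <- idx[st == s]
      states[sel] <- sample.int(m, length(sel), replace = TRUE,
                                prob = trans[, s])
    }
  }
  expect_lt(sum(alive), n_ind * 0.005)  # virtually all lives completed
  expect_equal(mean(offspring), R0_matrix, tolerance = 0.02)
})

test_that("maximal amplification matches brute-force enumeration", {
  expect_equal(as.numeric(max_amplification(matrix(0.7))), 1)
  expect_equal(as.numeric(max_amplification(diag(c(0.8, 0.4)))), 1)

  A <- matrix(c(0.1, 0.4, 2, 0.3), 2, 2)
  lam <- asymptotic_growth(A)
  Ahat <- A / lam
  B <- diag(2)
  brute <- -Inf
  for (t in 1:1000) {
    B <- Ahat %*% B
    brute <- max(brute, max(colSums(B)))
  }
  expect_equal(as.numeric(max_amplification(A)), brute, tolerance = 1e-10)
})

test_that("Kreiss bounds reduce to closed forms and agree with the dense
           grid oracle", {
  kb1 <- kreiss_bounds(matrix(0.9))
  expect_equal(kb1$upper, 1)
  expect_equal(kb1$lower, 1)
  expect_equal(transient_envelope(matrix(0.9)), 0)

  expect_warning(kbd <- kreiss_bounds(diag(c(0.8, 0.4))), "reducible")
  expect_equal(kbd$upper, 1, tolerance = 1e-6)
  expect_lt(kbd$lower, 1e-3)  # attenuation collapses for reducible structure

  A <- matrix(c(0.1, 0.4, 2, 0.3), 2, 2)
  kb <- kreiss_bounds(A)
  oracle <- kreiss_grid_oracle(A)
  expect_equal(kb$upper, oracle$upper, tolerance = 1e-6)
  expect_equal(kb$lower, oracle$lower, tolerance = 1e-6)
})

test_that("transient envelopes are non-negative and rank life histories as
           expected", {
  set.seed(3)
  for (i in 1:25) {
    M <- random_primitive_matrix(sample(2:12, 1))
    expect_gte(transient_envelope(M), -1e-10)
  }
  te_weedy <- transient_envelope(fixture_kernel("AT.weedy", m = 100))
  te_stress <- transient_envelope(fixture_kernel("AT.stress_tolerant",
                                                 m = 100))
  expect_gt(te_weedy, te_stress)
})

test_that("the metrics bundle satisfies its invariant chain and flags
           degenerate structure", {
  set.seed(4)
  for (i in 1:20) {
    m <- sample(2:15, 1)
    P <- random_primitive_matrix(m, scale = 0.5 / m)
    F <- random_primitive_matrix(m, scale = 0.5 / m)
    dm <- demographic_metrics(P, F)
    expect_gte(dm$damping_ratio, 1)
    expect_lte(dm$kreiss_lower, 1 + 1e-10)
    expect_gte(dm$kreiss_upper, 1 - 1e-10)
    expect_gte(dm$max_amplification, dm$kreiss_upper - 1e-8)
    expect_gte(dm$transient_envelope, -1e-10)
    expect_equal(sign(dm$R0 - 1), sign(dm$lambda - 1))
  }

  reducible <- rbind(c(0.5, 0.2), c(0, 0.3))
  dmr <- suppressWarnings(demographic_metrics(reducible,
                                              matrix(0, 2, 2)))
  expect_false(dmr$irreducible)
})

test_that("lambda scales linearly and the damping ratio is scale
           invariant", {
  set.seed(5)
  M <- random_primitive_matrix(20)
  expect_equal(asymptotic_growth(3 * M), 3 * asymptotic_growth(M),
               tolerance = 1e-10)
  expect_equal(as.numeric(damping_ratio(3 * M)),
               as.numeric(damping_ratio(M)), tolerance = 1e-10)
})
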