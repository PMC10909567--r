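make_survey <- function(p, n = 5000, seed = 1, years = 2) {
  simulate_survey(generative_params(survival = p$survival %||% c(-1, 0.45),
                                    growth = p$growth %||% c(0.6, 0.9, 0),
                                    growth_sd = p$growth_sd %||% 0.5,
                                    fragmentation =
                                      p$fragmentation %||% c(-4, 0.3, 0),
                                    n_colonies = n, n_years = years),
                  seed = seed)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("survival coefficients are recovered within their 95% CIs", {
  covered <- vapply(1:3, function(seed) {
    sim <- make_survey(list(survival = c(0.5, 0.8)), n = 5000, seed = seed)
    fit <- fit_survival(sim$survey)
    se <- sqrt(diag(fit$vcov))
    all(abs(fit$coefficients - c(0.5, 0.8)) <= 1.96 * se)
  }, logical(1))
  expect_gte(sum(covered), 2)  # joint 95% coverage over fixed seeds
  # logistic predictions stay inside [0, 1]
  sim <- make_survey(list(survival = c(0.5, 0.8)), n = 2000, seed = 4)
  fit <- fit_survival(sim$survey)
  z <- seq(-5, 15, length.out = 100)
  pr <- plogis(fit$coefficients[1] + fit$coefficients[2] * z)
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("all-survived input raises the separation flag", {
  sim <- make_survey(list(survival = c(25, 0)), n = 200, seed = 2)
  expect_warning(fit <- fit_survival(sim$survey), "separation")
  expect_true(fit$separation)
})

test_that("identity growth is fitted exactly and generative growth within
           CIs", {
  obs <- tiny_obs()[rep(1, 30), ]
  obs$colony_id <- sprintf("C%02d", 1:30)
  obs$size_t <- exp(runif(30, 1, 6))
  obs$size_t1 <- obs$size_t
  obs$survived <- TRUE
  obs$fragmented <- FALSE
  obs$remnant_sizes <- replicate(30, numeric(0), simplify = FALSE)
  fit <- fit_growth(obs)
  expect_equal(unname(fit$coefficients), c(0, 1, 0), tolerance = 1e-8)
  expect_lt(fit$sigma, 1e-8)

  covered <- vapply(1:3, function(seed) {
    sim <- make_survey(list(growth = c(0.4, 0.9, 0), growth_sd = 0.3),
                       n = 5000, seed = seed)
    gfit <- fit_growth(sim$survey)
    se <- sqrt(diag(gfit$vcov))
    all(abs(gfit$coefficients - c(0.4, 0.9, 0)) <= 1.96 * se)
  }, logical(1))
  expect_gte(sum(covered), 2)  # joint 95% coverage over fixed seeds

  simq <- make_survey(list(growth = c(0.4, 0.9, -0.02), growth_sd = 0.3),
                      n = 5000, seed = 32)
  qfit <- fit_growth(simq$survey)
  ci_lo <- qfit$coefficients[3] - 1.96 * sqrt(qfit$vcov[3, 3])
  ci_hi <- qfit$coefficients[3] + 1.96 * sqrt(qfit$vcov[3, 3])
  expect_true(ci_lo <= -0.02 && -0.02 <= ci_hi)
  expect_lt(ci_hi, 0)  # curvature detected as negative
})

test_that("fragmentation models recover generative coefficients and respect
           zero-truncation", {
  sim <- make_survey(list(fragmentation = c(-2, 0.5, 0)), n = 10000,
                     seed = 41)
  frag <- fit_fragmentation(sim$survey)
  se <- sqrt(diag(frag$probability$vcov))
  expect_true(all(abs(frag$probability$coefficients - c(-2, 0.5, 0)) <=
                    1.96 * se))
  vr <- suppressWarnings(fit_vital_rates(sim$survey, sim$recruits,
                                         simulate_fecundity(
                                           generative_params(), 200, 1)))
  z <- seq(0, 10, length.out = 50)
  kb <- coraldemog:::remnant_count_mean(vr, z)
  expect_true(all(kb >= 1))
})

test_that("absent fragmentation collapses kappa to zero with a warning", {
  sim <- make_survey(list(fragmentation = c(-30, 0, 0)), n = 300, seed = 5)
  expect_warning(frag <- fit_fragmentation(sim$survey), "no fragmentation")
  expect_true(frag$probability$zero)
  expect_null(frag$count)
})

test_that("fecundity fits are exact on noiseless tables and monotone when
           curvature is absent", {
  p0 <- generative_params(fecundity = c(-1, 0.8, 0.02),
                          fecundity_noise_sd = 0)
  fec <- simulate_fecundity(p0, n_records = 60, seed = 6)
  fit <- fit_fecundity(fec)
  expect_equal(unname(fit$coefficients), c(-1, 0.8, 0.02), tolerance = 1e-6)

  p1 <- generative_params(fecundity = c(-1, 0.8, 0), fecundity_noise_sd = 0)
  fit1 <- fit_fecundity(simulate_fecundity(p1, 60, seed = 7))
  z <- seq(0, 9, length.out = 40)
  pred <- exp(coraldemog:::poly_eval(fit1$coefficients, z))
  expect_true(all(diff(pred) > 0))

  fec$larval_output <- 0
  expect_error(fit_fecundity(fec), "degenerate")
})

test_that("settlement ratios follow their arithmetic definition", {
  # one colony of size e^1 with phi(z) = exp(ln 100) = 100 expected larvae
  obs <- data.frame(colony_id = "A", region = "R", site = "s", taxon = "t",
                    strategy = "weedy", year_t = 2016L, size_t = exp(1),
                    survived = TRUE, size_t1 = exp(1), fragmented = FALSE)
  obs$remnant_sizes <- list(numeric(0))
  fec_model <- list(coefficients = c(log(100), 0, 0))
  recr <- data.frame(region = "R", site = "s", year = 2017L, n_new = 10L)
  recr$new_sizes <- list(rep(2, 10))
  est <- estimate_settlement(recr, fec_model, obs)
  expect_equal(est$pooled, 0.1)

  recr0 <- recr
  recr0$n_new <- 0L
  recr0$new_sizes <- list(numeric(0))
  expect_warning(est0 <- estimate_settlement(recr0, fec_model, obs),
                 "zero recruits")
  expect_equal(est0$pooled, 0)
})

test_that("settlement recovers the generative probability", {
  p <- generative_params(settlement = 0.02, n_colonies = 3000, n_years = 4)
  sim <- simulate_survey(p, seed = 51)
  fec <- simulate_fecundity(p, 2000, seed = 52)
  vr <- suppressWarnings(fit_vital_rates(sim$survey, sim$recruits, fec))
  expect_lt(abs(vr$settlement$pooled - 0.02), 0.005)
})

test_that("recruit size distribution honours the sd floor and recovers
           generative moments", {
  recr <- data.frame(region = "R", site = "s", year = 2017L, n_new = 6L)
  recr$new_sizes <- list(rep(3, 6))
  fit <- fit_recruit_sizes(recr)
  expect_equal(fit$sd, 0.05)

  p <- generative_params(recruit_size_mean = 1.0, recruit_size_sd = 0.4,
                         n_colonies = 2000, n_years = 4)
  sim <- simulate_survey(p, seed = 61)
  rf <- fit_recruit_sizes(sim$recruits)
  n <- rf$n
  expect_lt(abs(rf$mean - 1.0), 1.96 * 0.4 / sqrt(n) * 1.5)
  expect_equal(rf$sd, 0.4, tolerance = 0.05)

  expect_error(fit_recruit_sizes(
    data.frame(region = "R", site = "s", year = 1L, n_new = 2L) |>
      (\(d) { d$new_sizes <- list(c(1, 2)); d })()), "pool")
})

test_that("vital-rate sets serialize to YAML and back", {
  p <- generative_params(n_colonies = 800, n_years = 3)
  sim <- simulate_survey(p, seed = 71)
  fec <- simulate_fecundity(p, 200, seed = 72)
  vr <- suppressWarnings(fit_vital_rates(sim$survey, sim$recruits, fec))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_vital_rates(vr, path)
  back <- read_vital_rates(path)
  expect_s3_class(back, "vital_rates")
  expect_equal(back$survival$coefficients, vr$survival$coefficients,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$growth$sigma, vr$growth$sigma, tolerance = 1e-9)
  expect_equal(back$settlement$pooled, vr$settlement$pooled,
               tolerance = 1e-9)
  expect_equal(back$size_range, vr$size_range, tolerance = 1e-9,
               ignore_attr = TRUE)
  # the round-tripped set builds the same kernel
  k1 <- build_kernel(vr, m = 50)
  k2 <- build_kernel(back, m = 50)
  expect_equal(k1$K, k2$K, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("the site random intercept barely moves predictions on balanced
           synthetic data", {
  skip_if_not_installed("lme4")
  p <- generative_params(n_colonies = 800, n_years = 3)
  sim <- simulate_survey(p, seed = 81)
  sim$survey$site <- rep(c("s1", "s2", "s3", "s4"),
                         length.out = nrow(sim$survey))
  f_fixed <- fit_survival(sim$survey)
  f_rand <- fit_survival(sim$survey, random_intercept = TRUE)
  z <- seq(1, 8, length.out = 25)
  pf <- plogis(coraldemog:::poly_eval(f_fixed$coefficients, z))
  pr <- plogis(coraldemog:::poly_eval(f_rand$coefficients, z))
  expect_true(all(abs(pf - pr) / pmax(pf, 1e-6) < 0.10))
})
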