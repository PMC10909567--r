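test_that("PLS captures an exact single-latent structure in one
           component", {
  set.seed(21)
  t1 <- rnorm(40)
  X <- outer(t1, c(1, -2, 0.5))
  X <- X + matrix(rnorm(120, sd = 1e-8), 40)  # break exact collinearity
  Y <- outer(t1, c(0.7, 1.3, -0.4))
  fit <- pls_regression(X, Y, n_components = 1)
  expect_equal(fit$ry2[1], 1, tolerance = 1e-8)
})

test_that("single-response PLS agrees with the singular-vector solution", {
  set.seed(22)
  X <- matrix(rnorm(60), 20, 3)
  y <- matrix(rnorm(20), 20, 1)
  fit <- pls_regression(X, y, n_components = 1)
  Xs <- scale(X)
  ys <- scale(y)
  w_svd <- drop(crossprod(Xs, ys))
  w_svd <- w_svd / sqrt(sum(w_svd^2))
  # weights match up to sign
  w_fit <- fit$weights[, 1]
  expect_equal(abs(sum(w_fit * w_svd)), 1, tolerance = 1e-8)
})

test_that("PLS variance proportions are permutation invariant and scores
           orthogonal", {
  set.seed(23)
  X <- matrix(rnorm(36), 12, 3)
  Y <- X %*% matrix(rnorm(9), 3) + matrix(rnorm(36, sd = 0.3), 12)
  fit <- pls_regression(X, Y, n_components = 2)
  perm <- sample(12)
  fit_p <- pls_regression(X[perm, ], Y[perm, ], n_components = 2)
  expect_equal(fit$x_variance, fit_p$x_variance, tolerance = 1e-9)
  expect_equal(fit$ry2, fit_p$ry2, tolerance = 1e-9)
  expect_lt(abs(crossprod(fit$x_scores[, 1], fit$x_scores[, 2])), 1e-8)
  expect_true(all(fit$x_variance >= 0 & fit$x_variance <= 1))
  expect_lte(sum(fit$x_variance), 1 + 1e-10)
})

test_that("full-rank PLS reconstructs the predictor block", {
  set.seed(24)
  X <- matrix(rnorm(24), 8, 3)
  Y <- matrix(rnorm(16), 8, 2)
  fit <- pls_regression(X, Y, n_components = 3)
  Xhat <- fit$x_scores %*% t(fit$x_loadings)
  expect_equal(Xhat, unclass(scale(X)), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("a constant predictor column is rejected by name", {
  X <- cbind(a = rnorm(10), b = rep(1, 10), c = rnorm(10))
  Y <- matrix(rnorm(10), 10, 1)
  expect_error(pls_regression(X, Y), "b")
})

test_that("ranged major axis regression matches closed forms and inverts
           under axis swap", {
  x <- c(1, 2, 3, 4, 5, 7)
  y <- 2 * x
  fit <- ranged_major_axis(x, y)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)

  set.seed(25)
  xs <- rnorm(30)
  ys <- xs + rnorm(30, sd = 0.4)
  f1 <- ranged_major_axis(xs, ys)
  f2 <- ranged_major_axis(ys, xs)
  # on range-symmetric data the ranged MA slope inverts under swap
  rel <- abs(f2$slope - 1 / f1$slope) / abs(1 / f1$slope)
  expect_lt(rel, 0.15)
})

test_that("the RMA slope minimizes perpendicular distances on the ranged
           variables", {
  set.seed(26)
  for (i in 1:50) {
    n <- sample(10:60, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3))
    y <- runif(1, -2, 2) * x + rnorm(n, sd = runif(1, 0.2, 2))
    if (diff(range(x)) == 0 || diff(range(y)) == 0) next
    fit <- ranged_major_axis(x, y)
    if (is.na(fit$slope)) next
    xs <- (x - min(x)) / diff(range(x))
    ys <- (y - min(y)) / diff(range(y))
    # intercept profiled out (the optimal line passes through the
    # centroid); the search runs over the line's angle so near-vertical
    # fits stay well conditioned
    xc <- xs - mean(xs)
    yc <- ys - mean(ys)
    perp <- function(th) sum((yc * cos(th) - xc * sin(th))^2)
    grid <- seq(-pi / 2, pi / 2, length.out = 10001)
    i0 <- which.min(vapply(grid, perp, numeric(1)))
    o <- optimize(perp, grid[c(max(1, i0 - 1), min(10001, i0 + 1))],
                  tol = 1e-12)
    b_scaled <- fit$slope * diff(range(x)) / diff(range(y))
    d_angle <- abs(atan(b_scaled) - o$minimum)
    expect_lt(min(d_angle, pi - d_angle), 1e-6)
  }
})

test_that("degenerate RMA inputs are flagged or rejected", {
  expect_error(ranged_major_axis(rep(1, 5), 1:5), "zero range")
  out <- suppressWarnings(ranged_major_axis(c(1, 2, 3, 4),
                                            c(1, -1, 1, -1) * 1e-9 +
                                              c(2, 2, 2, 2.0001)))
  expect_true(is.list(out))
})

test_that("the factorial ANOVA detects a pure ecoregion effect and only
           that effect", {
  set.seed(27)
  d <- expand.grid(country = c("Australia", "Japan"),
                   ecoregion = c("tropical", "subtropical"),
                   strategy = c("competitive", "stress_tolerant", "weedy"),
                   repn = 1:30)
  d$value <- rnorm(nrow(d)) + ifelse(d$ecoregion == "tropical", 5, 0)
  res <- factorial_anova(d$value, d$country, d$ecoregion, d$strategy)
  tab <- res$anova
  p_eco <- tab$`Pr(>F)`[tab$term == "ecoregion"]
  expect_lt(p_eco, 0.001)
  inter <- grepl(":", tab$term)
  expect_true(all(tab$`Pr(>F)`[inter] > 0.01))
  # Tukey contrasts: tropical vs subtropical within each cell, all
  # detecting the shift
  expect_equal(nrow(res$tukey), 6)
  expect_true(all(res$tukey$p.value < 0.001))
})

test_that("a balanced two-level single factor reproduces F = t^2", {
  set.seed(28)
  g <- rep(c("Australia", "Japan"), each = 12)
  v <- rnorm(24) + (g == "Japan") * 0.8
  res <- factorial_anova(v, g, rep("tropical", 24), rep("weedy", 24))
  Fstat <- res$anova$`F value`[res$anova$term == "country"]
  tt <- t.test(v ~ g, var.equal = TRUE)$statistic
  expect_equal(Fstat, unname(tt^2), tolerance = 1e-10)
})

test_that("term and residual sums of squares add to the total in balanced
           designs", {
  set.seed(29)
  d <- expand.grid(country = c("A", "J"), ecoregion = c("t", "s"),
                   strategy = c("c", "w"), repn = 1:8)
  d$value <- rnorm(nrow(d), mean = as.integer(d$country == "A"))
  res <- factorial_anova(d$value, d$country, d$ecoregion, d$strategy)
  total_ss <- sum((d$value - mean(d$value))^2)
  expect_equal(sum(res$anova$`Sum Sq`), total_ss, tolerance = 1e-8)
})

test_that("cells with too few observations are named in the error", {
  expect_error(
    factorial_anova(1:8, rep(c("A", "J"), 4),
                    c(rep("t", 7), "s"), rep("w", 8)),
    "fewer than 2")
})

test_that("an all-constant response yields no significant terms", {
  d <- expand.grid(country = c("A", "J"), ecoregion = c("t", "s"),
                   strategy = c("c", "w"), repn = 1:3)
  res <- suppressWarnings(factorial_anova(rep(1, nrow(d)), d$country,
                                          d$ecoregion, d$strategy))
  p <- res$anova$`Pr(>F)`
  expect_true(all(is.na(p) | p > 0.05))
})
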