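#' Two-block partial least squares regression (NIPALS)
#'
#' PLS2-mode NIPALS with deflation of both blocks on standardized inputs,
#' linking a block of predictors (here typically the three thermal-regime
#' metrics) to a block of responses (the assemblage-level demographic
#' metrics). Per-component X-variance proportions are
#' `||t_h p_h'||_F^2 / ||X||_F^2` and `ry2` is the cumulative fraction of
#' `||Y||_F^2` captured by the fitted components.
#'
#' @param X n x p predictor matrix (columns are standardized internally;
#'   a constant column is an error naming the column).
#' @param Y n x q response matrix (standardized internally).
#' @param n_components Number of latent components (default 2).
#' @param tol NIPALS convergence tolerance (default 1e-10).
#' @param max_iter Maximum NIPALS iterations per component.
#' @return An object of class `pls_fit`: `x_scores`, `y_scores`,
#'   `x_loadings`, `y_loadings`, `weights`, `x_variance` (per component),
#'   `ry2` (cumulative Y-variance fraction per component),
#'   `condition_number` and `predictor_correlations` (the collinearity
#'   report for the predictor block).
#' @export
pls_regression <- function(X, Y, n_components = 2, tol = 1e-10,
                           max_iter = 500) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= n_components + 2)
  standardize <- function(M, label) {
    sds <- apply(M, 2, stats::sd)
    if (any(sds == 0)) {
      stop("constant ", label, " column(s): ",
           paste(colnames(M)[sds == 0], collapse = ", "))
    }
    scale(M)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  X0 <- standardize(X, "predictor")
  Y0 <- standardize(Y, "response")
  sv <- svd(X0, nu = 0, nv = 0)$d
  cond_num <- sv[1] / sv[length(sv)]
  Xc <- X0
  Yc <- Y0
  ssx <- sum(X0^2)
  ssy <- sum(Y0^2)
  p <- ncol(X0)
  q <- ncol(Y0)
  Tm <- matrix(0, nrow(X0), n_components)
  Um <- matrix(0, nrow(X0), n_components)
  Pm <- matrix(0, p, n_components)
  Cm <- matrix(0, q, n_components)
  Wm <- matrix(0, p, n_components)
  xvar <- numeric(n_components)
  ry2 <- numeric(n_components)
  for (h in seq_len(n_components)) {
    if (sum(Xc^2) < 1e-20 || sum(Yc^2) < 1e-20) {
      # predictor or response block fully deflated; remaining components
      # carry no variance
      if (h > 1) {
        xvar[h:n_components] <- 0
        ry2[h:n_components] <- ry2[h - 1]
      }
      break
    }
    u <- Yc[, which.max(apply(Yc, 2, stats::var))]
    t_old <- rep(0, nrow(Xc))
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xc, u))
      w <- w / sqrt(sum(w^2))
      t_h <- drop(Xc %*% w)
      c_h <- drop(crossprod(Yc, t_h)) / sum(t_h^2)
      u <- drop(Yc %*% c_h) / sum(c_h^2)
      if (sqrt(sum((t_h - t_old)^2)) < tol * sqrt(sum(t_h^2))) break
      t_old <- t_h
    }
    p_h <- drop(crossprod(Xc, t_h)) / sum(t_h^2)
    Xc <- Xc - tcrossprod(t_h, p_h)
    Yc <- Yc - tcrossprod(t_h, c_h)
    Tm[, h] <- t_h
    Um[, h] <- u
    Pm[, h] <- p_h
    Cm[, h] <- c_h
    Wm[, h] <- w
    xvar[h] <- sum(t_h^2) * sum(p_h^2) / ssx
    ry2[h] <- 1 - sum(Yc^2) / ssy
  }
  dimnames(Pm) <- list(colnames(X), paste0("comp", seq_len(n_components)))
  dimnames(Cm) <- list(colnames(Y), paste0("comp", seq_len(n_components)))
  structure(list(x_scores = Tm, y_scores = Um, x_loadings = Pm,
                 y_loadings = Cm, weights = Wm,
                 x_variance = xvar, ry2 = ry2,
                 condition_number = cond_num,
                 predictor_correlations = stats::cor(X0)),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  nc <- length(x$x_variance)
  cat("Two-block PLS fit (", nc, " components)\n", sep = "")
  cat("  X-variance explained per component:",
      paste(format(100 * x$x_variance, digits = 4), collapse = ", "),
      "%\n")
  cat("  cumulative X-variance:",
      format(100 * sum(x$x_variance), digits = 4), "%\n")
  cat("  cumulative Y-variance (ry2):",
      format(100 * x$ry2[nc], digits = 4), "%\n")
  cat("  predictor condition number:",
      format(x$condition_number, digits = 4), "\n")
  invisible(x)
}

#' Ranged major axis (Type 2) regression
#'
#' Errors-in-both-variables regression for two non-independent variables:
#' both variables are range-scaled to [0, 1], the major-axis slope is
#' computed on the scaled variables,
#' `b' = ((s2y - s2x) + sqrt((s2y - s2x)^2 + 4 sxy^2)) / (2 sxy)`,
#' and the slope is back-transformed by range(y)/range(x); the line passes
#' through the means. r-squared is the squared Pearson correlation.
#'
#' @param x,y Numeric vectors (n >= 3, both with positive range).
#' @return A list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
ranged_major_axis <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rx <- diff(range(x))
  ry <- diff(range(y))
  if (rx == 0 || ry == 0) stop("zero range in x or y")
  xs <- (x - min(x)) / rx
  ys <- (y - min(y)) / ry
  s2x <- stats::var(xs)
  s2y <- stats::var(ys)
  sxy <- stats::cov(xs, ys)
  if (abs(sxy) < .Machine$double.eps) {
    warning("zero covariance on the ranged variables; slope undefined")
    return(list(slope = NA_real_, intercept = NA_real_,
                r_squared = stats::cor(x, y)^2, n = length(x)))
  }
  b_scaled <- ((s2y - s2x) + sqrt((s2y - s2x)^2 + 4 * sxy^2)) / (2 * sxy)
  slope <- b_scaled * ry / rx
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       r_squared = stats::cor(x, y)^2, n = length(x))
}

#' Three-way factorial ANOVA with Tukey contrasts
#'
#' Full-factorial linear model `value ~ country * ecoregion * strategy`
#' with Type II sums of squares (the ensembles are mildly unbalanced after
#' the lambda filter) and Tukey honest-significant-difference contrasts of
#' tropical vs subtropical within each country-by-strategy cell.
#'
#' @param values Numeric response (e.g. replicate-level lambda or DSI).
#' @param country,ecoregion,strategy Factor vectors of the same length.
#' @return A list with `anova` (Type II table as a data frame),
#'   `tukey` (ecoregion contrasts within country x strategy cells), and
#'   `model` (the underlying `lm`).
#' @export
factorial_anova <- function(values, country, ecoregion, strategy) {
  dat <- data.frame(value = values,
                    country = factor(country),
                    ecoregion = factor(ecoregion),
                    strategy = factor(strategy))
  # single-level factors carry no contrasts and are dropped from the model
  active <- c("country", "ecoregion", "strategy")
  active <- active[vapply(dat[active], nlevels, integer(1)) >= 2]
  if (length(active) == 0) stop("no factor has 2 or more levels")
  cells <- do.call(table, dat[active])
  if (any(cells < 2)) {
    empty <- which(cells < 2, arr.ind = TRUE)
    if (!is.matrix(empty)) empty <- matrix(empty, ncol = 1)
    labs <- apply(empty, 1, function(i) {
      paste(mapply(function(dn, j) dn[j], dimnames(cells), i),
            collapse = ":")
    })
    stop("cells with fewer than 2 observations: ",
         paste(labs, collapse = ", "))
  }
  form <- stats::as.formula(paste("value ~", paste(active, collapse = " * ")))
  model <- stats::lm(form, data = dat)
  tab <- tryCatch(as.data.frame(car::Anova(model, type = 2)),
                  error = function(e) {
                    # zero residual variance (e.g. a constant response)
                    # leaves every F undefined; return a flagged table
                    trms <- attr(stats::terms(model), "term.labels")
                    data.frame(`Sum Sq` = rep(NA_real_, length(trms)),
                               Df = NA_real_, `F value` = NA_real_,
                               `Pr(>F)` = NA_real_,
                               row.names = trms, check.names = FALSE)
                  })
  tab$term <- rownames(tab)
  rownames(tab) <- NULL
  tukey <- NULL
  if ("ecoregion" %in% active) {
    others <- setdiff(active, "ecoregion")
    spec <- if (length(others) > 0) {
      stats::as.formula(paste("~ ecoregion |", paste(others, collapse = " * ")))
    } else {
      stats::as.formula("~ ecoregion")
    }
    tukey <- tryCatch({
      emm <- emmeans::emmeans(model, spec)
      as.data.frame(summary(emmeans::contrast(emm, "pairwise",
                                              adjust = "tukey")))
    }, error = function(e) NULL)
  }
  list(anova = tab, tukey = tukey, model = model)
}
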