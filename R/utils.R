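# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state so
#' that seeded package functions do not disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Polynomial design matrix in z up to the given degree (raw powers, intercept
# first). Degree 0 gives an intercept-only column.
poly_design <- function(z, degree) {
  stopifnot(degree >= 0)
  X <- matrix(1, nrow = length(z), ncol = degree + 1)
  if (degree >= 1) for (d in seq_len(degree)) X[, d + 1] <- z^d
  colnames(X) <- c("(Intercept)", if (degree >= 1) paste0("z^", seq_len(degree)))
  X
}

# Evaluate a polynomial with coefficient vector (intercept first) at z.
poly_eval <- function(coefs, z) {
  out <- rep(coefs[1], length(z))
  if (length(coefs) > 1) {
    for (d in seq_along(coefs[-1])) out <- out + coefs[d + 1] * z^d
  }
  out
}

# Weighted least squares via lm.fit wrapper returning coefficients, their
# covariance and residual sd. Used by the fitting fast paths.
ls_fit <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  p <- fit$rank
  n <- length(y)
  rss <- sum(fit$residuals^2)
  sigma2 <- if (n > p) rss / (n - p) else 0
  R <- qr.R(fit$qr)
  XtXinv <- chol2inv(R)
  vcov <- XtXinv * sigma2
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(coefficients = stats::setNames(fit$coefficients, colnames(X)),
       vcov = vcov, sigma = sqrt(sigma2), df.residual = n - p, n = n)
}

# GLM fast path (binomial or poisson, canonical links) returning coefficients
# and covariance. Falls back to a ridge-penalized fit on separation.
glm_fast <- function(X, y, family = c("binomial", "poisson")) {
  family <- match.arg(family)
  fam <- if (family == "binomial") stats::binomial() else stats::poisson()
  separated <- FALSE
  fit <- withCallingHandlers(
    suppressWarnings(stats::glm.fit(X, y, family = fam,
                                    control = list(maxit = 50))),
    error = function(e) stop(e)
  )
  eta <- drop(X %*% fit$coefficients)
  if (family == "binomial") {
    mu <- stats::plogis(eta)
    # fitted probabilities numerically 0/1 together with huge coefficients
    # indicate (quasi-)complete separation
    if (any(abs(fit$coefficients) > 15) &&
        all(abs(y - mu) < 1e-6)) separated <- TRUE
    if (!fit$converged) separated <- TRUE
  }
  if (separated) {
    warning("complete or quasi-complete separation detected; ",
            "using ridge-penalized logistic fit")
    fit_pen <- ridge_logistic(X, y, lambda = 1e-2)
    return(list(coefficients = fit_pen$coefficients, vcov = fit_pen$vcov,
                separation = TRUE, converged = TRUE, n = length(y)))
  }
  R <- qr.R(fit$qr)
  vcov <- tryCatch(chol2inv(R), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(coefficients = stats::setNames(fit$coefficients, colnames(X)),
       vcov = vcov, separation = FALSE, converged = fit$converged,
       n = length(y))
}

# L2-penalized logistic regression by direct optimization; used only as the
# separation fallback for survival/fragmentation fits.
ridge_logistic <- function(X, y, lambda = 1e-2) {
  nll <- function(beta) {
    eta <- drop(X %*% beta)
    -sum(y * eta - log1p(exp(eta))) + lambda * sum(beta^2) / 2
  }
  gr <- function(beta) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    -drop(crossprod(X, y - mu)) + lambda * beta
  }
  opt <- stats::optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
                      control = list(maxit = 500))
  eta <- drop(X %*% opt$par)
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  H <- crossprod(X * w, X) + diag(lambda, ncol(X))
  vcov <- solve(H)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(coefficients = stats::setNames(opt$par, colnames(X)), vcov = vcov)
}

# Collapse a numeric vector to the semicolon-delimited subfield used in the
# survey CSV dialect, and its inverse.
pack_sizes <- function(x) {
  vapply(x, function(v) {
    if (is.null(v) || length(v) == 0) return("")
    paste(format(v, digits = 10, trim = TRUE, scientific = FALSE),
          collapse = ";")
  }, character(1))
}

unpack_sizes <- function(s) {
  lapply(s, function(v) {
    if (is.na(v) || !nzchar(v)) return(numeric(0))
    as.numeric(strsplit(v, ";", fixed = TRUE)[[1]])
  })
}
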