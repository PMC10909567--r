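#' @title Size-dependent vital-rate models
#'
#' @description
#' The demographic kernel is assembled from seven fitted components, all with
#' natural-log colony surface area z = log(cm2) as the covariate:
#' survival (logistic), growth (polynomial Gaussian), fragmentation
#' probability (polynomial logistic), remnant count (zero-truncated Poisson,
#' log-linear), remnant size (polynomial Gaussian), fecundity (log-linear
#' polynomial), plus the scalar settlement probability and the recruit
#' log-size distribution. [fit_vital_rates()] runs all fits and returns a
#' `vital_rates` object consumed by [build_kernel()].
#'
#' @name vital-rates
NULL

#' Fit the size-dependent survival model
#'
#' Logistic regression of annual survival on log colony size:
#' logit P(survive) = a0 + a1 z (+ higher powers if `degree > 1`).
#' Complete separation is flagged and replaced by a ridge-penalized fit with
#' a warning.
#'
#' @param obs Colony-observation data frame.
#' @param degree Polynomial degree of the linear predictor (default 1).
#' @param random_intercept If TRUE and lme4 is installed, adds a site random
#'   intercept; fixed-effect coefficients are returned either way.
#' @return A list with `coefficients`, `vcov`, `separation`, `n`, `degree`.
#' @export
fit_survival <- function(obs, degree = 1, random_intercept = FALSE) {
  y <- as.numeric(obs$survived)
  if (length(unique(y)) < 2) {
    warning("all colonies share one survival outcome; ",
            "complete separation, using ridge-penalized fit")
    X <- poly_design(log(obs$size_t), degree)
    fit <- ridge_logistic(X, y)
    return(c(fit, list(separation = TRUE, n = length(y), degree = degree)))
  }
  z <- log(obs$size_t)
  if (random_intercept && requireNamespace("lme4", quietly = TRUE)) {
    dat <- data.frame(y = y, z = z, site = obs$site)
    form <- stats::as.formula(paste(
      "y ~", paste0("I(z^", seq_len(degree), ")", collapse = " + "),
      "+ (1 | site)"))
    m <- lme4::glmer(form, data = dat, family = stats::binomial())
    beta <- lme4::fixef(m)
    V <- as.matrix(stats::vcov(m))
    return(list(coefficients = beta, vcov = V, separation = FALSE,
                n = length(y), degree = degree, random_intercept = TRUE))
  }
  X <- poly_design(z, degree)
  fit <- glm_fast(X, y, "binomial")
  c(fit[c("coefficients", "vcov", "separation", "n")],
    list(degree = degree))
}

#' Fit the size-transition (growth/shrinkage) model
#'
#' Polynomial Gaussian regression of log size at t+1 on log size at t,
#' using only survivors that did not fragment:
#' E(z') = b0 + b1 z + b2 z^2 with either a constant residual sd (default)
#' or a log-linear sd model.
#'
#' @param obs Colony-observation data frame.
#' @param degree Polynomial degree of the mean (default 2).
#' @param sd_model `"constant"` or `"loglinear"` residual sd in z.
#' @param random_intercept If TRUE and lme4 is installed, adds a site random
#'   intercept to the mean model.
#' @return A list with `coefficients`, `vcov`, `sigma` (and `sd_coefficients`
#'   for the log-linear sd model), `n`, `degree`.
#' @export
fit_growth <- function(obs, degree = 2, sd_model = c("constant", "loglinear"),
                       random_intercept = FALSE) {
  sd_model <- match.arg(sd_model)
  keep <- obs$survived & !obs$fragmented & !is.na(obs$size_t1)
  if (sum(keep) < 10) stop("fewer than 10 usable growth transitions")
  z <- log(obs$size_t[keep])
  z1 <- log(obs$size_t1[keep])
  if (sum(keep) <= degree + 1) stop("fewer rows than growth coefficients")
  if (random_intercept && requireNamespace("lme4", quietly = TRUE)) {
    dat <- data.frame(z1 = z1, z = z, site = obs$site[keep])
    form <- stats::as.formula(paste(
      "z1 ~", paste0("I(z^", seq_len(degree), ")", collapse = " + "),
      "+ (1 | site)"))
    m <- lme4::lmer(form, data = dat)
    fit <- list(coefficients = lme4::fixef(m),
                vcov = as.matrix(stats::vcov(m)),
                sigma = stats::sigma(m), n = sum(keep))
  } else {
    X <- poly_design(z, degree)
    fit <- ls_fit(X, z1)
  }
  out <- list(coefficients = fit$coefficients, vcov = fit$vcov,
              sigma = fit$sigma, sd_model = sd_model,
              sd_coefficients = NULL, n = sum(keep), degree = degree)
  if (sd_model == "loglinear") {
    res <- z1 - poly_eval(fit$coefficients, z)
    # E[log chi^2_1] = -1.270363; corrects the log-squared-residual regression
    lf <- ls_fit(poly_design(z, 1), log(pmax(res^2, 1e-300)))
    g <- lf$coefficients
    g[1] <- g[1] + 1.270363
    out$sd_coefficients <- g / 2  # log-sd scale
  }
  out
}

#' Fit the fragmentation sub-models
#'
#' Three components: the polynomial-logistic fragmentation probability
#' kappa(z) among survivors; the zero-truncated Poisson remnant count
#' kappa_b(z) = 1 + exp(d0 + d1 z); and the Gaussian remnant log-size
#' distribution with polynomial mean in parent log-size, fitted by maximum
#' likelihood with upper truncation at the parent size. With no
#' fragmentation events, kappa is the zero function and the count/size
#' components are undefined (the kernel then reduces to its
#' survival-growth term). With fewer than five events the count and size
#' components fall back to empirical constants with a warning.
#'
#' @param obs Colony-observation data frame.
#' @param degree Polynomial degree of the fragmentation logit (default 2).
#' @param size_degree Polynomial degree of the remnant-size mean (default 1).
#' @return A list with components `probability`, `count`, `size`.
#' @export
fit_fragmentation <- function(obs, degree = 2, size_degree = 1) {
  surv <- obs[obs$survived, , drop = FALSE]
  n_events <- sum(surv$fragmented)
  if (n_events == 0) {
    warning("no fragmentation events observed; kappa(z) = 0 and the ",
            "kernel reduces to its survival-growth term")
    return(list(probability = list(zero = TRUE, degree = degree,
                                   coefficients = NULL, n = nrow(surv)),
                count = NULL, size = NULL))
  }
  z <- log(surv$size_t)
  prob_fit <- glm_fast(poly_design(z, degree), as.numeric(surv$fragmented),
                       "binomial")
  prob <- c(list(zero = FALSE, degree = degree),
            prob_fit[c("coefficients", "vcov", "separation", "n")])

  ev <- surv[surv$fragmented, , drop = FALSE]
  zp <- log(ev$size_t)
  counts <- lengths(ev$remnant_sizes)
  rem_z <- log(unlist(ev$remnant_sizes))
  rem_parent <- rep(zp, counts)
  if (n_events < 5) {
    warning("fewer than 5 fragmentation events; remnant count and size ",
            "models fall back to empirical constants")
    count <- list(empirical = TRUE, mean_count = mean(counts), n = n_events)
    size <- list(empirical = TRUE, mean = mean(rem_z),
                 sigma = max(stats::sd(rem_z), 0.05), n = length(rem_z))
    return(list(probability = prob, count = count, size = size))
  }
  extra <- counts - 1L
  if (all(extra == 0)) {
    # every event produced exactly one remnant; the Poisson excess is zero
    count <- list(empirical = TRUE, mean_count = 1, n = n_events)
  } else {
    cfit <- glm_fast(poly_design(zp, 1), extra, "poisson")
    # predictions outside the observed parent-size range are clamped to the
    # range endpoints: the exponential count model is an extrapolation
    # hazard at the upper domain edge
    count <- c(list(empirical = FALSE, z_range = range(zp)),
               cfit[c("coefficients", "vcov", "n")])
  }
  sfit <- fit_truncated_gaussian(rem_z, rem_parent, size_degree)
  size <- list(empirical = FALSE, coefficients = sfit$coefficients,
               vcov = sfit$vcov, sigma = max(sfit$sigma, 0.05),
               degree = size_degree, n = length(rem_z))
  list(probability = prob, count = count, size = size)
}

# Maximum-likelihood fit of a Gaussian with polynomial mean in the parent
# log-size, upper-truncated at the parent log-size: a remnant cannot exceed
# the colony it broke from, and ignoring the truncation biases the mean
# downward for small parents. Falls back to least squares if the optimizer
# fails.
fit_truncated_gaussian <- function(y, parent, degree) {
  X <- poly_design(parent, degree)
  start_fit <- ls_fit(X, y)
  start <- c(start_fit$coefficients, log(max(start_fit$sigma, 1e-3)))
  nll <- function(theta) {
    mu <- drop(X %*% theta[-length(theta)])
    sig <- exp(theta[length(theta)])
    z <- (y - mu) / sig
    trunc <- stats::pnorm((parent - mu) / sig)
    if (any(trunc <= 0)) return(1e10)
    -sum(stats::dnorm(z, log = TRUE) - log(sig) - log(trunc))
  }
  opt <- tryCatch(
    stats::optim(start, nll, method = "BFGS", hessian = TRUE,
                 control = list(maxit = 500)),
    error = function(e) NULL)
  if (is.null(opt) || opt$convergence != 0 || !all(is.finite(opt$par))) {
    return(start_fit)
  }
  p <- length(opt$par) - 1
  vcov <- tryCatch(solve(opt$hessian)[seq_len(p), seq_len(p), drop = FALSE],
                   error = function(e) start_fit$vcov)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(coefficients = stats::setNames(opt$par[seq_len(p)], colnames(X)),
       vcov = vcov, sigma = exp(opt$par[p + 1]), n = length(y))
}

#' Fit the colony-fecundity model
#'
#' Log-linear polynomial regression of larval output on log colony size:
#' log E(larvae) = f0 + f1 z + f2 z^2, fitted by least squares on the log
#' scale. Zero outputs are dropped with a warning; an all-zero table is a
#' degenerate-model error.
#'
#' @param fec Fecundity data frame (see [read_fecundity()]).
#' @param degree Polynomial degree (default 2).
#' @return A list with `coefficients`, `vcov`, `sigma`, `n`, `degree`.
#' @export
fit_fecundity <- function(fec, degree = 2) {
  if (nrow(fec) < 10) stop("fewer than 10 fecundity records")
  keep <- fec$larval_output > 0
  if (!any(keep)) stop("degenerate fecundity table: all larval outputs zero")
  if (any(!keep)) {
    warning(sum(!keep), " zero larval-output record(s) dropped before the ",
            "log-scale fit")
  }
  z <- log(fec$colony_size[keep])
  fit <- ls_fit(poly_design(z, degree), log(fec$larval_output[keep]))
  c(fit[c("coefficients", "vcov", "sigma", "n")], list(degree = degree))
}

#' Estimate the settlement probability
#'
#' For every recruit-survey year, divides the observed count of newly
#' established colonies by the total larval output predicted (from the
#' fitted fecundity model) for the colonies present in the preceding survey.
#' The ratio is interpreted as a per-larva establishment probability; the
#' pooled estimate is the mean of the yearly values, and the yearly
#' minimum/maximum are retained so resampling can vary settlement within
#' observed limits.
#'
#' @param recruits Recruit-survey data frame.
#' @param fecundity Fitted fecundity model from [fit_fecundity()].
#' @param obs Colony-observation data frame supplying the parent colonies.
#' @return A list with `pooled`, `by_year` (data frame year/recruits/larvae/
#'   phi), `min`, `max`.
#' @export
estimate_settlement <- function(recruits, fecundity, obs) {
  counts <- tapply(recruits$n_new, recruits$year, sum)
  years <- as.integer(names(counts))
  rows <- lapply(years, function(ys) {
    parents <- obs[obs$year_t == ys - 1L, , drop = FALSE]
    if (nrow(parents) == 0) return(NULL)
    larvae <- sum(exp(poly_eval(fecundity$coefficients,
                                log(parents$size_t))))
    n_new <- counts[[as.character(ys)]]
    if (larvae == 0 && n_new > 0) {
      stop("undefined settlement ratio: zero predicted larval output with ",
           n_new, " recruits in year ", ys)
    }
    data.frame(year = ys, recruits = n_new, larvae = larvae,
               phi = if (larvae > 0) n_new / larvae else 0)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0) {
    stop("no recruit-survey year matches a preceding colony survey")
  }
  if (length(years) > nrow(rows)) {
    warning(length(years) - nrow(rows), " recruit year(s) without a ",
            "preceding colony survey were skipped")
  }
  pooled <- mean(rows$phi)
  if (pooled == 0) warning("zero recruits observed; settlement = 0 and the ",
                           "reproduction kernel vanishes")
  if (pooled > 1) {
    warning("pooled settlement ratio exceeds 1; clamping to 1")
    pooled <- 1
  }
  list(pooled = pooled, by_year = rows,
       min = min(rows$phi), max = max(rows$phi))
}

#' Fit the recruit log-size distribution
#'
#' Gaussian on the natural-log scale, pooled across sites and years, with an
#' sd floor of 0.05 log units so the distribution stays discretizable.
#'
#' @param recruits Recruit-survey data frame.
#' @return A list with `mean`, `sd`, `n`.
#' @export
fit_recruit_sizes <- function(recruits) {
  sizes <- unlist(recruits$new_sizes)
  if (length(sizes) < 5) {
    stop("fewer than 5 recruit sizes; pool recruit surveys across sites ",
         "and years before fitting")
  }
  lz <- log(sizes)
  list(mean = mean(lz), sd = max(stats::sd(lz), 0.05), n = length(lz))
}

#' Fit the complete vital-rate set for one assemblage
#'
#' Runs every component fit and records the observed raw size range (colony
#' sizes at t and t+1, remnants, and recruit sizes) used later to set the
#' kernel's size domain.
#'
#' @param obs Colony-observation data frame for one assemblage.
#' @param recruits Recruit-survey data frame.
#' @param fec Fecundity data frame.
#' @param growth_degree,frag_degree,fec_degree Polynomial degrees.
#' @param sd_model Growth residual sd model (see [fit_growth()]).
#' @param random_intercept Optional site random intercept for survival and
#'   growth.
#' @return An object of class `vital_rates`.
#' @export
fit_vital_rates <- function(obs, recruits, fec,
                            growth_degree = 2, frag_degree = 2,
                            fec_degree = 2,
                            sd_model = "constant",
                            random_intercept = FALSE) {
  survival <- fit_survival(obs, degree = 1,
                           random_intercept = random_intercept)
  growth <- fit_growth(obs, degree = growth_degree, sd_model = sd_model,
                       random_intercept = random_intercept)
  frag <- fit_fragmentation(obs, degree = frag_degree)
  fecundity <- fit_fecundity(fec, degree = fec_degree)
  settlement <- estimate_settlement(recruits, fecundity, obs)
  recruit_size <- fit_recruit_sizes(recruits)
  sizes <- c(obs$size_t, obs$size_t1[!is.na(obs$size_t1)],
             unlist(obs$remnant_sizes), unlist(recruits$new_sizes))
  structure(list(survival = survival, growth = growth,
                 fragmentation = frag$probability,
                 remnant_count = frag$count, remnant_size = frag$size,
                 fecundity = fecundity, settlement = settlement,
                 recruit_size = recruit_size,
                 size_range = range(sizes)),
            class = "vital_rates")
}

#' Vital-rate set holding the generative truth
#'
#' Wraps a [generative_params()] object as a `vital_rates` object so the
#' projection kernel implied by the generator can be built with the same
#' machinery as a fitted kernel (e.g. to compare fitted and generative
#' asymptotic growth rates).
#'
#' @param params A `generative_params` object.
#' @param size_range Raw cm2 size range for the kernel domain; defaults to
#'   the central 99.9% of the initial size distribution.
#' @return An object of class `vital_rates`.
#' @export
vital_rates_from_params <- function(params, size_range = NULL) {
  stopifnot(inherits(params, "generative_params"))
  if (is.null(size_range)) {
    size_range <- exp(stats::qnorm(c(5e-4, 1 - 5e-4), params$init_size_mean,
                                   params$init_size_sd))
  }
  structure(list(
    survival = list(coefficients = params$survival, vcov = NULL,
                    separation = FALSE, degree = 1),
    growth = list(coefficients = params$growth, vcov = NULL,
                  sigma = params$growth_sd, sd_model = "constant",
                  sd_coefficients = NULL,
                  degree = length(params$growth) - 1),
    fragmentation = list(zero = FALSE, coefficients = params$fragmentation,
                         degree = length(params$fragmentation) - 1),
    remnant_count = list(empirical = FALSE,
                         coefficients = params$remnant_count),
    remnant_size = list(empirical = FALSE,
                        coefficients = params$remnant_size,
                        sigma = params$remnant_size_sd,
                        degree = length(params$remnant_size) - 1),
    fecundity = list(coefficients = params$fecundity, vcov = NULL,
                     sigma = params$fecundity_noise_sd,
                     degree = length(params$fecundity) - 1),
    settlement = list(pooled = params$settlement, by_year = NULL,
                      min = params$settlement, max = params$settlement),
    recruit_size = list(mean = params$recruit_size_mean,
                        sd = params$recruit_size_sd, n = NA_integer_),
    size_range = size_range), class = "vital_rates")
}

# Component evaluators used by the kernel builder -----------------------------

survival_prob <- function(rates, z) {
  pmin(pmax(stats::plogis(poly_eval(rates$survival$coefficients, z)), 0), 1)
}

fragmentation_prob <- function(rates, z) {
  fr <- rates$fragmentation
  if (is.null(fr) || isTRUE(fr$zero)) return(rep(0, length(z)))
  pmin(pmax(stats::plogis(poly_eval(fr$coefficients, z)), 0), 1)
}

remnant_count_mean <- function(rates, z) {
  rc <- rates$remnant_count
  if (is.null(rc)) return(rep(1, length(z)))
  if (isTRUE(rc$empirical)) return(rep(rc$mean_count, length(z)))
  if (!is.null(rc$z_range)) z <- pmin(pmax(z, rc$z_range[1]), rc$z_range[2])
  1 + exp(poly_eval(rc$coefficients, z))
}

growth_mean <- function(rates, z) poly_eval(rates$growth$coefficients, z)

growth_sd <- function(rates, z) {
  g <- rates$growth
  if (!is.null(g$sd_coefficients)) {
    exp(poly_eval(g$sd_coefficients, z))
  } else rep(g$sigma, length(z))
}

fecundity_mean <- function(rates, z) {
  exp(poly_eval(rates$fecundity$coefficients, z))
}

#' @export
print.vital_rates <- function(x, ...) {
  cat("Vital-rate set (log-size covariate, natural log, raw sizes in cm2)\n")
  cat("  survival     :", format(x$survival$coefficients, digits = 4), "\n")
  cat("  growth       :", format(x$growth$coefficients, digits = 4),
      " sd", format(x$growth$sigma, digits = 4), "\n")
  if (isTRUE(x$fragmentation$zero)) {
    cat("  fragmentation: none observed (kappa = 0)\n")
  } else {
    cat("  fragmentation:", format(x$fragmentation$coefficients, digits = 4),
        "\n")
  }
  cat("  fecundity    :", format(x$fecundity$coefficients, digits = 4), "\n")
  cat("  settlement   :", format(x$settlement$pooled, digits = 4),
      " (yearly range", format(x$settlement$min, digits = 4), "-",
      format(x$settlement$max, digits = 4), ")\n")
  cat("  recruit size : mean", format(x$recruit_size$mean, digits = 4),
      " sd", format(x$recruit_size$sd, digits = 4), "(log scale)\n")
  cat("  size range   :", format(x$size_range, digits = 4), "cm2\n")
  invisible(x)
}

#' Serialize a vital-rate set to a structured text file
#'
#' Writes the point coefficients, dispersions, settlement table and size
#' range as YAML for kernel building and audit. Coefficient covariances are
#' not serialized; refit to recover them.
#'
#' @param rates A `vital_rates` object.
#' @param path Output file path.
#' @return `path` invisibly.
#' @export
write_vital_rates <- function(rates, path) {
  strip <- function(comp) {
    if (is.null(comp)) return(NULL)
    comp$vcov <- NULL
    lapply(comp, function(v) if (is.data.frame(v)) as.list(v) else v)
  }
  out <- lapply(unclass(rates), function(comp) {
    if (is.list(comp)) strip(comp) else comp
  })
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_vital_rates
#' @export
read_vital_rates <- function(path) {
  raw <- yaml::read_yaml(path)
  restore <- function(comp) {
    if (is.list(comp) && !is.null(comp$coefficients)) {
      comp$coefficients <- unlist(comp$coefficients)
    }
    if (is.list(comp) && !is.null(comp$by_year)) {
      comp$by_year <- as.data.frame(lapply(comp$by_year, unlist))
    }
    comp
  }
  out <- lapply(raw, function(comp) {
    if (is.list(comp)) restore(comp) else comp
  })
  out$size_range <- unlist(out$size_range)
  structure(out, class = "vital_rates")
}
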