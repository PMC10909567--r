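#' Jackknife ensemble of IPM variants
#'
#' Quantifies uncertainty in every demographic metric by rebuilding the IPM
#' many times, each time from a random 95% subsample of colonies drawn
#' without replacement (whole colonies, keeping all transition rows of a
#' colony together so within-colony dependence is respected) and with the
#' settlement probability drawn uniformly between its observed yearly
#' minimum and maximum. Each replicate refits all vital rates, rebuilds the
#' kernel, and recomputes the requested metrics. Replicates whose fits fail
#' are dropped and counted.
#'
#' @param obs Colony-observation data frame for one assemblage.
#' @param recruits Recruit-survey data frame.
#' @param fec Fecundity data frame.
#' @param reps Number of replicates (default 1000).
#' @param fraction Colony subsampling fraction (default 0.95).
#' @param seed Integer seed; the ensemble is reproducible given all inputs.
#' @param mesh Kernel mesh size per replicate.
#' @param metrics `"all"` for the full transient bundle or `"lambda"` for a
#'   fast growth-rate-only ensemble.
#' @param vary_settlement Draw settlement uniformly between observed yearly
#'   limits (default TRUE; FALSE fixes it at the pooled estimate).
#' @param ... Further arguments passed to [fit_vital_rates()].
#' @return An object of class `jackknife_ensemble`: a data frame with one
#'   row per successful replicate (metrics on the raw scale plus the drawn
#'   settlement probability), with attributes `n_failed`, `reps`,
#'   `fraction`, `seed`.
#' @export
jackknife_ipm <- function(obs, recruits, fec, reps = 1000, fraction = 0.95,
                          seed = 1, mesh = 200,
                          metrics = c("all", "lambda"),
                          vary_settlement = TRUE, ...) {
  metrics <- match.arg(metrics)
  ids <- unique(obs$colony_id)
  n_draw <- max(1L, round(fraction * length(ids)))
  rows_by_id <- split(seq_len(nrow(obs)), obs$colony_id)
  out <- vector("list", reps)
  n_failed <- 0L
  with_seed(seed, {
    for (r in seq_len(reps)) {
      take <- if (fraction >= 1) ids else sample(ids, n_draw)
      sub <- obs[unlist(rows_by_id[take], use.names = FALSE), , drop = FALSE]
      res <- tryCatch({
        vr <- suppressWarnings(fit_vital_rates(sub, recruits, fec, ...))
        phi_draw <- if (vary_settlement && vr$settlement$max >
                        vr$settlement$min) {
          stats::runif(1, vr$settlement$min, vr$settlement$max)
        } else {
          vr$settlement$pooled
        }
        k <- build_kernel(vr, m = mesh, phi = phi_draw,
                          check_growth_rate = metrics != "lambda")
        if (metrics == "lambda") {
          lam <- max(Mod(eigen(k$K, only.values = TRUE)$values))
          data.frame(rep = r, phi = phi_draw, lambda = lam)
        } else {
          dm <- suppressWarnings(demographic_metrics(k))
          data.frame(rep = r, phi = phi_draw, lambda = dm$lambda,
                     damping_ratio = dm$damping_ratio, R0 = dm$R0,
                     generation_time = dm$generation_time,
                     max_amplification = dm$max_amplification,
                     kreiss_upper = dm$kreiss_upper,
                     kreiss_lower = dm$kreiss_lower,
                     transient_envelope = dm$transient_envelope)
        }
      }, error = function(e) NULL)
      if (is.null(res)) n_failed <- n_failed + 1L else out[[r]] <- res
    }
  })
  ens <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (n_failed > 0) {
    warning(n_failed, " of ", reps, " jackknife replicate(s) failed and ",
            "were dropped")
  }
  structure(ens, class = c("jackknife_ensemble", "data.frame"),
            n_failed = n_failed, reps = reps, fraction = fraction,
            seed = seed)
}

#' Filter an ensemble and apply the normality transforms
#'
#' Drops replicates with lambda > 2 (implausible doubling-plus populations)
#' and adds the transformed columns used by downstream comparisons:
#' `log_generation_time`, `damping_ratio_t` (rho^-2.0), `transient_envelope_t`
#' (TE^-0.1), and the demographic stability index `dsi`
#' (max amplification^-0.5). The TE and amplification transforms are
#' order-reversing: larger raw values map to smaller transformed values, so
#' low DSI means high capacity for demographic amplification. Replicates
#' with TE = 0, where the power transform is undefined, are excluded and
#' counted.
#'
#' @param ensemble A `jackknife_ensemble` with the full metric set.
#' @param lambda_cap Exclusion threshold on lambda (default 2).
#' @return The filtered ensemble with transformed columns; attributes
#'   `n_lambda_excluded` and `n_te_excluded` count the dropped replicates.
#' @export
filter_and_transform <- function(ensemble, lambda_cap = 2) {
  stopifnot(nrow(ensemble) > 0)
  keep <- ensemble$lambda <= lambda_cap
  n_lambda <- sum(!keep)
  out <- ensemble[keep, , drop = FALSE]
  n_te <- 0L
  if (!is.null(out$transient_envelope)) {
    te_bad <- !is.na(out$transient_envelope) & out$transient_envelope <= 0
    n_te <- sum(te_bad)
    if (n_te > 0) out <- out[!te_bad, , drop = FALSE]
    out$transient_envelope_t <- out$transient_envelope^-0.1
  }
  if (!is.null(out$generation_time)) {
    out$log_generation_time <- log(out$generation_time)
  }
  if (!is.null(out$damping_ratio)) {
    out$damping_ratio_t <- out$damping_ratio^-2.0
  }
  if (!is.null(out$max_amplification)) {
    out$dsi <- out$max_amplification^-0.5
  }
  structure(out, class = c("jackknife_ensemble", "data.frame"),
            n_failed = attr(ensemble, "n_failed"),
            reps = attr(ensemble, "reps"),
            fraction = attr(ensemble, "fraction"),
            seed = attr(ensemble, "seed"),
            n_lambda_excluded = n_lambda, n_te_excluded = n_te)
}

#' Summarize an ensemble: means and 95% percentile intervals
#'
#' Percentile (2.5%, 97.5%) intervals per metric column; percentile
#' intervals commute with the monotone normality transforms, which is why
#' they are the interval type of choice here. Fewer than 30 retained
#' replicates triggers an instability warning.
#'
#' @param ensemble A `jackknife_ensemble` (filtered or not).
#' @return A data frame with one row per metric: mean, lower, upper, n.
#' @export
summarize_ensemble <- function(ensemble) {
  stopifnot(nrow(ensemble) > 0)
  if (nrow(ensemble) < 30) {
    warning("fewer than 30 retained replicates; intervals are unstable")
  }
  cols <- setdiff(names(ensemble), "rep")
  cols <- cols[vapply(ensemble[cols], is.numeric, logical(1))]
  out <- do.call(rbind, lapply(cols, function(cn) {
    v <- ensemble[[cn]]
    v <- v[is.finite(v)]
    if (length(v) == 0) {
      return(data.frame(metric = cn, mean = NA_real_, lower = NA_real_,
                        upper = NA_real_, n = 0L))
    }
    q <- stats::quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
    data.frame(metric = cn, mean = mean(v), lower = q[1], upper = q[2],
               n = length(v))
  }))
  rownames(out) <- NULL
  out
}
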