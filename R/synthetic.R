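#' Generative parameter set for synthetic colony surveys
#'
#' Bundles the coefficients of the generative demographic model used by
#' [simulate_survey()] and [simulate_fecundity()]. All size covariates are
#' natural-log surface areas (z = log cm2):
#'
#' * survival: P(survive) = logit^-1(a0 + a1 z)
#' * growth (survivors that do not fragment): z' ~ N(b0 + b1 z + b2 z^2, sd_growth)
#' * fragmentation (conditional on survival by default):
#'   P(fragment) = logit^-1(c0 + c1 z + c2 z^2)
#' * remnant count: 1 + Poisson(exp(d0 + d1 z)) (zero-truncated: an observed
#'   fragmentation event with no remnants would simply be a death)
#' * remnant log-size: N(e0 + e1 z, sd_remnant), truncated above at the parent
#'   log-size (a remnant cannot exceed its parent)
#' * fecundity: larvae = exp(f0 + f1 z + f2 z^2) x lognormal noise
#' * recruitment: yearly recruit count ~ Poisson(settlement x total expected
#'   larval output that year); recruit log-sizes ~ N(recruit_size_mean,
#'   recruit_size_sd)
#'
#' @param survival Numeric `c(a0, a1)`, logit scale.
#' @param growth Numeric `c(b0, b1, b2)`, log-size scale.
#' @param growth_sd Residual sd of growth on the log scale (> 0).
#' @param fragmentation Numeric `c(c0, c1, c2)`, logit scale.
#' @param remnant_count Numeric `c(d0, d1)`, log scale for the Poisson excess.
#' @param remnant_size Numeric `c(e0, e1)`, log-size scale.
#' @param remnant_size_sd Residual sd of remnant log-size (> 0).
#' @param fecundity Numeric `c(f0, f1, f2)`, log scale.
#' @param fecundity_noise_sd Lognormal noise sd for larval outputs.
#' @param settlement True per-larva establishment probability in (0, 1].
#' @param recruit_size_mean,recruit_size_sd Recruit log-size distribution.
#' @param init_size_mean,init_size_sd Initial colony log-size distribution.
#' @param n_colonies Number of tagged colonies (>= 1).
#' @param n_years Number of annual surveys (>= 2, i.e. >= 1 transition).
#' @param fragmentation_requires_survival If TRUE (default) fragmentation is
#'   drawn only among survivors, mirroring the survival-conditional reading of
#'   the projection kernel; FALSE draws it among all colonies.
#' @param region,site,strategy Labels copied onto generated records.
#' @return An object of class `generative_params`.
#' @seealso [assemblage_presets()] for the bundled study-design presets.
#' @export
generative_params <- function(survival = c(-1.0, 0.45),
                              growth = c(0.6, 0.9, 0), growth_sd = 0.5,
                              fragmentation = c(-4, 0.3, 0),
                              remnant_count = c(-1, 0.15),
                              remnant_size = c(0.5, 0.6),
                              remnant_size_sd = 0.6,
                              fecundity = c(-2, 1.2, 0),
                              fecundity_noise_sd = 0.3,
                              settlement = 0.01,
                              recruit_size_mean = 1.5, recruit_size_sd = 0.4,
                              init_size_mean = 4.0, init_size_sd = 1.5,
                              n_colonies = 1000, n_years = 4,
                              fragmentation_requires_survival = TRUE,
                              region = "R1", site = "S1",
                              strategy = "competitive") {
  p <- list(survival = survival, growth = growth, growth_sd = growth_sd,
            fragmentation = fragmentation, remnant_count = remnant_count,
            remnant_size = remnant_size, remnant_size_sd = remnant_size_sd,
            fecundity = fecundity, fecundity_noise_sd = fecundity_noise_sd,
            settlement = settlement,
            recruit_size_mean = recruit_size_mean,
            recruit_size_sd = recruit_size_sd,
            init_size_mean = init_size_mean, init_size_sd = init_size_sd,
            n_colonies = as.integer(n_colonies),
            n_years = as.integer(n_years),
            fragmentation_requires_survival = fragmentation_requires_survival,
            region = region, site = site, strategy = strategy)
  stopifnot(p$growth_sd > 0, p$remnant_size_sd > 0, p$recruit_size_sd > 0,
            p$init_size_sd > 0, p$settlement > 0, p$settlement <= 1,
            p$n_colonies >= 1, p$n_years >= 2,
            length(survival) == 2, length(growth) == 3,
            length(fragmentation) == 3, length(remnant_count) == 2,
            length(remnant_size) == 2, length(fecundity) == 3)
  structure(p, class = "generative_params")
}

#' Simulate a tagged-colony survey and its recruit counts
#'
#' Generates annual transition records for a cohort of tagged colonies under
#' the generative model of [generative_params()], together with the matching
#' yearly recruit surveys. Colonies that fragment continue as their largest
#' remnant in the following year; recruits are counted but not added to the
#' tagged cohort.
#'
#' @param params A `generative_params` object.
#' @param seed Integer seed; the output is reproducible given (params, seed).
#' @param start_year First survey calendar year.
#' @return A list with elements `survey` (colony-observation data frame) and
#'   `recruits` (recruit-survey data frame).
#' @export
simulate_survey <- function(params, seed = 1, start_year = 2016) {
  stopifnot(inherits(params, "generative_params"))
  p <- params
  with_seed(seed, {
    z0 <- stats::rnorm(p$n_colonies, p$init_size_mean, p$init_size_sd)
    mean_surv <- mean(stats::plogis(poly_eval(p$survival, z0)))
    if (mean_surv < 0.01) {
      stop("degenerate parameter set: mean survival over the initial size ",
           "distribution is ", format(mean_surv, digits = 3),
           " (< 0.01); no usable dataset can be generated")
    }
    ids <- sprintf("C%05d", seq_len(p$n_colonies))
    alive <- rep(TRUE, p$n_colonies)
    z <- z0
    rows <- vector("list", p$n_years - 1)
    recr <- vector("list", p$n_years - 1)
    for (t in seq_len(p$n_years - 1)) {
      idx <- which(alive)
      n <- length(idx)
      zt <- z[idx]
      surv <- stats::runif(n) < stats::plogis(poly_eval(p$survival, zt))
      frag_p <- stats::plogis(poly_eval(p$fragmentation, zt))
      frag <- stats::runif(n) < frag_p
      if (p$fragmentation_requires_survival) frag <- frag & surv
      grow <- surv & !frag
      z1 <- rep(NA_real_, n)
      z1[grow] <- stats::rnorm(sum(grow),
                               poly_eval(p$growth, zt[grow]), p$growth_sd)
      remn <- vector("list", n)
      if (any(frag)) {
        for (j in which(frag)) {
          k <- 1L + stats::rpois(1, exp(poly_eval(p$remnant_count, zt[j])))
          mu <- poly_eval(p$remnant_size, zt[j])
          # rejection sampling of the upper truncation at the parent log-size
          draws <- numeric(0)
          while (length(draws) < k) {
            cand <- stats::rnorm(2 * k, mu, p$remnant_size_sd)
            draws <- c(draws, cand[cand < zt[j]])
          }
          remn[[j]] <- exp(draws[seq_len(k)])
        }
      }
      rows[[t]] <- data.frame(
        colony_id = ids[idx], region = p$region, site = p$site,
        taxon = p$strategy, strategy = p$strategy,
        year_t = start_year + t - 1L,
        size_t = exp(zt), survived = surv,
        size_t1 = ifelse(is.na(z1), NA_real_, exp(z1)),
        fragmented = frag, stringsAsFactors = FALSE)
      rows[[t]]$remnant_sizes <- lapply(remn, function(v) {
        if (is.null(v)) numeric(0) else v
      })
      # recruitment driven by the total expected larval output at time t
      larvae <- sum(exp(poly_eval(p$fecundity, zt)))
      n_new <- stats::rpois(1, p$settlement * larvae)
      new_sizes <- exp(stats::rnorm(n_new, p$recruit_size_mean,
                                    p$recruit_size_sd))
      recr[[t]] <- data.frame(region = p$region, site = p$site,
                              year = start_year + t,
                              n_new = n_new, stringsAsFactors = FALSE)
      recr[[t]]$new_sizes <- list(new_sizes)
      # advance the cohort: growers take z', fragmenters continue as their
      # largest remnant, non-survivors leave
      znew <- z
      znew[idx[grow]] <- z1[grow]
      if (any(frag)) {
        znew[idx[frag]] <- vapply(remn[which(frag)],
                                  function(v) log(max(v)), numeric(1))
      }
      alive[idx[!surv]] <- FALSE
      z <- znew
    }
    survey <- do.call(rbind, rows)
    rownames(survey) <- NULL
    recruits <- do.call(rbind, recr)
    rownames(recruits) <- NULL
    list(survey = survey, recruits = recruits)
  })
}

#' Simulate a colony-size vs larval-output table
#'
#' Draws colony log-sizes from the initial size distribution and larval
#' outputs as `exp(f0 + f1 z + f2 z^2)` times lognormal noise, mirroring the
#' trait-table structure used to parameterize colony fecundity.
#'
#' @param params A `generative_params` object.
#' @param n_records Number of records (>= 10).
#' @param seed Integer seed.
#' @return A fecundity data frame (see [read_fecundity()]).
#' @export
simulate_fecundity <- function(params, n_records = 200, seed = 1) {
  stopifnot(inherits(params, "generative_params"), n_records >= 10)
  with_seed(seed, {
    z <- stats::rnorm(n_records, params$init_size_mean, params$init_size_sd)
    noise <- if (params$fecundity_noise_sd > 0) {
      stats::rnorm(n_records, 0, params$fecundity_noise_sd)
    } else rep(0, n_records)
    data.frame(strategy = params$strategy, colony_size = exp(z),
               larval_output = exp(poly_eval(params$fecundity, z) + noise),
               stringsAsFactors = FALSE)
  })
}

#' Parameters for synthetic sea surface temperature series
#'
#' @param beta Target spectral exponent (slope of log spectral density on log
#'   frequency; typically <= 0, with more negative values giving "redder",
#'   slower-fluctuating series). A positive value triggers a warning (a blue
#'   spectrum is unusual for SST) but is honoured.
#' @param mean Target series mean, degrees C.
#' @param sd Target series sd, degrees C (> 0).
#' @param annual_amplitude Optional amplitude of an added annual sinusoid,
#'   degrees C (applied before the final mean/sd rescaling).
#' @param n_months Series length (>= 24); 840 months matches a 69-year
#'   monthly record.
#' @param start_year First calendar year of the series.
#' @return An object of class `sst_params`.
#' @export
sst_params <- function(beta = -1, mean = 25, sd = 1.5,
                       annual_amplitude = 0, n_months = 840,
                       start_year = 1950) {
  stopifnot(n_months >= 24, sd > 0)
  if (beta > 0) warning("positive (blue) spectral exponent requested; ",
                        "unusual for SST but proceeding")
  structure(list(beta = beta, mean = mean, sd = sd,
                 annual_amplitude = annual_amplitude,
                 n_months = as.integer(n_months),
                 start_year = as.integer(start_year)),
            class = "sst_params")
}

#' Simulate a monthly SST series with a target spectral exponent
#'
#' Spectral synthesis: Fourier amplitudes proportional to f^(beta/2) with
#' uniform random phases are inverse-transformed to a real series, an
#' optional annual sinusoid is added, and the result is rescaled to the
#' target mean and sd (the mean is matched exactly).
#'
#' @param params An `sst_params` object.
#' @param seed Integer seed.
#' @return A data frame with columns `year`, `month`, `sst` carrying the
#'   location label `""` as attribute `location`.
#' @export
simulate_sst <- function(params, seed = 1) {
  stopifnot(inherits(params, "sst_params"))
  n <- params$n_months
  with_seed(seed, {
    half <- floor((n - 1) / 2)
    freq <- (1:half) / n
    amp <- freq^(params$beta / 2)
    phase <- stats::runif(half, 0, 2 * pi)
    spec <- complex(real = rep(0, n))
    spec[2:(half + 1)] <- amp * exp(1i * phase)
    spec[n:(n - half + 1)] <- Conj(spec[2:(half + 1)])
    if (n %% 2 == 0) {
      # real Nyquist component with random sign
      spec[n / 2 + 1] <- (n / 2 / n)^(params$beta / 2) *
        sign(stats::runif(1) - 0.5)
    }
    x <- Re(stats::fft(spec, inverse = TRUE)) / n
    if (params$annual_amplitude != 0) {
      x <- x + params$annual_amplitude * sin(2 * pi * seq_len(n) / 12)
    }
    x <- (x - mean(x)) / stats::sd(x) * params$sd + params$mean
    month0 <- seq_len(n) - 1L
    out <- data.frame(year = params$start_year + month0 %/% 12L,
                      month = month0 %% 12L + 1L, sst = x)
    attr(out, "location") <- ""
    out
  })
}

#' Bundled study-design presets: four regions by three strategies
#'
#' Returns the twelve generative parameter sets mimicking the sampling design
#' of paired tropical/subtropical coral assemblages in two countries:
#' regions AS and AT (Australian subtropics/tropics) and JS and JT (Japanese
#' subtropics/tropics), each crossed with competitive (fast-growing),
#' stress-tolerant (slow, high-survival), and weedy (fast-turnover,
#' fragmentation-prone) life histories. Tropical variants carry higher
#' survival and settlement than their subtropical counterparts, so the
#' presets span declining to near-stationary populations.
#'
#' @param n_colonies,n_years Cohort dimensions applied to every preset.
#' @return A named list of `generative_params`, names like `"AT.competitive"`.
#' @export
assemblage_presets <- function(n_colonies = 1000, n_years = 4) {
  strat <- list(
    competitive = list(survival = c(-1.6, 0.50), growth = c(0.9, 0.88, 0),
                       growth_sd = 0.55, fragmentation = c(-3.2, 0.25, 0),
                       fecundity = c(-1.5, 1.05, 0), settlement = 0.02,
                       init_size_mean = 4.2),
    stress_tolerant = list(survival = c(0.2, 0.45), growth = c(0.45, 0.93, 0),
                           growth_sd = 0.35, fragmentation = c(-4.5, 0.2, 0),
                           fecundity = c(-2.5, 1.0, 0), settlement = 0.012,
                           init_size_mean = 4.5),
    weedy = list(survival = c(-1.9, 0.42), growth = c(1.0, 0.82, 0),
                 growth_sd = 0.6, fragmentation = c(-2.6, 0.3, 0),
                 fecundity = c(-0.8, 1.0, 0), settlement = 0.03,
                 init_size_mean = 3.6)
  )
  # tropical assemblages enjoy a survival and settlement advantage
  region_shift <- list(AS = c(surv = -0.25, settle = 0.8),
                       AT = c(surv = 0.35, settle = 1.3),
                       JS = c(surv = -0.45, settle = 0.7),
                       JT = c(surv = 0.25, settle = 1.2))
  out <- list()
  for (rg in names(region_shift)) {
    for (st in names(strat)) {
      base <- strat[[st]]
      sh <- region_shift[[rg]]
      args <- c(base, list(n_colonies = n_colonies, n_years = n_years,
                           region = rg, strategy = st,
                           site = paste0(rg, "-plot")))
      args$survival[1] <- args$survival[1] + sh[["surv"]]
      args$settlement <- min(1, args$settlement * sh[["settle"]])
      out[[paste(rg, st, sep = ".")]] <- do.call(generative_params, args)
    }
  }
  out
}

#' Bundled SST presets for the four study regions
#'
#' Tropical cells are warmer, less variable, and less reddened than the
#' subtropical cells, reproducing the thermal gradient the study design
#' spans.
#'
#' @param n_months Series length in months.
#' @return A named list of `sst_params` (names AS, AT, JS, JT).
#' @export
region_sst_presets <- function(n_months = 840) {
  list(AS = sst_params(beta = -1.3, mean = 21.5, sd = 2.6,
                       n_months = n_months),
       AT = sst_params(beta = -0.8, mean = 25.5, sd = 2.0,
                       n_months = n_months),
       JS = sst_params(beta = -1.5, mean = 20.5, sd = 3.6,
                       n_months = n_months),
       JT = sst_params(beta = -1.0, mean = 24.5, sd = 2.4,
                       n_months = n_months))
}

#' Write a simulated SST series to the two-column CSV dialect
#'
#' @param sst SST data frame from [simulate_sst()] or [read_sst()].
#' @param path Output CSV path (`year_month, sst`).
#' @return `path` invisibly.
#' @export
write_sst <- function(sst, path) {
  out <- data.frame(year_month = sprintf("%04d-%02d", sst$year, sst$month),
                    sst = sst$sst)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
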