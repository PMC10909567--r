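#' Read a monthly SST series
#'
#' Two-column CSV dialect: `year_month` (YYYY-MM) and `sst` (degrees C).
#' Timestamps must be strictly increasing and gap-free.
#'
#' @param path CSV path.
#' @param location Optional location label attached as an attribute.
#' @return A data frame with columns `year`, `month`, `sst`.
#' @export
read_sst <- function(path, location = "") {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("year_month", "sst"), names(raw))
  if (length(missing_cols) > 0) {
    stop("SST file missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  parts <- strsplit(raw$year_month, "-", fixed = TRUE)
  year <- as.integer(vapply(parts, `[`, character(1), 1))
  month <- as.integer(vapply(parts, `[`, character(1), 2))
  idx <- year * 12L + month
  if (any(diff(idx) != 1L)) {
    stop("SST timestamps must be strictly increasing monthly values ",
         "without gaps")
  }
  out <- data.frame(year = year, month = month, sst = as.numeric(raw$sst))
  attr(out, "location") <- location
  out
}

#' Thermal-regime summary: mean and coefficient of variation
#'
#' Mean and sd/mean of the raw monthly series. A non-positive mean makes
#' the coefficient of variation scale-dependent and is flagged with a
#' warning.
#'
#' @param sst SST data frame (>= 24 months) or numeric vector.
#' @return Named numeric `c(mean, cv)`.
#' @export
sst_summary <- function(sst) {
  x <- if (is.data.frame(sst)) sst$sst else as.numeric(sst)
  stopifnot(length(x) >= 24)
  m <- mean(x)
  if (m <= 0) warning("series mean is <= 0 degrees C; the coefficient of ",
                      "variation is scale-dependent and unreliable")
  c(mean = m, cv = stats::sd(x) / m)
}

#' Spectral exponent of a monthly series
#'
#' Removes the series mean, computes the raw periodogram by discrete
#' Fourier transform at frequencies k/n for k = 1..floor(n/2), and returns
#' the ordinary-least-squares slope of log10 spectral density on log10
#' frequency. More negative exponents indicate variance dominated by slow
#' ("reddened") fluctuations. No tapering, smoothing, or deseasonalization
#' is applied by default; `deseasonalize = TRUE` removes monthly means
#' first for sensitivity checks.
#'
#' @param sst SST data frame (>= 64 months) or numeric vector.
#' @param deseasonalize Remove the mean annual cycle before the transform.
#' @return A list with `beta` (the slope), `r_squared`, `n_freq`,
#'   `low_r_squared` flag (fit dominated by few ordinates when
#'   r-squared < 0.05), and `n_dropped` zero ordinates excluded.
#' @export
spectral_exponent <- function(sst, deseasonalize = FALSE) {
  x <- if (is.data.frame(sst)) sst$sst else as.numeric(sst)
  n <- length(x)
  stopifnot(n >= 64)
  if (deseasonalize) {
    month <- if (is.data.frame(sst)) sst$month else ((seq_len(n) - 1) %% 12) + 1
    x <- x - stats::ave(x, month)
  }
  x <- x - mean(x)
  I_k <- Mod(stats::fft(x))^2 / n
  k <- seq_len(floor(n / 2))
  dens <- I_k[k + 1]
  freq <- k / n
  keep <- dens > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    warning(n_dropped, " zero periodogram ordinate(s) dropped from the ",
            "spectral regression")
  }
  lf <- log10(freq[keep])
  ld <- log10(dens[keep])
  fit <- stats::lm.fit(cbind(1, lf), ld)
  beta <- fit$coefficients[2]
  r2 <- 1 - sum(fit$residuals^2) / sum((ld - mean(ld))^2)
  list(beta = unname(beta), r_squared = r2, n_freq = sum(keep),
       low_r_squared = r2 < 0.05, n_dropped = n_dropped)
}
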