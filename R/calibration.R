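#' Clumped-isotope temperature calibration
#'
#' The community D47--temperature calibration has the form
#' \deqn{\Delta_{47} = a / T^2 + b}
#' with \eqn{T} in kelvin, so temperature follows by inversion:
#' \deqn{T = \sqrt{a / (\Delta_{47} - b)}.}
#' The defaults (a = 0.0391e6 permil K^2, b = 0.154 permil) are the unified
#' I-CDES carbonate calibration, under which bioapatite is statistically
#' indistinguishable from inorganic calcite. Both constants can be
#' overridden to swap in alternative calibrations.
#'
#' @param slope slope `a` in permil K^2; must be positive.
#' @param intercept intercept `b` in permil.
#' @return an object of class `"d47_calibration"`.
#' @export
#' @examples
#' cal <- d47_calibration()
#' delta47_to_temperature(0.582, cal)
d47_calibration <- function(slope = 0.0391e6, intercept = 0.154) {
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope),
            is.numeric(intercept), length(intercept) == 1L, is.finite(intercept))
  if (slope <= 0) stop("calibration slope must be positive")
  structure(list(slope = slope, intercept = intercept),
            class = "d47_calibration")
}

#' @export
print.d47_calibration <- function(x, ...) {
  cat(sprintf("D47 calibration: D47 = %.4g/T^2 + %.4g (T in K)\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Convert D47 to mineral formation temperature
#'
#' Inverts the quadratic-in-1/T calibration. Values of D47 at or below the
#' calibration intercept are non-physical (they would imply infinite or
#' imaginary temperature) and raise an error.
#'
#' @param d47 numeric vector of D47 values (permil, I-CDES).
#' @param cal a [d47_calibration()].
#' @return temperature(s) in degrees Celsius.
#' @export
delta47_to_temperature <- function(d47, cal = d47_calibration()) {
  stopifnot(inherits(cal, "d47_calibration"), is.numeric(d47))
  if (any(!is.finite(d47))) stop("non-finite D47 value")
  if (any(d47 <= cal$intercept)) {
    stop(sprintf(
      "D47 value(s) <= calibration intercept (%.4g permil): non-physical measurement",
      cal$intercept))
  }
  sqrt(cal$slope / (d47 - cal$intercept)) - 273.15
}

#' Forward-evaluate the calibration: temperature to D47
#'
#' @param t_celsius temperature(s) in degrees Celsius.
#' @inheritParams delta47_to_temperature
#' @return D47 value(s) in permil.
#' @export
temperature_to_delta47 <- function(t_celsius, cal = d47_calibration()) {
  stopifnot(inherits(cal, "d47_calibration"), is.numeric(t_celsius))
  t_k <- t_celsius + 273.15
  if (any(t_k <= 0)) stop("temperature below absolute zero")
  cal$slope / t_k^2 + cal$intercept
}

#' Propagate D47 standard error to temperature standard error
#'
#' Delta-method propagation through the inverted calibration:
#' \deqn{SE_T = |dT/d\Delta_{47}| \cdot SE_{\Delta_{47}},\quad
#'   dT/d\Delta_{47} = -\tfrac12 \sqrt{a}\,(\Delta_{47}-b)^{-3/2}.}
#' A central finite-difference mode is available as a cross-check.
#'
#' @param d47 mean D47 (permil).
#' @param d47_se standard error of the mean D47 (permil), >= 0.
#' @param cal a [d47_calibration()].
#' @param method `"delta"` (default) or `"finite_diff"` (half-range
#'   `(T(d47 - se) - T(d47 + se)) / 2`).
#' @return standard error on temperature, in kelvin (equivalently degC).
#' @export
propagate_temperature_se <- function(d47, d47_se, cal = d47_calibration(),
                                     method = c("delta", "finite_diff")) {
  method <- match.arg(method)
  stopifnot(is.numeric(d47), is.numeric(d47_se))
  if (any(d47_se < 0)) stop("d47_se must be non-negative")
  if (any(d47 <= cal$intercept)) {
    stop("D47 at or below calibration intercept: non-physical measurement")
  }
  if (method == "delta") {
    deriv <- 0.5 * sqrt(cal$slope) * (d47 - cal$intercept)^(-1.5)
    deriv * d47_se
  } else {
    ifelse(d47_se == 0, 0,
           (delta47_to_temperature(d47 - d47_se, cal) -
              delta47_to_temperature(d47 + d47_se, cal)) / 2)
  }
}

#' Aggregate replicate isotope measurements per sample
#'
#' Collapses replicate-level measurements (d13C, d18O on V-PDB, D47, D48)
#' to per-sample means. Spread statistics use the sample standard deviation
#' (n - 1 denominator); the standard error of the mean D47 is sd/sqrt(n).
#' Single-replicate samples get sd and se of 0 together with a
#' `single_replicate` warning flag (and an R warning), rather than an error.
#'
#' @param replicates data frame with columns `sample_id`, `d13C_vpdb`,
#'   `d18O_vpdb`, `D47` and optionally `D48` and `run_index`.
#' @return data frame with one row per sample: `sample_id`, `n`, means and
#'   sds of d13C and d18O, `D47_mean`, `D47_sd`, `D47_se`, `D48_mean`,
#'   `single_replicate`.
#' @export
aggregate_replicates <- function(replicates) {
  req <- c("sample_id", "d13C_vpdb", "d18O_vpdb", "D47")
  missing_cols <- setdiff(req, names(replicates))
  if (length(missing_cols)) {
    stop("replicates table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(replicates) == 0L) stop("no replicates to aggregate")
  if (!"D48" %in% names(replicates)) replicates$D48 <- NA_real_
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  out <- do.call(rbind, lapply(split(replicates, replicates$sample_id), function(g) {
    n <- nrow(g)
    data.frame(
      sample_id = g$sample_id[1L],
      n = n,
      d13C_mean = mean(g$d13C_vpdb), d13C_sd = sd0(g$d13C_vpdb),
      d18O_mean = mean(g$d18O_vpdb), d18O_sd = sd0(g$d18O_vpdb),
      D47_mean = mean(g$D47), D47_sd = sd0(g$D47),
      D47_se = sd0(g$D47) / sqrt(n),
      D48_mean = mean(g$D48),
      single_replicate = n == 1L,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  if (any(out$single_replicate)) {
    warning("sample(s) with a single replicate: sd and se set to 0 for ",
            paste(out$sample_id[out$single_replicate], collapse = ", "))
  }
  out
}

#' Convert d18O from the V-PDB to the V-SMOW scale
#'
#' Standard inter-scale conversion `1.03091 * x + 30.91`.
#'
#' @param d18O_vpdb numeric vector (permil, V-PDB).
#' @return numeric vector (permil, V-SMOW).
#' @export
vpdb_to_vsmow <- function(d18O_vpdb) {
  if (any(!is.finite(d18O_vpdb))) stop("non-finite d18O input")
  1.03091 * d18O_vpdb + 30.91
}

#' Estimate the d18O of mineral formation water
#'
#' Given the carbonate d18O (V-SMOW) and the formation temperature, solves
#' the carbonate-water oxygen-isotope fractionation for the water value.
#' The default strategy uses the calcite-water expression
#' \deqn{1000 \ln\alpha = 18.03 \times (10^3/T_K) - 32.42}
#' so \eqn{\delta^{18}O_w = (\delta^{18}O_c + 1000)/\alpha - 1000}. A
#' phosphate-thermometry strategy (`T = 117.4 - 4.50 (dp - dw)`) is
#' selectable for phosphate d18O inputs.
#'
#' @param d18O_mineral_vsmow mineral d18O in permil V-SMOW (carbonate for
#'   the default strategy, phosphate for `"phosphate"`).
#' @param t_celsius formation temperature in degC; must be in (-50, 100).
#' @param method `"carbonate"` (default) or `"phosphate"`.
#' @return water d18O in permil V-SMOW.
#' @export
estimate_water_d18O <- function(d18O_mineral_vsmow, t_celsius,
                                method = c("carbonate", "phosphate")) {
  method <- match.arg(method)
  if (any(t_celsius <= -50 | t_celsius >= 100)) {
    stop("temperature outside (-50, 100) degC: fractionation expression not applicable")
  }
  if (method == "carbonate") {
    t_k <- t_celsius + 273.15
    ln_alpha_1000 <- 18.03 * (1000 / t_k) - 32.42
    alpha <- exp(ln_alpha_1000 / 1000)
    (d18O_mineral_vsmow + 1000) / alpha - 1000
  } else {
    d18O_mineral_vsmow - (117.4 - t_celsius) / 4.50
  }
}

#' Flag samples with anomalously high D48
#'
#' Elevated D48 indicates isobaric contamination (e.g. residual organics)
#' that compromises the D47 measurement. The flag is strict: a mean D48
#' exactly at the threshold is not flagged.
#'
#' @param d48_mean mean D48 (permil); vectorised.
#' @param threshold contamination threshold in permil; must be positive.
#' @return logical vector, `TRUE` = suspected contamination.
#' @export
flag_d48 <- function(d48_mean, threshold = 1.0) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  if (threshold <= 0) stop("threshold must be positive")
  !is.na(d48_mean) & d48_mean > threshold
}
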