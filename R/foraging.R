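#' Construct a diet specification
#'
#' Default values describe a browse/leaf diet: 18 MJ gross energy per kg
#' dry matter, 45% digestibility, 30% dry matter.
#'
#' @param gross_energy_mj_kg gross energy, MJ per kg dry matter (> 0).
#' @param digestibility digestible fraction, (0, 1].
#' @param dry_matter_fraction dry matter fraction of wet forage, (0, 1].
#' @return object of class `"diet_spec"`.
#' @export
diet_spec <- function(gross_energy_mj_kg = 18, digestibility = 0.45,
                      dry_matter_fraction = 0.30) {
  if (gross_energy_mj_kg <= 0) stop("gross energy must be positive")
  if (digestibility <= 0 || digestibility > 1) stop("digestibility in (0, 1]")
  if (dry_matter_fraction <= 0 || dry_matter_fraction > 1) {
    stop("dry matter fraction in (0, 1]")
  }
  structure(list(gross_energy_mj_kg = gross_energy_mj_kg,
                 digestibility = digestibility,
                 dry_matter_fraction = dry_matter_fraction),
            class = "diet_spec")
}

#' Wet-mass forage intake required for a daily energy expenditure
#'
#' Dry intake = daily energy / (gross energy x digestibility); wet intake
#' scales by the dry matter fraction. Linear in the energy requirement.
#'
#' @param daily_kj daily metabolic expenditure, kJ (>= 0); vectorised.
#' @param diet a [diet_spec()].
#' @return wet forage mass in kg per day.
#' @export
wet_intake <- function(daily_kj, diet = diet_spec()) {
  stopifnot(inherits(diet, "diet_spec"))
  if (any(daily_kj < 0)) stop("daily energy must be >= 0")
  dry <- daily_kj / (diet$gross_energy_mj_kg * 1000 * diet$digestibility)
  dry / diet$dry_matter_fraction
}

#' Quadratic fit of monthly intake
#'
#' Ordinary least-squares second-order polynomial
#' `y = a x^2 + b x + c` over month index x, as used to summarise seasonal
#' trends in food consumption. `R^2 = 1 - SSres/SStot`, defined as 0 for
#' constant data.
#'
#' @param months month indices (1-12 typically); >= 3 distinct values.
#' @param intake_kg intake per day for each month.
#' @return list with `coefficients` (named a, b, c) and `r_squared`.
#' @export
fit_monthly_quadratic <- function(months, intake_kg) {
  if (length(months) != length(intake_kg)) stop("length mismatch")
  if (length(unique(months)) < 3L) stop("need >= 3 distinct month values")
  fit <- stats::lm(intake_kg ~ months + I(months^2))
  cf <- stats::coef(fit)
  ss_tot <- sum((intake_kg - mean(intake_kg))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(stats::resid(fit)^2) / ss_tot
  list(coefficients = c(a = unname(cf[3L]), b = unname(cf[2L]),
                        c = unname(cf[1L])),
       r_squared = r2)
}
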