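# Run code under an explicit seed, restoring any pre-existing global RNG
# state afterwards so generators leave no trace in the session.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Generate synthetic clumped-isotope replicate measurements
#'
#' Draws replicate D47 values from a normal distribution centred on the
#' calibration's forward value at the true core temperature, with stated
#' replicate-level noise; d13C and d18O are drawn around stated means.
#' Fully determined by the seed.
#'
#' @param true_t_c true core body temperature, degC.
#' @param n number of replicates (>= 1).
#' @param d47_sd replicate D47 standard deviation, permil (>= 0).
#' @param d13C_mean,d13C_sd d13C mean and sd (permil, V-PDB).
#' @param d18O_mean,d18O_sd d18O mean and sd (permil, V-PDB).
#' @param d48_mean,d48_sd D48 mean and sd (permil).
#' @param sample_id sample label.
#' @param seed integer seed.
#' @param cal a [d47_calibration()].
#' @return replicates data frame (columns `sample_id`, `run_index`,
#'   `d13C_vpdb`, `d18O_vpdb`, `D47`, `D48`) with attribute `truth`.
#' @export
gen_isotope_replicates <- function(true_t_c, n, d47_sd, d13C_mean = -9,
                                   d13C_sd = 0.1, d18O_mean = -1,
                                   d18O_sd = 0.2, d48_mean = 0.3,
                                   d48_sd = 0.05, sample_id = "SYN-1",
                                   seed = 1, cal = d47_calibration()) {
  if (n < 1) stop("n must be >= 1")
  if (d47_sd < 0 || d18O_sd < 0) stop("standard deviations must be >= 0")
  d47_true <- temperature_to_delta47(true_t_c, cal)
  out <- with_seed(seed, data.frame(
    sample_id = sample_id,
    run_index = seq_len(n),
    d13C_vpdb = stats::rnorm(n, d13C_mean, d13C_sd),
    d18O_vpdb = stats::rnorm(n, d18O_mean, d18O_sd),
    D47 = stats::rnorm(n, d47_true, d47_sd),
    D48 = stats::rnorm(n, d48_mean, d48_sd),
    stringsAsFactors = FALSE
  ))
  attr(out, "truth") <- list(true_t_c = true_t_c, d47_true = d47_true,
                             seed = seed)
  out
}

#' Generate synthetic REE concentration tables with a known index
#'
#' Cortical bone concentrations are drawn lognormally around the PAAS
#' reference; orthodentine is the bone profile with elementwise lognormal
#' jitter, rescaled so that the dentine:bone REE index equals
#' `true_ratio` exactly by construction.
#'
#' @param true_ratio target REE index (> 0).
#' @param seed integer seed.
#' @param ref PAAS reference, default [paas_reference()].
#' @return list with `dentine` and `bone` named concentration vectors
#'   (ppm) and `true_ratio`.
#' @export
gen_ree_tables <- function(true_ratio, seed = 1, ref = paas_reference()) {
  if (true_ratio <= 0) stop("true_ratio must be positive")
  with_seed(seed, {
    n <- length(ref)
    bone <- ref * stats::rlnorm(n, meanlog = 0, sdlog = 0.4)
    names(bone) <- names(ref)
    dentine <- bone * stats::rlnorm(n, meanlog = 0, sdlog = 0.2)
    # rescale dentine so the normalised-sum ratio hits the target exactly
    scale <- true_ratio * sum(bone / ref) / sum(dentine / ref)
    dentine <- dentine * scale
    list(dentine = dentine, bone = bone, true_ratio = true_ratio)
  })
}

#' Generate a synthetic monthly climate table
#'
#' Emulates the ambient regimes spanned by ground sloth localities:
#' `tropical` (annual means ~25 degC with weak seasonality, monthly
#' temperatures confined to roughly 2-30 degC), `temperate` (means 5-25
#' degC) and `cold` (means -5-15 degC, winter minima below freezing).
#' Seasonal amplitude grows with absolute latitude; the seasonal phase
#' follows the hemisphere. Deterministic per seed.
#'
#' @param regime one of `"tropical"`, `"temperate"`, `"cold"`.
#' @param latitude_deg latitude in degrees.
#' @param seed integer seed.
#' @return 12-row climate data frame suitable for [locality()].
#' @export
gen_climate <- function(regime = c("tropical", "temperate", "cold"),
                        latitude_deg = 0, seed = 1) {
  regime <- match.arg(regime)
  p <- switch(regime,
    tropical = list(mean = 25, amp0 = 0.5, amp_lat = 2.0, diurnal = 5,
                    rh = 80, cloud = 0.5, wind = 1.0),
    temperate = list(mean = 14, amp0 = 4, amp_lat = 8, diurnal = 8,
                     rh = 65, cloud = 0.5, wind = 2.0),
    cold = list(mean = 4, amp0 = 6, amp_lat = 8, diurnal = 8,
                rh = 60, cloud = 0.6, wind = 3.0))
  amp <- p$amp0 + p$amp_lat * abs(latitude_deg) / 90
  # winter at month 1 in the northern hemisphere, month 7 in the southern
  phase <- if (latitude_deg >= 0) 1 else 7
  with_seed(seed, {
    months <- 1:12
    seasonal <- -amp * cos(2 * pi * (months - phase) / 12)
    mean_t <- p$mean + seasonal + stats::runif(12, -0.5, 0.5)
    data.frame(
      month = months,
      tmax_c = mean_t + p$diurnal / 2,
      tmin_c = mean_t - p$diurnal / 2,
      rh_pct = pmin(100, pmax(0, p$rh + stats::runif(12, -5, 5))),
      cloud_frac = pmin(1, pmax(0, p$cloud + stats::runif(12, -0.1, 0.1))),
      wind_ms = pmax(0.1, p$wind + stats::runif(12, -0.3, 0.3)),
      paleo_offset_c = 0
    )
  })
}

#' Generate a synthetic analytical run of samples and standards
#'
#' Interleaves carbonate standards between sample replicates along a run
#' and applies a known affine distortion `measured = slope * true +
#' offset` to every measured D47 (samples and standards alike), so that
#' [correct_with_standards()] can be checked against recorded truth.
#'
#' @param n_samples number of sample replicates.
#' @param distortion length-2 numeric `c(slope, offset)`.
#' @param seed integer seed.
#' @param true_t_c true formation temperature of the samples, degC.
#' @param d47_sd replicate-level D47 noise before distortion (default 0
#'   for exact-inversion checks).
#' @param standards_every interleave one standards block after this many
#'   samples (default 2).
#' @param cal a [d47_calibration()].
#' @return list with `replicates`, `standards` data frames and `truth`.
#' @export
gen_standards_run <- function(n_samples, distortion = c(1, 0), seed = 1,
                              true_t_c = 31, d47_sd = 0,
                              standards_every = 2L,
                              cal = d47_calibration()) {
  stopifnot(length(distortion) == 2L, is.finite(distortion))
  if (distortion[1L] == 0) stop("distortion slope must be nonzero")
  slope <- distortion[1L]; offset <- distortion[2L]
  std_accepted <- eth_standards()[c("ETH-1", "ETH-2", "ETH-3")]
  d47_true <- temperature_to_delta47(true_t_c, cal)

  with_seed(seed, {
    run_index <- 0L
    reps <- list(); stds <- list()
    emit_block <- function() {
      for (nm in names(std_accepted)) {
        run_index <<- run_index + 1L
        stds[[length(stds) + 1L]] <<- data.frame(
          name = nm, run_index = run_index,
          measured_D47 = slope * std_accepted[[nm]] + offset,
          accepted_D47 = std_accepted[[nm]], stringsAsFactors = FALSE)
      }
    }
    emit_block()
    for (i in seq_len(n_samples)) {
      run_index <- run_index + 1L
      true_i <- d47_true + stats::rnorm(1, 0, d47_sd)
      reps[[length(reps) + 1L]] <- data.frame(
        sample_id = sprintf("SYN-%02d", i), run_index = run_index,
        d13C_vpdb = stats::rnorm(1, -9, 0.1),
        d18O_vpdb = stats::rnorm(1, -1, 0.2),
        D47 = slope * true_i + offset,
        D48 = stats::rnorm(1, 0.3, 0.05),
        D47_true = true_i, stringsAsFactors = FALSE)
      if (i %% standards_every == 0L) emit_block()
    }
    list(replicates = do.call(rbind, reps),
         standards = do.call(rbind, stds),
         truth = list(slope = slope, offset = offset, true_t_c = true_t_c,
                      d47_true = d47_true, seed = seed))
  })
}
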