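#' Solar declination
#'
#' Standard approximation: `-23.44 deg * cos(2 pi (doy + 10) / 365)`.
#'
#' @param day_of_year integer day of year (1-365).
#' @return declination in degrees.
#' @export
solar_declination <- function(day_of_year) {
  -23.44 * cos(2 * pi * (day_of_year + 10) / 365)
}

#' Local solar sunrise hour
#'
#' From the sunrise hour-angle `H = acos(-tan(lat) tan(decl))`; polar
#' day/night are clamped. Returned rounded to the nearest whole hour so
#' that diurnal temperature extremes land exactly on sampled hours.
#'
#' @param latitude_deg latitude in degrees.
#' @param day_of_year integer day of year.
#' @return sunrise in local solar hours (0-12).
#' @export
sunrise_hour <- function(latitude_deg, day_of_year) {
  decl <- solar_declination(day_of_year) * pi / 180
  lat <- latitude_deg * pi / 180
  x <- -tan(lat) * tan(decl)
  x <- min(1, max(-1, x))
  h_angle <- acos(x)  # radians
  round(12 - h_angle * 12 / pi)
}

#' Hourly air temperatures from monthly extremes
#'
#' Diurnal interpolation by sinusoidal segments: the minimum is anchored
#' at the (rounded) sunrise hour, the maximum at 14:00 local solar time,
#' with half-cosine transitions between them and periodic wrap-around.
#' Every day of a month shares the same trace; a paleoclimate offset is
#' added uniformly.
#'
#' @param t_min_c,t_max_c monthly minimum and maximum air temperature,
#'   degC, with `t_max_c >= t_min_c`.
#' @param latitude_deg latitude (sets sunrise hour).
#' @param day_of_year representative day of the month.
#' @param paleo_offset_c additive offset in degC (default 0).
#' @return numeric vector of 24 temperatures for hours 0-23.
#' @export
hourly_temperatures <- function(t_min_c, t_max_c, latitude_deg, day_of_year,
                                paleo_offset_c = 0) {
  if (t_max_c < t_min_c) stop("t_max_c must be >= t_min_c")
  h_sr <- sunrise_hour(latitude_deg, day_of_year)
  h_sr <- min(h_sr, 13)  # keep the rise segment non-degenerate
  h_max <- 14
  amp <- (t_max_c - t_min_c) / 2
  mid <- (t_max_c + t_min_c) / 2
  hours <- 0:23
  temp <- numeric(24)
  for (i in seq_along(hours)) {
    h <- hours[i]
    if (h >= h_sr && h <= h_max) {
      # rising half-cosine from minimum at sunrise to maximum at 14:00
      phase <- (h - h_sr) / (h_max - h_sr)
      temp[i] <- mid - amp * cos(pi * phase)
    } else {
      # falling half-cosine from 14:00 down to next sunrise
      h_adj <- if (h > h_max) h else h + 24
      phase <- (h_adj - h_max) / (h_sr + 24 - h_max)
      temp[i] <- mid + amp * cos(pi * phase)
    }
  }
  temp + paleo_offset_c
}

#' Clear-sky solar flux on a horizontal surface
#'
#' Beam attenuation through the atmosphere with a 0.7 zenith transmittance
#' raised to the optical air mass, projected on the horizontal and reduced
#' by cloud: `S = 1361 * 0.7^airmass * cos(zenith) * (1 - 0.75 cloud)`,
#' zero when the sun is below the horizon. The air mass is `1/cos(zenith)`
#' capped at 38 (horizon value).
#'
#' @param latitude_deg latitude in degrees.
#' @param day_of_year integer day of year.
#' @param hour local solar hour (0-23, solar noon = 12).
#' @param cloud_frac cloud fraction in \[0, 1\].
#' @return flux in W m^-2.
#' @export
solar_flux <- function(latitude_deg, day_of_year, hour, cloud_frac = 0) {
  if (cloud_frac < 0 || cloud_frac > 1) stop("cloud fraction in [0, 1]")
  decl <- solar_declination(day_of_year) * pi / 180
  lat <- latitude_deg * pi / 180
  hour_angle <- (hour - 12) * pi / 12
  cos_zen <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(hour_angle)
  if (cos_zen <= 0) return(0)
  airmass <- min(1 / cos_zen, 38)
  1361 * 0.7^airmass * cos_zen * (1 - 0.75 * cloud_frac)
}

#' Effective sky radiant temperature
#'
#' Clear-sky atmospheric emissivity from the empirical air-temperature
#' regression
#' \deqn{\epsilon = 1 - 0.261 \exp(-7.77\times10^{-4} (273 - T_K)^2)}
#' blended towards blackbody with cloud cover
#' (`eps_eff = eps + (1 - eps) * cloud`); the sky temperature is
#' `eps_eff^(1/4) * T_K`.
#'
#' @param t_air_c 2-m air temperature in degC; must lie in (-80, 60).
#' @param cloud_frac cloud fraction in \[0, 1\].
#' @return sky temperature in degC.
#' @export
sky_temperature <- function(t_air_c, cloud_frac = 0) {
  if (any(t_air_c <= -80 | t_air_c >= 60)) {
    stop("air temperature outside (-80, 60) degC")
  }
  if (cloud_frac < 0 || cloud_frac > 1) stop("cloud fraction in [0, 1]")
  t_k <- t_air_c + 273.15
  eps <- 1 - 0.261 * exp(-7.77e-4 * (273 - t_k)^2)
  eps_eff <- eps + (1 - eps) * cloud_frac
  eps_eff^0.25 * t_k - 273.15
}

#' Construct a locality
#'
#' @param name locality label.
#' @param latitude_deg latitude in degrees, \[-90, 90\].
#' @param climate data frame of 12 monthly rows with columns `month`,
#'   `tmax_c`, `tmin_c`, `rh_pct`, `cloud_frac`, `wind_ms` and optionally
#'   `paleo_offset_c`.
#' @param shade length-2 numeric: minimum- and maximum-shade fractions
#'   available to the animal (default c(0, 1)).
#' @return object of class `"locality"`.
#' @export
locality <- function(name, latitude_deg, climate, shade = c(0, 1)) {
  if (abs(latitude_deg) > 90) stop("latitude in [-90, 90]")
  need <- c("month", "tmax_c", "tmin_c", "rh_pct", "cloud_frac", "wind_ms")
  if (!all(need %in% names(climate))) {
    stop("climate table needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(climate) != 12L) stop("climate table must have 12 monthly rows")
  if (any(climate$tmax_c < climate$tmin_c)) stop("tmax_c must be >= tmin_c")
  if (!"paleo_offset_c" %in% names(climate)) climate$paleo_offset_c <- 0
  structure(list(name = name, latitude_deg = latitude_deg,
                 climate = climate, shade = sort(shade)),
            class = "locality")
}

# Representative day of year for month m (the 15th).
month_doy <- function(month) {
  cumdays <- c(0, 31, 59, 90, 120, 151, 181, 212, 243, 273, 304, 334)
  cumdays[month] + 15
}

#' Daily energy from an hourly power trace
#'
#' Trapezoidal integration of 24 hourly values over the periodic daily
#' cycle (hour 24 wraps to hour 0), which reduces to the hourly mean times
#' 86,400 s. A constant 1000 W trace therefore integrates to exactly
#' 86,400 kJ.
#'
#' @param hourly_w numeric vector of 24 power values in W.
#' @return energy in kJ per day.
#' @export
daily_energy <- function(hourly_w) {
  if (length(hourly_w) != 24L) stop("need 24 hourly values")
  # periodic trapezoid: sum over i of (w_i + w_{i+1})/2 * 3600 s, w_24 = w_0
  sum((hourly_w + c(hourly_w[-1L], hourly_w[1L])) / 2) * 3600 / 1000
}

#' Classify daily expenditure against the comfort target zone
#'
#' Above the field-metabolic upper bound the animal is spending extra
#' energy to stay warm ("cold stress"); below the basal lower bound it
#' must suppress metabolism to avoid overheating ("heat stress");
#' in between is the thermal-comfort zone.
#'
#' @param daily_kj daily expenditure, kJ.
#' @param bounds named `c(lower, upper)` from [daily_bounds()].
#' @return one of `"comfort"`, `"cold_stress"`, `"heat_stress"`.
#' @export
classify_stress <- function(daily_kj, bounds) {
  if (daily_kj > bounds[["upper"]]) "cold_stress"
  else if (daily_kj < bounds[["lower"]]) "heat_stress"
  else "comfort"
}

#' Simulate one representative day of a month
#'
#' Builds hourly driving environments from the monthly climate (sinusoidal
#' air temperature, solar geometry, sky radiant temperature) and solves
#' the animal heat balance each hour under the locality's minimum-shade
#' (full sun, radiant environment averaged between sky and ground) and
#' maximum-shade (solar blocked, radiant environment at air temperature)
#' options, keeping whichever brings the requirement closest to BMR.
#' Negative requirements (net heat load) integrate as zero production and
#' are flagged. Daily energy is the periodic trapezoidal integral;
#' active hours count the hours in which basal rate can be met in minimum
#' shade (full sun) without suppression below 0.95 BMR.
#'
#' @param taxon a [taxon_spec()].
#' @param fur a [fur_layer()].
#' @param loc a [locality()].
#' @param month month index 1-12.
#' @param evap_fraction passed to [solve_required_metabolism()].
#' @return object of class `"daily_budget"`: `hourly_m_w`, `choice`,
#'   `daily_kj`, `stress`, `active_hours`, `heat_load_hours`, `bmr_w`,
#'   `bounds_kj`.
#' @export
simulate_day <- function(taxon, fur, loc, month, evap_fraction = 0.05) {
  stopifnot(inherits(taxon, "taxon_spec"), inherits(fur, "fur_layer"),
            inherits(loc, "locality"), month %in% 1:12)
  row <- loc$climate[loc$climate$month == month, , drop = FALSE]
  if (nrow(row) != 1L) stop("month ", month, " not found in climate table")
  doy <- month_doy(month)
  temps <- hourly_temperatures(row$tmin_c, row$tmax_c, loc$latitude_deg, doy,
                               row$paleo_offset_c)
  geom <- geometry_from_mass(taxon$mass_kg)
  bmr <- xenarthran_bmr(taxon$mass_kg)
  bounds <- daily_bounds(bmr, taxon$activity_multiplier)

  m_sun <- numeric(24)
  m_kept <- numeric(24)
  choice <- character(24)
  for (h in 0:23) {
    t_air <- temps[h + 1L]
    sol <- solar_flux(loc$latitude_deg, doy, h, row$cloud_frac)
    t_sky <- sky_temperature(t_air, row$cloud_frac)
    env_sun <- environment_state(
      t_air, t_rad_c = (t_sky + t_air) / 2, wind_ms = row$wind_ms,
      rh_pct = row$rh_pct, solar_wm2 = sol, shade_fraction = loc$shade[1L])
    env_shade <- environment_state(
      t_air, t_rad_c = t_air, wind_ms = row$wind_ms, rh_pct = row$rh_pct,
      solar_wm2 = sol, shade_fraction = loc$shade[2L])
    s_sun <- tryCatch(
      solve_required_metabolism(geom, fur, env_sun, taxon$t_core_c,
                                evap_fraction = evap_fraction),
      error = function(e) stop("hour ", h, ": ", conditionMessage(e)))
    s_shade <- tryCatch(
      solve_required_metabolism(geom, fur, env_shade, taxon$t_core_c,
                                evap_fraction = evap_fraction),
      error = function(e) stop("hour ", h, ": ", conditionMessage(e)))
    m_sun[h + 1L] <- s_sun$m_req_w
    if (abs(s_sun$m_req_w - bmr) <= abs(s_shade$m_req_w - bmr)) {
      m_kept[h + 1L] <- s_sun$m_req_w
      choice[h + 1L] <- "min_shade"
    } else {
      m_kept[h + 1L] <- s_shade$m_req_w
      choice[h + 1L] <- "max_shade"
    }
  }
  m_int <- pmax(m_kept, 0)
  daily_kj <- daily_energy(m_int)
  structure(list(
    hourly_m_w = m_kept,
    choice = choice,
    daily_kj = daily_kj,
    stress = classify_stress(daily_kj, bounds),
    active_hours = active_hours(m_sun, bmr),
    heat_load_hours = sum(m_kept < 0),
    bmr_w = bmr,
    bounds_kj = bounds
  ), class = "daily_budget")
}

#' Hours per day with basal rate sustainable in full sun
#'
#' Counts the hours whose minimum-shade (full sun) metabolic requirement
#' is at least 0.95 x BMR, i.e. hours in which the animal can hold basal
#' output without needing shade to shed heat.
#'
#' @param m_min_shade_w 24 hourly minimum-shade requirements, W.
#' @param bmr_w basal metabolic rate, W.
#' @param frac suppression threshold as fraction of BMR (default 0.95).
#' @return hours per day, 0-24.
#' @export
active_hours <- function(m_min_shade_w, bmr_w, frac = 0.95) {
  if (length(m_min_shade_w) != 24L) stop("need 24 hourly values")
  sum(m_min_shade_w >= frac * bmr_w)
}

#' Annual simulation summary over fur configurations and localities
#'
#' Runs [simulate_day()] for every month x fur configuration x locality,
#' returning the per-month records and, per locality, the fur
#' configuration with the fewest thermally stressed months (ties broken
#' towards thinner, then sparser, coats).
#'
#' @param taxon a [taxon_spec()].
#' @param fur_configs named list of [fur_layer()] objects.
#' @param localities list of [locality()] objects.
#' @return list with `records` (data frame) and `selection` (data frame,
#'   one row per locality).
#' @export
annual_summary <- function(taxon, fur_configs, localities) {
  if (length(fur_configs) == 0L || length(localities) == 0L) {
    stop("need at least one fur configuration and one locality")
  }
  if (is.null(names(fur_configs))) {
    names(fur_configs) <- paste0("fur", seq_along(fur_configs))
  }
  records <- list()
  for (loc in localities) {
    for (fn in names(fur_configs)) {
      for (m in 1:12) {
        day <- simulate_day(taxon, fur_configs[[fn]], loc, m)
        records[[length(records) + 1L]] <- data.frame(
          taxon = taxon$name, locality = loc$name, fur = fn, month = m,
          daily_kj = day$daily_kj, stress = day$stress,
          active_hours = day$active_hours,
          heat_load_hours = day$heat_load_hours,
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, records)

  selection <- do.call(rbind, lapply(localities, function(loc) {
    sub <- records[records$locality == loc$name, , drop = FALSE]
    stressed <- vapply(names(fur_configs), function(fn) {
      sum(sub$stress[sub$fur == fn] != "comfort")
    }, integer(1))
    depth <- vapply(fur_configs, function(f) f$depth_m, numeric(1))
    dens <- vapply(fur_configs, function(f) f$density_cm2, numeric(1))
    ord <- order(stressed, depth, dens)
    best <- names(fur_configs)[ord[1L]]
    data.frame(locality = loc$name, best_fur = best,
               stressed_months = stressed[[best]],
               stringsAsFactors = FALSE)
  }))
  rownames(selection) <- NULL
  list(records = records, selection = selection)
}
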