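test_that("hourly temperature interpolation hits the monthly extremes", {
  flat <- hourly_temperatures(20, 20, 10, 196)
  expect_equal(flat, rep(20, 24))
  temps <- hourly_temperatures(5, 25, 40, 196)
  expect_equal(min(temps), 5, tolerance = 1e-9)
  expect_equal(max(temps), 25, tolerance = 1e-9)
  expect_equal(which.max(temps) - 1, 14)  # maximum at 14:00 solar
  # additive paleoclimate offset
  shifted <- hourly_temperatures(5, 25, 40, 196, paleo_offset_c = -5)
  expect_equal(shifted, temps - 5)
  expect_error(hourly_temperatures(25, 5, 40, 196), ">=")
})

test_that("solar flux follows zenith geometry and cloud attenuation", {
  expect_equal(solar_flux(0, 80, 0, 0), 0)   # midnight
  expect_equal(solar_flux(45, 355, 23, 0), 0)
  # equator near equinox, solar noon, clear: ~1361 * 0.7
  noon <- solar_flux(0, 80, 12, 0)
  expect_equal(noon, 1361 * 0.7, tolerance = 0.01)
  # full overcast leaves 25% of clear sky
  expect_equal(solar_flux(0, 80, 12, 1), 0.25 * noon, tolerance = 1e-9)
  # flux never negative through the day
  day <- vapply(0:23, function(h) solar_flux(30, 172, h, 0.3), numeric(1))
  expect_true(all(day >= 0))
  expect_error(solar_flux(0, 80, 12, 2), "cloud")
})

test_that("sky temperature follows the emissivity regression", {
  expect_equal(sky_temperature(0, 0), -19.9, tolerance = 0.01)
  # full cloud: blackbody sky at air temperature
  expect_equal(sky_temperature(10, 1), 10, tolerance = 1e-9)
  # clear-sky emissivity grows away from 273 K
  eps <- function(t_c) 1 - 0.261 * exp(-7.77e-4 * (273 - (t_c + 273.15))^2)
  expect_true(eps(-30) > eps(0))
  expect_true(eps(40) > eps(0))
  # sky is never warmer than air
  for (t in c(-30, 0, 25)) expect_lte(sky_temperature(t, 0.4), t)
  expect_error(sky_temperature(-100, 0), "outside")
})

test_that("daily trapezoidal integration is exact for constants and periodic", {
  expect_equal(daily_energy(rep(1000, 24)), 86400)
  # periodicity: rotation leaves the integral unchanged
  set.seed(21)
  trace <- runif(24, 0, 800)
  base <- daily_energy(trace)
  for (k in c(1, 5, 13)) {
    rotated <- c(trace[-seq_len(k)], trace[seq_len(k)])
    expect_equal(daily_energy(rotated), base, tolerance = 1e-12)
  }
  # sinusoid: closed-form integral is mean * 86400 s
  sine <- 500 + 200 * sin(2 * pi * (0:23) / 24)
  expect_equal(daily_energy(sine), 500 * 86.4, tolerance = 0.005 * 500 * 86.4)
})

test_that("stress classification partitions daily expenditure", {
  bounds <- c(lower = 1000, upper = 2000)
  expect_equal(classify_stress(1500, bounds), "comfort")
  expect_equal(classify_stress(2500, bounds), "cold_stress")
  expect_equal(classify_stress(500, bounds), "heat_stress")
  expect_equal(classify_stress(1000, bounds), "comfort")  # closed bounds
  expect_equal(classify_stress(2000, bounds), "comfort")
})

test_that("active hours count full-sun hours at basal output", {
  expect_equal(active_hours(rep(1000, 24), 1000), 24)
  expect_equal(active_hours(rep(100, 24), 1000), 0)
  trace <- c(rep(1000, 15), rep(100, 9))
  expect_equal(active_hours(trace, 1000), 15)
  # threshold is 0.95 x bmr
  expect_equal(active_hours(rep(0.95 * 1000, 24), 1000), 24)
  expect_equal(active_hours(rep(0.9499 * 1000, 24), 1000), 0)
})

test_that("simulate_day produces a coherent daily budget", {
  taxon <- taxon_spec("Mylodon", 1986, 33)
  fur <- fur_layer(0.03, 2000)
  loc <- locality("temperate", 40, gen_climate("temperate", 40, seed = 2))
  day <- simulate_day(taxon, fur, loc, month = 1)
  expect_length(day$hourly_m_w, 24)
  expect_true(day$stress %in% c("comfort", "cold_stress", "heat_stress"))
  expect_gte(day$active_hours, 0); expect_lte(day$active_hours, 24)
  expect_equal(day$daily_kj, daily_energy(pmax(day$hourly_m_w, 0)),
               tolerance = 1e-9)
  expect_true(all(day$choice %in% c("min_shade", "max_shade")))
})

test_that("daily expenditure falls as a cold climate warms", {
  taxon <- taxon_spec("Mylodon", 1986, 33)
  fur <- fur_layer(0.01, 8.5)  # sparse coat, cold-stressed
  kjs <- vapply(c(-20, -10, 0, 10), function(t_c) {
    loc <- locality("syn", 45, flat_climate(t_c, diurnal = 6))
    simulate_day(taxon, fur, loc, month = 1)$daily_kj
  }, numeric(1))
  expect_true(all(diff(kjs) < 0))
})

test_that("annual summary selects the least-stressed configuration", {
  taxon <- taxon_spec("Nothrotheriops", 463, 32)
  furs <- list(sparse_10mm = fur_layer(0.01, 8.5),
               dense_30mm = fur_layer(0.03, 2000))
  loc <- locality("cold", 50, gen_climate("cold", 50, seed = 4))
  ann <- annual_summary(taxon, furs, list(loc))
  expect_equal(nrow(ann$records), 24)  # 12 months x 2 furs
  expect_true(all(ann$records$stress %in%
                    c("comfort", "cold_stress", "heat_stress")))
  # exhaustive-enumeration oracle for the selection
  stressed <- tapply(ann$records$stress != "comfort", ann$records$fur, sum)
  depth <- c(sparse_10mm = 0.01, dense_30mm = 0.03)
  expected <- names(stressed)[order(stressed, depth[names(stressed)])][1]
  expect_equal(ann$selection$best_fur, expected)
})
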