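test_that("geometry from mass matches closed forms and scaling", {
  g <- geometry_from_mass(1000, shape_ratio = 1)
  r <- (3 / (4 * pi))^(1 / 3)
  expect_equal(g$b_m, r, tolerance = 1e-12)
  expect_equal(g$area_m2, 4 * pi * r^2, tolerance = 1e-9)
  expect_equal(g$volume_m3, 1, tolerance = 1e-12)
  # mass x8 at fixed ratio: linear dims x2, area x4
  g1 <- geometry_from_mass(500, shape_ratio = 2)
  g8 <- geometry_from_mass(4000, shape_ratio = 2)
  expect_equal(g8$b_m / g1$b_m, 2, tolerance = 1e-12)
  expect_equal(g8$area_m2 / g1$area_m2, 4, tolerance = 1e-12)
  # quadrature oracle for the prolate area
  g2 <- geometry_from_mass(4490, shape_ratio = 2)
  expect_equal(g2$area_m2, quadrature_prolate_area(g2$a_m, g2$b_m),
               tolerance = 1e-3)
  expect_equal(g2$volume_m3, 4.49, tolerance = 1e-12)
  expect_error(geometry_from_mass(100, shape_ratio = 0.5), ">= 1")
  # area never below the equal-volume sphere
  for (ratio in c(1, 1.5, 2, 4)) {
    gg <- geometry_from_mass(1500, shape_ratio = ratio)
    sphere_area <- 4 * pi * (3 * gg$volume_m3 / (4 * pi))^(2 / 3)
    expect_gte(gg$area_m2, sphere_area - 1e-9)
  }
})

test_that("fur effective conductivity follows the linear mixing rule", {
  expect_equal(fur_effective_conductivity(fur_layer(0.03, 0)), 0.0257)
  f <- fur_layer(0.05, 2000)
  expect_equal(f$f, 2000 * 1e4 * pi * (5e-5)^2, tolerance = 1e-12)
  expect_equal(f$f, 0.157, tolerance = 1e-3)
  expect_equal(fur_effective_conductivity(f),
               0.0257 + (0.209 - 0.0257) * f$f, tolerance = 1e-12)
  expect_equal(fur_effective_conductivity(f), 0.0545, tolerance = 1e-3)
  same_k <- fur_layer(0.05, 2000, k_hair = 0.0257)
  expect_equal(fur_effective_conductivity(same_k), 0.0257)
  expect_error(fur_layer(0.05, 2e5), "over-dense")
})

test_that("skin conduction flux is the linear slab law", {
  expect_equal(skin_conduction_flux(0.3, 0.01, 34, 34), 0)
  expect_equal(skin_conduction_flux(0.3, 0.01, 34, 24), 300)
  expect_equal(skin_conduction_flux(0.3, 0.02, 34, 24), 150)
  expect_error(skin_conduction_flux(0.3, 0, 34, 24), "positive")
})

test_that("convection coefficient honours the correlation and its floor", {
  env_still <- environment_state(20, wind_ms = 0)
  d <- 1
  k_film <- 0.0243 + 7.0e-5 * 20
  expect_equal(convection_coefficient(20, env_still, d), 2 * k_film / d,
               tolerance = 1e-12)
  # hand evaluation of the correlation at 0.1 m/s
  env <- environment_state(20, wind_ms = 0.1)
  nu_air <- 1.33e-5 + 9.0e-8 * 20
  re <- 0.1 * d / nu_air
  h_hand <- (0.35 + 0.56 * re^0.52) * k_film / d
  expect_equal(convection_coefficient(20, env, d), h_hand, tolerance = 1e-12)
  # h increases with wind
  winds <- c(0.1, 0.5, 2, 5)
  hs <- vapply(winds, function(w)
    convection_coefficient(20, environment_state(20, wind_ms = w), d),
    numeric(1))
  expect_true(all(diff(hs) > 0))
})

test_that("zero-gradient chamber requires no metabolic heat", {
  geom <- geometry_from_mass(1000)
  fur <- fur_layer(0.03, 2000)
  env <- environment_state(34, t_rad_c = 34, wind_ms = 0.1)
  sol <- solve_required_metabolism(geom, fur, env, 34, evap_fraction = 0)
  expect_lt(abs(sol$m_req_w), 0.1)
  expect_lt(abs(sol$residual_w), 0.1)
})

test_that("returned solutions close the energy balance", {
  set.seed(99)
  for (i in 1:200) {
    geom <- geometry_from_mass(runif(1, 100, 5000))
    fur <- fur_layer(runif(1, 0, 0.05), runif(1, 0, 2000))
    env <- environment_state(runif(1, -40, 40),
                             t_rad_c = runif(1, -50, 40),
                             wind_ms = runif(1, 0, 8),
                             solar_wm2 = runif(1, 0, 1000),
                             shade_fraction = runif(1, 0, 1))
    sol <- solve_required_metabolism(geom, fur, env, runif(1, 28, 38))
    expect_lt(abs(sol$residual_w), 0.1)
    # closure identity: M - evap + solar = conv + IR (within residual)
    closure <- sol$m_req_w - sol$q_evap_w + sol$q_solar_abs_w -
      (sol$q_conv_w + sol$q_ir_w)
    expect_lt(abs(closure), 0.1)
  }
})

test_that("independent flux-sum oracle agrees at the returned surface", {
  geom <- geometry_from_mass(2000)
  fur <- fur_layer(0.03, 1300)
  env <- environment_state(5, t_rad_c = -5, wind_ms = 1, solar_wm2 = 300,
                           shade_fraction = 0.2)
  sol <- solve_required_metabolism(geom, fur, env, 33)
  # recompute every flux independently at the reported surface temperature
  depth <- fur$depth_m
  a_out <- geom$a_m + depth; b_out <- geom$b_m + depth
  e <- sqrt(1 - (b_out / a_out)^2)
  area_out <- 2 * pi * b_out^2 + 2 * pi * a_out * b_out * asin(e) / e
  ts <- sol$t_fur_surface_c
  h <- convection_coefficient(ts, env, geom$d_char_m + 2 * depth)
  q_conv <- h * area_out * (ts - env$t_air_c)
  q_ir <- 0.95 * 5.670374419e-8 * area_out *
    ((ts + 273.15)^4 - (env$t_rad_c + 273.15)^4)
  q_solar <- 0.8 * 0.25 * (1 - env$shade_fraction) * env$solar_wm2 * area_out
  expect_equal(sol$q_conv_w, q_conv, tolerance = 1e-9)
  expect_equal(sol$q_ir_w, q_ir, tolerance = 1e-9)
  expect_equal(sol$q_solar_abs_w, q_solar, tolerance = 1e-9)
  expect_lt(abs((sol$m_req_w - sol$q_evap_w) - (q_conv + q_ir - q_solar)), 0.1)
})

test_that("zero-fur solutions equal the bare-skin closed form", {
  geom <- geometry_from_mass(3706)
  bare <- fur_layer(0, 0)
  for (t_air in c(-10, 10, 25)) {
    env <- environment_state(t_air, wind_ms = 0.5)
    sol <- solve_required_metabolism(geom, bare, env, 31)
    # independent bare-skin oracle: surface at core temperature
    h <- convection_coefficient(31, env, geom$d_char_m)
    q <- h * geom$area_m2 * (31 - t_air) +
      0.95 * 5.670374419e-8 * geom$area_m2 *
        ((31 + 273.15)^4 - (t_air + 273.15)^4)
    expect_equal(sol$m_req_w, q / 0.95, tolerance = 1e-6)
    expect_equal(sol$t_fur_surface_c, 31)
  }
})

test_that("required metabolism is monotone in air temperature and fur", {
  geom <- geometry_from_mass(1986)
  fur <- fur_layer(0.03, 2000)
  t_core <- 33
  m <- vapply(seq(-30, 30, by = 5), function(t_air) {
    solve_required_metabolism(geom, fur,
                              environment_state(t_air, wind_ms = 0.1),
                              t_core)$m_req_w
  }, numeric(1))
  expect_true(all(diff(m) < 0))  # warmer -> less required heat
  # deeper fur reduces the requirement in the cold
  m_depth <- vapply(c(0.01, 0.03, 0.05), function(d) {
    solve_required_metabolism(geom, fur_layer(d, 2000),
                              environment_state(-10, wind_ms = 0.1),
                              t_core)$m_req_w
  }, numeric(1))
  expect_true(all(diff(m_depth) < 0))
  # denser fur likewise
  m_dens <- vapply(c(8.5, 300, 2000), function(dn) {
    solve_required_metabolism(geom, fur_layer(0.03, dn),
                              environment_state(-10, wind_ms = 0.1),
                              t_core)$m_req_w
  }, numeric(1))
  expect_true(all(diff(m_dens) < 0))
})

test_that("TNZ extraction matches the analytic band intersection", {
  # synthetic linear profile M(T) = 2000 - 20 T, bmr = 1000, band 950-1050:
  # inside for T in [47.5, 52.5]
  t_grid <- seq(0, 100, by = 0.5)
  m <- 2000 - 20 * t_grid
  zone <- tnz_from_profile(t_grid, m, 1000)
  expect_true(zone$present)
  expect_lte(abs(zone$lct_c - 47.5), 0.25)
  expect_lte(abs(zone$uct_c - 52.5), 0.25)
  # band fully outside the sweep
  none <- tnz_from_profile(t_grid, m + 1e6, 1000)
  expect_false(none$present)
  expect_true(is.na(none$lct_c))
})

test_that("chamber sweep refinement moves bounds by at most a step", {
  geom <- geometry_from_mass(463)
  fur <- fur_layer(0.03, 2000)
  bmr <- xenarthran_bmr(463)
  coarse <- metabolic_chamber_sweep(geom, fur, 32, bmr, step = 1)
  fine <- metabolic_chamber_sweep(geom, fur, 32, bmr, step = 0.5)
  expect_true(coarse$present && fine$present)
  expect_lte(abs(coarse$lct_c - fine$lct_c), 1)
  expect_lte(abs(coarse$uct_c - fine$uct_c), 1)
})

test_that("deeper dense coats extend the TNZ to lower temperatures", {
  geom <- geometry_from_mass(3706)
  bmr <- xenarthran_bmr(3706)
  z10 <- metabolic_chamber_sweep(geom, fur_layer(0.01, 2000), 31, bmr)
  z50 <- metabolic_chamber_sweep(geom, fur_layer(0.05, 2000), 31, bmr)
  expect_true(z10$present && z50$present)
  expect_lt(z50$lct_c, z10$lct_c)
  expect_lte(z50$lct_c, -10)  # directionally consistent with deep cold tolerance
})

test_that("heterothermic relaxation picks the cheapest admissible set-point", {
  geom <- geometry_from_mass(463)
  fur <- fur_layer(0.03, 2000)
  env <- environment_state(10, wind_ms = 0.1)
  bmr <- xenarthran_bmr(463)
  het <- heterothermic_solution(geom, fur, env, c(30, 34), bmr)
  expect_true(het$t_core_c >= 30 && het$t_core_c <= 34)
  # exhaustive-grid oracle
  grid <- seq(30, 34, by = 0.25)
  devs <- vapply(grid, function(tc)
    abs(solve_required_metabolism(geom, fur, env, tc)$m_req_w - bmr),
    numeric(1))
  expect_equal(het$t_core_c, grid[which.min(devs)])
  # never beaten by the fixed mid-range set-point
  fixed <- solve_required_metabolism(geom, fur, env, 32)
  expect_lte(abs(het$m_req_w - bmr), abs(fixed$m_req_w - bmr) + 1e-9)
})
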