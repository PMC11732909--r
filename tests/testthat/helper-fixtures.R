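# Shared fixtures built in code.

# Finite-difference cross-check for temperature SE propagation.
fd_temperature_se <- function(d47, d47_se, cal = d47_calibration()) {
  (delta47_to_temperature(d47 - d47_se, cal) -
     delta47_to_temperature(d47 + d47_se, cal)) / 2
}

# Numerical surface-of-revolution area for an ellipse with semi-major a
# (x axis) and semi-minor b, rotated about the x axis.
quadrature_prolate_area <- function(a, b) {
  integrand <- function(x) {
    y <- b * sqrt(pmax(0, 1 - (x / a)^2))
    dydx <- ifelse(abs(x) < a, -b * x / (a^2 * sqrt(pmax(1e-300, 1 - (x / a)^2))), 0)
    2 * pi * y * sqrt(1 + dydx^2)
  }
  stats::integrate(integrand, -a, a, rel.tol = 1e-9)$value
}

# Four paper-scale taxa at reduced precision needs: masses in kg.
sloth_masses <- c(Eremotherium = 4490, Megatherium = 3706,
                  Mylodon = 1986, Nothrotheriops = 463)

# A small constant-weather climate table for pipeline tests.
flat_climate <- function(t_c = 25, diurnal = 0) {
  data.frame(month = 1:12,
             tmax_c = t_c + diurnal / 2, tmin_c = t_c - diurnal / 2,
             rh_pct = 70, cloud_frac = 0.5, wind_ms = 1,
             paleo_offset_c = 0)
}
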