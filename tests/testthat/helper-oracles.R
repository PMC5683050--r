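# Independent oracles used across the suite.  These are written directly from
# the printed formulas / finite differences and never call the implementation
# paths they are used to check.

# Literal evaluation of the printed degree-9 polynomial divided by lambda^3.
p9_stress_direct <- function(lambda, c1, c2, c3) {
  p <- 3 * c3 * lambda^9 + (2 * c2 - 18 * c3) * lambda^7 + 9 * c3 * lambda^6 +
    (27 * c3 - 6 * c2 + c1) * lambda^5 + (2 * c2 - 18 * c3) * lambda^4 +
    (-27 * c3 + 6 * c2 - c1) * lambda^2 + (36 * c3 - 4 * c2) * lambda -
    12 * c3
  p / lambda^3
}

# Stress from the stress-tensor relation with dPsi/dI1 obtained by central
# finite differencing of the strain energy (no analytic derivative reused).
sef_stress_fd <- function(lambda, params, h = 1e-6) {
  I1 <- lambda^2 + 2 / lambda
  dpsi <- (strain_energy(I1 + h, params) - strain_energy(I1 - h, params)) /
    (2 * h)
  2 * dpsi * (lambda^2 - 1 / lambda)
}

# Central-difference slope of the uniaxial stress.
stress_slope_fd <- function(lambda, params, h = 1e-7) {
  (uniaxial_stress(lambda + h, params) - uniaxial_stress(lambda - h, params)) /
    (2 * h)
}

random_params <- function(n = 1) {
  lapply(seq_len(n), function(i)
    yeoh_params(stats::runif(1, 0.1, 20), stats::runif(1, 0, 20),
                stats::runif(1, 0, 10000)))
}

# small clamped axisymmetric pig solution shared by FE tests
pig_slice_solution <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- rescale_to_circle(specimen_geometry("ellipse", a = 1.785, b = 1.14,
                                               length = 69, name = "pig"))
      bc <- boundary_conditions(
        stretch_to_displacement(seq(1.02, 1.08, by = 0.02), 69),
        symmetry = "axisymmetric")
      m <- generate_mesh(g, bc, resolution = c(6, 23))
      cache <<- solve_stretch(m, species_preset("pig")$params)
    }
    cache
  }
})
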