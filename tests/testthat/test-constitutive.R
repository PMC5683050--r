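test_that("strain energy is the cubic in (I1 - 3), zero at the reference state", {
  p <- yeoh_params(1, 2, 3)
  expect_equal(strain_energy(3, p), 0)
  expect_equal(strain_energy(4, yeoh_params(1, 0, 0)), 1)
  expect_equal(strain_energy(5, p), 1 * 2 + 2 * 4 + 3 * 8)  # 34 kPa by hand
  expect_error(strain_energy(2.5, p), "domain")
})

test_that("uniaxial kinematics: I1 = lambda^2 + 2/lambda, transverse 1/sqrt(lambda)", {
  k <- uniaxial_invariant(c(1, 2, 5))
  expect_equal(k$I1, c(3, 5, 25.4))
  expect_equal(k$lambda_transverse, 1 / sqrt(c(1, 2, 5)))
  expect_error(uniaxial_invariant(0), "positive")
  # incompressibility identity lambda_t^2 * lambda = 1, exactly
  lam <- seq(0.5, 6, by = 0.25)
  expect_equal(uniaxial_invariant(lam)$lambda_transverse^2 * lam,
               rep(1, length(lam)))
})

test_that("degree-9 coefficient vector matches its closed form and sums to zero", {
  expect_equal(unname(p9_coefficients(yeoh_params(0, 0, 1))),
               c(3, 0, -18, 9, 27, -18, 0, -27, 36, -12))
  k100 <- unname(p9_coefficients(yeoh_params(1, 0, 0)))
  expect_equal(k100, c(0, 0, 0, 0, 1, 0, 0, -1, 0, 0))  # only lambda^5 and lambda^2
  set.seed(1)
  for (p in random_params(5)) {
    expect_equal(sum(p9_coefficients(p)), 0)
    lam <- seq(0.5, 6, length.out = 23)
    expect_equal(uniaxial_stress(lam, p),
                 p9_stress_direct(lam, p$c1, p$c2, p$c3), tolerance = 1e-12)
  }
})

test_that("uniaxial stress vanishes at lambda = 1 and matches the frozen Aplysia value", {
  set.seed(2)
  for (p in random_params(5)) expect_equal(uniaxial_stress(1, p), 0)
  ap <- species_preset("aplysia")$params
  expect_equal(uniaxial_stress(5, ap), 210.7874, tolerance = 1e-6)
  expect_error(uniaxial_stress(-1, ap), "positive")
  # vectorized evaluation agrees with scalar loop
  lam <- c(1, 1.3, 2.7, 5)
  expect_equal(uniaxial_stress(lam, ap),
               vapply(lam, uniaxial_stress, 0, params = ap))
})

test_that("small-strain slope is 3 c1 (as printed) and 6 c1 (standard)", {
  p <- yeoh_params(7, 3, 1000)
  expect_equal(stress_slope_fd(1, p), 3 * 7, tolerance = 1e-5)
  ps <- yeoh_params(7, 3, 1000, convention = "standard")
  expect_equal(stress_slope_fd(1, ps), 6 * 7, tolerance = 1e-5)
})

test_that("stress-tensor derivation equals twice the printed form, for all params", {
  p100 <- yeoh_params(1, 0, 0)
  expect_equal(derive_stress_from_sef(2, p100), 7)  # 2 (4 - 1/2) by hand
  expect_equal(derive_stress_from_sef(1, yeoh_params(3, 2, 1)), 0)
  set.seed(3)
  for (p in random_params(8)) {
    lam <- stats::runif(5, 1.01, 5)
    expect_equal(derive_stress_from_sef(lam, p) / uniaxial_stress(lam, p),
                 rep(2, 5), tolerance = 1e-12)
    # and against the finite-difference oracle of the tensor relation
    expect_equal(derive_stress_from_sef(lam, p), sef_stress_fd(lam, p),
                 tolerance = 1e-6)
  }
  # standard convention equals the tensor derivation exactly
  p <- yeoh_params(4, 5, 600, convention = "standard")
  lam <- seq(1, 3, by = 0.5)
  expect_equal(uniaxial_stress(lam, p),
               derive_stress_from_sef(lam, yeoh_params(4, 5, 600)))
})

test_that("convention conversion preserves the stress curve", {
  p <- species_preset("pig")$params
  ps <- convert_convention(p, "standard")
  expect_equal(ps$c1, p$c1 / 2)
  lam <- seq(1, 1.08, by = 0.01)
  expect_equal(uniaxial_stress(lam, ps), uniaxial_stress(lam, p))
  expect_equal(as.numeric(convert_convention(ps, "as_printed")),
               as.numeric(p))
})

test_that("Drucker margin is positive for every species preset over its range", {
  for (nm in species_preset()) {
    sp <- species_preset(nm)
    expect_gt(drucker_margin(sp$params, c(1, sp$lambda_max)), 0)
  }
  expect_lt(drucker_margin(yeoh_params(-1, 0, 0), c(1, 1.1)), 0)
  expect_error(drucker_margin(yeoh_params(1, 1, 1), c(1.2, 1.1)), "lower < upper")
  # margin agrees with dense finite-difference slopes
  p <- species_preset("lobster")$params
  lam <- seq(1.0005, 1.4995, length.out = 200)
  expect_equal(drucker_margin(p, c(1, 1.5)),
               min(stress_slope_fd(lam, p)), tolerance = 1e-4)
})

test_that("species are strictly stress-increasing over their printed ranges", {
  for (nm in species_preset()) {
    sp <- species_preset(nm)
    lam <- seq(1, sp$lambda_max, length.out = 100)
    expect_true(all(diff(uniaxial_stress(lam, sp$params)) > 0))
  }
})

test_that("nominal stress conversion and parameter validation behave", {
  expect_equal(cauchy_to_nominal(10, 2), 5)
  expect_error(yeoh_params(1, NA, 3), "finite")
  expect_error(yeoh_params(Inf, 1, 3), "finite")
  expect_silent(yeoh_params(140, 140, 0))  # c3 = 0 allowed (lobster)
})

test_that("species presets are serialized to and from JSON faithfully", {
  path <- tempfile(fileext = ".json")
  presets <- lapply(species_preset(), species_preset)
  write_presets(presets, path)
  back <- read_presets(path)
  expect_named(back, species_preset())
  expect_equal(as.numeric(back$pig$params), as.numeric(species_preset("pig")$params))
  expect_equal(back$aplysia$lambda_max, 5)
})
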