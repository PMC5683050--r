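test_that("coefficient of determination follows its definition", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)  # 1 - 1/2 by hand
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(r_squared(1:3, 1:4), "equal-length")
})

test_that("noiseless curves recover every species' constants to 0.1%", {
  for (nm in species_preset()) {
    sp <- species_preset(nm)
    cu <- generate_curve(sp$params, sp$lambda_max, 50)
    fit <- fit_yeoh(cu)
    expect_lt(abs(fit$params$c1 - sp$params$c1) / max(sp$params$c1, 1e-12),
              1e-3)
    expect_lt(abs(fit$params$c3 - sp$params$c3) / max(sp$params$c3, 1e-3),
              1e-3)
    expect_gte(fit$r_squared, 0.999999)
    expect_true(fit$converged)
  }
})

test_that("the lobster curve identifies c3 = 0 under a wide bound", {
  sp <- species_preset("lobster")
  cu <- generate_curve(sp$params, 1.5, 50)
  fit <- fit_yeoh(cu, c3_bounds = c(0, 50000))
  expect_lt(fit$params$c3, 1)        # ~0 kPa against a 50 MPa-wide bound
  expect_equal(fit$params$c1, 140, tolerance = 1e-3)
})

test_that("pinning c3 via a degenerate bound gives a two-parameter fit", {
  sp <- species_preset("lobster")
  cu <- generate_curve(sp$params, 1.5, 40)
  fit <- fit_yeoh(cu, c3_bounds = c(0, 0))
  expect_identical(fit$params$c3, 0)
  expect_equal(fit$params$c1, 140, tolerance = 1e-6)
})

test_that("optimum is invariant to the choice among the five printed starts", {
  cu <- generate_curve(species_preset("pig")$params, 1.08, 50,
                       noise_spec(multiplicative_sd = 0.01, seed = 7))
  fits <- lapply(list(c(10, 0), c(12.99, 0), c(0, 12.40), c(0, 11.99)),
                 function(g) fit_yeoh(cu, guesses = list(g),
                                      c3_bounds = c(6000, 9000)))
  c1s <- vapply(fits, function(f) f$params$c1, 0)
  c3s <- vapply(fits, function(f) f$params$c3, 0)
  expect_lt(diff(range(c1s)) / mean(c1s), 1e-4)
  expect_lt(diff(range(c3s)) / mean(c3s), 1e-4)
})

test_that("tied c1 = c2 fit enforces the constraint exactly and a brute-force
           grid search lands in the same place", {
  cu <- generate_curve(species_preset("pig")$params, 1.08, 50,
                       noise_spec(multiplicative_sd = 0.01, seed = 99))
  fit <- fit_yeoh(cu, c3_bounds = c(0, 20000), tie_c1_c2 = TRUE)
  expect_identical(fit$params$c1, fit$params$c2)

  # independent oracle: dense grid over (c1 = c2, c3), residual sum of squares
  # from the printed polynomial directly
  c12g <- seq(3, 9, length.out = 200)
  c3g <- seq(6000, 9500, length.out = 200)
  ss <- vapply(c3g, function(c3) {
    vapply(c12g, function(c12)
      sum((cu$stress - p9_stress_direct(cu$lambda, c12, c12, c3))^2), 0)
  }, numeric(length(c12g)))
  ij <- which(ss == min(ss), arr.ind = TRUE)
  expect_lt(abs(fit$params$c1 - c12g[ij[1]]), diff(c12g[1:2]))
  expect_lt(abs(fit$params$c3 - c3g[ij[2]]), diff(c3g[1:2]))

  # maximizing R^2 and minimizing SS_res agree on the grid (SS_tot data-only)
  r2 <- 1 - ss / sum((cu$stress - mean(cu$stress))^2)
  expect_identical(which(ss == min(ss)), which(r2 == max(r2)))
})

test_that("1% multiplicative noise at n = 50 recovers c1 and c3 within 5%", {
  pg <- species_preset("pig")$params
  for (s in 1:3) {
    cu <- generate_curve(pg, 1.08, 50, noise_spec(multiplicative_sd = 0.01,
                                                  seed = s))
    fit <- fit_yeoh(cu, c3_bounds = c(6000, 9000), tie_c1_c2 = TRUE)
    expect_lt(abs(fit$params$c1 - pg$c1) / pg$c1, 0.05)
    expect_lt(abs(fit$params$c3 - pg$c3) / pg$c3, 0.05)
  }
})

test_that("fewer points than free parameters is refused", {
  cu <- data.frame(lambda = c(1, 1.1), stress = c(0, 1))
  expect_error(fit_yeoh(cu), "fewer data points")
})

test_that("fit object methods are coherent", {
  cu <- generate_curve(species_preset("rabbit")$params, 1.3, 30)
  fit <- fit_yeoh(cu)
  expect_named(coef(fit), c("c1", "c2", "c3"))
  expect_length(residuals(fit), 30)
  expect_equal(fitted(fit) + residuals(fit), cu$stress)
  expect_equal(predict(fit, data.frame(lambda = cu$lambda)), fitted(fit),
               tolerance = 1e-6)
  s <- summary(fit)
  expect_s3_class(s, "summary.yeoh_fit")
  expect_output(print(s), "Drucker margin")
  sim <- simulate(fit, nsim = 2, seed = 5)
  expect_length(sim, 2)
  expect_equal(nrow(sim[[1]]), 30)
  grDevices::pdf(NULL); on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
  rep_path <- tempfile(fileext = ".txt")
  write_fit_report(fit, rep_path)
  expect_true(any(grepl("r_squared", readLines(rep_path))))
})

test_that("sensitivity index follows the printed formula", {
  p <- yeoh_params(1, 1, 1)
  # degenerate ranges give SI = 0 everywhere
  rep0 <- sensitivity_index(p, list(), 1.5)
  expect_equal(unname(rep0$si), c(0, 0, 0))
  # hand-computable single-constant range
  s1 <- uniaxial_stress(1.5, yeoh_params(1, 1, 1))
  s0 <- uniaxial_stress(1.5, yeoh_params(0, 1, 1))
  rep1 <- sensitivity_index(p, list(c1 = c(0, 1)), 1.5)
  expect_equal(rep1$si[["c1"]], (s1 - s0) / s1)
  # joint positive rescaling leaves SI unchanged (stress linear in constants)
  k <- 7.3
  repk <- sensitivity_index(yeoh_params(k, k, k), list(c1 = k * c(0, 1)), 1.5)
  expect_equal(repk$si[["c1"]], rep1$si[["c1"]])
})

test_that("SI ordering over the per-extension pig ranges puts c2 lowest", {
  rep <- sensitivity_index(species_preset("pig")$params,
                           list(c1 = c(4.99, 6.49), c2 = c(4.99, 6.49),
                                c3 = c(7460, 8210)),
                           lambda_eval = 1.08)
  expect_lt(rep$si[["c2"]], rep$si[["c1"]])
  expect_lt(rep$si[["c2"]], rep$si[["c3"]])
})

test_that("constants correlation reproduces the printed extension statistics", {
  tab <- data.frame(c1 = c(4.99, 6.49, 6.20, 5.99, 4.99),
                    c2 = c(4.99, 6.49, 6.20, 5.99, 4.99),
                    c3 = c(8130, 7950, 7460, 7610, 8210))
  cc <- constants_correlation(tab)
  expect_equal(cc$r_squared[["c1_c2"]], 1)
  expect_equal(cc$r_squared[["c1_c3"]], 0.49, tolerance = 0.015)
  # hand-computed Pearson r of the printed vectors is about -0.70
  expect_equal(cc$pearson_r[["c1_c3"]], -0.7046, tolerance = 1e-3)
  expect_error(constants_correlation(data.frame(c1 = c(1, 1, 1),
                                                c2 = c(1, 2, 3),
                                                c3 = c(1, 2, 3))),
               "zero variance")
  expect_error(constants_correlation(tab[1:2, ]), "at least 3")
})
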