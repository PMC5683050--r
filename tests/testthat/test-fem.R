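# The homogeneous patch tests have an exact affine solution that bilinear /
# trilinear elements reproduce; they exercise every kernel term (including the
# axisymmetric hoop coupling) against the closed form.

test_that("axisymmetric patch test matches the closed form to 1e-6 relative", {
  g <- rescale_to_circle(specimen_geometry("ellipse", a = 1.785, b = 1.14,
                                           length = 69, name = "pig"))
  bc <- boundary_conditions(stretch_to_displacement(seq(1.02, 1.08, 0.02), 69),
                            moving_end_lateral = "free",
                            symmetry = "axisymmetric")
  m <- generate_mesh(g, bc, resolution = c(3, 8))
  sol <- solve_stretch(m, species_preset("pig")$params)
  rep <- compare_to_theory(sol)
  expect_lt(max(abs(rep$fe_kpa - rep$theory_kpa) / rep$theory_kpa), 1e-6)
  # exact kinematics: transverse stretch 1/sqrt(lambda), pointwise J = 1
  expect_lt(max(abs(rep$fe_lt - 1 / sqrt(rep$lambda))), 1e-6)
  expect_lt(max(sol$jdev_qp), 1e-6)
  expect_lt(max(abs(rep$lambda_local - rep$lambda)), 1e-9)
})

test_that("hexahedral patch test on the quarter ellipse is exact too", {
  g <- specimen_geometry("ellipse", a = 1.785, b = 1.14, length = 20)
  bc <- boundary_conditions(stretch_to_displacement(c(1.02, 1.04), 20),
                            moving_end_lateral = "free", symmetry = "quarter")
  m <- generate_mesh(g, bc, resolution = c(2, 4))
  sol <- solve_stretch(m, species_preset("pig")$params)
  rep <- compare_to_theory(sol)
  expect_lt(max(abs(rep$fe_kpa - rep$theory_kpa) / rep$theory_kpa), 1e-6)
  expect_lt(max(abs(rep$fe_lt_x - 1 / sqrt(rep$lambda))), 1e-6)
  expect_lt(max(abs(rep$fe_lt_y - 1 / sqrt(rep$lambda))), 1e-6)
  expect_lt(max(sol$jdev_qp), 1e-6)
})

test_that("a lambda = 1 step returns the zero solution", {
  g <- specimen_geometry("circle", r = 1, length = 5)
  bc <- boundary_conditions(0.1, symmetry = "axisymmetric")
  m <- generate_mesh(g, bc, resolution = c(2, 4))
  sol <- solve_stretch(m, species_preset("pig")$params, lambda_targets = 1)
  expect_lt(max(abs(sol$U[[1]])), 1e-7)      # zero displacement (solver noise)
  f <- compare_to_theory(sol)
  expect_lt(abs(f$fe_kpa), 1e-5)             # zero stress (kPa)
  expect_true(is.na(f$pct_err))
})

test_that("clamped pig slice agrees with theory at the attained local stretch", {
  sol <- pig_slice_solution()
  rep <- compare_to_theory(sol)
  expect_lt(max(abs(rep$pct_err)), 0.05)
  expect_lt(max(abs(rep$dlt)), 1e-4)
  # clamp redistribution: local stretch exceeds nominal, and the nominal-
  # reference comparison shows the (physical) boundary-layer effect
  expect_true(all(rep$lambda_local > rep$lambda))
  repn <- compare_to_theory(sol, reference = "nominal")
  expect_gt(max(abs(repn$pct_err)), max(abs(rep$pct_err)))
  # element-mean incompressibility at every stored step
  expect_lt(max(sol$jbar_dev), 1e-6)
  # blocked end keeps its radius: transverse stretch -> 1 at the clamp
  k <- length(sol$lambda)
  top <- sol$mesh$node_sets$moving_end
  expect_equal(max(abs(sol$U[[k]][top, 1])), 0)
})

test_that("quarter and full 3-D models coincide nodewise", {
  g <- specimen_geometry("ellipse", a = 1.785, b = 1.14, length = 69)
  lamt <- c(1.01, 1.02)
  bcq <- boundary_conditions(stretch_to_displacement(lamt, 69),
                             symmetry = "quarter")
  bcf <- boundary_conditions(stretch_to_displacement(lamt, 69),
                             symmetry = "full")
  mq <- generate_mesh(g, bcq, resolution = c(2, 8))
  mf <- generate_mesh(g, bcf, resolution = c(2, 8))
  pg <- species_preset("pig")$params
  sq <- solve_stretch(mq, pg)
  sf <- solve_stretch(mf, pg)
  key <- function(M) paste(round(abs(M[, 1]), 9), round(abs(M[, 2]), 9),
                           round(M[, 3], 9))
  idx <- match(key(mf$nodes), key(mq$nodes))
  expect_false(anyNA(idx))   # every full node has a quarter image
  uq <- sq$U[[2]][idx, ]; uf <- sf$U[[2]]
  err <- max(abs(abs(uq[, 1]) - abs(uf[, 1])),
             abs(abs(uq[, 2]) - abs(uf[, 2])),
             abs(uq[, 3] - uf[, 3]))
  expect_lt(err, 1e-9)
})

test_that("elliptic and area-equivalent circular 3-D models agree within 0.1%", {
  ge <- specimen_geometry("ellipse", a = 1.785, b = 1.14, length = 69)
  gc <- rescale_to_circle(ge)
  bc <- boundary_conditions(stretch_to_displacement(c(1.01, 1.02), 69),
                            symmetry = "quarter")
  pg <- species_preset("pig")$params
  se <- solve_stretch(generate_mesh(ge, bc, resolution = c(2, 8)), pg)
  sc <- solve_stretch(generate_mesh(gc, bc, resolution = c(2, 8)), pg)
  me <- midlength_stress_strain(se)
  mc <- midlength_stress_strain(sc)
  expect_lt(max(abs(me$sigma_fe - mc$sigma_fe) / mc$sigma_fe), 0.001)
})

test_that("mid-length error decreases under mesh refinement (stubby specimen)", {
  # short specimen (L = 8 mm ~ 5.6 radii) so clamp layers genuinely reach
  # mid-length and refinement has something to converge
  g <- specimen_geometry("circle", r = 1.4265, length = 8)
  pg <- species_preset("pig")$params
  errs <- vapply(list(c(3, 8), c(6, 16), c(12, 32)), function(res) {
    bc <- boundary_conditions(stretch_to_displacement(1.04, 8),
                              symmetry = "axisymmetric")
    m <- generate_mesh(g, bc, resolution = res)
    sol <- solve_stretch(m, pg, lambda_targets = c(1.02, 1.04))
    max(abs(compare_to_theory(sol)$pct_err))
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("penalty formulation reproduces the mixed solution", {
  g <- rescale_to_circle(specimen_geometry("ellipse", a = 1.785, b = 1.14,
                                           length = 69))
  bc <- boundary_conditions(stretch_to_displacement(c(1.02, 1.04), 69),
                            symmetry = "axisymmetric")
  m <- generate_mesh(g, bc, resolution = c(4, 12))
  pg <- species_preset("pig")$params
  rm_ <- compare_to_theory(solve_stretch(m, pg))
  rp <- compare_to_theory(solve_stretch(m, pg, formulation = "penalty"))
  expect_lt(max(abs(rm_$fe_kpa - rp$fe_kpa) / rm_$fe_kpa), 1e-4)
})

test_that("solver input validation and failure reporting", {
  g <- specimen_geometry("circle", r = 1, length = 5)
  bc <- boundary_conditions(0.5, symmetry = "axisymmetric")
  m <- generate_mesh(g, bc, resolution = c(2, 4))
  pg <- species_preset("pig")$params
  expect_error(solve_stretch(m, pg, lambda_targets = c(1.2, 1.1)),
               "increasing")
  expect_error(solve_stretch(m, pg, lambda_targets = c(0.8, 1.1)),
               "increasing|>= 1")
})

test_that("solution summaries and plots render", {
  sol <- pig_slice_solution()
  expect_output(print(sol), "load steps")
  s <- summary(sol)
  expect_output(print(s), "stress error")
  grDevices::pdf(NULL); on.exit(grDevices::dev.off())
  expect_silent(plot(sol))
  q <- attr(compare_to_theory(sol), "nodal_quantiles")
  expect_length(q, 101)
  expect_true(all(diff(q) >= 0))
})

test_that("VTK and comparison CSV exports are well-formed", {
  sol <- pig_slice_solution()
  vtk <- tempfile(fileext = ".vtk")
  write_vtk(sol, vtk)
  lines <- readLines(vtk)
  expect_identical(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^POINTS 168 double", lines)))
  expect_true(any(grepl("^CELLS 138 690", lines)))
  expect_true(any(grepl("VECTORS displacement", lines)))
  csv <- tempfile(fileext = ".csv")
  write_comparison_csv(compare_to_theory(sol), csv)
  expect_identical(readLines(csv, n = 1),
                   "lambda,theory_kpa,fe_kpa,pct_err,theory_lt,fe_lt,dlt")
})
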