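# Post-processing of FE solutions: mid-length stress/stretch extraction,
# theory-vs-simulation comparison reports, nodal stress fields, VTK export.

# Quadrature-point fields for one stored step: columns elem, x1, x2, x3, w, J,
# I1, s11, s22, s33, s12, s13, s23 (axisymmetric: x1=R, x2=Z, s22 axial;
# hexahedral: x3=Z, s33 axial).
.step_fields <- function(sol, step) {
  pint <- sol$params_internal
  .fem_fields(sol$mesh$nodes, sol$mesh$elems, sol$U[[step]], sol$P[[step]],
              sol$kappa, pint$c1, pint$c2, pint$c3,
              .mesh_kind_int(sol$mesh),
              if (sol$formulation == "mixed") 0L else 1L,
              sol$kstab %||% 0)
}

.axial_cols <- function(mesh) {
  if (mesh$kind == "axi4") list(z = 3L, s = 9L) else list(z = 4L, s = 10L)
}

#' Mid-length stress and transverse stretch of an FE solution
#'
#' The axial Cauchy stress is averaged (volume-weighted) over the quadrature
#' points of the element layer nearest mid-length — the region farthest from
#' both clamps, where the Saint-Venant boundary layers have decayed.  The
#' transverse stretch is taken from the lateral displacement of the mid-length
#' outer-surface nodes: `1 + u_r / r` for the axisymmetric slice, and
#' `1 + u_x / a`, `1 + u_y / b` at the section-axis ends for 3-D models.
#'
#' @param sol An [solve_stretch()] solution.
#' @return A data frame with one row per stored load step: `lambda` (imposed
#'   nominal stretch), `lambda_local` (volume-weighted axial stretch attained
#'   in the sampling band, slightly above nominal for clamped models),
#'   `sigma_fe` (kPa), and `lt_fe` (plus `lt_x`, `lt_y` for 3-D meshes, with
#'   `lt_fe` their mean).
#' @export
midlength_stress_strain <- function(sol) {
  stopifnot(inherits(sol, "fe_solution"))
  if (!length(sol$U)) stop("solution holds no converged steps")
  mesh <- sol$mesh
  L <- mesh$geom$length
  cols <- .axial_cols(mesh)
  dim <- .mesh_dim(mesh)

  # element layer nearest mid-length, from reference qp coordinates (step 1)
  f1 <- .step_fields(sol, 1L)
  ez <- tapply(f1[, cols$z], f1[, 1], mean)
  band_z <- ez[which.min(abs(ez - L / 2))]
  band_el <- as.numeric(names(ez)[abs(ez - band_z) < 1e-9])

  # mid-length outer-surface nodes
  ns <- mesh$node_sets
  if (mesh$kind == "axi4") {
    cand <- ns$outer
    n_out <- cand[which.min(abs(mesh$nodes[cand, 2] - L / 2))]
    r_out <- mesh$nodes[n_out, 1]
  } else {
    na <- ns$axis_a[which.min(abs(mesh$nodes[ns$axis_a, 3] - L / 2))]
    nb <- ns$axis_b[which.min(abs(mesh$nodes[ns$axis_b, 3] - L / 2))]
    a_out <- mesh$nodes[na, 1]; b_out <- mesh$nodes[nb, 2]
  }

  out <- lapply(seq_along(sol$lambda), function(k) {
    f <- .step_fields(sol, k)
    sel <- f[, 1] %in% band_el
    w <- f[sel, 5]
    sig <- sum(f[sel, cols$s] * w) / sum(w)
    lam_loc <- sum(f[sel, 14] * w) / sum(w)   # axial stretch attained in band
    if (mesh$kind == "axi4") {
      lt <- 1 + sol$U[[k]][n_out, 1] / r_out
      data.frame(lambda = sol$lambda[k], lambda_local = lam_loc,
                 sigma_fe = sig, lt_fe = lt)
    } else {
      ltx <- 1 + sol$U[[k]][na, 1] / a_out
      lty <- 1 + sol$U[[k]][nb, 2] / b_out
      data.frame(lambda = sol$lambda[k], lambda_local = lam_loc,
                 sigma_fe = sig, lt_fe = (ltx + lty) / 2,
                 lt_x = ltx, lt_y = lty)
    }
  })
  do.call(rbind, out)
}

#' Compare an FE solution with the closed-form uniaxial response
#'
#' Tabulates, per stored load step, the theoretical axial Cauchy stress
#' [uniaxial_stress()], the FE mid-length stress, the percent stress error
#' \eqn{100 (\sigma_{FE} - \sigma_{th}) / \sigma_{th}} (undefined and `NA`
#' at \eqn{\lambda = 1}), the theoretical transverse stretch
#' \eqn{1/\sqrt{\lambda}}, the FE transverse stretch, and their difference.
#' For 3-D models both section axes are reported (`dlt` is the
#' larger-magnitude difference).  Nodal axial-stress quantiles at the final
#' step are attached as attribute `"nodal_quantiles"`.
#'
#' With clamped ends the specimen's end layers cannot contract and therefore
#' barely stretch, so the mid-length section attains a slightly larger axial
#' stretch than the imposed nominal `d/L + 1`.  The default
#' `reference = "local"` evaluates the closed form at the stretch actually
#' attained in the sampling band (`lambda_local`), which verifies that the FE
#' response reproduces the constitutive closed form; `reference = "nominal"`
#' evaluates it at the imposed stretch instead, which additionally counts the
#' (physical, mesh-converged) clamp redistribution as error.
#'
#' @param sol An [solve_stretch()] solution.
#' @param params Parameters for the theory curve; defaults to the solution's
#'   own (convention respected).
#' @param reference `"local"` (default) or `"nominal"`: the stretch at which
#'   the theory curve is evaluated per step.
#' @return A data frame of class `"fe_comparison"` with columns `lambda`,
#'   `lambda_local`, `theory_kpa`, `fe_kpa`, `pct_err`, `theory_lt`, `fe_lt`,
#'   `dlt` (and `fe_lt_x`, `fe_lt_y`, `dlt_x`, `dlt_y` for 3-D meshes).
#' @export
compare_to_theory <- function(sol, params = NULL,
                              reference = c("local", "nominal")) {
  stopifnot(inherits(sol, "fe_solution"))
  reference <- match.arg(reference)
  if (is.null(params)) params <- sol$params
  ml <- midlength_stress_strain(sol)
  lam <- if (reference == "local") ml$lambda_local else ml$lambda
  th <- uniaxial_stress(lam, params)
  pct <- ifelse(ml$lambda > 1 & abs(lam - 1) > 1e-12,
                100 * (ml$sigma_fe - th) / th, NA_real_)
  th_lt <- 1 / sqrt(lam)
  rep <- data.frame(lambda = ml$lambda, lambda_local = ml$lambda_local,
                    theory_kpa = th, fe_kpa = ml$sigma_fe,
                    pct_err = pct, theory_lt = th_lt)
  if (!is.null(ml$lt_x)) {
    dx <- ml$lt_x - th_lt; dy <- ml$lt_y - th_lt
    worse <- abs(dx) >= abs(dy)
    rep$fe_lt <- ifelse(worse, ml$lt_x, ml$lt_y)
    rep$dlt <- ifelse(worse, dx, dy)
    rep$fe_lt_x <- ml$lt_x; rep$fe_lt_y <- ml$lt_y
    rep$dlt_x <- dx; rep$dlt_y <- dy
  } else {
    rep$fe_lt <- ml$lt_fe
    rep$dlt <- ml$lt_fe - th_lt
  }
  attr(rep, "nodal_quantiles") <-
    stats::quantile(nodal_stress(sol, length(sol$lambda)),
                    probs = seq(0, 1, 0.01), names = TRUE)
  class(rep) <- c("fe_comparison", "data.frame")
  rep
}

#' Nodal axial Cauchy stress field
#'
#' Quadrature-point axial stresses averaged element-by-element and scattered to
#' the element nodes (count-averaged) — the usual nodal extrapolation used for
#' stress-distribution (quantile) plots.
#'
#' @param sol An [solve_stretch()] solution.
#' @param step Stored step index (default: last).
#' @return Numeric vector of nodal axial stress (kPa), one value per mesh node.
#' @export
nodal_stress <- function(sol, step = length(sol$lambda)) {
  stopifnot(inherits(sol, "fe_solution"))
  mesh <- sol$mesh
  f <- .step_fields(sol, step)
  scol <- .axial_cols(mesh)$s
  es <- tapply(f[, scol], f[, 1], mean)      # per-element mean axial stress
  acc <- numeric(nrow(mesh$nodes)); cnt <- numeric(nrow(mesh$nodes))
  for (e in seq_len(nrow(mesh$elems))) {
    nd <- mesh$elems[e, ]
    acc[nd] <- acc[nd] + es[[e]]
    cnt[nd] <- cnt[nd] + 1
  }
  acc / pmax(cnt, 1)
}

#' Write a comparison report to CSV
#'
#' Columns `lambda,theory_kpa,fe_kpa,pct_err,theory_lt,fe_lt,dlt`.
#'
#' @param report A [compare_to_theory()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(report, path) {
  cols <- c("lambda", "theory_kpa", "fe_kpa", "pct_err",
            "theory_lt", "fe_lt", "dlt")
  utils::write.csv(as.data.frame(report)[, cols], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export an FE solution step as legacy ASCII VTK
#'
#' Writes the mesh with nodal displacement vectors, nodal axial Cauchy stress
#' and element pressure for inspection in ParaView-compatible viewers.
#'
#' @param sol An [solve_stretch()] solution.
#' @param path Output `.vtk` path.
#' @param step Stored step index (default: last).
#' @return `path`, invisibly.
#' @export
write_vtk <- function(sol, path, step = length(sol$lambda)) {
  stopifnot(inherits(sol, "fe_solution"))
  mesh <- sol$mesh
  nn <- nrow(mesh$nodes); nel <- nrow(mesh$elems)
  nen <- ncol(mesh$elems)
  pts <- cbind(mesh$nodes, matrix(0, nn, 3 - ncol(mesh$nodes)))
  U <- cbind(sol$U[[step]], matrix(0, nn, 3 - ncol(sol$U[[step]])))
  ctype <- if (mesh$kind == "axi4") 9L else 12L   # VTK_QUAD / VTK_HEXAHEDRON
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("nervestretch step %d (lambda = %g)", step,
                       sol$lambda[step]),
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  utils::write.table(format(pts, digits = 12), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", nel, nel * (nen + 1)), con)
  utils::write.table(cbind(nen, mesh$elems - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", nel), con)
  writeLines(as.character(rep(ctype, nel)), con)
  writeLines(c(sprintf("POINT_DATA %d", nn),
               "VECTORS displacement double"), con)
  utils::write.table(format(U, digits = 12), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  writeLines(c("SCALARS axial_stress_kpa double 1",
               "LOOKUP_TABLE default"), con)
  writeLines(format(nodal_stress(sol, step), digits = 12), con)
  writeLines(c(sprintf("CELL_DATA %d", nel),
               "SCALARS pressure_kpa double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(sol$P[[step]], digits = 12), con)
  invisible(path)
}
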