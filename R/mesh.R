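# Structured meshes for the reduced-order specimen models.
#
# 3-D elliptic/circular cylinders use the concentric square-to-disk map
# (scaled by the semi-axes): for |u| >= |v|, rho = |u|, phi = (pi/4) v/u, and
# symmetrically for |v| > |u|; then x = a rho cos(phi), y = b rho sin(phi).
# Boundary nodes lie exactly on the ellipse and element Jacobians stay bounded
# away from zero everywhere (no degenerate corner).  The 2-D axisymmetric
# slice is the rectangle [0, r] x [0, L] in (radial, axial) coordinates.

.ellipse_map <- function(u, v, a, b) {
  au <- abs(u); av <- abs(v)
  rho <- pmax(au, av)
  phi <- ifelse(rho == 0, 0,
         ifelse(au >= av, (pi / 4) * av / pmax(au, 1e-300),
                pi / 2 - (pi / 4) * au / pmax(av, 1e-300)))
  cbind(sign(u) * a * rho * cos(phi), sign(v) * b * rho * sin(phi))
}

#' Generate a structured mesh for a stretch simulation
#'
#' Builds the mesh matching the symmetry reduction in `bc`:
#' `"axisymmetric"` gives a bilinear quadrilateral grid of the radial-axial
#' rectangle (circular sections only), `"quarter"` a trilinear hexahedral grid
#' of one quadrant of the (elliptic or circular) cylinder with symmetry node
#' sets on the two cut planes, `"full"` the whole cylinder.
#'
#' @param geom A [specimen_geometry()].
#' @param bc A [boundary_conditions()]; its `symmetry` selects the reduction
#'   and the set is stored on the mesh for the solver.
#' @param resolution Integer 2-vector `c(n_section, n_axial)`: elements across
#'   the section (per radius / per quadrant direction) and along the axis.
#' @return An object of class `"fe_mesh"`: list with `nodes` (mm), `elems`
#'   (1-based connectivity), `kind` (`"axi4"` or `"hex8"`), `node_sets`
#'   (named index vectors: `fixed_end`, `moving_end`, and `axis` /
#'   `sym_x`, `sym_y` / `outer`, `axis_a`, `axis_b` as applicable), `geom`,
#'   `bc`.
#' @examples
#' g <- rescale_to_circle(specimen_geometry("ellipse", a = 1.785, b = 1.14,
#'                                          length = 69))
#' bc <- boundary_conditions(stretch_to_displacement(1.08, 69),
#'                           symmetry = "axisymmetric")
#' m <- generate_mesh(g, bc, resolution = c(6, 23))
#' @export
generate_mesh <- function(geom, bc, resolution = c(6L, 23L)) {
  stopifnot(inherits(geom, "specimen_geometry"),
            inherits(bc, "boundary_conditions"))
  ns <- as.integer(resolution[1]); nz <- as.integer(resolution[2])
  if (ns < 1 || nz < 1) stop("resolution must be positive element counts")
  L <- geom$length
  if (bc$symmetry == "axisymmetric") {
    if (geom$section != "circle")
      stop("axisymmetric reduction requires a circular section; ",
           "use rescale_to_circle() first")
    r <- geom$a
    rr <- seq(0, r, length.out = ns + 1)
    zz <- seq(0, L, length.out = nz + 1)
    nodes <- cbind(rep(rr, times = nz + 1), rep(zz, each = ns + 1))
    idx <- function(i, k) (k - 1L) * (ns + 1L) + i
    e <- expand.grid(i = seq_len(ns), k = seq_len(nz))
    elems <- cbind(idx(e$i, e$k), idx(e$i + 1L, e$k),
                   idx(e$i + 1L, e$k + 1L), idx(e$i, e$k + 1L))
    sets <- list(fixed_end = which(nodes[, 2] == 0),
                 moving_end = which(nodes[, 2] == L),
                 axis = which(nodes[, 1] == 0),
                 outer = which(nodes[, 1] == r))
    kind <- "axi4"
  } else {
    quarter <- bc$symmetry == "quarter"
    uu <- if (quarter) seq(0, 1, length.out = ns + 1)
          else seq(-1, 1, length.out = 2L * ns + 1)
    nu <- length(uu)
    g2 <- expand.grid(u = uu, v = uu)
    xy <- .ellipse_map(g2$u, g2$v, geom$a, geom$b)
    zz <- seq(0, L, length.out = nz + 1)
    nodes <- cbind(rep(xy[, 1], times = nz + 1), rep(xy[, 2], times = nz + 1),
                   rep(zz, each = nrow(xy)))
    idx <- function(i, j, k) ((k - 1L) * nu + (j - 1L)) * nu + i
    e <- expand.grid(i = seq_len(nu - 1L), j = seq_len(nu - 1L),
                     k = seq_len(nz))
    elems <- cbind(idx(e$i, e$j, e$k),        idx(e$i + 1L, e$j, e$k),
                   idx(e$i + 1L, e$j + 1L, e$k), idx(e$i, e$j + 1L, e$k),
                   idx(e$i, e$j, e$k + 1L),   idx(e$i + 1L, e$j, e$k + 1L),
                   idx(e$i + 1L, e$j + 1L, e$k + 1L), idx(e$i, e$j + 1L, e$k + 1L))
    un <- rep(rep(g2$u, times = nz + 1), 1)
    vn <- rep(rep(g2$v, times = nz + 1), 1)
    on_outer <- abs(abs(un) - 1) < 1e-12 | abs(abs(vn) - 1) < 1e-12
    sets <- list(fixed_end = which(nodes[, 3] == 0),
                 moving_end = which(nodes[, 3] == L),
                 outer = which(on_outer),
                 axis_a = which(abs(un - 1) < 1e-12 & abs(vn) < 1e-12),
                 axis_b = which(abs(un) < 1e-12 & abs(vn - 1) < 1e-12))
    if (quarter) {
      sets$sym_x <- which(abs(un) < 1e-12)  # x = 0 plane: block x
      sets$sym_y <- which(abs(vn) < 1e-12)  # y = 0 plane: block y
    }
    kind <- "hex8"
  }
  mesh <- structure(list(nodes = nodes, elems = elems, kind = kind,
                         node_sets = sets, geom = geom, bc = bc),
                    class = "fe_mesh")
  if (min_jacobian(mesh) <= 0)
    stop("generated mesh has a non-positive Jacobian")  # not reachable for these grids
  mesh
}

#' Minimum reference Jacobian determinant of a mesh
#'
#' @param mesh An [generate_mesh()] result.
#' @return Minimum `det(J)` over all quadrature points; positive for a valid
#'   mesh.
#' @export
min_jacobian <- function(mesh) {
  stopifnot(inherits(mesh, "fe_mesh"))
  .fem_min_detj(mesh$nodes, mesh$elems, if (mesh$kind == "axi4") 0L else 1L)
}

#' @method print fe_mesh
#' @export
print.fe_mesh <- function(x, ...) {
  cat(sprintf("FE mesh (%s, %s symmetry): %d nodes, %d elements\n",
              x$kind, x$bc$symmetry, nrow(x$nodes), nrow(x$elems)))
  invisible(x)
}
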