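#' Stress-stretch curve for one extension
#'
#' Ordered samples of a tensile test: stretch ratios and the corresponding
#' stresses in kPa, tagged with the extension number and the stress measure.
#'
#' @param lambda Strictly increasing stretch ratios, first value `>= 1`,
#'   at least 4 points.
#' @param stress Stresses in kPa, same length as `lambda`.
#' @param extension_id Integer label of the extension (loading cycle).
#' @param stress_measure `"cauchy"` (default) or `"nominal"`.
#' @return An object of class `"stress_stretch_curve"` (also a data frame with
#'   columns `lambda`, `stress`).
#' @export
stress_stretch_curve <- function(lambda, stress, extension_id = 1L,
                                 stress_measure = c("cauchy", "nominal")) {
  stress_measure <- match.arg(stress_measure)
  if (length(lambda) != length(stress)) stop("lambda and stress lengths differ")
  if (length(lambda) < 4) stop("a curve needs at least 4 points")
  if (is.unsorted(lambda, strictly = TRUE)) stop("lambda must be strictly increasing")
  if (lambda[1] < 1) stop("first stretch must be >= 1")
  out <- data.frame(lambda = as.numeric(lambda), stress = as.numeric(stress))
  attr(out, "extension_id") <- as.integer(extension_id)
  attr(out, "stress_measure") <- stress_measure
  class(out) <- c("stress_stretch_curve", "data.frame")
  out
}

#' Read stress-stretch curves from CSV
#'
#' The file dialect is comma-separated UTF-8 with header
#' `stretch,stress_kpa[,extension]`; the optional third column separates
#' extensions of a multi-extension experiment.
#'
#' @param path CSV file path.
#' @param stress_measure Stress measure tag to attach to the curves.
#' @return A list of [stress_stretch_curve()] objects, one per extension, in
#'   increasing extension order.
#' @export
read_curves <- function(path, stress_measure = "cauchy") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stretch", "stress_kpa")
  if (!all(need %in% names(d))) {
    bad <- setdiff(need, names(d))
    stop("malformed curve CSV '", path, "': missing column(s) ",
         paste(bad, collapse = ", "), " in header (line 1)")
  }
  if (!("extension" %in% names(d))) d$extension <- 1L
  d$stretch <- suppressWarnings(as.numeric(d$stretch))
  d$stress_kpa <- suppressWarnings(as.numeric(d$stress_kpa))
  bad <- which(!is.finite(d$stretch) | !is.finite(d$stress_kpa))
  if (length(bad))
    stop("malformed curve CSV '", path, "': non-numeric data at line ", bad[1] + 1L)
  ids <- sort(unique(d$extension))
  lapply(ids, function(id) {
    di <- d[d$extension == id, ]
    di <- di[order(di$stretch), ]
    stress_stretch_curve(di$stretch, di$stress_kpa, extension_id = id,
                         stress_measure = stress_measure)
  })
}

#' Write stress-stretch curves to CSV
#'
#' @param curves A single curve or list of [stress_stretch_curve()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @rdname read_curves
#' @export
write_curves <- function(curves, path) {
  if (inherits(curves, "stress_stretch_curve")) curves <- list(curves)
  d <- do.call(rbind, lapply(curves, function(cu) {
    data.frame(stretch = cu$lambda, stress_kpa = cu$stress,
               extension = attr(cu, "extension_id"))
  }))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
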