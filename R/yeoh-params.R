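#' Yeoh material constants for nervous tissue
#'
#' Container for the three constants of the reduced (first-invariant only)
#' Yeoh strain energy function
#' \deqn{\Psi(I_1) = c_1 (I_1 - 3) + c_2 (I_1 - 3)^2 + c_3 (I_1 - 3)^3,}
#' all expressed in kPa.  The `convention` flag records which uniaxial stress
#' formula the constants belong to:
#'
#' * `"as_printed"` (default): the closed-form axial Cauchy stress is
#'   \eqn{\sigma_z = \wp^{[9]}(\lambda)/\lambda^3}, the degree-9 polynomial
#'   form in which published nerve constants are reported.
#' * `"standard"`: the textbook incompressible uniaxial stress
#'   \eqn{\sigma_z = 2\,\Psi'(I_1)(\lambda^2 - 1/\lambda)}, which is exactly
#'   twice the `"as_printed"` value for the same constants.
#'
#' The two conventions differ by an exact factor of two; constants fitted under
#' one convention equal twice the constants fitted under the other.  See
#' [convert_convention()].
#'
#' @param c1,c2,c3 Material constants in kPa.  All must be finite; `c3 = 0` is
#'   allowed (lobster nerve behaves quadratically in `I1 - 3`).
#' @param convention Either `"as_printed"` or `"standard"`.
#' @return An object of class `"yeoh_params"`: a named list with fields
#'   `c1`, `c2`, `c3` (kPa) and `convention`.
#' @examples
#' p <- yeoh_params(5.89, 5.89, 7750)
#' uniaxial_stress(1.08, p)
#' @export
yeoh_params <- function(c1, c2, c3, convention = c("as_printed", "standard")) {
  convention <- match.arg(convention)
  vals <- c(c1 = c1, c2 = c2, c3 = c3)
  if (!all(is.finite(vals)))
    stop("Yeoh constants must all be finite, got (",
         paste(signif(vals, 6), collapse = ", "), ")")
  structure(list(c1 = as.numeric(c1), c2 = as.numeric(c2), c3 = as.numeric(c3),
                 convention = convention),
            class = "yeoh_params")
}

#' @method print yeoh_params
#' @export
print.yeoh_params <- function(x, ...) {
  cat("Yeoh constants (kPa):\n")
  cat(sprintf("  c1 = %g, c2 = %g, c3 = %g   [%s convention]\n",
              x$c1, x$c2, x$c3, x$convention))
  invisible(x)
}

# as.numeric() dispatches through as.double methods
#' @export
as.double.yeoh_params <- function(x, ...) c(c1 = x$c1, c2 = x$c2, c3 = x$c3)

is_yeoh_params <- function(x) inherits(x, "yeoh_params")

#' Convert Yeoh constants between stress conventions
#'
#' The `"as_printed"` uniaxial stress is exactly half of the `"standard"`
#' (textbook) stress for equal constants, so converting a parameter set from
#' one convention to the other while preserving the predicted stress-stretch
#' curve means halving or doubling the constants.
#'
#' @param params A [yeoh_params()] object.
#' @param to Target convention.
#' @return A `yeoh_params` object in the target convention that predicts the
#'   same uniaxial stress as `params`.
#' @export
convert_convention <- function(params, to = c("standard", "as_printed")) {
  stopifnot(is_yeoh_params(params))
  to <- match.arg(to)
  if (params$convention == to) return(params)
  f <- if (to == "standard") 0.5 else 2   # printed constants / 2 give the same curve under the textbook formula
  yeoh_params(f * params$c1, f * params$c2, f * params$c3, convention = to)
}

# Published species constants, all converted to kPa.  lambda_max is the largest
# stretch each data set covers.
.species_table <- list(
  pig     = list(c1 = 5.89,   c2 = 5.89,   c3 = 7750,  lambda_max = 1.08,
                 source_units = "c1,c2 kPa; c3 MPa"),
  rabbit  = list(c1 = 200,    c2 = 200,    c3 = 43700, lambda_max = 1.3,
                 source_units = "MPa"),
  lobster = list(c1 = 140,    c2 = 140,    c3 = 0,     lambda_max = 1.5,
                 source_units = "MPa"),
  aplysia = list(c1 = 0.0081, c2 = 0.0081, c3 = 0.0054, lambda_max = 5,
                 source_units = "kPa")
)

#' Species presets for nerve stress-stretch behaviour
#'
#' Published Yeoh constants (converted to kPa, `"as_printed"` convention) and
#' the stretch range over which each species' nerve was characterised:
#' pig peroneal nerve to \eqn{\lambda = 1.08}, rabbit to 1.3, lobster to 1.5
#' (with \eqn{c_3 = 0}), and the *Aplysia* cerebro-abdominal connective to 5.
#'
#' @param name One of `"pig"`, `"rabbit"`, `"lobster"`, `"aplysia"`, or `NULL`
#'   to list all preset names.
#' @return For a single name, a list with elements `name`, `params`
#'   (a [yeoh_params()]), `lambda_max` and `source_units`; for `NULL`, a
#'   character vector of available names.
#' @examples
#' species_preset("pig")$params
#' @export
species_preset <- function(name = NULL) {
  if (is.null(name)) return(names(.species_table))
  name <- match.arg(tolower(name), names(.species_table))
  s <- .species_table[[name]]
  list(name = name,
       params = yeoh_params(s$c1, s$c2, s$c3),
       lambda_max = s$lambda_max,
       source_units = s$source_units)
}

#' Read or write species presets as JSON
#'
#' Presets are exchanged as a JSON array of records with fields `name`,
#' `c1_kpa`, `c2_kpa`, `c3_kpa`, `lambda_max`.
#'
#' @param path File path.
#' @param presets For writing: a list of preset lists as returned by
#'   [species_preset()].
#' @return `read_presets()` returns a named list of presets; `write_presets()`
#'   returns `path` invisibly.
#' @export
read_presets <- function(path) {
  rec <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  out <- lapply(seq_len(nrow(rec)), function(i) {
    list(name = rec$name[i],
         params = yeoh_params(rec$c1_kpa[i], rec$c2_kpa[i], rec$c3_kpa[i]),
         lambda_max = rec$lambda_max[i],
         source_units = "kPa")
  })
  names(out) <- rec$name
  out
}

#' @rdname read_presets
#' @export
write_presets <- function(presets, path) {
  if (!is.null(presets$params)) presets <- list(presets)
  rec <- data.frame(
    name = vapply(presets, `[[`, "", "name"),
    c1_kpa = vapply(presets, function(p) p$params$c1, 0),
    c2_kpa = vapply(presets, function(p) p$params$c2, 0),
    c3_kpa = vapply(presets, function(p) p$params$c3, 0),
    lambda_max = vapply(presets, `[[`, 0, "lambda_max"))
  jsonlite::write_json(rec, path, digits = NA, pretty = TRUE)
  invisible(path)
}
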