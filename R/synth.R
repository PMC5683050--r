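# Synthetic stress-stretch data with the statistical structure of the
# multi-extension nerve experiments: the deterministic closed-form curve, a
# small multiplicative (instrument-proportional) Gaussian noise, an optional
# additive floor noise, and between-extension drift of the material constants.

#' Noise specification for synthetic curves
#'
#' @param additive_sd Additive Gaussian noise SD in kPa (default 0).
#' @param multiplicative_sd Multiplicative Gaussian noise SD as a fraction of
#'   the stress (default 0.01, the scale of the published min-max scatter).
#' @param seed Integer seed; generation with the same seed is reproducible.
#'   `NULL` uses (and advances) the session RNG.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(additive_sd = 0, multiplicative_sd = 0.01, seed = NULL) {
  if (additive_sd < 0 || multiplicative_sd < 0)
    stop("noise standard deviations must be >= 0")
  structure(list(additive_sd = additive_sd,
                 multiplicative_sd = multiplicative_sd,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "noise_spec")
}

# Run expr under a local RNG stream seeded with `seed`, restoring the session
# RNG afterwards; seed = NULL leaves the session RNG in charge.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate one synthetic stress-stretch curve
#'
#' Evaluates the closed-form uniaxial stress on an equally spaced stretch grid
#' over `[1, lambda_max]` and perturbs it as
#' `stress * (1 + eps_mult) + eps_add` with independent Gaussian noise terms.
#' Zero-noise output equals [uniaxial_stress()] on the grid exactly.
#'
#' @param params A [yeoh_params()] object.
#' @param lambda_max Largest stretch (`> 1`).
#' @param n_points Number of grid points (`>= 4`).
#' @param noise A [noise_spec()].
#' @param extension_id Extension label for the output curve.
#' @return A [stress_stretch_curve()].
#' @examples
#' generate_curve(species_preset("pig")$params, 1.08, 10,
#'                noise_spec(seed = 1))
#' @export
generate_curve <- function(params, lambda_max, n_points = 50L,
                           noise = noise_spec(multiplicative_sd = 0),
                           extension_id = 1L) {
  stopifnot(is_yeoh_params(params), inherits(noise, "noise_spec"))
  if (lambda_max <= 1) stop("lambda_max must exceed 1")
  if (n_points < 4) stop("need at least 4 points")
  lam <- seq(1, lambda_max, length.out = n_points)
  sig <- uniaxial_stress(lam, params)
  sig <- with_local_seed(noise$seed, {
    m <- if (noise$multiplicative_sd > 0)
      stats::rnorm(n_points, 0, noise$multiplicative_sd) else 0
    a <- if (noise$additive_sd > 0)
      stats::rnorm(n_points, 0, noise$additive_sd) else 0
    sig * (1 + m) + a
  })
  stress_stretch_curve(lam, sig, extension_id = extension_id)
}

#' Between-extension drift of the material constants
#'
#' Consecutive extensions of the same specimen yield slightly different fitted
#' constants (preconditioning drift).  The drift is specified as per-extension
#' `c1` and `c3` values; `c2` is set equal to `c1`, reflecting the observed
#' near-equality of the two constants.  Defaults are the published
#' per-extension pig values (kPa).
#'
#' @param c1_values Per-extension `c1` in kPa.
#' @param c3_values Per-extension `c3` in kPa, same length.
#' @return An object of class `"extension_drift"`.
#' @export
extension_drift <- function(c1_values = c(4.99, 6.49, 6.20, 5.99, 4.99),
                            c3_values = c(8130, 7950, 7460, 7610, 8210)) {
  if (length(c1_values) != length(c3_values))
    stop("c1_values and c3_values must have equal length")
  structure(list(c1_values = c1_values, c3_values = c3_values),
            class = "extension_drift")
}

#' Generate a synthetic multi-extension experiment
#'
#' One curve per extension, each from its own drifting constants, plus the
#' pointwise mean curve and min-max range across extensions (the way
#' multi-extension experiments are summarised).
#'
#' @param drift An [extension_drift()].
#' @param lambda_max,n_points,noise As in [generate_curve()]; per-extension
#'   noise streams are derived from `noise$seed` deterministically.
#' @return A list with elements `curves` (list of curves), `mean` (data frame
#'   `lambda`, `stress`, `stress_min_kpa`, `stress_max_kpa`) and `drift`.
#' @export
generate_experiment <- function(drift = extension_drift(), lambda_max = 1.08,
                                n_points = 50L,
                                noise = noise_spec(multiplicative_sd = 0)) {
  stopifnot(inherits(drift, "extension_drift"))
  nex <- length(drift$c1_values)
  curves <- lapply(seq_len(nex), function(i) {
    ni <- noise
    if (!is.null(noise$seed)) ni$seed <- noise$seed + i - 1L
    p <- yeoh_params(drift$c1_values[i], drift$c1_values[i], drift$c3_values[i])
    generate_curve(p, lambda_max, n_points, ni, extension_id = i)
  })
  S <- vapply(curves, function(cu) cu$stress, numeric(n_points))
  if (nex == 1L) S <- matrix(S, ncol = 1L)
  mean_curve <- data.frame(lambda = curves[[1]]$lambda,
                           stress = rowMeans(S),
                           stress_min_kpa = apply(S, 1, min),
                           stress_max_kpa = apply(S, 1, max))
  list(curves = curves, mean = mean_curve, drift = drift)
}
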