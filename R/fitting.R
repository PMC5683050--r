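#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with the total sum of squares taken about
#' the mean of the observations.  Maximising \eqn{R^2} over model parameters is
#' equivalent to minimising the residual sum of squares, since \eqn{SS_{tot}}
#' depends on the data only.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 2);
#'   `observed` must not be constant.
#' @return \eqn{R^2 \le 1} (can be negative for fits worse than the mean).
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2)
    stop("observed and predicted must be equal-length vectors of length >= 2")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("R^2 is undefined for a constant observed vector")
  1 - sum((observed - predicted)^2) / ss_tot
}

# Regression basis of the closed-form uniaxial stress: sigma(lambda) is linear
# in (c1, c2, c3) with columns  A = lambda^2 - 1/lambda,  2*x*A,  3*x^2*A
# where x = I1 - 3.  (Equal to p9(lambda)/lambda^3 split by constant.)
.stress_basis <- function(lambda) {
  A <- lambda^2 - 1 / lambda
  x <- lambda^2 + 2 / lambda - 3
  cbind(c1 = A, c2 = 2 * x * A, c3 = 3 * x^2 * A)
}

# Default starting pairs for (c1, c2), kPa: the guess set used when the
# published pig curves were identified.
.default_guesses <- list(c(10.00, 0), c(12.99, 0), c(0, 12.40),
                         c(0, 11.99), c(10.00, 0))

#' Fit Yeoh constants to a stress-stretch curve
#'
#' Identifies `(c1, c2, c3)` of the cubic Yeoh model (uniaxial closed form,
#' `"as_printed"` convention) from a measured stress-stretch curve by bounded
#' quasi-Newton minimisation (L-BFGS-B with analytic gradient) of the residual
#' sum of squares — equivalently, maximisation of \eqn{R^2}.  Each starting
#' pair in `guesses` seeds one optimisation run; the best run (highest
#' \eqn{R^2}, ties broken by the smaller `c3`) is returned.
#'
#' @param curve A [stress_stretch_curve()] (or data frame with columns
#'   `lambda` and `stress` in kPa).
#' @param guesses List of starting `(c1, c2)` pairs in kPa.  The default is
#'   the five-pair guess set used for the pig nerve identification.
#' @param c3_bounds Length-2 interval constraining `c3` (kPa).  Use
#'   `c(0, 0)` to pin `c3` at zero (lobster-like quadratic response);
#'   `c(6000, 9000)` is the range used for the pig nerve.
#' @param tie_c1_c2 If `TRUE`, impose the constraint `c1 = c2` exactly
#'   (one fewer free parameter).  Off by default: near-equality of the two
#'   constants is an empirical finding, not a constraint.
#' @param c12_bounds Length-2 interval constraining `c1` and `c2` (kPa).
#' @param control Optimiser control: `maxit` (default 500) and `factr`
#'   (L-BFGS-B tolerance, default 10).
#' @return An object of class `"yeoh_fit"` with components `params`
#'   (a [yeoh_params()]), `r_squared`, `residuals` (kPa, observed - fitted),
#'   `fitted`, `guess` (the winning start), `converged`, `n_iter`, `curve`,
#'   and `all_starts` (per-start diagnostics).  Standard methods
#'   [coef()], [predict()], [residuals()], [fitted()], [summary()], [plot()]
#'   and [simulate()] apply.
#' @examples
#' cu <- generate_curve(species_preset("pig")$params, 1.08, 50)
#' fit <- fit_yeoh(cu, c3_bounds = c(6000, 9000))
#' coef(fit)
#' summary(fit)
#' @export
fit_yeoh <- function(curve, guesses = .default_guesses,
                     c3_bounds = c(0, Inf), tie_c1_c2 = FALSE,
                     c12_bounds = c(0, Inf),
                     control = list(maxit = 500L, factr = 10)) {
  if (!is.data.frame(curve) || !all(c("lambda", "stress") %in% names(curve)))
    stop("curve must have columns 'lambda' and 'stress'")
  if (length(c3_bounds) != 2 || c3_bounds[1] > c3_bounds[2])
    stop("c3_bounds must be a non-empty interval")
  if (!is.list(guesses)) guesses <- list(guesses)
  lam <- curve$lambda; y <- curve$stress
  npar <- if (tie_c1_c2) 2L else 3L
  if (length(lam) < npar)
    stop("fewer data points than free parameters")

  X3 <- .stress_basis(lam)
  X <- if (tie_c1_c2) cbind(c12 = X3[, 1] + X3[, 2], c3 = X3[, 3]) else X3
  # column scaling for a well-conditioned quasi-Newton problem
  s <- apply(X, 2, function(col) max(sqrt(mean(col^2)), 1e-300))
  Xs <- sweep(X, 2, s, "/")
  lower <- (if (tie_c1_c2) c(c12_bounds[1], c3_bounds[1])
            else c(c12_bounds[1], c12_bounds[1], c3_bounds[1])) * s
  upper <- (if (tie_c1_c2) c(c12_bounds[2], c3_bounds[2])
            else c(c12_bounds[2], c12_bounds[2], c3_bounds[2])) * s

  fn <- function(b) { r <- y - Xs %*% b; sum(r * r) }
  gr <- function(b) { r <- y - Xs %*% b; -2 * drop(crossprod(Xs, r)) }
  c3_start <- if (is.finite(c3_bounds[2])) mean(c3_bounds) else max(1, c3_bounds[1])
  clamp <- function(v) pmin(pmax(v, lower / s), upper / s)

  ss_tot <- sum((y - mean(y))^2)
  runs <- lapply(guesses, function(g) {
    start0 <- if (tie_c1_c2) c(mean(g[1:2]), c3_start) else c(g[1], g[2], c3_start)
    b0 <- clamp(start0) * s  # clamp in original units, optimise in scaled units
    opt <- stats::optim(b0, fn, gr, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = control$maxit %||% 500L,
                                       factr = control$factr %||% 10))
    cc <- opt$par / s
    list(coef = cc, ss = opt$value, converged = opt$convergence == 0,
         n_iter = opt$counts[["function"]], guess = g)
  })
  ss <- vapply(runs, `[[`, 0, "ss")
  c3s <- vapply(runs, function(r) r$coef[[length(r$coef)]], 0)
  best <- order(ss, c3s)[1]
  win <- runs[[best]]
  cc <- win$coef
  params <- if (tie_c1_c2) yeoh_params(cc[1], cc[1], cc[2])
            else yeoh_params(cc[1], cc[2], cc[3])
  fit_vals <- drop(X %*% cc)
  res <- y - fit_vals
  structure(list(params = params,
                 r_squared = 1 - win$ss / ss_tot,
                 residuals = res,
                 fitted = fit_vals,
                 guess = win$guess,
                 converged = all(vapply(runs, `[[`, TRUE, "converged")),
                 n_iter = win$n_iter,
                 tie_c1_c2 = tie_c1_c2,
                 c3_bounds = c3_bounds,
                 curve = curve,
                 all_starts = runs,
                 call = match.call()),
            class = "yeoh_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @method print yeoh_fit
#' @export
print.yeoh_fit <- function(x, ...) {
  cat("Yeoh uniaxial fit\n")
  cat(sprintf("  c1 = %.6g kPa, c2 = %.6g kPa, c3 = %.6g kPa%s\n",
              x$params$c1, x$params$c2, x$params$c3,
              if (x$tie_c1_c2) "  (c1 = c2 tied)" else ""))
  cat(sprintf("  R^2 = %.6f on %d points%s\n", x$r_squared, nrow(x$curve),
              if (x$converged) "" else "  [NOT converged]"))
  invisible(x)
}

#' @export
coef.yeoh_fit <- function(object, ...) as.numeric(object$params)

#' @export
residuals.yeoh_fit <- function(object, ...) object$residuals

#' @export
fitted.yeoh_fit <- function(object, ...) object$fitted

#' @export
predict.yeoh_fit <- function(object, newdata = NULL, ...) {
  lam <- if (is.null(newdata)) object$curve$lambda
         else if (is.data.frame(newdata)) newdata$lambda else newdata
  uniaxial_stress(lam, object$params)
}

#' @method summary yeoh_fit
#' @export
summary.yeoh_fit <- function(object, ...) {
  out <- list(params = object$params, r_squared = object$r_squared,
              n = nrow(object$curve),
              lambda_range = range(object$curve$lambda),
              resid_range = range(object$residuals),
              rmse = sqrt(mean(object$residuals^2)),
              guess = object$guess, converged = object$converged,
              n_iter = object$n_iter, tie_c1_c2 = object$tie_c1_c2,
              drucker = drucker_margin(object$params,
                                       c(1, max(object$curve$lambda, 1.0001))))
  class(out) <- "summary.yeoh_fit"
  out
}

#' @method print summary.yeoh_fit
#' @export
print.summary.yeoh_fit <- function(x, ...) {
  cat("Yeoh uniaxial fit (closed-form Cauchy stress, as-printed convention)\n")
  cat(sprintf("  constants (kPa): c1 = %.6g, c2 = %.6g, c3 = %.6g%s\n",
              x$params$c1, x$params$c2, x$params$c3,
              if (x$tie_c1_c2) "  [c1 = c2 tied]" else ""))
  cat(sprintf("  R^2 = %.6f over %d points, lambda in [%g, %g]\n",
              x$r_squared, x$n, x$lambda_range[1], x$lambda_range[2]))
  cat(sprintf("  residuals (kPa): RMSE %.4g, range [%.4g, %.4g]\n",
              x$rmse, x$resid_range[1], x$resid_range[2]))
  cat(sprintf("  winning start (c1, c2) = (%g, %g); %sconverged in %d evaluations\n",
              x$guess[1], x$guess[2], if (x$converged) "" else "NOT ", x$n_iter))
  cat(sprintf("  Drucker margin over the data range: %.4g kPa (%s)\n",
              x$drucker, if (x$drucker > 0) "stable" else "UNSTABLE"))
  invisible(x)
}

#' @export
plot.yeoh_fit <- function(x, ...) {
  lam <- x$curve$lambda
  grid <- seq(min(lam), max(lam), length.out = 200)
  graphics::plot(lam, x$curve$stress, pch = 1,
                 xlab = expression(lambda), ylab = "Cauchy stress (kPa)",
                 main = "Yeoh uniaxial fit", ...)
  graphics::lines(grid, uniaxial_stress(grid, x$params), col = 2, lwd = 2)
  graphics::legend("topleft", c("data", "fit"), pch = c(1, NA),
                   lty = c(NA, 1), col = c(1, 2), bty = "n")
  invisible(x)
}

#' @export
simulate.yeoh_fit <- function(object, nsim = 1, seed = NULL, ...) {
  lmax <- max(object$curve$lambda)
  sdm <- sqrt(mean((object$residuals / pmax(abs(object$fitted), 1e-12))^2))
  lapply(seq_len(nsim), function(i) {
    ns <- noise_spec(multiplicative_sd = sdm,
                     seed = if (is.null(seed)) NULL else seed + i - 1L)
    generate_curve(object$params, lmax, nrow(object$curve), ns,
                   extension_id = i)
  })
}

#' Sensitivity index of the stress to each material constant
#'
#' For each constant, the closed-form stress at `lambda_eval` is evaluated at
#' the two endpoints of that constant's range with the other constants held at
#' their values in `params`; the index is
#' \eqn{SI = (\sigma_{max} - \sigma_{min}) / \sigma_{max}}.  A degenerate range
#' gives `SI = 0`.  The index is invariant under joint positive rescaling of
#' all constants and ranges (the stress is linear in the constants).
#'
#' @param params Optimal constants ([yeoh_params()]).
#' @param ranges Named list with any of `c1`, `c2`, `c3`, each a length-2
#'   interval in kPa.  Missing constants get a degenerate range at their
#'   `params` value (`SI = 0`).
#' @param lambda_eval Stretch at which the stress is evaluated.
#' @return A list of class `"sensitivity_report"`: `si` (named vector),
#'   `ranges`, `lambda_eval`, `sigma_at` (the endpoint stresses).
#' @export
sensitivity_index <- function(params, ranges, lambda_eval) {
  stopifnot(is_yeoh_params(params))
  base <- as.numeric(params)
  full <- list(c1 = ranges$c1 %||% rep(base[["c1"]], 2),
               c2 = ranges$c2 %||% rep(base[["c2"]], 2),
               c3 = ranges$c3 %||% rep(base[["c3"]], 2))
  sig_at <- lapply(names(full), function(nm) {
    vapply(full[[nm]], function(v) {
      cc <- base; cc[[nm]] <- v
      uniaxial_stress(lambda_eval, yeoh_params(cc[1], cc[2], cc[3]))
    }, 0)
  })
  names(sig_at) <- names(full)
  si <- vapply(sig_at, function(s) {
    smax <- max(s); smin <- min(s)
    if (smax == smin) return(0)
    if (smax == 0) stop("sensitivity index undefined: sigma_max = 0 at lambda_eval")
    (smax - smin) / smax
  }, 0)
  structure(list(si = si, ranges = full, lambda_eval = lambda_eval,
                 sigma_at = sig_at),
            class = "sensitivity_report")
}

#' @method print sensitivity_report
#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Sensitivity indices at lambda = %g:\n", x$lambda_eval))
  for (nm in names(x$si))
    cat(sprintf("  SI(%s) = %.4g   range [%g, %g] kPa\n", nm, x$si[[nm]],
                x$ranges[[nm]][1], x$ranges[[nm]][2]))
  invisible(x)
}

#' Cross-correlation of fitted constants across extensions
#'
#' Squared Pearson correlations between the per-extension `c1` and `c2`
#' values and between `c1` and `c3`, with the ordinary-least-squares line for
#' each pair.  Used to assess whether the constants drift together from one
#' loading cycle to the next.
#'
#' @param c_values A matrix or data frame with columns `c1`, `c2`, `c3` (kPa)
#'   and one row per extension (>= 3 rows).
#' @return A list of class `"constants_correlation"` with elements
#'   `r_squared` (named: `c1_c2`, `c1_c3`), `pearson_r`, and `ols` (named list
#'   of `c(intercept, slope)`).
#' @examples
#' tab <- cbind(c1 = c(4.99, 6.49, 6.20, 5.99, 4.99),
#'              c2 = c(4.99, 6.49, 6.20, 5.99, 4.99),
#'              c3 = c(8130, 7950, 7460, 7610, 8210))
#' constants_correlation(tab)$r_squared
#' @export
constants_correlation <- function(c_values) {
  c_values <- as.data.frame(c_values)
  if (!all(c("c1", "c2", "c3") %in% names(c_values)))
    stop("c_values needs columns c1, c2, c3")
  if (nrow(c_values) < 3) stop("need at least 3 extensions")
  pair <- function(x, y) {
    if (stats::var(x) == 0 || stats::var(y) == 0)
      stop("correlation undefined: a constant has zero variance across extensions")
    r <- stats::cor(x, y)
    slope <- stats::cov(x, y) / stats::var(x)
    c(r = r, intercept = mean(y) - slope * mean(x), slope = slope)
  }
  p12 <- pair(c_values$c1, c_values$c2)
  p13 <- pair(c_values$c1, c_values$c3)
  structure(list(
    r_squared = c(c1_c2 = unname(p12["r"]^2), c1_c3 = unname(p13["r"]^2)),
    pearson_r = c(c1_c2 = unname(p12["r"]), c1_c3 = unname(p13["r"])),
    ols = list(c1_c2 = p12[c("intercept", "slope")],
               c1_c3 = p13[c("intercept", "slope")])),
    class = "constants_correlation")
}

#' @method print constants_correlation
#' @export
print.constants_correlation <- function(x, ...) {
  cat("Cross-correlation of fitted constants across extensions:\n")
  cat(sprintf("  R^2(c1, c2) = %.4f   (r = %+.4f)\n",
              x$r_squared[["c1_c2"]], x$pearson_r[["c1_c2"]]))
  cat(sprintf("  R^2(c1, c3) = %.4f   (r = %+.4f)\n",
              x$r_squared[["c1_c3"]], x$pearson_r[["c1_c3"]]))
  invisible(x)
}

#' Write a fit report as plain text
#'
#' @param fit A [fit_yeoh()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "yeoh_fit"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "Yeoh uniaxial fit report",
    sprintf("c1_kpa: %.10g", fit$params$c1),
    sprintf("c2_kpa: %.10g", fit$params$c2),
    sprintf("c3_kpa: %.10g", fit$params$c3),
    sprintf("r_squared: %.10g", fit$r_squared),
    sprintf("converged: %s", fit$converged),
    "residuals_kpa:",
    paste0("  ", format(fit$residuals, digits = 8))), con)
  invisible(path)
}
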