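#' Fit a hormone-induction binding isotherm
#'
#' Nonlinear least-squares fit of the single-site binding curve
#' `YFP(H) = A_max * H / (k_half + H)` used to characterize
#' hormone-inducible reporter transcription factors: `A_max` is the
#' maximal signal (arbitrary fluorescence units) and `k_half` the
#' hormone concentration (nM) giving half-maximal signal.  The curve is
#' forced through the origin; an optional basal-fluorescence offset term
#' is available but off by default.
#'
#' Initialization is deterministic — `A_max` starts at the maximum
#' signal, `k_half` at the median concentration — so the fit does not
#' depend on data order.
#'
#' @param concentrations hormone concentrations (nM), at least 3
#'   distinct values, at least one positive.
#' @param signals measured signals (same length).
#' @param offset if `TRUE`, adds a fitted baseline `y0`.
#' @return An `isotherm_fit`: list with `A_max`, `k_half`, optional
#'   `y0`, `rss`, `se` (per-parameter standard errors), and the `nls`
#'   object.
#' @examples
#' h <- c(0, 5, 10, 25, 100, 400)
#' y <- 1000 * h / (25 + h)
#' fit_isotherm(h, y)
#' @export
fit_isotherm <- function(concentrations, signals, offset = FALSE) {
  if (length(concentrations) != length(signals))
    stop_ciber("concentrations and signals must have equal length")
  if (length(unique(concentrations)) < 3L)
    stop_ciber("need at least 3 distinct concentrations")
  if (all(concentrations <= 0)) stop_ciber("need at least one positive concentration")
  if (all(signals == 0)) stop_ciber("all signals are zero; nothing to fit")
  df <- data.frame(H = concentrations, Y = signals)
  start <- list(A_max = max(signals), k_half = stats::median(concentrations))
  # scaleOffset makes the convergence test valid for zero-residual data
  ctrl <- stats::nls.control(maxiter = 200, scaleOffset = 1)
  fit <- tryCatch({
    if (offset) {
      start$y0 <- min(signals)
      stats::nls(Y ~ y0 + A_max * H / (k_half + H), data = df, start = start,
                 control = ctrl)
    } else {
      stats::nls(Y ~ A_max * H / (k_half + H), data = df, start = start,
                 control = ctrl)
    }
  }, error = function(e) stop_ciber("isotherm fit did not converge: %s",
                                    conditionMessage(e)))
  cf <- stats::coef(fit)
  if (cf[["A_max"]] <= 0 || cf[["k_half"]] <= 0)
    stop_ciber("fit produced non-positive A_max or k_half")
  se <- summary(fit)$coefficients[, "Std. Error"]
  structure(list(A_max = cf[["A_max"]], k_half = cf[["k_half"]],
                 y0 = if (offset) cf[["y0"]] else NULL,
                 rss = sum(stats::resid(fit)^2), se = se, nls = fit),
            class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf("binding isotherm: A_max = %.6g (SE %.3g), k_half = %.6g nM (SE %.3g), RSS = %.3g\n",
              x$A_max, x$se[["A_max"]], x$k_half, x$se[["k_half"]], x$rss))
  invisible(x)
}

#' @export
predict.isotherm_fit <- function(object, newdata = NULL, ...) {
  H <- if (is.null(newdata)) stats::fitted(object$nls) else {
    h <- if (is.list(newdata)) newdata$H else newdata
    (if (is.null(object$y0)) 0 else object$y0) +
      object$A_max * h / (object$k_half + h)
  }
  H
}

#' @export
coef.isotherm_fit <- function(object, ...) stats::coef(object$nls)
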