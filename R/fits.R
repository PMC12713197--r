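#' Regress per-cell sensitivity on the design parameters
#'
#' Ordinary least squares of interaction-test sensitivity (fraction scale) on
#' treatment effect size, test-retest weight and per-group sample size across
#' the grid cells. Slopes are in sensitivity fraction per predictor unit
#' (z-unit, weight unit, participant). Cells with undefined sensitivity are
#' dropped with a message.
#'
#' @param summaries Data frame of [summarize_setting()] rows (needs columns
#'   `sensitivity`, `effect_size`, `retest_weight`, `n_per_group`).
#' @return An object of class `regression_fit`: coefficients, standard
#'   errors, t-values, p-values, `residual_df` (n_cells - 4) and
#'   `adjusted_r2`.
#' @section Errors: fewer than 5 usable cells or a rank-deficient design
#'   (e.g. a grid degenerate in one parameter) raises a
#'   `singular_design_error`.
#' @export
fit_sensitivity_regression <- function(summaries) {
  keep <- !is.na(summaries$sensitivity)
  if (sum(!keep) > 0L)
    message(sprintf("dropping %d cell(s) with undefined sensitivity", sum(!keep)))
  dat <- summaries[keep, , drop = FALSE]
  if (nrow(dat) < 5L)
    stop_posthocsim("need at least 5 cells with defined sensitivity",
                    "singular_design_error")
  fit <- lm(sensitivity ~ effect_size + retest_weight + n_per_group, data = dat)
  if (fit$rank < 4L || any(is.na(coef(fit))))
    stop_posthocsim("design matrix is rank deficient (degenerate grid)",
                    "singular_design_error")
  sm <- summary(fit)
  ct <- sm$coefficients
  structure(list(
    coefficients = setNames(ct[, "Estimate"], rownames(ct)),
    std_errors   = setNames(ct[, "Std. Error"], rownames(ct)),
    t_values     = setNames(ct[, "t value"], rownames(ct)),
    p_values     = setNames(ct[, "Pr(>|t|)"], rownames(ct)),
    residual_df  = fit$df.residual,
    adjusted_r2  = sm$adj.r.squared,
    n_cells      = nrow(dat)),
    class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> sensitivity ~ effect_size + retest_weight + n_per_group (%d cells)\n",
              x$n_cells))
  tab <- cbind(estimate = x$coefficients, se = x$std_errors,
               t = x$t_values, p = x$p_values)
  print(round(tab, 4))
  cat(sprintf("residual df %d, adjusted R^2 %.4f\n", x$residual_df, x$adjusted_r2))
  invisible(x)
}

curve_models <- list(
  inv_sqrt = list(
    label = "y = a/(sqrt(x) + b) + c",
    transform = function(x) sqrt(x)),
  recip_quad = list(
    label = "y = a/(x^2 + b) + c",
    transform = function(x) x^2))

#' Fit an inverse curve by multi-start nonlinear least squares
#'
#' Fits one of two three-parameter inverse families relating statistical
#' power to a selection artifact:
#' `inv_sqrt`, y = a / (sqrt(x) + b) + c (control-arm false-positive rate
#' against sensitivity), or `recip_quad`, y = a / (x^2 + b) + c (effect-size
#' inflation against sensitivity).
#'
#' The objective is multimodal in `b`, so the fit is multi-started: for each
#' of `n_starts` values of `b` log-spaced over the scale of the transformed
#' predictor, `a` and `c` are initialised by the exact linear least-squares
#' solution conditional on that `b` (the model is linear in `a`, `c`), and
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]) refines all three parameters
#' under the constraint `b > 0` (the pole must stay outside the data domain).
#' The converged solution with the smallest residual sum of squares wins.
#'
#' @param x Non-negative predictor vector (length >= 4), typically per-cell
#'   sensitivity on the fraction scale.
#' @param y Response vector, same length.
#' @param model_id `"inv_sqrt"` or `"recip_quad"`.
#' @param n_starts Number of starting values for `b` (default 7, minimum 5).
#' @param weights Optional non-negative case weights (e.g. replicate counts).
#' @return An object of class `curve_fit`: `model_id`, `params` (named a, b,
#'   c), `adjusted_r2` (three fitted parameters), `r2`, `rss`, `n_points`,
#'   `converged`, and `n_starts_converged`.
#' @section Errors: no converged start raises a `non_convergence_error`
#'   carrying the per-start diagnostics.
#' @export
#' @examples
#' x <- seq(0.01, 1, length.out = 50)
#' y <- 0.1 / (sqrt(x) + 0.05) - 0.02
#' fit_curve(x, y, "inv_sqrt")
fit_curve <- function(x, y, model_id = c("inv_sqrt", "recip_quad"),
                      n_starts = 7L, weights = NULL) {
  model_id <- match.arg(model_id)
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    stop_posthocsim("x and y must be numeric vectors of equal length",
                    "invalid_fit_error")
  if (anyNA(x) || anyNA(y))
    stop_posthocsim("x and y must not contain NA; drop incomplete cells first",
                    "invalid_fit_error")
  if (length(x) < 4L)
    stop_posthocsim("need at least 4 points to fit 3 parameters",
                    "invalid_fit_error")
  if (any(x < 0))
    stop_posthocsim("x must be non-negative", "invalid_fit_error")
  n_starts <- max(5L, as.integer(n_starts))
  if (is.null(weights)) weights <- rep(1, length(x))
  if (any(weights < 0) || all(weights == 0))
    stop_posthocsim("weights must be non-negative and not all zero",
                    "invalid_fit_error")

  z <- curve_models[[model_id]]$transform(x)
  zmax <- max(z)
  b_starts <- 10^seq(log10(max(zmax, 1e-8)) - 6, log10(max(zmax, 1e-8)) + 1,
                     length.out = n_starts)
  dat <- data.frame(z = z, y = y)
  best <- NULL
  diagnostics <- character(n_starts)
  n_conv <- 0L
  for (i in seq_along(b_starts)) {
    b0 <- b_starts[i]
    # conditional on b, the model is linear in (a, c): exact LS start
    lin <- lm(y ~ I(1 / (z + b0)), data = dat, weights = weights)
    start <- list(a = unname(coef(lin)[2]), b = b0, c = unname(coef(lin)[1]))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a / (z + b) + c, data = dat, start = start,
                        weights = weights,
                        lower = c(a = -Inf, b = .Machine$double.eps, c = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      diagnostics[i] <- sprintf("b0=%.3g: %s", b0, conditionMessage(fit))
      next
    }
    n_conv <- n_conv + 1L
    rss <- sum(weights * resid(fit)^2)
    diagnostics[i] <- sprintf("b0=%.3g: rss=%.6g", b0, rss)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop_posthocsim(
      paste0("no start converged for model ", model_id, ":\n  ",
             paste(diagnostics, collapse = "\n  ")),
      "non_convergence_error", diagnostics = diagnostics)

  wm <- sum(weights * y) / sum(weights)
  tss <- sum(weights * (y - wm)^2)
  r2 <- 1 - best$rss / tss
  n <- length(x)
  structure(list(model_id = model_id,
                 label = curve_models[[model_id]]$label,
                 params = coef(best$fit)[c("a", "b", "c")],
                 r2 = r2,
                 adjusted_r2 = 1 - (1 - r2) * (n - 1) / (n - 4),
                 rss = best$rss,
                 n_points = n,
                 converged = TRUE,
                 n_starts_converged = n_conv,
                 diagnostics = diagnostics),
            class = "curve_fit")
}

#' Evaluate a fitted inverse curve
#'
#' @param object A `curve_fit`.
#' @param newdata Numeric vector of predictor values (same scale as the `x`
#'   the curve was fitted on).
#' @param ... Unused.
#' @return Fitted responses.
#' @export
predict.curve_fit <- function(object, newdata, ...) {
  z <- curve_models[[object$model_id]]$transform(newdata)
  p <- object$params
  p[["a"]] / (z + p[["b"]]) + p[["c"]]
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("<curve_fit %s> %s\n", x$model_id, x$label))
  cat(sprintf("  a = %.4g, b = %.4g, c = %.4g\n",
              x$params[["a"]], x$params[["b"]], x$params[["c"]]))
  cat(sprintf("  adjusted R^2 = %.4f over %d points (%d/%d starts converged)\n",
              x$adjusted_r2, x$n_points, x$n_starts_converged,
              length(x$diagnostics)))
  invisible(x)
}
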