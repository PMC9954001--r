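# Chou median-effect fitting and Chou-Talalay combination-index analysis.

#' Fraction of cells affected by a treatment
#'
#' `fa = 1 - viability`, clamped to the open working interval (default
#' \[0.01, 0.99\]) because the median-effect linearization diverges at 0
#' and 1. Clamped points are flagged; they are excluded from median-effect
#' regressions but may still be evaluated (flagged) in CI tables.
#'
#' @param viability Vehicle-normalized viability fractions.
#' @param clamp Length-2 clamping bounds inside (0, 1).
#' @return `data.frame(viability, fa, clamped)`.
#' @examples
#' fraction_affected(c(0.8, 1.0, 0.0))
#' @export
fraction_affected <- function(viability, clamp = c(0.01, 0.99)) {
  check_clamp(clamp)
  fa_raw <- 1 - viability
  clamped <- fa_raw < clamp[1L] | fa_raw > clamp[2L]
  data.frame(viability = viability,
             fa = pmin(pmax(fa_raw, clamp[1L]), clamp[2L]),
             clamped = clamped)
}

check_clamp <- function(clamp) {
  if (length(clamp) != 2L || clamp[1L] <= 0 || clamp[2L] >= 1 ||
      clamp[1L] >= clamp[2L])
    stop("'clamp' must satisfy 0 < low < high < 1")
  invisible(clamp)
}

#' Fit the Chou median-effect model
#'
#' Ordinary least squares of `log10(fa / (1 - fa))` on `log10(dose)`; the
#' slope is the sigmoidicity `m` and the intercept gives the median-effect
#' dose `Dm = 10^(-intercept / m)` (the dose producing fa = 0.5).
#'
#' @param dose Positive doses in uM (>= 2 distinct values).
#' @param fa Fractions affected strictly inside (0, 1); clamped points
#'   (see [fraction_affected()]) should be excluded before fitting.
#' @return An object of class `median_effect_fit` with components
#'   `coefficients` (`dm`, `m`), `intercept`, `r` (correlation of the
#'   linearized fit), `n_points`, `fitted.values`, `residuals` (linearized
#'   scale) and `data`.
#' @examples
#' d <- c(0.5, 1, 2, 4)
#' fa <- (d / 2)^1.5 / (1 + (d / 2)^1.5)
#' coef(fit_median_effect(d, fa))  # dm = 2, m = 1.5
#' @export
fit_median_effect <- function(dose, fa) {
  if (length(dose) != length(fa)) stop("'dose' and 'fa' lengths differ")
  keep <- is.finite(dose) & is.finite(fa)
  dose <- dose[keep]; fa <- fa[keep]
  if (any(dose <= 0)) stop("zero or negative dose in median-effect fit")
  if (any(fa <= 0 | fa >= 1))
    stop("'fa' must lie strictly inside (0, 1); exclude clamped points")
  if (length(unique(dose)) < 2L)
    stop("need at least 2 usable points with distinct doses")
  x <- log10(dose)
  y <- log10(fa / (1 - fa))
  cf <- stats::lm.fit(cbind(intercept = 1, x = x), y)$coefficients
  m <- unname(cf["x"]); b <- unname(cf["intercept"])
  if (!is.finite(m) || m == 0) stop("degenerate median-effect fit (zero slope)")
  r <- if (stats::sd(y) == 0) 1 else stats::cor(x, y)
  fitted_y <- b + m * x
  structure(list(coefficients = c(dm = 10^(-b / m), m = m),
                 intercept = b, r = r, n_points = length(x),
                 fitted.values = fitted_y, residuals = y - fitted_y,
                 data = data.frame(dose = dose, fa = fa)),
            class = "median_effect_fit")
}

#' @export
print.median_effect_fit <- function(x, digits = 4, ...) {
  cat("Median-effect fit: log10(fa/(1-fa)) ~ log10(dose)\n")
  cat(sprintf("  Dm = %.*g uM, m = %.*g (r = %.3f, n = %d)\n",
              digits, x$coefficients[["dm"]], digits, x$coefficients[["m"]],
              x$r, x$n_points))
  invisible(x)
}

#' @export
coef.median_effect_fit <- function(object, ...) object$coefficients

#' Predicted fraction affected from a median-effect fit
#' @param object A `median_effect_fit`.
#' @param newdata Optional dose vector (uM); defaults to fitted doses.
#' @param ... Unused.
#' @export
predict.median_effect_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$dose else newdata
  dm <- object$coefficients[["dm"]]; m <- object$coefficients[["m"]]
  r <- (d / dm)^m
  r / (1 + r)
}

#' @export
residuals.median_effect_fit <- function(object, ...) object$residuals

#' Plot the linearized median-effect fit
#' @param x A `median_effect_fit`.
#' @param ... Passed to [plot()].
#' @export
plot.median_effect_fit <- function(x, ...) {
  lx <- log10(x$data$dose)
  ly <- log10(x$data$fa / (1 - x$data$fa))
  plot(lx, ly, xlab = "log10 dose (uM)", ylab = "log10(fa / (1 - fa))", ...)
  graphics::abline(x$intercept, x$coefficients[["m"]])
  invisible(x)
}

#' Dose required to reach a given fraction affected
#'
#' Chou inversion `Dx = Dm * (fa / (1 - fa))^(1/m)`.
#'
#' @param fit A `median_effect_fit`.
#' @param fa Fractions affected strictly inside (0, 1).
#' @return Dose(s) in uM.
#' @examples
#' fit <- fit_median_effect(c(1, 4), c(0.5, 0.8))
#' required_dose(fit, 0.5)  # = Dm
#' @export
required_dose <- function(fit, fa) {
  stopifnot(inherits(fit, "median_effect_fit"))
  if (any(fa <= 0 | fa >= 1)) stop("'fa' must lie strictly inside (0, 1)")
  fit$coefficients[["dm"]] *
    (fa / (1 - fa))^(1 / fit$coefficients[["m"]])
}

classify_ci <- function(ci, additive_band = 0.05) {
  ifelse(abs(ci - 1) <= additive_band, "additive",
         ifelse(ci < 1, "synergism", "antagonism"))
}

#' Chou-Talalay combination index at observed dose pairs
#'
#' For each measured combination point,
#' `CI = d_a / Dx_a(fa) + d_b / Dx_b(fa)` with `Dx_i` the single-agent dose
#' required to reach the observed fraction affected. CI < 1 indicates
#' synergism, CI = 1 additivity (Loewe), CI > 1 antagonism; values within
#' `additive_band` of 1 are classified additive to avoid noise-driven sign
#' flips (the raw CI is always reported). This is the non-constant-ratio
#' form: each dose pair is evaluated at its own observed fa.
#'
#' @param dose_a,dose_b Component doses in uM (non-negative, not both 0).
#' @param fa Observed fractions affected, strictly inside (0, 1).
#' @param fit_a,fit_b Single-agent `median_effect_fit` objects.
#' @param additive_band Half-width of the additive classification band.
#' @return `data.frame(dose_a, dose_b, fa, ci, classification)`.
#' @export
combination_index <- function(dose_a, dose_b, fa, fit_a, fit_b,
                              additive_band = 0.05) {
  stopifnot(inherits(fit_a, "median_effect_fit"),
            inherits(fit_b, "median_effect_fit"))
  if (any(dose_a < 0) || any(dose_b < 0)) stop("doses must be non-negative")
  if (any(dose_a + dose_b == 0)) stop("dose pair (0, 0) is degenerate")
  if (any(fa <= 0 | fa >= 1)) stop("'fa' must lie strictly inside (0, 1)")
  ci <- dose_a / required_dose(fit_a, fa) + dose_b / required_dose(fit_b, fa)
  data.frame(dose_a = dose_a, dose_b = dose_b, fa = fa, ci = ci,
             classification = classify_ci(ci, additive_band),
             stringsAsFactors = FALSE)
}

#' Fa-CI table for a measured combination series
#'
#' Computes the combination index at every measured dose pair of a
#' combination (each at its own observed fraction affected), sorted by fa
#' as in a Fa-CI plot. The series is flagged synergistic overall when the
#' majority of points have CI < 1.
#'
#' @param combo `data.frame` with columns `dose_a_um`, `dose_b_um` and
#'   `viability` (one row per measured pair), e.g. the relevant rows of
#'   [normalize_viability()] output.
#' @param fit_a,fit_b Single-agent `median_effect_fit` objects.
#' @param clamp fa clamping bounds (see [fraction_affected()]).
#' @param additive_band Additive classification band (see
#'   [combination_index()]).
#' @return A `data.frame` of class `fa_ci_table` sorted by fa with columns
#'   `dose_a, dose_b, fa, fa_clamped, ci, classification` and attribute
#'   `synergistic_overall`.
#' @export
fa_ci_table <- function(combo, fit_a, fit_b, clamp = c(0.01, 0.99),
                        additive_band = 0.05) {
  need <- c("dose_a_um", "dose_b_um", "viability")
  if (!all(need %in% names(combo)))
    stop("'combo' must have columns ", paste(need, collapse = ", "))
  if (!nrow(combo)) stop("'combo' is empty")
  fa <- fraction_affected(combo$viability, clamp)
  res <- combination_index(combo$dose_a_um, combo$dose_b_um, fa$fa,
                           fit_a, fit_b, additive_band)
  res$fa_clamped <- fa$clamped
  res <- res[order(res$fa), c("dose_a", "dose_b", "fa", "fa_clamped",
                              "ci", "classification")]
  rownames(res) <- NULL
  attr(res, "synergistic_overall") <-
    mean(res$classification == "synergism") > 0.5
  class(res) <- c("fa_ci_table", "data.frame")
  res
}

#' @export
print.fa_ci_table <- function(x, digits = 4, ...) {
  cat("Fa-CI table (", nrow(x), " points)\n", sep = "")
  print.data.frame(x, digits = digits, ...)
  cat(if (attr(x, "synergistic_overall"))
    "overall: synergistic (CI < 1 at the majority of points)\n"
    else "overall: not synergistic\n")
  invisible(x)
}
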