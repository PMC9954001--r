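# Vehicle normalization, Hill fitting, trapezoidal AUC and the 0-100 score.

#' Normalize raw plate signals to vehicle and average replicates
#'
#' Divides every raw signal by the mean vehicle signal of its sample, then
#' averages replicate wells per (sample, treatment, dose). Viability above 1
#' (growth stimulation) is preserved, not clipped.
#'
#' @param plate Long-format plate `data.frame` (see
#'   [simulate_single_agent()] for the schema).
#' @return A `data.frame` with one row per (sample, treatment, dose pair):
#'   `sample_id, treatment_id, dose_a_um, dose_b_um, viability,
#'   viability_sd, n_reps`, sorted by sample, treatment and ascending dose.
#' @export
normalize_viability <- function(plate) {
  check_plate(plate)
  plate$viability <- NA_real_
  for (sid in unique(plate$sample_id)) {
    sel <- plate$sample_id == sid
    veh <- plate$raw_signal[sel & plate$is_vehicle]
    if (!length(veh))
      stop("sample '", sid, "' has no vehicle wells")
    vmean <- mean(veh)
    if (!is.finite(vmean) || vmean <= 0)
      stop("sample '", sid, "' has zero/invalid vehicle signal")
    plate$viability[sel] <- plate$raw_signal[sel] / vmean
  }
  trt <- plate[!plate$is_vehicle, , drop = FALSE]
  key <- interaction(trt$sample_id, trt$treatment_id,
                     trt$dose_a_um, trt$dose_b_um, drop = TRUE)
  idx <- split(seq_len(nrow(trt)), key)
  out <- do.call(rbind, lapply(idx, function(i) {
    data.frame(sample_id = trt$sample_id[i[1L]],
               treatment_id = trt$treatment_id[i[1L]],
               dose_a_um = trt$dose_a_um[i[1L]],
               dose_b_um = trt$dose_b_um[i[1L]],
               viability = mean(trt$viability[i]),
               viability_sd = stats::sd(trt$viability[i]),
               n_reps = length(i), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$sample_id, out$treatment_id,
                   out$dose_a_um, out$dose_b_um), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trapezoidal area under a dose-response curve
#'
#' Sums `dX * (Y1 + Y2) / 2` over adjacent dose pairs with X the dose axis
#' (log10 concentration by default) and Y the vehicle-normalized viability.
#' Negative viabilities are floored at 0 before integration, matching the
#' score's semantics in which full kill is the maximal effect; viability
#' above 1 is kept as-is so growth stimulation inflates the area.
#'
#' @param dose Dose vector in uM (positive when `axis = "log10"`).
#' @param viability Viability fractions, same length as `dose`.
#' @param axis `"log10"` (default) or `"linear"` concentration axis.
#' @param floor Floor negative viability at 0 before integrating.
#' @return The area (viability-fraction x axis units).
#' @examples
#' compute_auc(c(0.1, 1, 10), c(1, 0.5, 0))  # 1.0
#' @export
compute_auc <- function(dose, viability, axis = c("log10", "linear"),
                        floor = TRUE) {
  axis <- match.arg(axis)
  if (length(dose) < 2L) stop("need at least 2 doses for an AUC")
  if (length(dose) != length(viability))
    stop("'dose' and 'viability' lengths differ")
  if (axis == "log10" && any(dose <= 0))
    stop("non-positive dose on a log10 axis")
  ord <- order(dose)
  dose <- dose[ord]; viability <- viability[ord]
  if (any(duplicated(dose))) stop("doses must be distinct")
  x <- if (axis == "log10") log10(dose) else dose
  y <- if (floor) pmax(viability, 0) else viability
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

#' Theoretical AUC anchors for a dose ladder
#'
#' The full-kill reference (`auc_min = 0`: viability 0 everywhere) and the
#' no-effect reference (`auc_max`: viability 1 across the ladder, i.e. the
#' axis range). Theoretical anchors make scores comparable across plates.
#'
#' @inheritParams compute_auc
#' @return `list(auc_min = 0, auc_max = <axis range>)`.
#' @export
auc_anchors <- function(dose, axis = c("log10", "linear")) {
  axis <- match.arg(axis)
  if (axis == "log10" && any(dose <= 0))
    stop("non-positive dose on a log10 axis")
  x <- if (axis == "log10") log10(dose) else dose
  list(auc_min = 0, auc_max = diff(range(x)))
}

#' Min-max drug score from an AUC
#'
#' `score = 100 * (1 - (AUC - AUC_min) / (AUC_max - AUC_min))`: 100 means
#' all cells killed, 0 no effect, and drugs that stimulate growth score
#' below 0 (no clipping).
#'
#' @param auc Observed area(s) under the curve.
#' @param auc_min Full-kill reference area.
#' @param auc_max No-effect reference area (> `auc_min`).
#' @return Score(s) on the 0-100 scale (possibly negative).
#' @export
score_from_auc <- function(auc, auc_min, auc_max) {
  if (!is.numeric(auc_max) || !is.numeric(auc_min) || any(auc_max <= auc_min))
    stop("'auc_max' must be greater than 'auc_min'")
  100 * (1 - (auc - auc_min) / (auc_max - auc_min))
}

#' Score every dose-response curve in a normalized screen
#'
#' Applies [compute_auc()] and [score_from_auc()] per (sample, treatment)
#' curve. Anchors are theoretical by default ([auc_anchors()]); with
#' `anchors = "empirical"` the observed min/max AUC across the screen is
#' used instead. Curves with fewer than 2 doses are excluded with a
#' message. Combination curves are integrated over drug A's dose axis
#' (uniform half-log steps make the two axes equivalent up to the shared
#' step width).
#'
#' @param curves Output of [normalize_viability()].
#' @param axis Dose axis, `"log10"` or `"linear"`.
#' @param anchors `"theoretical"` or `"empirical"`.
#' @param fit Also fit a Hill curve per treatment ([fit_hill()]) and report
#'   EC50 and convergence (slower; off by default).
#' @return A `data.frame` with one row per curve: `sample_id, treatment_id,
#'   n_doses, auc, auc_min, auc_max, score` (+ `ec50, hill_converged` when
#'   `fit = TRUE`).
#' @export
score_curves <- function(curves, axis = c("log10", "linear"),
                         anchors = c("theoretical", "empirical"),
                         fit = FALSE) {
  axis <- match.arg(axis)
  anchors <- match.arg(anchors)
  key <- interaction(curves$sample_id, curves$treatment_id, drop = TRUE)
  idx <- split(seq_len(nrow(curves)), key)
  rows <- lapply(idx, function(i) {
    g <- curves[i, , drop = FALSE]
    dose <- if (all(g$dose_a_um > 0)) g$dose_a_um else g$dose_b_um
    if (length(unique(dose)) < 2L) {
      message("excluding curve ", g$sample_id[1L], " / ",
              g$treatment_id[1L], ": fewer than 2 distinct doses")
      return(NULL)
    }
    anc <- auc_anchors(dose, axis)
    out <- data.frame(sample_id = g$sample_id[1L],
                      treatment_id = g$treatment_id[1L],
                      n_doses = length(unique(dose)),
                      auc = compute_auc(dose, g$viability, axis),
                      auc_min = anc$auc_min, auc_max = anc$auc_max,
                      stringsAsFactors = FALSE)
    if (fit) {
      hf <- fit_hill(dose, g$viability)
      out$ec50 <- unname(coef(hf)["ec50"])
      out$hill_converged <- hf$converged
    }
    out
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no scorable curves in input")
  rownames(res) <- NULL
  if (anchors == "empirical") {
    res$auc_min <- min(res$auc)
    res$auc_max <- max(res$auc)
    if (res$auc_max[1L] <= res$auc_min[1L])
      stop("empirical anchors degenerate: all AUCs identical")
  }
  res$score <- score_from_auc(res$auc, res$auc_min, res$auc_max)
  res
}

#' Fit a four-parameter logistic (Hill) curve
#'
#' Least-squares fit of
#' `viability = bottom + (top - bottom) / (1 + (dose / ec50)^slope)`
#' on a log10-dose axis via Levenberg-Marquardt. With fewer than 4 distinct
#' doses the asymptotes are fixed at the observed max/min and only EC50 and
#' slope are estimated. Curves whose viability range is below 0.05 are
#' flagged flat and returned unconverged with both asymptotes at the mean.
#'
#' @param dose Positive doses in uM (>= 2 distinct values).
#' @param viability Vehicle-normalized viability fractions.
#' @return An object of class `hill_fit` with components `coefficients`
#'   (`top`, `bottom`, `ec50`, `slope`), `converged`, `flat`, `rss`,
#'   `fitted.values`, `residuals` and `data`.
#' @examples
#' d <- dose_ladder(20)
#' v <- 0 + 1 / (1 + (d / 2)^1)
#' coef(fit_hill(d, v))
#' @export
fit_hill <- function(dose, viability) {
  if (length(dose) != length(viability))
    stop("'dose' and 'viability' lengths differ")
  if (any(dose <= 0)) stop("doses must be positive")
  n_distinct <- length(unique(dose))
  if (n_distinct < 2L) stop("need at least 2 distinct doses")
  lx <- log10(dose)
  rng <- max(viability) - min(viability)
  mk <- function(cf, converged, flat, fitted) {
    structure(list(coefficients = cf, converged = converged, flat = flat,
                   rss = sum((viability - fitted)^2),
                   fitted.values = fitted, residuals = viability - fitted,
                   data = data.frame(dose = dose, viability = viability)),
              class = "hill_fit")
  }
  if (rng < 0.05) {
    m <- mean(viability)
    return(mk(c(top = m, bottom = m, ec50 = NA_real_, slope = NA_real_),
              converged = FALSE, flat = TRUE, fitted = rep(m, length(dose))))
  }
  top0 <- max(viability); bot0 <- min(viability)
  lec0 <- lx[which.min(abs(viability - (top0 + bot0) / 2))]
  model_4pl <- function(p) {
    # p on the optimizer scale: lec50 = log10(ec50)
    p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
      (1 + 10^(p[["slope"]] * (lx - p[["lec50"]])))
  }
  free <- if (n_distinct >= 4L) c("top", "bottom", "lec50", "slope")
  else c("lec50", "slope")
  start <- c(top = top0, bottom = bot0, lec50 = lec0, slope = 1)
  lower <- c(top = -Inf, bottom = -Inf, lec50 = min(lx) - 3, slope = 1e-3)
  upper <- c(top = Inf, bottom = Inf, lec50 = max(lx) + 3, slope = 100)
  fit <- try(minpack.lm::nls.lm(
    par = start[free],
    fn = function(p) viability - model_4pl(c(start[setdiff(names(start),
                                                           free)], p)),
    lower = lower[free], upper = upper[free],
    control = minpack.lm::nls.lm.control(
      maxiter = 500, ftol = 1e-15, ptol = 1e-15)), silent = TRUE)
  if (inherits(fit, "try-error") || !fit$info %in% 1:4) {
    m <- mean(viability)
    return(mk(c(top = top0, bottom = bot0, ec50 = NA_real_, slope = NA_real_),
              converged = FALSE, flat = FALSE, fitted = rep(m, length(dose))))
  }
  p_hat <- c(start[setdiff(names(start), free)], fit$par)
  mk(c(top = p_hat[["top"]], bottom = p_hat[["bottom"]],
       ec50 = 10^p_hat[["lec50"]], slope = p_hat[["slope"]]),
     converged = TRUE, flat = FALSE, fitted = model_4pl(p_hat))
}

#' @export
print.hill_fit <- function(x, digits = 4, ...) {
  cat("Four-parameter logistic fit (log10-dose axis)\n")
  if (x$flat) cat("  flat curve (viability range < 0.05); not fitted\n")
  print(round(x$coefficients, digits))
  cat(sprintf("  converged: %s, RSS: %.4g, n = %d\n",
              x$converged, x$rss, nrow(x$data)))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' Predicted viability from a Hill fit
#' @param object A `hill_fit`.
#' @param newdata Optional dose vector (uM); defaults to the fitted doses.
#' @param ... Unused.
#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$data$dose else newdata
  cf <- object$coefficients
  if (object$flat) return(rep(cf[["top"]], length(d)))
  cf[["bottom"]] + (cf[["top"]] - cf[["bottom"]]) /
    (1 + (d / cf[["ec50"]])^cf[["slope"]])
}

#' @export
residuals.hill_fit <- function(object, ...) object$residuals

#' @export
fitted.hill_fit <- function(object, ...) object$fitted.values

#' Plot a Hill fit over its data
#' @param x A `hill_fit`.
#' @param n_grid Points on the fitted-curve grid.
#' @param ... Passed to [plot()].
#' @export
plot.hill_fit <- function(x, n_grid = 100, ...) {
  d <- x$data$dose
  plot(log10(d), x$data$viability, xlab = "log10 dose (uM)",
       ylab = "viability (fraction of vehicle)", ...)
  grid_d <- 10^seq(min(log10(d)), max(log10(d)), length.out = n_grid)
  graphics::lines(log10(grid_d), predict(x, grid_d))
  invisible(x)
}
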