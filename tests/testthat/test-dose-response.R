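test_that("vehicle normalization divides by the sample's vehicle mean", {
  plate <- data.frame(
    sample_id = "S1", treatment_id = c("veh", "veh", "d", "d", "d"),
    dose_a_um = c(0, 0, 1, 1, 10), dose_b_um = 0,
    replicate = c(1, 2, 1, 2, 1),
    raw_signal = c(900, 1100, 1000, 0, 1500),
    is_vehicle = c(TRUE, TRUE, FALSE, FALSE, FALSE), flag = "")
  cv <- normalize_viability(plate)
  expect_equal(cv$viability[cv$dose_a_um == 1], 0.5)  # mean of 1.0 and 0.0
  # growth stimulation preserved, not clipped
  expect_equal(cv$viability[cv$dose_a_um == 10], 1.5)
  expect_equal(cv$n_reps, c(2L, 1L))
  # missing vehicle wells -> hard error naming the sample
  bad <- plate[!plate$is_vehicle, ]
  expect_error(normalize_viability(bad), "S1")
  zero <- plate; zero$raw_signal[zero$is_vehicle] <- 0
  expect_error(normalize_viability(zero), "vehicle")
})

test_that("trapezoidal AUC matches hand-computed values", {
  # hand trapezoid: uniform log10 steps of width 1
  expect_equal(compute_auc(c(0.1, 1, 10), c(1.0, 0.5, 0.0)), 1.0)
  # unit rectangle: viability 1 over a log10 range of width W
  d <- dose_ladder(20)
  W <- log10(20) - log10(min(d))
  expect_equal(compute_auc(d, rep(1, 6)), W)
  expect_equal(compute_auc(d, rep(0, 6)), 0)
  # negative viability floored at 0 before integration
  expect_equal(compute_auc(c(0.1, 1, 10), c(0, -1, 0)), 0)
  # linear axis option
  expect_equal(compute_auc(c(0, 2), c(1, 1), axis = "linear"), 2)
  expect_error(compute_auc(c(0, 1), c(1, 1)), "log10")
  expect_error(compute_auc(1, 1), "at least 2")
})

test_that("AUC on measured 6-point ladders tracks fine-grid integration", {
  # oracle: adaptive quadrature of the smooth Hill curve on the log10 axis
  for (pars in list(c(ec50 = 2, slope = 1), c(ec50 = 0.5, slope = 2),
                    c(ec50 = 8, slope = 0.7))) {
    sp <- drug_spec("d", cmax = 20, ec50 = pars[["ec50"]],
                    hill_slope = pars[["slope"]])
    d <- dose_ladder(20)
    auc6 <- compute_auc(d, hill_viability(d, sp))
    fine <- stats::integrate(function(lx) hill_viability(10^lx, sp),
                             log10(min(d)), log10(20), rel.tol = 1e-10)$value
    expect_lt(abs(auc6 - fine) / fine, 0.02)
  }
})

test_that("score formula maps the AUC anchors exactly", {
  d <- dose_ladder(20)
  anc <- auc_anchors(d)
  # full kill scores exactly 100
  expect_equal(score_from_auc(compute_auc(d, rep(0, 6)),
                              anc$auc_min, anc$auc_max), 100)
  # no effect scores exactly 0
  expect_equal(score_from_auc(compute_auc(d, rep(1, 6)),
                              anc$auc_min, anc$auc_max), 0)
  # growth stimulation: auc = 1.2 * auc_max with auc_min = 0 -> -20
  expect_equal(score_from_auc(1.2 * anc$auc_max, 0, anc$auc_max), -20)
  expect_error(score_from_auc(1, 2, 2), "auc_max")
})

test_that("score is monotone in viability and affine-invariant in its anchors", {
  d <- dose_ladder(10)
  anc <- auc_anchors(d)
  set.seed(42)
  for (i in 1:25) {
    v1 <- runif(6, 0, 1.3)
    v2 <- pmax(v1 - runif(6, 0, 0.3), 0)  # pointwise lower
    a1 <- compute_auc(d, v1); a2 <- compute_auc(d, v2)
    expect_lte(a2, a1)
    expect_gte(score_from_auc(a2, anc$auc_min, anc$auc_max),
               score_from_auc(a1, anc$auc_min, anc$auc_max))
    k <- runif(1, 0.1, 10)  # common positive rescaling leaves score unchanged
    expect_equal(score_from_auc(k * a1, k * anc$auc_min, k * anc$auc_max),
                 score_from_auc(a1, anc$auc_min, anc$auc_max))
  }
})

test_that("Hill fit recovers planted parameters on noise-free ladders", {
  cases <- list(c(top = 1, bottom = 0, ec50 = 1, slope = 1),
                c(top = 1, bottom = 0.1, ec50 = 3, slope = 2),
                c(top = 0.95, bottom = 0, ec50 = 0.4, slope = 0.8))
  for (tr in cases) {
    sp <- drug_spec("d", cmax = 20, ec50 = tr[["ec50"]],
                    hill_slope = tr[["slope"]], hill_top = tr[["top"]],
                    hill_bottom = tr[["bottom"]])
    cv <- normalize_viability(simulate_single_agent(sp, noise_sd = 0, seed = 1))
    hf <- fit_hill(cv$dose_a_um, cv$viability)
    expect_true(hf$converged)
    rel <- abs(coef(hf) - tr) / pmax(abs(tr), 1)
    expect_lt(max(rel), 1e-6)
    # 4PL midpoint identity: fitted response at d = ec50 is (top + bottom)/2
    expect_equal(predict(hf, coef(hf)[["ec50"]]),
                 (tr[["top"]] + tr[["bottom"]]) / 2, tolerance = 1e-6)
  }
})

test_that("degenerate and short curves are handled", {
  d <- dose_ladder(10)
  flat <- fit_hill(d, rep(1, 6))
  expect_false(flat$converged)
  expect_true(flat$flat)
  expect_error(fit_hill(1, 0.5), "at least 2")
  expect_error(fit_hill(c(-1, 1), c(1, 0)), "positive")
  # < 4 distinct doses: asymptotes fixed at observed max/min
  sp <- drug_spec("d", cmax = 10, ec50 = 1)
  d3 <- c(0.1, 1, 10)
  hf <- fit_hill(d3, hill_viability(d3, sp))
  expect_true(hf$converged)
  expect_equal(coef(hf)[["top"]], max(hill_viability(d3, sp)))
})

test_that("hill_fit behaves like a model object", {
  sp <- spec_a()
  cv <- normalize_viability(simulate_single_agent(sp, noise_sd = 0.05, seed = 2))
  hf <- fit_hill(cv$dose_a_um, cv$viability)
  expect_s3_class(hf, "hill_fit")
  expect_named(coef(hf), c("top", "bottom", "ec50", "slope"))
  expect_equal(length(residuals(hf)), nrow(cv))
  expect_equal(fitted(hf) + residuals(hf), cv$viability)
  expect_output(print(hf), "logistic")
})

test_that("score_curves scores every curve and excludes degenerate ones", {
  pan <- simulate_panel(2, list(spec_a(), spec_b()), seed = 1, noise_sd = 0)
  scored <- score_curves(normalize_viability(pan))
  expect_equal(nrow(scored), 2L * 4L)  # 2 samples x 2 drugs x 2 tiers
  expect_true(all(is.finite(scored$score)))
  expect_true(all(scored$auc_max > scored$auc_min))
  # single-dose curve is excluded with a message
  cv <- normalize_viability(pan)
  one <- cv[cv$sample_id == "S01" & cv$treatment_id == "drugA@cmax", ][1, ]
  expect_message(score_curves(rbind(cv, transform(one, sample_id = "S99"))),
                 "fewer than 2")
  # empirical anchors span the observed AUCs
  emp <- score_curves(cv, anchors = "empirical")
  expect_equal(max(emp$score), 100)
  expect_equal(min(emp$score), 0)
})
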