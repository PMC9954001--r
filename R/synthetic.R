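# Synthetic screen generator: plate-level viability with known ground truth.
# Every generator takes an explicit seed and leaves the caller's RNG alone.

plate_columns <- c("sample_id", "treatment_id", "dose_a_um", "dose_b_um",
                   "replicate", "raw_signal", "is_vehicle", "flag")

new_plate_rows <- function(sample_id, treatment_id, dose_a, dose_b,
                           replicate, viability, noise_sd, signal_scale,
                           is_vehicle = FALSE, flag = "") {
  n <- length(viability)
  noise <- if (noise_sd > 0) exp(stats::rnorm(n, 0, noise_sd)) else rep(1, n)
  data.frame(sample_id = sample_id, treatment_id = treatment_id,
             dose_a_um = dose_a, dose_b_um = dose_b, replicate = replicate,
             raw_signal = signal_scale * viability * noise,
             is_vehicle = is_vehicle, flag = flag,
             stringsAsFactors = FALSE)
}

vehicle_rows <- function(sample_id, n_vehicle, noise_sd, signal_scale) {
  new_plate_rows(sample_id, "vehicle", 0, 0, seq_len(n_vehicle),
                 rep(1, n_vehicle), noise_sd, signal_scale, is_vehicle = TRUE)
}

#' Simulate a single-agent 6-point dose-response plate
#'
#' Generates replicate luminescence-like signals along a serial-dilution
#' ladder whose top dose is the drug's Cmax. Noise-free mean viability at
#' dose d is the Hill curve of the spec; observed signals carry
#' multiplicative lognormal noise with standard deviation `noise_sd` on the
#' log scale. Vehicle wells (expected viability 1) are included so the
#' table can be normalized like a real plate.
#'
#' @param spec A [drug_spec()].
#' @param n_doses Number of doses on the ladder (>= 2; default 6).
#' @param n_reps Replicate wells per dose.
#' @param noise_sd Lognormal sd of the multiplicative noise (0 = noise-free).
#' @param seed Integer seed; identical seeds give bit-identical tables.
#' @param dilution Fold-dilution between doses (default half-log).
#' @param sample_id Sample identifier for the generated rows.
#' @param n_vehicle Number of vehicle wells.
#' @param signal_scale Expected vehicle signal (arbitrary luminescence units).
#' @return A long-format plate `data.frame` with columns
#'   `sample_id, treatment_id, dose_a_um, dose_b_um, replicate, raw_signal,
#'   is_vehicle, flag`.
#' @examples
#' plate <- simulate_single_agent(drug_spec("erlotinib", cmax = 20, ec50 = 2),
#'                                noise_sd = 0.05, seed = 1)
#' @export
simulate_single_agent <- function(spec, n_doses = 6, n_reps = 3,
                                  noise_sd = 0, seed = 1L,
                                  dilution = sqrt(10), sample_id = "S1",
                                  n_vehicle = 6, signal_scale = 1e4) {
  stopifnot(inherits(spec, "drug_spec"))
  if (n_doses < 2) stop("'n_doses' must be >= 2")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  doses <- dose_ladder(spec$cmax, n_doses, dilution)
  with_seed(seed, {
    veh <- vehicle_rows(sample_id, n_vehicle, noise_sd, signal_scale)
    v <- hill_viability(rep(doses, each = n_reps), spec)
    trt <- new_plate_rows(sample_id, spec$name,
                          dose_a = rep(doses, each = n_reps), dose_b = 0,
                          replicate = rep(seq_len(n_reps), times = n_doses),
                          viability = v, noise_sd = noise_sd,
                          signal_scale = signal_scale)
    rbind(veh, trt)
  })
}

# Solve the scaled Loewe equation for the fraction affected at one dose pair.
# The left-hand side decreases monotonically in fa from +Inf to psi*0 - 1 < 0,
# so a root always exists in (0, 1); roots outside [lower, upper] are clamped
# and flagged (the pair saturates the assay's dynamic range).
solve_loewe_fa <- function(dose_a, dose_b, psi, me_a, me_b,
                           lower = 1e-6, upper = 1 - 1e-6) {
  required <- function(me, fa) me[["dm"]] * (fa / (1 - fa))^(1 / me[["m"]])
  g <- function(fa) {
    psi * dose_a / required(me_a, fa) + psi * dose_b / required(me_b, fa) - 1
  }
  if (g(lower) < 0) return(list(fa = lower, clamped = TRUE))
  if (g(upper) > 0) return(list(fa = upper, clamped = TRUE))
  root <- stats::uniroot(g, c(lower, upper), tol = 1e-12)$root
  list(fa = root, clamped = FALSE)
}

#' Simulate combination responses with known ground-truth synergy
#'
#' For each dose pair in the [combo_spec()], the noise-free fraction
#' affected solves the scaled Loewe equation
#' `psi * d_a / Dx_a(fa) + psi * d_b / Dx_b(fa) = 1`
#' using the components' exact median-effect parameters, and viability is
#' `1 - fa` noised as in [simulate_single_agent()]. The combination index
#' recovered by the synergy module on this data equals `1 / psi`. Pairs
#' whose root falls outside the open interval are clamped and flagged
#' `"saturated"`.
#'
#' @inheritParams simulate_single_agent
#' @param spec A [combo_spec()].
#' @return A plate `data.frame` (see [simulate_single_agent()]).
#' @export
simulate_combination <- function(spec, n_reps = 3, noise_sd = 0, seed = 1L,
                                 sample_id = "S1", n_vehicle = 6,
                                 signal_scale = 1e4) {
  stopifnot(inherits(spec, "combo_spec"))
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  me_a <- median_effect_params(spec$drug_a)
  me_b <- median_effect_params(spec$drug_b)
  sol <- apply(spec$dose_pairs, 1L, function(p)
    solve_loewe_fa(p[1L], p[2L], spec$psi, me_a, me_b))
  fa <- vapply(sol, `[[`, numeric(1), "fa")
  clamped <- vapply(sol, `[[`, logical(1), "clamped")
  if (any(clamped))
    warning(sum(clamped), " dose pair(s) saturate the assay; fa clamped")
  n_pairs <- nrow(spec$dose_pairs)
  with_seed(seed, {
    veh <- vehicle_rows(sample_id, n_vehicle, noise_sd, signal_scale)
    trt <- new_plate_rows(
      sample_id, spec$name,
      dose_a = rep(spec$dose_pairs[, 1L], each = n_reps),
      dose_b = rep(spec$dose_pairs[, 2L], each = n_reps),
      replicate = rep(seq_len(n_reps), times = n_pairs),
      viability = rep(1 - fa, each = n_reps),
      noise_sd = noise_sd, signal_scale = signal_scale,
      flag = rep(ifelse(clamped, "saturated", ""), each = n_reps))
    rbind(veh, trt)
  })
}

#' Simulate a multi-sample screening panel
#'
#' Emulates the screen design in which every treatment (single drugs and
#' drug pairs) is tested on every sample at two dose tiers: a ladder topped
#' at Cmax and one topped at 10% Cmax. Sample-to-sample heterogeneity is a
#' lognormal multiplier on each drug's EC50 (slope untouched, so parameter
#' recovery stays single-parameter). A `missing_fraction` of
#' (sample, treatment-tier) cells is dropped to mimic untested pairs.
#'
#' @inheritParams simulate_single_agent
#' @param n_samples Number of samples in the panel.
#' @param treatments List of [drug_spec()] / [combo_spec()] objects.
#' @param missing_fraction Probability that a (sample, treatment) cell is
#'   untested (0 <= f < 1).
#' @param dose_tiers Character subset of `c("cmax", "10pct_cmax")`; each
#'   treatment is laddered from `cmax` or `0.1 * cmax` accordingly, and the
#'   tier is appended to the treatment id as `"name@tier"`.
#' @param sample_cv Lognormal sd of the per-sample EC50 multiplier.
#' @return A plate `data.frame` covering all samples.
#' @export
simulate_panel <- function(n_samples, treatments, missing_fraction = 0,
                           seed = 1L, dose_tiers = c("cmax", "10pct_cmax"),
                           n_doses = 6, n_reps = 3, noise_sd = 0.05,
                           sample_cv = 0.3, dilution = sqrt(10),
                           n_vehicle = 6, signal_scale = 1e4) {
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("'missing_fraction' must be in [0, 1)")
  dose_tiers <- match.arg(dose_tiers, c("cmax", "10pct_cmax"),
                          several.ok = TRUE)
  if (!length(treatments)) stop("'treatments' must be a non-empty list")
  ok <- vapply(treatments, function(t)
    inherits(t, "drug_spec") || inherits(t, "combo_spec"), logical(1))
  if (!all(ok)) stop("'treatments' must contain drug_spec/combo_spec objects")
  tier_factor <- c(cmax = 1, "10pct_cmax" = 0.1)
  sample_ids <- sprintf("S%02d", seq_len(n_samples))

  with_seed(seed, {
    mult <- stats::setNames(exp(stats::rnorm(n_samples, 0, sample_cv)),
                            sample_ids)
    out <- vector("list", n_samples)
    for (si in seq_len(n_samples)) {
      sid <- sample_ids[si]
      blocks <- list(vehicle_rows(sid, n_vehicle, noise_sd, signal_scale))
      for (trt in treatments) {
        for (tier in dose_tiers) {
          if (stats::runif(1) < missing_fraction) next
          f <- tier_factor[[tier]]
          tid <- paste0(if (inherits(trt, "combo_spec")) trt$name
                        else trt$name, "@", tier)
          if (inherits(trt, "drug_spec")) {
            sp <- trt
            sp$ec50 <- sp$ec50 * mult[[sid]]
            doses <- dose_ladder(trt$cmax * f, n_doses, dilution)
            v <- hill_viability(rep(doses, each = n_reps), sp)
            blocks[[length(blocks) + 1L]] <- new_plate_rows(
              sid, tid, dose_a = rep(doses, each = n_reps), dose_b = 0,
              replicate = rep(seq_len(n_reps), times = n_doses),
              viability = v, noise_sd = noise_sd,
              signal_scale = signal_scale)
          } else {
            me_a <- median_effect_params(trt$drug_a)
            me_b <- median_effect_params(trt$drug_b)
            me_a[["dm"]] <- me_a[["dm"]] * mult[[sid]]
            me_b[["dm"]] <- me_b[["dm"]] * mult[[sid]]
            da <- dose_ladder(trt$drug_a$cmax * f, n_doses, dilution)
            db <- dose_ladder(trt$drug_b$cmax * f, n_doses, dilution)
            sol <- mapply(function(a, b)
              solve_loewe_fa(a, b, trt$psi, me_a, me_b),
              da, db, SIMPLIFY = FALSE)
            fa <- vapply(sol, `[[`, numeric(1), "fa")
            clamped <- vapply(sol, `[[`, logical(1), "clamped")
            blocks[[length(blocks) + 1L]] <- new_plate_rows(
              sid, tid, dose_a = rep(da, each = n_reps),
              dose_b = rep(db, each = n_reps),
              replicate = rep(seq_len(n_reps), times = n_doses),
              viability = rep(1 - fa, each = n_reps),
              noise_sd = noise_sd, signal_scale = signal_scale,
              flag = rep(ifelse(clamped, "saturated", ""), each = n_reps))
          }
        }
      }
      out[[si]] <- do.call(rbind, blocks)
    }
    do.call(rbind, out)
  })
}

#' Simulate a two-group expression matrix with planted fold changes
#'
#' Gene intensities are generated on the log2 scale (per-gene baseline
#' uniform on \[6, 14\], gaussian noise of sd `sigma`) and exponentiated to
#' linear fluorescence intensities. The first `de_genes` genes carry a
#' group-mean log2 difference of exactly `log2fc` (second group relative to
#' the first); the remainder carry 0.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per group.
#' @param de_genes Number of planted differentially expressed genes.
#' @param log2fc Planted log2 fold change.
#' @param sigma Gaussian noise sd on the log2 scale (> 0).
#' @param seed Integer seed.
#' @param groups Two group labels.
#' @return An [expression_table()] with attribute `planted_genes`.
#' @export
simulate_expression <- function(n_genes = 200, n_per_group = 5,
                                de_genes = 20, log2fc = 2, sigma = 0.1,
                                seed = 1L,
                                groups = c("control", "treated")) {
  if (de_genes > n_genes) stop("'de_genes' must be <= 'n_genes'")
  if (sigma <= 0) stop("'sigma' must be > 0")
  if (length(groups) != 2L) stop("exactly two group labels are required")
  genes <- sprintf("gene%04d", seq_len(n_genes))
  samples <- paste0(rep(groups, each = n_per_group), "_",
                    rep(seq_len(n_per_group), times = 2L))
  grp <- stats::setNames(rep(groups, each = n_per_group), samples)
  with_seed(seed, {
    baseline <- stats::runif(n_genes, 6, 14)
    log2mat <- matrix(baseline, n_genes, 2L * n_per_group) +
      matrix(stats::rnorm(n_genes * 2L * n_per_group, 0, sigma),
             n_genes, 2L * n_per_group)
    if (de_genes > 0)
      log2mat[seq_len(de_genes), grp == groups[2L]] <-
        log2mat[seq_len(de_genes), grp == groups[2L]] + log2fc
    dimnames(log2mat) <- list(genes, samples)
    et <- expression_table(2^log2mat, grp)
    attr(et, "planted_genes") <- genes[seq_len(de_genes)]
    et
  })
}

#' Simulate a qPCR Ct table with planted ddCt shifts
#'
#' Produces replicate threshold-cycle (Ct) values for target genes and a
#' reference gene in a calibrator and a treated group. The treated group's
#' target Cts are shifted by `planted_ddct`, so the downstream relative
#' quantification recovers a fold change of `2^(-planted_ddct)` per gene.
#'
#' @param targets Target gene names.
#' @param reference Reference (housekeeping) gene name.
#' @param planted_ddct Per-target ddCt shifts (recycled; named vectors are
#'   matched to `targets`).
#' @param sd Gaussian sd of replicate Ct values (0 = exact).
#' @param n_reps Replicates per (gene, group) (>= 2 for error propagation).
#' @param seed Integer seed.
#' @param groups Labels for the calibrator and treated group, in that order.
#' @param base_ct_target,base_ct_ref Baseline mean Cts.
#' @return A `data.frame` with columns `gene, group, replicate, ct`.
#' @export
simulate_ct <- function(targets, reference = "RAB14", planted_ddct = 0,
                        sd = 0.2, n_reps = 3, seed = 1L,
                        groups = c("calibrator", "treated"),
                        base_ct_target = 25, base_ct_ref = 20) {
  if (n_reps < 2) stop("'n_reps' must be >= 2 (error propagation needs variance)")
  if (sd < 0) stop("'sd' must be >= 0")
  if (reference %in% targets) stop("'reference' must not be among 'targets'")
  if (!is.null(names(planted_ddct))) {
    planted_ddct <- planted_ddct[targets]
    if (anyNA(planted_ddct)) stop("named 'planted_ddct' must cover all targets")
  } else {
    planted_ddct <- rep_len(planted_ddct, length(targets))
  }
  with_seed(seed, {
    rows <- list()
    for (g in seq_along(groups)) {
      shift <- if (g == 2L) planted_ddct else rep(0, length(targets))
      for (i in seq_along(targets)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = targets[i], group = groups[g],
          replicate = seq_len(n_reps),
          ct = base_ct_target + shift[i] + stats::rnorm(n_reps, 0, sd),
          stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene = reference, group = groups[g], replicate = seq_len(n_reps),
        ct = base_ct_ref + stats::rnorm(n_reps, 0, sd),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}
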