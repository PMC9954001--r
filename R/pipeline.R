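# Run configuration and the end-to-end screen pipeline.

#' Pipeline run configuration
#'
#' Collects every tunable of a screen run with validation; round-trips
#' losslessly through YAML ([write_run_config()] / [read_run_config()]).
#'
#' @param plate_csv Path to the input plate CSV (`NULL` when simulating).
#' @param dose_axis AUC axis, `"log10"` or `"linear"`.
#' @param anchors Score anchors, `"theoretical"` or `"empirical"`.
#' @param clamp fa clamping bounds (0 < low < high < 1).
#' @param additive_band Additive CI classification half-width (>= 0).
#' @param fc_threshold,alpha,adjust DEG filter settings.
#' @param dose_tier Tier used for the headline ranking.
#' @param min_samples Minimum tested samples for a treatment to be ranked.
#' @param pairs List of drug pairs for synergy analysis; each element a
#'   list/vector with elements `a`, `b` and `combo` (treatment-id prefixes).
#' @param seed Integer seed for any simulation step.
#' @param out_dir Output directory.
#' @param simulate Optional simulation block (see [run_pipeline()]).
#' @return An object of class `run_config`.
#' @export
run_config <- function(plate_csv = NULL, dose_axis = "log10",
                       anchors = "theoretical", clamp = c(0.01, 0.99),
                       additive_band = 0.05, fc_threshold = 1,
                       alpha = 0.05, adjust = FALSE,
                       dose_tier = "10pct_cmax", min_samples = 3,
                       pairs = list(), seed = 1L, out_dir = tempfile("run_"),
                       simulate = NULL) {
  dose_axis <- match.arg(dose_axis, c("log10", "linear"))
  anchors <- match.arg(anchors, c("theoretical", "empirical"))
  dose_tier <- match.arg(dose_tier, c("10pct_cmax", "cmax"))
  check_clamp(clamp)
  if (additive_band < 0) stop("'additive_band' must be >= 0")
  if (fc_threshold < 0) stop("'fc_threshold' must be >= 0")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  if (min_samples < 1) stop("'min_samples' must be >= 1")
  structure(list(plate_csv = plate_csv, dose_axis = dose_axis,
                 anchors = anchors, clamp = clamp,
                 additive_band = additive_band,
                 fc_threshold = fc_threshold, alpha = alpha,
                 adjust = adjust, dose_tier = dose_tier,
                 min_samples = min_samples, pairs = pairs,
                 seed = as.integer(seed), out_dir = out_dir,
                 simulate = simulate),
            class = "run_config")
}

#' Write a run configuration to YAML
#' @param config A [run_config()].
#' @param path Output YAML path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML path.
#' @return A validated [run_config()].
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

# Build the plate from a config's simulation block: n_samples, treatments
# given as drugs (list of name/cmax/ec50/hill_slope) and combos (list of
# a/b/psi referencing drug names), plus noise_sd / missing_fraction.
panel_from_config <- function(sim, seed) {
  drugs <- lapply(sim$drugs, function(d)
    drug_spec(d$name, cmax = d$cmax, ec50 = d$ec50,
              hill_slope = if (is.null(d$hill_slope)) 1 else d$hill_slope))
  names(drugs) <- vapply(drugs, `[[`, character(1), "name")
  combos <- lapply(sim$combos, function(cb)
    combo_spec(drugs[[cb$a]], drugs[[cb$b]],
               psi = if (is.null(cb$psi)) 1 else cb$psi))
  simulate_panel(
    n_samples = sim$n_samples, treatments = c(unname(drugs), combos),
    missing_fraction = if (is.null(sim$missing_fraction)) 0
    else sim$missing_fraction,
    noise_sd = if (is.null(sim$noise_sd)) 0.05 else sim$noise_sd,
    seed = seed)
}

#' Run the end-to-end screening pipeline
#'
#' Executes normalize -> score -> rank (at the configured dose tier) ->
#' synergy (for each configured pair), writing `scores.tsv`,
#' `ranking.tsv`, `heatmap.tsv`, one `synergy_<pair>.tsv` per pair, the
#' resolved configuration and a run manifest (inputs, config hash, seed,
#' versions, excluded/flagged counts) to the output directory. The run is
#' deterministic given the config and seed. Any stage error halts the run
#' naming the stage.
#'
#' @param config A [run_config()]. Input is either `config$plate_csv` or,
#'   when that is `NULL`, a plate simulated from `config$simulate` (fields
#'   `n_samples`, `drugs`, `combos`, `noise_sd`, `missing_fraction`) under
#'   `config$seed`.
#' @return Invisibly, a list with the scored curves, score matrix,
#'   ranking, per-pair Fa-CI tables, and output file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  plate <- stage("input", {
    if (!is.null(config$plate_csv)) read_plate_csv(config$plate_csv)
    else if (!is.null(config$simulate))
      panel_from_config(config$simulate, config$seed)
    else stop("config has neither 'plate_csv' nor a 'simulate' block")
  })
  curves <- stage("normalize", normalize_viability(plate))
  scored <- stage("score", score_curves(curves, axis = config$dose_axis,
                                        anchors = config$anchors))
  paths$scores <- write_tsv(scored, file.path(config$out_dir, "scores.tsv"))

  has_tiers <- any(grepl("@", scored$treatment_id, fixed = TRUE))
  sm <- stage("rank", build_score_matrix(
    scored, dose_tier = if (has_tiers) config$dose_tier else NULL))
  ranking <- stage("rank", rank_treatments(sm, min_samples = config$min_samples))
  paths$ranking <- write_tsv(as.data.frame(ranking),
                             file.path(config$out_dir, "ranking.tsv"))
  paths$heatmap <- write_tsv(to_heatmap_table(sm, ranking),
                             file.path(config$out_dir, "heatmap.tsv"))

  synergy <- list()
  n_clamped <- 0L
  for (pair in config$pairs) {
    pair <- as.list(pair)
    tab <- stage(paste0("synergy ", pair$a, "+", pair$b), {
      pick <- function(id) curves$treatment_id == id |
        startsWith(curves$treatment_id, paste0(id, "@"))
      fit_one <- function(id) {
        cc <- curves[pick(id) & curves$dose_b_um == 0, , drop = FALSE]
        if (!nrow(cc)) stop("no single-agent curve for '", id, "'")
        fa <- fraction_affected(cc$viability, config$clamp)
        keep <- !fa$clamped
        fit_median_effect(cc$dose_a_um[keep], fa$fa[keep])
      }
      fit_a <- fit_one(pair$a)
      fit_b <- fit_one(pair$b)
      combo_id <- if (!is.null(pair$combo)) pair$combo
      else paste0(pair$a, "+", pair$b)
      combo <- curves[pick(combo_id) & curves$dose_b_um > 0, , drop = FALSE]
      if (!nrow(combo)) stop("no combination rows for '", combo_id, "'")
      fa_ci_table(combo, fit_a, fit_b, clamp = config$clamp,
                  additive_band = config$additive_band)
    })
    n_clamped <- n_clamped + sum(tab$fa_clamped)
    key <- paste0(pair$a, "+", pair$b)
    synergy[[key]] <- tab
    paths[[paste0("synergy_", key)]] <- write_tsv(
      as.data.frame(tab), file.path(config$out_dir,
                                    paste0("synergy_", key, ".tsv")))
  }

  cfg_path <- write_run_config(config, file.path(config$out_dir, "config.yaml"))
  manifest <- list(
    input = if (!is.null(config$plate_csv)) config$plate_csv else "simulated",
    config_file = "config.yaml",
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    n_plate_rows = nrow(plate), n_curves = nrow(scored),
    n_treatments_ranked = sum(!is.na(ranking$rank)),
    n_clamped_fa_points = n_clamped,
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    package_version = as.character(utils::packageVersion("combiscreen")))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  paths$manifest <- file.path(config$out_dir, "manifest.yaml")

  message(sprintf("pipeline: %d curves scored, %d treatments ranked, %d synergy pair(s)",
                  nrow(scored), sum(!is.na(ranking$rank)), length(synergy)))
  invisible(list(scored = scored, score_matrix = sm, ranking = ranking,
                 synergy = synergy, paths = paths))
}
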