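# Treatment x sample score matrices and panel-wide treatment ranking.

#' Assemble a treatment x sample score matrix
#'
#' Builds the heatmap object behind panel-wide ranking: one row per
#' treatment, one column per sample, untested cells `NA` (excluded from
#' every aggregate). When `dose_tier` is given, only treatment ids carrying
#' that tier suffix (`"name@tier"`, as produced by [simulate_panel()]) are
#' kept.
#'
#' @param scored Output of [score_curves()] (columns `sample_id`,
#'   `treatment_id`, `score`).
#' @param dose_tier Optional tier filter, `"cmax"` or `"10pct_cmax"`.
#' @return An object of class `score_matrix`: a numeric matrix
#'   (treatments x samples) with `NA` for untested cells and attribute
#'   `dose_tier`.
#' @export
build_score_matrix <- function(scored, dose_tier = NULL) {
  need <- c("sample_id", "treatment_id", "score")
  if (!all(need %in% names(scored)))
    stop("'scored' must have columns ", paste(need, collapse = ", "))
  if (!is.null(dose_tier)) {
    dose_tier <- match.arg(dose_tier, c("cmax", "10pct_cmax"))
    suffix <- paste0("@", dose_tier)
    scored <- scored[endsWith(scored$treatment_id, suffix), , drop = FALSE]
    if (!nrow(scored)) stop("no treatments at dose tier '", dose_tier, "'")
  }
  dup <- duplicated(scored[c("sample_id", "treatment_id")])
  if (any(dup))
    stop("duplicate (sample, treatment) entries: ",
         paste(unique(paste(scored$sample_id[dup], scored$treatment_id[dup],
                            sep = "/")), collapse = ", "))
  treatments <- sort(unique(scored$treatment_id))
  samples <- unique(scored$sample_id)
  m <- matrix(NA_real_, length(treatments), length(samples),
              dimnames = list(treatments, samples))
  m[cbind(match(scored$treatment_id, treatments),
          match(scored$sample_id, samples))] <- scored$score
  structure(m, dose_tier = dose_tier, class = c("score_matrix", "matrix"))
}

#' @export
print.score_matrix <- function(x, digits = 1, ...) {
  tier <- attr(x, "dose_tier")
  cat(sprintf("<score_matrix> %d treatments x %d samples%s (%d untested cells)\n",
              nrow(x), ncol(x),
              if (is.null(tier)) "" else paste0(" at tier ", tier),
              sum(is.na(x))))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Rank treatments across a sample panel
#'
#' Aggregates each treatment's scores over the samples on which it was
#' tested (unweighted mean by default) and ranks treatments by descending
#' aggregate. Ties share the minimum rank and are listed lexicographically.
#' Treatments tested on fewer than `min_samples` samples are reported
#' unranked (`rank = NA`) to avoid single-sample winners.
#'
#' @param x A [build_score_matrix()] result.
#' @param min_samples Minimum number of tested samples to be ranked.
#' @param aggregate `"mean"` (default) or `"median"`.
#' @return An object of class `treatment_ranking`: a `data.frame` with
#'   columns `treatment, aggregate_score, n_samples_tested, rank`, ranked
#'   rows first in rank order.
#' @export
rank_treatments <- function(x, min_samples = 3,
                            aggregate = c("mean", "median")) {
  stopifnot(inherits(x, "score_matrix"))
  aggregate <- match.arg(aggregate)
  if (min_samples < 1) stop("'min_samples' must be >= 1")
  if (!nrow(x)) stop("empty score matrix")
  agg_fun <- if (aggregate == "mean") mean else stats::median
  agg <- apply(unclass(x), 1L, agg_fun, na.rm = TRUE)
  n_tested <- rowSums(!is.na(unclass(x)))
  agg[n_tested == 0L] <- NA_real_
  out <- data.frame(treatment = rownames(x), aggregate_score = unname(agg),
                    n_samples_tested = unname(n_tested),
                    stringsAsFactors = FALSE)
  eligible <- out$n_samples_tested >= min_samples
  if (any(!eligible))
    message("unranked (tested on < ", min_samples, " samples): ",
            paste(out$treatment[!eligible], collapse = ", "))
  out$rank <- NA_integer_
  if (any(eligible))
    out$rank[eligible] <- rank(-out$aggregate_score[eligible],
                               ties.method = "min")
  ord <- order(!eligible, out$rank, out$treatment)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, aggregate = aggregate, min_samples = min_samples,
            class = c("treatment_ranking", "data.frame"))
}

#' @export
print.treatment_ranking <- function(x, digits = 2, ...) {
  cat(sprintf("Treatment ranking (aggregate = %s over tested samples)\n",
              attr(x, "aggregate")))
  y <- x
  y$aggregate_score <- round(y$aggregate_score, digits)
  print.data.frame(y, ...)
  invisible(x)
}

#' Long-format heatmap table from a ranked score matrix
#'
#' Emits one row per (treatment, sample) cell with treatments in rank
#' order (unranked treatments last), samples in matrix column order, and a
#' `"not_tested"` sentinel status for masked cells.
#'
#' @param x A [build_score_matrix()] result.
#' @param ranking The matching [rank_treatments()] result.
#' @return A `data.frame` with columns
#'   `treatment, sample, score, status, rank`.
#' @export
to_heatmap_table <- function(x, ranking) {
  stopifnot(inherits(x, "score_matrix"), inherits(ranking, "treatment_ranking"))
  if (!setequal(ranking$treatment, rownames(x)))
    stop("'ranking' does not match the score matrix's treatments")
  out <- do.call(rbind, lapply(seq_len(nrow(ranking)), function(i) {
    trt <- ranking$treatment[i]
    sc <- unclass(x)[trt, ]
    data.frame(treatment = trt, sample = colnames(x), score = unname(sc),
               status = ifelse(is.na(sc), "not_tested", "tested"),
               rank = ranking$rank[i], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
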