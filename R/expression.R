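# Expression-stage computations: DEG filter, heatmap gene selection,
# mean-centering, average-linkage clustering, and 2^-ddCt quantification.

#' Gene-by-sample expression table
#'
#' Container pairing a non-negative intensity matrix (genes x samples,
#' `NA` allowed) with per-sample group labels.
#'
#' @param intensity Numeric matrix, rows = genes (unique rownames),
#'   columns = samples.
#' @param groups Character vector of group labels, one per column (named
#'   vectors are matched to column names).
#' @return An object of class `expression_table` (list with `intensity`
#'   and `groups`).
#' @export
expression_table <- function(intensity, groups) {
  intensity <- as.matrix(intensity)
  if (is.null(rownames(intensity)) || anyDuplicated(rownames(intensity)))
    stop("'intensity' needs unique gene rownames")
  if (is.null(colnames(intensity))) stop("'intensity' needs sample colnames")
  if (any(intensity < 0, na.rm = TRUE)) stop("intensities must be non-negative")
  if (!is.null(names(groups))) {
    if (!all(colnames(intensity) %in% names(groups)))
      stop("'groups' names do not cover all samples")
    groups <- groups[colnames(intensity)]
  } else if (length(groups) != ncol(intensity)) {
    stop("'groups' must have one label per sample")
  }
  groups <- stats::setNames(as.character(groups), colnames(intensity))
  structure(list(intensity = intensity, groups = groups),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table> %d genes x %d samples; groups: %s\n",
              nrow(x$intensity), ncol(x$intensity),
              paste(sprintf("%s (n=%d)", names(table(x$groups)),
                            table(x$groups)), collapse = ", ")))
  invisible(x)
}

group_columns <- function(expr, group) {
  idx <- which(expr$groups == group)
  if (!length(idx)) stop("group '", group, "' not found")
  idx
}

#' Two-rule differential expression filter
#'
#' Per gene, the log2 fold change is the difference of group-mean log2
#' intensities (`group_b` minus `group_a`) and the p-value comes from a
#' two-sample unequal-variance (Welch) t-test on log2 intensities. Genes
#' pass by either of two rules: (1) `|log2 FC| >= fc_threshold` and
#' `p < alpha`; (2) the log2 ratio is undefined (one group has no positive,
#' non-missing intensities) and the groups' mean raw intensities differ by
#' at least `na_intensity_cutoff`.
#'
#' @param expr An [expression_table()].
#' @param group_a,group_b Group labels; fold change is `group_b` relative
#'   to `group_a`.
#' @param fc_threshold Absolute log2 fold-change gate (default 1).
#' @param alpha P-value gate (default 0.05).
#' @param adjust Apply Benjamini-Hochberg adjustment and gate on the
#'   adjusted p-value (default off).
#' @param na_intensity_cutoff Minimum mean raw-intensity difference for
#'   the undefined-ratio rule (default 1000).
#' @return A `data.frame` with one row per gene: `gene, log2_fc, p_value`
#'   (+ `p_adjusted` when `adjust = TRUE`), `mean_intensity_a,
#'   mean_intensity_b, passed_rule` (`"fc_and_p"`, `"na_intensity"` or
#'   `"none"`).
#' @export
differential_expression <- function(expr, group_a, group_b,
                                    fc_threshold = 1, alpha = 0.05,
                                    adjust = FALSE,
                                    na_intensity_cutoff = 1000) {
  stopifnot(inherits(expr, "expression_table"))
  if (fc_threshold < 0 || alpha <= 0 || alpha >= 1)
    stop("invalid thresholds: need fc_threshold >= 0 and alpha in (0, 1)")
  ia <- expr$intensity[, group_columns(expr, group_a), drop = FALSE]
  ib <- expr$intensity[, group_columns(expr, group_b), drop = FALSE]
  small <- ncol(ia) < 2L || ncol(ib) < 2L
  if (small)
    warning("a group has < 2 samples; p-values skipped, NA-intensity rule still applied")
  genes <- rownames(expr$intensity)
  n <- length(genes)
  log2_fc <- p <- rep(NA_real_, n)
  mean_a <- mean_b <- numeric(n)
  for (i in seq_len(n)) {
    a <- ia[i, ]; b <- ib[i, ]
    la <- log2(a[!is.na(a) & a > 0]); lb <- log2(b[!is.na(b) & b > 0])
    mean_a[i] <- if (all(is.na(a))) 0 else mean(a, na.rm = TRUE)
    mean_b[i] <- if (all(is.na(b))) 0 else mean(b, na.rm = TRUE)
    if (length(la) && length(lb)) {
      log2_fc[i] <- mean(lb) - mean(la)
      if (!small && length(la) >= 2L && length(lb) >= 2L &&
          (stats::sd(la) > 0 || stats::sd(lb) > 0))
        p[i] <- stats::t.test(lb, la, var.equal = FALSE)$p.value
    }
  }
  p_gate <- if (adjust) stats::p.adjust(p, method = "BH") else p
  rule1 <- !is.na(log2_fc) & abs(log2_fc) >= fc_threshold &
    !is.na(p_gate) & p_gate < alpha
  rule2 <- is.na(log2_fc) & abs(mean_a - mean_b) >= na_intensity_cutoff
  out <- data.frame(gene = genes, log2_fc = log2_fc, p_value = p,
                    stringsAsFactors = FALSE)
  if (adjust) out$p_adjusted <- p_gate
  out$mean_intensity_a <- mean_a
  out$mean_intensity_b <- mean_b
  out$passed_rule <- ifelse(rule1, "fc_and_p",
                            ifelse(rule2, "na_intensity", "none"))
  out
}

#' Select heatmap genes by within-gene intensity range
#'
#' Ranks genes by their max - min intensity across samples (descending,
#' ties broken lexicographically by gene id) and returns the top `k`.
#'
#' @param expr An [expression_table()] or a numeric matrix with gene
#'   rownames.
#' @param k Number of genes to select (1 <= k <= number of genes).
#' @return Character vector of `k` gene ids in selection order.
#' @export
select_heatmap_genes <- function(expr, k) {
  m <- if (inherits(expr, "expression_table")) expr$intensity else as.matrix(expr)
  if (k <= 0) stop("'k' must be positive")
  if (k > nrow(m)) stop("'k' exceeds the number of genes")
  rng <- apply(m, 1L, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    max(v) - min(v)
  })
  ord <- order(-rng, rownames(m), na.last = TRUE)
  rownames(m)[ord][seq_len(k)]
}

#' Log2-transform and mean-center an expression matrix
#'
#' Row-centers each gene to mean 0 (the standard preprocessing before
#' average-linkage clustering of expression heatmaps), after a log2
#' transformation of the intensities by default.
#'
#' @param expr An [expression_table()] or numeric matrix.
#' @param log2_transform Apply `log2()` before centering (intensities must
#'   then be strictly positive).
#' @return The centered numeric matrix.
#' @export
mean_center <- function(expr, log2_transform = TRUE) {
  m <- if (inherits(expr, "expression_table")) expr$intensity else as.matrix(expr)
  if (log2_transform) {
    if (any(m <= 0, na.rm = TRUE))
      stop("log2 transform requires strictly positive intensities")
    m <- log2(m)
  }
  m - rowMeans(m, na.rm = TRUE)
}

#' Average-linkage (UPGMA) clustering of genes
#'
#' Agglomerates genes by repeatedly merging the pair of clusters with the
#' smallest average inter-cluster distance; merge heights are those
#' averages and are non-decreasing. Distances are euclidean by default or
#' `1 - Pearson correlation` across samples; rows with undefined
#' correlation (zero variance) are dropped with a warning in the latter
#' case.
#'
#' @param m Centered numeric matrix (genes x samples), e.g. from
#'   [mean_center()]; >= 2 rows.
#' @param distance `"euclidean"` or `"pearson"` (meaning 1 - r).
#' @return An object of class `linkage_tree`: list with `merge`, `height`,
#'   `order`, `labels`, the underlying `hclust` object and the distance
#'   used.
#' @export
average_linkage_cluster <- function(m, distance = c("euclidean", "pearson")) {
  distance <- match.arg(distance)
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least 2 genes to cluster")
  if (distance == "pearson") {
    sds <- apply(m, 1L, stats::sd)
    if (any(sds == 0 | is.na(sds))) {
      warning("dropping ", sum(sds == 0 | is.na(sds)),
              " gene(s) with undefined correlation (zero variance)")
      m <- m[!(sds == 0 | is.na(sds)), , drop = FALSE]
      if (nrow(m) < 2L) stop("fewer than 2 genes left after dropping")
    }
    d <- stats::as.dist(1 - stats::cor(t(m)))
  } else {
    d <- stats::dist(m)
  }
  h <- stats::hclust(d, method = "average")
  structure(list(merge = h$merge, height = h$height, order = h$order,
                 labels = h$labels, hclust = h, distance = distance),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("<linkage_tree> UPGMA on %d genes (%s distance), %d merges\n",
              length(x$labels), x$distance, nrow(x$merge)))
  invisible(x)
}

#' @export
as.hclust.linkage_tree <- function(x, ...) x$hclust

#' Relative quantification by the 2^-ddCt method with error propagation
#'
#' Per group, `dCt = mean Ct_target - mean Ct_reference`; then
#' `ddCt = dCt_treated - dCt_calibrator` and the fold change is
#' `2^-ddCt`. The propagated standard deviation of ddCt is the quadrature
#' sum of the four mean Cts' standard errors, reported alongside the
#' fold-change interval `[2^(-ddCt - sd), 2^(-ddCt + sd)]`.
#'
#' @param ct `data.frame` with columns `gene, group, replicate, ct`.
#' @param target Target gene.
#' @param reference Reference (housekeeping) gene, e.g. RAB14.
#' @param calibrator_group,treated_group Group labels; fold change is
#'   treated relative to calibrator.
#' @return One-row `data.frame`: `gene, reference, ddct, fold_change,
#'   propagated_sd, fold_lower, fold_upper`. With single replicates the
#'   point estimate is returned and the sd fields are `NA` (warned).
#' @export
ddct_fold_change <- function(ct, target, reference,
                             calibrator_group = "calibrator",
                             treated_group = "treated") {
  need <- c("gene", "group", "ct")
  if (!all(need %in% names(ct)))
    stop("'ct' must have columns ", paste(need, collapse = ", "))
  cell <- function(gene, group) {
    v <- ct$ct[ct$gene == gene & ct$group == group]
    if (!length(v))
      stop("no Ct values for gene '", gene, "' in group '", group, "'")
    list(mean = mean(v), se = if (length(v) >= 2L)
      stats::sd(v) / sqrt(length(v)) else NA_real_, n = length(v))
  }
  t_cal <- cell(target, calibrator_group)
  t_trt <- cell(target, treated_group)
  r_cal <- cell(reference, calibrator_group)
  r_trt <- cell(reference, treated_group)
  ddct <- (t_trt$mean - r_trt$mean) - (t_cal$mean - r_cal$mean)
  ses <- c(t_trt$se, r_trt$se, t_cal$se, r_cal$se)
  if (anyNA(ses)) {
    warning("single-replicate group(s): propagated sd unavailable")
    sd_ddct <- NA_real_
  } else {
    sd_ddct <- sqrt(sum(ses^2))
  }
  data.frame(gene = target, reference = reference, ddct = ddct,
             fold_change = 2^(-ddct), propagated_sd = sd_ddct,
             fold_lower = 2^(-ddct - sd_ddct), fold_upper = 2^(-ddct + sd_ddct),
             stringsAsFactors = FALSE)
}
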