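toy_expr <- function() {
  m <- rbind(geneA = c(1000, 1100, 900, 4000, 4400, 3600),   # ~2-fold up
             geneB = c(1000, 1050, 950, 1800, 1900, 1700),   # < 2-fold
             geneC = c(500, 550, 450, 520, 530, 510))        # null
  colnames(m) <- paste0("s", 1:6)
  expression_table(m, rep(c("V", "T"), each = 3))
}

test_that("DEG rule 1 gates on both fold change and p-value", {
  deg <- differential_expression(toy_expr(), "V", "T")
  expect_equal(deg$passed_rule[deg$gene == "geneA"], "fc_and_p")
  # |log2 FC| = 0.86 < 1 with tiny p still fails the FC gate
  expect_lt(abs(deg$log2_fc[deg$gene == "geneB"]), 1)
  expect_lt(deg$p_value[deg$gene == "geneB"], 0.05)
  expect_equal(deg$passed_rule[deg$gene == "geneB"], "none")
  expect_equal(deg$passed_rule[deg$gene == "geneC"], "none")
  # relaxing either threshold never removes a selected gene
  deg_relax_fc <- differential_expression(toy_expr(), "V", "T",
                                          fc_threshold = 0.5)
  deg_relax_p <- differential_expression(toy_expr(), "V", "T", alpha = 0.2)
  for (g in deg$gene[deg$passed_rule == "fc_and_p"]) {
    expect_equal(deg_relax_fc$passed_rule[deg_relax_fc$gene == g], "fc_and_p")
    expect_equal(deg_relax_p$passed_rule[deg_relax_p$gene == g], "fc_and_p")
  }
})

test_that("NA-intensity rule fires only on undefined ratios with large differences", {
  m <- rbind(gone = c(NA, NA, NA, 1500, 1300, 1100),   # undefined, diff 1300
             gsmall = c(NA, NA, NA, 400, 500, 450),    # undefined, diff < 1000
             gzero = c(0, 0, 0, 1600, 1500, 1400),     # zeros: ratio undefined
             gfine = c(1000, 900, 1100, 2500, 2600, 2400))
  colnames(m) <- paste0("s", 1:6)
  et <- expression_table(m, rep(c("V", "T"), each = 3))
  deg <- differential_expression(et, "V", "T")
  expect_equal(deg$passed_rule[deg$gene == "gone"], "na_intensity")
  expect_equal(deg$passed_rule[deg$gene == "gsmall"], "none")
  expect_equal(deg$passed_rule[deg$gene == "gzero"], "na_intensity")
  expect_equal(deg$passed_rule[deg$gene == "gfine"], "fc_and_p")
  expect_true(is.na(deg$log2_fc[deg$gene == "gone"]))
})

test_that("planted fold changes are detected and the BH flag is honoured", {
  et <- simulate_expression(n_genes = 100, n_per_group = 5, de_genes = 20,
                            log2fc = 2, sigma = 0.1, seed = 5)
  deg <- differential_expression(et, "control", "treated")
  planted <- attr(et, "planted_genes")
  expect_true(all(deg$passed_rule[deg$gene %in% planted] == "fc_and_p"))
  expect_true(all(deg$passed_rule[!deg$gene %in% planted] == "none"))
  dega <- differential_expression(et, "control", "treated", adjust = TRUE)
  expect_true("p_adjusted" %in% names(dega))
  expect_true(all(dega$p_adjusted >= dega$p_value, na.rm = TRUE))
})

test_that("heatmap gene selection sorts by max-min range with ties lexicographic", {
  m <- rbind(A = c(0, 500), B = c(0, 1500), C = c(100, 200),
             D = c(50, 1550), E = c(7, 7))
  colnames(m) <- c("s1", "s2")
  expect_equal(select_heatmap_genes(m, 2), c("B", "D"))  # both range 1500, tie
  expect_equal(select_heatmap_genes(m, 4), c("B", "D", "A", "C"))
  # constant gene selected last only when k spans all genes
  expect_equal(select_heatmap_genes(m, 5)[5], "E")
  # invariant to sample order and to adding a constant
  expect_equal(select_heatmap_genes(m[, c(2, 1)], 3),
               select_heatmap_genes(m, 3))
  expect_equal(select_heatmap_genes(m + 100, 3), select_heatmap_genes(m, 3))
  expect_error(select_heatmap_genes(m, 0), "positive")
  expect_error(select_heatmap_genes(m, 6), "exceeds")
})

test_that("mean centering zeroes every gene's row mean", {
  expect_equal(mean_center(rbind(g = c(4, 6)), log2_transform = FALSE),
               rbind(g = c(-1, 1)))
  m <- matrix(2^rnorm(20, 8), 4, 5,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  cm <- mean_center(m)
  expect_equal(unname(rowMeans(cm)), rep(0, 4))
  # already-centered rows unchanged
  expect_equal(mean_center(cm, log2_transform = FALSE), cm)
  # single-sample row centers to zero
  expect_equal(unname(mean_center(matrix(5, 1, 1,
                                         dimnames = list("g", "s")),
                                  log2_transform = FALSE))[1, 1], 0)
  expect_error(mean_center(rbind(g = c(0, 1))), "positive")
})

test_that("UPGMA equals the brute-force all-pairs oracle", {
  set.seed(99)
  for (i in 1:30) {
    m <- matrix(rnorm(24), 6, 4,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
    tree <- average_linkage_cluster(m)
    expect_equal(nrow(tree$merge), 5L)  # n - 1 merges
    # heights non-decreasing along merges (UPGMA monotonicity)
    expect_false(is.unsorted(tree$height))
    coph <- as.matrix(stats::cophenetic(as.hclust(tree)))
    oracle <- naive_upgma_cophenetic(m)
    dimnames(oracle) <- dimnames(coph)
    expect_equal(coph, oracle, tolerance = 1e-12)
  }
})

test_that("UPGMA handles identical rows and degenerate correlation rows", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(9, 1, 4))
  tree <- average_linkage_cluster(m)
  expect_equal(tree$height[1], 0)  # identical rows merge at height 0
  # zero-variance rows are dropped for the correlation metric
  m2 <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(3, 2, 1), d = c(2, 4, 6))
  expect_warning(tree2 <- average_linkage_cluster(m2, distance = "pearson"),
                 "zero variance")
  expect_equal(length(tree2$labels), 3L)
  expect_error(average_linkage_cluster(m[1, , drop = FALSE]), "at least 2")
})

test_that("ddCt fold change and error propagation follow the 2^-ddCt method", {
  ct <- simulate_ct(c("CCL2", "POSTN"),
                    planted_ddct = c(CCL2 = -1, POSTN = 1.5),
                    sd = 0, n_reps = 3, seed = 2)
  expect_equal(ddct_fold_change(ct, "CCL2", "RAB14")$fold_change, 2)
  expect_equal(ddct_fold_change(ct, "POSTN", "RAB14")$fold_change, 2^-1.5)
  # a gene referenced against itself gives fold change exactly 1 with an
  # interval containing 1
  ctn <- simulate_ct("CCL2", planted_ddct = 2, sd = 0.3, n_reps = 4, seed = 3)
  self <- ddct_fold_change(ctn, "RAB14", "RAB14")
  expect_equal(self$fold_change, 1)
  expect_lte(self$fold_lower, 1)
  expect_gte(self$fold_upper, 1)
  # quadrature of standard errors against a Monte-Carlo resampling oracle
  cells <- split(ctn$ct, paste(ctn$gene, ctn$group))
  B <- 20000L
  set.seed(11)
  draws <- vapply(cells[c("CCL2 treated", "RAB14 treated",
                          "CCL2 calibrator", "RAB14 calibrator")],
                  function(v) colMeans(matrix(stats::rnorm(length(v) * B,
                                                           mean(v), sd(v)),
                                              length(v), B)),
                  numeric(B))
  mc_sd <- sd((draws[, 1] - draws[, 2]) - (draws[, 3] - draws[, 4]))
  res <- ddct_fold_change(ctn, "CCL2", "RAB14")
  expect_lt(abs(res$propagated_sd - mc_sd) / mc_sd, 0.05)
  # missing reference gene errors; single replicate warns
  expect_error(ddct_fold_change(ctn, "CCL2", "GAPDH"), "GAPDH")
  ct1 <- ctn[!(ctn$gene == "CCL2" & ctn$group == "treated" &
                 ctn$replicate > 1), ]
  expect_warning(r1 <- ddct_fold_change(ct1, "CCL2", "RAB14"), "single")
  expect_true(is.na(r1$propagated_sd))
})

test_that("null expression data yields few rule-1 calls", {
  # type-I behaviour: with no planted effects the FC gate keeps the
  # passing fraction far below alpha
  fracs <- vapply(1:10, function(s) {
    et <- simulate_expression(n_genes = 150, n_per_group = 5, de_genes = 0,
                              sigma = 0.1, seed = s)
    deg <- differential_expression(et, "control", "treated")
    mean(deg$passed_rule == "fc_and_p")
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)
})
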