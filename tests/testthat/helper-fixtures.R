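# Shared fixtures: canonical drug specs, exact median-effect fits built
# from noise-free ladders, and independent brute-force oracles.

spec_a <- function() drug_spec("drugA", cmax = 20, ec50 = 2, hill_slope = 1)
spec_b <- function() drug_spec("drugB", cmax = 5, ec50 = 0.5, hill_slope = 1.5)

# Median-effect fit from exact (noise-free) fa values on a drug's ladder,
# clamped points excluded as the pipeline does.
exact_me_fit <- function(spec, n_doses = 6) {
  d <- dose_ladder(spec$cmax, n_doses)
  r <- (d / spec$ec50)^spec$hill_slope
  fa <- fraction_affected(1 - r / (1 + r))
  fit_median_effect(d[!fa$clamped], fa$fa[!fa$clamped])
}

# Full single-agent -> normalize -> fa -> median-effect pipeline run.
pipeline_me_fit <- function(spec, noise_sd = 0, seed = 1, n_reps = 3) {
  cv <- normalize_viability(simulate_single_agent(
    spec, noise_sd = noise_sd, seed = seed, n_reps = n_reps))
  cv <- cv[cv$treatment_id == spec$name, ]
  fa <- fraction_affected(cv$viability)
  fit_median_effect(cv$dose_a_um[!fa$clamped], fa$fa[!fa$clamped])
}

# Brute-force O(n^3) UPGMA: returns the cophenetic distance matrix.
# Cluster-to-cluster distance is the mean over all member pairs.
naive_upgma_cophenetic <- function(m) {
  n <- nrow(m)
  D <- as.matrix(stats::dist(m))
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < bestd) { bestd <- d; best <- c(j, i) }
      }
    }
    ci <- clusters[[best[1L]]]; cj <- clusters[[best[2L]]]
    coph[ci, cj] <- bestd
    coph[cj, ci] <- bestd
    clusters[[best[1L]]] <- c(ci, cj)
    clusters[[best[2L]]] <- NULL
  }
  coph
}

# Scored synthetic panel: 12 treatments (7 singles + 5 combos) including a
# planted uniformly-best combination of two ultra-potent drugs.
panel_treatments <- function() {
  singles <- list(
    drug_spec("erlotinib", cmax = 20, ec50 = 4),
    drug_spec("mln0128", cmax = 1, ec50 = 0.3, hill_slope = 1.2),
    drug_spec("cobimetinib", cmax = 0.5, ec50 = 0.4),
    drug_spec("osimertinib", cmax = 2, ec50 = 1.5),
    drug_spec("drugE", cmax = 10, ec50 = 12),
    drug_spec("drugF", cmax = 5, ec50 = 6, hill_slope = 0.8),
    drug_spec("drugG", cmax = 8, ec50 = 10))
  potent_a <- drug_spec("potentA", cmax = 10, ec50 = 0.01)
  potent_b <- drug_spec("potentB", cmax = 10, ec50 = 0.01)
  combos <- list(
    combo_spec(singles[[1L]], singles[[2L]], psi = 1.5),
    combo_spec(singles[[1L]], singles[[3L]], psi = 1),
    combo_spec(singles[[2L]], singles[[4L]], psi = 0.8),
    combo_spec(singles[[5L]], singles[[6L]], psi = 1),
    combo_spec(potent_a, potent_b, psi = 2))
  c(singles, combos)
}
planted_winner_id <- "potentA+potentB"
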