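#' Single-drug specification for the synthetic screen
#'
#' Describes one drug by its clinical anchor concentration (Cmax, the highest
#' dose tested on the plate) and the four-parameter Hill curve that generates
#' its noise-free viability response. For a fully efficacious inhibitor
#' (`hill_top = 1`, `hill_bottom = 0`) the Hill curve is exactly the Chou
#' median-effect model with `Dm = ec50` and `m = hill_slope`, which is what
#' makes closed-form recovery tests possible downstream.
#'
#' @param name Drug identifier.
#' @param cmax Maximum plasma concentration in uM; top dose of the ladder.
#' @param ec50 Concentration of half-maximal effect in uM.
#' @param hill_slope Hill coefficient (> 0; larger = steeper).
#' @param hill_top Viability as dose -> 0 (vehicle-normalized fraction).
#' @param hill_bottom Viability at saturating dose.
#' @return An object of class `drug_spec`.
#' @examples
#' erlotinib <- drug_spec("erlotinib", cmax = 20, ec50 = 2)
#' @export
drug_spec <- function(name, cmax, ec50 = cmax / 10, hill_slope = 1,
                      hill_top = 1, hill_bottom = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(cmax) || length(cmax) != 1L || cmax <= 0)
    stop("'cmax' must be a single positive concentration (uM)")
  if (!is.numeric(ec50) || length(ec50) != 1L || ec50 <= 0)
    stop("'ec50' must be a single positive concentration (uM)")
  if (!is.numeric(hill_slope) || hill_slope <= 0)
    stop("'hill_slope' must be > 0")
  if (hill_bottom < 0 || hill_bottom > hill_top)
    stop("need 0 <= hill_bottom <= hill_top")
  structure(list(name = name, cmax = cmax, ec50 = ec50,
                 hill_slope = hill_slope, hill_top = hill_top,
                 hill_bottom = hill_bottom),
            class = "drug_spec")
}

#' @export
print.drug_spec <- function(x, ...) {
  cat(sprintf("<drug_spec> %s: Cmax %g uM, EC50 %g uM, slope %g, range [%g, %g]\n",
              x$name, x$cmax, x$ec50, x$hill_slope, x$hill_bottom, x$hill_top))
  invisible(x)
}

#' Drug-pair specification with known ground-truth interaction
#'
#' Describes a two-drug combination whose responses are generated under a
#' scaled Loewe-additivity construction: the noise-free fraction affected
#' `fa` at a dose pair (d_a, d_b) solves
#' `psi * d_a / Dx_a(fa) + psi * d_b / Dx_b(fa) = 1`,
#' where `Dx_i(fa) = Dm_i * (fa / (1 - fa))^(1/m_i)` comes from each
#' component's exact median-effect parameters. By construction the
#' combination index recovered downstream equals `1 / psi` at every dose
#' pair, so `psi > 1` plants synergy and `psi < 1` antagonism.
#'
#' @param drug_a,drug_b [drug_spec()] objects; both must be strictly
#'   monotone (`hill_top > hill_bottom`).
#' @param psi Interaction factor (> 0); ground-truth CI of the generated
#'   data is `1 / psi`.
#' @param dose_pairs Two-column matrix (uM) of (dose_a, dose_b) pairs.
#'   Default: a 6-point half-log co-dilution ladder topped at each drug's
#'   Cmax, mirroring a screen that co-dilutes the pair from (Cmax_a, Cmax_b).
#' @return An object of class `combo_spec`.
#' @export
combo_spec <- function(drug_a, drug_b, psi = 1, dose_pairs = NULL) {
  stopifnot(inherits(drug_a, "drug_spec"), inherits(drug_b, "drug_spec"))
  if (drug_a$hill_top <= drug_a$hill_bottom ||
      drug_b$hill_top <= drug_b$hill_bottom)
    stop("both component drugs must be strictly monotone (hill_top > hill_bottom)")
  if (!is.numeric(psi) || length(psi) != 1L || psi <= 0)
    stop("'psi' must be a single value > 0")
  if (is.null(dose_pairs)) {
    dose_pairs <- cbind(dose_a = dose_ladder(drug_a$cmax),
                        dose_b = dose_ladder(drug_b$cmax))
  }
  dose_pairs <- as.matrix(dose_pairs)
  if (ncol(dose_pairs) != 2L) stop("'dose_pairs' needs two columns (dose_a, dose_b)")
  if (any(dose_pairs < 0)) stop("dose pairs must be non-negative")
  if (any(rowSums(dose_pairs) == 0))
    stop("dose pair (0, 0) is degenerate: at least one component dose must be > 0")
  colnames(dose_pairs) <- c("dose_a", "dose_b")
  structure(list(drug_a = drug_a, drug_b = drug_b, psi = psi,
                 dose_pairs = dose_pairs,
                 name = paste0(drug_a$name, "+", drug_b$name)),
            class = "combo_spec")
}

#' @export
print.combo_spec <- function(x, ...) {
  cat(sprintf("<combo_spec> %s: psi = %g (ground-truth CI = %g), %d dose pairs\n",
              x$name, x$psi, 1 / x$psi, nrow(x$dose_pairs)))
  invisible(x)
}

#' Half-log dose ladder anchored at Cmax
#'
#' Serial dilution from the top dose downwards; returned ascending.
#'
#' @param cmax Top dose (uM).
#' @param n_doses Number of doses (>= 2).
#' @param dilution Fold-dilution between adjacent doses (default sqrt(10),
#'   i.e. half-log steps).
#' @return Ascending numeric vector of length `n_doses`.
#' @examples
#' dose_ladder(20)  # 20 / 10^(k/2), k = 5..0
#' @export
dose_ladder <- function(cmax, n_doses = 6, dilution = sqrt(10)) {
  if (!is.numeric(cmax) || cmax <= 0) stop("'cmax' must be positive")
  if (n_doses < 2) stop("'n_doses' must be >= 2")
  if (dilution <= 1) stop("'dilution' must be > 1")
  sort(cmax / dilution^(seq_len(n_doses) - 1))
}

# Noise-free viability from the 4PL / Hill model; dose 0 returns hill_top.
hill_viability <- function(dose, spec) {
  with(spec, ifelse(dose <= 0, hill_top,
                    hill_bottom + (hill_top - hill_bottom) /
                      (1 + (dose / ec50)^hill_slope)))
}

# Exact median-effect parameters of a drug_spec: with effect measured
# relative to the drug's own span, fa/(1-fa) = (d/ec50)^slope exactly.
median_effect_params <- function(spec) {
  c(dm = spec$ec50, m = spec$hill_slope)
}

# Evaluate code with a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}
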