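# Chou-Talalay-style n-drug combination index applied directly to measured
# viabilities (% of control):
#   CI = [ sum_k 1/V_k - (n-1)/100 ] / (1/V_comb)
# CI < 0.8 -> synergy; CI in [0.8, 1] -> additive band; CI > 1 -> antagonism.

# external-metric constants: thresholds obtained by linearly interpolating
# the CI = 0.8 synergy cutoff onto Combenefit's Loewe and Bliss scales;
# stored for interoperability only, no surface fitting is performed here
LOEWE_SYNERGY_THRESHOLD <- 7.8
BLISS_ADDITIVITY_THRESHOLD <- 2.5

ci_classify <- function(ci) {
  ifelse(ci < 0.8, "synergy", ifelse(ci > 1, "antagonism", "additive-band"))
}

check_percent_scale <- function(v) {
  # the (n-1)/100 correction makes the formula unit-dependent: viability
  # must be percent of control, so fraction-scale input is rejected
  if (all(v <= 1))
    stop("viabilities look like fractions; the combination index requires ",
         "percent of control (0-100 scale)")
}

#' n-drug combination index (median-effect principle)
#'
#' @param v_singles viabilities (% of control) of each drug alone, length
#'   n >= 2.
#' @param v_comb measured viability (%) of the n-drug combination.
#' @param v_floor viabilities below this are floored to it before taking
#'   reciprocals (default 1%), with a QC flag.
#' @return Object of class `ci_result`: `n`, `v_singles`, `v_comb`, `ci`,
#'   `classification`, `bliss_excess`, `hsa_excess`, `floored`.
#' @export
combination_index <- function(v_singles, v_comb, v_floor = 1) {
  if (length(v_singles) < 2) stop("need at least 2 single-agent viabilities")
  if (length(v_comb) != 1) stop("v_comb must be a single value")
  check_percent_scale(c(v_singles, v_comb))
  floored <- any(c(v_singles, v_comb) < v_floor)
  v_singles <- pmax(v_singles, v_floor)
  v_comb <- max(v_comb, v_floor)
  n <- length(v_singles)
  ci <- (sum(1 / v_singles) - (n - 1) / 100) / (1 / v_comb)
  bh <- bliss_hsa(v_singles, v_comb)
  structure(list(n = n, v_singles = v_singles, v_comb = v_comb,
                 ci = ci, classification = ci_classify(ci),
                 bliss_excess = bh$bliss_excess,
                 hsa_excess = bh$hsa_excess, floored = floored),
            class = "ci_result")
}

#' @export
print.ci_result <- function(x, ...) {
  cat(sprintf("CI(%d drugs) = %.4g [%s]\n", x$n, x$ci, x$classification))
  invisible(x)
}

#' Secondary combination index for multi-drug designs
#'
#' The combined effect of the first two drugs is treated as a single-drug
#' effect and the synergy of the third drug is scored on top of it:
#' `secondary_ci(V_AB, V_C, V_ABC) == combination_index(c(V_AB, V_C),
#' V_ABC)`. All three rotations (\[AB\]+C, \[BC\]+A, \[AC\]+B) are obtained
#' by permuting the arguments.
#'
#' @param v_pair_comb viability (%) of the two-drug combination.
#' @param v_third viability (%) of the third drug alone.
#' @param v_triple viability (%) of the triple combination.
#' @param v_floor as in [combination_index()].
#' @return A `ci_result` with n = 2.
#' @export
secondary_ci <- function(v_pair_comb, v_third, v_triple, v_floor = 1) {
  combination_index(c(v_pair_comb, v_third), v_triple, v_floor = v_floor)
}

#' Bliss and HSA excess over reference surfaces
#'
#' Bliss reference: product of single-agent fractional viabilities; HSA
#' (highest single agent) reference: the best single-drug effect. Positive
#' excess means the combination kills more than the reference predicts.
#'
#' @param v_singles single-agent viabilities (%), in \[0, 100\].
#' @param v_comb combination viability (%).
#' @return List with `bliss_excess` and `hsa_excess`, both in percentage
#'   points.
#' @export
bliss_hsa <- function(v_singles, v_comb) {
  stopifnot(all(v_singles >= 0 & v_singles <= 100), v_comb >= 0)
  list(bliss_excess = prod(v_singles / 100) * 100 - v_comb,
       hsa_excess = min(v_singles) - v_comb)
}

#' Score a checkerboard plate cell by cell and summarize
#'
#' For a two-drug plate every combination cell (both doses > 0) is scored
#' with [combination_index()] against the single-agent viabilities at the
#' matching doses. In secondary mode (three-drug plates) the pair
#' combination at (i, j) is treated as one agent and the third drug's
#' single-agent effect as the other. Cells whose combination viability
#' falls outside `[v_floor, v_ceiling]` are ineligible (reciprocals blow
#' up near 0 and CI is uninformative near the control); the summary CI is
#' the mean (or median) over eligible cells.
#'
#' @param plate a [checkerboard_plate].
#' @param mode `"primary"` (n-drug CI of all drugs at once) or
#'   `"secondary"` (third drug on top of the pair; 3-drug plates only).
#' @param summary `"mean"` (default) or `"median"`.
#' @param v_floor,v_ceiling eligibility window for combination viability
#'   (defaults 1 and 100%; lower the ceiling, e.g. to 99, to drop cells
#'   indistinguishable from the untreated control).
#' @return Object of class `plate_summary`: `cells` (data.frame with doses,
#'   viabilities, `ci`, `eligible`), `summary_ci`, `classification`,
#'   `n_eligible`, thresholds applied.
#' @export
summarize_plate <- function(plate, mode = c("primary", "secondary"),
                            summary = c("mean", "median"),
                            v_floor = 1, v_ceiling = 100) {
  mode <- match.arg(mode)
  summary <- match.arg(summary)
  stopifnot(inherits(plate, "checkerboard_plate"))
  nd <- length(plate$drugs)
  if (mode == "secondary" && nd != 3)
    stop("secondary mode requires a 3-drug plate")
  V <- plate$viability
  grid <- expand.grid(lapply(plate$doses, seq_along))
  rows <- list()
  for (r in seq_len(nrow(grid))) {
    idx <- as.integer(grid[r, ])
    if (sum(idx > 1) < 2) next          # untreated or single-agent cell
    v_comb <- V[matrix(idx, 1)]
    if (mode == "primary") {
      active <- which(idx > 1)
      v_singles <- vapply(active, function(a) {
        ii <- rep(1L, nd); ii[a] <- idx[a]
        V[matrix(ii, 1)]
      }, numeric(1))
    } else {
      if (idx[3] == 1) next             # secondary CI needs the third drug
      if (idx[1] == 1 || idx[2] == 1) next
      v_pair <- V[matrix(c(idx[1], idx[2], 1L), 1)]
      v_third <- V[matrix(c(1L, 1L, idx[3]), 1)]
      v_singles <- c(v_pair, v_third)
    }
    if (anyNA(c(v_singles, v_comb))) {
      rows[[length(rows) + 1L]] <-
        data.frame(cell = r, v_comb = v_comb, ci = NA_real_,
                   eligible = FALSE)
      next
    }
    ci <- combination_index(v_singles, v_comb, v_floor = v_floor)$ci
    rows[[length(rows) + 1L]] <-
      data.frame(cell = r, v_comb = v_comb, ci = ci,
                 eligible = v_comb >= v_floor && v_comb <= v_ceiling)
  }
  cells <- do.call(rbind, rows)
  dose_cols <- as.data.frame(lapply(seq_len(nd), function(k)
    plate$doses[[k]][grid[cells$cell, k]]))
  names(dose_cols) <- paste0("dose_", letters[seq_len(nd)])
  cells <- cbind(dose_cols, cells[, c("v_comb", "ci", "eligible")])
  n_inelig_na <- sum(is.na(cells$ci))
  if (n_inelig_na > 0)
    message(n_inelig_na, " cell(s) without single-agent reference skipped")
  elig <- cells$eligible & !is.na(cells$ci)
  summary_ci <- if (any(elig)) {
    if (summary == "mean") mean(cells$ci[elig]) else median(cells$ci[elig])
  } else NA_real_
  structure(list(drugs = plate$drugs, cells = cells,
                 summary_ci = summary_ci,
                 classification = if (is.na(summary_ci)) NA_character_
                 else ci_classify(summary_ci),
                 n_eligible = sum(elig), summary_stat = summary,
                 thresholds = c(ci_synergy = 0.8,
                                loewe = LOEWE_SYNERGY_THRESHOLD,
                                bliss = BLISS_ADDITIVITY_THRESHOLD)),
            class = "plate_summary")
}

#' @export
print.plate_summary <- function(x, ...) {
  cat(sprintf("plate %s: summary CI (%s) = %.4g [%s], %d eligible cells\n",
              paste(x$drugs, collapse = "+"), x$summary_stat,
              x$summary_ci, x$classification, x$n_eligible))
  invisible(x)
}
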