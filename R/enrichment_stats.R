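# Comparison statistics for distance/sensitivity sets and screen
# enrichment: one-sided Welch t-tests on distance distributions,
# chi-square enrichment of screen hits over a background rate, and a
# sensitivity-vs-synergy report stratified by targeting.

comparison_result <- function(kind, groups, sizes, means, ses, statistic,
                              p, extra = list()) {
  structure(c(list(test = kind, groups = groups, sizes = sizes,
                   means = means, standard_errors = ses,
                   statistic = statistic, p = p), extra),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %s | stat = %.4g, p = %.3g\n", x$test,
              paste(sprintf("%s (n=%d, mean=%.3g)", x$groups, x$sizes,
                            x$means), collapse = " vs "),
              x$statistic, x$p))
  invisible(x)
}

#' One-sided comparison of two distance sets
#'
#' Welch (unequal-variance) t-test of whether the synergy-pair distances
#' exceed the reference distances, plus shared histogram bins for
#' plotting both distributions.
#'
#' @param synergy_distances,reference_distances numeric vectors, each of
#'   length >= 2.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @param bins number of shared histogram bins (default 20).
#' @return A `comparison_result` with extra fields `histogram` (data.frame
#'   `mid`, `count_synergy`, `count_reference`).
#' @export
compare_distance_sets <- function(synergy_distances, reference_distances,
                                  alternative = "greater", bins = 20) {
  x <- synergy_distances[!is.na(synergy_distances)]
  y <- reference_distances[!is.na(reference_distances)]
  if (length(x) < 2 || length(y) < 2)
    stop("each distance set needs at least 2 values")
  if (sd(x) == 0 && sd(y) == 0) {
    # degenerate: both sets constant; the test statistic is +-Inf or 0
    dm <- mean(x) - mean(y)
    p <- switch(alternative,
                greater = if (dm > 0) 0 else if (dm < 0) 1 else 0.5,
                less = if (dm < 0) 0 else if (dm > 0) 1 else 0.5,
                if (dm == 0) 1 else 0)
    tt <- list(statistic = c(t = if (dm == 0) 0 else sign(dm) * Inf),
               p.value = p)
  } else {
    tt <- t.test(x, y, alternative = alternative, var.equal = FALSE)
  }
  breaks <- seq(min(c(x, y)), max(c(x, y)), length.out = bins + 1)
  breaks[1] <- breaks[1] - 1e-9; breaks[bins + 1] <- breaks[bins + 1] + 1e-9
  hx <- table(cut(x, breaks)); hy <- table(cut(y, breaks))
  comparison_result(
    "t_one_sided", c("synergy", "reference"),
    c(length(x), length(y)), c(mean(x), mean(y)),
    c(sd(x) / sqrt(length(x)), sd(y) / sqrt(length(y))),
    unname(tt$statistic), tt$p.value,
    extra = list(alternative = alternative,
                 histogram = data.frame(
                   mid = (head(breaks, -1) + breaks[-1]) / 2,
                   count_synergy = as.integer(hx),
                   count_reference = as.integer(hy))))
}

#' Chi-square enrichment of screen hits over background
#'
#' 2x2 chi-square (no Yates correction by default) comparing the hit
#' proportion of a screen against a background proportion.
#'
#' @param hits_a,total_a hits and total for the screen.
#' @param hits_b,total_b hits and total for the background.
#' @param correct apply Yates continuity correction (default FALSE).
#' @return A `comparison_result` with extra fields `observed` and
#'   `expected` (2x2 matrices). Expected cells below 1 trigger a warning
#'   recommending an exact test.
#' @export
enrichment_chi2 <- function(hits_a, total_a, hits_b, total_b,
                            correct = FALSE) {
  stopifnot(total_a >= hits_a, total_b >= hits_b, hits_a >= 0, hits_b >= 0)
  tab <- matrix(c(hits_a, total_a - hits_a,
                  hits_b, total_b - hits_b), 2, byrow = TRUE,
                dimnames = list(c("screen", "background"),
                                c("hit", "no_hit")))
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  if (any(ct$expected < 1))
    warning("expected cell count < 1; consider an exact test")
  comparison_result(
    "chi2", rownames(tab), c(total_a, total_b),
    c(hits_a / total_a, hits_b / total_b),
    c(NA_real_, NA_real_),
    unname(ct$statistic), ct$p.value,
    extra = list(observed = tab, expected = ct$expected))
}

#' Sensitivity-versus-synergy comparison report
#'
#' Compares the tissue-normalized sensitivity S of (cell line, drug)
#' cases that appear in synergy-labelled pairs against the overall S of
#' the same drugs, stratified by the targeted flag (drug targets a gene
#' mutated in the cell line). Lower S means more sensitive, so the
#' one-sided alternative is that synergy cases have smaller S. A
#' Benjamini-Hochberg column is added for transparency; no correction is
#' applied to the individual tests.
#'
#' @param sens_records output of [normalize_tissue()] (columns
#'   `cell_line`, `drug`, `tissue`, `S`).
#' @param labels a [synergy_table]; rows with `label == 1` define the
#'   synergy cases.
#' @param ann an [annotation] for the targeted stratification.
#' @return data.frame with one row per stratum (`all`, `targeted`,
#'   `non_targeted`): group sizes, mean S, t statistic, one-sided p, BH-
#'   adjusted p. Empty strata are skipped.
#' @export
sensitivity_synergy_report <- function(sens_records, labels, ann) {
  stopifnot(inherits(labels, "synergy_table"))
  pos <- labels[labels$label == 1, , drop = FALSE]
  case_keys <- unique(c(paste(pos$cell_line, pos$drug_a),
                        paste(pos$cell_line, pos$drug_b)))
  case_drugs <- unique(c(pos$drug_a, pos$drug_b))
  rec <- sens_records[sens_records$drug %in% case_drugs, , drop = FALSE]
  rec$is_case <- paste(rec$cell_line, rec$drug) %in% case_keys
  rec$targeted <- suppressWarnings(
    targeted_flag(rec$cell_line, rec$drug, ann)) == 1
  strata <- list(all = rep(TRUE, nrow(rec)),
                 targeted = rec$targeted,
                 non_targeted = !rec$targeted)
  rows <- list()
  for (nm in names(strata)) {
    rr <- rec[strata[[nm]], , drop = FALSE]
    if (sum(rr$is_case) < 2 || sum(!rr$is_case) < 2) next
    tt <- t.test(rr$S[rr$is_case], rr$S[!rr$is_case],
                 alternative = "less", var.equal = FALSE)
    rows[[nm]] <- data.frame(
      stratum = nm, n_synergy = sum(rr$is_case),
      n_overall = sum(!rr$is_case),
      mean_S_synergy = mean(rr$S[rr$is_case]),
      mean_S_overall = mean(rr$S[!rr$is_case]),
      statistic = unname(tt$statistic), p_one_sided = tt$p.value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$p_bh <- p.adjust(out$p_one_sided, "BH")
  rownames(out) <- NULL
  out
}
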