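#' Tissue-normalized drug sensitivity
#'
#' Within each (tissue, drug) stratum the log2 IC50 values are shifted so
#' the stratum average maps to 1: `S = 1 + (log2 IC50 - stratum mean)`.
#' S below 1 means more sensitive than the tissue average for that drug.
#' Records with a missing IC50 are skipped (count reported in a message).
#'
#' @param records data.frame with columns `cell_line`, `drug`, `tissue`,
#'   `log2_ic50`.
#' @return The records with an added column `S`; within every stratum
#'   `mean(S) == 1` exactly.
#' @export
normalize_tissue <- function(records) {
  need <- c("cell_line", "drug", "tissue", "log2_ic50")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  miss <- is.na(records$log2_ic50)
  if (any(miss)) {
    message("skipping ", sum(miss), " record(s) with missing IC50")
    records <- records[!miss, , drop = FALSE]
  }
  strat <- interaction(records$tissue, records$drug, drop = TRUE)
  mu <- ave(records$log2_ic50, strat)
  records$S <- 1 + (records$log2_ic50 - mu)
  records
}

#' Min-max 0-1 sensitivity scaling over a panel
#'
#' Per drug, values over the tested panel are scaled to \[0, 1\] with 0 for
#' the most sensitive (lowest IC50) and 1 for the least sensitive cell
#' line. A constant panel maps to 0.5 with a warning.
#'
#' @param records data.frame with columns `drug` and the value column.
#' @param value_col column to scale (default `"log2_ic50"`).
#' @return Records with an added `scaled01` column.
#' @export
scale01 <- function(records, value_col = "log2_ic50") {
  if (!value_col %in% names(records)) stop("no column ", value_col)
  v <- records[[value_col]]
  out <- rep(NA_real_, length(v))
  for (dr in unique(records$drug)) {
    i <- which(records$drug == dr & !is.na(v))
    if (length(i) < 2) {
      if (length(i) == 1) { out[i] <- 0.5
        warning("single value for drug ", dr, "; scaled01 set to 0.5") }
      next
    }
    rng <- range(v[i])
    if (diff(rng) == 0) {
      out[i] <- 0.5
      warning("constant panel for drug ", dr, "; scaled01 set to 0.5")
    } else out[i] <- (v[i] - rng[1]) / diff(rng)
  }
  records$scaled01 <- out
  records
}

#' Mutation-target flag for (cell line, drug) cases
#'
#' T is 1 when the drug's annotated target genes intersect the genes
#' affected (mutated or amplified) in the cell line, and 0.01 otherwise.
#' Drugs absent from the annotation get 0.01 with a warning.
#'
#' @param cell_line,drug equal-length character vectors.
#' @param ann an [annotation].
#' @return Numeric vector of T values in {0.01, 1}.
#' @export
targeted_flag <- function(cell_line, drug, ann) {
  stopifnot(inherits(ann, "annotation"), length(cell_line) == length(drug))
  unknown <- setdiff(unique(drug), names(ann$targets_of))
  if (length(unknown))
    warning("drug(s) without target annotation (T = 0.01): ",
            paste(unknown, collapse = ", "))
  vapply(seq_along(drug), function(i) {
    tg <- ann$targets_of[[drug[i]]]
    mu <- ann$mutated_in[[cell_line[i]]]
    if (length(tg) && length(mu) && length(intersect(tg, mu))) 1 else 0.01
  }, numeric(1))
}

#' Reduce a dose-response curve to absolute IC50 and AUC
#'
#' The absolute IC50 is the dose at which the interpolated viability
#' crosses 50% (linear interpolation in log2 dose between the flanking
#' points); missing when 50% is never crossed. The AUC is the trapezoid of
#' viability/100 over log2 dose, normalized by the dose span so it lies in
#' \[0, 1\]. A non-monotone (oscillating) curve is still reduced but
#' flagged for QC.
#'
#' @param dose positive doses, strictly increasing, length >= 4.
#' @param viability percent of untreated control at each dose.
#' @return List with `ic50`, `auc`, `qc_flag`.
#' @export
dose_response_reduce <- function(dose, viability) {
  stopifnot(length(dose) == length(viability), length(dose) >= 4,
            all(dose > 0), all(diff(dose) > 0))
  ld <- log2(dose)
  v <- viability
  # QC: total variation much larger than net drop indicates oscillation
  tv <- sum(abs(diff(v)))
  qc_flag <- tv > 2 * abs(v[1] - v[length(v)]) + 20
  auc <- sum(diff(ld) * (head(v, -1) + v[-1]) / 2) / 100 / diff(range(ld))
  ic50 <- NA_real_
  cross <- which((head(v, -1) - 50) * (v[-1] - 50) <= 0 &
                   (head(v, -1) != v[-1]))
  exact <- which(v == 50)
  if (length(exact)) {
    ic50 <- dose[exact[1]]
  } else if (length(cross)) {
    i <- cross[1]
    t <- (50 - v[i]) / (v[i + 1] - v[i])
    ic50 <- 2^(ld[i] + t * (ld[i + 1] - ld[i]))
  }
  list(ic50 = ic50, auc = auc, qc_flag = qc_flag)
}
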