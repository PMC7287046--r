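# Ground-truth generator. The generative picture: a small number of
# independent cellular "processes"; each drug inhibits exactly one
# process; each cell line is vulnerable to a subset of processes (driver
# mutations make vulnerability likely). A drug kills a line iff the line
# is vulnerable to the drug's process, so within-process drugs share
# response profiles and cross-process pairs are distant. Synergy arises
# for co-vulnerable cross-process pairs.

#' Simulation configuration
#'
#' Defaults describe a panel of 4 processes x 8 drugs over 60 cell lines
#' in 3 tissues with response noise sd 0.08 -- small enough to run a full
#' end-to-end analysis in seconds while preserving the planted structure.
#'
#' @param n_processes number of independent processes (default 4).
#' @param drugs_per_process drugs targeting each process (default 8).
#' @param n_cell_lines panel size (default 60).
#' @param tissues tissue labels cycled over cell lines.
#' @param vuln_prob baseline probability a line is vulnerable to a process
#'   (default 0.3).
#' @param mutation_rate per-line probability each driver gene is mutated
#'   (default 0.25).
#' @param p_vuln_given_mut vulnerability probability given the matching
#'   driver mutation (default 0.95).
#' @param base_resistant AUC of a resistant (line, drug) pair (default
#'   0.9).
#' @param effect AUC drop when the line is vulnerable to the drug's
#'   process (default 0.55).
#' @param noise_sd Gaussian response noise sd on the AUC scale (default
#'   0.08).
#' @param label_coefs named vector `alpha`, `beta`, `delta`, `gamma` of
#'   the label-generating logistic mechanism (defaults -2.2, 2, 3, -1).
#' @param synergy_factor multiplicative viability factor applied to
#'   combination cells of co-vulnerable cross-process pairs (default
#'   0.5; 1 = Bliss-independent).
#' @param plate_noise_sd multiplicative viability noise sd on plates
#'   (default 0.02).
#' @param seed mandatory integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_processes = 4, drugs_per_process = 8,
                       n_cell_lines = 60,
                       tissues = c("brain", "breast", "skin"),
                       vuln_prob = 0.3, mutation_rate = 0.25,
                       p_vuln_given_mut = 0.95,
                       base_resistant = 0.9, effect = 0.55,
                       noise_sd = 0.08,
                       label_coefs = c(alpha = -2.2, beta = 2,
                                       delta = 3, gamma = -1),
                       synergy_factor = 0.5, plate_noise_sd = 0.02,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(noise_sd > 0, vuln_prob >= 0, vuln_prob <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            p_vuln_given_mut >= 0, p_vuln_given_mut <= 1,
            all(c("alpha", "beta", "delta", "gamma") %in%
                  names(label_coefs)))
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a process-structured response panel with annotation
#'
#' Each cell line draws a driver-mutation profile (one driver gene per
#' process) and a vulnerability set; AUC = `base_resistant` - `effect` x
#' (vulnerable to the drug's process) + Gaussian noise, clipped to
#' \[0, 1\] (a warning reports clip fractions above 20%). Drugs are
#' annotated with their process's driver gene as target; a log2 IC50
#' sensitivity table consistent with the AUCs is derived for the
#' sensitivity workflow.
#'
#' @param cfg a [sim_config].
#' @return List of class `sim_panel`: `response` ([response_matrix]),
#'   `annotation` ([annotation]), `sensitivity` (data.frame `cell_line`,
#'   `drug`, `tissue`, `log2_ic50`), `truth` (process of each drug,
#'   vulnerability and mutation matrices).
#' @export
generate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    P <- cfg$n_processes
    drugs <- sprintf("drug%02d", seq_len(P * cfg$drugs_per_process))
    process_of_drug <- setNames(rep(seq_len(P), each = cfg$drugs_per_process),
                                drugs)
    genes <- sprintf("GENE%d", seq_len(P))
    lines <- sprintf("CL%03d", seq_len(cfg$n_cell_lines))
    tissue_of <- setNames(rep_len(cfg$tissues, cfg$n_cell_lines), lines)
    mut <- matrix(rbinom(cfg$n_cell_lines * P, 1, cfg$mutation_rate),
                  cfg$n_cell_lines, P, dimnames = list(lines, genes))
    p_vuln <- ifelse(mut == 1, cfg$p_vuln_given_mut, cfg$vuln_prob)
    vuln <- matrix(rbinom(length(p_vuln), 1, as.vector(p_vuln)),
                   nrow(p_vuln), ncol(p_vuln),
                   dimnames = dimnames(mut))
    auc_raw <- matrix(NA_real_, length(drugs), length(lines),
                      dimnames = list(drugs, lines))
    for (dr in drugs) {
      v <- vuln[, process_of_drug[dr]]
      auc_raw[dr, ] <- cfg$base_resistant - cfg$effect * v +
        rnorm(length(lines), 0, cfg$noise_sd)
    }
    clipped <- mean(auc_raw < 0 | auc_raw > 1)
    if (clipped > 0.2)
      warning(sprintf("%.0f%% of AUC values clipped to [0, 1]",
                      100 * clipped))
    auc <- pmin(pmax(auc_raw, 0), 1)
    resp <- response_matrix(auc, "auc", tissue_of)
    ann <- annotation(
      targets_of = lapply(process_of_drug, function(p) genes[p]),
      mutated_in = lapply(lines, function(cl) genes[mut[cl, ] == 1]) |>
        setNames(lines),
      pathway_of = setNames(paste0("process_", process_of_drug), drugs))
    sens <- data.frame(
      cell_line = rep(lines, each = length(drugs)),
      drug = rep(drugs, times = length(lines)),
      tissue = rep(unname(tissue_of[lines]), each = length(drugs)),
      log2_ic50 = as.vector(8 * (auc[, lines] - 0.5)),
      stringsAsFactors = FALSE)
    structure(list(response = resp, annotation = ann, sensitivity = sens,
                   truth = list(process_of_drug = process_of_drug,
                                vulnerable = vuln, mutated = mut,
                                genes = genes)),
              class = "sim_panel")
  })
}

#' Generate synergy labels from the planted mechanism
#'
#' For every (cell line, drug pair) a label is drawn Bernoulli(theta)
#' with `logit(theta) = alpha + beta * t + delta * d_true + gamma *
#' (S_a + S_b)`, where `t` is the mutation-target flag, `d_true` a
#' smoothed cross-process indicator (cross-process pairs draw from
#' \[0.6, 1\], within-process from \[0, 0.4\]) and `S` the 0-1 scaled
#' sensitivity. Ground-truth coefficients and `d_true` are stored as
#' attributes for recovery tests.
#'
#' @param panel a `sim_panel`.
#' @param cfg the [sim_config] used to generate it.
#' @param max_rows optional cap: a random subset of this many rows.
#' @return A [synergy_table] with attributes `coefs`, `rows`
#'   (the generating covariates incl. `d_true` and `cross_process`).
#' @export
generate_labels <- function(panel, cfg, max_rows = NULL) {
  stopifnot(inherits(panel, "sim_panel"))
  with_seed(cfg$seed + 1L, {
    drugs <- rownames(panel$response$values)
    lines <- colnames(panel$response$values)
    prs <- t(combn(drugs, 2))
    rows <- data.frame(
      cell_line = rep(lines, each = nrow(prs)),
      drug_a = rep(prs[, 1], times = length(lines)),
      drug_b = rep(prs[, 2], times = length(lines)),
      stringsAsFactors = FALSE)
    if (!is.null(max_rows) && nrow(rows) > max_rows)
      rows <- rows[sample.int(nrow(rows), max_rows), , drop = FALSE]
    pod <- panel$truth$process_of_drug
    cross <- pod[rows$drug_a] != pod[rows$drug_b]
    d_true <- ifelse(cross, runif(nrow(rows), 0.6, 1),
                     runif(nrow(rows), 0, 0.4))
    tt <- suppressWarnings(
      pmax(targeted_flag(rows$cell_line, rows$drug_a, panel$annotation),
           targeted_flag(rows$cell_line, rows$drug_b, panel$annotation)))
    s01 <- scale01(panel$sensitivity)
    skey <- setNames(s01$scaled01, paste(s01$cell_line, s01$drug))
    s_a <- unname(skey[paste(rows$cell_line, rows$drug_a)])
    s_b <- unname(skey[paste(rows$cell_line, rows$drug_b)])
    cf <- cfg$label_coefs
    eta <- cf["alpha"] + cf["beta"] * tt + cf["delta"] * d_true +
      cf["gamma"] * (s_a + s_b)
    lab <- rbinom(nrow(rows), 1, plogis(eta))
    st <- synergy_table(rows$cell_line, rows$drug_a, rows$drug_b, lab,
                        source = "simulated")
    # canonical ordering in synergy_table never swaps here: pairs from
    # combn over sorted drug names are already lexicographic
    attr(st, "coefs") <- cf
    attr(st, "rows") <- cbind(rows, d_true = d_true, t = tt,
                              s_a = s_a, s_b = s_b,
                              cross_process = cross, theta = plogis(eta))
    st
  })
}

#' Simulate model rows directly from the logistic mechanism
#'
#' Draws covariates (t uniform over {0.01, 1}, d ~ U(0, 1), sensitivities
#' ~ U(0, 1)) and labels from `logit(theta) = alpha + beta t + delta d +
#' gamma (S_a + S_b)`. This is the parameter-recovery oracle for
#' [fit_logistic()]: fitting the same covariates on these rows should
#' recover the generating slopes.
#'
#' @param n number of rows.
#' @param alpha,beta,delta,gamma generating coefficients (defaults -1.5,
#'   2, 3, -1).
#' @param tissues tissue labels assigned at random.
#' @param seed integer seed.
#' @return A `pair_rows` data.frame with attribute `coefs`.
#' @export
simulate_pair_rows <- function(n, alpha = -1.5, beta = 2, delta = 3,
                               gamma = -1,
                               tissues = c("brain", "breast", "skin"),
                               seed = 1L) {
  with_seed(seed, {
    n_drugs <- max(8L, ceiling(sqrt(4 * n)))
    drugs <- sprintf("drug%03d", seq_len(n_drugs))
    pick <- t(vapply(seq_len(n), function(i)
      sort(sample(drugs, 2)), character(2)))
    tt <- ifelse(runif(n) < 0.5, 1, 0.01)
    d <- runif(n)
    s_a <- runif(n); s_b <- runif(n)
    eta <- alpha + beta * tt + delta * d + gamma * (s_a + s_b)
    out <- data.frame(
      cell_line = sprintf("CL%04d", sample.int(200, n, replace = TRUE)),
      tissue = sample(tissues, n, replace = TRUE),
      drug_a = pick[, 1], drug_b = pick[, 2],
      d = d, s_a = s_a, s_b = s_b,
      t_a = tt, t_b = 0.01, t = tt, c = 1L,
      label = rbinom(n, 1, plogis(eta)),
      stringsAsFactors = FALSE)
    class(out) <- c("pair_rows", "data.frame")
    attr(out, "coefs") <- c(alpha = alpha, beta = beta, delta = delta,
                            gamma = gamma)
    out
  })
}

#' Generate checkerboard plates from the panel
#'
#' Single-agent dose-response follows a unit-slope Hill curve anchored at
#' the (drug, line) IC50 implied by the panel sensitivity; dose ladders
#' run twofold downward from the IC50 (untreated + 5 doses). Combination
#' viability is the Bliss product times a synergy factor: `synergy_factor`
#' for co-vulnerable cross-process pairs, 1 otherwise, with small
#' multiplicative noise.
#'
#' @param panel a `sim_panel`.
#' @param cfg its [sim_config].
#' @param pairs 2-column character matrix of drug pairs (default: one
#'   within-process and one cross-process pair).
#' @param cell_lines cell lines to plate (default: first 6).
#' @return List of [checkerboard_plate]s with attributes `cell_line`,
#'   `pair` and `truth_factor` on each element.
#' @export
generate_plates <- function(panel, cfg, pairs = NULL, cell_lines = NULL) {
  stopifnot(inherits(panel, "sim_panel"))
  drugs <- rownames(panel$response$values)
  pod <- panel$truth$process_of_drug
  if (is.null(pairs)) {
    within <- drugs[pod == pod[1]][1:2]
    crossd <- c(drugs[pod == pod[1]][1], drugs[pod != pod[1]][1])
    pairs <- rbind(within, crossd)
  }
  if (is.null(cell_lines))
    cell_lines <- head(colnames(panel$response$values), 6)
  sens <- panel$sensitivity
  ic50_of <- setNames(2^sens$log2_ic50, paste(sens$cell_line, sens$drug))
  with_seed(cfg$seed + 2L, {
    plates <- list()
    for (cl in cell_lines) {
      for (r in seq_len(nrow(pairs))) {
        da <- pairs[r, 1]; db <- pairs[r, 2]
        co_vuln <- pod[da] != pod[db] &&
          panel$truth$vulnerable[cl, pod[da]] == 1 &&
          panel$truth$vulnerable[cl, pod[db]] == 1
        fac <- if (co_vuln) cfg$synergy_factor else 1
        mk_doses <- function(dr) {
          top <- unname(ic50_of[paste(cl, dr)])
          c(0, top / 2^(4:0))
        }
        doses <- list(mk_doses(da), mk_doses(db))
        hill <- function(dose, top) ifelse(dose == 0, 100,
                                           100 / (1 + dose / top))
        va <- hill(doses[[1]], unname(ic50_of[paste(cl, da)]))
        vb <- hill(doses[[2]], unname(ic50_of[paste(cl, db)]))
        V <- outer(va, vb, function(x, y) x * y / 100)
        comb <- outer(seq_along(va) > 1, seq_along(vb) > 1, `&`)
        V[comb] <- V[comb] * fac
        noise <- matrix(exp(rnorm(length(V), 0, cfg$plate_noise_sd)),
                        nrow(V))
        noise[1, 1] <- 1                  # untreated control stays at 100
        V <- V * noise
        pl <- checkerboard_plate(c(da, db), doses, V)
        attr(pl, "cell_line") <- cl
        attr(pl, "pair") <- c(da, db)
        attr(pl, "truth_factor") <- fac
        plates[[length(plates) + 1L]] <- pl
      }
    }
    plates
  })
}
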