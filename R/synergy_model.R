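# Feature assembly and logistic synergy models. One row per (cell line,
# unordered drug pair) with: normalized cophenetic distance d, per-drug
# normalized sensitivities S_i/S_j, target flags T in {0.01, 1} and their
# max t, availability flag C, binary synergy Label. Model covariates:
#   IA : t            IB : t + d
#   IIA: t + S_i+S_j  IIB: t + d + S_i + S_j
# The two sensitivity covariates share one coefficient gamma (the
# unordered-pair exchangeability of i and j forces a single slope).

#' Assemble model rows from distances, sensitivities, annotation and labels
#'
#' @param distances symmetric drug distance matrix (normalized cophenetic,
#'   see [cophenetic_distance()]).
#' @param sensitivities data.frame with `cell_line`, `drug`, `tissue` and a
#'   sensitivity column (default `S` from [normalize_tissue()]).
#' @param ann an [annotation] for target flags.
#' @param labels a [synergy_table].
#' @param sens_col sensitivity column name (default `"S"`).
#' @param strict if TRUE (default) `C = 1` requires sensitivity for both
#'   drugs (models IIA/IIB); if FALSE one drug suffices (IA/IB reading).
#' @return data.frame of class `pair_rows`: `cell_line`, `tissue`,
#'   `drug_a`, `drug_b`, `d`, `s_a`, `s_b`, `t_a`, `t_b`, `t`, `c`,
#'   `label`. Pairs without a distance are dropped (message).
#' @export
assemble_features <- function(distances, sensitivities, ann, labels,
                              sens_col = "S", strict = TRUE) {
  stopifnot(inherits(labels, "synergy_table"), inherits(ann, "annotation"))
  dm <- as.matrix(distances)
  ok_pair <- labels$drug_a %in% rownames(dm) & labels$drug_b %in% rownames(dm)
  have_d <- ok_pair
  have_d[ok_pair] <- !is.na(dm[cbind(labels$drug_a[ok_pair],
                                     labels$drug_b[ok_pair])])
  if (any(!have_d)) {
    message("dropping ", sum(!have_d), " row(s) with no pair distance")
    labels <- labels[have_d, , drop = FALSE]
  }
  skey <- paste(sensitivities$cell_line, sensitivities$drug)
  sval <- setNames(sensitivities[[sens_col]], skey)
  tis <- setNames(as.character(sensitivities$tissue),
                  sensitivities$cell_line)
  s_a <- unname(sval[paste(labels$cell_line, labels$drug_a)])
  s_b <- unname(sval[paste(labels$cell_line, labels$drug_b)])
  t_a <- suppressWarnings(targeted_flag(labels$cell_line, labels$drug_a, ann))
  t_b <- suppressWarnings(targeted_flag(labels$cell_line, labels$drug_b, ann))
  cc <- if (strict) as.integer(!is.na(s_a) & !is.na(s_b)) else
    as.integer(!is.na(s_a) | !is.na(s_b))
  out <- data.frame(cell_line = labels$cell_line,
                    tissue = unname(tis[labels$cell_line]),
                    drug_a = labels$drug_a, drug_b = labels$drug_b,
                    d = dm[cbind(labels$drug_a, labels$drug_b)],
                    s_a = s_a, s_b = s_b, t_a = t_a, t_b = t_b,
                    t = pmax(t_a, t_b), c = cc,
                    label = labels$label, stringsAsFactors = FALSE)
  class(out) <- c("pair_rows", "data.frame")
  out
}

#' Per-row objective combining sensitivity, distance and targeting
#'
#' Computes `C * (-s * S_bar + d * D + t * (T_a + T_b))` per row, with
#' `S_bar = (S_a + S_b) / 2`. Rows with `C = 0` contribute 0.
#'
#' @param rows a `pair_rows` data.frame.
#' @param s,d,t non-negative weight parameters.
#' @return Numeric vector of per-row values with attribute `"total"`.
#' @export
eq_objective <- function(rows, s = 1, d = 1, t = 1) {
  s_bar <- (rows$s_a + rows$s_b) / 2
  val <- rows$c * (-s * s_bar + d * rows$d + t * (rows$t_a + rows$t_b))
  val[rows$c == 0] <- 0
  structure(val, total = sum(val, na.rm = TRUE))
}

#' Bounded diagnostic fit of the objective weights
#'
#' The loss is the squared error between the logistic transform of the
#' per-row objective and the synergy label, minimized per tissue over a
#' bounded box. This is a diagnostic score, not the predictor; the
#' logistic models are the fitting route.
#'
#' @param rows a `pair_rows` data.frame.
#' @param lower,upper box bounds for (s, d, t).
#' @return data.frame with one row per tissue: fitted `s`, `d`, `t`, loss.
#' @export
eq_objective_minimize <- function(rows, lower = c(0, 0, 0),
                                  upper = c(10, 10, 10)) {
  rows <- rows[rows$c == 1 & complete.cases(rows[, c("s_a", "s_b", "d")]), ]
  do.call(rbind, lapply(split(rows, rows$tissue), function(rr) {
    loss <- function(p) {
      v <- eq_objective(rr, p[1], p[2], p[3])
      mean((plogis(v) - rr$label)^2)
    }
    fit <- optim(c(1, 1, 1), loss, method = "L-BFGS-B",
                 lower = lower, upper = upper)
    data.frame(tissue = rr$tissue[1], s = fit$par[1], d = fit$par[2],
               t = fit$par[3], loss = fit$value)
  }))
}

#' Simplistic closed-form synergy score
#'
#' `theta = t * exp(d) / (1 + t * exp(d))`: increasing in both the drug
#' distance d and the target flag t, and close to zero when neither drug
#' targets a mutated gene (t = 0.01). Identical to the logistic inverse
#' link of `d + log(t)`.
#'
#' @param t target flag(s) in {0.01, 1} (numeric, vectorized).
#' @param d non-negative drug distance(s).
#' @return theta in (0, 1).
#' @export
simplistic_theta <- function(t, d) {
  stopifnot(all(d >= 0))
  t * exp(d) / (1 + t * exp(d))
}

#' Average the simplistic score per drug pair over its cell lines
#'
#' @param rows a `pair_rows` data.frame.
#' @return data.frame with `drug_a`, `drug_b`, `theta` (mean over cell
#'   lines), `n_cell_lines`.
#' @export
simplistic_pair_scores <- function(rows) {
  th <- simplistic_theta(rows$t, rows$d)
  agg <- aggregate(list(theta = th),
                   by = list(drug_a = rows$drug_a, drug_b = rows$drug_b),
                   FUN = mean)
  cnt <- aggregate(list(n_cell_lines = th),
                   by = list(drug_a = rows$drug_a, drug_b = rows$drug_b),
                   FUN = length)
  merge(agg, cnt, by = c("drug_a", "drug_b"))
}

model_covariates <- function(model) {
  switch(model,
         IA = "t", IB = c("t", "d"),
         IIA = c("t", "s_sum"), IIB = c("t", "d", "s_sum"),
         stop("unknown model ", model))
}

prep_rows <- function(rows, model) {
  rows <- rows[rows$c == 1, , drop = FALSE]
  rows$s_sum <- rows$s_a + rows$s_b
  need <- c(model_covariates(model), "label", "tissue")
  rows[complete.cases(rows[, need, drop = FALSE]), , drop = FALSE]
}

balanced_draw <- function(rows) {
  # within each tissue keep all positives and draw an equal number of
  # negatives at random (class balance exactly 1:1 per tissue)
  idx <- unlist(lapply(split(seq_len(nrow(rows)), rows$tissue), function(i) {
    pos <- i[rows$label[i] == 1]
    neg <- i[rows$label[i] == 0]
    if (length(pos) == 0 || length(neg) == 0) return(integer())
    c(pos, neg[sample.int(length(neg), length(pos),
                          replace = length(neg) < length(pos))])
  }), use.names = FALSE)
  rows[idx, , drop = FALSE]
}

fit_one_glm <- function(dat, covars) {
  f <- stats::as.formula(paste("label ~", paste(covars, collapse = " + ")))
  sep_flag <- FALSE
  fit <- withCallingHandlers(
    glm(f, data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_flag <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- coef(fit)
  if (sep_flag || any(!is.finite(cf)) || any(abs(cf) > 50)) {
    # near-separation: refit with a tiny L2 ridge for a finite estimate
    x <- as.matrix(dat[, covars, drop = FALSE])
    if (ncol(x) == 1) x <- cbind(x, jitter_col = 0)  # glmnet needs >= 2 cols
    rf <- glmnet::glmnet(x, dat$label, family = "binomial", alpha = 0,
                         lambda = 1e-6, standardize = FALSE)
    cf2 <- as.numeric(coef(rf))
    names(cf2) <- rownames(coef(rf))
    cf <- c(`(Intercept)` = cf2[1],
            setNames(cf2[match(covars, names(cf2))], covars))
    names(cf)[1] <- "(Intercept)"
    attr(cf, "ridge") <- TRUE
  }
  cf
}

#' Fit a logistic synergy model with balanced negative resampling
#'
#' Per resample, every positive row is kept and an equal number of
#' negative rows is drawn at random within each tissue; a maximum-
#' likelihood logistic fit of the model's covariates is computed on the
#' pooled balanced data (set `per_tissue = TRUE` for separate fits per
#' tissue stratum, skipping strata with fewer than `min_pos` positives).
#' Aggregate coefficients are the means over resamples. Resamples hitting
#' perfect separation are refit with a small L2 ridge and flagged.
#'
#' @param rows a `pair_rows` data.frame.
#' @param model `"IA"`, `"IB"`, `"IIA"` or `"IIB"`.
#' @param n_resamples number of balanced negative draws (default 1000).
#' @param seed integer seed; fits are deterministic given it.
#' @param per_tissue fit separately per tissue (default FALSE, pooled with
#'   tissue-stratified draws).
#' @param min_pos minimum positives per tissue stratum when
#'   `per_tissue = TRUE` (default 5).
#' @return Object of class `logistic_fit`: `model`, `coefficients`
#'   (aggregate means), `resample_coefficients` (matrix), `n_resamples`,
#'   `n_ridge` (separation-flagged resamples), `covariates`.
#' @export
fit_logistic <- function(rows, model = c("IB", "IA", "IIA", "IIB"),
                         n_resamples = 1000, seed = 1L,
                         per_tissue = FALSE, min_pos = 5) {
  model <- match.arg(model)
  covars <- model_covariates(model)
  dat <- prep_rows(rows, model)
  if (!all(c(0, 1) %in% dat$label)) stop("need both label classes")
  with_seed(seed, {
    n_ridge <- 0L
    cmat <- matrix(NA_real_, n_resamples, length(covars) + 1,
                   dimnames = list(NULL, c("(Intercept)", covars)))
    for (r in seq_len(n_resamples)) {
      bal <- balanced_draw(dat)
      if (per_tissue) {
        tissues <- names(which(table(bal$tissue[bal$label == 1]) >= min_pos))
        if (!length(tissues))
          stop("no tissue stratum with >= ", min_pos, " positives")
        cfs <- vapply(tissues, function(ts)
          fit_one_glm(bal[bal$tissue == ts, , drop = FALSE], covars),
          numeric(length(covars) + 1))
        cf <- rowMeans(cfs)
      } else {
        cf <- fit_one_glm(bal, covars)
      }
      if (isTRUE(attr(cf, "ridge"))) n_ridge <- n_ridge + 1L
      cmat[r, ] <- cf[colnames(cmat)]
    }
    structure(list(model = model, covariates = covars,
                   coefficients = colMeans(cmat),
                   resample_coefficients = cmat,
                   n_resamples = n_resamples, n_ridge = n_ridge,
                   sigma2 = NA_real_),
              class = "logistic_fit")
  })
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("logistic_fit model", x$model, "(", x$n_resamples, "resamples )\n")
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' Predicted synergy probability for candidate rows
#'
#' @param object a `logistic_fit`.
#' @param newdata a `pair_rows` data.frame.
#' @param ... unused.
#' @return Numeric vector of predicted theta.
#' @export
predict.logistic_fit <- function(object, newdata, ...) {
  newdata$s_sum <- newdata$s_a + newdata$s_b
  x <- as.matrix(newdata[, object$covariates, drop = FALSE])
  eta <- object$coefficients[1] +
    as.vector(x %*% object$coefficients[object$covariates])
  plogis(eta)
}

# exact rank-statistic AUC: probability that a random positive scores
# above a random negative, ties counted half
auc_rank <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) stop("need both classes for AUC")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  tpr <- cumsum(lab == 1) / sum(lab == 1)
  fpr <- cumsum(lab == 0) / sum(lab == 0)
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' ROC curve and AUC of a fitted synergy model
#'
#' AUC is the exact rank statistic (probability a random positive row
#' scores above a random negative). Scheme `"cv_kfold"` refits the model
#' on k-1 folds and scores the held-out fold, with folds stratified by
#' drug pair so no pair spans folds; `"holdout"` splits pairs once;
#' `"external"` scores the frozen coefficients on the given rows.
#'
#' @param fit a `logistic_fit`.
#' @param rows a `pair_rows` data.frame containing both classes.
#' @param scheme `"external"`, `"cv_kfold"` or `"holdout"`.
#' @param k folds (default 5).
#' @param holdout_fraction pair fraction held out (default 0.3).
#' @param seed integer seed for fold assignment and refits.
#' @param n_resamples resamples for refits in cv/holdout (default 25).
#' @return List with `auc` and `roc` (data.frame `fpr`, `tpr`).
#' @export
evaluate_auc <- function(fit, rows,
                         scheme = c("external", "cv_kfold", "holdout"),
                         k = 5, holdout_fraction = 0.3, seed = 1L,
                         n_resamples = 25) {
  scheme <- match.arg(scheme)
  dat <- prep_rows(rows, fit$model)
  if (!all(c(0, 1) %in% dat$label)) stop("need both label classes")
  if (scheme == "external") {
    sc <- predict(fit, dat)
    return(list(auc = auc_rank(sc, dat$label),
                roc = roc_points(sc, dat$label)))
  }
  pair_id <- paste(dat$drug_a, dat$drug_b)
  pairs <- unique(pair_id)
  with_seed(seed, {
    if (scheme == "cv_kfold") {
      fold_of <- setNames(sample(rep_len(seq_len(k), length(pairs))), pairs)
      folds <- fold_of[pair_id]
      sc <- rep(NA_real_, nrow(dat))
      for (f in seq_len(k)) {
        train <- dat[folds != f, , drop = FALSE]
        if (!all(c(0, 1) %in% train$label)) next
        m <- fit_logistic(train, fit$model, n_resamples = n_resamples,
                          seed = sample.int(2^30, 1))
        sc[folds == f] <- predict(m, dat[folds == f, , drop = FALSE])
      }
      keep <- !is.na(sc)
      list(auc = auc_rank(sc[keep], dat$label[keep]),
           roc = roc_points(sc[keep], dat$label[keep]))
    } else {
      test_pairs <- sample(pairs, ceiling(holdout_fraction * length(pairs)))
      test <- pair_id %in% test_pairs
      m <- fit_logistic(dat[!test, , drop = FALSE], fit$model,
                        n_resamples = n_resamples,
                        seed = sample.int(2^30, 1))
      sc <- predict(m, dat[test, , drop = FALSE])
      list(auc = auc_rank(sc, dat$label[test]),
           roc = roc_points(sc, dat$label[test]))
    }
  })
}

#' Compare covariate contributions across the four model fits
#'
#' Fits IA vs IB and IIA vs IIB over paired balanced resamples and tests
#' whether adding the drug distance raises the AUC (one-sided paired
#' t-test on resample-level AUC differences).
#'
#' @param rows a `pair_rows` data.frame.
#' @param n_resamples paired resamples (default 50).
#' @param seed integer seed.
#' @return List with `auc_table` (mean AUC per model) and `contrasts`
#'   (data.frame: comparison, mean delta AUC, one-sided p).
#' @export
covariate_contribution <- function(rows, n_resamples = 50, seed = 1L) {
  models <- c("IA", "IB", "IIA", "IIB")
  dat <- prep_rows(rows, "IIB")
  if (!all(c(0, 1) %in% dat$label)) stop("need both label classes")
  with_seed(seed, {
    aucs <- matrix(NA_real_, n_resamples, length(models),
                   dimnames = list(NULL, models))
    for (r in seq_len(n_resamples)) {
      bal <- balanced_draw(dat)
      for (m in models) {
        cf <- fit_one_glm(bal, model_covariates(m))
        fobj <- structure(list(model = m,
                               covariates = model_covariates(m),
                               coefficients = cf),
                          class = "logistic_fit")
        aucs[r, m] <- auc_rank(predict(fobj, dat), dat$label)
      }
    }
    contrast <- function(a, b) {
      dlt <- aucs[, b] - aucs[, a]
      p <- if (sd(dlt) == 0) as.numeric(mean(dlt) <= 0) else
        t.test(dlt, alternative = "greater")$p.value
      data.frame(comparison = paste(b, ">", a),
                 delta_auc = mean(dlt), p_one_sided = p)
    }
    list(auc_table = colMeans(aucs),
         resample_aucs = aucs,
         contrasts = rbind(contrast("IA", "IB"), contrast("IIA", "IIB")))
  })
}

#' Rank candidate drug pairs by predicted synergy
#'
#' Candidates are sorted by predicted theta (descending); ties break
#' toward the larger drug distance, then lexicographically by pair.
#'
#' @param fit a `logistic_fit`.
#' @param candidates a `pair_rows` data.frame (labels may be `NA`).
#' @return The candidate rows with a `theta` column, ranked.
#' @export
rank_predictions <- function(fit, candidates) {
  candidates$theta <- predict(fit, candidates)
  ord <- order(-candidates$theta, -candidates$d,
               candidates$drug_a, candidates$drug_b)
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
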