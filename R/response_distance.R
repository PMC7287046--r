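#' Cosine dissimilarity of drug-effect vectors
#'
#' Each drug's effect over the panel is represented as its 1-AUC vector
#' (high = sensitive cell line). The dissimilarity between two drugs is
#' 1 minus the cosine of the angle between their 1-AUC vectors, restricted
#' to cell lines where both drugs were measured. For non-negative vectors
#' the result lies in \[0, 1\].
#'
#' @param m a [response_matrix] with `value_kind == "auc"`.
#' @param min_overlap minimum number of shared measured cell lines per drug
#'   pair; pairs below it get a missing entry with a warning. Default 5.
#' @return A symmetric matrix of class `dist_matrix` with zero diagonal and
#'   attribute `metric = "cosine"`.
#' @export
cosine_dissimilarity <- function(m, min_overlap = 5) {
  stopifnot(inherits(m, "response_matrix"))
  if (m$value_kind != "auc")
    stop("cosine dissimilarity is defined on AUC data")
  eff <- 1 - m$values                      # 1-AUC effect vectors
  n <- nrow(eff)
  drugs <- rownames(eff)
  zero <- vapply(seq_len(n), function(i) {
    v <- eff[i, ]
    all(v[!is.na(v)] == 0)
  }, logical(1))
  if (any(zero))
    stop("all-zero effect vector (cosine undefined) for: ",
         paste(drugs[zero], collapse = ", "))
  d <- matrix(0, n, n, dimnames = list(drugs, drugs))
  n_low <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(eff[i, ]) & !is.na(eff[j, ])
      if (sum(ok) < min_overlap) {
        d[i, j] <- d[j, i] <- NA_real_
        n_low <- n_low + 1L
        next
      }
      a <- eff[i, ok]; b <- eff[j, ok]
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      if (na == 0 || nb == 0) {
        d[i, j] <- d[j, i] <- NA_real_
        n_low <- n_low + 1L
        next
      }
      d[i, j] <- d[j, i] <- 1 - sum(a * b) / (na * nb)
    }
  }
  if (n_low > 0)
    warning(n_low, " drug pair(s) below min_overlap or degenerate; ",
            "entries set to missing")
  d[d < 0 & !is.na(d)] <- 0                # guard tiny negative round-off
  structure(d, metric = "cosine", class = c("dist_matrix", "matrix"))
}

#' Hierarchically cluster drugs from a dissimilarity matrix
#'
#' Drugs are ordered lexicographically before linkage so the merge set is
#' invariant to input row order; missing entries are imputed by the matrix
#' median (message emitted).
#'
#' @param d symmetric dissimilarity matrix (e.g. from
#'   [cosine_dissimilarity()]).
#' @param method `"ward_d2"` or `"average"` linkage.
#' @return An object of class `drug_tree` wrapping the `hclust` result,
#'   with fields `hclust`, `labels`, `method`.
#' @export
cluster_drugs <- function(d, method = c("ward_d2", "average")) {
  method <- match.arg(method)
  d <- as.matrix(d)
  if (nrow(d) < 2) stop("need at least 2 drugs to cluster")
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  up <- d[upper.tri(d)]
  if (anyNA(up)) {
    med <- median(up, na.rm = TRUE)
    message("imputing ", sum(is.na(up)),
            " missing distance(s) by matrix median ", signif(med, 4))
    d[is.na(d)] <- med
    diag(d) <- 0
  }
  hc <- hclust(as.dist(d),
               method = if (method == "ward_d2") "ward.D2" else "average")
  structure(list(hclust = hc, labels = hc$labels, method = method),
            class = "drug_tree")
}

#' @export
print.drug_tree <- function(x, ...) {
  cat("drug_tree:", length(x$labels), "leaves,", x$method, "linkage,",
      "root height", signif(max(x$hclust$height), 4), "\n")
  invisible(x)
}

#' Build a drug_tree directly from merge structure (mainly for testing)
#'
#' @param merge,height,labels as in [stats::hclust].
#' @param method linkage tag.
#' @return A `drug_tree`.
#' @export
drug_tree <- function(merge, height, labels, method = "average") {
  hc <- structure(list(merge = merge, height = height, labels = labels,
                       order = seq_along(labels), method = method,
                       call = NULL, dist.method = NULL),
                  class = "hclust")
  # hclust plotting wants a valid order; compute one by traversal
  hc$order <- order_hclust(hc)
  structure(list(hclust = hc, labels = labels, method = method),
            class = "drug_tree")
}

order_hclust <- function(hc) {
  n <- length(hc$labels)
  if (n == 1) return(1L)
  leaves <- function(k) {
    if (k < 0) return(-k)
    c(leaves(hc$merge[k, 1]), leaves(hc$merge[k, 2]))
  }
  as.integer(leaves(nrow(hc$merge)))
}

#' Cophenetic distance matrix of a drug tree
#'
#' The cophenetic distance of two leaves is the merge height of their
#' lowest common ancestor. With `normalize = TRUE` (default) distances are
#' divided by the root height so the maximum is 1, making them comparable
#' across datasets and usable as a bounded covariate.
#'
#' @param tree a `drug_tree`.
#' @param normalize divide by root height (default TRUE).
#' @return Symmetric `dist_matrix` (metric `"cophenetic"`), ultrametric by
#'   construction.
#' @export
cophenetic_distance <- function(tree, normalize = TRUE) {
  stopifnot(inherits(tree, "drug_tree"))
  cm <- as.matrix(stats::cophenetic(tree$hclust))
  if (normalize) {
    root <- max(tree$hclust$height)
    if (root > 0) cm <- cm / root
  }
  structure(cm, metric = "cophenetic",
            normalized = normalize, class = c("dist_matrix", "matrix"))
}

#' Cophenetic correlation coefficient
#'
#' Quantifies how faithfully the dendrogram preserves the input distances:
#' the correlation between the input dissimilarities x(i,j) and the
#' dendrogrammatic (cophenetic) distances t(i,j) over all pairs i < j,
#' computed term-by-term as
#' \deqn{c = \frac{\sum_{i<j}(x(i,j)-\bar x)(t(i,j)-\bar t)}
#'   {\sqrt{[\sum_{i<j}(x(i,j)-\bar x)^2][\sum_{i<j}(t(i,j)-\bar t)^2]}}}
#' which is algebraically the Pearson correlation of the two pair vectors.
#'
#' @param input_d dissimilarity matrix the tree was built from.
#' @param tree a `drug_tree` on the same items.
#' @return Object of class `cophenetic_report`: fields `c`, `pairs`
#'   (data.frame with `item_a`, `item_b`, `x`, `t`), `x_bar`, `t_bar`.
#'   `c` is `NA` with a warning when the cophenetic distances are constant.
#' @export
cophenetic_correlation <- function(input_d, tree) {
  stopifnot(inherits(tree, "drug_tree"))
  x <- as.matrix(input_d)
  items <- tree$labels
  if (!setequal(rownames(x), items))
    stop("item sets of distance matrix and tree differ")
  x <- x[items, items]
  tm <- cophenetic_distance(tree, normalize = FALSE)
  ut <- upper.tri(x)
  idx <- which(ut, arr.ind = TRUE)
  xv <- x[ut]; tv <- tm[ut]
  x_bar <- mean(xv); t_bar <- mean(tv)
  den <- sqrt(sum((xv - x_bar)^2) * sum((tv - t_bar)^2))
  cc <- if (den == 0) {
    warning("constant cophenetic (or input) distances; correlation undefined")
    NA_real_
  } else sum((xv - x_bar) * (tv - t_bar)) / den
  structure(list(c = cc,
                 pairs = data.frame(item_a = items[idx[, 1]],
                                    item_b = items[idx[, 2]],
                                    x = xv, t = tv,
                                    stringsAsFactors = FALSE),
                 x_bar = x_bar, t_bar = t_bar),
            class = "cophenetic_report")
}

#' @export
print.cophenetic_report <- function(x, ...) {
  cat("cophenetic correlation c =", signif(x$c, 4), "over",
      nrow(x$pairs), "pairs\n")
  invisible(x)
}

#' Target-level cophenetic distance matrix
#'
#' Because several drugs can share a target, target-target distance is the
#' mean cophenetic distance over all cross pairs (one drug carrying target
#' u, one carrying target v), excluding pairs formed by the same drug. The
#' diagonal holds the mean within-target cross-drug distance (0 for
#' single-drug targets).
#'
#' @param tree a `drug_tree`.
#' @param ann an [annotation] whose `targets_of` covers the tree's drugs.
#' @param normalize passed to [cophenetic_distance()].
#' @return Symmetric `dist_matrix` over targets; entries with no valid
#'   cross pair are `NA`.
#' @export
target_distance <- function(tree, ann, normalize = TRUE) {
  stopifnot(inherits(ann, "annotation"))
  cm <- cophenetic_distance(tree, normalize = normalize)
  drugs <- tree$labels
  tmap <- ann$targets_of[intersect(names(ann$targets_of), drugs)]
  targets <- sort(unique(unlist(tmap)))
  if (!length(targets)) stop("no targets map to drugs in the tree")
  drugs_of <- lapply(targets, function(tg)
    names(tmap)[vapply(tmap, function(v) tg %in% v, logical(1))])
  names(drugs_of) <- targets
  k <- length(targets)
  out <- matrix(NA_real_, k, k, dimnames = list(targets, targets))
  for (u in seq_len(k)) {
    for (v in u:k) {
      du <- drugs_of[[u]]; dv <- drugs_of[[v]]
      pairs <- expand.grid(a = du, b = dv, stringsAsFactors = FALSE)
      pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
      if (u == v)  # unordered within-target pairs, each once
        pairs <- pairs[pairs$a < pairs$b, , drop = FALSE]
      if (nrow(pairs) == 0) {
        if (u == v && length(du) == 1) out[u, v] <- 0
        next
      }
      out[u, v] <- out[v, u] <-
        mean(cm[cbind(pairs$a, pairs$b)])
    }
  }
  structure(out, metric = "cophenetic_target",
            class = c("dist_matrix", "matrix"))
}

#' Within- and between-pathway cophenetic distance sets
#'
#' Splits all drug pairs into same-ontology-group and different-group sets
#' of cophenetic distances. Drugs flagged as cross-reactive over multiple
#' pathways are excluded from both sets, as are drugs without a pathway
#' label.
#'
#' @param tree a `drug_tree`.
#' @param ann an [annotation] with non-empty `pathway_of`.
#' @param normalize passed to [cophenetic_distance()].
#' @return List with numeric vectors `within` and `between`.
#' @export
pathway_distance_sets <- function(tree, ann, normalize = TRUE) {
  stopifnot(inherits(ann, "annotation"))
  if (is.null(ann$pathway_of) || !length(ann$pathway_of))
    stop("annotation has no pathway labels")
  cm <- cophenetic_distance(tree, normalize = normalize)
  drugs <- intersect(tree$labels, names(ann$pathway_of))
  drugs <- setdiff(drugs, ann$cross_reactive)
  within <- numeric(); between <- numeric()
  if (length(drugs) >= 2) {
    cmb <- combn(sort(drugs), 2)
    same <- ann$pathway_of[cmb[1, ]] == ann$pathway_of[cmb[2, ]]
    dd <- cm[cbind(cmb[1, ], cmb[2, ])]
    within <- dd[same]
    between <- dd[!same]
  }
  list(within = unname(within), between = unname(between))
}
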