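# Independent oracles used across tests. These deliberately avoid the
# package's own code paths.

# random binary merge tree as a drug_tree: merge heights strictly
# increasing so the result is a valid dendrogram
random_tree <- function(n_leaves, seed) {
  set.seed(seed)
  labels <- sprintf("L%02d", seq_len(n_leaves))
  merge <- matrix(0L, n_leaves - 1, 2)
  active <- as.list(-seq_len(n_leaves))   # negative = leaf index
  heights <- sort(runif(n_leaves - 1, 0.1, 1)) + seq_len(n_leaves - 1) * 1e-3
  for (m in seq_len(n_leaves - 1)) {
    pick <- sample(length(active), 2)
    merge[m, ] <- c(active[[pick[1]]], active[[pick[2]]])
    active <- c(active[-pick], list(m))
  }
  drug_tree(merge, heights, labels)
}

# brute-force cophenetic distances: for every leaf pair walk the merge
# list and record the first (lowest) merge joining their clusters
brute_cophenetic <- function(tree) {
  hc <- tree$hclust
  n <- length(hc$labels)
  members <- vector("list", nrow(hc$merge))
  for (m in seq_len(nrow(hc$merge))) {
    get <- function(k) if (k < 0) -k else members[[k]]
    members[[m]] <- c(get(hc$merge[m, 1]), get(hc$merge[m, 2]))
  }
  out <- matrix(0, n, n, dimnames = list(hc$labels, hc$labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      for (m in seq_len(nrow(hc$merge))) {
        left <- if (hc$merge[m, 1] < 0) -hc$merge[m, 1] else
          members[[hc$merge[m, 1]]]
        right <- if (hc$merge[m, 2] < 0) -hc$merge[m, 2] else
          members[[hc$merge[m, 2]]]
        if ((i %in% left && j %in% right) ||
            (i %in% right && j %in% left)) {
          out[i, j] <- out[j, i] <- hc$height[m]
          break
        }
      }
    }
  }
  out
}

# exhaustive k-clique scan over all C(n, k) vertex subsets
brute_cliques <- function(adj, k) {
  n <- nrow(adj)
  if (n < k) return(character())
  combs <- combn(n, k)
  hits <- character()
  for (c in seq_len(ncol(combs))) {
    vs <- combs[, c]
    pairs <- combn(vs, 2)
    if (all(adj[t(pairs)] == 1))
      hits <- c(hits, paste(sort(rownames(adj)[vs]), collapse = "/"))
  }
  sort(hits)
}

# small helper: 3-leaf tree A,B at height h1 then C at h2
three_leaf_tree <- function(h1 = 1, h2 = 2, labels = c("A", "B", "C")) {
  drug_tree(merge = rbind(c(-1L, -2L), c(1L, -3L)),
            height = c(h1, h2), labels = labels)
}

make_response <- function(values, tissue = NULL) {
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("c%02d", seq_len(ncol(values)))
  response_matrix(values, "auc", tissue)
}
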