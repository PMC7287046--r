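# Dual-synergy graphs and multi-drug candidate enumeration. An edge joins
# two drugs whose checkerboard summary CI falls below the synergy
# threshold in enough cell lines; connected k-cliques (triangles for
# k = 3) are multi-drug candidates, ranked by mean edge CI ascending
# (strongest dual synergy first).

#' Build a dual-synergy graph from plate summaries
#'
#' @param summaries data.frame with columns `cell_line`, `drug_a`,
#'   `drug_b`, `ci` (one row per scored pair per cell line; e.g. collected
#'   from [summarize_plate()] results).
#' @param ci_threshold pairs with CI below this are synergistic edges
#'   (default 0.8).
#' @param min_cell_lines an edge requires synergy in at least this many
#'   cell lines (default 1).
#' @return An `igraph` object of class `synergy_graph`; edge attribute
#'   `ci` is the mean CI over the supporting cell lines, `n_lines` their
#'   count. The threshold is stored as a graph attribute.
#' @export
build_graph <- function(summaries, ci_threshold = 0.8, min_cell_lines = 1) {
  need <- c("cell_line", "drug_a", "drug_b", "ci")
  if (!all(need %in% names(summaries)))
    stop("summaries must have columns: ", paste(need, collapse = ", "))
  drugs <- sort(unique(c(summaries$drug_a, summaries$drug_b)))
  syn <- summaries[!is.na(summaries$ci) & summaries$ci < ci_threshold, ,
                   drop = FALSE]
  g <- igraph::make_empty_graph(n = length(drugs), directed = FALSE)
  igraph::V(g)$name <- drugs
  if (nrow(syn)) {
    a <- pmin(syn$drug_a, syn$drug_b); b <- pmax(syn$drug_a, syn$drug_b)
    key <- paste(a, b, sep = "\r")
    n_lines <- vapply(split(syn$cell_line, key),
                      function(v) length(unique(v)), integer(1))
    mean_ci <- vapply(split(syn$ci, key), mean, numeric(1))
    keep <- n_lines >= min_cell_lines
    if (any(keep)) {
      ab <- do.call(rbind, strsplit(names(n_lines)[keep], "\r"))
      g <- igraph::add_edges(g, t(cbind(match(ab[, 1], drugs),
                                        match(ab[, 2], drugs))))
      igraph::E(g)$ci <- unname(mean_ci[keep])
      igraph::E(g)$n_lines <- unname(n_lines[keep])
    }
  }
  g <- igraph::set_graph_attr(g, "ci_threshold", ci_threshold)
  g <- igraph::set_graph_attr(g, "min_cell_lines", min_cell_lines)
  class(g) <- c("synergy_graph", class(g))
  g
}

#' Enumerate k-drug candidates (k-cliques) in a synergy graph
#'
#' Exact enumeration of all k-cliques, ranked by ascending mean edge CI so
#' the strongest dual-synergy combinations come first.
#'
#' @param g a `synergy_graph`.
#' @param k clique size, >= 3 (default 3: triangles).
#' @param max_nodes enumeration cap; graphs with more nodes raise a
#'   warning and are still processed exactly (default 200).
#' @return data.frame with one row per clique: `drugs`
#'   (slash-separated), `mean_ci`, `max_ci`.
#' @export
enumerate_candidates <- function(g, k = 3, max_nodes = 200) {
  stopifnot(k >= 3)
  if (igraph::vcount(g) > max_nodes)
    warning("graph has ", igraph::vcount(g), " nodes; exact ", k,
            "-clique enumeration may be slow")
  cl <- igraph::cliques(g, min = k, max = k)
  if (!length(cl))
    return(data.frame(drugs = character(), mean_ci = numeric(),
                      max_ci = numeric()))
  rows <- lapply(cl, function(vs) {
    nm <- sort(igraph::V(g)$name[as.integer(vs)])
    sub <- igraph::induced_subgraph(g, vs)
    cis <- igraph::E(sub)$ci
    data.frame(drugs = paste(nm, collapse = "/"),
               mean_ci = mean(cis), max_ci = max(cis),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mean_ci, out$drugs), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlate dual-combination CIs with multi-drug CIs across cell lines
#'
#' @param dual_ci numeric vector: summary CI of a dual combination per
#'   cell line.
#' @param multi_ci numeric vector: multi-drug CI for the same cell lines.
#' @param alternative test direction (default `"greater"`: dual synergy
#'   predicts multi-drug synergy, positive correlation).
#' @return List `r`, `p`, `n`; `r` is `NA` with a warning for constant
#'   input.
#' @export
dual_multi_correlation <- function(dual_ci, multi_ci,
                                   alternative = "greater") {
  ok <- !is.na(dual_ci) & !is.na(multi_ci)
  dual_ci <- dual_ci[ok]; multi_ci <- multi_ci[ok]
  if (length(dual_ci) < 3) stop("need at least 3 paired observations")
  if (sd(dual_ci) == 0 || sd(multi_ci) == 0) {
    warning("constant CI vector; correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = length(dual_ci)))
  }
  ct <- cor.test(dual_ci, multi_ci, alternative = alternative,
                 method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(dual_ci))
}
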