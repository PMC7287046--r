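# Flattening the drug dendrogram into a 2D Voronoi treemap ("drug atlas").
# The recursion follows the binary cluster tree; each internal node's region
# is split between its two children by the exact 2-site power-diagram cut
# (a straight line, located by area bisection), and each top-level group's
# region is then smoothed by a capacity-constrained centroidal power
# diagram, accepted only when it reaches the area tolerance.

#' Branch grouping threshold of a cluster tree
#'
#' The threshold b is the merge height at which the cumulative fraction of
#' merges, counted from the leaves upward, first reaches `depth_fraction`.
#' Branches merging below b are grouped into one top-level atlas region.
#'
#' @param tree a `drug_tree`.
#' @param depth_fraction fraction in (0, 1); `depth_fraction -> 1` gives the
#'   root height. Default 0.25.
#' @return The threshold height b (numeric scalar).
#' @export
branch_threshold <- function(tree, depth_fraction = 0.25) {
  stopifnot(inherits(tree, "drug_tree"),
            depth_fraction > 0, depth_fraction <= 1)
  h <- sort(tree$hclust$height)
  if (length(unique(h)) == 1)
    warning("degenerate tree: all merge heights equal")
  k <- ceiling(depth_fraction * length(h))
  h[max(1L, min(k, length(h)))]
}

# group membership: connected components of merges with height < b
tree_groups <- function(tree, b) {
  hc <- tree$hclust
  n <- length(tree$labels)
  grp <- seq_len(n)
  find <- function(i) { while (grp[i] != i) i <- grp[i]; i }
  node_rep <- integer(nrow(hc$merge))
  for (m in seq_len(nrow(hc$merge))) {
    l <- hc$merge[m, 1]; r <- hc$merge[m, 2]
    li <- if (l < 0) -l else node_rep[l]
    ri <- if (r < 0) -r else node_rep[r]
    if (hc$height[m] < b) {
      a <- find(li); bb <- find(ri)
      grp[bb] <- a
      node_rep[m] <- a
    } else {
      node_rep[m] <- find(li)   # arbitrary member; groups stay separate
    }
  }
  ids <- vapply(seq_len(n), find, integer(1))
  setNames(match(ids, unique(ids)), tree$labels)
}

# recursive node list from hclust merge matrix
build_nodes <- function(hc) {
  n <- length(hc$labels)
  mk_leaf <- function(i) list(leaf = TRUE, label = hc$labels[i],
                              members = hc$labels[i], height = 0)
  nodes <- vector("list", nrow(hc$merge))
  for (m in seq_len(nrow(hc$merge))) {
    get <- function(k) if (k < 0) mk_leaf(-k) else nodes[[k]]
    l <- get(hc$merge[m, 1]); r <- get(hc$merge[m, 2])
    nodes[[m]] <- list(leaf = FALSE, height = hc$height[m],
                       members = c(l$members, r$members),
                       left = l, right = r)
  }
  nodes[[nrow(hc$merge)]]
}

#' Lay the drug cluster tree out as a Voronoi treemap
#'
#' Recursively partitions a convex container among the tree's leaves so
#' that each drug gets one convex cell whose area is proportional to its
#' weight, with tree-adjacent drugs placed in adjacent regions. Splits
#' follow the dendrogram: at each internal node the current region is cut
#' by the two-site power-diagram line (area-exact bisection along the
#' region's principal axis, so early -- high -- splits claim the widest
#' extent of the container and early-diverging branches end up at opposite
#' ends). Regions of top-level groups (below the grouping threshold b) are
#' then smoothed with a capacity-constrained centroidal power diagram;
#' the smoothed tiling is kept only when every cell's area is within
#' `area_tol` of its weight-proportional target, otherwise the exact
#' bisection cells are retained and a warning reports the achieved
#' tolerance.
#'
#' @param tree a `drug_tree`.
#' @param b grouping threshold; computed via [branch_threshold()] when
#'   `NULL`.
#' @param depth_fraction used when `b` is `NULL` (default 0.25).
#' @param container `"circle"` (default) or `"rect"`, or a convex polygon
#'   matrix.
#' @param weights named positive weights per drug; uniform by default.
#' @param seed integer; the layout is fully deterministic given the seed.
#' @param max_iter smoothing iteration cap per group (default 200).
#' @param area_tol relative area tolerance for smoothing acceptance
#'   (default 0.02).
#' @param smooth logical; set `FALSE` to keep the raw bisection tiling.
#' @return An object of class `atlas_layout`: `container`, `cells` (named
#'   list of convex polygons), `sites`, `weights`, `groups` (top-level
#'   group id per drug), `group_regions`, `threshold`, `achieved_tol`,
#'   and `borders` once [border_weights()] has been applied.
#' @export
layout_voronoi_treemap <- function(tree, b = NULL, depth_fraction = 0.25,
                                   container = "circle", weights = NULL,
                                   seed = 1L, max_iter = 200,
                                   area_tol = 0.02, smooth = TRUE) {
  stopifnot(inherits(tree, "drug_tree"))
  drugs <- tree$labels
  if (is.null(weights)) weights <- setNames(rep(1, length(drugs)), drugs)
  if (!all(drugs %in% names(weights)))
    stop("weights missing for some drugs")
  weights <- weights[drugs]
  if (any(!is.finite(weights) | weights <= 0))
    stop("weights must be positive and finite")
  poly <- if (is.matrix(container)) container else
    container_polygon(container)

  if (length(drugs) == 1) {
    layout <- structure(list(container = poly,
                             cells = setNames(list(poly), drugs),
                             sites = matrix(poly_centroid(poly), 1, 2,
                                            dimnames = list(drugs, NULL)),
                             weights = weights,
                             groups = setNames(1L, drugs),
                             group_regions = list(poly),
                             threshold = 0, achieved_tol = 0),
                        class = "atlas_layout")
    return(layout)
  }

  if (is.null(b)) b <- branch_threshold(tree, depth_fraction)
  groups <- tree_groups(tree, b)
  root <- build_nodes(tree$hclust)

  with_seed(seed, {
    # deterministic per-node jitter of the cut direction breaks the
    # degeneracy of repeated principal axes in symmetric regions
    jitter_angles <- runif(2 * length(drugs), -0.15, 0.15)
    jit_i <- 0L
    cells <- list()
    recurse <- function(node, region) {
      if (node$leaf) {
        cells[[node$label]] <<- region
        return(invisible())
      }
      wl <- sum(weights[node$left$members])
      wr <- sum(weights[node$right$members])
      u <- poly_principal_axis(region)
      jit_i <<- jit_i + 1L
      th <- jitter_angles[jit_i]
      u <- c(cos(th) * u[1] - sin(th) * u[2],
             sin(th) * u[1] + cos(th) * u[2])
      sp <- bisect_polygon(region, u, wl / (wl + wr))
      recurse(node$left, sp$lo)
      recurse(node$right, sp$hi)
    }
    recurse(root, poly)

    # each group's region is the union of its member cells; the union is
    # convex because the subtree was carved out by half-plane cuts, so the
    # convex hull recovers it exactly
    region_of_group <- lapply(sort(unique(groups)), function(g)
      convex_union(cells[names(groups)[groups == g]]))

    achieved <- 0
    if (smooth) {
      for (g in sort(unique(groups))) {
        members <- names(groups)[groups == g]
        if (length(members) < 2) next
        reg <- region_of_group[[g]]
        targ <- weights[members]
        init <- t(vapply(cells[members], poly_centroid, numeric(2)))
        res <- cvt_power_partition(reg, targ, init,
                                   max_iter = max_iter,
                                   area_tol = area_tol * 0.5)
        if (res$achieved_tol <= area_tol) {
          for (i in seq_along(members)) cells[[members[i]]] <- res$cells[[i]]
          achieved <- max(achieved, res$achieved_tol)
        } else {
          warning("smoothing for group ", g, " reached tolerance ",
                  signif(res$achieved_tol, 3), " > ", area_tol,
                  "; exact bisection cells kept for this group")
        }
      }
    }
    structure(list(container = poly, cells = cells[drugs],
                   sites = t(vapply(cells[drugs], poly_centroid,
                                    numeric(2))),
                   weights = weights, groups = groups,
                   group_regions = region_of_group,
                   threshold = b, achieved_tol = achieved),
              class = "atlas_layout")
  })
}

# convex union of convex polygons that tile a convex region: their convex
# hull (exact because the union is convex by construction of the cuts)
convex_union <- function(polys) {
  pts <- do.call(rbind, polys)
  hull <- grDevices::chull(pts)
  pts[rev(hull), , drop = FALSE]   # chull is clockwise; reverse to CCW
}

#' @export
print.atlas_layout <- function(x, ...) {
  cat("atlas_layout:", length(x$cells), "cells, container area",
      signif(poly_area(x$container), 4),
      ", threshold b =", signif(x$threshold, 4), "\n")
  invisible(x)
}

#' Annotate cell boundaries with cophenetic border weights
#'
#' Each boundary shared by two cells carries the cophenetic distance of the
#' two drugs: boundaries crossing splits higher in the tree are heavier
#' (drawn thicker), so the map's line weights encode the dendrogram cutoff
#' separating neighbouring drugs.
#'
#' @param layout an `atlas_layout`.
#' @param tree the `drug_tree` the layout was built from.
#' @param normalize use normalized cophenetic distances (default TRUE).
#' @return The layout with a `borders` data.frame (`drug_a`, `drug_b`,
#'   `weight`, segment endpoints `x1`,`y1`,`x2`,`y2`, `length`).
#' @export
border_weights <- function(layout, tree, normalize = TRUE) {
  stopifnot(inherits(layout, "atlas_layout"), inherits(tree, "drug_tree"))
  cm <- cophenetic_distance(tree, normalize = normalize)
  drugs <- names(layout$cells)
  rows <- list()
  if (length(drugs) >= 2) {
    cmb <- combn(drugs, 2)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1, k]; b <- cmb[2, k]
      sb <- shared_boundary(layout$cells[[a]], layout$cells[[b]])
      if (sb$length > 1e-6)
        rows[[length(rows) + 1L]] <-
          data.frame(drug_a = a, drug_b = b, weight = cm[a, b],
                     x1 = sb$a[1], y1 = sb$a[2],
                     x2 = sb$b[1], y2 = sb$b[2],
                     length = sb$length, stringsAsFactors = FALSE)
    }
  }
  layout$borders <- if (length(rows)) do.call(rbind, rows) else
    data.frame(drug_a = character(), drug_b = character(),
               weight = numeric(), x1 = numeric(), y1 = numeric(),
               x2 = numeric(), y2 = numeric(), length = numeric())
  layout
}
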