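# Convex-polygon primitives for the treemap layout. Polygons are two-column
# matrices of vertices in counter-clockwise order, implicitly closed.

poly_area <- function(p) {
  n <- nrow(p)
  if (is.null(n) || n < 3) return(0)
  i <- seq_len(n); j <- c(2:n, 1)
  abs(sum(p[i, 1] * p[j, 2] - p[j, 1] * p[i, 2])) / 2
}

poly_centroid <- function(p) {
  n <- nrow(p)
  if (n < 3) return(colMeans(p))
  i <- seq_len(n); j <- c(2:n, 1)
  cr <- p[i, 1] * p[j, 2] - p[j, 1] * p[i, 2]
  a <- sum(cr) / 2
  if (abs(a) < 1e-300) return(colMeans(p))
  c(sum((p[i, 1] + p[j, 1]) * cr), sum((p[i, 2] + p[j, 2]) * cr)) / (6 * a)
}

# clip convex polygon to half-plane {x : a . x <= c}; Sutherland-Hodgman
clip_halfplane <- function(p, a, c0) {
  n <- nrow(p)
  if (is.null(n) || n == 0) return(p[0, , drop = FALSE])
  s <- as.vector(p %*% a) - c0
  inside <- s <= 1e-12
  if (all(inside)) return(p)
  if (!any(inside)) return(p[0, , drop = FALSE])
  out <- matrix(NA_real_, n + 4, 2)
  m <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) { m <- m + 1L; out[m, ] <- p[i, ] }
    if (xor(inside[i], inside[j])) {
      t <- s[i] / (s[i] - s[j])
      m <- m + 1L
      out[m, ] <- p[i, ] + t * (p[j, ] - p[i, ])
    }
  }
  out[seq_len(m), , drop = FALSE]
}

regular_polygon <- function(n = 72, r = 1, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

container_polygon <- function(container = c("circle", "rect")) {
  container <- match.arg(container)
  if (container == "circle") regular_polygon(72)
  else cbind(c(-1, 1, 1, -1), c(-1, -1, 1, 1))
}

# principal axis (unit vector) of a polygon's vertex cloud; falls back to
# the x axis for degenerate clouds. Sign convention: first nonzero
# component positive, for determinism.
poly_principal_axis <- function(p) {
  q <- sweep(p, 2, colMeans(p))
  cv <- crossprod(q) / nrow(q)
  e <- eigen(cv, symmetric = TRUE)
  u <- e$vectors[, 1]
  if (abs(u[1]) < 1e-12) u <- c(0, sign(u[2]))
  else if (u[1] < 0) u <- -u
  u / sqrt(sum(u^2))
}

# split convex polygon by a line u . x = c into pieces with area fractions
# (frac, 1 - frac); c is found by monotone bisection. Returns list(lo, hi)
# where lo is the {u . x <= c} side.
bisect_polygon <- function(p, u, frac, tol = 1e-10) {
  total <- poly_area(p)
  proj <- as.vector(p %*% u)
  lo <- min(proj); hi <- max(proj)
  f <- function(c0) poly_area(clip_halfplane(p, u, c0)) / total - frac
  c0 <- uniroot(f, c(lo, hi), tol = tol * (hi - lo))$root
  list(lo = clip_halfplane(p, u, c0),
       hi = clip_halfplane(p, -u, -c0),
       cut = c(u, c0))
}

# additively weighted (power) Voronoi cells of sites inside a convex
# polygon: cell_i = P intersected with {x : 2(s_j - s_i).x <= |s_j|^2 -
# |s_i|^2 + w_i - w_j} for all j != i.
power_cells <- function(poly, sites, w) {
  k <- nrow(sites)
  nrm <- rowSums(sites^2)
  lapply(seq_len(k), function(i) {
    cell <- poly
    for (j in seq_len(k)) {
      if (j == i || nrow(cell) == 0) next
      a <- 2 * (sites[j, ] - sites[i, ])
      c0 <- nrm[j] - nrm[i] + w[i] - w[j]
      cell <- clip_halfplane(cell, a, c0)
    }
    cell
  })
}

# capacity-constrained centroidal power diagram: iterate weight adaptation
# (to match target area fractions) and Lloyd moves. Returns sites, weights,
# cells and the achieved maximum relative area error.
cvt_power_partition <- function(poly, targets, init_sites,
                                max_iter = 200, area_tol = 0.02) {
  k <- length(targets)
  total <- poly_area(poly)
  targ_area <- targets / sum(targets) * total
  sites <- init_sites
  w <- rep(0, k)
  diam2 <- max(dist(poly))^2
  best <- NULL; best_err <- Inf
  prev_err <- Inf
  lr <- 0.6
  lloyd <- TRUE
  for (it in seq_len(max_iter)) {
    cells <- power_cells(poly, sites, w)
    areas <- vapply(cells, poly_area, numeric(1))
    empty <- areas < 1e-12 * total
    if (any(empty)) {
      # revive empty cells: bump weight toward the target share
      w[empty] <- w[empty] + 0.05 * diam2
      w <- w - mean(w)
      next
    }
    err <- max(abs(areas - targ_area) / targ_area)
    if (err < best_err) {
      best_err <- err
      best <- list(sites = sites, w = w, cells = cells)
    }
    if (err <= area_tol && it > 1) break
    if (err > prev_err) lr <- max(lr * 0.7, 0.02)
    prev_err <- err
    # once close, freeze Lloyd moves and let the weights finish the job
    if (err < 4 * area_tol) lloyd <- FALSE
    # multiplicative-style capacity update in weight units of diam^2
    w <- w + lr * diam2 * (targ_area - areas) / total
    w <- w - mean(w)
    if (lloyd) sites <- t(vapply(cells, poly_centroid, numeric(2)))
  }
  c(best, list(achieved_tol = best_err))
}

# quasi-random (Halton) points inside a convex polygon, deterministic
halton_in_polygon <- function(poly, n) {
  halton1 <- function(i, base) {
    f <- 1; r <- 0
    while (i > 0) {
      f <- f / base
      r <- r + f * (i %% base)
      i <- i %/% base
    }
    r
  }
  bb <- apply(poly, 2, range)
  pts <- matrix(NA_real_, n, 2)
  got <- 0L; i <- 1L
  while (got < n && i < 100000L) {
    x <- bb[1, 1] + halton1(i, 2) * diff(bb[, 1])
    y <- bb[1, 2] + halton1(i, 3) * diff(bb[, 2])
    if (point_in_convex(poly, c(x, y))) {
      got <- got + 1L
      pts[got, ] <- c(x, y)
    }
    i <- i + 1L
  }
  pts[seq_len(got), , drop = FALSE]
}

point_in_convex <- function(poly, pt, tol = 1e-9) {
  n <- nrow(poly)
  i <- seq_len(n); j <- c(2:n, 1)
  ex <- poly[j, 1] - poly[i, 1]; ey <- poly[j, 2] - poly[i, 2]
  cr <- ex * (pt[2] - poly[i, 2]) - ey * (pt[1] - poly[i, 1])
  all(cr >= -tol) || all(cr <= tol)
}

# shared collinear boundary segment between two convex polygons; returns
# list(length, a, b) for the longest overlap (length 0 if not adjacent)
shared_boundary <- function(p1, p2, tol = 1e-7) {
  seg_of <- function(p) {
    n <- nrow(p)
    cbind(p, p[c(2:n, 1), , drop = FALSE])
  }
  s1 <- seg_of(p1); s2 <- seg_of(p2)
  best <- list(length = 0, a = c(NA_real_, NA_real_),
               b = c(NA_real_, NA_real_))
  for (i in seq_len(nrow(s1))) {
    a1 <- s1[i, 1:2]; b1 <- s1[i, 3:4]
    d1 <- b1 - a1; L1 <- sqrt(sum(d1^2))
    if (L1 < tol) next
    u <- d1 / L1
    for (j in seq_len(nrow(s2))) {
      a2 <- s2[j, 1:2]; b2 <- s2[j, 3:4]
      # both endpoints of segment 2 must lie on segment 1's line
      off2a <- abs((a2[1] - a1[1]) * u[2] - (a2[2] - a1[2]) * u[1])
      off2b <- abs((b2[1] - a1[1]) * u[2] - (b2[2] - a1[2]) * u[1])
      if (off2a > tol || off2b > tol) next
      t2 <- sort(c(sum((a2 - a1) * u), sum((b2 - a1) * u)))
      lo <- max(0, t2[1]); hi <- min(L1, t2[2])
      if (hi - lo > best$length)
        best <- list(length = hi - lo, a = a1 + lo * u, b = a1 + hi * u)
    }
  }
  best
}
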