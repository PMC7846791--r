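# Exact convex-hull volume in arbitrary (small) dimension, by incremental
# beneath-beyond construction: maintain the simplicial facets of the current
# hull, and for each new point replace the facets it can see with the cone
# over its horizon ridges. Volume is the fan of simplices from an interior
# point. Intended regime: d <= 5, a few hundred points.

# outward unit normal and offset of the hyperplane through d points (rows),
# oriented away from `interior`
facet_plane <- function(pts, interior) {
  d <- ncol(pts)
  if (d == 1) {
    normal <- 1
  } else {
    edges <- pts[-1, , drop = FALSE] - matrix(pts[1, ], d - 1, d, byrow = TRUE)
    qr_ <- qr(t(edges))
    normal <- qr.Q(qr_, complete = TRUE)[, d]
  }
  offset <- sum(normal * pts[1, ])
  if (sum(normal * interior) > offset) {
    normal <- -normal
    offset <- -offset
  }
  list(normal = normal, offset = offset)
}

#' Volume of the convex hull of a point set
#'
#' Exact d-dimensional hull volume (length for d = 1, area for d = 2, ...) via
#' incremental facet construction. The set must have full affine rank (at
#' least d + 1 points in general position), else an error advises reducing the
#' dimensionality.
#'
#' @param points numeric matrix, one point per row
#' @return hull volume (> 0)
#' @export
convex_hull_volume <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  d <- ncol(points)
  if (n < d + 1) stop("need at least d + 1 = ", d + 1, " points")
  if (d == 1) return(diff(range(points)))
  scale <- max(abs(points), 1e-12)
  eps <- 1e-9 * scale

  # initial simplex: greedily add the point farthest from the affine span
  vert <- which.max(points[, 1])
  basis <- NULL # orthonormal basis of span directions
  for (step in seq_len(d)) {
    resid <- points - matrix(points[vert[1], ], n, d, byrow = TRUE)
    if (!is.null(basis)) resid <- resid - resid %*% basis %*% t(basis)
    dist <- sqrt(rowSums(resid^2))
    cand <- which.max(dist)
    if (dist[cand] < eps)
      stop("degenerate point set (affine rank < ", d,
           "); reduce the number of axes")
    vert <- c(vert, cand)
    newdir <- resid[cand, ] / dist[cand]
    basis <- cbind(basis, newdir)
  }
  interior <- colMeans(points[vert, , drop = FALSE])

  facets <- list()
  combs <- utils::combn(d + 1, d)
  for (j in seq_len(ncol(combs))) {
    v <- vert[combs[, j]]
    pl <- facet_plane(points[v, , drop = FALSE], interior)
    facets[[length(facets) + 1]] <- list(v = v, normal = pl$normal,
                                         offset = pl$offset)
  }

  rest <- setdiff(order(-rowSums((points - matrix(interior, n, d,
                                                  byrow = TRUE))^2)), vert)
  for (p in rest) {
    x <- points[p, ]
    vis <- vapply(facets, function(f) sum(f$normal * x) > f$offset + eps,
                  logical(1))
    if (!any(vis)) next
    # horizon ridges: (d-1)-faces of visible facets that are not shared by two
    # visible facets
    ridge_tab <- new.env(parent = emptyenv())
    for (f in facets[vis]) {
      for (j in seq_len(d)) {
        r <- sort(f$v[-j])
        key <- paste(r, collapse = ",")
        prev <- ridge_tab[[key]]
        ridge_tab[[key]] <- if (is.null(prev)) list(count = 1L, r = r)
                            else list(count = prev$count + 1L, r = r)
      }
    }
    new_facets <- list()
    for (key in ls(ridge_tab)) {
      entry <- ridge_tab[[key]]
      if (entry$count != 1L) next
      v <- c(entry$r, p)
      pl <- facet_plane(points[v, , drop = FALSE], interior)
      new_facets[[length(new_facets) + 1]] <- list(v = v, normal = pl$normal,
                                                   offset = pl$offset)
    }
    facets <- c(facets[!vis], new_facets)
  }

  vol <- 0
  for (f in facets) {
    m <- points[f$v, , drop = FALSE] - matrix(interior, d, d, byrow = TRUE)
    vol <- vol + abs(det(m))
  }
  vol / factorial(d)
}
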