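# Trait-space construction and functional diversity: Gower distance over the
# 12 mixed-type traits, PCoA embedding, convex-hull functional richness
# normalized to [0,1] by the global pool hull, and complete-linkage clustering
# of OTUs into ecological strategies.

#' Gower distance over a mixed-type trait table
#'
#' Range-normalized absolute difference for numeric traits, simple mismatch
#' for categorical/binary ones; a trait missing in either row carries zero
#' weight for that pair. A pair of rows with no mutually observed trait is an
#' error.
#'
#' @param traits data.frame with rows = taxonomic references or OTUs and the
#'   trait columns (extra columns `taxref` / `obligate_phototroph` are
#'   ignored); row names are the labels.
#' @param columns trait columns to use (default: the 12 standard traits
#'   present in the table)
#' @return labelled symmetric matrix in \[0, 1\]
#' @export
gower_distance <- function(traits, columns = NULL) {
  if (nrow(traits) < 2) stop("need >= 2 rows")
  if (is.null(columns)) columns <- intersect(TRAIT_COLUMNS, names(traits))
  if (!length(columns)) stop("no trait columns found")
  df <- traits[, columns, drop = FALSE]
  for (col in columns)
    if (!col %in% TRAIT_NUMERIC) df[[col]] <- factor(df[[col]])
  d <- as.matrix(cluster::daisy(df, metric = "gower", warnBin = FALSE,
                                warnAsym = FALSE, warnConst = FALSE))
  if (anyNA(d)) {
    bad <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)[1, ]
    stop("rows '", rownames(d)[bad[1]], "' and '", rownames(d)[bad[2]],
         "' share no observed trait")
  }
  dimnames(d) <- list(rownames(traits), rownames(traits))
  as_dist_matrix(d, tol = 1e-8)
}

#' Principal coordinate analysis of a distance matrix
#'
#' Eigen-decomposition of the Gower-centred -d^2/2 matrix; coordinates are
#' scaled by the square root of their eigenvalues. Negative eigenvalues are
#' dropped (their total inertia is reported via a message); no Cailliez/
#' Lingoes correction is applied.
#'
#' @param D labelled distance matrix over n objects
#' @param m number of axes to retain (n > m >= 1)
#' @return a `functional_space`: list with `coordinates` (n x m), all
#'   non-negative `eigenvalues` (non-increasing), `m`, `negative_inertia`,
#'   and `pool_hull_volume` (hull volume of all points on the m axes)
#' @export
pcoa <- function(D, m = 4) {
  D <- as_dist_matrix(D, tol = 1e-8)
  n <- nrow(D)
  if (m < 1 || m >= n) stop("need n > m >= 1")
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(D), k = n - 1, eig = TRUE))
  eig <- fit$eig
  tol <- max(abs(eig)) * 1e-9
  pos <- eig > tol
  if (sum(pos) < m)
    stop("only ", sum(pos), " positive eigenvalue(s); use a smaller m")
  neg <- sum(abs(eig[eig < -tol]))
  if (neg > 0)
    message(sprintf("pcoa: dropped negative eigenvalues (%.1f%% of total inertia)",
                    100 * neg / sum(abs(eig))))
  coords <- fit$points[, seq_len(m), drop = FALSE]
  rownames(coords) <- rownames(D)
  structure(list(coordinates = coords, eigenvalues = eig[pos], m = m,
                 negative_inertia = neg,
                 pool_hull_volume = convex_hull_volume(coords)),
            class = "functional_space")
}

#' @export
print.functional_space <- function(x, ...) {
  cat("functional_space:", nrow(x$coordinates), "objects on", x$m,
      "axes; pool hull volume", signif(x$pool_hull_volume, 4), "\n")
  invisible(x)
}

#' Functional richness of communities in trait space
#'
#' FRic(set) = hull volume of the set's coordinates on the retained axes,
#' divided by the global-pool hull volume; the full pool scores exactly 1.
#' Sets must contain more than m members in general position.
#'
#' @param space a [pcoa()] `functional_space`
#' @param presence named list of OTU-id vectors (e.g. per station x season)
#' @return named numeric vector of FRic values in \[0, 1\]
#' @export
functional_richness <- function(space, presence) {
  pool <- rownames(space$coordinates)
  vapply(presence, function(set) {
    set <- intersect(unique(set), pool)
    if (length(set) <= space$m)
      stop("set with ", length(set), " members in the space; need > m = ", space$m)
    convex_hull_volume(space$coordinates[set, , drop = FALSE]) /
      space$pool_hull_volume
  }, numeric(1))
}

#' Cluster OTUs into ecological strategies
#'
#' Complete-linkage agglomerative clustering of the Gower distance matrix cut
#' into exactly k clusters. Ties between candidate merges are broken towards
#' the pair whose smallest member labels sort first, making the partition
#' invariant to input order. Cluster ids are numbered by their
#' lexicographically smallest member.
#'
#' @param D labelled Gower distance matrix
#' @param k number of strategies (default 9)
#' @return named integer vector: cluster id in 1..k per row of `D`
#' @export
strategy_clustering <- function(D, k = 9) {
  D <- as_dist_matrix(D, tol = 1e-8)
  n <- nrow(D)
  if (k > n) stop("k = ", k, " exceeds the number of objects (", n, ")")
  orig_labels <- rownames(D)
  ord <- order(orig_labels)
  D <- D[ord, ord]
  labels <- orig_labels[ord]
  members <- as.list(seq_len(n)) # indices into sorted labels
  M <- D
  diag(M) <- Inf
  active <- rep(TRUE, n)
  n_active <- n
  while (n_active > k) {
    sub <- which(active)
    block <- M[sub, sub, drop = FALSE]
    mn <- min(block)
    ties <- which(block <= mn + 0, arr.ind = TRUE)
    ties <- ties[ties[, 1] < ties[, 2], , drop = FALSE]
    # rows of `block` are already in sorted-label order of cluster
    # representatives, so the first row-major minimum is the lexicographic one
    pick <- ties[order(ties[, 1], ties[, 2])[1], ]
    i <- sub[pick[1]]; j <- sub[pick[2]]
    members[[i]] <- c(members[[i]], members[[j]])
    active[j] <- FALSE
    upd <- pmax(M[i, ], M[j, ])
    M[i, ] <- upd
    M[, i] <- upd
    M[i, i] <- Inf
    n_active <- n_active - 1
  }
  out <- integer(n)
  reps <- which(active)
  reps <- reps[order(vapply(members[reps], min, numeric(1)))]
  for (cl in seq_along(reps)) out[members[[reps[cl]]]] <- cl
  res <- stats::setNames(out, labels)
  res[orig_labels]
}

#' Per-station distribution of ecological strategies
#'
#' Counts, per station, the present OTUs in each strategy; OTUs without a
#' strategy (insufficient trait annotation) are counted in the `unannotated`
#' row, so column sums equal station richness.
#'
#' @param assign named cluster vector from [strategy_clustering()] (names may
#'   be taxrefs; supply `taxref` to map OTUs)
#' @param presence named list: station -> vector of present OTU ids
#' @param taxref optional named map OTU -> taxref used to look up `assign`
#' @return data.frame rows = strategies 1..k plus `unannotated`, columns =
#'   stations
#' @export
strategy_distribution <- function(assign, presence, taxref = NULL) {
  k <- max(assign)
  rows <- c(as.character(seq_len(k)), "unannotated")
  out <- matrix(0L, nrow = length(rows), ncol = length(presence),
                dimnames = list(rows, names(presence)))
  for (st in names(presence)) {
    otus <- unique(presence[[st]])
    key <- if (is.null(taxref)) otus else unname(taxref[otus])
    cl <- assign[key]
    out["unannotated", st] <- sum(is.na(cl))
    tab <- table(cl[!is.na(cl)])
    out[names(tab), st] <- as.integer(tab)
  }
  as.data.frame(out)
}
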