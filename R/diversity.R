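# Diversity partitioning: phototroph filtering, richness, analytic
# rarefaction, Chao1, occurrence categories (shared vs station-specific),
# abundance classes, OTU-connectivity and its curated-richness control.

#' Keep only obligate-phototroph OTUs
#'
#' Retains exactly the OTUs whose taxonomic reference is flagged
#' `obligate_phototroph = TRUE` in the trait table; OTUs whose reference is
#' unresolvable are treated as non-phototrophs. The retained fraction of OTUs
#' and of reads is reported as a message.
#'
#' @param table an [otu_table()]
#' @param traits trait data.frame with `obligate_phototroph`
#' @return the filtered `otu_table`
#' @export
filter_phototrophs <- function(table, traits) {
  flag <- traits$obligate_phototroph
  names(flag) <- rownames(traits)
  is_photo <- flag[table$taxref]
  is_photo[is.na(is_photo)] <- FALSE
  keep <- colnames(table$counts)[is_photo]
  if (length(keep) == 0)
    stop("no obligate-phototroph OTUs retained; check the obligate_phototroph column")
  out <- subset_otu_table(table, otus = keep)
  message(sprintf("phototroph filter: kept %d/%d OTUs (%.1f%%), %.1f%% of reads",
                  length(keep), n_otus(table), 100 * length(keep) / n_otus(table),
                  100 * sum(out$counts) / sum(table$counts)))
  out
}

#' Per-sample OTU richness
#'
#' @param table an [otu_table()]
#' @param per optional metadata fields to merge over before counting (e.g.
#'   `c("station","season")` keeps those and collapses the rest)
#' @return data.frame `sample_id`, retained metadata fields, `richness`
#' @export
richness <- function(table, per = NULL) {
  if (!is.null(per)) {
    keys <- setdiff(intersect(METADATA_FIELDS, names(table$metadata)), per)
    if (length(keys)) table <- merge_samples(table, keys)
  }
  r <- rowSums(table$counts > 0)
  if (any(r == 0)) warning("all-zero sample(s): ",
                           paste(names(r)[r == 0], collapse = ", "))
  out <- table$metadata
  out$richness <- as.integer(r[out$sample_id])
  rownames(out) <- NULL
  out
}

#' Analytic rarefaction curve for one sample
#'
#' Expected richness in a random subsample of n reads,
#' E\[S_n\] = sum_i (1 - C(N - N_i, n) / C(N, n)), evaluated with
#' log-combinatorics so large read counts do not overflow.
#'
#' @param counts integer vector of per-OTU read counts for one sample
#' @param depths subsample sizes n (1 <= n <= N)
#' @return numeric vector of expected richness, one per depth
#' @export
rarefaction_curve <- function(counts, depths) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (any(depths < 1 | depths > N)) stop("depths must be within [1, ", N, "]")
  vapply(depths, function(n) {
    # lchoose(N - Ni, n) is -Inf when n > N - Ni: that OTU is always seen
    sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
  }, numeric(1))
}

#' Chao1 richness estimate
#'
#' Bias-corrected by default: S_obs + F1 (F1 - 1) / (2 (F2 + 1)), with F1/F2
#' the singleton/doubleton counts; the classic estimator
#' S_obs + F1^2 / (2 F2) is available via `bias_corrected = FALSE` (it falls
#' back to the corrected form when F2 = 0).
#'
#' @param counts integer vector of per-OTU read counts for one sample
#' @param bias_corrected use the bias-corrected variant (default)
#' @return estimated asymptotic richness
#' @export
chao1 <- function(counts, bias_corrected = TRUE) {
  counts <- counts[counts > 0]
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected || f2 == 0) s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  else s_obs + f1^2 / (2 * f2)
}

#' Occurrence categories: shared vs station-specific OTUs
#'
#' On a table merged to one sample per (station, season), each OTU present in a
#' season is labelled `"shared"` when it occurs at >= 2 stations of that
#' season, else `"specific:<station>"`.
#'
#' @param table an [otu_table()] with exactly one sample per (station, season)
#' @return data.frame `otu_id`, `season`, `label`
#' @export
occurrence_categories <- function(table) {
  md <- table$metadata
  if (!all(c("station", "season") %in% names(md)))
    stop("table must carry station and season metadata")
  if (anyDuplicated(md[, c("station", "season")]))
    stop("table must be merged to one sample per (station, season); ",
         "call merge_samples() first")
  pres <- presence_matrix(table)
  out <- list()
  for (season in unique(md$season)) {
    rows <- md$sample_id[md$season == season]
    sub <- pres[rows, , drop = FALSE]
    n_st <- colSums(sub)
    present <- which(n_st > 0)
    if (!length(present)) next
    label <- ifelse(n_st[present] >= 2, "shared",
                    paste0("specific:",
                           md$station[match(rows, md$sample_id)][
                             apply(sub[, present, drop = FALSE], 2, which.max)]))
    out[[season]] <- data.frame(otu_id = colnames(pres)[present],
                                season = season, label = unname(label),
                                stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Abundance classes within a season
#'
#' Per-OTU share of the season's total reads: abundant when > 0.1%, low in
#' (0.01%, 0.1%\], rare in (0, 0.01%\]. Reads exactly on a threshold fall to
#' the lower class (strict `>`).
#'
#' @param table an [otu_table()] with a `season` metadata field
#' @param season season to classify
#' @param theta_hi,theta_lo class thresholds as read-share fractions
#' @return data.frame `otu_id`, `season`, `reads`, `share`, `class`
#' @export
abundance_classes <- function(table, season, theta_hi = 0.001, theta_lo = 0.0001) {
  rows <- table$metadata$sample_id[table$metadata$season == season]
  if (!length(rows)) stop("no samples in season ", season)
  reads <- colSums(table$counts[rows, , drop = FALSE])
  total <- sum(reads)
  if (total <= 0) stop("season ", season, " has zero total reads")
  present <- reads > 0
  share <- reads[present] / total
  cls <- ifelse(share > theta_hi, "abundant",
                ifelse(share > theta_lo, "low", "rare"))
  data.frame(otu_id = names(share), season = season,
             reads = as.integer(reads[present]), share = unname(share),
             class = unname(cls), stringsAsFactors = FALSE, row.names = NULL)
}

#' OTU-connectivity network
#'
#' Nodes are station x season (optionally x depth) groups with their OTU
#' richness; edge weights are the numbers of OTUs shared between the two
#' groups' presence sets. Every node pair gets an edge (weight may be 0);
#' edges are flagged intra- vs cross-season.
#'
#' @param table an [otu_table()]
#' @param node_keys metadata fields defining the nodes (default station,
#'   season, plus depth when a DCM sample exists)
#' @return `connectivity_network`: list with `nodes` (node, station, season,
#'   \[depth,\] richness) and `edges` (node_a, node_b, shared_otus,
#'   intra_season)
#' @export
otu_connectivity <- function(table, node_keys = NULL) {
  md <- table$metadata
  if (is.null(node_keys)) {
    node_keys <- c("station", "season")
    if ("depth" %in% names(md) && any(md$depth == "DCM"))
      node_keys <- c(node_keys, "depth")
  }
  if (!all(node_keys %in% names(md)))
    stop("metadata lacks node key field(s): ",
         paste(setdiff(node_keys, names(md)), collapse = ", "))
  keys <- setdiff(intersect(METADATA_FIELDS, names(md)), node_keys)
  merged <- if (length(keys)) merge_samples(table, keys) else table
  pres <- presence_matrix(merged)
  nodes <- merged$metadata
  nodes$node <- nodes$sample_id
  nodes$richness <- as.integer(rowSums(pres)[nodes$sample_id])
  nodes <- nodes[, c("node", intersect(node_keys, names(nodes)), "richness")]
  rownames(nodes) <- NULL
  if (nrow(nodes) < 2) {
    warning("single node: empty edge set")
    edges <- data.frame(node_a = character(), node_b = character(),
                        shared_otus = integer(), intra_season = logical())
  } else {
    shared <- tcrossprod(pres * 1) # shared OTU counts
    idx <- which(upper.tri(shared), arr.ind = TRUE)
    season_of <- stats::setNames(as.character(nodes$season), nodes$node)
    edges <- data.frame(
      node_a = rownames(shared)[idx[, 1]],
      node_b = colnames(shared)[idx[, 2]],
      shared_otus = as.integer(shared[idx]),
      stringsAsFactors = FALSE)
    edges$intra_season <- season_of[edges$node_a] == season_of[edges$node_b]
  }
  structure(list(nodes = nodes, edges = edges, node_keys = node_keys),
            class = "connectivity_network")
}

#' @export
print.connectivity_network <- function(x, ...) {
  cat("connectivity_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges; node keys:", paste(x$node_keys, collapse = ", "), "\n")
  invisible(x)
}

#' Curated-richness control for OTU-connectivity
#'
#' Tests whether unequal richness across seasons drives the connectivity
#' pattern: within each season the season's OTU set is subsampled uniformly
#' (without replacement, seeded) down to the minimum seasonal richness, the
#' network is rebuilt on the curated presence sets, and the Spearman rank
#' correlation between the original and curated edge weights is returned.
#'
#' @param table an [otu_table()]
#' @param node_keys as in [otu_connectivity()]
#' @param seed integer seed for the subsampling
#' @return list `network` (curated `connectivity_network`), `rho` (Spearman,
#'   `NA` with a warning when a weight vector is constant), `curated_k`
#'   (per-season retained OTU count), `seed`
#' @export
curated_connectivity_control <- function(table, node_keys = NULL, seed = 1L) {
  md <- table$metadata
  seasons <- unique(as.character(md$season))
  if (length(seasons) < 2) stop("need >= 2 seasons for the curated control")
  season_sets <- lapply(seasons, function(se) {
    rows <- md$sample_id[md$season == se]
    set <- colnames(table$counts)[colSums(table$counts[rows, , drop = FALSE]) > 0]
    if (!length(set)) stop("season ", se, " has zero OTUs")
    set
  })
  names(season_sets) <- seasons
  k <- min(lengths(season_sets))

  original <- otu_connectivity(table, node_keys)
  set.seed(seed)
  curated_counts <- table$counts
  for (se in seasons) {
    keep <- season_sets[[se]]
    if (length(keep) > k) keep <- sample(keep, k)
    drop <- setdiff(season_sets[[se]], keep)
    rows <- md$sample_id[md$season == se]
    curated_counts[rows, drop] <- 0
  }
  curated_table <- structure(list(counts = curated_counts, metadata = md,
                                  taxref = table$taxref), class = "otu_table")
  curated <- otu_connectivity(curated_table, node_keys)

  key <- function(net) paste(net$edges$node_a, net$edges$node_b)
  stopifnot(identical(key(original), key(curated)))
  w0 <- original$edges$shared_otus
  w1 <- curated$edges$shared_otus
  rho <- if (length(unique(w0)) < 2 || length(unique(w1)) < 2) {
    warning("constant edge weights: Spearman rho undefined")
    NA_real_
  } else spearman(w0, w1)
  list(network = curated, rho = rho,
       curated_k = stats::setNames(rep(k, length(seasons)), seasons),
       seed = seed)
}
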