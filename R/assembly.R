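# Null-model inference of community assembly processes: phylogenetic turnover
# (betaMNTD), its standardized effect size against tip-shuffle nulls (betaNTI),
# compositional turnover against occupancy-weighted richness-preserving nulls
# (Raup-Crick), and the five-process classification.

PROCESS_LEVELS <- c("HomogeneousSelection", "VariableSelection",
                    "DispersalLimitation", "HomogenizingDispersal", "Drift")

#' Cophenetic (tip-to-tip) distances of a phylogeny
#'
#' @param tree a rooted `phylo` with branch lengths
#' @return labelled symmetric matrix of path-length distances
#' @export
cophenetic_distances <- function(tree) {
  validate_tree(tree)
  as_dist_matrix(ape::cophenetic.phylo(tree))
}

#' Jaccard dissimilarity of two presence sets
#'
#' @param presence_a,presence_b character vectors of OTU ids (non-empty)
#' @return 1 - |intersection| / |union|
#' @export
jaccard_dissimilarity <- function(presence_a, presence_b) {
  a <- unique(presence_a); b <- unique(presence_b)
  if (!length(a) || !length(b)) stop("both presence sets must be non-empty")
  1 - length(intersect(a, b)) / length(union(a, b))
}

#' beta-mean-nearest-taxon distance between two communities
#'
#' Presence-based (unweighted): the mean, over taxa of one community, of the
#' phylogenetic distance to the nearest taxon of the other, averaged over both
#' directions. Taxa shared by both communities contribute 0.
#'
#' @param presence_a,presence_b character vectors of OTU ids
#' @param phylo labelled cophenetic distance matrix covering all ids
#' @return betaMNTD >= 0
#' @export
bmntd <- function(presence_a, presence_b, phylo) {
  a <- unique(presence_a); b <- unique(presence_b)
  if (!length(a) || !length(b)) stop("both communities must be non-empty")
  miss <- setdiff(c(a, b), rownames(phylo))
  if (length(miss)) stop("taxa missing from the distance matrix: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  ia <- match(a, rownames(phylo)) - 1L
  ib <- match(b, rownames(phylo)) - 1L
  cpp_bmntd_matrix(phylo, list(ia, ib))[1, 2]
}

table_communities <- function(table, labels) {
  pres <- presence_matrix(table)
  if (any(rowSums(pres) == 0))
    stop("all-zero sample(s): ",
         paste(rownames(pres)[rowSums(pres) == 0], collapse = ", "))
  lapply(seq_len(nrow(pres)), function(s)
    match(colnames(pres)[pres[s, ]], labels) - 1L)
}

#' beta-nearest-taxon index (betaNTI) for all sample pairs
#'
#' betaNTI = (betaMNTD_obs - mean(betaMNTD_null)) / sd(betaMNTD_null), the
#' nulls obtained by shuffling tip labels across the full regional-pool tree
#' (every tip of `tree`, observed in the table or not), one shared permutation
#' per null replicate. `sd = 0` (e.g. a star tree, where every shuffle leaves
#' distances unchanged) yields betaNTI = 0.
#'
#' @param table an [otu_table()]; all OTUs must be tips of `tree`
#' @param tree rooted `phylo` with branch lengths; its tip set defines the
#'   regional pool, so prune it to the intended pool beforehand
#' @param n_null number of tip-shuffle null replicates (>= 2)
#' @param seed integer seed
#' @param pool `"regional"` (default): shuffle across all tree tips;
#'   `"table"`: restrict the shuffle to OTUs present in the table
#' @param drop_missing drop OTUs absent from the tree instead of erroring
#' @return list of labelled sample x sample matrices: `bnti`, `bmntd_obs`,
#'   `null_mean`, `null_sd`
#' @export
bnti <- function(table, tree, n_null = 999, seed = 1L,
                 pool = c("regional", "table"), drop_missing = FALSE) {
  pool <- match.arg(pool)
  if (n_null < 2) stop("n_null must be >= 2")
  miss <- setdiff(colnames(table$counts), tree$tip.label)
  if (length(miss)) {
    if (!drop_missing)
      stop(length(miss), " OTU(s) absent from the tree (e.g. ",
           paste(utils::head(miss, 3), collapse = ", "),
           "); set drop_missing = TRUE to drop them")
    table <- subset_otu_table(table, otus = setdiff(colnames(table$counts), miss))
  }
  otus <- if (pool == "regional") tree$tip.label else colnames(table$counts)
  D <- cophenetic_distances(tree)[otus, otus]
  comms <- table_communities(table, otus)
  n <- length(otus)
  set.seed(seed)
  perms <- t(replicate(n_null, sample.int(n) - 1L))
  obs <- cpp_bmntd_matrix(D, comms)
  nul <- cpp_bmntd_null(D, comms, perms)
  b <- (obs - nul$mean) / nul$sd
  b[nul$sd <= 1e-6 * (abs(nul$mean) + 1e-12)] <- 0 # shuffle-invariant pairs
  diag(b) <- 0
  ids <- rownames(table$counts)
  dimnames(b) <- dimnames(obs) <- dimnames(nul$mean) <- dimnames(nul$sd) <-
    list(ids, ids)
  list(bnti = b, bmntd_obs = obs, null_mean = nul$mean, null_sd = nul$sd)
}

#' Raup-Crick compositional turnover for all sample pairs
#'
#' Null model of compositional turnover: the pool is every OTU in the table;
#' each null replicate draws, for each sample of a pair, a community of the
#' same observed richness by weighted sampling without replacement, and
#' compares the null Jaccard dissimilarity (presence-based, like the observed
#' one) to the observed value. Ties count 0.5 (mid-P) and the rate is rescaled
#' to \[-1, 1\].
#'
#' Pool weights default to each OTU's regional read share (`"abundance"`):
#' with community sizes far exceeding the pool richness, membership is
#' abundance-driven and only an abundance-informed null is calibrated (a
#' neutral well-mixed metacommunity then yields RC near 0). Occupancy weights
#' (fraction of samples occupied, `"occupancy"`) are available but are poorly
#' resolved when few samples are available and saturate the null.
#'
#' @param table an [otu_table()] with >= 2 samples
#' @param n_null number of null draws per pair
#' @param seed integer seed
#' @param pool_weighting `"abundance"` (regional read share, default) or
#'   `"occupancy"` (fraction of samples occupied)
#' @return labelled sample x sample matrix of RC in \[-1, 1\]
#' @export
raup_crick <- function(table, n_null = 999, seed = 1L,
                       pool_weighting = c("abundance", "occupancy")) {
  pool_weighting <- match.arg(pool_weighting)
  pres <- presence_matrix(table)
  if (nrow(pres) < 2) stop("need >= 2 samples")
  occ <- if (pool_weighting == "abundance")
    colSums(table$counts) / sum(table$counts) else colMeans(pres)
  set.seed(seed)
  rc <- cpp_raup_crick(pres, occ, as.integer(n_null))
  dimnames(rc) <- list(rownames(pres), rownames(pres))
  rc
}

#' Classify the dominant assembly process of a sample pair
#'
#' Strict thresholds: betaNTI < -2 homogeneous selection, > 2 variable
#' selection; otherwise RC > 0.95 dispersal limitation, RC < -0.95 homogenizing
#' dispersal, else ecological drift. Boundary values (|betaNTI| = 2,
#' |RC| = 0.95) fall to the non-selection / drift side.
#'
#' @param bnti betaNTI value(s)
#' @param rc Raup-Crick value(s) in \[-1, 1\]
#' @return character vector of process labels
#' @export
classify_process <- function(bnti, rc) {
  if (any(!is.finite(bnti)) || any(!is.finite(rc)))
    stop("non-finite betaNTI or RC")
  if (any(rc < -1 | rc > 1)) stop("RC outside [-1, 1]")
  ifelse(bnti < -2, "HomogeneousSelection",
  ifelse(bnti > 2, "VariableSelection",
  ifelse(rc > 0.95, "DispersalLimitation",
  ifelse(rc < -0.95, "HomogenizingDispersal", "Drift"))))
}

#' Full pairwise assembly analysis
#'
#' Runs [bnti()] and [raup_crick()] on the same table and classifies every
#' sample pair.
#'
#' @inheritParams bnti
#' @param rc_seed seed for the Raup-Crick nulls (default derived from `seed`)
#' @return data.frame with one row per unordered sample pair: `sample_a`,
#'   `sample_b`, `bmntd_obs`, `null_mean`, `null_sd`, `bnti`, `rc`, `process`,
#'   `n_null`
#' @export
assembly_analysis <- function(table, tree, n_null = 999, seed = 1L,
                              rc_seed = seed + 1L, drop_missing = FALSE) {
  bn <- bnti(table, tree, n_null = n_null, seed = seed,
             drop_missing = drop_missing)
  rc <- raup_crick(table, n_null = n_null, seed = rc_seed)
  idx <- which(upper.tri(bn$bnti), arr.ind = TRUE)
  ids <- rownames(bn$bnti)
  out <- data.frame(
    sample_a = ids[idx[, 1]], sample_b = ids[idx[, 2]],
    bmntd_obs = bn$bmntd_obs[idx], null_mean = bn$null_mean[idx],
    null_sd = bn$null_sd[idx], bnti = bn$bnti[idx], rc = rc[idx],
    n_null = as.integer(n_null), stringsAsFactors = FALSE)
  out$process <- classify_process(out$bnti, out$rc)
  out
}

#' Summarise assembly processes over all pairs
#'
#' Counts pairs per process and builds the edge list of pairs whose dominant
#' process is not homogeneous selection, with nodes grouped to (station,
#' season) and multiplicity across replicates preserved as edge weight.
#'
#' @param results data.frame from [assembly_analysis()]
#' @param metadata sample metadata with `sample_id`, `station`, `season`
#' @return list `counts` (named integer vector over the five processes),
#'   `n_pairs`, `edges` (node_a, node_b, process, multiplicity)
#' @export
process_summary <- function(results, metadata = NULL) {
  if (!nrow(results)) stop("no pairwise results")
  counts <- table(factor(results$process, levels = PROCESS_LEVELS))
  non_hs <- results[results$process != "HomogeneousSelection", , drop = FALSE]
  if (nrow(non_hs)) {
    if (!is.null(metadata)) {
      node <- stats::setNames(paste(metadata$station, metadata$season, sep = "|"),
                              metadata$sample_id)
      na <- node[non_hs$sample_a]; nb <- node[non_hs$sample_b]
    } else {
      na <- non_hs$sample_a; nb <- non_hs$sample_b
    }
    swap <- na > nb
    tmp <- na[swap]; na[swap] <- nb[swap]; nb[swap] <- tmp
    agg <- stats::aggregate(list(multiplicity = rep(1L, nrow(non_hs))),
                            by = list(node_a = na, node_b = nb,
                                      process = non_hs$process), FUN = sum)
    edges <- agg[order(agg$node_a, agg$node_b, agg$process), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(node_a = character(), node_b = character(),
                        process = character(), multiplicity = integer())
  }
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       n_pairs = nrow(results), edges = edges)
}

#' Mantel test between phylogenetic and trait distances
#'
#' Tests the working hypothesis of the null-model framework - that phylogeny
#' is a proxy for niche/trait divergence - by correlating cophenetic and trait
#' (Gower) distances with a one-sided permutation test.
#'
#' @param phylo,traits labelled distance matrices over the same ids
#' @param n_perm permutations
#' @param seed integer seed
#' @return list `r` (Mantel statistic: Pearson correlation of off-diagonal
#'   entries), `p` (one-sided permutation p-value), `n_perm`
#' @export
phylo_trait_signal <- function(phylo, traits, n_perm = 999, seed = 1L) {
  if (!identical(sort(rownames(phylo)), sort(rownames(traits))))
    stop("matrices must cover the same ids")
  traits <- traits[rownames(phylo), rownames(phylo)]
  lo <- lower.tri(phylo)
  if (stats::sd(phylo[lo]) == 0 || stats::sd(traits[lo]) == 0)
    stop("constant distance matrix: Mantel statistic undefined")
  set.seed(seed)
  m <- vegan::mantel(stats::as.dist(phylo), stats::as.dist(traits),
                     method = "pearson", permutations = n_perm)
  list(r = unname(m$statistic), p = unname(m$signif), n_perm = n_perm)
}
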