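# Permutation and rank statistics used throughout the pipeline. PERMANOVA is
# delegated to vegan::adonis2 (sequential sums of squares, raw permutation of
# sample identities); Kruskal-Wallis and Spearman to base stats.

#' Bray-Curtis dissimilarity of all sample pairs
#'
#' BC(a,b) = sum_i |x_ai - x_bi| / sum_i (x_ai + x_bi).
#'
#' @param table an [otu_table()] with no all-zero sample
#' @return labelled sample x sample matrix in \[0, 1\]
#' @export
bray_curtis <- function(table) {
  if (any(rowSums(table$counts) == 0))
    stop("all-zero sample(s): ",
         paste(rownames(table$counts)[rowSums(table$counts) == 0], collapse = ", "))
  as_dist_matrix(as.matrix(vegan::vegdist(table$counts, method = "bray")),
                 tol = 1e-8)
}

#' PERMANOVA on a distance matrix
#'
#' Partitions the Gower-centred -d^2/2 matrix with sequential (Type I) sums of
#' squares in the given term order; significance by raw permutation of sample
#' identities. Continuous and categorical terms are both supported. The
#' p-value convention is (count of permuted F >= observed + 1)/(n_perm + 1),
#' except under exhaustive enumeration (a permutation matrix), where it is the
#' exact proportion.
#'
#' @param D labelled distance matrix
#' @param data data.frame of covariates, rows matching `D`'s labels (matched by
#'   row name when present)
#' @param terms character vector of column names, in model order
#' @param n_perm number of permutations, or a permutation matrix (one
#'   permutation of `1:n` per row) for exhaustive tests
#' @param seed integer seed
#' @return data.frame with one row per term plus Residual and Total: `term`,
#'   `df`, `sum_sq`, `r2`, `f`, `p`
#' @export
permanova <- function(D, data, terms, n_perm = 9999, seed = 1L) {
  D <- as_dist_matrix(D, tol = 1e-8)
  n <- nrow(D)
  if (n < 3) stop("need >= 3 samples")
  if (!all(terms %in% names(data)))
    stop("unknown term(s): ", paste(setdiff(terms, names(data)), collapse = ", "))
  if (!is.null(rownames(data)) && all(rownames(D) %in% rownames(data)))
    data <- data[rownames(D), , drop = FALSE]
  else if (nrow(data) != n)
    stop("data rows do not match distance matrix labels")
  for (term in terms) {
    v <- data[[term]]
    if (length(unique(v[!is.na(v)])) < 2)
      stop("constant/confounded term: ", term)
  }
  fml <- stats::as.formula(paste("D ~", paste(sprintf("`%s`", terms), collapse = " + ")))
  env <- list2env(list(D = stats::as.dist(D)))
  if (is.matrix(n_perm)) {
    # exhaustive enumeration: drop identity rows (adonis2 counts the observed
    # ordering itself), so p = #(F_perm >= F_obs) / #relabelings
    n_perm <- n_perm[rowSums(n_perm != rep(seq_len(n), each = nrow(n_perm))) > 0,
                     , drop = FALSE]
  }
  set.seed(seed)
  fit <- vegan::adonis2(fml, data = data, permutations = n_perm,
                        by = "terms", environment = env)
  out <- data.frame(term = rownames(fit), df = fit$Df, sum_sq = fit$SumOfSqs,
                    r2 = fit$R2, f = fit$F, p = fit$`Pr(>F)`,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$term <- sub("^`(.*)`$", "\\1", out$term)
  out
}

#' Kruskal-Wallis rank test
#'
#' H with tie correction; p from the chi-square approximation with k - 1
#' degrees of freedom. All-tied data yield H = 0 (p = 1) rather than NaN.
#'
#' @param values numeric vector
#' @param groups grouping vector of the same length (>= 2 non-empty groups)
#' @return list `h`, `p`, `df`
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (length(unique(values)) == 1)
    return(list(h = 0, p = 1, df = nlevels(groups) - 1L))
  k <- stats::kruskal.test(values, groups)
  list(h = unname(k$statistic), p = unname(k$p.value),
       df = unname(k$parameter))
}

#' Spearman rank correlation
#'
#' Pearson correlation of tie-averaged ranks. A constant input is undefined
#' and reported as `NA` with a warning.
#'
#' @param x,y numeric vectors of equal length >= 3
#' @return rho in \[-1, 1\], or `NA`
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: Spearman rho undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}
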