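# Independent oracles and shared fixtures. Each oracle is a deliberately
# naive implementation kept separate from the package code paths it checks.

# brute-force double-loop betaMNTD
bmntd_brute <- function(a, b, D) {
  ma <- vapply(a, function(i) min(D[i, b]), numeric(1))
  mb <- vapply(b, function(j) min(D[j, a]), numeric(1))
  0.5 * (mean(ma) + mean(mb))
}

# exact distribution over k-subsets under successive weighted sampling
# without replacement (probability of each ordered draw = prod w / remaining)
swr_set_probs <- function(w, k) {
  res <- new.env(parent = emptyenv())
  rec <- function(remaining, chosen, p) {
    if (length(chosen) == k) {
      key <- paste(sort(chosen), collapse = ",")
      prev <- if (!is.null(res[[key]])) res[[key]]$p else 0
      res[[key]] <- list(p = prev + p, set = sort(chosen))
      return()
    }
    wr <- w[remaining]
    tot <- sum(wr)
    for (i in seq_along(remaining))
      rec(remaining[-i], c(chosen, remaining[i]), p * wr[i] / tot)
  }
  rec(which(w > 0), integer(), 1)
  lapply(ls(res), function(k_) res[[k_]])
}

# exact Raup-Crick for a two-sample table under given pool weights
raup_crick_exact <- function(pres_a, pres_b, w) {
  jac <- function(a, b) 1 - length(intersect(a, b)) / length(union(a, b))
  j_obs <- jac(pres_a, pres_b)
  sets_a <- swr_set_probs(w, length(pres_a))
  sets_b <- swr_set_probs(w, length(pres_b))
  below <- ties <- 0
  for (sa in sets_a) for (sb in sets_b) {
    j <- jac(sa$set, sb$set)
    p <- sa$p * sb$p
    if (j < j_obs - 1e-12) below <- below + p
    else if (j < j_obs + 1e-12) ties <- ties + p
  }
  2 * (below + 0.5 * ties) - 1
}

# matrix-algebra PERMANOVA (single term) + exhaustive permutation p-value
permanova_oracle <- function(D, x, exhaustive = TRUE) {
  n <- nrow(D)
  G <- -0.5 * D^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% G %*% C
  ss_total <- sum(diag(G))
  fstat <- function(xi) {
    X <- stats::model.matrix(~xi)
    H <- X %*% solve(crossprod(X)) %*% t(X)
    ss_m <- sum(diag(H %*% G))
    df1 <- qr(X)$rank - 1
    df2 <- n - qr(X)$rank
    (ss_m / df1) / ((ss_total - ss_m) / df2)
  }
  f_obs <- fstat(x)
  perms <- NULL
  if (exhaustive) {
    perms <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), ,
                   drop = FALSE]
    f_perm <- apply(perms, 1, function(p) fstat(x[p]))
    p_val <- mean(f_perm >= f_obs - 1e-12)
  } else p_val <- NA
  X <- stats::model.matrix(~x)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  ss_m <- sum(diag(H %*% G))
  list(f = f_obs, r2 = ss_m / ss_total, p = p_val, perms = perms)
}

# shared toy tree for the hand-worked phylogenetic examples
four_tip_tree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# printed diversity fixture: 6 merged samples (3 stations x 2 seasons),
# 10 OTUs, season totals 10000 (March) and 5000 (July); all expectations in
# the tests are hand counts on this table
toy_diversity_table <- function() {
  otus <- sprintf("t%02d", 1:10)
  counts <- rbind(
    "March|O1" = c(5000, 1500, 10,  0, 1, 0,  0, 0, 0, 0),
    "March|F"  = c(2001,    0,  5, 10, 0, 2,  0, 0, 0, 0),
    "March|C1" = c(1200,  260,  0,  0, 0, 0, 11, 0, 0, 0),
    "July|O1"  = c(   0,  300, 100, 0, 0, 0,  0, 6, 0, 0),
    "July|F"   = c(   0,  400, 150, 40, 0, 0, 0, 0, 1, 0),
    "July|C1"  = c(   0,    0, 4000, 0, 0, 0, 0, 0, 0, 3))
  colnames(counts) <- otus
  meta <- data.frame(
    sample_id = rownames(counts),
    season = rep(c("March", "July"), each = 3),
    station = rep(c("O1", "F", "C1"), 2),
    stringsAsFactors = FALSE)
  otu_table(counts, meta)
}

# small random otu_table helper
random_table <- function(n_samples, n_otus, seed, lambda = 3) {
  set.seed(seed)
  counts <- matrix(stats::rpois(n_samples * n_otus, lambda),
                   nrow = n_samples,
                   dimnames = list(paste0("s", seq_len(n_samples)),
                                   sprintf("OTU%04d", seq_len(n_otus))))
  counts[, colSums(counts) > 0, drop = FALSE]
  otu_table(counts[, colSums(counts) > 0, drop = FALSE],
            data.frame(sample_id = rownames(counts)))
}
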