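test_that("cophenetic distances are path-length sums", {
  D <- cophenetic_distances(four_tip_tree())
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(D["C", "D"], 2)
  expect_true(all(diag(D) == 0))
  star <- ape::read.tree(text = "(A:3,B:3,C:3,D:3);")
  Ds <- cophenetic_distances(star)
  expect_true(all(Ds[upper.tri(Ds)] == 6))
})

test_that("jaccard dissimilarity covers identity, disjoint and partial overlap", {
  expect_equal(jaccard_dissimilarity(c("A", "B"), c("A", "B")), 0)
  expect_equal(jaccard_dissimilarity("A", "B"), 1)
  expect_equal(jaccard_dissimilarity(c("A", "B"), c("B", "C")), 1 - 1 / 3)
  expect_error(jaccard_dissimilarity(character(), "A"), "non-empty")
})

test_that("bmntd matches the hand examples and the brute-force oracle", {
  D <- cophenetic_distances(four_tip_tree())
  expect_equal(bmntd(c("A", "B"), c("C", "D"), D), 4)
  expect_equal(bmntd("A", c("A", "C"), D), 1)
  expect_equal(bmntd(c("A", "C"), "A", D), 1) # symmetric
  expect_equal(bmntd(c("A", "B"), c("A", "B"), D), 0)
  set.seed(11)
  for (i in 1:50) {
    n <- sample(5:32, 1)
    tree <- ape::rtree(n)
    Dr <- cophenetic_distances(tree)
    a <- sample(tree$tip.label, sample(2:n, 1))
    b <- sample(tree$tip.label, sample(2:n, 1))
    expect_equal(bmntd(a, b, Dr), bmntd_brute(a, b, Dr), tolerance = 1e-12)
  }
})

test_that("bmntd agrees with the picante implementation", {
  set.seed(3)
  tree <- ape::rtree(24)
  D <- cophenetic_distances(tree)
  comm <- matrix(rbinom(48, 1, 0.5), nrow = 2,
                 dimnames = list(c("a", "b"), tree$tip.label))
  comm[, colSums(comm) == 0][1, ] <- 1
  ref <- as.matrix(picante::comdistnt(comm, D, exclude.conspecifics = FALSE))
  a <- colnames(comm)[comm["a", ] > 0]
  b <- colnames(comm)[comm["b", ] > 0]
  # same-sized communities make the pooled and two-way means coincide
  k <- min(length(a), length(b))
  comm2 <- comm * 0
  comm2["a", a[1:k]] <- 1; comm2["b", b[1:k]] <- 1
  ref2 <- as.matrix(picante::comdistnt(comm2, D, exclude.conspecifics = FALSE))
  expect_equal(bmntd(a[1:k], b[1:k], D), ref2["a", "b"], tolerance = 1e-10)
})

test_that("adding a shared taxon never increases bmntd", {
  set.seed(21)
  tree <- ape::rtree(20)
  D <- cophenetic_distances(tree)
  for (i in 1:20) {
    a <- sample(tree$tip.label, 6)
    b <- sample(tree$tip.label, 6)
    extra <- sample(setdiff(tree$tip.label, union(a, b)), 1)
    expect_lte(bmntd(c(a, extra), c(b, extra), D), bmntd(a, b, D) + 1e-12)
  }
})

test_that("betaNTI is zero on a star tree and reproducible under a seed", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1);")
  counts <- rbind(s1 = c(1, 1, 0, 0, 1), s2 = c(0, 1, 1, 1, 0),
                  s3 = c(1, 0, 1, 0, 1))
  colnames(counts) <- star$tip.label
  tab <- otu_table(counts, data.frame(sample_id = rownames(counts)))
  bn <- bnti(tab, star, n_null = 99, seed = 1)
  expect_true(all(bn$bnti == 0)) # shuffle-invariant distances -> sd 0 -> 0
  tab2 <- random_table(6, 30, seed = 5)
  tree <- generate_tree(30, seed = 5)
  b1 <- bnti(tab2, tree, n_null = 199, seed = 42)
  b2 <- bnti(tab2, tree, n_null = 199, seed = 42)
  expect_identical(b1$bnti, b2$bnti)
  expect_error(bnti(tab2, tree, n_null = 1), "n_null")
})

test_that("OTUs missing from the tree error by default, drop on request", {
  tree <- generate_tree(10, seed = 2)
  counts <- matrix(1, 2, 11,
                   dimnames = list(c("s1", "s2"),
                                   c(tree$tip.label, "OTU9999")))
  tab <- otu_table(counts, data.frame(sample_id = c("s1", "s2")))
  expect_error(bnti(tab, tree, n_null = 9, seed = 1), "OTU9999")
  bn <- bnti(tab, tree, n_null = 9, seed = 1, drop_missing = TRUE)
  expect_equal(dim(bn$bnti), c(2L, 2L))
})

test_that("raup_crick handles the exact and degenerate cases", {
  cnt <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("A", "B"), c("X", "Y")))
  tab <- otu_table(cnt, data.frame(sample_id = c("A", "B")))
  rc <- raup_crick(tab, n_null = 49999, seed = 1, pool_weighting = "occupancy")
  expect_equal(rc["A", "B"], 0.5, tolerance = 0.02) # exact enumeration: 0.5
  # both samples = whole pool: every null equals the observed pair
  full <- otu_table(matrix(1, 2, 3, dimnames = list(c("A", "B"), c("x", "y", "z"))),
                    data.frame(sample_id = c("A", "B")))
  expect_equal(raup_crick(full, n_null = 99, seed = 1)["A", "B"], 0)
  r1 <- raup_crick(random_table(5, 20, seed = 8), n_null = 199, seed = 3)
  r2 <- raup_crick(random_table(5, 20, seed = 8), n_null = 199, seed = 3)
  expect_identical(r1, r2)
  expect_true(all(r1 >= -1 & r1 <= 1))
})

test_that("raup_crick Monte Carlo matches exhaustive enumeration on small pools", {
  set.seed(14)
  for (i in 1:6) {
    n_pool <- sample(3:6, 1)
    otus <- paste0("o", seq_len(n_pool))
    repeat {
      ca <- rbinom(n_pool, 1, 0.6); cb <- rbinom(n_pool, 1, 0.6)
      if (sum(ca) >= 1 && sum(cb) >= 1 && any(ca + cb > 0)) break
    }
    counts <- rbind(A = ca * sample(1:5, n_pool, TRUE),
                    B = cb * sample(1:5, n_pool, TRUE))
    colnames(counts) <- otus
    counts <- counts[, colSums(counts) > 0, drop = FALSE]
    tab <- otu_table(counts, data.frame(sample_id = c("A", "B")))
    w <- colSums(tab$counts) / sum(tab$counts)
    exact <- raup_crick_exact(which(tab$counts["A", ] > 0),
                              which(tab$counts["B", ] > 0), w)
    mc <- raup_crick(tab, n_null = 9999, seed = i)["A", "B"]
    expect_lt(abs(mc - exact), 0.05)
  }
})

test_that("raup_crick depends only on presence structure, not OTU labels", {
  tab <- random_table(5, 15, seed = 4)
  rc1 <- raup_crick(tab, n_null = 1999, seed = 7, pool_weighting = "occupancy")
  set.seed(4)
  perm <- sample(ncol(tab$counts))
  tab2 <- tab
  tab2$counts <- tab$counts[, perm]
  colnames(tab2$counts) <- colnames(tab$counts) # relabel
  tab2$taxref <- tab$taxref
  rc2 <- raup_crick(tab2, n_null = 1999, seed = 8, pool_weighting = "occupancy")
  expect_lt(max(abs(rc1 - rc2)), 0.15) # same null distribution, MC noise only
})

test_that("the five-process classification applies strict thresholds", {
  expect_equal(classify_process(-3.1, 0.2), "HomogeneousSelection")
  expect_equal(classify_process(2.5, -0.2), "VariableSelection")
  expect_equal(classify_process(0.5, 0.97), "DispersalLimitation")
  expect_equal(classify_process(1.0, -0.99), "HomogenizingDispersal")
  expect_equal(classify_process(0, 0), "Drift")
  # boundaries fall to the non-selection / drift side
  expect_equal(classify_process(-2, 0), "Drift")
  expect_equal(classify_process(2, 0), "Drift")
  expect_equal(classify_process(0, 0.95), "Drift")
  expect_equal(classify_process(0, -0.95), "Drift")
  expect_equal(classify_process(2, 0.96), "DispersalLimitation")
  expect_error(classify_process(NaN, 0), "non-finite")
  expect_error(classify_process(0, 1.2), "RC outside")
})

test_that("process summaries count pairs and preserve edge multiplicity", {
  res <- data.frame(
    sample_a = c("s1", "s1", "s2", "s3"), sample_b = c("s2", "s3", "s3", "s4"),
    bnti = 0, rc = 0,
    process = c("HomogeneousSelection", "DispersalLimitation",
                "DispersalLimitation", "HomogeneousSelection"))
  # s1, s2 are replicates of C1 in July; s3, s4 of F in September
  md <- data.frame(sample_id = paste0("s", 1:4),
                   station = c("C1", "C1", "F", "F"),
                   season = c("July", "July", "September", "September"))
  sm <- process_summary(res, md)
  expect_equal(sm$n_pairs, 4L)
  expect_equal(sm$counts[["HomogeneousSelection"]], 2L)
  expect_equal(sm$counts[["DispersalLimitation"]], 2L)
  expect_equal(sum(sm$counts), 4L)
  # the two DL pairs map to the same (station|season) node pair -> multiplicity 2
  expect_equal(nrow(sm$edges), 1L)
  expect_equal(sm$edges$multiplicity, 2L)
  all_hs <- res; all_hs$process <- "HomogeneousSelection"
  expect_equal(nrow(process_summary(all_hs, md)$edges), 0L)
})

test_that("mantel statistic and permutation p behave at the extremes", {
  set.seed(2)
  pts <- matrix(rnorm(24), ncol = 2)
  D1 <- as.matrix(dist(pts)); dimnames(D1) <- list(paste0("t", 1:12), paste0("t", 1:12))
  D2 <- 2 * D1 + 0.3; diag(D2) <- 0
  sig <- phylo_trait_signal(D1, D2, n_perm = 199, seed = 1)
  expect_equal(sig$r, 1, tolerance = 1e-12)
  expect_equal(sig$p, 1 / 200)
  expect_error(phylo_trait_signal(D1 * 0, D2, n_perm = 99, seed = 1), "constant")
})

test_that("mantel Monte-Carlo p matches exhaustive enumeration at n = 5", {
  set.seed(6)
  lab <- paste0("x", 1:5)
  D1 <- as.matrix(dist(rnorm(5))); dimnames(D1) <- list(lab, lab)
  D2 <- as.matrix(dist(rnorm(5))); dimnames(D2) <- list(lab, lab)
  lo <- lower.tri(D1)
  r_obs <- cor(D1[lo], D2[lo])
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  r_perm <- apply(perms, 1, function(p) {
    Dp <- D2[p, p]
    cor(D1[lo], Dp[lo])
  })
  p_exact <- mean(r_perm >= r_obs - 1e-12)
  p_mc <- phylo_trait_signal(D1, D2, n_perm = 999, seed = 3)$p
  expect_lt(abs(p_mc - p_exact), 0.1)
})
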