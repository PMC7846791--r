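make_traits <- function() {
  # 6 rows over the 12 standard traits; crafted ranges for the hand examples
  df <- data.frame(
    SizeMin = c(10, 20, 50, 30, 25, 15),
    SizeMax = c(12, 25, 60, 35, 30, 18),
    check.names = FALSE)
  for (col in c("Cell Cover", "Cell Shape", "Cell Symmetry", "Cell Polarity",
                "Ingestion method", "Symbiosis type", "Presence of Spicule",
                "Coloniality", "Motility", "Resting Stage"))
    df[[col]] <- "same"
  rownames(df) <- paste0("r", 1:6)
  df
}

test_that("gower distance follows the range-normalized mixed formula", {
  tr <- make_traits()
  # identical rows -> 0
  tr2 <- tr; tr2[2, ] <- tr2[1, ]; rownames(tr2) <- rownames(tr)
  expect_equal(gower_distance(tr2)["r1", "r2"], 0)
  # one categorical mismatch out of 12 -> 1/12
  tr3 <- tr
  tr3[["Cell Shape"]][2] <- "other"
  tr3$SizeMin <- 10; tr3$SizeMax <- 12
  expect_equal(gower_distance(tr3)["r1", "r2"], 1 / 12)
  # SizeMin 10 vs 20 with pool range 40, all else equal -> (10/40)/12
  tr4 <- tr
  tr4$SizeMin <- c(10, 20, 50, 30, 25, 15) # range 40
  tr4$SizeMax <- 60
  expect_equal(gower_distance(tr4)["r1", "r2"], (10 / 40) / 12)
  # missing cells drop the trait for the pair; no-overlap pair errors
  tr5 <- tr
  tr5[1, ] <- NA; tr5$SizeMin[1] <- 10; tr5$SizeMax[1] <- 12
  tr5$SizeMin[2] <- NA; tr5$SizeMax[2] <- NA
  expect_error(gower_distance(tr5), "share no observed trait")
  g <- gower_distance(make_traits())
  expect_true(all(g >= 0 & g <= 1))
})

test_that("pcoa recovers euclidean configurations", {
  # collinear points 0,1,2: axis-1 distances exact, second eigenvalue ~ 0
  x <- c(0, 1, 2)
  D <- as.matrix(dist(x)); dimnames(D) <- list(letters[1:3], letters[1:3])
  sp <- pcoa(D, m = 1)
  expect_equal(sort(as.vector(dist(sp$coordinates))), c(1, 1, 2), tolerance = 1e-9)
  expect_length(sp$eigenvalues, 1) # the zero eigenvalue is not positive
  # planar configuration reproduced exactly by 2 axes
  set.seed(4)
  pts <- matrix(rnorm(20), ncol = 2)
  D2 <- as.matrix(dist(pts))
  dimnames(D2) <- list(paste0("p", 1:10), paste0("p", 1:10))
  sp2 <- pcoa(D2, m = 2)
  expect_equal(as.matrix(dist(sp2$coordinates)), unname(D2) + 0 * D2,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(pcoa(D, m = 2), "smaller m")
})

test_that("hull volumes are exact on closed-form shapes", {
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  expect_equal(convex_hull_volume(sq), 1)
  expect_equal(convex_hull_volume(sq[1:3, ]), 0.5)
  expect_equal(convex_hull_volume(as.matrix(expand.grid(0:1, 0:1, 0:1))), 1)
  expect_equal(convex_hull_volume(as.matrix(expand.grid(0:1, 0:1, 0:1, 0:1))), 1)
  expect_equal(convex_hull_volume(rbind(0, diag(4))), 1 / factorial(4))
  expect_equal(convex_hull_volume(matrix(c(0, 2, 7), 3)), 7) # 1-D range
  # interior points change nothing
  set.seed(2)
  pts <- matrix(rnorm(30), ncol = 3)
  inner <- colMeans(pts)
  expect_equal(convex_hull_volume(rbind(pts, inner)), convex_hull_volume(pts))
  expect_error(convex_hull_volume(cbind(1:5, 2 * (1:5))), "degenerate")
})

test_that("2-D hull volumes match the chull/shoelace oracle on random sets", {
  set.seed(9)
  for (i in 1:10) {
    pts <- matrix(rnorm(40), ncol = 2)
    h <- chull(pts)
    xy <- pts[h, ]
    shoelace <- abs(sum(xy[, 1] * xy[c(2:nrow(xy), 1), 2] -
                        xy[c(2:nrow(xy), 1), 1] * xy[, 2])) / 2
    expect_equal(convex_hull_volume(pts), shoelace, tolerance = 1e-9)
  }
})

test_that("functional richness is pool-normalized, monotone and sign-invariant", {
  sq <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(0.5, 0.5))
  rownames(sq) <- paste0("o", 1:5)
  space <- structure(list(coordinates = sq, eigenvalues = c(1, 1), m = 2,
                          negative_inertia = 0, pool_hull_volume = 1),
                     class = "functional_space")
  fr <- functional_richness(space, list(pool = rownames(sq),
                                        tri = c("o1", "o2", "o3"),
                                        with_inner = c("o1", "o2", "o3", "o5")))
  expect_equal(unname(fr["pool"]), 1)
  expect_equal(unname(fr["tri"]), 0.5)         # triangle is half the square
  expect_equal(unname(fr["with_inner"]), 0.5)  # interior point adds nothing
  # sign-flipped axes give identical values
  flipped <- space
  flipped$coordinates[, 1] <- -flipped$coordinates[, 1]
  expect_equal(functional_richness(flipped, list(tri = c("o1", "o2", "o3"))),
               fr["tri"])
  expect_error(functional_richness(space, list(small = c("o1", "o2"))), "need > m")
})

test_that("functional richness never decreases when OTUs are added", {
  set.seed(12)
  pts <- matrix(rnorm(60), ncol = 2)
  rownames(pts) <- paste0("o", 1:30)
  space <- structure(list(coordinates = pts, eigenvalues = c(1, 1), m = 2,
                          negative_inertia = 0,
                          pool_hull_volume = convex_hull_volume(pts)),
                     class = "functional_space")
  for (i in 1:20) {
    small <- sample(rownames(pts), sample(5:15, 1))
    big <- union(small, sample(rownames(pts), sample(5:15, 1)))
    fr <- functional_richness(space, list(s = small, b = big))
    expect_lte(fr[["s"]], fr[["b"]] + 1e-12)
    expect_lte(fr[["b"]], 1 + 1e-12)
  }
})

test_that("strategy clustering is deterministic and matches hclust off ties", {
  set.seed(5)
  pts <- matrix(rnorm(40), ncol = 2)
  rownames(pts) <- paste0("o", 1:20)
  D <- as.matrix(dist(pts)); dimnames(D) <- list(rownames(pts), rownames(pts))
  cl <- strategy_clustering(D, k = 4)
  ref <- cutree(hclust(as.dist(D), method = "complete"), k = 4)
  expect_equal(unname(table(cl)[as.character(cl)]),
               unname(table(ref)[as.character(ref)])) # same partition sizes
  # partitions agree up to relabelling
  expect_equal(length(unique(paste(cl, ref))), 4L)
  # invariant to input order
  perm <- sample(20)
  cl2 <- strategy_clustering(D[perm, perm], k = 4)
  expect_equal(length(unique(paste(cl, cl2[names(cl)]))), 4L)
  # trivial cuts
  expect_length(unique(strategy_clustering(D, k = 20)), 20L)
  expect_error(strategy_clustering(D, k = 21), "exceeds")
})

test_that("well-separated trait blobs are recovered as clusters", {
  set.seed(7)
  blob <- rbind(matrix(rnorm(20, 0, 0.1), ncol = 2),
                matrix(rnorm(20, 5, 0.1), ncol = 2))
  rownames(blob) <- paste0("o", 1:20)
  D <- as.matrix(dist(blob)); dimnames(D) <- list(rownames(blob), rownames(blob))
  cl <- strategy_clustering(D, k = 2)
  expect_equal(length(unique(cl[1:10])), 1L)
  expect_equal(length(unique(cl[11:20])), 1L)
  expect_true(cl[1] != cl[11])
})

test_that("strategy distributions tally per station with an unannotated row", {
  assign <- c(a = 1, b = 1, c = 2)
  presence <- list(F = c("o1", "o2", "o4"), C1 = c("o2", "o3"))
  taxref <- c(o1 = "a", o2 = "b", o3 = "c", o4 = "zz") # zz unannotated
  distr <- strategy_distribution(assign, presence, taxref = taxref)
  expect_equal(distr[["F"]], c(2L, 0L, 1L))       # strategies 1,2 + unannotated
  expect_equal(distr[["C1"]], c(1L, 1L, 0L))
  expect_equal(colSums(distr), c(F = 3, C1 = 2))  # station richness
})
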