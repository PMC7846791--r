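test_that("phototroph filtering keeps flagged taxa and reports fractions", {
  counts <- matrix(c(800, 100, 100), 1, dimnames = list("s1", c("a", "b", "c")))
  tab <- otu_table(counts, data.frame(sample_id = "s1"),
                   taxref = c(a = "P", b = "H", c = "P2"))
  traits <- data.frame(taxref = c("P", "H", "P2"),
                       obligate_phototroph = c(TRUE, FALSE, TRUE),
                       row.names = c("P", "H", "P2"))
  expect_message(out <- filter_phototrophs(tab, traits), "90.0% of reads")
  expect_setequal(colnames(out$counts), c("a", "c"))
  # all-true flag is the identity
  traits$obligate_phototroph <- TRUE
  expect_equal(ncol(filter_phototrophs(tab, traits)$counts), 3L)
  traits$obligate_phototroph <- FALSE
  expect_error(filter_phototrophs(tab, traits), "obligate_phototroph")
})

test_that("richness counts present OTUs per sample and per merged group", {
  counts <- rbind(s1 = c(0, 3, 1), s2 = c(1, 0, 0))
  colnames(counts) <- paste0("o", 1:3)
  meta <- data.frame(sample_id = c("s1", "s2"), season = "July",
                     station = "F", replicate = 1:2)
  tab <- otu_table(counts, meta)
  expect_equal(richness(tab)$richness, c(2L, 1L))
  expect_equal(richness(tab, per = c("season", "station"))$richness, 3L)
})

test_that("analytic rarefaction matches the hypergeometric and Monte-Carlo", {
  expect_equal(rarefaction_curve(c(2, 2), 2), 5 / 3)
  cts <- c(5, 3, 2, 1, 1)
  expect_equal(rarefaction_curve(cts, sum(cts)), 5)       # n = N
  expect_equal(rarefaction_curve(cts, 1), 1)              # one read, one OTU
  expect_error(rarefaction_curve(cts, 13), "within")
  curve <- rarefaction_curve(cts, 1:12)
  expect_true(all(diff(curve) >= 0))
  expect_equal(curve, suppressWarnings(
    as.numeric(vegan::rarefy(cts, 1:12))), tolerance = 1e-10)
  # Monte-Carlo subsampling at N/2 agrees within 3 standard errors
  set.seed(42)
  pool <- rep(seq_along(cts), cts)
  sims <- replicate(1000, length(unique(sample(pool, 6))))
  se <- sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - rarefaction_curve(cts, 6)), 3 * se)
})

test_that("chao1 follows the bias-corrected formula", {
  cts <- c(rep(1, 4), rep(2, 2), rep(5, 4)) # S=10, F1=4, F2=2
  expect_equal(chao1(cts), 12)
  expect_equal(chao1(cts), unname(vegan::estimateR(cts)["S.chao1"]))
  expect_equal(chao1(c(2, 3, 4)), 3)     # F1 = 0
  expect_equal(chao1(c(3, 3, 5, 7)), 4)  # all >= 3
})

test_that("occurrence categories follow the shared / station-specific rule", {
  occ <- occurrence_categories(toy_diversity_table())
  lab <- function(otu, season) occ$label[occ$otu_id == otu & occ$season == season]
  expect_equal(lab("t01", "March"), "shared")
  expect_equal(lab("t04", "March"), "specific:F")
  expect_equal(lab("t05", "March"), "specific:O1")
  expect_equal(lab("t03", "July"), "shared")
  expect_equal(lab("t10", "July"), "specific:C1")
  expect_length(lab("t08", "March"), 0) # absent from the season: no label
  # unmerged input is rejected
  tab <- toy_diversity_table()
  tab$metadata$station[2] <- "O1"
  expect_error(occurrence_categories(tab), "merged")
})

test_that("abundance classes partition present OTUs with strict thresholds", {
  tab <- toy_diversity_table()
  ab <- abundance_classes(tab, "March") # season total 10000
  cls <- setNames(ab$class, ab$otu_id)
  expect_equal(unname(cls[c("t01", "t02", "t03", "t07")]), rep("abundant", 4))
  expect_equal(unname(cls["t04"]), "low")  # exactly 0.1% -> lower class
  expect_equal(unname(cls["t05"]), "rare") # exactly 0.01% -> lower class
  expect_equal(unname(cls["t06"]), "low")
  expect_setequal(ab$otu_id, paste0("t0", 1:7))
  # moving one read across a threshold flips exactly one label
  tab$counts["March|F", "t04"] <- 11
  ab2 <- abundance_classes(tab, "March")
  changed <- setdiff(paste(ab2$otu_id, ab2$class), paste(ab$otu_id, ab$class))
  expect_equal(changed, "t04 abundant")
})

test_that("connectivity weights are shared-OTU counts with the right bounds", {
  net <- otu_connectivity(toy_diversity_table(), node_keys = c("station", "season"))
  w <- function(a, b) {
    e <- net$edges
    e$shared_otus[(e$node_a == a & e$node_b == b) | (e$node_a == b & e$node_b == a)]
  }
  expect_equal(w("March|O1", "March|F"), 2L)
  expect_equal(w("March|F", "March|C1"), 1L)
  expect_equal(w("March|C1", "July|C1"), 0L) # disjoint: edge kept at 0
  expect_equal(w("July|O1", "July|F"), 2L)
  rich <- setNames(net$nodes$richness, net$nodes$node)
  expect_equal(unname(rich[c("March|O1", "July|C1")]), c(4L, 2L))
  expect_true(all(net$edges$shared_otus <=
                  pmin(rich[net$edges$node_a], rich[net$edges$node_b])))
  expect_equal(nrow(net$edges), choose(6, 2))
  expect_equal(sum(net$edges$intra_season), 6L)
})

test_that("connectivity is invariant to replicate structure and sample order", {
  sim <- generate_metacommunity(synthetic_config(n_otus = 40, J = 300, seed = 6))
  net1 <- otu_connectivity(sim$otu)
  merged <- merge_samples(sim$otu, c("replicate", "size_fraction"))
  net2 <- otu_connectivity(merged)
  key <- function(n) {
    e <- n$edges
    setNames(e$shared_otus, paste(pmin(e$node_a, e$node_b), pmax(e$node_a, e$node_b)))
  }
  k1 <- key(net1)
  expect_equal(k1, key(net2)[names(k1)])
  shuf <- subset_otu_table(sim$otu, samples = rev(rownames(sim$otu$counts)))
  k3 <- key(otu_connectivity(shuf))
  expect_equal(k1, k3[names(k1)])
})

test_that("curated control is the identity at equal richness and flags constants", {
  tab <- toy_diversity_table()
  # equalize seasonal richness at 4 OTUs so no subsampling happens
  tab$counts[1:3, c("t05", "t06", "t07")] <- 0
  tab$counts[4:6, c("t08", "t09")] <- 0
  cc <- curated_connectivity_control(tab, node_keys = c("station", "season"),
                                     seed = 1)
  expect_equal(cc$rho, 1)
  # constant-weight degenerate case
  cnt <- rbind("March|O1" = c(1, 1), "July|O1" = c(1, 1))
  colnames(cnt) <- c("o1", "o2")
  meta <- data.frame(sample_id = rownames(cnt), season = c("March", "July"),
                     station = "O1")
  flat <- otu_table(cnt, meta)
  expect_warning(cc2 <- curated_connectivity_control(flat,
    node_keys = c("station", "season"), seed = 1), "undefined")
  expect_true(is.na(cc2$rho))
})
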