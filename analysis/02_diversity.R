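#!/usr/bin/env Rscript
# Stage 2 — phytoplankton diversity partitioning.
#
# Restricts the table to obligate phototrophs, then computes per-sample and
# station x season richness, an analytic rarefaction curve and Chao1 for the
# deepest sample, shared vs station-specific occurrence categories, and the
# abundant / low-abundance / rare classes at the 0.1% / 0.01% read-share
# thresholds. Tables go to results/diversity/.

library(frontassembly)

dir.create("results/diversity", recursive = TRUE, showWarnings = FALSE)
otu <- read_otu_table("results/inputs/otu.tsv",
                      "results/inputs/otu_metadata.csv",
                      taxref_path = "results/inputs/otu_taxref.csv")
traits <- read_traits("results/inputs/traits.csv")
photo <- filter_phototrophs(otu, traits)

rich <- richness(photo)
write_results(rich, "results/diversity/richness_samples.tsv")
merged <- merge_samples(photo, c("replicate", "depth", "size_fraction"))
rich15 <- richness(merged)
write_results(rich15, "results/diversity/richness_station_season.tsv")
cat("total richness per station x season (merged to",
    nrow(rich15), "samples):\n")
print(stats::xtabs(richness ~ season + station, rich15))

deepest <- which.max(rowSums(photo$counts))
cts <- photo$counts[deepest, ]
depths <- unique(round(seq(1, sum(cts), length.out = 30)))
write_results(data.frame(depth = depths,
                         expected_richness = rarefaction_curve(cts, depths)),
              "results/diversity/rarefaction_deepest.tsv")
cat("deepest sample:", rownames(photo$counts)[deepest], "-",
    sum(cts), "reads,", sum(cts > 0), "OTUs, Chao1 =",
    round(chao1(cts), 1), "\n")

occ <- occurrence_categories(merged)
write_results(occ, "results/diversity/occurrence_categories.tsv")
cat("occurrence labels by season:\n")
print(table(occ$season, sub(":.*", "", occ$label)))

classes <- do.call(rbind, lapply(unique(photo$metadata$season), function(se)
  abundance_classes(photo, se)))
write_results(classes, "results/diversity/abundance_classes.tsv")
cat("abundance classes by season:\n")
print(table(classes$season, classes$class))
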