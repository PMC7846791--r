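#!/usr/bin/env Rscript
# Stage 6 — trait space, functional richness and ecological strategies.
#
# Gower distance over the 12 morphological/trophic traits of the annotated
# references, PCoA embedding (4 axes), convex-hull functional richness per
# station x season normalized to the global pool, complete-linkage clustering
# into 9 ecological strategies, and the per-station strategy distribution in
# the last sampled season.

library(frontassembly)

dir.create("results/functional", recursive = TRUE, showWarnings = FALSE)
otu <- read_otu_table("results/inputs/otu.tsv",
                      "results/inputs/otu_metadata.csv",
                      taxref_path = "results/inputs/otu_taxref.csv")
traits <- read_traits("results/inputs/traits.csv")
photo <- filter_phototrophs(otu, traits)

trait_cols <- setdiff(names(traits), c("taxref", "obligate_phototroph"))
annotated <- rownames(traits)[rowSums(!is.na(traits[, trait_cols])) >= 6]
ids <- intersect(names(photo$taxref)[photo$taxref %in% annotated],
                 colnames(photo$counts))
cat(sprintf("trait-annotated OTUs: %d of %d (%.0f%%)\n", length(ids),
            n_otus(photo), 100 * length(ids) / n_otus(photo)))

gower <- gower_distance(traits[unique(photo$taxref[ids]), ])
space <- pcoa(gower, m = 4)
write_results(as.data.frame(space$coordinates), "results/functional/pcoa.tsv")
cat(sprintf("PCoA: first 4 axes carry %.0f%% of positive inertia\n",
            100 * sum(space$eigenvalues[1:4]) / sum(space$eigenvalues)))

merged <- merge_samples(photo, c("replicate", "depth", "size_fraction"))
pres <- presence_matrix(merged)
sets <- lapply(rownames(pres), function(r)
  unique(photo$taxref[intersect(colnames(pres)[pres[r, ]], ids)]))
names(sets) <- rownames(pres)
fric <- functional_richness(space, sets[lengths(sets) > space$m])
write_results(data.frame(sample = names(fric), fric = fric),
              "results/functional/fric.tsv")
cat("functional richness by station x season:\n")
print(round(sort(fric, decreasing = TRUE), 3))
cat(sprintf("taxonomic vs functional richness Spearman rho = %.2f\n",
            spearman(rowSums(pres)[names(fric)], fric)))

assign <- strategy_clustering(gower, k = 9)
write_results(data.frame(taxref = names(assign), strategy = assign),
              "results/functional/strategies.tsv")
seasons <- unique(merged$metadata$season)
last <- seasons[length(seasons)]
rows <- merged$metadata$sample_id[merged$metadata$season == last]
st_pres <- lapply(rows, function(r) colnames(pres)[pres[r, ]])
names(st_pres) <- merged$metadata$station[match(rows, merged$metadata$sample_id)]
distr <- strategy_distribution(assign, st_pres, taxref = photo$taxref)
write_results(cbind(strategy = rownames(distr), distr),
              "results/functional/strategy_distribution.tsv")
cat("richness within the 9 ecological strategies across stations,", last, ":\n")
print(distr)
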