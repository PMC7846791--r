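# End-to-end orchestration: simulate -> phototroph filter -> diversity ->
# assembly -> environmental PERMANOVA -> functional diversity, from one config,
# writing every intermediate artifact plus a manifest under the output
# directory. Reruns with the same config are byte-identical.

#' Build a pipeline run configuration
#'
#' @param scenario generator scenario (`"custom"` uses the full sampling-design
#'   defaults of [synthetic_config()]; preset names use [scenario_config()]),
#'   or `NULL` to read inputs from `input_dir`
#' @param input_dir directory with `otu.tsv`, `otu_metadata.csv`,
#'   `otu_taxref.csv`, `tree.nwk`, `traits.csv`, `environment.csv` (as written
#'   by [write_metacommunity()]); ignored when `scenario` is given
#' @param outdir output directory
#' @param seed global seed; per-stage substreams are derived from it
#' @param n_otus,J generator sizes (custom scenario)
#' @param n_null null replicates for betaNTI and Raup-Crick
#' @param n_perm permutations for PERMANOVA and Mantel
#' @param theta_hi,theta_lo abundance-class thresholds (read-share fractions)
#' @param m_axes retained PCoA axes
#' @param k_clusters number of ecological strategies
#' @param permanova_terms environment columns for the turnover PERMANOVA (the
#'   second model drops `temperature`)
#' @return a `run_config` list
#' @export
run_config <- function(scenario = "custom", input_dir = NULL,
                       outdir = "results/run", seed = 1L,
                       n_otus = 192, J = 2000, n_null = 499, n_perm = 999,
                       theta_hi = 0.001, theta_lo = 0.0001,
                       m_axes = 4, k_clusters = 9,
                       permanova_terms = c("temperature", "NOx", "ammonium",
                                           "silicate", "PAR")) {
  if (is.null(scenario) && is.null(input_dir))
    stop("either a scenario or an input_dir is required")
  if (!is.null(input_dir)) {
    need <- file.path(input_dir, c("otu.tsv", "otu_metadata.csv", "tree.nwk",
                                   "traits.csv", "environment.csv"))
    missing <- need[!file.exists(need)]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys are [run_config()] arguments
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

stage_log <- function(manifest, stage, t0, params) {
  message(sprintf("[%s] done in %.1fs (%s)", stage,
                  as.numeric(Sys.time()) - t0,
                  paste(names(params), unlist(params), sep = "=", collapse = ", ")))
  manifest$stages[[stage]] <- list(
    elapsed_s = round(as.numeric(Sys.time()) - t0, 2), params = params)
  manifest
}

#' Run the full pipeline
#'
#' Executes the six stages in dependency order and writes all artifacts under
#' `config$outdir`: simulated inputs, filtered table, richness/rarefaction/
#' occurrence/abundance tables, the connectivity network and its curated
#' control, per-fraction pairwise assembly results and process summaries, the
#' two environmental PERMANOVA tables, the functional-richness and strategy
#' tables, and `manifest.json` (parameters, per-stage seeds, timings, input
#' checksums). A failed stage aborts with its name; later stages do not run.
#'
#' @param config a [run_config()]
#' @return invisibly, the output directory
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  stage_seed <- stats::setNames(sample.int(2147483646L, 6L),
                                c("simulate", "diversity", "assembly",
                                  "stats", "functional", "spare"))
  manifest <- list(package_version = as.character(utils::packageVersion("frontassembly")),
                   seed = config$seed, stage_seeds = as.list(stage_seed),
                   config = config[setdiff(names(config), "outdir")],
                   stages = list())

  ## stage 1: simulate (or load)
  t0 <- as.numeric(Sys.time())
  if (!is.null(config$scenario)) {
    cfg <- if (config$scenario == "custom")
      synthetic_config(n_otus = config$n_otus, J = config$J,
                       seed = stage_seed[["simulate"]])
    else scenario_config(config$scenario, seed = stage_seed[["simulate"]])
    sim <- generate_metacommunity(cfg)
    write_metacommunity(sim, file.path(outdir, "inputs"))
  } else {
    dirp <- config$input_dir
    sim <- list(
      otu = read_otu_table(file.path(dirp, "otu.tsv"),
                           file.path(dirp, "otu_metadata.csv"),
                           taxref_path = file.path(dirp, "otu_taxref.csv")),
      tree = read_tree(file.path(dirp, "tree.nwk")),
      traits = read_traits(file.path(dirp, "traits.csv")),
      env = read_env(file.path(dirp, "environment.csv")))
  }
  manifest$input_checksums <- as.list(tools::md5sum(
    list.files(file.path(outdir, "inputs"), full.names = TRUE)))
  manifest <- stage_log(manifest, "simulate", t0,
                        list(scenario = config$scenario %||% "files",
                             n_samples = n_samples(sim$otu),
                             n_otus = n_otus(sim$otu)))

  ## stage 2: phototroph filter
  t0 <- as.numeric(Sys.time())
  photo <- filter_phototrophs(sim$otu, sim$traits)
  manifest <- stage_log(manifest, "filter", t0,
                        list(otus_kept = n_otus(photo)))

  ## stage 3: diversity
  t0 <- as.numeric(Sys.time())
  set.seed(stage_seed[["diversity"]])
  rich <- richness(photo)
  write_results(rich, file.path(outdir, "richness_samples.tsv"))
  merged <- merge_samples(photo, intersect(c("replicate", "depth", "size_fraction"),
                                           names(photo$metadata)))
  write_results(richness(merged), file.path(outdir, "richness_station_season.tsv"))
  deepest <- which.max(rowSums(photo$counts))
  cts <- photo$counts[deepest, ]
  depths <- unique(round(seq(1, sum(cts), length.out = 25)))
  write_results(data.frame(sample_id = rownames(photo$counts)[deepest],
                           depth = depths,
                           expected_richness = rarefaction_curve(cts, depths)),
                file.path(outdir, "rarefaction_deepest_sample.tsv"))
  chao <- vapply(rownames(photo$counts),
                 function(s) chao1(photo$counts[s, ]), numeric(1))
  write_results(data.frame(sample_id = names(chao), chao1 = chao),
                file.path(outdir, "chao1_samples.tsv"))
  occ <- occurrence_categories(merged)
  write_results(occ, file.path(outdir, "occurrence_categories.tsv"))
  ab <- do.call(rbind, lapply(unique(photo$metadata$season), function(se)
    abundance_classes(photo, se, config$theta_hi, config$theta_lo)))
  write_results(ab, file.path(outdir, "abundance_classes.tsv"))
  net <- otu_connectivity(photo)
  write_results(net, file.path(outdir, "connectivity_edges.tsv"))
  ctrl <- if (length(unique(photo$metadata$season)) >= 2) {
    cc <- curated_connectivity_control(photo, seed = stage_seed[["diversity"]])
    write_results(list(rho = cc$rho, seed = cc$seed,
                       curated_k = as.list(cc$curated_k)),
                  file.path(outdir, "curated_control.json"))
    cc
  }
  manifest <- stage_log(manifest, "diversity", t0,
                        list(rho_curated = if (!is.null(ctrl)) round(ctrl$rho, 4) else NA))

  ## stage 4: assembly (per size fraction when fractions exist)
  t0 <- as.numeric(Sys.time())
  fractions <- if ("size_fraction" %in% names(photo$metadata))
    unique(photo$metadata$size_fraction) else NA
  assembly <- list()
  for (fr in fractions) {
    sub <- if (is.na(fr[1])) photo else
      subset_otu_table(photo, samples = photo$metadata$size_fraction == fr,
                       drop_empty_otus = TRUE)
    res <- assembly_analysis(sub, sim$tree, n_null = config$n_null,
                             seed = stage_seed[["assembly"]])
    tag <- if (is.na(fr[1])) "all" else fr
    write_results(res, file.path(outdir, paste0("assembly_pairs_", tag, ".tsv")))
    summ <- process_summary(res, sub$metadata)
    write_results(list(counts = as.list(summ$counts), n_pairs = summ$n_pairs),
                  file.path(outdir, paste0("assembly_summary_", tag, ".json")))
    write_results(summ$edges, file.path(outdir, paste0("assembly_edges_", tag, ".tsv")))
    assembly[[tag]] <- list(pairs = res, summary = summ, table = sub)
  }
  # phylogeny-trait signal check backing the framework's niche-proxy assumption
  annotated <- rownames(sim$traits)[rowSums(!is.na(
    sim$traits[, intersect(TRAIT_COLUMNS, names(sim$traits))])) >= 6]
  sig_ids <- intersect(annotated, sim$tree$tip.label)
  signal <- phylo_trait_signal(
    cophenetic_distances(sim$tree)[sig_ids, sig_ids],
    gower_distance(sim$traits[sig_ids, ]),
    n_perm = config$n_perm, seed = stage_seed[["assembly"]])
  write_results(signal, file.path(outdir, "phylo_trait_signal.json"))
  manifest <- stage_log(manifest, "assembly", t0,
                        list(n_null = config$n_null,
                             mantel_r = round(signal$r, 4)))

  ## stage 5: environmental PERMANOVA + Kruskal-Wallis
  t0 <- as.numeric(Sys.time())
  perm_rows <- list()
  for (tag in names(assembly)) {
    a <- assembly[[tag]]
    D <- bmntd_matrix_from_pairs(a$pairs)
    env <- sim$env[rownames(D), , drop = FALSE]
    for (model in list(config$permanova_terms,
                       setdiff(config$permanova_terms, "temperature"))) {
      ok <- model[vapply(model, function(v)
        length(unique(env[[v]])) > 1, logical(1))]
      fit <- permanova(D, env, ok, n_perm = config$n_perm,
                       seed = stage_seed[["stats"]])
      fit$fraction <- tag
      fit$model <- paste(model, collapse = "+")
      perm_rows[[length(perm_rows) + 1]] <- fit
    }
  }
  perm_tab <- do.call(rbind, perm_rows)
  write_results(perm_tab, file.path(outdir, "permanova_bmntd_env.tsv"))
  kw <- kruskal_wallis(rich$richness, rich$season)
  write_results(data.frame(test = "richness_by_season", h = kw$h, p = kw$p),
                file.path(outdir, "kruskal_richness.tsv"))
  manifest <- stage_log(manifest, "stats", t0,
                        list(n_perm = config$n_perm))

  ## stage 6: functional diversity
  t0 <- as.numeric(Sys.time())
  trait_otus <- names(photo$taxref)[photo$taxref %in% annotated]
  gower <- gower_distance(sim$traits[unique(photo$taxref[trait_otus]), ])
  space <- pcoa(gower, m = config$m_axes)
  write_results(as.data.frame(space$coordinates),
                file.path(outdir, "pcoa_coordinates.tsv"))
  pres_merged <- presence_matrix(merged)
  sets <- lapply(rownames(pres_merged), function(s) {
    otus <- colnames(pres_merged)[pres_merged[s, ]]
    unique(photo$taxref[intersect(otus, trait_otus)])
  })
  names(sets) <- rownames(pres_merged)
  usable <- lengths(sets) > config$m_axes
  fric <- functional_richness(space, sets[usable])
  write_results(data.frame(sample = names(fric), fric = fric),
                file.path(outdir, "functional_richness.tsv"))
  assign <- strategy_clustering(gower, k = config$k_clusters)
  write_results(data.frame(taxref = names(assign), strategy = assign),
                file.path(outdir, "strategy_assignment.tsv"))
  seasons <- unique(photo$metadata$season)
  last_season <- seasons[length(seasons)]
  md <- merged$metadata
  st_rows <- md$sample_id[md$season == last_season]
  st_pres <- lapply(st_rows, function(s)
    colnames(pres_merged)[pres_merged[s, ]])
  names(st_pres) <- md$station[match(st_rows, md$sample_id)]
  distr <- strategy_distribution(assign, st_pres, taxref = photo$taxref)
  distr <- cbind(strategy = rownames(distr), distr)
  write_results(distr, file.path(outdir, "strategy_distribution.tsv"))
  manifest <- stage_log(manifest, "functional", t0,
                        list(m_axes = config$m_axes, k = config$k_clusters,
                             season = last_season))

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rebuild the betaMNTD sample x sample matrix from pairwise results
#' @param pairs data.frame from [assembly_analysis()]
#' @export
bmntd_matrix_from_pairs <- function(pairs) {
  ids <- sort(unique(c(pairs$sample_a, pairs$sample_b)))
  D <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  D[cbind(pairs$sample_a, pairs$sample_b)] <- pairs$bmntd_obs
  D[cbind(pairs$sample_b, pairs$sample_a)] <- pairs$bmntd_obs
  D
}
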