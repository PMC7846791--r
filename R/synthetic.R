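# Synthetic metacommunity generator. Emulates the statistical structure the
# downstream analyses assume: a 3-season x 5-station x (<=2 depth) x 3-fraction
# x 3-replicate sampling design, a phylogeny with heritable (phylogenetically
# autocorrelated) niche optima and traits, environmental gradients with a
# frontal station receiving a pulsed nutrient input (modelled as a locally
# enlarged community and relaxed selection), and community assembly under
# tunable selection (Gaussian niche filtering on a temperature-like axis),
# dispersal (station pools mixed with the regional pool at rate m) and drift
# (multinomial sampling of J individuals).

CAT_VOCAB <- list(
  "Cell Cover"       = c("naked", "organic", "silica", "calcium"),
  "Cell Shape"       = c("spherical", "elongated", "complex"),
  "Cell Symmetry"    = c("radial", "bilateral", "asymmetric"),
  "Cell Polarity"    = c("isopolar", "anisopolar"),
  "Ingestion method" = c("none", "osmotrophy", "phagotrophy"),
  "Symbiosis type"   = c("none", "photosymbiont", "parasite"),
  "Presence of Spicule" = c("no", "yes"),
  "Coloniality"      = c("no", "yes"),
  "Motility"         = c("no", "yes"),
  "Resting Stage"    = c("no", "yes")
)

#' Configuration of a synthetic metacommunity
#'
#' Defaults describe the full sampling design analog (3 seasons, 5 stations
#' ocean->coast with a frontal station F, surface everywhere plus a deep
#' chlorophyll maximum offshore in stratified seasons, 3 size fractions, 3
#' replicates, J = 2000 individuals per community). Scenario presets override
#' the process parameters (see [scenario_config()]).
#'
#' @param n_otus number of OTUs (tips) in the regional pool
#' @param seasons,stations sampled seasons and stations (subsets of the
#'   controlled vocabularies)
#' @param dcm_stations,dcm_seasons station/season combinations where a DCM is
#'   sampled in addition to the surface
#' @param size_fractions 3 (micro/nano/pico splitting) or 1 (whole community)
#' @param replicates replicate communities per water mass
#' @param J community size: individuals drawn per replicate community
#' @param sigma_sel niche-filter width on the temperature axis (degrees C);
#'   `Inf` disables selection (neutral)
#' @param niche_power exponent of the niche kernel
#'   exp(-0.5 (|env - mu| / sigma_sel)^p): 2 = Gaussian, larger values give a
#'   flat-topped tolerance envelope with sharp limits
#' @param selection_floor residual establishment weight for taxa outside the
#'   niche window (mass-effect immigration floor added to the Gaussian filter)
#' @param drift_sdlog sd of a per-replicate log-normal jitter on OTU weights
#'   (compositional drift between replicate communities)
#' @param niche_heritability phylogenetic heritability of niche optima in
#'   \[0,1\]: 1 = pure Brownian motion on the tree, 0 = independent noise
#' @param niche_burst early-burst concentration of niche evolution: rate of
#'   exponential decay of the Brownian rate with node depth (0 = plain
#'   Brownian motion; larger values make niches clade-conserved)
#' @param niche_center,niche_sd location and spread (degrees C) of niche optima
#' @param trait_signal phylogenetic heritability of trait liabilities in \[0,1\]
#' @param phototroph_fraction fraction of taxonomic references flagged as
#'   obligate phototrophs
#' @param trait_missing_rate per-cell probability of a missing trait value
#' @param trait_unannotated_frac fraction of taxonomic references with no
#'   trait annotation at all (literature gaps; they feed the "unannotated"
#'   class downstream)
#' @param migration_rate m in \[0,1\]: weight of the regional pool when mixing
#'   with station-local pools (1 = well mixed)
#' @param station_isolation give each station its own local species pool
#' @param local_pool_frac fraction of the regional pool present in each local
#'   pool
#' @param pool_mode "global", "station_local", or "source_sink" (all stations
#'   but the last share one source pool; the last holds the complementary pool)
#' @param source_pool_frac fraction of OTUs in the source pool under
#'   "source_sink"
#' @param abundance_sdlog sd of regional log-abundances (log-normal rank
#'   abundance)
#' @param seasonal_amplitude scaling of the seasonal warming component of
#'   temperature (0 = no seasonal contrast)
#' @param spatial_amplitude scaling of the cross-shore temperature contrast in
#'   stratified seasons (0 = spatially uniform)
#' @param front_station station receiving the frontal nutrient pulse
#' @param front_pulse apply the pulse (enlarged J, relaxed selection) at the
#'   front in stratified seasons
#' @param front_J_factor,front_sigma_factor pulse strength: multipliers on J
#'   and on sigma_sel at the front
#' @param env_anchor couple the sampled environment to the evolved niches:
#'   `"none"` uses the temperature profile as is; `"regional"` shifts niche
#'   optima so the regional mean temperature coincides with the niche mean of
#'   the tightest mid-size clade (a region selecting a lineage adapted to it);
#'   `"stations"` sets each station's stratified-season temperature to the
#'   niche mean of a distinct tight clade (water masses each dominated by an
#'   adapted lineage)
#' @param scenario free-form label; use [scenario_config()] for presets
#' @param seed root seed; all sub-draws come from named substreams
#' @return a `synthetic_config` list
#' @export
synthetic_config <- function(n_otus = 256,
                             seasons = SEASON_LEVELS,
                             stations = STATION_LEVELS,
                             dcm_stations = c("O1", "O2"),
                             dcm_seasons = c("July", "September"),
                             size_fractions = 3,
                             replicates = 3,
                             J = 2000,
                             sigma_sel = 1.2,
                             niche_power = 2,
                             selection_floor = 0.01,
                             drift_sdlog = 1,
                             niche_heritability = 1,
                             niche_burst = 0,
                             niche_center = 12,
                             niche_sd = 2,
                             trait_signal = 0.7,
                             phototroph_fraction = 1.0,
                             trait_missing_rate = 0.05,
                             trait_unannotated_frac = 0.15,
                             migration_rate = 1,
                             station_isolation = FALSE,
                             local_pool_frac = 0.5,
                             pool_mode = if (station_isolation) "station_local" else "global",
                             source_pool_frac = 0.6,
                             abundance_sdlog = 2.5,
                             seasonal_amplitude = 1,
                             spatial_amplitude = 1,
                             front_station = "F",
                             front_pulse = TRUE,
                             front_J_factor = 1.5,
                             front_sigma_factor = 2,
                             env_anchor = c("none", "regional", "stations"),
                             scenario = "custom",
                             seed = 1L) {
  if (n_otus < 4) stop("n_otus must be >= 4")
  if (J <= 0) stop("J must be positive")
  if (migration_rate < 0 || migration_rate > 1) stop("migration_rate must be in [0,1]")
  if (!is.infinite(sigma_sel) && sigma_sel <= 0) stop("sigma_sel must be > 0 or Inf")
  if (niche_heritability < 0 || niche_heritability > 1)
    stop("niche_heritability must be in [0,1]")
  if (trait_signal < 0 || trait_signal > 1) stop("trait_signal must be in [0,1]")
  if (!size_fractions %in% c(1L, 3L)) stop("size_fractions must be 1 or 3")
  env_anchor <- match.arg(env_anchor)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "synthetic_config")
}

#' Scenario presets for assembly-process recovery
#'
#' Each preset fixes the process parameters so that one assembly process
#' dominates the generated metacommunity, at the scale used throughout for
#' null-model work: 128 OTUs, one season, 5 stations x 4 replicates (20
#' samples), no size-fraction splitting, J = 2000.
#'
#' * `homogeneous_selection` - identical environment everywhere, strong niche
#'   filtering on phylogenetically heritable optima.
#' * `variable_selection` - strong filtering with large temperature contrasts
#'   between stations.
#' * `dispersal_limitation` - neutral, isolated station pools, weak migration.
#' * `homogenizing_dispersal` - neutral mass effects: all but one station are
#'   homogenized from a single source pool; the last station holds the
#'   complementary regional pool.
#' * `drift` - neutral, well mixed.
#'
#' @param scenario preset name
#' @param seed root seed
#' @param n_otus,replicates,J sizes (defaults are the standard calibration
#'   sizes)
#' @return a `synthetic_config`
#' @export
scenario_config <- function(scenario = c("homogeneous_selection", "variable_selection",
                                         "dispersal_limitation", "homogenizing_dispersal",
                                         "drift"),
                            seed = 1L, n_otus = 128, replicates = 4, J = 2000) {
  scenario <- match.arg(scenario)
  base <- list(n_otus = n_otus, seasons = "July", stations = STATION_LEVELS,
               dcm_stations = character(), size_fractions = 1L,
               replicates = replicates, J = J, front_pulse = FALSE,
               trait_missing_rate = 0, trait_unannotated_frac = 0,
               scenario = scenario, seed = seed)
  tweak <- switch(scenario,
    homogeneous_selection = list(sigma_sel = 0.4, niche_power = 4,
                                 seasonal_amplitude = 0, spatial_amplitude = 0,
                                 selection_floor = 0, drift_sdlog = 2.5,
                                 niche_burst = 5, env_anchor = "regional",
                                 niche_heritability = 1, migration_rate = 1),
    variable_selection    = list(sigma_sel = 0.4, niche_power = 4,
                                 seasonal_amplitude = 0, spatial_amplitude = 8,
                                 selection_floor = 0, drift_sdlog = 1.5,
                                 niche_burst = 5, env_anchor = "stations",
                                 niche_heritability = 1, migration_rate = 1,
                                 niche_sd = 4),
    dispersal_limitation  = list(sigma_sel = Inf, station_isolation = TRUE,
                                 migration_rate = 0.05, local_pool_frac = 0.35,
                                 drift_sdlog = 0),
    homogenizing_dispersal = list(sigma_sel = Inf, pool_mode = "source_sink",
                                  source_pool_frac = 0.6, migration_rate = 0,
                                  abundance_sdlog = 1.5, drift_sdlog = 0),
    drift                 = list(sigma_sel = Inf, migration_rate = 1,
                                 drift_sdlog = 0)
  )
  do.call(synthetic_config, c(base, tweak))
}

sub_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(2147483646L, 7L),
                  c("tree", "traits", "niche", "abundances", "pools",
                    "communities", "missing"))
}

#' Simulate a pure-birth (Yule) phylogeny of OTUs
#'
#' @param n_otus number of tips (>= 2)
#' @param seed integer seed; output is deterministic given the seed
#' @return rooted ultrametric `phylo` with tips `OTU0001`, `OTU0002`, ...
#' @export
generate_tree <- function(n_otus, seed = 1L) {
  if (n_otus < 2) stop("n_otus must be >= 2")
  set.seed(seed)
  tree <- ape::rphylo(n_otus, birth = 1, death = 0)
  tree$tip.label <- sprintf("OTU%04d", seq_len(n_otus))
  tree
}

# Phylogenetically heritable standard-normal liability: sqrt(s) * standardized
# Brownian tip values + sqrt(1-s) * iid noise. s = 1 gives pure Brownian
# structure, s = 0 independent noise; tip variance is ~1 either way.
# burst > 0 concentrates the Brownian variance on deep branches (early-burst /
# ACDC evolution: rate decays as exp(-burst * depth)), producing clade-level
# conservatism of the resulting value.
heritable_liability <- function(tree, s, burst = 0) {
  n <- length(tree$tip.label)
  bm <- if (burst > 0) {
    nd <- ape::node.depth.edgelength(tree)
    val <- numeric(n + tree$Nnode)
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      rate <- exp(-burst * (nd[par] + nd[ch]) / 2)
      val[ch] <- val[par] +
        stats::rnorm(1, 0, sqrt(tree$edge.length[e] * rate))
    }
    stats::setNames(val[seq_len(n)], tree$tip.label)
  } else ape::rTraitCont(tree, model = "BM", sigma = 1)
  z <- if (stats::sd(bm) > 0) (bm - mean(bm)) / stats::sd(bm) else rep(0, n)
  sqrt(s) * z + sqrt(1 - s) * stats::rnorm(n)
}

#' Simulate a trait table on a phylogeny
#'
#' Numeric sizes come from exponentiated heritable liabilities (SizeMax =
#' SizeMin x (1 + |liability|)); categorical and binary traits threshold
#' independent heritable liabilities into their controlled vocabularies.
#' Phylogenetic signal in every trait increases with `trait_signal`.
#'
#' @param tree a `phylo` with >= 4 tips
#' @param config a [synthetic_config()] (fields `trait_signal`,
#'   `phototroph_fraction`, `trait_missing_rate` are used)
#' @param seed integer seed
#' @return trait data.frame (taxref = tip label, 1:1) as from [read_traits()]
#' @export
generate_traits <- function(tree, config = synthetic_config(), seed = 1L) {
  if (length(tree$tip.label) < 4) stop("tree must have >= 4 tips")
  s <- config$trait_signal
  if (s < 0) stop("trait_signal must be non-negative")
  set.seed(seed)
  tips <- tree$tip.label
  n <- length(tips)

  l_size <- heritable_liability(tree, s)
  l_span <- heritable_liability(tree, s)
  size_min <- exp(1.0 + 1.3 * l_size)          # micrometres, median ~ 2.7
  size_max <- size_min * (1 + abs(l_span))

  tr <- data.frame(taxref = tips, SizeMin = round(size_min, 3),
                   SizeMax = round(size_max, 3),
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (trait in names(CAT_VOCAB)) {
    vocab <- CAT_VOCAB[[trait]]
    k <- length(vocab)
    lia <- heritable_liability(tree, s)
    cuts <- stats::qnorm(seq_len(k - 1) / k)
    tr[[trait]] <- vocab[findInterval(lia, cuts) + 1L]
  }

  n_photo <- round(config$phototroph_fraction * n)
  photo <- rep(FALSE, n)
  photo[sample.int(n, n_photo)] <- TRUE
  tr$obligate_phototroph <- photo

  if (config$trait_missing_rate > 0) {
    for (trait in c("SizeMin", "SizeMax", names(CAT_VOCAB))) {
      miss <- stats::runif(n) < config$trait_missing_rate
      tr[[trait]][miss] <- NA
    }
    # keep the SizeMin <= SizeMax invariant interpretable: drop pairs together
    half <- is.na(tr$SizeMin) != is.na(tr$SizeMax)
    tr$SizeMin[half] <- NA
    tr$SizeMax[half] <- NA
  }
  if (config$trait_unannotated_frac > 0) {
    gap <- stats::runif(n) < config$trait_unannotated_frac
    tr[gap, c("SizeMin", "SizeMax", names(CAT_VOCAB))] <- NA
  }
  rownames(tr) <- tips
  tr
}

# Per (season, station, depth) environment: seasonal warming, a cross-shore
# gradient in stratified seasons, nutrient drawdown over the year with a
# remineralization rise in ammonium, and a nutrient pulse at the frontal
# station in stratified seasons. The two amplitudes scale the temperature
# contrasts; 0 collapses every water mass onto the same environment.
build_env_profile <- function(config) {
  grid <- expand.grid(season = config$seasons, station = config$stations,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    season <- grid$season[i]; station <- grid$station[i]
    depths <- "surface"
    if (station %in% config$dcm_stations && season %in% config$dcm_seasons)
      depths <- c("surface", "DCM")
    season_warm <- c(March = 0, July = 4, September = 5)[[season]]
    # ocean (O1) warm/stratified in summer, coast (C2) mixed/cooler, front cool
    cross <- c(O1 = 1, O2 = 0.5, F = -1, C1 = 0, C2 = -0.5)[station]
    if (is.na(cross)) cross <- 0
    stratified <- season != "March"
    temp <- 11 + config$seasonal_amplitude * season_warm +
      config$spatial_amplitude * (if (stratified) cross else 0)
    at_front <- station == config$front_station && stratified && config$front_pulse
    nox <- max(0.1, (8 - 2.5 * season_warm / 2) * (if (at_front) 1 else 0.4 + 0.6 * !stratified)) +
      if (at_front) 1.5 else 0
    amm <- 0.1 + 0.15 * season_warm
    sil <- max(0.3, 4 - 1.2 * season_warm / 2 + if (at_front) 0.8 else 0)
    par <- c(March = 60, July = 220, September = 150)[[season]]
    data.frame(season = season, station = station, depth = depths,
               temperature = temp - ifelse(depths == "DCM", 1.5, 0),
               NOx = round(nox, 3), ammonium = round(amm, 3),
               silicate = round(sil, 3),
               PAR = round(par * ifelse(depths == "DCM", 0.15, 1), 1),
               front_pulse = at_front, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Tight clades: internal nodes with lo..hi tip descendants, ranked by the
# standard deviation of their tips' niche optima; greedily selected disjoint.
tight_clades <- function(tree, mu, lo = 15, hi = 60, k = 1) {
  n <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  cand <- list()
  for (i in seq_along(parts)) {
    tips <- tree$tip.label[parts[[i]]]
    if (length(tips) < lo || length(tips) > hi) next
    cand[[length(cand) + 1]] <- list(tips = tips, sd = stats::sd(mu[tips]))
  }
  if (!length(cand)) return(list())
  cand <- cand[order(vapply(cand, `[[`, numeric(1), "sd"))]
  picked <- list(); used <- character()
  for (cl in cand) {
    if (length(picked) >= k) break
    if (length(intersect(cl$tips, used))) next
    picked[[length(picked) + 1]] <- cl$tips
    used <- c(used, cl$tips)
  }
  picked
}

# station -> normalized sampling-weight vector over OTUs
station_pools <- function(config, regional_ab, n) {
  norm <- function(w) w / sum(w)
  global <- norm(regional_ab)
  m <- config$migration_rate
  pools <- list()
  if (config$pool_mode == "global") {
    for (st in config$stations) pools[[st]] <- global
  } else if (config$pool_mode == "station_local") {
    for (st in config$stations) {
      mask <- stats::runif(n) < config$local_pool_frac
      if (!any(mask)) mask[sample.int(n, 1)] <- TRUE
      local <- exp(stats::rnorm(n, 0, config$abundance_sdlog)) * mask
      pools[[st]] <- m * global + (1 - m) * norm(local)
    }
  } else if (config$pool_mode == "source_sink") {
    src_mask <- rep(FALSE, n)
    src_mask[sample.int(n, round(config$source_pool_frac * n))] <- TRUE
    src <- norm(regional_ab * src_mask)
    sink <- norm(regional_ab * !src_mask)
    last <- config$stations[length(config$stations)]
    for (st in config$stations)
      pools[[st]] <- if (st == last) m * global + (1 - m) * sink
                     else m * global + (1 - m) * src
  } else stop("unknown pool_mode: ", config$pool_mode)
  pools
}

# dominant size fraction per OTU from geometric mean cell size, with 10%
# leakage into each other fraction (cross-fraction contamination)
fraction_affinity <- function(traits) {
  gm <- sqrt(pmax(traits$SizeMin, 0.1) * pmax(traits$SizeMax, 0.1))
  gm[is.na(gm)] <- 3
  dominant <- ifelse(gm > 10, "micro", ifelse(gm > 3, "nano", "pico"))
  aff <- matrix(0.1, nrow = nrow(traits), ncol = 3,
                dimnames = list(traits$taxref, FRACTION_LEVELS))
  aff[cbind(seq_len(nrow(aff)), match(dominant, FRACTION_LEVELS))] <- 0.8
  aff
}

#' Generate a full synthetic metacommunity
#'
#' For each sampled water mass (season x station x depth) and replicate, a
#' community of J individuals is drawn multinomially with per-OTU weights
#' proportional to regional abundance x Gaussian niche filter
#' exp(-(env - mu_i)^2 / (2 sigma_sel^2)) x station dispersal weight; the
#' multinomial draw is the drift component. Counts are then split across size
#' fractions by a per-OTU fraction affinity (when `size_fractions == 3`).
#'
#' @param config a [synthetic_config()] or [scenario_config()]
#' @return list with elements `otu` ([otu_table()]), `tree` (`phylo`),
#'   `traits` (trait data.frame), `env` (sample x environment data.frame) and
#'   `truth` (niche optima, regional log-abundances, per-water-mass
#'   environment, scenario, substream seeds)
#' @export
generate_metacommunity <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  seeds <- sub_seeds(config$seed)
  n <- config$n_otus

  tree <- generate_tree(n, seeds[["tree"]])
  traits <- generate_traits(tree, config, seeds[["traits"]])

  set.seed(seeds[["niche"]])
  mu <- config$niche_center +
    config$niche_sd * heritable_liability(tree, config$niche_heritability,
                                          config$niche_burst)
  names(mu) <- tree$tip.label

  set.seed(seeds[["abundances"]])
  log_ab <- stats::rnorm(n, 0, config$abundance_sdlog)
  regional_ab <- exp(log_ab)

  set.seed(seeds[["pools"]])
  pools <- station_pools(config, regional_ab, n)

  env_profile <- build_env_profile(config)
  if (config$env_anchor == "regional") {
    clade <- tight_clades(tree, mu, lo = 25, hi = 60, k = 1)
    if (length(clade))
      mu <- mu + (mean(env_profile$temperature) - mean(mu[clade[[1]]]))
  } else if (config$env_anchor == "stations") {
    clades <- tight_clades(tree, mu, lo = 15, hi = 60,
                           k = length(config$stations))
    anchors <- vapply(clades, function(tips) mean(mu[tips]), numeric(1))
    for (i in seq_along(anchors)) {
      st <- config$stations[i]
      rows <- env_profile$station == st & env_profile$season != "March"
      env_profile$temperature[rows] <- anchors[i] -
        ifelse(env_profile$depth[rows] == "DCM", 1.5, 0)
    }
  }
  aff <- if (config$size_fractions == 3L) fraction_affinity(traits)

  set.seed(seeds[["communities"]])
  rows <- list(); meta <- list(); env_rows <- list()
  for (i in seq_len(nrow(env_profile))) {
    ep <- env_profile[i, ]
    sigma <- config$sigma_sel
    J <- config$J
    if (ep$front_pulse) {
      sigma <- sigma * config$front_sigma_factor
      J <- round(J * config$front_J_factor)
    }
    sel <- if (is.infinite(sigma)) rep(1, n)
           else exp(-0.5 * (abs(ep$temperature - mu) / sigma)^config$niche_power) +
                config$selection_floor
    w_base <- pools[[ep$station]] * sel
    if (sum(w_base) <= 0 || !any(w_base > 0))
      stop("all-zero sampling weights at ", ep$season, "/", ep$station,
           "; use broader niches (larger sigma_sel or niche_sd)")
    for (rep_i in seq_len(config$replicates)) {
      w <- if (config$drift_sdlog > 0)
        w_base * exp(stats::rnorm(n, 0, config$drift_sdlog)) else w_base
      comm <- as.vector(stats::rmultinom(1, J, w))
      if (config$size_fractions == 3L) {
        frac_counts <- matrix(0L, nrow = 3, ncol = n,
                              dimnames = list(FRACTION_LEVELS, tree$tip.label))
        present <- which(comm > 0)
        for (k in present)
          frac_counts[, k] <- stats::rmultinom(1, comm[k], aff[k, ])
        for (fr in FRACTION_LEVELS) {
          sid <- paste(ep$season, ep$station, ep$depth, fr, rep_i, sep = "|")
          rows[[sid]] <- frac_counts[fr, ]
          meta[[sid]] <- data.frame(sample_id = sid, season = ep$season,
                                    station = ep$station, depth = ep$depth,
                                    size_fraction = fr, replicate = rep_i,
                                    stringsAsFactors = FALSE)
          env_rows[[sid]] <- data.frame(sample_id = sid, ep[, c("temperature",
            "NOx", "ammonium", "silicate", "PAR")], stringsAsFactors = FALSE)
        }
      } else {
        sid <- paste(ep$season, ep$station, ep$depth, rep_i, sep = "|")
        rows[[sid]] <- stats::setNames(comm, tree$tip.label)
        meta[[sid]] <- data.frame(sample_id = sid, season = ep$season,
                                  station = ep$station, depth = ep$depth,
                                  replicate = rep_i, stringsAsFactors = FALSE)
        env_rows[[sid]] <- data.frame(sample_id = sid, ep[, c("temperature",
          "NOx", "ammonium", "silicate", "PAR")], stringsAsFactors = FALSE)
      }
    }
  }

  counts <- do.call(rbind, rows)
  rownames(counts) <- names(rows)
  metadata <- do.call(rbind, meta)
  env <- do.call(rbind, env_rows)
  rownames(env) <- env$sample_id
  taxref <- stats::setNames(tree$tip.label, tree$tip.label) # 1:1 in synthesis
  otu <- suppressWarnings(otu_table(counts, metadata, taxref = taxref))

  truth <- list(niche_optimum = mu, regional_log_abundance =
                  stats::setNames(log_ab, tree$tip.label),
                env_profile = env_profile, scenario = config$scenario,
                sub_seeds = as.list(seeds))
  list(otu = otu, tree = tree, traits = traits, env = env, truth = truth)
}

#' Write all synthetic inputs to a directory
#'
#' Emits the four analysis inputs (counts TSV + metadata CSV + taxref CSV,
#' Newick tree, trait CSV, environment CSV) plus a `truth.json`.
#'
#' @param sim result of [generate_metacommunity()]
#' @param dir output directory (created if needed)
#' @export
write_metacommunity <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_otu_table(sim$otu, file.path(dir, "otu"))
  write_tree(sim$tree, file.path(dir, "tree.nwk"))
  write_traits(sim$traits, file.path(dir, "traits.csv"))
  utils::write.csv(sim$env, file.path(dir, "environment.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- sim$truth
  truth$env_profile <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
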