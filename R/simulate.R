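#' Simulate an ultrametric host phylogeny
#'
#' Pure-birth (Yule) tree with unit speciation rate, rescaled to unit root
#' height. The tree shape is not an inferential target anywhere in the
#' pipeline; a Yule process is simply the simplest generator of rooted,
#' binary, ultrametric, labeled trees.
#'
#' @param n_species Number of tips (>= 2).
#' @param seed RNG seed; for a fixed seed the returned newick string is
#'   identical across calls.
#' @param labels Optional tip labels (default `sp1..spN`).
#' @return An [ape::phylo] object: rooted, binary, ultrametric, with
#'   strictly positive branch lengths.
#' @export
simulate_host_tree <- function(n_species, seed = NULL, labels = NULL) {
  if (!is.numeric(n_species) || n_species < 2)
    stop("n_species must be at least 2")
  n_species <- as.integer(n_species)
  tr <- with_seed_(seed, ape::rphylo(n_species, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  if (is.null(labels)) labels <- paste0("sp", seq_len(n_species))
  if (length(labels) != n_species) stop("labels must have length n_species")
  tr$tip.label <- labels
  tr
}

# Non-ultrametric constraint is not needed for the bacterial tree either;
# reuse the Yule generator with OTU ids as tips.
simulate_bacterial_tree <- function(otu_ids, seed = NULL) {
  simulate_host_tree(length(otu_ids), seed = seed, labels = otu_ids)
}

#' Configuration for the synthetic community generator
#'
#' Defaults emulate a two-locality, multi-species amphibian skin survey:
#' 8 host units (5 at locality `CA`, 3 at locality `QB`; a widespread
#' generalist is represented by one population per locality, and locality
#' `QB` hosts a rock/cave specialist), four microhabitats, 9-15 frogs per
#' host unit (default 12), 40 environmental samples and a small battery of
#' extraction/field controls.
#'
#' @param n_species Number of host units (tips of the host tree).
#' @param localities Locality labels.
#' @param species_to_locality Named character vector: host unit -> locality.
#'   Every host unit must map to exactly one locality (species are nested
#'   in locality).
#' @param species_to_microhabitat Named character vector: host unit ->
#'   microhabitat (nested likewise).
#' @param samples_per_group Skin samples per host unit.
#' @param n_environment_samples Environmental samples (split evenly across
#'   localities).
#' @param n_control_samples Negative-control samples.
#' @param n_otus Size of the skin OTU pool.
#' @param environment_extra_otus OTUs found only in the environment pool,
#'   so environmental richness exceeds skin richness.
#' @param depth_mean Mean sequencing depth per skin/environment sample.
#'   Depths are drawn negative-binomially (`depth_dispersion`), so a
#'   realistic fraction of samples falls below a 3,000-read rarefaction
#'   depth and exercises sample dropping.
#' @param depth_dispersion Negative-binomial size parameter for depths.
#' @param locality_effect Fraction in `[0, 1]` of skin OTUs whose presence
#'   is restricted to a home locality (composition effect).
#' @param species_effect Log-scale standard deviation of per-species OTU
#'   abundance multipliers (structure effect).
#' @param phylosymbiosis_strength Scale of Brownian-motion species offsets
#'   evolved on the host tree and applied (on log abundance) to the
#'   phylo-responsive OTU subset.
#' @param phylo_fraction Fraction of skin OTUs that respond to the host
#'   phylogeny.
#' @param phylo_presence_threshold Optional numeric; when set, an OTU in
#'   the phylo-responsive subset is additionally *absent* from species
#'   whose Brownian offset falls below this threshold, injecting the
#'   phylogenetic signal into composition as well as structure.
#' @param n_contaminants Number of injected contaminant OTUs.
#' @param contaminant_boost Enrichment of contaminants in controls relative
#'   to the mean control base weight (> 1).
#' @param contaminant_leak Fraction of each contaminant's control relative
#'   abundance leaked into skin samples.
#' @param control_base_scale Total weight of the near-empty control base
#'   relative to a mean-weight OTU (small: controls are dominated by
#'   contaminants).
#' @param control_depth_mean Mean depth of control samples.
#' @param seed RNG seed; the whole dataset is deterministic given the seed.
#' @return A `simulation_config` list, validated.
#' @export
simulation_config <- function(
    n_species = 8,
    localities = c("CA", "QB"),
    species_to_locality = NULL,
    species_to_microhabitat = NULL,
    samples_per_group = 12,
    n_environment_samples = 40,
    n_control_samples = 8,
    n_otus = 300,
    environment_extra_otus = 120,
    depth_mean = 5000,
    depth_dispersion = 5,
    locality_effect = 0,
    species_effect = 0,
    phylosymbiosis_strength = 0,
    phylo_fraction = 0.5,
    phylo_presence_threshold = NULL,
    n_contaminants = 10,
    contaminant_boost = 50,
    contaminant_leak = 0.1,
    control_base_scale = 0.02,
    control_depth_mean = 100,
    seed = 1) {
  species <- paste0("sp", seq_len(n_species))
  if (is.null(species_to_locality)) {
    # default layout: first ceil(5/8 * n) units at the first locality
    n_first <- max(1L, min(n_species - 1L, ceiling(n_species * 5 / 8)))
    species_to_locality <- stats::setNames(
      rep(localities, times = c(n_first, n_species - n_first))[
        seq_len(n_species)],
      species)
  }
  if (is.null(species_to_microhabitat)) {
    mh <- c("herbaceous", "arboreal", "arboreal", "terrestrial", "arboreal",
            "arboreal", "terrestrial", "cave")
    species_to_microhabitat <- stats::setNames(
      rep_len(mh, n_species), species)
  }
  cfg <- list(n_species = as.integer(n_species), localities = localities,
              species = species,
              species_to_locality = species_to_locality,
              species_to_microhabitat = species_to_microhabitat,
              samples_per_group = as.integer(samples_per_group),
              n_environment_samples = as.integer(n_environment_samples),
              n_control_samples = as.integer(n_control_samples),
              n_otus = as.integer(n_otus),
              environment_extra_otus = as.integer(environment_extra_otus),
              depth_mean = depth_mean,
              depth_dispersion = depth_dispersion,
              locality_effect = locality_effect,
              species_effect = species_effect,
              phylosymbiosis_strength = phylosymbiosis_strength,
              phylo_fraction = phylo_fraction,
              phylo_presence_threshold = phylo_presence_threshold,
              n_contaminants = as.integer(n_contaminants),
              contaminant_boost = contaminant_boost,
              contaminant_leak = contaminant_leak,
              control_base_scale = control_base_scale,
              control_depth_mean = control_depth_mean,
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  if (cfg$samples_per_group < 1) stop("samples_per_group must be >= 1")
  if (cfg$n_otus < 2) stop("n_otus must be >= 2")
  if (cfg$depth_mean < 10) stop("depth_mean must be positive (>= 10)")
  if (cfg$locality_effect < 0 || cfg$locality_effect > 1)
    stop("locality_effect must be in [0, 1]")
  if (cfg$species_effect < 0) stop("species_effect must be >= 0")
  if (cfg$phylosymbiosis_strength < 0)
    stop("phylosymbiosis_strength must be >= 0")
  if (cfg$n_contaminants > 0 && cfg$contaminant_boost <= 1)
    stop("contaminant_boost must exceed 1")
  miss <- setdiff(cfg$species, names(cfg$species_to_locality))
  if (length(miss))
    stop("species without a locality: ", paste(miss, collapse = ", "))
  if (!all(cfg$species_to_locality[cfg$species] %in% cfg$localities))
    stop("species mapped to unknown locality")
  miss <- setdiff(cfg$species, names(cfg$species_to_microhabitat))
  if (length(miss))
    stop("species without a microhabitat: ", paste(miss, collapse = ", "))
  invisible(cfg)
}

#' Simulate a full survey-shaped dataset
#'
#' Generates a host tree, a bacterial tree over all OTUs, sample metadata
#' and an OTU count table for skin, environment and control samples.
#' Per-species expected skin relative abundances are built as a log-normal
#' per-OTU baseline, multiplied by per-species log-normal offsets
#' (`species_effect`), by the exponential of Brownian-motion offsets on the
#' host tree (`phylosymbiosis_strength`, phylo-responsive subset only),
#' and masked so that a fraction `locality_effect` of OTUs is present only
#' in its home locality. Counts are multinomial at negative-binomial
#' depths. Environment samples draw from an enlarged OTU pool; controls
#' draw from a near-empty base plus boosted contaminants, which leak into
#' skin at `contaminant_leak` of their control relative abundance.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_dataset`: list with `otu_table`, `metadata`
#'   (data frame), `bacterial_tree`, `host_tree` and a `truth` record of
#'   injected contaminant ids, locality-restricted ids (with home
#'   locality), species multipliers and phylo-responsive OTU ids.
#' @export
simulate_community <- function(config) {
  cfg <- validate_config(config)
  with_seed_(cfg$seed, simulate_community_impl(cfg))
}

simulate_community_impl <- function(cfg) {
  n_pool <- cfg$n_otus + cfg$environment_extra_otus + cfg$n_contaminants
  otu_ids <- sprintf("otu%04d", seq_len(n_pool))
  skin_ids <- otu_ids[seq_len(cfg$n_otus)]
  env_ids <- otu_ids[seq_len(cfg$n_otus + cfg$environment_extra_otus)]
  contam_ids <- if (cfg$n_contaminants > 0)
    otu_ids[(n_pool - cfg$n_contaminants + 1):n_pool] else character()

  host_tree <- simulate_host_tree(cfg$n_species, labels = cfg$species)
  bacterial_tree <- simulate_bacterial_tree(otu_ids)

  # taxonomy strings: phylum-level bins plus a couple of organelle decoys
  phyla <- c("Proteobacteria", "Bacteroidetes", "Actinobacteria",
             "Acidobacteria", "Firmicutes", "Verrucomicrobia")
  taxonomy <- stats::setNames(
    paste0("k__Bacteria;p__", sample(phyla, n_pool, replace = TRUE)),
    otu_ids)
  if (cfg$environment_extra_otus >= 2) {
    decoys <- setdiff(env_ids, skin_ids)[1:2]
    taxonomy[decoys] <- c(
      "k__Bacteria;p__Cyanobacteria;c__Chloroplast",
      "k__Bacteria;p__Proteobacteria;f__mitochondria")
  }

  baseline <- stats::setNames(stats::rlnorm(cfg$n_otus, 0, 1), skin_ids)

  # locality-restricted OTUs (presence effect)
  n_restricted <- floor(cfg$locality_effect * cfg$n_otus)
  restricted <- sample(skin_ids, n_restricted)
  home <- stats::setNames(
    sample(cfg$localities, n_restricted, replace = TRUE), restricted)

  # per-species abundance multipliers (structure effect)
  spec_mult <- matrix(1, cfg$n_species, cfg$n_otus,
                      dimnames = list(cfg$species, skin_ids))
  if (cfg$species_effect > 0)
    spec_mult[] <- exp(matrix(
      stats::rnorm(cfg$n_species * cfg$n_otus, 0, cfg$species_effect),
      cfg$n_species))

  # Brownian offsets on the host tree for the phylo-responsive subset
  n_phylo <- floor(cfg$phylo_fraction * cfg$n_otus)
  phylo_ids <- sample(skin_ids, n_phylo)
  phylo_offsets <- matrix(0, cfg$n_species, n_phylo,
                          dimnames = list(cfg$species, phylo_ids))
  if (cfg$phylosymbiosis_strength > 0 && n_phylo > 0) {
    vcv <- ape::vcv(host_tree)[cfg$species, cfg$species]
    L <- chol(vcv + diag(1e-10, cfg$n_species))
    z <- matrix(stats::rnorm(cfg$n_species * n_phylo), cfg$n_species)
    phylo_offsets[] <- cfg$phylosymbiosis_strength * (t(L) %*% z)
  }

  # expected skin relative abundances per species
  weights <- matrix(rep(baseline, each = cfg$n_species), cfg$n_species,
                    dimnames = list(cfg$species, skin_ids))
  weights <- weights * spec_mult
  if (n_phylo > 0)
    weights[, phylo_ids] <- weights[, phylo_ids] * exp(phylo_offsets)
  if (!is.null(cfg$phylo_presence_threshold) && n_phylo > 0)
    weights[, phylo_ids][phylo_offsets < cfg$phylo_presence_threshold] <- 0
  if (n_restricted > 0) {
    sp_loc <- cfg$species_to_locality[cfg$species]
    for (o in restricted)
      weights[sp_loc != home[[o]], o] <- 0
  }
  w_species <- weights / rowSums(weights)

  # control composition: near-empty base + boosted contaminants
  base_w <- baseline / sum(baseline) * cfg$control_base_scale
  contam_w <- rep(cfg$contaminant_boost * mean(base_w), cfg$n_contaminants)
  w_control <- c(base_w, stats::setNames(contam_w, contam_ids))
  w_control <- w_control / sum(w_control)
  contam_rel <- w_control[contam_ids]

  # leak contaminants into every skin sample's expected composition
  if (cfg$n_contaminants > 0) {
    leak <- cfg$contaminant_leak * contam_rel
    w_species <- cbind(w_species * (1 - sum(leak)),
                       matrix(rep(leak, each = cfg$n_species),
                              cfg$n_species,
                              dimnames = list(cfg$species, contam_ids)))
  }

  # environment composition: independent log-normal over the larger pool
  env_base <- stats::setNames(stats::rlnorm(length(env_ids), 0, 1), env_ids)
  w_env <- env_base / sum(env_base)

  # skin/environment depths are overdispersed (gamma-mixed Poisson) so a
  # realistic fraction of samples falls below the rarefaction depth;
  # control depths are Poisson: blank depth is set by the sequencer, not
  # by biomass variation
  draw_sample <- function(w, depth_mean, poisson = FALSE) {
    depth <- if (poisson) stats::rpois(1, depth_mean)
    else stats::rnbinom(1, size = cfg$depth_dispersion, mu = depth_mean)
    stats::rmultinom(1, depth, w)[, 1]
  }

  rows <- list(); meta <- list()
  for (sp in cfg$species) {
    for (k in seq_len(cfg$samples_per_group)) {
      id <- sprintf("%s_skin%02d", sp, k)
      cts <- draw_sample(w_species[sp, ], cfg$depth_mean)
      rows[[id]] <- cts
      meta[[id]] <- data.frame(
        sample_id = id, sample_type = "skin", species = sp,
        locality = unname(cfg$species_to_locality[[sp]]),
        microhabitat = unname(cfg$species_to_microhabitat[[sp]]),
        stringsAsFactors = FALSE)
    }
  }
  env_loc <- rep_len(cfg$localities, cfg$n_environment_samples)
  for (k in seq_len(cfg$n_environment_samples)) {
    id <- sprintf("env%02d", k)
    cts <- stats::setNames(numeric(n_pool), otu_ids)
    cts[env_ids] <- draw_sample(w_env, cfg$depth_mean)
    rows[[id]] <- cts
    meta[[id]] <- data.frame(
      sample_id = id, sample_type = "environment", species = "environment",
      locality = env_loc[k], microhabitat = "environment",
      stringsAsFactors = FALSE)
  }
  for (k in seq_len(cfg$n_control_samples)) {
    id <- sprintf("control%02d", k)
    cts <- stats::setNames(numeric(n_pool), otu_ids)
    cts[names(w_control)] <- draw_sample(w_control, cfg$control_depth_mean,
                                         poisson = TRUE)
    rows[[id]] <- cts
    meta[[id]] <- data.frame(
      sample_id = id, sample_type = "control", species = "control",
      locality = "control", microhabitat = "control",
      stringsAsFactors = FALSE)
  }

  counts <- matrix(0L, length(rows), n_pool,
                   dimnames = list(names(rows), otu_ids))
  for (id in names(rows)) {
    v <- rows[[id]]
    counts[id, names(v)] <- as.integer(v)
  }
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  metadata$group <- ifelse(metadata$sample_type == "skin",
                           paste(metadata$species, metadata$locality,
                                 sep = "_"),
                           metadata$sample_type)

  structure(list(
    otu_table = otu_table(counts, taxonomy),
    metadata = metadata,
    bacterial_tree = bacterial_tree,
    host_tree = host_tree,
    truth = list(contaminant_ids = contam_ids,
                 locality_restricted = home,
                 species_multipliers = spec_mult,
                 phylo_otu_ids = phylo_ids,
                 phylo_offsets = phylo_offsets),
    config = cfg),
    class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset\n")
  print(x$otu_table)
  cat(sprintf("  %d host units, %d localities, %d contaminant OTUs\n",
              x$config$n_species, length(x$config$localities),
              length(x$truth$contaminant_ids)))
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes the OTU table (OTUs x samples TSV with taxonomy column), sample
#' metadata TSV, both trees as newick, and the ground-truth record as JSON.
#' Output is deterministic for a fixed simulation seed.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(dataset$otu_table, file.path(dir, "otu_table.tsv"))
  write_metadata(dataset$metadata, file.path(dir, "metadata.tsv"))
  ape::write.tree(dataset$bacterial_tree,
                  file.path(dir, "bacterial_tree.nwk"))
  ape::write.tree(dataset$host_tree, file.path(dir, "host_tree.nwk"))
  truth <- dataset$truth
  truth$species_multipliers <- NULL
  truth$phylo_offsets <- NULL
  truth$locality_restricted <- as.list(truth$locality_restricted)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
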