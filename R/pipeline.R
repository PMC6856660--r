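#' Pipeline configuration
#'
#' Collects every tunable of the full survey-shaped analysis. Inputs come
#' either from a [simulation_config()] (`simulate = TRUE`) or from files
#' on disk (OTU table TSV, metadata TSV, two newick trees).
#'
#' @param simulate Whether to generate the dataset with
#'   [simulate_community()].
#' @param sim A [simulation_config()] (used when `simulate = TRUE`).
#' @param table_path,metadata_path,bacterial_tree_path,host_tree_path
#'   Input file paths (used when `simulate = FALSE`).
#' @param rarefaction_depth Reads per sample after rarefaction
#'   (default 3,000).
#' @param permutations Permutations for all permutation tests
#'   (default 999).
#' @param random_trees Random topologies for the congruence null
#'   (default 1,000).
#' @param jackknife_reps Jackknife replicates for dendrogram supports
#'   (default 100).
#' @param lda_threshold Discriminant-feature cutoff on the log10 LDA
#'   scale (default 3.0, strict).
#' @param core_prevalence Core-microbiota prevalence threshold
#'   (default 0.90, inclusive).
#' @param alpha Significance level (default 0.05).
#' @param seed Master seed; every stochastic stage derives its own seed
#'   from it.
#' @param output_dir Directory for per-stage artifacts (`NULL` = do not
#'   write).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = TRUE, sim = simulation_config(),
                            table_path = NULL, metadata_path = NULL,
                            bacterial_tree_path = NULL,
                            host_tree_path = NULL,
                            rarefaction_depth = 3000, permutations = 999,
                            random_trees = 1000, jackknife_reps = 100,
                            lda_threshold = 3.0, core_prevalence = 0.90,
                            alpha = 0.05, seed = 1, output_dir = NULL) {
  if (rarefaction_depth < 1) stop("rarefaction_depth must be positive")
  if (permutations < 1) stop("permutations must be positive")
  if (core_prevalence <= 0 || core_prevalence > 1)
    stop("core_prevalence must be in (0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!simulate) {
    for (p in c(table_path, metadata_path, bacterial_tree_path,
                host_tree_path))
      if (is.null(p) || !file.exists(p)) stop("missing input file: ", p)
  }
  structure(list(simulate = simulate, sim = sim, table_path = table_path,
                 metadata_path = metadata_path,
                 bacterial_tree_path = bacterial_tree_path,
                 host_tree_path = host_tree_path,
                 rarefaction_depth = as.integer(rarefaction_depth),
                 permutations = as.integer(permutations),
                 random_trees = as.integer(random_trees),
                 jackknife_reps = as.integer(jackknife_reps),
                 lda_threshold = lda_threshold,
                 core_prevalence = core_prevalence, alpha = alpha,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stage order: load-or-simulate, preprocessing (organelle, rare-OTU and
#' contaminant filters, rarefaction), alpha diversity (PD, Shannon) with
#' the skin-versus-environment contrast, beta diversity (both UniFrac
#' metrics), permutation inference per factor plus the sequential
#' locality + microhabitat + species model and pairwise batteries,
#' discriminant taxa by locality, core microbiota per host group, and
#' the host-phylogeny congruence battery. Deterministic for a fixed
#' config seed; when `output_dir` is set, writes per-stage artifacts and
#' a `manifest.json` echoing all parameters.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list with all stage results.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  if (!inherits(cfg, "pipeline_config")) stop("config must be a pipeline_config")
  if (cfg$simulate) {
    sim <- cfg$sim
    sim$seed <- cfg$seed
    ds <- simulate_community(sim)
    table <- ds$otu_table; metadata <- ds$metadata
    btree <- ds$bacterial_tree; htree <- ds$host_tree
    truth <- ds$truth
  } else {
    table <- read_otu_table(cfg$table_path)
    metadata <- read_metadata(cfg$metadata_path)
    btree <- ape::read.tree(cfg$bacterial_tree_path)
    htree <- ape::read.tree(cfg$host_tree_path)
    truth <- NULL
  }
  need <- c("sample_id", "sample_type", "species", "locality",
            "microhabitat")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    stop("metadata lacks columns: ", paste(miss, collapse = ", "))

  pre <- preprocess(table, metadata, depth = cfg$rarefaction_depth,
                    alpha = cfg$alpha, seed = cfg$seed + 1L)
  tab <- pre$table
  md <- align_metadata(metadata, sample_ids(tab))
  skin_ids <- md$sample_id[md$sample_type == "skin"]
  env_ids <- md$sample_id[md$sample_type == "environment"]

  alpha_div <- alpha_diversity(tab, btree)
  pd_by_type <- split(alpha_div$pd,
                      md$sample_type[match(alpha_div$sample_id,
                                           md$sample_id)])
  skin_env_t <- if (length(env_ids) >= 2 && length(skin_ids) >= 2)
    nonparametric_t_test(pd_by_type$environment, pd_by_type$skin,
                         n_perm = cfg$permutations, seed = cfg$seed + 2L)
  else NULL

  skin_tab <- subset_otu_table(tab, samples = skin_ids)
  skin_md <- align_metadata(md, skin_ids)
  dms <- list(
    unweighted_unifrac = beta_diversity_matrix(tab, btree,
                                               "unweighted_unifrac"),
    weighted_unifrac = beta_diversity_matrix(tab, btree,
                                             "weighted_unifrac"))
  skin_dms <- lapply(dms, function(d) d[skin_ids, skin_ids])

  skin_env_anosim <- lapply(dms, function(d)
    anosim(d, md$sample_type, n_perm = cfg$permutations,
           seed = cfg$seed + 3L))

  factors <- c("locality", "microhabitat", "species")
  per_factor <- lapply(skin_dms, function(d) {
    res <- list()
    for (f in factors) {
      res[[f]] <- list(
        anosim = anosim(d, skin_md[[f]], n_perm = cfg$permutations,
                        seed = cfg$seed + 4L),
        permanova = permanova(d, skin_md[[f]], n_perm = cfg$permutations,
                              seed = cfg$seed + 5L))
    }
    res
  })
  sequential <- lapply(skin_dms, function(d)
    permanova_sequential(d, skin_md, factor_order = factors,
                         n_perm = cfg$permutations, seed = cfg$seed + 6L))
  pairwise <- lapply(skin_dms, function(d)
    pairwise_groups(d, skin_md$species, test = "anosim",
                    n_perm = cfg$permutations, seed = cfg$seed + 7L))

  kw_pd <- kruskal_wallis(split(alpha_div$pd[match(skin_ids,
                                                   alpha_div$sample_id)],
                                skin_md$species))

  lefse <- lda_effect_size(skin_tab, skin_md, "locality",
                           alpha = cfg$alpha,
                           threshold = cfg$lda_threshold,
                           seed = cfg$seed + 8L)
  core <- core_otus(skin_tab, skin_md, "species",
                    prevalence = cfg$core_prevalence)

  congruence <- congruence_pipeline(
    skin_tab, skin_md, btree, htree, group_factor = "species",
    n_random = cfg$random_trees, n_jackknife = cfg$jackknife_reps,
    n_perm = cfg$permutations, seed = cfg$seed + 9L)

  report <- structure(list(
    config = cfg, preprocessing = pre$log,
    contaminants = pre$contaminants, truth = truth,
    table = tab, metadata = md, alpha_diversity = alpha_div,
    skin_env_t = skin_env_t, skin_env_anosim = skin_env_anosim,
    beta = skin_dms, per_factor = per_factor, sequential = sequential,
    pairwise = pairwise, kw_pd_species = kw_pd, discriminant = lefse,
    core = core, congruence = congruence),
    class = "pipeline_report")
  if (!is.null(cfg$output_dir)) write_pipeline_report(report, cfg$output_dir)
  report
}

write_pipeline_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- report$config
  write_otu_table(report$table, file.path(dir, "otu_table_rarefied.tsv"))
  write_metadata(report$metadata, file.path(dir, "metadata.tsv"))
  write_tsv_(report$alpha_diversity, file.path(dir, "alpha_diversity.tsv"))
  write_contaminant_report(report$contaminants,
                           file.path(dir, "contaminants.tsv"))
  for (m in names(report$beta))
    write_dist_matrix(report$beta[[m]],
                      file.path(dir, paste0("beta_", m, ".tsv")))
  for (m in names(report$sequential))
    write_tsv_(report$sequential[[m]],
               file.path(dir, paste0("permanova_sequential_", m, ".tsv")))
  for (m in names(report$pairwise))
    write_tsv_(report$pairwise[[m]],
               file.path(dir, paste0("pairwise_anosim_", m, ".tsv")))
  if (nrow(report$discriminant) > 0)
    write_tsv_(report$discriminant,
               file.path(dir, "discriminant_taxa.tsv"))
  for (m in names(report$congruence$metrics)) {
    r <- report$congruence$metrics[[m]]
    ape::write.tree(r$dendrogram,
                    file.path(dir, paste0("dendrogram_", m, ".nwk")))
  }
  manifest <- list(
    package = "phylosym",
    version = as.character(utils::packageVersion("phylosym")),
    seed = cfg$seed,
    parameters = cfg[c("rarefaction_depth", "permutations",
                       "random_trees", "jackknife_reps", "lda_threshold",
                       "core_prevalence", "alpha")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  cat(sprintf("  rarefied table: %d samples x %d OTUs\n",
              n_samples(x$table), n_otus(x$table)))
  cat(sprintf("  contaminants flagged: %d\n",
              length(x$contaminants$flagged)))
  for (m in names(x$per_factor)) {
    cat(sprintf("  %s ANOSIM R: ", m))
    cat(paste(sprintf("%s = %.3f",
                      names(x$per_factor[[m]]),
                      vapply(x$per_factor[[m]],
                             function(r) r$anosim$statistic, numeric(1))),
              collapse = ", "), "\n")
  }
  invisible(x)
}
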