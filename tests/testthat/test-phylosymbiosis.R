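test_that("group collapse averages per-sample relative abundances", {
  counts <- rbind(s1 = c(10L, 10L, 0L), s2 = c(0L, 5L, 5L),
                  s3 = c(8L, 0L, 0L))
  colnames(counts) <- c("a", "b", "c")
  md <- data.frame(sample_id = rownames(counts),
                   grp = c("g1", "g1", "g2"))
  coll <- collapse_by_group(otu_table(counts), md, "grp")
  expect_equal(unname(rowSums(coll)), c(1, 1), tolerance = 1e-12)
  expect_equal(coll["g2", ], c(a = 1, b = 0, c = 0))
  expect_equal(coll["g1", "a"], mean(c(0.5, 0)))
})

test_that("UPGMA reproduces hand agglomeration and ultrametric inputs", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(dm)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  coph <- patristic_distances(tr)
  expect_equal(coph["A", "B"], 2)
  expect_equal(coph["A", "C"], 4)

  # cophenetic reconstruction for ultrametric input
  ref <- random_fixture_tree(paste0("t", 1:7), seed = 3)
  dmu <- ape::cophenetic.phylo(ref)
  rec <- patristic_distances(upgma(dmu))
  expect_equal(rec[rownames(dmu), colnames(dmu)], dmu, tolerance = 1e-8)

  two <- matrix(c(0, 3, 3, 0), 2, 2,
                dimnames = list(c("x", "y"), c("x", "y")))
  cherry <- upgma(two)
  expect_equal(unname(cherry$edge.length), c(1.5, 1.5))
})

test_that("normalized Robinson-Foulds counts nontrivial clade symmetric difference", {
  t1 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  expect_equal(robinson_foulds_normalized(t1, t1), 0)
  t2 <- ape::read.tree(text = "((A,C),(B,(D,E)));")  # shares only {D,E}
  expect_equal(robinson_foulds_normalized(t1, t2), 4 / 6, tolerance = 1e-12)
  a4 <- ape::read.tree(text = "((A,B),(C,D));")
  b4 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(robinson_foulds_normalized(a4, b4), 1)
  bad <- ape::read.tree(text = "((A,B),(C,Z));")
  expect_error(robinson_foulds_normalized(a4, bad), "differ")
})

test_that("random tree null matches exhaustive topology enumeration", {
  ref5 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  all5 <- enumerate_topologies(c("A", "B", "C", "D", "E"))
  expect_equal(length(all5), 105)
  nrf_all <- vapply(all5, function(tr)
    robinson_foulds_normalized(
      ape::read.tree(text = nested_to_newick(tr)), ref5), numeric(1))
  # p for a perfectly congruent dendrogram: exact share of nRF == 0
  p_exact <- mean(nrf_all <= 1e-12)
  res <- random_tree_null(ref5, 0, n_random = 1000, seed = 4)
  se <- sqrt(p_exact * (1 - p_exact) / 1000)
  expect_lt(abs(res$p_value - p_exact), 3 * se + 2 / 1000)
  expect_equal(random_tree_null(ref5, 1, n_random = 200, seed = 5)$p_value,
               1.0)

  # 4 tips: the sampled null distribution matches the exact one (chi-sq GOF)
  ref4 <- ape::read.tree(text = "((A,B),(C,D));")
  all4 <- enumerate_topologies(c("A", "B", "C", "D"))
  expect_equal(length(all4), 15)
  nrf4 <- vapply(all4, function(tr)
    robinson_foulds_normalized(
      ape::read.tree(text = nested_to_newick(tr)), ref4), numeric(1))
  exact_tab <- table(round(nrf4, 10)) / length(nrf4)
  draw <- random_tree_null(ref4, 0, n_random = 1000, seed = 6)
  obs_tab <- table(factor(round(draw$null_distribution, 10),
                          levels = names(exact_tab)))
  gof <- suppressWarnings(
    stats::chisq.test(obs_tab, p = as.numeric(exact_tab)))
  expect_gt(gof$p.value, 0.01)
})

test_that("patristic distances sum branch lengths along paths", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  d <- patristic_distances(tr)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  expect_true(all(diag(d) == 0))
  # ultrametric: distance = 2 x MRCA height
  u <- random_fixture_tree(paste0("t", 1:5), seed = 9)
  du <- patristic_distances(u)
  h <- max(ape::node.depth.edgelength(u))
  expect_lte(max(du), 2 * h + 1e-8)
})

test_that("partial Mantel matches the closed form and detects identity", {
  set.seed(14)
  pts <- matrix(rnorm(10), 5, 2)
  rownames(pts) <- paste0("g", 1:5)
  a <- as.matrix(stats::dist(pts))
  b <- as.matrix(stats::dist(pts + matrix(rnorm(10, sd = 0.3), 5, 2)))
  cc <- as.matrix(stats::dist(matrix(rnorm(10), 5, 2)))
  dimnames(b) <- dimnames(cc) <- dimnames(a)
  lt <- lower.tri(a)
  rab <- cor(a[lt], b[lt]); rac <- cor(a[lt], cc[lt])
  rbc <- cor(b[lt], cc[lt])
  expected <- (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
  res <- partial_mantel(a, b, cc, n_perm = 99, seed = 2)
  expect_lt(abs(res$statistic - expected), 1e-12)
  ref <- vegan::mantel.partial(stats::as.dist(a), stats::as.dist(b),
                               stats::as.dist(cc), permutations = 19)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)

  # A == B with independent control: r_partial ~ 1 and small p
  same <- partial_mantel(a, a + 0, cc, n_perm = 199, seed = 3)
  expect_gt(same$statistic, 0.999)
  expect_lt(same$p_value, 0.05)
})

test_that("PVR MANOVA separates a locality-clustered dendrogram", {
  # two deep clades = two localities; microhabitat scattered across them
  txt <- "(((g1:1,g2:1):1,(g3:0.5,g4:0.5):1.5):3,((g5:1,g6:1):1,(g7:0.5,g8:0.5):1.5):3);"
  dendro <- ape::read.tree(text = txt)
  gf <- data.frame(
    locality = rep(c("CA", "QB"), each = 4),
    microhabitat = rep(c("arb", "ter"), times = 4),
    row.names = paste0("g", 1:8))
  res <- pvr_manova(dendro, gf)
  expect_lt(res$p_value[res$factor == "locality"], 0.05)
  expect_gt(res$p_value[res$factor == "microhabitat"], 0.1)
  expect_error(pvr_manova(dendro, data.frame(
    f = factor(paste0("l", 1:8)), row.names = paste0("g", 1:8))),
    "insufficient|residual")
})

test_that("PVR p-values are calibrated for unrelated factors", {
  set.seed(15)
  ps <- vapply(1:100, function(k) {
    pts <- matrix(rnorm(20), 10, 2)
    rownames(pts) <- paste0("g", 1:10)
    dendro <- upgma(as.matrix(stats::dist(pts)))
    gf <- data.frame(f = sample(rep(c("u", "v"), each = 5)),
                     row.names = paste0("g", 1:10))
    pvr_manova(dendro, gf)$p_value[1]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("jackknife supports are well-formed and saturate at full depth", {
  cfg <- simulation_config(n_species = 5, samples_per_group = 3,
                           n_environment_samples = 0,
                           n_control_samples = 0, n_contaminants = 0,
                           n_otus = 60, environment_extra_otus = 2,
                           depth_mean = 600, species_effect = 0.8,
                           seed = 61)
  ds <- simulate_community(cfg)
  md <- ds$metadata
  full <- jackknife_support(ds$otu_table, md, "species",
                            ds$bacterial_tree,
                            metric = "weighted_unifrac",
                            depth_fraction = 1.0, n_reps = 5, seed = 1)
  expect_true(all(full$supports == 1))
  jk <- jackknife_support(ds$otu_table, md, "species", ds$bacterial_tree,
                          metric = "weighted_unifrac",
                          depth_fraction = 0.75, n_reps = 10, seed = 2)
  expect_true(all(abs(jk$supports * 10 - round(jk$supports * 10)) < 1e-9))
  expect_error(jackknife_support(ds$otu_table, md, "species",
                                 ds$bacterial_tree, depth_fraction = 1.5),
               "depth_fraction")
})

test_that("congruence pipeline runs end to end and supports group removal", {
  cfg <- simulation_config(seed = 71, phylosymbiosis_strength = 1.5,
                           phylo_fraction = 1, samples_per_group = 3,
                           n_environment_samples = 0,
                           n_control_samples = 0, n_contaminants = 0,
                           n_otus = 100, environment_extra_otus = 2,
                           depth_mean = 1000)
  ds <- simulate_community(cfg)
  rep <- congruence_pipeline(ds$otu_table, ds$metadata,
                             ds$bacterial_tree, ds$host_tree,
                             n_random = 99, n_jackknife = 5,
                             n_perm = 99, seed = 3)
  expect_equal(length(rep$groups), 8)
  for (m in names(rep$metrics)) {
    r <- rep$metrics[[m]]
    expect_gte(r$nrf, 0); expect_lte(r$nrf, 1)
    expect_equal(length(r$dendrogram$tip.label), 8)
    expect_gte(r$null$p_value, 1 / 100)
  }
  # leave-one-group-out re-analysis works on the subset
  md2 <- ds$metadata[ds$metadata$species != "sp8", ]
  tab2 <- phylosym:::subset_otu_table(ds$otu_table,
                                      samples = md2$sample_id)
  rep2 <- congruence_pipeline(tab2, md2, ds$bacterial_tree, ds$host_tree,
                              n_random = 99, n_jackknife = 0,
                              n_perm = 99, seed = 3)
  expect_equal(length(rep2$groups), 7)

  # a group missing from the host tree is an error
  host_small <- ape::keep.tip(ds$host_tree, paste0("sp", 1:6))
  expect_error(congruence_pipeline(ds$otu_table, ds$metadata,
                                   ds$bacterial_tree, host_small,
                                   n_random = 9, n_jackknife = 0,
                                   n_perm = 9),
               "missing groups")
})
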