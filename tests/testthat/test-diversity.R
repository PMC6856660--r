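test_that("shannon matches hand-computed values", {
  expect_equal(shannon(c(10, 10, 10, 10)), 2.0)
  expect_equal(shannon(c(30)), 0.0)
  expect_equal(shannon(c(3, 1)), 0.811278, tolerance = 1e-6)
  expect_equal(shannon(c(1, 1), log_base = exp(1)), log(2))
  expect_error(shannon(c(0, 0)), "positive total")
})

test_that("faith_pd sums the spanning subtree rooted at the tree root", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(faith_pd(c("A", "B"), tr), 3.0)
  expect_equal(faith_pd(c("A", "B", "C", "D"), tr),
               sum(tr$edge.length))
  expect_equal(faith_pd("A", tr), 2.0)  # root-to-tip path
  expect_error(faith_pd(c("A", "Z"), tr), "Z")

  # monotone: adding a tip never decreases PD
  for (s in 1:20) {
    tree <- random_fixture_tree(paste0("t", 1:8), seed = s)
    base <- sample(tree$tip.label, 3)
    extra <- sample(setdiff(tree$tip.label, base), 1)
    expect_gte(faith_pd(c(base, extra), tree), faith_pd(base, tree) - 1e-12)
  }
})

test_that("unweighted UniFrac matches manual branch enumeration", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  s <- function(...) stats::setNames(rep(1, length(c(...))), c(...))
  expect_equal(unweighted_unifrac(s("A", "B"), s("A", "B"), tr), 0)
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_equal(unweighted_unifrac(s("A", "B"), s("C", "D"), star), 1)
  expect_equal(unweighted_unifrac(s("A", "B"), s("A", "C"), tr), 0.6)
  expect_error(unweighted_unifrac(s("A") * 0, s("B") * 0, tr), "empty")
})

test_that("weighted UniFrac matches the branch-mass formula", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  a <- c(A = 10); b <- c(B = 7)
  expect_equal(weighted_unifrac(a, b, star), 2.0)
  expect_equal(weighted_unifrac(a, b, star, normalized = TRUE), 1.0)
  expect_equal(weighted_unifrac(c(A = 2, B = 2), c(A = 5, B = 5), star), 0)
  # linearity in branch lengths
  tr <- random_fixture_tree(LETTERS[1:6], seed = 4)
  x <- stats::setNames(rpois(6, 5) + 1, tr$tip.label)
  y <- stats::setNames(rpois(6, 5) + 1, tr$tip.label)
  d1 <- weighted_unifrac(x, y, tr)
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 3
  expect_equal(weighted_unifrac(x, y, tr2), 3 * d1, tolerance = 1e-12)
  expect_error(weighted_unifrac(x * 0, y, tr), "positive total")
})

test_that("beta_diversity_matrix agrees with the per-branch oracle", {
  set.seed(42)
  for (rep in 1:5) {
    tr <- random_fixture_tree(paste0("o", 1:10), seed = rep)
    counts <- matrix(rpois(6 * 10, 4), 6, 10,
                     dimnames = list(paste0("s", 1:6), tr$tip.label))
    counts[counts < 0] <- 0
    counts <- counts + 1L  # keep totals positive
    tab <- otu_table(counts)
    for (metric in c("unweighted_unifrac", "weighted_unifrac")) {
      dm <- beta_diversity_matrix(tab, tr, metric)
      for (i in 1:5) for (j in (i + 1):6) {
        o <- oracle_unifrac(counts[i, ], counts[j, ], tr,
                            weighted = metric == "weighted_unifrac")
        expect_lt(abs(dm[i, j] - o), 1e-10)
      }
    }
  }
})

test_that("beta_diversity_matrix handles degenerate shapes", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  one <- otu_table(matrix(c(1L, 2L, 0L), 1, 3,
                          dimnames = list("s1", c("A", "B", "C"))))
  expect_equal(beta_diversity_matrix(one, tr, "unweighted_unifrac"),
               matrix(0, 1, 1, dimnames = list("s1", "s1")))
  dup <- otu_table(matrix(c(1L, 2L, 0L, 1L, 2L, 0L), 2, 3, byrow = TRUE,
                          dimnames = list(c("s1", "s2"),
                                          c("A", "B", "C"))))
  dm <- beta_diversity_matrix(dup, tr, "weighted_unifrac")
  expect_equal(dm["s1", "s2"], 0)
})

test_that("faith_pd and alpha_diversity agree with picante", {
  tr <- random_fixture_tree(paste0("o", 1:12), seed = 7)
  set.seed(8)
  counts <- matrix(rpois(4 * 12, 3), 4, 12,
                   dimnames = list(paste0("s", 1:4), tr$tip.label)) + 1L
  tab <- otu_table(counts)
  mine <- alpha_diversity(tab, tr)
  ref <- picante::pd(counts, tr, include.root = TRUE)
  expect_equal(mine$pd, ref$PD, tolerance = 1e-10)
})

test_that("unweighted UniFrac behaves as a metric on random triples", {
  set.seed(5)
  for (rep in 1:50) {
    tr <- random_fixture_tree(paste0("o", 1:8), seed = 200 + rep)
    picks <- lapply(1:3, function(k) {
      tips <- sample(tr$tip.label, sample(2:6, 1))
      stats::setNames(rep(1, length(tips)), tips)
    })
    d12 <- unweighted_unifrac(picks[[1]], picks[[2]], tr)
    d13 <- unweighted_unifrac(picks[[1]], picks[[3]], tr)
    d23 <- unweighted_unifrac(picks[[2]], picks[[3]], tr)
    d21 <- unweighted_unifrac(picks[[2]], picks[[1]], tr)
    expect_equal(d12, d21)
    expect_gte(d12, 0); expect_lte(d12, 1)
    expect_lte(d12, d13 + d23 + 1e-12)
  }
})

test_that("PD is higher in environment samples when the pool is larger", {
  cfg <- simulation_config(n_species = 4, samples_per_group = 4,
                           n_environment_samples = 10,
                           n_control_samples = 0, n_contaminants = 0,
                           n_otus = 100, environment_extra_otus = 80,
                           depth_mean = 1200, seed = 55)
  ds <- simulate_community(cfg)
  ad <- alpha_diversity(ds$otu_table, ds$bacterial_tree)
  md <- ds$metadata[match(ad$sample_id, ds$metadata$sample_id), ]
  expect_gt(mean(ad$pd[md$sample_type == "environment"]),
            mean(ad$pd[md$sample_type == "skin"]))
})

test_that("pcoa recovers planar configurations and degenerate inputs", {
  set.seed(9)
  pts <- matrix(rnorm(12), 6, 2)
  rownames(pts) <- paste0("p", 1:6)
  dm <- as.matrix(stats::dist(pts))
  res <- pcoa(dm, n_axes = 2)
  expect_true(all(res$eigenvalues > -1e-10))
  # Procrustes: recovered distances must reproduce the input
  rec <- as.matrix(stats::dist(res$coordinates))
  expect_lt(max(abs(rec - dm)), 1e-8)

  zero <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  rz <- pcoa(zero, n_axes = 2)
  expect_true(all(abs(rz$coordinates) < 1e-12))
  expect_warning(pcoa(dm, n_axes = 10), "clamped")
})
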