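fixture_dm <- function(values, labels) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- values
  m + t(m)
}

test_that("ANOSIM hits its boundary values", {
  labs <- paste0("s", 1:6)
  g <- rep(c("a", "b"), each = 3)
  const <- fixture_dm(rep(2, 15), labs)
  res <- anosim(const, g, n_perm = 99, seed = 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # every between-group distance above every within-group distance
  m <- matrix(5, 6, 6, dimnames = list(labs, labs))
  m[1:3, 1:3] <- 1; m[4:6, 4:6] <- 1; diag(m) <- 0
  expect_equal(anosim(m, g, n_perm = 9, seed = 1)$statistic, 1)

  expect_error(anosim(const, c("a", rep("b", 5)), n_perm = 9),
               "at least two samples")
})

test_that("ANOSIM permutation p matches exhaustive enumeration", {
  set.seed(3)
  labs <- paste0("s", 1:6)
  dm <- fixture_dm(sample(1:15), labs)
  g <- rep(c("a", "b"), each = 3)
  p_exact <- exact_two_group_p(dm, g, function(gg) oracle_anosim_R(dm, gg))
  res <- anosim(dm, g, n_perm = 9999, seed = 7)
  tol <- 3 * sqrt(p_exact * (1 - p_exact) / 9999) + 2 / 9999
  expect_lt(abs(res$p_value - p_exact), tol)
  expect_equal(res$statistic, oracle_anosim_R(dm, g))
})

test_that("ANOSIM agrees with vegan on a random instance", {
  set.seed(11)
  pts <- matrix(rnorm(24), 12, 2)
  rownames(pts) <- paste0("s", 1:12)
  dm <- as.matrix(stats::dist(pts))
  g <- rep(c("a", "b", "c"), each = 4)
  mine <- anosim(dm, g, n_perm = 99, seed = 1)
  ref <- vegan::anosim(stats::as.dist(dm), g, permutations = 99)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
})

test_that("PERMANOVA pseudo-F equals classical ANOVA F on Euclidean input", {
  set.seed(4)
  y <- rnorm(15)
  g <- factor(rep(c("a", "b", "c"), each = 5))
  dm <- as.matrix(stats::dist(y))
  rownames(dm) <- colnames(dm) <- paste0("s", 1:15)
  res <- permanova(dm, g, n_perm = 49, seed = 1)
  f_ref <- summary(stats::aov(y ~ g))[[1]]$`F value`[1]
  expect_lt(abs(res$statistic - f_ref), 1e-10)

  ref <- vegan::adonis2(stats::as.dist(dm) ~ g, permutations = 19)
  expect_equal(res$statistic, ref$F[1], tolerance = 1e-10)
  expect_equal(res$effect_size, ref$R2[1], tolerance = 1e-10)
})

test_that("PERMANOVA saturates when groups are point clouds of duplicates", {
  y <- c(0, 0, 0, 5, 5, 5)
  dm <- as.matrix(stats::dist(y))
  rownames(dm) <- colnames(dm) <- paste0("s", 1:6)
  res <- permanova(dm, rep(c("a", "b"), each = 3), n_perm = 19, seed = 2)
  expect_equal(res$effect_size, 1, tolerance = 1e-12)
  expect_true(is.infinite(res$statistic) || res$statistic > 1e10)
})

test_that("sequential PERMANOVA reduces, commutes, and orders correctly", {
  set.seed(6)
  # single factor: identical to plain permanova
  pts <- matrix(rnorm(32), 16, 2)
  rownames(pts) <- paste0("s", 1:16)
  dm <- as.matrix(stats::dist(pts))
  md <- data.frame(sample_id = rownames(dm),
                   f1 = rep(c("a", "b"), each = 8),
                   f2 = rep(c("x", "y"), times = 8))
  seq1 <- permanova_sequential(dm, md, factor_order = "f1", n_perm = 49,
                               seed = 3)
  plain <- permanova(dm, md$f1, n_perm = 49, seed = 3)
  expect_equal(seq1$pseudo_F[1], plain$statistic, tolerance = 1e-10)
  expect_equal(seq1$r2[1], plain$effect_size, tolerance = 1e-10)

  # orthogonal balanced design: R2 invariant to term order
  s12 <- permanova_sequential(dm, md, c("f1", "f2"), n_perm = 0)
  s21 <- permanova_sequential(dm, md, c("f2", "f1"), n_perm = 0)
  expect_lt(abs(s12$r2[s12$term == "f1"] - s21$r2[s21$term == "f1"]),
            1e-10)
  expect_lt(abs(s12$r2[s12$term == "f2"] - s21$r2[s21$term == "f2"]),
            1e-10)

  # nested factors: order changes the attribution
  md$sp <- paste0(md$f1, rep(1:2, each = 4))  # species nested in f1
  shift <- ifelse(md$sp == "a1", 3, ifelse(md$sp == "b2", -2, 0))
  dmn <- as.matrix(stats::dist(pts + shift))
  rownames(dmn) <- colnames(dmn) <- rownames(dm)
  sA <- permanova_sequential(dmn, md, c("f1", "sp"), n_perm = 0)
  sB <- permanova_sequential(dmn, md, c("sp", "f1"), n_perm = 0)
  expect_gt(abs(sA$r2[sA$term == "sp"] - sB$r2[sB$term == "sp"]), 1e-6)
  # fully aliased trailing term gets zero df and no test
  expect_equal(sB$df[sB$term == "f1"], 0)
  expect_true(is.na(sB$p_value[sB$term == "f1"]))
})

test_that("sequential PERMANOVA matches adonis2 term decomposition", {
  set.seed(16)
  pts <- matrix(rnorm(36), 18, 2)
  rownames(pts) <- paste0("s", 1:18)
  dm <- as.matrix(stats::dist(pts))
  md <- data.frame(sample_id = rownames(dm),
                   f1 = rep(c("a", "b", "c"), each = 6),
                   f2 = rep(rep(c("x", "y"), each = 3), 3))
  mine <- permanova_sequential(dm, md, c("f1", "f2"), n_perm = 0)
  ref <- vegan::adonis2(stats::as.dist(dm) ~ f1 + f2, data = md,
                        permutations = 19, by = "terms")
  expect_equal(mine$r2[1:2], ref$R2[1:2], tolerance = 1e-10)
  expect_equal(mine$pseudo_F[1:2], ref$F[1:2], tolerance = 1e-10)
})

test_that("kruskal_wallis matches the rank formula and is rank-invariant", {
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$statistic, 3.857143, tolerance = 1e-6)
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2)))$statistic, 0)
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2)))$p_value, 1)
  r2 <- kruskal_wallis(list(exp(c(1, 2, 3)), exp(c(4, 5, 6))))
  expect_equal(r2$statistic, res$statistic)
})

test_that("nonparametric t-test is exact, symmetric and degenerate-safe", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 4)
  expect_gte(nonparametric_t_test(x, y, n_perm = 99, seed = 1)$p_value,
             0.99)
  set.seed(12)
  a <- rnorm(4); b <- rnorm(3) + 2
  v <- c(a, b)
  tfun <- function(gg) {
    xa <- v[gg == "x"]; xb <- v[gg == "y"]
    sp2 <- ((length(xa) - 1) * var(xa) + (length(xb) - 1) * var(xb)) /
      (length(v) - 2)
    abs((mean(xa) - mean(xb)) / sqrt(sp2 * (1 / length(xa) + 1 / length(xb))))
  }
  g0 <- rep(c("x", "y"), c(4, 3))
  p_exact <- exact_two_group_p(v, g0, tfun)
  res <- nonparametric_t_test(a, b, n_perm = 9999, seed = 5)
  tol <- 3 * sqrt(p_exact * (1 - p_exact) / 9999) + 2 / 9999
  expect_lt(abs(res$p_value - p_exact), tol)
  swapped <- nonparametric_t_test(b, a, n_perm = 9999, seed = 5)
  expect_lt(abs(res$p_value - swapped$p_value), 0.02)
  const <- nonparametric_t_test(c(2, 2), c(2, 2), n_perm = 99)$p_value
  expect_equal(const, 1)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  p <- c(0.001, 0.04, 0.03, 0.8)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("pairwise battery enumerates group pairs with FDR across them", {
  set.seed(13)
  pts <- c(rnorm(4), rnorm(4) + 3)
  dm <- as.matrix(stats::dist(pts))
  rownames(dm) <- colnames(dm) <- paste0("s", 1:8)
  two <- pairwise_groups(dm, rep(c("a", "b"), each = 4), n_perm = 99,
                         seed = 2)
  expect_equal(nrow(two), 1)
  expect_equal(two$q, two$p)

  g8 <- rep(paste0("g", 1:8), each = 3)
  pts8 <- rnorm(24)
  dm8 <- as.matrix(stats::dist(pts8))
  rownames(dm8) <- colnames(dm8) <- paste0("s", 1:24)
  res <- pairwise_groups(dm8, g8, n_perm = 19, seed = 3)
  expect_equal(nrow(res), 28)
  expect_true(all(res$q >= res$p - 1e-12))
})
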