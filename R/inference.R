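#' Analysis of similarity (ANOSIM)
#'
#' Rank-based permutation test comparing between-group versus within-group
#' distances. `R = (mean rank between - mean rank within) / (M / 2)` with
#' `M = n(n-1)/2` pairwise distances; `R` lies in `[-1, 1]`. The p-value
#' uses the add-one rule `(1 + b) / (n_perm + 1)` over free label
#' permutations.
#'
#' @param dm Distance matrix over samples.
#' @param grouping Factor (or coercible) of group labels, one per sample,
#'   in `dm` row order. At least two groups, each with at least two
#'   samples.
#' @param n_perm Number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return A [test_result()] with `statistic_name = "R"`.
#' @export
anosim <- function(dm, grouping, n_perm = 999, seed = NULL) {
  dm <- check_dist_matrix(dm)
  g <- droplevels(as.factor(grouping))
  n <- nrow(dm)
  if (length(g) != n) stop("grouping length must match dm")
  if (nlevels(g) < 2) stop("need at least two groups")
  if (any(table(g) < 2)) stop("every group needs at least two samples")
  pr <- lower_pairs(n)
  r <- rank(dm[lower.tri(dm)])
  m <- length(r)
  stat <- function(gg) {
    within <- gg[pr$i] == gg[pr$j]
    (mean(r[!within]) - mean(r[within])) / (m / 2)
  }
  obs <- stat(g)
  perms <- with_seed_(seed, vapply(seq_len(n_perm), function(k)
    stat(g[sample.int(n)]), numeric(1)))
  test_result("R", obs, perm_pvalue(perms, obs), n_perm, seed = seed)
}

#' PERMANOVA (single factor)
#'
#' Distance-based multivariate ANOVA: sums of squares are read off the
#' Gower-centered matrix; `pseudo-F = (SS_between / (a-1)) /
#' (SS_within / (N-a))`, with effect size `R^2 = SS_between / SS_total`.
#' For univariate Euclidean input the pseudo-F coincides with the
#' classical one-way ANOVA F. Permutation p-value by free permutation of
#' observations.
#'
#' @inheritParams anosim
#' @return A [test_result()] with `statistic_name = "pseudo_F"` and
#'   `effect_size = R^2`.
#' @export
permanova <- function(dm, grouping, n_perm = 999, seed = NULL) {
  dm <- check_dist_matrix(dm)
  g <- droplevels(as.factor(grouping))
  n <- nrow(dm)
  if (length(g) != n) stop("grouping length must match dm")
  if (nlevels(g) < 2) stop("need at least two groups")
  if (any(table(g) < 2)) stop("every group needs at least two samples")
  a <- nlevels(g)
  G <- gower_center(dm)
  X <- stats::model.matrix(~g)
  H <- X %*% solve(crossprod(X), t(X))
  ss_total <- sum(diag(G))
  if (ss_total <= 1e-12)
    return(test_result("pseudo_F", 0, 1, n_perm, effect_size = 0,
                       seed = seed))
  f_of <- function(idx) {
    Gp <- G[idx, idx]
    ssb <- sum(H * Gp)
    ssw <- sum(diag(Gp)) - ssb
    (ssb / (a - 1)) / (ssw / (n - a))
  }
  obs <- f_of(seq_len(n))
  r2 <- sum(H * G) / ss_total
  perms <- with_seed_(seed, vapply(seq_len(n_perm), function(k)
    f_of(sample.int(n)), numeric(1)))
  test_result("pseudo_F", obs, perm_pvalue(perms, obs), n_perm,
              effect_size = r2, seed = seed,
              extra = list(df = c(a - 1, n - a)))
}

#' Sequential (Type-I) PERMANOVA
#'
#' Adds model terms in the given order and attributes to each term the
#' increment in explained sum of squares (the `adonis`-style sequential
#' decomposition); term order matters whenever factors are correlated,
#' e.g. when host species is nested in locality. Permutation of raw
#' observations gives each term's p-value. Terms whose marginal degrees
#' of freedom are zero (fully aliased by earlier terms) are reported with
#' `df = 0` and no test.
#'
#' @param dm Distance matrix over samples.
#' @param metadata Data frame with one row per sample (aligned to `dm` via
#'   its `sample_id` column if present, otherwise by position).
#' @param factor_order Character vector of metadata column names, in the
#'   order terms enter the model.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return Data frame with one row per term: `term`, `df`, `ss`, `r2`,
#'   `pseudo_F`, `p_value`, plus a residual row.
#' @export
permanova_sequential <- function(dm, metadata,
                                 factor_order = c("locality",
                                                  "microhabitat",
                                                  "species"),
                                 n_perm = 999, seed = NULL) {
  dm <- check_dist_matrix(dm)
  n <- nrow(dm)
  if ("sample_id" %in% names(metadata))
    metadata <- align_metadata(metadata, rownames(dm))
  if (nrow(metadata) != n) stop("metadata must have one row per sample")
  miss <- setdiff(factor_order, names(metadata))
  if (length(miss))
    stop("metadata lacks factors: ", paste(miss, collapse = ", "))
  G <- gower_center(dm)
  ss_total <- sum(diag(G))

  # cumulative hat matrices
  hats <- list(); ranks <- integer()
  fmla <- "~ 1"
  dat <- metadata[, factor_order, drop = FALSE]
  dat[] <- lapply(dat, function(x) droplevels(as.factor(x)))
  for (k in seq_along(factor_order)) {
    fmla <- paste(fmla, "+", factor_order[k])
    X <- stats::model.matrix(stats::as.formula(fmla), dat)
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    hats[[k]] <- tcrossprod(Q)
    ranks[k] <- q$rank
  }
  df_terms <- diff(c(1L, ranks))
  rank_full <- ranks[length(ranks)]
  df_res <- n - rank_full

  term_ss <- function(idx) {
    Gp <- G[idx, idx]
    cum <- vapply(hats, function(H) sum(H * Gp), numeric(1))
    list(ss = diff(c(0, cum)), res = sum(diag(Gp)) - cum[length(cum)])
  }
  obs <- term_ss(seq_len(n))
  f_obs <- ifelse(df_terms > 0,
                  (obs$ss / df_terms) / (obs$res / df_res), NA_real_)

  exceed <- numeric(length(factor_order))
  if (any(df_terms > 0) && n_perm > 0) {
    exceed <- with_seed_(seed, {
      acc <- numeric(length(factor_order))
      for (b in seq_len(n_perm)) {
        p <- term_ss(sample.int(n))
        fp <- (p$ss / df_terms) / (p$res / df_res)
        acc <- acc + as.numeric(fp >= f_obs - 1e-12)
      }
      acc
    })
  }
  p <- ifelse(df_terms > 0, (1 + exceed) / (n_perm + 1), NA_real_)
  out <- data.frame(term = factor_order, df = df_terms, ss = obs$ss,
                    r2 = obs$ss / ss_total, pseudo_F = f_obs, p_value = p,
                    stringsAsFactors = FALSE)
  rbind(out, data.frame(term = "residual", df = df_res, ss = obs$res,
                        r2 = obs$res / ss_total, pseudo_F = NA_real_,
                        p_value = NA_real_))
}

#' Kruskal-Wallis rank-sum test
#'
#' Thin wrapper over [stats::kruskal.test()] (tie-corrected H, chi-square
#' p with k-1 degrees of freedom) returning a [test_result()]; the
#' degenerate all-identical case yields `H = 0`, `p = 1`.
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups,
#'   total n >= 3).
#' @return A [test_result()] with `statistic_name = "H"`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3) stop("need total n >= 3")
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1)
    return(test_result("H", 0, 1))
  kw <- stats::kruskal.test(x, g)
  test_result("H", unname(kw$statistic), kw$p.value)
}

#' Nonparametric two-sample t-test
#'
#' Pooled-variance two-sample t statistic with a two-sided Monte-Carlo
#' permutation p-value (group labels permuted, add-one rule). If the
#' pooled variance is zero and the means are equal, `p = 1`.
#'
#' @param x,y Numeric vectors with at least two observations each.
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return A [test_result()] with `statistic_name = "t"`.
#' @export
nonparametric_t_test <- function(x, y, n_perm = 999, seed = NULL) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least two observations")
  nx <- length(x); ny <- length(y)
  tstat <- function(v) {
    a <- v[seq_len(nx)]; b <- v[-seq_len(nx)]
    sp2 <- ((nx - 1) * stats::var(a) + (ny - 1) * stats::var(b)) /
      (nx + ny - 2)
    d <- mean(a) - mean(b)
    if (sp2 <= 0) return(if (abs(d) < 1e-15) 0 else Inf * sign(d))
    d / sqrt(sp2 * (1 / nx + 1 / ny))
  }
  v <- c(x, y)
  obs <- tstat(v)
  if (!is.finite(obs) && abs(mean(x) - mean(y)) < 1e-15) obs <- 0
  perms <- with_seed_(seed, vapply(seq_len(n_perm), function(k)
    tstat(v[sample.int(nx + ny)]), numeric(1)))
  p <- (1 + sum(abs(perms) >= abs(obs) - 1e-12)) / (n_perm + 1)
  test_result("t", obs, p, n_perm, seed = seed)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values via [stats::p.adjust()], clipped at 1,
#' original order preserved.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Vector of q-values, same order and length.
#' @export
bh_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Pairwise post hoc battery over group pairs
#'
#' Applies ANOSIM or PERMANOVA to the sub-matrix of every pair of groups
#' and adjusts the p-values with Benjamini-Hochberg FDR across all pairs.
#'
#' @param dm Distance matrix over samples.
#' @param grouping Group labels (>= 2 groups).
#' @param test `"anosim"` or `"permanova"`.
#' @param n_perm Permutations per pair.
#' @param seed RNG seed (incremented per pair for independence).
#' @return Data frame with `group_a`, `group_b`, `statistic`, `p`, `q`
#'   (one row per unordered pair, lexicographic order).
#' @export
pairwise_groups <- function(dm, grouping, test = c("anosim", "permanova"),
                            n_perm = 999, seed = NULL) {
  test <- match.arg(test)
  dm <- check_dist_matrix(dm)
  g <- droplevels(as.factor(grouping))
  lv <- sort(levels(g))
  if (length(lv) < 2) stop("need at least two groups")
  pairs <- utils::combn(lv, 2)
  fun <- if (test == "anosim") anosim else permanova
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    sel <- g %in% pairs[, k]
    res <- tryCatch(
      fun(dm[sel, sel, drop = FALSE], g[sel], n_perm = n_perm,
          seed = if (is.null(seed)) NULL else seed + k),
      error = function(e) NULL)
    data.frame(group_a = pairs[1, k], group_b = pairs[2, k],
               statistic = if (is.null(res)) NA_real_ else res$statistic,
               p = if (is.null(res)) NA_real_ else res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bh_fdr(out$p[ok])
  out
}
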