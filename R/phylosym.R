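#' Collapse an OTU table by group
#'
#' Per group (e.g. host species, or species-by-locality population), the
#' mean of per-sample relative-abundance vectors — each individual gets
#' equal weight regardless of sequencing depth. Rows sum to 1.
#'
#' @param table An [otu_table()].
#' @param metadata Metadata with `sample_id` and the grouping column.
#' @param group_factor Metadata column defining groups.
#' @return Groups x OTUs matrix of mean relative abundances.
#' @export
collapse_by_group <- function(table, metadata, group_factor) {
  md <- align_metadata(metadata, sample_ids(table))
  g <- droplevels(as.factor(md[[group_factor]]))
  if (any(base::table(g) == 0)) stop("empty group")
  rel <- relative_abundance(table)
  out <- t(vapply(levels(g), function(lv)
    colMeans(rel[g == lv, , drop = FALSE]), numeric(ncol(rel))))
  rownames(out) <- levels(g)
  out
}

#' UPGMA dendrogram
#'
#' Average-linkage agglomeration with merge height equal to half the
#' average inter-cluster distance, so cophenetic distances on the
#' returned tree reproduce an ultrametric input exactly. Ties in the
#' minimal distance are broken by the lexicographic order of each
#' cluster's smallest member label, making the topology deterministic.
#'
#' @param dm Distance matrix (no NAs), `n >= 2`.
#' @return Rooted ultrametric [ape::phylo] over the row labels.
#' @export
upgma <- function(dm) {
  dm <- check_dist_matrix(dm)
  n <- nrow(dm)
  if (n < 2) stop("need at least two labels")
  labels <- rownames(dm)
  # clusters carry a newick fragment, a height, a size and a min label
  nwk <- labels
  height <- numeric(n)
  size <- rep(1L, n)
  minlab <- labels
  d <- dm
  active <- seq_len(n)
  while (length(active) > 1) {
    best <- NULL; bestkey <- NULL
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1):length(active)) {
        a <- active[ii]; b <- active[jj]
        key <- list(d[a, b], sort(c(minlab[a], minlab[b])))
        better <- is.null(best) ||
          d[a, b] < bestkey[[1]] - 1e-12 ||
          (abs(d[a, b] - bestkey[[1]]) <= 1e-12 &&
             (key[[2]][1] < bestkey[[2]][1] ||
                (key[[2]][1] == bestkey[[2]][1] &&
                   key[[2]][2] < bestkey[[2]][2])))
        if (better) { best <- c(a, b); bestkey <- key }
      }
    }
    a <- best[1]; b <- best[2]
    h <- d[a, b] / 2
    nwk_new <- sprintf("(%s:%.12g,%s:%.12g)",
                       nwk[a], h - height[a], nwk[b], h - height[b])
    # average-linkage update into slot a
    others <- setdiff(active, c(a, b))
    for (k in others) {
      d[a, k] <- d[k, a] <-
        (size[a] * d[a, k] + size[b] * d[b, k]) / (size[a] + size[b])
    }
    nwk[a] <- nwk_new
    height[a] <- h
    size[a] <- size[a] + size[b]
    minlab[a] <- min(minlab[a], minlab[b])
    active <- setdiff(active, b)
  }
  ape::read.tree(text = paste0(nwk[active], ";"))
}

# Nontrivial clades of a rooted tree: for each internal node except the
# root, the set of descendant tip labels, encoded as a sorted "|"-joined
# string.
clade_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  sets <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1L]; ch <- tr$edge[k, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  root <- ntip + 1L
  internal <- setdiff(unique(tr$edge[, 1L]), root)
  vapply(sets[internal], function(s) paste(sort(s), collapse = "|"),
         character(1))
}

#' Normalized Robinson-Foulds distance (rooted)
#'
#' Symmetric difference of the two trees' nontrivial clade sets (internal
#' nodes excluding the root; tips excluded), divided by the total number
#' of nontrivial clades `|C_a| + |C_b|`. Ranges from 0 (identical clade
#' sets) to 1 (no shared clades). Branch lengths are ignored;
#' multifurcations are allowed.
#'
#' @param tree_a,tree_b Rooted [ape::phylo] trees over the same tip set
#'   (>= 3 tips).
#' @return Normalized RF distance in `[0, 1]`.
#' @export
robinson_foulds_normalized <- function(tree_a, tree_b) {
  if (length(tree_a$tip.label) < 3) stop("trees need at least 3 tips")
  mism <- c(setdiff(tree_a$tip.label, tree_b$tip.label),
            setdiff(tree_b$tip.label, tree_a$tip.label))
  if (length(mism))
    stop("tip sets differ: ", paste(mism, collapse = ", "))
  nrf_from_sets(clade_sets(tree_a), clade_sets(tree_b))
}

nrf_from_sets <- function(ca, cb) {
  denom <- length(ca) + length(cb)
  if (denom == 0) return(0)
  (sum(!(ca %in% cb)) + sum(!(cb %in% ca))) / denom
}

# Uniform random rooted binary topology over `labels` by random addition:
# each new tip attaches to one of the 2k-1 positions (any edge, or above
# the root), which weights every labeled topology equally. Returns the
# clade-set encoding (cheap; no phylo object needed for the null).
random_topology_clades <- function(labels) {
  n <- length(labels)
  if (n < 2) stop("need >= 2 labels")
  # node ids: tips 1..n, internal nodes n+1, n+2, ...
  edges <- matrix(c(n + 1L, 1L, n + 1L, 2L), 2, 2, byrow = TRUE)
  root <- n + 1L
  nxt <- n + 2L
  for (k in seq_len(n)[-(1:2)]) {
    pos <- sample.int(nrow(edges) + 1L, 1L)
    if (pos > nrow(edges)) {
      edges <- rbind(edges, c(nxt, root), c(nxt, k))
      root <- nxt
    } else {
      child <- edges[pos, 2L]
      edges[pos, 2L] <- nxt
      edges <- rbind(edges, c(nxt, child), c(nxt, k))
    }
    nxt <- nxt + 1L
  }
  clades_from_edges(edges, root, n, labels)
}

clades_from_edges <- function(edges, root, n, labels) {
  nnode <- max(edges)
  sets <- vector("list", nnode)
  for (i in seq_len(n)) sets[[i]] <- labels[i]
  # accumulate children into parents in reverse creation order: every
  # internal node's children are created after it only via subdivision,
  # so iterate until stable over a topological order by repeated passes
  remaining <- edges
  done <- c(rep(TRUE, n), rep(FALSE, nnode - n))
  while (nrow(remaining) > 0) {
    ready <- done[remaining[, 2L]]
    for (r in which(ready)) {
      p <- remaining[r, 1L]
      sets[[p]] <- c(sets[[p]], sets[[remaining[r, 2L]]])
    }
    # a parent is done when all its outgoing edges are consumed
    consumed <- remaining[ready, 1L]
    remaining <- remaining[!ready, , drop = FALSE]
    for (p in unique(consumed))
      if (!any(remaining[, 1L] == p)) done[p] <- TRUE
  }
  internal <- setdiff((n + 1L):nnode, root)
  vapply(sets[internal], function(s) paste(sort(s), collapse = "|"),
         character(1))
}

#' Random-topology null for Robinson-Foulds congruence
#'
#' Draws `n_random` rooted binary topologies uniformly over labeled
#' topologies with the reference tree's tips, computes each one's
#' normalized RF distance to the reference, and reports the add-one
#' probability of a random tree being at least as congruent (nRF <=
#' observed) as the observed dendrogram.
#'
#' @param reference_tree Rooted [ape::phylo] (>= 3 tips), e.g. the host
#'   phylogeny.
#' @param observed_nrf Observed normalized RF distance in `[0, 1]`.
#' @param n_random Number of random trees (default 1,000).
#' @param seed RNG seed.
#' @return A `congruence_result`: list with `nrf_observed`, `n_random`,
#'   `p_value` and `null_distribution`.
#' @export
random_tree_null <- function(reference_tree, observed_nrf,
                             n_random = 1000, seed = NULL) {
  if (length(reference_tree$tip.label) < 3)
    stop("reference tree needs >= 3 tips")
  if (is.na(observed_nrf) || observed_nrf < 0 || observed_nrf > 1)
    stop("observed_nrf must lie in [0, 1]")
  ref <- clade_sets(reference_tree)
  labels <- reference_tree$tip.label
  null <- with_seed_(seed, vapply(seq_len(n_random), function(k)
    nrf_from_sets(random_topology_clades(labels), ref), numeric(1)))
  p <- (1 + sum(null <= observed_nrf + 1e-12)) / (n_random + 1)
  structure(list(nrf_observed = observed_nrf, n_random = n_random,
                 p_value = p, null_distribution = null),
            class = "congruence_result")
}

#' @export
print.congruence_result <- function(x, ...) {
  cat(sprintf("nRF = %.4f, p = %.4g (%d random trees)\n",
              x$nrf_observed, x$p_value, x$n_random))
  invisible(x)
}

#' Patristic distance matrix
#'
#' Tip-to-tip path lengths (sums of branch lengths) of a tree.
#'
#' @param tree Rooted [ape::phylo] with branch lengths on every edge.
#' @return Symmetric distance matrix over tip labels (sorted).
#' @export
patristic_distances <- function(tree) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))[1]
    stop("missing branch length on edge ",
         paste(tree$edge[bad, ], collapse = "->"))
  }
  d <- ape::cophenetic.phylo(tree)
  ord <- sort(rownames(d))
  check_dist_matrix(d[ord, ord])
}

#' Jackknife support for a UPGMA dendrogram
#'
#' Rebuilds the group dendrogram `n_reps` times after subsampling every
#' sample without replacement to `floor(depth_fraction x its depth)`,
#' and scores each clade of the full-data tree by the fraction of
#' replicate trees containing it. The full-data topology is returned with
#' supports as node labels.
#'
#' @param table Rarefied [otu_table()].
#' @param metadata Metadata with `sample_id` and the grouping column.
#' @param group_factor Metadata column defining dendrogram tips.
#' @param tree Bacterial [ape::phylo] for the UniFrac metric.
#' @param metric `"unweighted_unifrac"` or `"weighted_unifrac"`.
#' @param depth_fraction Subsampling fraction in `(0, 1]`.
#' @param n_reps Number of jackknife replicates (default 100).
#' @param seed RNG seed.
#' @param normalized Normalization flag for the weighted metric.
#' @return List with `tree` (phylo, node labels = supports) and
#'   `supports` (named numeric, one entry per internal node clade).
#' @export
jackknife_support <- function(table, metadata, group_factor, tree,
                              metric = "unweighted_unifrac",
                              depth_fraction = 0.75, n_reps = 100,
                              seed = NULL, normalized = FALSE) {
  if (depth_fraction <= 0 || depth_fraction > 1)
    stop("depth_fraction must be in (0, 1]")
  collapsed <- collapse_by_group(table, metadata, group_factor)
  dm_full <- beta_diversity_matrix(collapsed, tree, metric,
                                   normalized = normalized)
  full <- upgma(dm_full)
  full_clades <- clade_sets(full)
  hits <- stats::setNames(numeric(length(full_clades)), full_clades)
  with_seed_(seed, {
    for (r in seq_len(n_reps)) {
      sub <- table
      if (depth_fraction < 1) {
        counts <- table$counts
        for (s in seq_len(nrow(counts))) {
          tot <- sum(counts[s, ])
          target <- floor(depth_fraction * tot)
          expanded <- rep.int(seq_len(ncol(counts)), counts[s, ])
          counts[s, ] <- tabulate(sample(expanded, target),
                                  nbins = ncol(counts))
        }
        sub <- otu_table(counts, table$taxonomy)
      }
      coll <- collapse_by_group(sub, metadata, group_factor)
      dmr <- beta_diversity_matrix(coll, tree, metric,
                                   normalized = normalized)
      rep_clades <- clade_sets(upgma(dmr))
      hits[full_clades %in% rep_clades] <-
        hits[full_clades %in% rep_clades] + 1
    }
  })
  supports <- hits / n_reps
  # attach supports as node labels in the tree's internal-node order
  ntip <- length(full$tip.label)
  lab <- rep("", full$Nnode)
  cl_by_node <- clade_sets_by_node(full)
  for (i in seq_len(full$Nnode)) {
    key <- cl_by_node[i]
    lab[i] <- if (is.na(key)) "" else sprintf("%.2f", supports[[key]])
  }
  full$node.label <- lab
  list(tree = full, supports = supports)
}

# clade string per internal node in node order (NA for the root).
clade_sets_by_node <- function(tree) {
  ntip <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  sets <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1L]; ch <- tr$edge[k, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  out <- rep(NA_character_, tree$Nnode)
  if (tree$Nnode >= 2) {
    for (nd in (ntip + 2L):(ntip + tree$Nnode))
      out[nd - ntip] <- paste(sort(sets[[nd]]), collapse = "|")
  }
  out
}

#' Partial Mantel test
#'
#' Partial Pearson correlation between two distance matrices controlling
#' for a third, computed on the off-diagonal entries:
#' `r_AB.C = (r_AB - r_AC r_BC) / sqrt((1 - r_AC^2)(1 - r_BC^2))`.
#' Significance by permuting rows/columns of the first matrix; one-sided
#' (`r_perm >= r_obs`), matching the alternative that closely related
#' hosts carry similar microbiota.
#'
#' @param d_target,d_other,d_control Conformable distance matrices over
#'   identical labels (target is permuted).
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A [test_result()] with `statistic_name = "r_partial"`.
#' @export
partial_mantel <- function(d_target, d_other, d_control, n_perm = 999,
                           seed = NULL, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  a <- check_dist_matrix(d_target, "d_target")
  b <- check_dist_matrix(d_other, "d_other")
  cc <- check_dist_matrix(d_control, "d_control")
  if (!identical(rownames(a), rownames(b)) ||
      !identical(rownames(a), rownames(cc))) {
    b <- b[rownames(a), rownames(a)]
    cc <- cc[rownames(a), rownames(a)]
  }
  lt <- lower.tri(a)
  vb <- b[lt]; vc <- cc[lt]
  if (method == "spearman") { vb <- rank(vb); vc <- rank(vc) }
  partial_r <- function(am) {
    va <- am[lt]
    if (method == "spearman") va <- rank(va)
    rab <- stats::cor(va, vb); rac <- stats::cor(va, vc)
    rbc <- stats::cor(vb, vc)
    if (abs(rac) >= 1 - 1e-12 || abs(rbc) >= 1 - 1e-12)
      stop("degenerate control correlation (|r| = 1)")
    (rab - rac * rbc) / sqrt((1 - rac^2) * (1 - rbc^2))
  }
  obs <- partial_r(a)
  n <- nrow(a)
  perms <- with_seed_(seed, vapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    partial_r(a[p, p])
  }, numeric(1)))
  test_result("r_partial", obs, perm_pvalue(perms, obs), n_perm,
              seed = seed)
}

#' Phylogenetic eigenvector regression with MANOVA
#'
#' Decomposes a dendrogram into phylogenetic eigenvectors: cophenetic
#' (patristic) distances are double-centered and eigendecomposed;
#' positive-eigenvalue vectors are retained up to the smaller of 95%
#' cumulative variance and `n_tips - levels - 1` axes. Each factor is
#' then tested one at a time by MANOVA (Pillai's trace with its F
#' approximation) of the retained coordinates on the factor. With a
#' single retained axis the Pillai F reduces to the one-way ANOVA F.
#'
#' @param dendrogram Rooted [ape::phylo] with branch lengths (tips are
#'   groups).
#' @param group_factors Data frame of factors, one row per tip (matched
#'   by row names, or by a `group` column if present).
#' @param var_cutoff Cumulative-variance cutoff for retained axes.
#' @return Data frame with one row per factor: `factor`, `pillai`,
#'   `approx_F`, `df1`, `df2`, `p_value`, `n_axes`.
#' @export
pvr_manova <- function(dendrogram, group_factors, var_cutoff = 0.95) {
  d <- patristic_distances(dendrogram)
  tips <- rownames(d)
  if ("group" %in% names(group_factors)) {
    rownames(group_factors) <- group_factors$group
    group_factors$group <- NULL
  }
  miss <- setdiff(tips, rownames(group_factors))
  if (length(miss))
    stop("group_factors missing tips: ", paste(miss, collapse = ", "))
  gf <- group_factors[tips, , drop = FALSE]
  n <- length(tips)
  g <- gower_center(d)
  eg <- eigen(g, symmetric = TRUE)
  pos <- which(eg$values > max(eg$values) * 1e-8)
  if (length(pos) == 0) stop("dendrogram has no positive eigenvalues")
  cumvar <- cumsum(eg$values[pos]) / sum(eg$values[pos])
  k95 <- which(cumvar >= var_cutoff - 1e-12)[1]

  rows <- lapply(names(gf), function(fct) {
    f <- droplevels(as.factor(gf[[fct]]))
    lv <- nlevels(f)
    kmax <- n - lv - 1
    if (kmax < 1)
      stop("insufficient residual df for factor ", fct,
           ": need at least ", lv + 2, " tips")
    k <- min(k95, kmax, length(pos))
    Y <- eg$vectors[, pos[seq_len(k)], drop = FALSE] %*%
      diag(sqrt(eg$values[pos[seq_len(k)]]), k)
    # Pillai's trace V = tr(H (H+E)^-1) with its standard F approximation;
    # computed from the SSCP matrices directly so that axes perfectly
    # explained by the factor (singular residuals) remain testable
    res <- stats::lm.fit(stats::model.matrix(~f), Y)$residuals
    E <- crossprod(as.matrix(res))
    Tt <- crossprod(Y)  # eigenvector axes are already centered
    V <- sum(diag((Tt - E) %*% solve(Tt)))
    s <- min(k, lv - 1)
    mm <- (abs(k - lv + 1) - 1) / 2
    uu <- (n - lv - k - 1) / 2
    df1 <- s * (2 * mm + s + 1)
    df2 <- s * (2 * uu + s + 1)
    Fs <- if (V >= s - 1e-12) Inf else
      ((2 * uu + s + 1) / (2 * mm + s + 1)) * V / (s - V)
    p <- stats::pf(Fs, df1, df2, lower.tail = FALSE)
    data.frame(factor = fct, pillai = V, approx_F = Fs, df1 = df1,
               df2 = df2, p_value = max(p, .Machine$double.xmin),
               n_axes = k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Host-phylogeny congruence battery
#'
#' Runs the full congruence analysis for one or both UniFrac metrics:
#' collapse the table by group, build the UPGMA dendrogram (with optional
#' jackknife supports), compute the normalized Robinson-Foulds distance
#' to the host tree and its random-topology null p-value (overall and,
#' when localities hold at least three groups each, per locality), run a
#' partial Mantel test of host patristic distances against the group
#' UniFrac matrix controlling for locality (binary same/different
#' locality matrix), and a PVR MANOVA of dendrogram structure on locality
#' and microhabitat.
#'
#' @param table Rarefied [otu_table()] of skin samples.
#' @param metadata Metadata with `sample_id`, the grouping column,
#'   `locality` and `microhabitat`.
#' @param bacterial_tree Bacterial [ape::phylo] over the OTUs.
#' @param host_tree Host [ape::phylo]; its tips must include every group.
#' @param group_factor Metadata column defining groups (default
#'   `"species"`).
#' @param metrics UniFrac metrics to run.
#' @param n_random Random trees for the nRF null.
#' @param n_jackknife Jackknife replicates (0 skips supports).
#' @param depth_fraction Jackknife subsampling fraction.
#' @param n_perm Permutations for the partial Mantel test.
#' @param seed RNG seed.
#' @return A `congruence_report`: per-metric list with the collapsed
#'   table, dendrogram, nRF results (overall and per locality), partial
#'   Mantel result and PVR MANOVA table.
#' @export
congruence_pipeline <- function(table, metadata, bacterial_tree, host_tree,
                                group_factor = "species",
                                metrics = c("unweighted_unifrac",
                                            "weighted_unifrac"),
                                n_random = 1000, n_jackknife = 100,
                                depth_fraction = 0.75, n_perm = 999,
                                seed = NULL) {
  md <- align_metadata(metadata, sample_ids(table))
  if ("sample_type" %in% names(md) && any(md$sample_type != "skin")) {
    keep <- md$sample_id[md$sample_type == "skin"]
    table <- subset_otu_table(table, samples = keep)
    md <- align_metadata(md, keep)
  }
  groups <- sort(unique(as.character(md[[group_factor]])))
  miss <- setdiff(groups, host_tree$tip.label)
  if (length(miss))
    stop("host tree missing groups: ", paste(miss, collapse = ", "))
  host <- ape::keep.tip(host_tree, groups)
  # factor levels per group (species nested in locality/microhabitat)
  gmap <- unique(md[, c(group_factor, "locality", "microhabitat")])
  if (anyDuplicated(gmap[[group_factor]]))
    stop("groups must map to a single locality and microhabitat")
  rownames(gmap) <- gmap[[group_factor]]
  gmap <- gmap[groups, , drop = FALSE]
  loc <- stats::setNames(as.character(gmap$locality), groups)
  ctrl <- outer(loc, loc, FUN = function(x, y) as.numeric(x != y))
  dimnames(ctrl) <- list(groups, groups)
  host_d <- patristic_distances(host)[groups, groups]

  seed_k <- 0L
  next_seed <- function() {
    if (is.null(seed)) return(NULL)
    seed_k <<- seed_k + 1L
    seed + seed_k
  }

  per_metric <- lapply(metrics, function(metric) {
    collapsed <- collapse_by_group(table, md, group_factor)
    if (n_jackknife > 0) {
      jk <- jackknife_support(table, md, group_factor, bacterial_tree,
                              metric = metric,
                              depth_fraction = depth_fraction,
                              n_reps = n_jackknife, seed = next_seed())
      dendro <- jk$tree
      supports <- jk$supports
    } else {
      dmg <- beta_diversity_matrix(collapsed, bacterial_tree, metric)
      dendro <- upgma(dmg)
      supports <- NULL
    }
    dm_groups <- beta_diversity_matrix(collapsed, bacterial_tree, metric)
    nrf <- robinson_foulds_normalized(dendro, host)
    null <- random_tree_null(host, nrf, n_random = n_random,
                             seed = next_seed())
    by_locality <- list()
    for (l in unique(loc)) {
      gl <- groups[loc == l]
      if (length(gl) >= 3) {
        sub_d <- upgma_subtree(dendro, gl)
        sub_h <- ape::keep.tip(host, gl)
        nrf_l <- robinson_foulds_normalized(sub_d, sub_h)
        by_locality[[l]] <- random_tree_null(sub_h, nrf_l,
                                             n_random = n_random,
                                             seed = next_seed())
      }
    }
    mantel <- partial_mantel(host_d, dm_groups[groups, groups], ctrl,
                             n_perm = n_perm, seed = next_seed())
    pvr <- tryCatch(
      pvr_manova(dendro, gmap[, c("locality", "microhabitat")]),
      error = function(e) conditionMessage(e))
    list(metric = metric, collapsed = collapsed, dendrogram = dendro,
         supports = supports, nrf = nrf, null = null,
         by_locality = by_locality, partial_mantel = mantel, pvr = pvr)
  })
  names(per_metric) <- metrics
  structure(list(groups = groups, host_tree = host, metrics = per_metric),
            class = "congruence_report")
}

# Restrict a dendrogram to a tip subset (drop others, keep topology).
upgma_subtree <- function(tree, tips) {
  ape::keep.tip(tree, tips)
}

#' @export
print.congruence_report <- function(x, ...) {
  cat(sprintf("congruence_report over %d groups\n", length(x$groups)))
  for (m in names(x$metrics)) {
    r <- x$metrics[[m]]
    cat(sprintf("  %s: nRF = %.3f (null p = %.3g), partial Mantel r = %.3f (p = %.3g)\n",
                m, r$nrf, r$null$p_value, r$partial_mantel$statistic,
                r$partial_mantel$p_value))
  }
  invisible(x)
}
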