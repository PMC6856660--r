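# Independent oracles used across the suite. These deliberately avoid the
# package's internal code paths (postorder edge-mass accumulation, clade
# hashing): each one recomputes the quantity the slow, obvious way.

# Tip labels descending from a node, by naive recursive descent.
oracle_desc_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, oracle_desc_tips, tree = tree))
}

# Per-branch brute-force UniFrac for a pair of named abundance vectors.
oracle_unifrac <- function(a, b, tree, weighted = FALSE,
                           normalized = FALSE) {
  ids <- union(names(a), names(b))
  av <- stats::setNames(numeric(length(ids)), ids); av[names(a)] <- a
  bv <- stats::setNames(numeric(length(ids)), ids); bv[names(b)] <- b
  pa <- av / sum(av); pb <- bv / sum(bv)
  num <- 0; den <- 0
  for (k in seq_len(nrow(tree$edge))) {
    tips <- oracle_desc_tips(tree, tree$edge[k, 2])
    tips <- intersect(tips, ids)
    wa <- sum(pa[tips]); wb <- sum(pb[tips])
    ca <- sum(av[tips]) > 0; cb <- sum(bv[tips]) > 0
    len <- tree$edge.length[k]
    if (weighted) {
      num <- num + len * abs(wa - wb)
      den <- den + len * (wa + wb)
    } else {
      num <- num + len * as.numeric(xor(ca, cb))
      den <- den + len * as.numeric(ca || cb)
    }
  }
  if (weighted && !normalized) return(num)
  if (den == 0) return(0)
  num / den
}

# All rooted binary labeled topologies over a label set, as nested lists.
# A leaf is a character scalar; an internal node is list(left, right).
enumerate_topologies <- function(labels) {
  attach_all <- function(tr, lab) {
    out <- list(list(tr, lab))
    if (is.list(tr)) {
      for (sub in attach_all(tr[[1]], lab))
        out <- c(out, list(list(sub, tr[[2]])))
      for (sub in attach_all(tr[[2]], lab))
        out <- c(out, list(list(tr[[1]], sub)))
    }
    out
  }
  trees <- list(list(labels[1], labels[2]))
  for (lab in labels[-(1:2)])
    trees <- unlist(lapply(trees, attach_all, lab = lab),
                    recursive = FALSE)
  trees
}

nested_to_newick <- function(tr) {
  f <- function(x) if (is.character(x)) x else
    sprintf("(%s,%s)", f(x[[1]]), f(x[[2]]))
  paste0(f(tr), ";")
}

# ANOSIM R computed directly from first principles for a labeling.
oracle_anosim_R <- function(dm, g) {
  n <- nrow(dm)
  r <- rank(dm[lower.tri(dm)])
  idx <- which(lower.tri(dm), arr.ind = TRUE)
  within <- g[idx[, 1]] == g[idx[, 2]]
  m <- length(r)
  (mean(r[!within]) - mean(r[within])) / (m / 2)
}

# Exact permutation p over all distinct two-group assignments.
exact_two_group_p <- function(values_or_dm, g, stat_fun) {
  n <- length(g)
  lv <- unique(g)
  k <- sum(g == lv[1])
  obs <- stat_fun(g)
  combs <- utils::combn(n, k)
  stats <- apply(combs, 2, function(sel) {
    gg <- rep(lv[2], n); gg[sel] <- lv[1]
    stat_fun(gg)
  })
  mean(stats >= obs - 1e-12)
}

# Small random ultrametric tree over given tip labels (for fixtures).
random_fixture_tree <- function(labels, seed) {
  phylosym:::with_seed_(seed, {
    tr <- ape::rcoal(length(labels))
    tr$tip.label <- labels
    tr
  })
}
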