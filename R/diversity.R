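#' Shannon diversity index
#'
#' `H = -sum p_i log(p_i)` over positive proportions. Base 2 by default;
#' the base is part of the reported value, so it is an explicit argument.
#'
#' @param counts Non-negative numeric vector with positive total.
#' @param log_base Logarithm base (default 2).
#' @return Shannon index (numeric scalar).
#' @examples
#' shannon(c(10, 10, 10, 10))  # 2 bits
#' @export
shannon <- function(counts, log_base = 2) {
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  tot <- sum(counts)
  if (tot <= 0) stop("counts must have positive total")
  p <- counts[counts > 0] / tot
  -sum(p * log(p, base = log_base))
}

# Per-edge descendant mass for a set of samples.
# counts: samples x OTUs matrix (column names are tip labels or a subset).
# Returns list(edge_mass = samples x edges matrix, lengths, tree).
edge_masses <- function(counts, tree) {
  extra <- setdiff(colnames(counts)[colSums(counts) > 0], tree$tip.label)
  if (length(extra))
    stop("OTUs not in tree: ", paste(utils::head(extra, 5), collapse = ", "))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ntip <- length(tree$tip.label)
  tr <- stats::reorder(tree, "postorder")
  nnode <- ntip + tr$Nnode
  m <- matrix(0, nrow(counts), nnode)
  hit <- intersect(colnames(counts), tr$tip.label)
  m[, match(hit, tr$tip.label)] <- counts[, hit, drop = FALSE]
  for (k in seq_len(nrow(tr$edge)))
    m[, tr$edge[k, 1L]] <- m[, tr$edge[k, 1L]] + m[, tr$edge[k, 2L]]
  list(edge_mass = m[, tr$edge[, 2L], drop = FALSE],
       lengths = tr$edge.length)
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree connecting the present tips
#' to the root (root-inclusive, so PD of a single tip is its root-to-tip
#' path length).
#'
#' @param presence_set Character vector of present tip labels (nonempty).
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @return PD (numeric scalar).
#' @export
faith_pd <- function(presence_set, tree) {
  if (length(presence_set) == 0) stop("presence_set must be nonempty")
  miss <- setdiff(presence_set, tree$tip.label)
  if (length(miss))
    stop("tip not in tree: ", paste(miss, collapse = ", "))
  cts <- matrix(1, 1, length(presence_set),
                dimnames = list("s", unique(presence_set)))
  em <- edge_masses(cts, tree)
  sum(em$lengths[em$edge_mass[1, ] > 0])
}

#' Pairwise UniFrac distances
#'
#' `unweighted_unifrac()` is the fraction of branch length unique to one
#' sample's observed subtree over the branch length of the union subtree
#' (composition). `weighted_unifrac()` is
#' `sum_i b_i |p_i^A - p_i^B|` over branches, where `p_i^X` is the
#' fraction of sample X's reads descending from branch `i` (structure);
#' with `normalized = TRUE` it is divided by `sum_i b_i (p_i^A + p_i^B)`.
#'
#' @param sample_a,sample_b Named non-negative count (or relative
#'   abundance) vectors; names are tips of `tree`.
#' @param tree Rooted [ape::phylo] with branch lengths.
#' @param normalized Whether to normalize the weighted distance into
#'   `[0, 1]`.
#' @return Distance (numeric scalar).
#' @export
unweighted_unifrac <- function(sample_a, sample_b, tree) {
  m <- two_sample_matrix(sample_a, sample_b)
  if (all(m == 0)) stop("both samples are empty")
  em <- edge_masses(m, tree)
  pa <- em$edge_mass[1, ] > 0
  pb <- em$edge_mass[2, ] > 0
  union <- sum(em$lengths[pa | pb])
  if (union == 0) return(0)
  sum(em$lengths[xor(pa, pb)]) / union
}

#' @rdname unweighted_unifrac
#' @export
weighted_unifrac <- function(sample_a, sample_b, tree, normalized = FALSE) {
  m <- two_sample_matrix(sample_a, sample_b)
  tot <- rowSums(m)
  if (any(tot <= 0)) stop("each sample must have a positive total")
  m <- m / tot
  em <- edge_masses(m, tree)
  raw <- sum(em$lengths * abs(em$edge_mass[1, ] - em$edge_mass[2, ]))
  if (!normalized) return(raw)
  denom <- sum(em$lengths * (em$edge_mass[1, ] + em$edge_mass[2, ]))
  if (denom == 0) return(0)
  raw / denom
}

two_sample_matrix <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b)))
    stop("samples must be named vectors of tip abundances")
  ids <- union(names(a), names(b))
  m <- matrix(0, 2, length(ids), dimnames = list(c("a", "b"), ids))
  m[1, names(a)] <- a
  m[2, names(b)] <- b
  m
}

#' Beta-diversity distance matrix
#'
#' Computes all pairwise UniFrac distances over the samples of a table in
#' a single pass (per-branch masses are accumulated once), consistent with
#' the pairwise operations.
#'
#' @param table An [otu_table()] (or a plain samples x OTUs matrix of
#'   abundances, e.g. a group-collapsed relative-abundance table).
#' @param tree Rooted [ape::phylo] over the OTUs.
#' @param metric `"unweighted_unifrac"` or `"weighted_unifrac"`.
#' @param normalized Normalization flag for the weighted metric.
#' @return Symmetric distance matrix with sample labels.
#' @export
beta_diversity_matrix <- function(table, tree,
                                  metric = c("unweighted_unifrac",
                                             "weighted_unifrac"),
                                  normalized = FALSE) {
  metric <- match.arg(metric)
  counts <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  n <- nrow(counts)
  if (n == 0) stop("table has no samples")
  em <- edge_masses(counts, tree)
  b <- em$lengths
  dm <- matrix(0, n, n, dimnames = list(rownames(counts), rownames(counts)))
  if (metric == "unweighted_unifrac") {
    pres <- em$edge_mass > 0
    if (any(rowSums(pres) == 0)) stop("empty sample in table")
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      pa <- pres[i, ]; pb <- pres[j, ]
      union <- sum(b[pa | pb])
      d <- if (union == 0) 0 else sum(b[xor(pa, pb)]) / union
      dm[i, j] <- dm[j, i] <- d
    }
  } else {
    tot <- rowSums(counts)
    if (any(tot <= 0)) stop("empty sample in table")
    pm <- em$edge_mass / tot
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      raw <- sum(b * abs(pm[i, ] - pm[j, ]))
      if (normalized) {
        denom <- sum(b * (pm[i, ] + pm[j, ]))
        raw <- if (denom == 0) 0 else raw / denom
      }
      dm[i, j] <- dm[j, i] <- raw
    }
  }
  dm
}

#' Alpha diversity per sample
#'
#' Faith's PD and Shannon (base 2 by default) for every sample of a table.
#'
#' @param table An [otu_table()].
#' @param tree Rooted [ape::phylo] over the OTUs.
#' @param log_base Shannon logarithm base.
#' @return Data frame with columns `sample_id`, `pd`, `shannon`.
#' @export
alpha_diversity <- function(table, tree, log_base = 2) {
  em <- edge_masses(table$counts, tree)
  pd <- as.vector((em$edge_mass > 0) %*% em$lengths)
  sh <- apply(table$counts, 1, shannon, log_base = log_base)
  data.frame(sample_id = sample_ids(table), pd = pd, shannon = sh,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: eigendecomposition of the Gower-centered
#' squared-distance matrix. Eigenvalues are returned in descending order
#' (negative ones are possible for non-Euclidean distances and are
#' reported, not silently dropped); coordinates use the top positive
#' axes.
#'
#' @param dm Distance matrix.
#' @param n_axes Number of axes requested; clamped to `n - 1` with a
#'   warning if larger.
#' @return List with `coordinates` (n x k matrix) and `eigenvalues`
#'   (length n).
#' @export
pcoa <- function(dm, n_axes = 2) {
  dm <- check_dist_matrix(dm)
  n <- nrow(dm)
  if (n_axes > n - 1) {
    warning("n_axes clamped to n - 1")
    n_axes <- max(n - 1, 1)
  }
  g <- gower_center(dm)
  eg <- eigen(g, symmetric = TRUE)
  k <- min(n_axes, n)
  lam <- pmax(eg$values[seq_len(k)], 0)
  coords <- eg$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
  rownames(coords) <- rownames(dm)
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coordinates = coords, eigenvalues = eg$values)
}
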