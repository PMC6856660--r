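# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream. seed = NULL means "use the current stream".
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_dist_matrix <- function(dm, arg = "dm") {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm)) stop(arg, " must be a square matrix")
  if (is.null(rownames(dm))) stop(arg, " must carry sample labels")
  if (anyNA(dm)) stop(arg, " contains NA/NaN values")
  if (max(abs(dm - t(dm))) > 1e-8) stop(arg, " must be symmetric")
  if (any(abs(diag(dm)) > 1e-12)) stop(arg, " must have a zero diagonal")
  if (any(dm < -1e-12)) stop(arg, " entries must be non-negative")
  colnames(dm) <- rownames(dm)
  dm
}

# Index pairs (i > j) of the strict lower triangle, in column-major order
# matching dm[lower.tri(dm)].
lower_pairs <- function(n) {
  idx <- which(lower.tri(diag(n)), arr.ind = TRUE)
  list(i = idx[, 1L], j = idx[, 2L])
}

# Gower-centered inner-product matrix from a distance matrix:
# G = -(1/2) C D^2 C with C the centering matrix.
gower_center <- function(dm) {
  a <- -0.5 * dm^2
  rm <- rowMeans(a)
  sweep(sweep(a, 1L, rm), 2L, rm) + mean(a)
}

# Add-one permutation p-value.
perm_pvalue <- function(perm_stats, observed) {
  (1 + sum(perm_stats >= observed - 1e-12)) / (length(perm_stats) + 1)
}

write_tsv_ <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_ <- function(path) {
  utils::read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Permutation/rank test result
#'
#' Lightweight container for the outcome of a single hypothesis test
#' (ANOSIM `R`, PERMANOVA pseudo-`F`, Kruskal-Wallis `H`, permutation `t`,
#' partial Mantel `r`, Pillai's trace).
#'
#' @param statistic_name One of `"R"`, `"pseudo_F"`, `"H"`, `"t"`,
#'   `"r_partial"`, `"pillai"`.
#' @param statistic Observed value of the statistic.
#' @param p_value P-value in `(0, 1]`; for permutation tests the add-one
#'   rule `(b + 1) / (m + 1)` guarantees it never reaches zero.
#' @param n_permutations Number of permutations used (`NA` for analytic
#'   tests).
#' @param effect_size Optional effect size (e.g. PERMANOVA `R^2`).
#' @param seed RNG seed used for the permutations, if any.
#' @param extra Named list of additional fields (degrees of freedom, etc.).
#' @return An object of class `phylosym_test`.
#' @export
test_result <- function(statistic_name, statistic, p_value = NA_real_,
                        n_permutations = NA_integer_, effect_size = NULL,
                        seed = NULL, extra = list()) {
  stopifnot(statistic_name %in% c("R", "pseudo_F", "H", "t", "r_partial",
                                  "pillai"))
  structure(
    c(list(statistic_name = statistic_name,
           statistic = as.numeric(statistic),
           p_value = as.numeric(p_value),
           n_permutations = if (is.na(n_permutations)) NA_integer_
                            else as.integer(n_permutations),
           effect_size = if (is.null(effect_size)) NULL
                         else as.numeric(effect_size),
           seed = seed),
      extra),
    class = "phylosym_test")
}

#' @export
print.phylosym_test <- function(x, ...) {
  cat(sprintf("%s = %.6g", x$statistic_name, x$statistic))
  if (!is.null(x$effect_size)) cat(sprintf(", R2 = %.4g", x$effect_size))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.4g", x$p_value))
  if (!is.na(x$n_permutations))
    cat(sprintf(" (%d permutations)", x$n_permutations))
  cat("\n")
  invisible(x)
}
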