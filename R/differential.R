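#' Discriminant OTUs by linear-discriminant effect size
#'
#' Simplified reimplementation of the LEfSe idea for a single class
#' factor: per-OTU relative abundances (rescaled to the conventional
#' 1e6 scale) are screened with a Kruskal-Wallis test across classes; for
#' survivors the effect size is the log10 of the bootstrap-averaged
#' absolute spread of class means of the (one-dimensional) feature, and
#' only features with effect size strictly greater than `threshold`
#' (default 3.0 on the log10 scale) are reported. There is no subclass /
#' Wilcoxon stage: the designs this package targets have a single class
#' factor per run.
#'
#' @param table An [otu_table()] (rarefied).
#' @param metadata Metadata with `sample_id` and the class column.
#' @param class_factor Metadata column defining the classes (>= 2 classes;
#'   classes with fewer than 3 samples are excluded with a warning).
#' @param alpha Kruskal-Wallis screening level.
#' @param threshold Strict lower bound on the log10 effect size.
#' @param n_boot Bootstrap resamples for the effect-size estimate.
#' @param seed RNG seed.
#' @return Data frame with `otu_id`, `enriched_class`, `lda_score`,
#'   `kw_p` (possibly zero rows), sorted by decreasing score.
#' @export
lda_effect_size <- function(table, metadata, class_factor, alpha = 0.05,
                            threshold = 3.0, n_boot = 30, seed = NULL) {
  md <- align_metadata(metadata, sample_ids(table))
  cls <- droplevels(as.factor(md[[class_factor]]))
  small <- names(which(base::table(cls) < 3))
  if (length(small)) {
    warning("excluding classes with < 3 samples: ",
            paste(small, collapse = ", "))
    keep <- !(cls %in% small)
    table <- subset_otu_table(table, samples = sample_ids(table)[keep])
    cls <- droplevels(cls[keep])
  }
  if (nlevels(cls) < 2) stop("need at least two classes with >= 3 samples")
  rel <- relative_abundance(table) * 1e6
  idx <- split(seq_len(nrow(rel)), cls)

  kw_p <- apply(rel, 2, function(x) {
    if (length(unique(x)) == 1) return(1)
    stats::kruskal.test(x, cls)$p.value
  })
  survivors <- otu_ids(table)[kw_p < alpha]
  if (length(survivors) == 0)
    return(data.frame(otu_id = character(), enriched_class = character(),
                      lda_score = numeric(), kw_p = numeric(),
                      stringsAsFactors = FALSE))
  res <- with_seed_(seed, {
    lapply(survivors, function(o) {
      x <- rel[, o]
      scores <- vapply(seq_len(n_boot), function(b) {
        mu <- vapply(idx, function(ii)
          mean(x[sample(ii, length(ii), replace = TRUE)]), numeric(1))
        spread <- max(mu) - min(mu)
        if (spread > 0) log10(spread) else NA_real_
      }, numeric(1))
      sc <- mean(scores, na.rm = TRUE)
      mu_obs <- vapply(idx, function(ii) mean(x[ii]), numeric(1))
      data.frame(otu_id = o,
                 enriched_class = names(which.max(mu_obs)),
                 lda_score = sc, kw_p = unname(kw_p[o]),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, res)
  out <- out[is.finite(out$lda_score) & out$lda_score > threshold, ,
             drop = FALSE]
  out <- out[order(-out$lda_score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Core microbiota per category
#'
#' For each level of a metadata factor, the OTUs present in at least
#' `prevalence` (default 90%, inclusive) of that level's samples; also
#' reports the intersection across all levels (the shared core).
#'
#' @param table An [otu_table()] (rarefied).
#' @param metadata Metadata with `sample_id` and the category column.
#' @param category_factor Metadata column defining categories.
#' @param prevalence Within-category prevalence threshold (inclusive).
#' @return A `core_sets` list: `per_category` (named list of OTU id
#'   vectors), `shared` (intersection across categories) and
#'   `prevalence`.
#' @export
core_otus <- function(table, metadata, category_factor, prevalence = 0.90) {
  md <- align_metadata(metadata, sample_ids(table))
  cats <- droplevels(as.factor(md[[category_factor]]))
  if (any(base::table(cats) == 0) || nlevels(cats) == 0)
    stop("empty category")
  pres <- table$counts > 0
  per <- lapply(levels(cats), function(lv) {
    sel <- cats == lv
    prev <- colMeans(pres[sel, , drop = FALSE])
    otu_ids(table)[prev >= prevalence - 1e-12]
  })
  names(per) <- levels(cats)
  structure(list(per_category = per,
                 shared = Reduce(intersect, per),
                 prevalence = prevalence),
            class = "core_sets")
}

#' @export
print.core_sets <- function(x, ...) {
  cat(sprintf("core_sets at prevalence >= %.0f%%:\n", 100 * x$prevalence))
  for (nm in names(x$per_category))
    cat(sprintf("  %s: %d OTUs\n", nm, length(x$per_category[[nm]])))
  cat(sprintf("  shared across all: %d OTUs\n", length(x$shared)))
  invisible(x)
}
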