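#' Remove chloroplast and mitochondrial OTUs
#'
#' Drops every OTU whose taxonomy string contains a chloroplast or
#' mitochondria token at any rank (case-insensitive; both "mitochondria"
#' and "mitochondrion" spellings match). OTUs without taxonomy are kept.
#'
#' @param table An [otu_table()] with taxonomy.
#' @return Filtered `otu_table`.
#' @export
remove_organelle_otus <- function(table) {
  if (is.null(table$taxonomy)) stop("table has no taxonomy")
  bad <- grepl("chloroplast|mitochondri", table$taxonomy,
               ignore.case = TRUE)
  bad[is.na(bad)] <- FALSE
  if (!any(bad)) return(table)
  subset_otu_table(table, otus = otu_ids(table)[!bad])
}

#' Remove rare OTUs
#'
#' Drops OTUs whose total count across all samples is strictly less than
#' `min_fraction` of the grand total (default 0.001% = 1e-5). Applied to
#' the pre-rarefaction table over all sample types jointly.
#'
#' @param table An [otu_table()].
#' @param min_fraction Strict lower bound on the OTU's share of the grand
#'   total; an OTU at exactly the threshold is retained.
#' @return Filtered `otu_table`.
#' @export
remove_rare_otus <- function(table, min_fraction = 1e-5) {
  totals <- colSums(table$counts)
  grand <- sum(as.numeric(totals))
  if (grand <= 0) stop("table has zero total count")
  keep <- (totals / grand) >= min_fraction - 1e-15
  subset_otu_table(table, otus = otu_ids(table)[keep])
}

#' Identify contaminant OTUs from negative controls
#'
#' An OTU present in at least one control sample is flagged as a
#' contaminant iff its prevalence in controls is at least its prevalence
#' in skin samples AND its mean per-sample relative abundance in controls
#' is at least that in skin, OR a Kruskal-Wallis test on per-sample
#' relative abundances (controls vs skin) is significant at `alpha` with
#' the control mean rank above the skin mean rank. OTUs absent from every
#' control are never flagged: cross-contamination from true samples into
#' controls means control presence alone is not evidence of contamination.
#'
#' @param table An [otu_table()].
#' @param metadata Sample metadata with `sample_id` and `sample_type`
#'   columns; must label at least one `control` and one `skin` sample
#'   present in the table.
#' @param alpha Significance level for the directional Kruskal-Wallis arm.
#' @return A `contaminant_report`: list with `flagged` (character vector)
#'   and `per_otu` (data frame of prevalences, mean relative abundances,
#'   KW statistic/p and the flagging `reason`:
#'   `"prevalence+abundance"`, `"prevalence+kw"` or `"not_flagged"`).
#' @export
identify_contaminants <- function(table, metadata, alpha = 0.05) {
  md <- align_metadata(metadata, sample_ids(table))
  ctrl <- md$sample_id[md$sample_type == "control"]
  skin <- md$sample_id[md$sample_type == "skin"]
  if (length(ctrl) == 0) stop("no control samples in table")
  if (length(skin) == 0) stop("no skin samples in table")
  rel <- relative_abundance(table)
  rel_c <- rel[ctrl, , drop = FALSE]
  rel_s <- rel[skin, , drop = FALSE]
  prev_c <- colMeans(rel_c > 0)
  prev_s <- colMeans(rel_s > 0)
  mean_c <- colMeans(rel_c)
  mean_s <- colMeans(rel_s)

  cand <- otu_ids(table)[prev_c > 0]
  res <- data.frame(otu_id = cand,
                    prevalence_control = prev_c[cand],
                    prevalence_skin = prev_s[cand],
                    mean_relabund_control = mean_c[cand],
                    mean_relabund_skin = mean_s[cand],
                    kw_statistic = NA_real_, kw_p = NA_real_,
                    reason = "not_flagged",
                    stringsAsFactors = FALSE, row.names = NULL)
  for (r in seq_len(nrow(res))) {
    o <- res$otu_id[r]
    if (res$prevalence_control[r] < res$prevalence_skin[r]) next
    if (res$mean_relabund_control[r] >= res$mean_relabund_skin[r]) {
      res$reason[r] <- "prevalence+abundance"
      next
    }
    x <- c(rel_c[, o], rel_s[, o])
    g <- factor(rep(c("control", "skin"), c(length(ctrl), length(skin))))
    if (length(unique(x)) > 1) {
      kw <- stats::kruskal.test(x, g)
      res$kw_statistic[r] <- unname(kw$statistic)
      res$kw_p[r] <- kw$p.value
      ranks <- rank(x)
      if (!is.na(kw$p.value) && kw$p.value < alpha &&
          mean(ranks[g == "control"]) > mean(ranks[g == "skin"]))
        res$reason[r] <- "prevalence+kw"
    }
  }
  structure(list(flagged = res$otu_id[res$reason != "not_flagged"],
                 per_otu = res, alpha = alpha),
            class = "contaminant_report")
}

#' @export
print.contaminant_report <- function(x, ...) {
  cat(sprintf("contaminant_report: %d of %d control-present OTUs flagged\n",
              length(x$flagged), nrow(x$per_otu)))
  invisible(x)
}

#' Write a contaminant report as TSV
#' @param report A `contaminant_report`.
#' @param path File path.
#' @export
write_contaminant_report <- function(report, path) {
  df <- report$per_otu
  df$flagged <- df$otu_id %in% report$flagged
  write_tsv_(df, path)
  invisible(path)
}

#' Remove flagged contaminant OTUs
#'
#' @param table An [otu_table()].
#' @param report A `contaminant_report` computed from the same table.
#' @return `otu_table` without the flagged OTU columns; samples unchanged.
#' @export
remove_contaminants <- function(table, report) {
  keep <- setdiff(otu_ids(table), report$flagged)
  subset_otu_table(table, otus = keep)
}

#' Rarefy an OTU table to fixed depth
#'
#' Each sample with total count >= `depth` is replaced by a uniform random
#' subsample without replacement summing exactly to `depth`; samples below
#' the depth are dropped. Deterministic for a fixed seed.
#'
#' @param table An [otu_table()].
#' @param depth Target depth per sample (default 3,000 reads).
#' @param seed RNG seed.
#' @return Rarefied `otu_table` whose every row sums to `depth`.
#' @export
rarefy <- function(table, depth = 3000, seed = NULL) {
  if (depth < 1) stop("depth must be positive")
  depth <- as.integer(depth)
  with_seed_(seed, {
    totals <- rowSums(table$counts)
    keep <- sample_ids(table)[totals >= depth]
    counts <- table$counts[keep, , drop = FALSE]
    out <- counts
    for (s in keep) {
      tot <- sum(counts[s, ])
      if (tot == depth) next
      expanded <- rep.int(seq_len(ncol(counts)), counts[s, ])
      picked <- sample(expanded, depth)
      out[s, ] <- tabulate(picked, nbins = ncol(counts))
    }
    otu_table(out, table$taxonomy)
  })
}

#' Full preprocessing chain
#'
#' Applies, in order: organelle removal, rare-OTU removal (0.001% of the
#' grand total, strict), control-based contaminant identification and
#' removal, then rarefaction. Control samples are dropped from the output
#' table after decontamination.
#'
#' @param table An [otu_table()].
#' @param metadata Sample metadata (`sample_id`, `sample_type`).
#' @param depth Rarefaction depth.
#' @param min_fraction Rare-OTU threshold.
#' @param alpha Significance level for the contaminant KW arm.
#' @param seed RNG seed for rarefaction.
#' @return List with the final `table`, the `contaminants` report and a
#'   small `log` of per-stage dimensions.
#' @export
preprocess <- function(table, metadata, depth = 3000, min_fraction = 1e-5,
                       alpha = 0.05, seed = NULL) {
  log <- list(input = dim(table$counts))
  t1 <- remove_organelle_otus(table)
  log$organelle <- dim(t1$counts)
  t2 <- remove_rare_otus(t1, min_fraction)
  log$rare <- dim(t2$counts)
  rep <- identify_contaminants(t2, metadata, alpha)
  t3 <- remove_contaminants(t2, rep)
  log$contaminant <- dim(t3$counts)
  md <- align_metadata(metadata, sample_ids(t3))
  t3 <- subset_otu_table(t3, samples = md$sample_id[md$sample_type != "control"])
  t4 <- rarefy(t3, depth, seed)
  log$rarefied <- dim(t4$counts)
  list(table = t4, contaminants = rep, log = log)
}
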