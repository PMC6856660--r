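#' OTU count table
#'
#' Container for a community count matrix with optional per-OTU taxonomy.
#' Samples are rows, OTUs are columns; counts are non-negative integers.
#' This is the single currency of community data across all pipeline
#' stages (filtering, rarefaction, diversity, inference).
#'
#' @param counts Non-negative integer matrix, samples x OTUs, with unique
#'   row (sample) and column (OTU) names.
#' @param taxonomy Optional named character vector mapping OTU ids to a
#'   semicolon-delimited rank string (e.g. `"k__Bacteria;p__Proteobacteria"`).
#'   Names must be a subset of the OTU ids.
#' @return An object of class `otu_table` with elements `counts` and
#'   `taxonomy`.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("otu1", "otu2")))
#' tab <- otu_table(m, c(otu1 = "k__Bacteria"))
#' n_otus(tab)
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("counts must have sample row names and OTU column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids in counts")
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and free of NA")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy)))
      stop("taxonomy must be a named character vector")
    extra <- setdiff(names(taxonomy), colnames(counts))
    if (length(extra))
      stop("taxonomy refers to unknown OTUs: ",
           paste(utils::head(extra, 5), collapse = ", "))
    taxonomy <- as.character(taxonomy)[match(colnames(counts),
                                             names(taxonomy))]
    names(taxonomy) <- colnames(counts)
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "otu_table")
}

#' @rdname otu_table
#' @param x,table An `otu_table`.
#' @export
n_samples <- function(x) nrow(x$counts)

#' @rdname otu_table
#' @export
n_otus <- function(x) ncol(x$counts)

#' @rdname otu_table
#' @export
sample_ids <- function(x) rownames(x$counts)

#' @rdname otu_table
#' @export
otu_ids <- function(x) colnames(x$counts)

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs (total %s counts)%s\n",
              n_samples(x), n_otus(x),
              format(sum(as.numeric(x$counts)), big.mark = ","),
              if (is.null(x$taxonomy)) "" else ", with taxonomy"))
  invisible(x)
}

#' @rdname otu_table
#' @details `relative_abundance()` divides each sample (row) by its total;
#'   samples with zero total yield a row of zeros.
#' @export
relative_abundance <- function(table) {
  tot <- rowSums(table$counts)
  p <- table$counts / ifelse(tot > 0, tot, 1)
  p[tot == 0, ] <- 0
  p
}

# Subset helper; keeps taxonomy aligned.
subset_otu_table <- function(table, samples = NULL, otus = NULL) {
  counts <- table$counts
  if (!is.null(samples)) counts <- counts[samples, , drop = FALSE]
  if (!is.null(otus)) counts <- counts[, otus, drop = FALSE]
  tax <- table$taxonomy
  if (!is.null(tax)) tax <- tax[colnames(counts)]
  otu_table(counts, tax)
}

#' Read / write OTU tables as TSV
#'
#' On disk the table is transposed to the conventional layout: OTUs as
#' rows, samples as columns, with an optional final `taxonomy` column of
#' semicolon-delimited ranks.
#'
#' @param table An `otu_table`.
#' @param path File path.
#' @return `read_otu_table()` returns an `otu_table`;
#'   `write_otu_table()` returns `path` invisibly.
#' @export
write_otu_table <- function(table, path) {
  m <- t(table$counts)
  df <- data.frame(otu_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(table$taxonomy)) df$taxonomy <- unname(table$taxonomy)
  write_tsv_(df, path)
  invisible(path)
}

#' @rdname write_otu_table
#' @export
read_otu_table <- function(path) {
  df <- read_tsv_(path)
  tax <- NULL
  if ("taxonomy" %in% names(df)) {
    tax <- stats::setNames(as.character(df$taxonomy), df$otu_id)
    df$taxonomy <- NULL
  }
  m <- as.matrix(df[, setdiff(names(df), "otu_id"), drop = FALSE])
  rownames(m) <- df$otu_id
  otu_table(t(m), tax)
}

#' Read / write sample metadata as TSV
#'
#' Metadata is a data frame keyed by `sample_id` with the study factors
#' `sample_type` (`skin`, `environment`, `control`), `species`, `locality`
#' and `microhabitat`.
#'
#' @param metadata Data frame with a `sample_id` column.
#' @param path File path.
#' @export
write_metadata <- function(metadata, path) {
  write_tsv_(metadata, path)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  df <- read_tsv_(path)
  if (!"sample_id" %in% names(df)) stop("metadata must have a sample_id column")
  df
}

# Align metadata rows to the samples of a table (or any vector of ids).
align_metadata <- function(metadata, ids) {
  if (!"sample_id" %in% names(metadata))
    stop("metadata must have a sample_id column")
  m <- match(ids, metadata$sample_id)
  if (anyNA(m))
    stop("metadata is missing samples: ",
         paste(utils::head(ids[is.na(m)], 5), collapse = ", "))
  metadata[m, , drop = FALSE]
}

#' Write a square distance matrix as TSV
#'
#' @param dm Symmetric matrix with sample labels.
#' @param path File path.
#' @export
write_dist_matrix <- function(dm, path) {
  dm <- check_dist_matrix(dm)
  df <- data.frame(sample_id = rownames(dm), dm, check.names = FALSE)
  write_tsv_(df, path)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @export
read_dist_matrix <- function(path) {
  df <- read_tsv_(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  check_dist_matrix(m)
}
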