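# Core data containers and TSV readers/writers.
#
# The pipeline's canonical objects are deliberately light-weight:
#   * cr_counts   -- integer gene x sample matrix with unique dimnames
#   * cr_samples  -- data.frame of sample metadata (treatment/tissue/duration)
#   * cr_features -- samples x features table (numeric gene features + one
#                    categorical "tissue" feature) with the treatment label
#                    attached as an attribute
#   * annotation  -- plain data.frame keyed by gene_id

TREATMENT_LEVELS <- c("control", "CR")
DURATION_LEVELS <- c("short", "long")

#' Construct a validated count matrix
#'
#' @param counts numeric matrix of non-negative integer counts, genes in rows,
#'   samples in columns. Dimnames are required and must be unique.
#' @return an integer matrix of class `cr_counts`
#' @export
count_matrix <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene (row) and sample (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "count for gene '%s', sample '%s' is not a non-negative integer (value: %s)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, , drop = FALSE]])))
  }
  storage.mode(counts) <- "integer"
  structure(counts, class = c("cr_counts", class(matrix())))
}

#' @export
print.cr_counts <- function(x, ...) {
  cat(sprintf("<cr_counts> %d genes x %d samples\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Read a gene x sample count matrix from a delimited text file
#'
#' First column holds gene ids, the header row holds sample ids.
#'
#' @param path file path
#' @param delimiter field delimiter, tab by default
#' @return a `cr_counts` matrix with row/column order preserved
#' @export
read_count_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (nrow(df) == 0 || ncol(df) < 2) stop("no genes parsed from ", path)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count cells in ", path)
  rownames(m) <- genes
  count_matrix(m)
}

#' Write a count matrix as TSV
#' @param cm a `cr_counts` matrix
#' @param path output path
#' @export
write_count_matrix <- function(cm, path) {
  df <- data.frame(gene_id = rownames(cm), cm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample metadata table
#'
#' Required columns: `sample_id`, `treatment` (control/CR), `tissue`,
#' `duration` (short/long).
#'
#' @param path file path
#' @param delimiter field delimiter
#' @return a validated data.frame of class `cr_samples`
#' @export
read_sample_table <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, comment.char = "")
  sample_table(df)
}

#' Validate a sample metadata data.frame
#' @param df data.frame with sample_id, treatment, tissue, duration columns
#' @return the validated data.frame, class `cr_samples`
#' @export
sample_table <- function(df) {
  required <- c("sample_id", "treatment", "tissue", "duration")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("missing required columns: ", paste(missing, collapse = ", "),
         " (required: ", paste(required, collapse = ", "), ")")
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad_tr <- setdiff(unique(df$treatment), TREATMENT_LEVELS)
  if (length(bad_tr) > 0)
    stop("unknown treatment level(s): ", paste(bad_tr, collapse = ", "),
         " (expected: ", paste(TREATMENT_LEVELS, collapse = ", "), ")")
  bad_du <- setdiff(unique(df$duration), DURATION_LEVELS)
  if (length(bad_du) > 0)
    stop("unknown duration level(s): ", paste(bad_du, collapse = ", "))
  df$treatment <- factor(df$treatment, levels = TREATMENT_LEVELS)
  df$tissue <- factor(df$tissue)
  df$duration <- factor(df$duration, levels = DURATION_LEVELS)
  class(df) <- c("cr_samples", "data.frame")
  df
}

#' Write a sample table as TSV
#' @param st a `cr_samples` data.frame
#' @param path output path
#' @export
write_sample_table <- function(st, path) {
  utils::write.table(as.data.frame(st), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table (gene_id, symbol, protein_class)
#' @param path file path
#' @param delimiter field delimiter
#' @return a data.frame with unique gene_id
#' @export
read_annotation_table <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, comment.char = "")
  required <- c("gene_id", "symbol", "protein_class")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("missing required columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicated gene_id in annotation table")
  df
}

#' Assemble the mixed feature table fed to the attribute weighters
#'
#' Samples become rows; each retained gene becomes one numeric feature
#' (default unit log2 CPM, `log2(1e6 * count / library_size + 1)`); the tissue
#' of each sample is appended as a single categorical feature named
#' `"tissue"`; the treatment label travels along as an attribute.
#'
#' @param cm a `cr_counts` matrix
#' @param st a `cr_samples` table covering the same samples
#' @param transform expression unit: `"log2cpm"` (default), `"vst_log"`
#'   (log2 of size-factor-normalized count + 1), or `"none"` (raw counts)
#' @param gene_subset optional character vector of gene ids to retain
#' @return data.frame of class `cr_features`: numeric gene columns plus a
#'   `tissue` factor column; `attr(, "label")` holds the treatment factor
#' @export
build_feature_table <- function(cm, st,
                                transform = c("log2cpm", "vst_log", "none"),
                                gene_subset = NULL) {
  transform <- match.arg(transform)
  st <- if (inherits(st, "cr_samples")) st else sample_table(st)
  if (!setequal(colnames(cm), st$sample_id))
    stop("samples of count matrix and sample table do not match")
  st <- st[match(colnames(cm), st$sample_id), ]
  if (!is.null(gene_subset)) {
    absent <- setdiff(gene_subset, rownames(cm))
    if (length(absent) > 0)
      stop("gene_subset ids absent from count matrix: ",
           paste(absent, collapse = ", "))
    cm <- cm[gene_subset, , drop = FALSE]
  }
  x <- switch(transform,
    log2cpm = {
      lib <- colSums(unclass(cm))
      log2(t(t(unclass(cm)) * 1e6 / pmax(lib, 1)) + 1)
    },
    vst_log = {
      sf <- size_factors(cm)
      log2(t(t(unclass(cm)) / sf) + 1)
    },
    none = unclass(cm) * 1.0
  )
  ft <- as.data.frame(t(x), check.names = FALSE)
  ft$tissue <- factor(st$tissue)
  attr(ft, "label") <- factor(st$treatment, levels = TREATMENT_LEVELS)
  class(ft) <- c("cr_features", "data.frame")
  ft
}

#' Treatment label of a feature table
#' @param ft a `cr_features` table
#' @return factor of treatment labels aligned with rows
#' @export
feature_label <- function(ft) attr(ft, "label")

#' Gene (numeric) feature names of a feature table
#' @param ft a `cr_features` table
#' @return character vector of gene feature names (tissue excluded)
#' @export
gene_features <- function(ft) setdiff(names(ft), "tissue")
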