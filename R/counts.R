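#' Construct a validated gene-by-sample count matrix
#'
#' Bundles an integer count matrix with per-sample class labels. All
#' downstream functions take this container (or the log-normalized matrix
#' derived from it) rather than bare matrices, so validation happens once.
#'
#' @param counts numeric matrix of non-negative integer counts, genes in
#'   rows and samples in columns; must carry rownames (gene IDs) and
#'   colnames (sample IDs), both unique.
#' @param class_labels named character vector mapping every sample ID to a
#'   class name. Labels are keyed by sample ID, never by column position.
#' @return An object of class `"count_matrix"`: a list with elements
#'   `counts` (integer matrix) and `class_labels` (named character vector,
#'   reordered to match the columns).
#' @examples
#' m <- matrix(c(10L, 0L, 7L, 20L, 5L, 7L), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' cm <- count_matrix(m, c(s1 = "A", s2 = "B"))
#' @export
count_matrix <- function(counts, class_labels) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have rownames (gene IDs) and colnames (sample IDs)")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ID: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ID: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric with no missing values")
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid count at gene '%s', sample '%s': %s",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
                 format(counts[bad[1, , drop = FALSE]])))
  storage.mode(counts) <- "integer"
  class_labels <- validate_labels(class_labels, colnames(counts))
  structure(list(counts = counts, class_labels = class_labels),
            class = "count_matrix")
}

validate_labels <- function(class_labels, sample_ids) {
  if (is.null(names(class_labels)))
    stop("'class_labels' must be named by sample ID")
  missing <- setdiff(sample_ids, names(class_labels))
  if (length(missing) > 0)
    stop("no class label for sample(s): ", paste(missing, collapse = ", "))
  stats::setNames(as.character(class_labels[sample_ids]), sample_ids)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$class_labels)
  cat("classes:", paste(sprintf("%s (n=%d)", names(tab), tab),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Read a gene-by-sample count table from a delimited text file
#'
#' Expects a header row of sample IDs and a first column of gene IDs.
#' The delimiter is auto-detected from the header line (tab preferred,
#' comma fallback).
#'
#' @param path path to a TSV or CSV count table.
#' @param labels either a named character vector mapping sample IDs to
#'   class names, or the path to a two-column (sample, class) TSV/CSV
#'   side-car file with or without a header.
#' @return A [count_matrix()].
#' @examples
#' cm <- read_count_table(
#'   system.file("extdata", "toy_counts.tsv", package = "lpecount"),
#'   system.file("extdata", "toy_labels.tsv", package = "lpecount"))
#' cm
#' @export
read_count_table <- function(path, labels) {
  if (!file.exists(path)) stop("count table not found: ", path)
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "#")
  if (ncol(df) < 2) stop("count table needs a gene-ID column plus >= 1 sample")
  gene_ids <- df[[1]]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ID: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  num <- suppressWarnings(
    vapply(df[-1], function(col) as.numeric(col), numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(gene_ids, colnames(df)[-1]))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric count at gene '%s', sample '%s'",
                 gene_ids[bad[1]], colnames(num)[bad[2]]))
  }
  if (is.character(labels) && length(labels) == 1 && is.null(names(labels)))
    labels <- read_class_labels(labels)
  count_matrix(num, labels)
}

#' Read a two-column sample/class label file
#'
#' @param path path to a TSV or CSV file whose first column is the sample
#'   ID and second column the class name. A header line is tolerated.
#' @return Named character vector of class labels.
#' @export
read_class_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = FALSE, sep = sep,
                          colClasses = "character", comment.char = "#")
  if (ncol(df) < 2) stop("label file needs two columns: sample, class")
  # drop a header row if present (first field matches common header names)
  if (tolower(df[1, 1]) %in% c("sample", "sample_id", "id"))
    df <- df[-1, , drop = FALSE]
  stats::setNames(df[[2]], df[[1]])
}

detect_sep <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0 || grepl("\t", lines[1])) "\t" else ","
}

#' Write a differential expression result table
#'
#' Writes the result of [lpe_test()] as a tab-separated file with columns
#' `gene_id`, `median_x`, `median_y`, `var_x`, `var_y`, `z`, `p_value`,
#' `adj_p_value`, `is_de`. Numeric values are written with 15 significant
#' digits so a round trip through [read_de_table()] reproduces them.
#'
#' @param result a `lpe_de` data frame from [lpe_test()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_de_table <- function(result, path) {
  cols <- c("gene_id", "median_x", "median_y", "var_x", "var_y",
            "z", "p_value", "adj_p_value", "is_de")
  if (!all(cols %in% names(result)))
    stop("result is missing columns: ",
         paste(setdiff(cols, names(result)), collapse = ", "))
  out <- result[cols]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.15g", v))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(out) > 0)
    utils::write.table(out, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read back a differential expression result table
#'
#' @param path path written by [write_de_table()].
#' @return data frame with the same columns and types as the
#'   [lpe_test()] result.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("result table not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE,
                          colClasses = c(gene_id = "character"))
  df$is_de <- as.logical(df$is_de)
  df
}
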