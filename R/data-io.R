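#' Construct an expression dataset
#'
#' Bundles a samples-by-genes expression matrix with integer class labels.
#' This is the container every other function in the package consumes:
#' rows are samples, columns are genes, and labels are coded `1..C` with the
#' original label strings kept as `label_levels` (lexicographic coding, so
#' the same input always maps to the same integers).
#'
#' @param matrix Numeric matrix, samples in rows, genes in columns. Row and
#'   column names are used as sample and gene identifiers (generated when
#'   absent). `NA` marks a missing measurement.
#' @param labels Vector of class labels, one per sample. Character or factor
#'   labels are recoded to integers `1..C` in lexicographic order; integer
#'   labels must already be `1..C`.
#' @param label_levels Optional character vector naming the classes behind
#'   integer `labels`.
#' @return An object of class `expression_dataset`: a list with elements
#'   `matrix`, `labels` (integer), `label_levels`, and convenience counts
#'   `n`, `p`, `C`.
#' @examples
#' X <- matrix(rnorm(20), 4, 5)
#' ds <- expression_dataset(X, c("tumour", "normal", "tumour", "normal"))
#' ds$C
#' @export
expression_dataset <- function(matrix, labels, label_levels = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    abort("`matrix` must be a numeric matrix (samples x genes).")
  }
  n <- nrow(matrix)
  p <- ncol(matrix)
  if (length(labels) != n) {
    abort(sprintf("length(labels) is %d but the matrix has %d rows.",
                  length(labels), n))
  }
  if (is.null(rownames(matrix))) rownames(matrix) <- paste0("sample", seq_len(n))
  if (is.null(colnames(matrix))) colnames(matrix) <- paste0("gene", seq_len(p))
  if (anyDuplicated(rownames(matrix))) {
    abort(sprintf("duplicated sample id: %s",
                  rownames(matrix)[duplicated(rownames(matrix))][1]))
  }
  if (anyDuplicated(colnames(matrix))) {
    abort(sprintf("duplicated gene id: %s",
                  colnames(matrix)[duplicated(colnames(matrix))][1]))
  }
  if (anyNA(labels)) abort("labels contain missing values.")
  if (is.numeric(labels) && !is.factor(labels)) {
    y <- as.integer(labels)
    if (is.null(label_levels)) label_levels <- as.character(sort(unique(y)))
    if (!all(y %in% seq_along(label_levels))) {
      abort("integer labels must lie in 1..C.")
    }
  } else {
    lev <- sort(unique(as.character(labels)))
    y <- match(as.character(labels), lev)
    label_levels <- lev
  }
  C <- length(unique(y))
  if (C < 2) abort("labels must take at least 2 distinct values.")
  if (min(table(y)) < 2) {
    warn("some class has fewer than 2 samples; stratified splitting will fail.")
  }
  structure(
    list(matrix = matrix, labels = y, label_levels = label_levels,
         n = n, p = p, C = C),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d samples x %d genes, %d classes (%s)\n",
              x$n, x$p, x$C,
              paste(x$label_levels, collapse = ", ")))
  counts <- table(factor(x$labels, levels = seq_len(x$C)))
  cat("  class sizes:", paste(counts, collapse = "/"), "\n")
  invisible(x)
}

# keep a dataset's invariants intact after column subsetting
subset_genes <- function(ds, keep) {
  m <- ds$matrix[, keep, drop = FALSE]
  if (ncol(m) == 0L) abort("no genes left in dataset.", class = "isoga_empty_dataset")
  expression_dataset(m, ds$labels, ds$label_levels)
}

detect_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix with class labels
#'
#' Reads a delimited text file (CSV or TSV, auto-detected from the extension)
#' holding an expression matrix with one header row of ids and one leading id
#' column. Labels come either from a designated column of the matrix file or
#' from a separate two-column file (`sample_id<TAB>label`). Empty cells and
#' the string `NA` are read as missing values.
#'
#' @param path Path to the expression matrix file.
#' @param orientation `"samples_x_genes"` (default) or `"genes_x_samples"`;
#'   the latter is transposed on read so the returned matrix always has
#'   samples in rows.
#' @param label_column Name of a matrix column holding the class labels.
#' @param label_file Path to a two-column label file. Exactly one of
#'   `label_column` / `label_file` must be given.
#' @param delim Field delimiter; overrides extension-based detection.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path,
                            orientation = c("samples_x_genes", "genes_x_samples"),
                            label_column = NULL, label_file = NULL,
                            delim = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(label_column) == is.null(label_file)) {
    abort("give exactly one of `label_column` or `label_file`.")
  }
  sep <- detect_delim(path, delim)
  raw <- read.delim(path, sep = sep, header = TRUE, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicated id in first column: %s", ids[duplicated(ids)][1]))
  }
  body <- raw[, -1, drop = FALSE]
  labels <- NULL
  if (!is.null(label_column)) {
    if (orientation != "samples_x_genes") {
      abort("`label_column` requires samples_x_genes orientation.")
    }
    if (!label_column %in% names(body)) {
      abort(sprintf("label column '%s' not found.", label_column))
    }
    labels <- body[[label_column]]
    body <- body[, setdiff(names(body), label_column), drop = FALSE]
  }
  # every remaining cell must be numeric or missing; report coordinates
  mat <- as.matrix(body)
  num <- suppressWarnings(array(as.numeric(mat), dim = dim(mat)))
  bad <- which(is.na(num) & !is.na(mat), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-numeric value '%s' at row %d, column '%s'.",
                  mat[bad[1, 1], bad[1, 2]], bad[1, 1], colnames(body)[bad[1, 2]]))
  }
  dimnames(num) <- list(ids, colnames(body))
  if (orientation == "genes_x_samples") num <- t(num)
  if (!is.null(label_file)) {
    lab <- read.delim(label_file, sep = detect_delim(label_file, delim),
                      header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE)
    if (ncol(lab) < 2) abort("label file needs two columns: sample_id, label.")
    idx <- match(rownames(num), as.character(lab[[1]]))
    if (anyNA(idx)) {
      abort(sprintf("label missing for sample '%s'.",
                    rownames(num)[which(is.na(idx))[1]]))
    }
    labels <- lab[[2]][idx]
  }
  if (anyNA(labels)) {
    abort(sprintf("label missing for sample '%s'.",
                  rownames(num)[which(is.na(labels))[1]]))
  }
  expression_dataset(num, labels)
}

#' Write an expression dataset to delimited text
#'
#' Inverse of [read_expression()]: writes the matrix with a leading
#' `sample_id` column plus a trailing `class` column holding the original
#' label strings.
#'
#' @param ds An [expression_dataset()].
#' @param path Output path; delimiter chosen from the extension.
#' @param delim Optional delimiter override.
#' @param include_labels Append a `class` column with the label strings
#'   (set `FALSE` when labels are shipped as a separate file).
#' @return `path`, invisibly.
#' @export
write_expression <- function(ds, path, delim = NULL, include_labels = TRUE) {
  sep <- detect_delim(path, delim)
  df <- data.frame(sample_id = rownames(ds$matrix), ds$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (include_labels) df$class <- ds$label_levels[ds$labels]
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene-selection report
#'
#' Writes a tab-separated report of per-gene selection counts over the
#' bootstrap bags, with a metadata header block (`# key\tvalue` lines) so the
#' run can be reconstructed: neighbourhood size `k`, embedding dimension `d`,
#' inclusion threshold `c`, bag count `B`, and the seed.
#'
#' @param result An `iso_ga_result` from [iso_ga_select()].
#' @param path Output path for the TSV report.
#' @return `path`, invisibly.
#' @seealso [read_selection_report()]
#' @export
write_selection_report <- function(result, path) {
  stopifnot(inherits(result, "iso_ga_result"))
  if (length(result$s_best) == 0L) {
    warn("s_best is empty: report will mark every gene included = FALSE.")
  }
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(k = result$k, d = result$d, c = result$threshold$c,
            B = result$config$bags, seed = result$config$seed)
  writeLines(sprintf("# %s\t%s", names(meta), unname(meta)), con)
  df <- tidy(result)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a gene-selection report
#'
#' @param path Path written by [write_selection_report()].
#' @return A list with `genes` (tibble: `gene_id`, `selection_count`,
#'   `included`) and `meta` (named numeric vector `k`, `d`, `c`, `B`, `seed`).
#' @export
read_selection_report <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- do.call(rbind, strsplit(sub("^# ", "", lines[meta_lines]), "\t"))
  df <- read.delim(text = lines[-meta_lines], sep = "\t",
                   stringsAsFactors = FALSE)
  list(
    genes = tibble::tibble(gene_id = as.character(df$gene_id),
                           selection_count = as.integer(df$selection_count),
                           included = as.logical(df$included)),
    meta = setNames(as.numeric(meta[, 2]), meta[, 1])
  )
}
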