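#' Construct a CountMatrix
#'
#' A `CountMatrix` holds gene-level integer read counts for a set of samples
#' together with per-sample library sizes. Library sizes default to column
#' sums and may be overridden (e.g. with externally computed totals).
#'
#' @param counts integer matrix, genes in rows and samples in columns; must
#'   carry unique rownames (gene ids) and colnames (sample ids).
#' @param lib_sizes optional numeric vector of positive library sizes, one per
#'   sample. Defaults to `colSums(counts)`.
#' @return An object of class `CountMatrix`: a list with elements `counts`
#'   (integer matrix) and `lib_sizes` (named numeric vector).
#' @examples
#' m <- matrix(c(1L, 3L, 2L, 4L), 2, 2,
#'             dimnames = list(c("G1", "G2"), c("S1", "S2")))
#' cm <- count_matrix(m)
#' cm$lib_sizes
#' @export
count_matrix <- function(counts, lib_sizes = NULL) {
  if (!is.matrix(counts)) {
    stop("'counts' must be a matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("'counts' must have rownames (gene ids) and colnames (sample ids)")
  }
  dup_g <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_g)) {
    stop("duplicated gene_id: ", paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_s)) {
    stop("duplicated sample_id: ", paste(dup_s, collapse = ", "))
  }
  if (anyNA(counts)) stop("'counts' contains missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (any(counts != round(counts))) {
    bad <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  storage.mode(counts) <- "integer"
  if (is.null(lib_sizes)) {
    lib_sizes <- colSums(counts)
  }
  if (length(lib_sizes) != ncol(counts)) {
    stop("'lib_sizes' must have one entry per sample")
  }
  if (any(!is.finite(lib_sizes)) || any(lib_sizes <= 0)) {
    stop("'lib_sizes' must be positive and finite")
  }
  lib_sizes <- as.numeric(lib_sizes)
  names(lib_sizes) <- colnames(counts)
  structure(list(counts = counts, lib_sizes = lib_sizes),
            class = "CountMatrix")
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("library sizes:", paste(utils::head(format(x$lib_sizes, trim = TRUE), 5),
                              collapse = " "),
      if (ncol(x$counts) > 5) "..." else "", "\n")
  invisible(x)
}

#' Subset a CountMatrix by gene and/or sample identifiers
#'
#' Library sizes are carried over unchanged (they describe sequencing depth,
#' not the retained gene set).
#'
#' @param cm a [count_matrix()].
#' @param genes,samples character vectors of identifiers to keep; `NULL`
#'   keeps all.
#' @return A `CountMatrix`.
#' @export
subset_counts <- function(cm, genes = NULL, samples = NULL) {
  stopifnot(inherits(cm, "CountMatrix"))
  counts <- cm$counts
  lib <- cm$lib_sizes
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(counts))
    if (length(missing)) {
      stop("unknown gene ids: ", paste(utils::head(missing, 5), collapse = ", "))
    }
    counts <- counts[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(counts))
    if (length(missing)) {
      stop("unknown sample ids: ", paste(utils::head(missing, 5), collapse = ", "))
    }
    counts <- counts[, samples, drop = FALSE]
    lib <- lib[samples]
  }
  count_matrix(counts, lib_sizes = lib)
}

#' Read a gene x sample count table from TSV
#'
#' Expects a header row whose first column is `gene_id` followed by one column
#' per sample; cells must be non-negative integers. Input row and column order
#' is preserved.
#'
#' @param path path to a tab-separated file.
#' @return A [count_matrix()] with `lib_sizes` equal to column sums.
#' @export
read_counts <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1))
  if (ncol(dt) < 2) stop("count table needs a gene_id column plus >=1 sample")
  gene_ids <- dt[[1]]
  mat <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(dt[, -1], 2, as.numeric))),
                 arr.ind = TRUE)
    loc <- if (length(bad)) {
      sprintf(" (first at row %d, column '%s')", bad[1, 1],
              colnames(dt[, -1])[bad[1, 2]])
    } else ""
    stop("non-numeric count cell", loc)
  }
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("missing/non-integer count at row %d, column '%s'",
                 bad[1], colnames(mat)[bad[2]]))
  }
  rownames(mat) <- gene_ids
  count_matrix(mat)
}

#' Write a CountMatrix to TSV
#'
#' Inverse of [read_counts()]; integer cells round-trip exactly.
#'
#' @param cm a [count_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path) {
  stopifnot(inherits(cm, "CountMatrix"))
  dt <- data.table::data.table(gene_id = rownames(cm$counts), cm$counts)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Counts per million, optionally log2
#'
#' CPM is `count / library_size * 1e6`. With `log2 = TRUE` the value is
#' `log2(CPM + pseudocount)`; the default pseudocount 0.5 keeps zeros finite
#' while leaving CPM 1 near zero on the log scale. With pseudocount 0 and
#' library sizes equal to column sums, each sample's raw CPM column sums to
#' exactly 1e6.
#'
#' @param cm a [count_matrix()].
#' @param log2 return log2-transformed values?
#' @param pseudocount non-negative value added before the log transform.
#' @return A numeric matrix (the expression matrix used by the co-expression
#'   models), same dimnames as the counts.
#' @export
compute_cpm <- function(cm, log2 = FALSE, pseudocount = 0.5) {
  stopifnot(inherits(cm, "CountMatrix"))
  if (pseudocount < 0) stop("'pseudocount' must be >= 0")
  cpm <- sweep(cm$counts, 2, cm$lib_sizes, "/") * 1e6
  if (log2) base::log2(cpm + pseudocount) else cpm
}

#' Write a tabular result deterministically
#'
#' Writes any data frame as TSV with a header. Double columns are formatted in
#' scientific notation with 6 significant digits so reruns diff clean;
#' integers and strings are written verbatim.
#'
#' @param x a data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.double(x[[j]])) {
      x[[j]] <- ifelse(is.na(x[[j]]), NA_character_,
                       sprintf("%.5e", x[[j]]))
    }
  }
  ok <- tryCatch({
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path file path.
#' @return A data frame with numeric columns restored.
#' @export
read_table_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
}
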