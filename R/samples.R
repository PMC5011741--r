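#' Construct a sample table
#'
#' Per-sample metadata for the two-group design: tissue type (normal = 0,
#' tumor = 1), age in years, sequencing batch, and optional QC metrics used
#' by [filter_samples()].
#'
#' @param df data frame with columns `sample_id`, `tissue_type` (0/1 or
#'   `"normal"`/`"tumor"`), `age`, `batch`, and optionally
#'   `pct_genes_detected` and `pct_reads_mapped` (fractions in \[0, 1\]).
#' @return A validated data frame of class `SampleTable` with `tissue_type`
#'   coded as integer 0/1.
#' @export
sample_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("sample_id", "tissue_type", "age", "batch")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("sample table lacks columns: ", paste(missing, collapse = ", "))
  }
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) stop("duplicated sample_id: ", paste(dup, collapse = ", "))
  tt <- df$tissue_type
  if (is.character(tt) || is.factor(tt)) {
    tt <- as.character(tt)
    map <- c(normal = 0L, tumor = 1L, "0" = 0L, "1" = 1L)
    if (any(!tt %in% names(map))) {
      stop("tissue_type must be 0/1 or 'normal'/'tumor'")
    }
    tt <- unname(map[tt])
  }
  tt <- as.integer(tt)
  if (any(!tt %in% c(0L, 1L))) stop("tissue_type must be coded 0/1")
  df$tissue_type <- tt
  df$age <- as.numeric(df$age)
  if (anyNA(df$age)) stop("age contains missing values")
  df$batch <- as.character(df$batch)
  for (col in c("pct_genes_detected", "pct_reads_mapped")) {
    if (col %in% names(df)) {
      v <- as.numeric(df[[col]])
      if (any(v < 0 | v > 1, na.rm = TRUE)) {
        stop("'", col, "' must be a fraction in [0, 1]")
      }
      df[[col]] <- v
    }
  }
  class(df) <- c("SampleTable", "data.frame")
  df
}

#' Read a sample table from TSV
#'
#' @param path tab-separated file with the [sample_table()] columns.
#' @return A `SampleTable`.
#' @export
read_samples <- function(path) {
  sample_table(as.data.frame(data.table::fread(path, sep = "\t",
                                               header = TRUE)))
}

#' Write a sample table to TSV
#' @param st a [sample_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(st, path) {
  utils::write.table(as.data.frame(st), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Covariate design matrix for the per-gene and pairwise models
#'
#' Builds `[intercept, tissue, batch indicators, age]` with the first batch
#' as reference. Constant covariate columns (single batch, constant age) are
#' dropped so designs stay full rank; the tissue column is always kept and
#' both tissue levels must be present.
#'
#' @param st a [sample_table()].
#' @param require_both_tissues error unless both tissue levels are present.
#' @return Numeric matrix with one row per sample, rownames = sample ids.
#' @export
build_design <- function(st, require_both_tissues = TRUE) {
  stopifnot(inherits(st, "SampleTable"))
  if (require_both_tissues && length(unique(st$tissue_type)) < 2) {
    stop("both tissue types must be present")
  }
  X <- cbind("(Intercept)" = 1, tissue = st$tissue_type)
  batches <- sort(unique(st$batch))
  if (length(batches) > 1) {
    for (b in batches[-1]) {
      X <- cbind(X, as.numeric(st$batch == b))
      colnames(X)[ncol(X)] <- paste0("batch", b)
    }
  }
  if (stats::var(st$age) > 0) {
    X <- cbind(X, age = st$age)
  }
  rownames(X) <- st$sample_id
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("collinear design columns: ", paste(drop, collapse = ", "))
  }
  X
}
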