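#' @name qc_filters
#' @title Sample- and gene-level quality-control filters
#'
#' @description
#' The filters mirror a standard bulk RNA-seq pre-processing chain and are
#' applied in a fixed order: metric-based sample filters, PCA outlier
#' removal, then the low-expression gene filter. Each filter returns the
#' filtered object together with a `QCReport` recording what was removed and
#' why.
NULL

qc_report <- function(removed_samples = data.frame(sample_id = character(),
                                                   reason = character()),
                      removed_genes = data.frame(gene_id = character(),
                                                 reason = character()),
                      thresholds = list(), pc_scores = NULL) {
  structure(list(removed_samples = removed_samples,
                 removed_genes = removed_genes,
                 thresholds = thresholds,
                 pc_scores = pc_scores),
            class = "QCReport")
}

#' @export
print.QCReport <- function(x, ...) {
  cat("QCReport:", nrow(x$removed_samples), "samples and",
      nrow(x$removed_genes), "genes removed\n")
  invisible(x)
}

#' Filter samples on detection and mapping percentages
#'
#' Removes samples whose fraction of detected genes (count > 0) falls below
#' `min_pct_genes` or whose fraction of reads mapped falls below
#' `min_pct_mapped`. `pct_genes_detected` is computed from the counts when
#' absent from the sample table; `pct_reads_mapped` can only come from
#' metadata, so that rule is skipped with a warning when the column is
#' missing. When a sample fails both rules, low detection is recorded as the
#' primary reason.
#'
#' @param cm a [count_matrix()].
#' @param st a [sample_table()] covering the samples of `cm`.
#' @param min_pct_genes minimum fraction of genes detected (default 0.50).
#' @param min_pct_mapped minimum fraction of reads mapped (default 0.25).
#' @return `list(counts = CountMatrix, samples = SampleTable, report = QCReport)`.
#' @export
filter_samples <- function(cm, st, min_pct_genes = 0.50,
                           min_pct_mapped = 0.25) {
  stopifnot(inherits(cm, "CountMatrix"), inherits(st, "SampleTable"))
  st <- st[match(colnames(cm$counts), st$sample_id), , drop = FALSE]
  if (anyNA(st$sample_id)) stop("sample table does not cover all samples")
  pct_det <- if ("pct_genes_detected" %in% names(st) &&
                 !anyNA(st$pct_genes_detected)) {
    st$pct_genes_detected
  } else {
    colMeans(cm$counts > 0)
  }
  fail_det <- pct_det < min_pct_genes
  fail_map <- rep(FALSE, nrow(st))
  if ("pct_reads_mapped" %in% names(st) && !anyNA(st$pct_reads_mapped)) {
    fail_map <- st$pct_reads_mapped < min_pct_mapped
  } else {
    warning("pct_reads_mapped not available; mapping-rate rule skipped")
  }
  reason <- ifelse(fail_det, "low_detection",
                   ifelse(fail_map, "low_mapping", NA_character_))
  removed <- which(!is.na(reason))
  if (length(removed) == nrow(st)) stop("all samples removed by QC filters")
  report <- qc_report(
    removed_samples = data.frame(sample_id = st$sample_id[removed],
                                 reason = reason[removed]),
    thresholds = list(min_pct_genes = min_pct_genes,
                      min_pct_mapped = min_pct_mapped))
  keep <- st$sample_id[setdiff(seq_len(nrow(st)), removed)]
  st_out <- st[st$sample_id %in% keep, , drop = FALSE]
  class(st_out) <- class(st)
  list(counts = subset_counts(cm, samples = keep), samples = st_out,
       report = report)
}

#' Flag PCA outlier samples
#'
#' PCA is computed by singular value decomposition of the gene-centered
#' log-CPM matrix (samples as observations). A sample is flagged when its
#' score on PC1 or PC2 lies more than `n_sd` robust standard deviations
#' (median +/- n_sd * 1.4826 * MAD) from the median score.
#'
#' @param em numeric expression matrix (genes x samples), typically
#'   `compute_cpm(cm, log2 = TRUE)`.
#' @param n_sd robust z-score cutoff (default 3); `Inf` disables removal.
#' @return `list(retained = character ids, report = QCReport)` with per-sample
#'   PC1/PC2 scores in the report.
#' @export
pca_outlier_filter <- function(em, n_sd = 3.0) {
  if (ncol(em) < 4) stop("PCA outlier filtering needs >= 4 samples")
  centered <- t(em - rowMeans(em))      # samples x genes, gene-centered
  sv <- svd(centered, nu = 2, nv = 0)
  scores <- sv$u %*% diag(sv$d[1:2], 2, 2)
  rownames(scores) <- colnames(em)
  colnames(scores) <- c("PC1", "PC2")
  flag <- rep(FALSE, nrow(scores))
  for (j in 1:2) {
    s <- scores[, j]
    med <- stats::median(s)
    sd_rob <- 1.4826 * stats::mad(s, constant = 1)
    if (sd_rob > 0) {
      flag <- flag | abs(s - med) > n_sd * sd_rob
    }
  }
  removed <- colnames(em)[flag]
  if (length(removed) == ncol(em)) stop("all samples flagged as PCA outliers")
  report <- qc_report(
    removed_samples = data.frame(sample_id = removed,
                                 reason = rep("pca_outlier", length(removed))),
    thresholds = list(n_sd = n_sd),
    pc_scores = as.data.frame(scores))
  list(retained = setdiff(colnames(em), removed), report = report)
}

#' Filter genes below a CPM threshold
#'
#' Keeps genes with CPM >= `cpm_threshold` in at least `min_samples` samples.
#' The default `min_samples` is half (rounded up) of the smaller tissue group
#' when a sample table is supplied, else half of all samples. An optional
#' annotation restricts the filter to chosen biotypes (genes of other
#' biotypes are retained unconditionally).
#'
#' @param cm a [count_matrix()].
#' @param cpm_threshold CPM cutoff (default 1).
#' @param min_samples minimum number of samples at or above the cutoff.
#' @param st optional [sample_table()] used for the `min_samples` default.
#' @param annotation optional [gene_annotation()].
#' @param biotypes biotypes subject to the filter when `annotation` is given.
#' @return `list(counts = CountMatrix, report = QCReport)`.
#' @export
filter_low_expression <- function(cm, cpm_threshold = 1.0, min_samples = NULL,
                                  st = NULL, annotation = NULL,
                                  biotypes = c("lncRNA", "mRNA")) {
  stopifnot(inherits(cm, "CountMatrix"))
  if (is.null(min_samples)) {
    min_samples <- if (!is.null(st)) {
      ceiling(min(table(st$tissue_type)) / 2)
    } else {
      ceiling(ncol(cm$counts) / 2)
    }
  }
  if (min_samples < 1) stop("'min_samples' must be >= 1")
  cpm <- compute_cpm(cm, log2 = FALSE)
  pass <- rowSums(cpm >= cpm_threshold) >= min_samples
  if (!is.null(annotation)) {
    bt <- annotation$biotype[match(rownames(cm$counts), annotation$gene_id)]
    pass <- pass | !(bt %in% biotypes)
  }
  if (!any(pass)) stop("all genes removed by the expression filter")
  report <- qc_report(
    removed_genes = data.frame(gene_id = rownames(cm$counts)[!pass],
                               reason = rep("low_expression", sum(!pass))),
    thresholds = list(cpm_threshold = cpm_threshold,
                      min_samples = min_samples))
  list(counts = subset_counts(cm, genes = rownames(cm$counts)[pass]),
       report = report)
}

#' Run the full QC chain: sample filters, PCA outliers, gene filter
#'
#' @param cm a [count_matrix()].
#' @param st a [sample_table()].
#' @param annotation optional [gene_annotation()] for per-biotype gene
#'   filtering.
#' @param min_pct_genes,min_pct_mapped see [filter_samples()].
#' @param pca_sd see [pca_outlier_filter()] (`Inf` disables).
#' @param cpm_threshold,min_samples see [filter_low_expression()].
#' @return `list(counts, samples, report)` where `report` merges the three
#'   stage reports (fields `samples`, `pca`, `genes`).
#' @export
run_qc <- function(cm, st, annotation = NULL,
                   min_pct_genes = 0.50, min_pct_mapped = 0.25,
                   pca_sd = 3.0, cpm_threshold = 1.0, min_samples = NULL) {
  s1 <- suppressWarnings(filter_samples(cm, st, min_pct_genes,
                                        min_pct_mapped))
  em <- compute_cpm(s1$counts, log2 = TRUE)
  s2 <- pca_outlier_filter(em, n_sd = pca_sd)
  cm2 <- subset_counts(s1$counts, samples = s2$retained)
  st2 <- s1$samples[s1$samples$sample_id %in% s2$retained, , drop = FALSE]
  class(st2) <- class(st)
  s3 <- filter_low_expression(cm2, cpm_threshold, min_samples, st = st2,
                              annotation = annotation)
  list(counts = s3$counts, samples = st2,
       report = list(samples = s1$report, pca = s2$report,
                     genes = s3$report))
}
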