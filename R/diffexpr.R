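#' Empirical-Bayes negative-binomial dispersion estimation
#'
#' Estimates a common dispersion by maximising the summed adjusted profile
#' likelihood over genes and per-gene (tagwise) dispersions by
#' weighted-likelihood shrinkage toward the common value, as implemented in
#' edgeR (the standard empirical-Bayes NB machinery for bulk RNA-seq).
#'
#' @param cm a [count_matrix()].
#' @param design covariate design matrix, e.g. [build_design()]; must be full
#'   rank with >= 2 residual degrees of freedom.
#' @param prior_df prior degrees of freedom controlling shrinkage strength;
#'   `Inf` forces tagwise == common.
#' @return An object of class `DispersionModel`: list with `common` (scalar
#'   phi), `tagwise` (named per-gene phi) and `prior_df`.
#' @export
estimate_dispersions <- function(cm, design, prior_df = 10) {
  stopifnot(inherits(cm, "CountMatrix"))
  qx <- qr(design)
  if (qx$rank < ncol(design)) {
    bad <- colnames(design)[qx$pivot[(qx$rank + 1):ncol(design)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  if (nrow(design) - ncol(design) < 2) {
    stop("need >= 2 residual degrees of freedom")
  }
  y <- edgeR::DGEList(counts = cm$counts, lib.size = cm$lib_sizes)
  y <- edgeR::estimateGLMCommonDisp(y, design)
  if (is.infinite(prior_df)) {
    tagwise <- rep(y$common.dispersion, nrow(cm$counts))
  } else {
    y <- edgeR::estimateGLMTagwiseDisp(y, design, prior.df = prior_df)
    tagwise <- y$tagwise.dispersion
  }
  names(tagwise) <- rownames(cm$counts)
  structure(list(common = y$common.dispersion, tagwise = tagwise,
                 prior_df = prior_df),
            class = "DispersionModel")
}

#' Per-gene differential expression between tissues (NB GLM, LRT)
#'
#' Fits, for every gene, a negative-binomial GLM of counts on tissue type
#' with batch and age covariates and a log-library-size offset, and tests
#' the tissue coefficient by likelihood-ratio (chi-square, df = 1). The
#' reported `log2fc` is the tissue coefficient on the log2 scale
#' (tumor vs normal, tissue coded normal = 0 / tumor = 1).
#'
#' @param cm a [count_matrix()].
#' @param st a [sample_table()] with both tissue levels present.
#' @param disp a [estimate_dispersions()] result, or `NULL` to estimate with
#'   defaults.
#' @return Data frame of class `DEResult` with columns `gene_id`, `log2fc`,
#'   `p_value`, `fdr_p` (BH-adjusted) and `is_de` (`NA` until [call_de()]).
#' @export
fit_model1 <- function(cm, st, disp = NULL) {
  stopifnot(inherits(cm, "CountMatrix"), inherits(st, "SampleTable"))
  st <- st[match(colnames(cm$counts), st$sample_id), , drop = FALSE]
  if (anyNA(st$sample_id)) stop("sample table does not cover all samples")
  class(st) <- c("SampleTable", "data.frame")
  design <- build_design(st)
  if (is.null(disp)) disp <- estimate_dispersions(cm, design)
  y <- edgeR::DGEList(counts = cm$counts, lib.size = cm$lib_sizes)
  fit <- edgeR::glmFit(y, design, dispersion = disp$tagwise)
  lrt <- edgeR::glmLRT(fit, coef = "tissue")
  tab <- lrt$table
  res <- data.frame(gene_id = rownames(cm$counts),
                    log2fc = tab$logFC,
                    p_value = tab$PValue,
                    fdr_p = bh_adjust(tab$PValue),
                    is_de = NA,
                    row.names = NULL)
  class(res) <- c("DEResult", "data.frame")
  res
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR adjustment: `adj_i = min_{j >= rank(i)} (m/j) p_(j)`,
#' capped at 1 (ties need no special handling under the cumulative-minimum
#' form).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Apply the differential-expression significance rule
#'
#' A gene is called DE when its BH-adjusted p-value is below `fdr_threshold`
#' and its absolute log2 fold change is at least `min_abs_log2fc`
#' (two-fold by default).
#'
#' @param results a `DEResult` from [fit_model1()].
#' @param fdr_threshold adjusted-p cutoff (default 0.01).
#' @param min_abs_log2fc fold-change gate on the log2 scale (default 1;
#'   0 disables).
#' @return The `DEResult` with `is_de` set.
#' @export
call_de <- function(results, fdr_threshold = 0.01, min_abs_log2fc = 1.0) {
  stopifnot(is.data.frame(results))
  results$is_de <- results$fdr_p < fdr_threshold &
    abs(results$log2fc) >= min_abs_log2fc
  results
}

#' Full DE stage: dispersion, per-gene fits, BH, significance call
#'
#' @inheritParams fit_model1
#' @inheritParams call_de
#' @param prior_df see [estimate_dispersions()].
#' @return A `DEResult` with `is_de` set.
#' @export
run_de <- function(cm, st, fdr_threshold = 0.01, min_abs_log2fc = 1.0,
                   prior_df = 10) {
  design <- build_design(st[match(colnames(cm$counts), st$sample_id), ,
                            drop = FALSE])
  disp <- estimate_dispersions(cm, design, prior_df = prior_df)
  call_de(fit_model1(cm, st, disp), fdr_threshold, min_abs_log2fc)
}
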