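#' Bonferroni-corrected significance threshold for the pairwise scan
#'
#' The family-wise alpha divided by the number of lncRNA x mRNA pairs
#' scanned. At the scale of a filtered human transcriptome (7,450 lncRNAs x
#' 22,362 mRNAs) this gives 3.0e-10.
#'
#' @param n_lncRNA,n_mRNA gene counts after filtering.
#' @param family_alpha family-wise error rate (default 0.05).
#' @return The per-test threshold, with attribute `display` holding the
#'   one-significant-figure form used for reporting.
#' @export
bonferroni_alpha <- function(n_lncRNA, n_mRNA, family_alpha = 0.05) {
  if (n_lncRNA < 1 || n_mRNA < 1) stop("gene counts must be >= 1")
  alpha <- family_alpha / (as.numeric(n_lncRNA) * as.numeric(n_mRNA))
  attr(alpha, "display") <- signif(alpha, 1)
  alpha
}

## Design matrices for the pairwise models. Model 2 regresses mRNA
## expression on lncRNA expression, tissue, their interaction, batch and
## age; Model 3 drops the interaction. Tissue is coded normal = 0 /
## tumor = 1, so Model 2's lncRNA coefficient is the normal-tissue slope and
## lncRNA + interaction the tumor slope.
pair_designs <- function(x, st) {
  base <- build_design(st)           # intercept, tissue, batch..., age
  covar <- base[, setdiff(colnames(base), c("(Intercept)", "tissue")),
                drop = FALSE]
  tissue <- base[, "tissue"]
  X2 <- cbind("(Intercept)" = 1, x = x, tissue = tissue,
              "x:tissue" = x * tissue, covar)
  X3 <- cbind("(Intercept)" = 1, x = x, tissue = tissue, covar)
  list(X2 = X2, X3 = X3, tissue = tissue)
}

## OLS of one design against a response matrix Y (n x m): shared projection
## through one QR factorisation, per-response residual variance, and the
## t-test of the coefficient named `test_coef`.
ols_scan <- function(X, Y, test_coef) {
  n <- nrow(X)
  p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) stop("collinear pairwise design")
  coefs <- qr.coef(qx, Y)                    # p x m
  resid <- qr.resid(qx, Y)
  df <- n - p
  sigma2 <- colSums(resid^2) / df
  ip <- order(qx$pivot)                      # undo any QR column pivoting
  xtx_inv <- chol2inv(qr.R(qx))[ip, ip]
  j <- match(test_coef, colnames(X))
  se <- sqrt(sigma2 * xtx_inv[j, j])
  tstat <- coefs[j, ] / se
  list(coefs = coefs, se = se,
       p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
       df = df, xtx_inv = xtx_inv, sigma2 = sigma2)
}

#' Fit Models 2 and 3 for a single lncRNA-mRNA pair
#'
#' Model 2 regresses mRNA expression on lncRNA expression, tissue type,
#' their interaction, batch and age; Model 3 drops the interaction. With the
#' default Gaussian family both are ordinary least squares on log2-CPM with
#' two-sided t-tests. With `family = "negative_binomial"` the response is
#' the raw count vector (`y_counts`) fitted through edgeR's NB GLM with a
#' log link and log-library-size offset (dispersion estimated for that
#' response), p-values come from likelihood-ratio tests, coefficients are
#' rescaled to the log2 response scale, and standard errors are not
#' reported (`NA`).
#'
#' A lncRNA that is constant within either tissue cannot support an
#' interaction slope; such fits are returned with `degenerate = TRUE` and
#' missing p-values.
#'
#' @param y response vector: log2-CPM mRNA expression (Gaussian family).
#' @param x log2-CPM lncRNA expression.
#' @param st a [sample_table()].
#' @param family `"gaussian"` or `"negative_binomial"`.
#' @param y_counts integer counts for the NB family.
#' @param lib_sizes library sizes for the NB offset.
#' @return A list of class `PairFit` with elements `b1`, `b3`, `se_b1`,
#'   `se_b3`, `p_interaction`, `slope_normal` (= b1), `slope_tumor`
#'   (= b1 + b3), `b1_m3`, `se_b1_m3`, `p_b1_m3`, `n_used`, `degenerate`.
#' @export
fit_pair <- function(y, x, st, family = c("gaussian", "negative_binomial"),
                     y_counts = NULL, lib_sizes = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(st, "SampleTable"))
  tissue <- st$tissue_type
  if (length(unique(tissue)) < 2) stop("both tissue types must be present")
  v0 <- stats::var(x[tissue == 0])
  v1 <- stats::var(x[tissue == 1])
  if (v0 == 0 || v1 == 0 || stats::var(x) == 0) {
    return(structure(list(b1 = NA_real_, b3 = NA_real_, se_b1 = NA_real_,
                          se_b3 = NA_real_, p_interaction = NA_real_,
                          slope_normal = NA_real_, slope_tumor = NA_real_,
                          b1_m3 = NA_real_, se_b1_m3 = NA_real_,
                          p_b1_m3 = NA_real_, n_used = length(x),
                          degenerate = TRUE), class = "PairFit"))
  }
  if (family == "gaussian") {
    d <- pair_designs(x, st)
    m2 <- ols_scan(d$X2, cbind(y), "x:tissue")
    m3 <- ols_scan(d$X3, cbind(y), "x")
    b1 <- m2$coefs["x", 1]
    b3 <- m2$coefs["x:tissue", 1]
    se_b1 <- sqrt(m2$sigma2[1] * m2$xtx_inv[match("x", colnames(d$X2)),
                                            match("x", colnames(d$X2))])
    fit <- list(b1 = unname(b1), b3 = unname(b3), se_b1 = unname(se_b1),
                se_b3 = unname(m2$se[1]), p_interaction = unname(m2$p[1]),
                slope_normal = unname(b1), slope_tumor = unname(b1 + b3),
                b1_m3 = unname(m3$coefs["x", 1]),
                se_b1_m3 = unname(m3$se[1]), p_b1_m3 = unname(m3$p[1]),
                n_used = length(y), degenerate = FALSE)
  } else {
    if (is.null(y_counts) || is.null(lib_sizes)) {
      stop("the negative-binomial family needs 'y_counts' and 'lib_sizes'")
    }
    d <- pair_designs(x, st)
    ymat <- matrix(as.numeric(y_counts), 1,
                   dimnames = list("y", names(y_counts)))
    off <- log(lib_sizes)
    phi <- edgeR::estimateGLMCommonDisp(ymat, design = d$X2, offset = off)
    fit2 <- edgeR::glmFit(ymat, design = d$X2, dispersion = phi,
                          offset = off)
    lrt2 <- edgeR::glmLRT(fit2, coef = "x:tissue")
    fit3 <- edgeR::glmFit(ymat, design = d$X3, dispersion = phi,
                          offset = off)
    lrt3 <- edgeR::glmLRT(fit3, coef = "x")
    # coefficients are natural-log per unit of log2-CPM x; report on log2
    b1 <- fit2$coefficients[1, "x"] / log(2)
    b3 <- fit2$coefficients[1, "x:tissue"] / log(2)
    fit <- list(b1 = unname(b1), b3 = unname(b3),
                se_b1 = NA_real_, se_b3 = NA_real_,
                p_interaction = lrt2$table$PValue[1],
                slope_normal = unname(b1), slope_tumor = unname(b1 + b3),
                b1_m3 = unname(fit3$coefficients[1, "x"] / log(2)),
                se_b1_m3 = NA_real_,
                p_b1_m3 = lrt3$table$PValue[1],
                n_used = length(y_counts), degenerate = FALSE)
  }
  structure(fit, class = "PairFit")
}

#' Classify one fitted pair into a co-expression pattern
#'
#' Differential co-expression: interaction p-value below the Bonferroni
#' threshold. Dose-response co-expression: not differential, `|b3| <
#' dose_b3_max`, Model-3 slope p-value below the threshold, and at least one
#' member differentially expressed. Differential takes precedence; the
#' `ambiguous` flag records pairs where both rule sets fire. Degenerate fits
#' are null with a flag.
#'
#' @param fit a [fit_pair()] result.
#' @param de_lnc,de_mrna DE flags for the two members.
#' @param alpha_bonf per-test threshold, see [bonferroni_alpha()].
#' @param dose_b3_max effect-size gate on the interaction coefficient for
#'   dose-response calls (default 0.01, on the analysis scale).
#' @return List with `pattern` (`"differential"`, `"dose_response"` or
#'   `"null"`), `ambiguous`, `degenerate` and the individual `criteria`
#'   flags.
#' @export
classify_pair <- function(fit, de_lnc, de_mrna, alpha_bonf,
                          dose_b3_max = 0.01) {
  if (isTRUE(fit$degenerate)) {
    return(list(pattern = "null", ambiguous = FALSE, degenerate = TRUE,
                criteria = list(differential = FALSE, dose = FALSE)))
  }
  is_diff <- is.finite(fit$p_interaction) && fit$p_interaction < alpha_bonf
  is_dose_crit <- is.finite(fit$p_b1_m3) &&
    abs(fit$b3) < dose_b3_max && fit$p_b1_m3 < alpha_bonf &&
    (isTRUE(de_lnc) || isTRUE(de_mrna))
  pattern <- if (is_diff) "differential"
             else if (is_dose_crit) "dose_response"
             else "null"
  list(pattern = pattern, ambiguous = is_diff && is_dose_crit,
       degenerate = FALSE,
       criteria = list(differential = is_diff, dose = is_dose_crit))
}

#' Genome-wide batched scan of all lncRNA x mRNA pairs
#'
#' For each lncRNA the Model-2 and Model-3 design matrices are fixed, so the
#' coefficients for every mRNA are obtained through one shared QR projection
#' with per-mRNA residual variances for the t-statistics; results agree with
#' per-pair [fit_pair()] to numerical precision. lncRNAs that are constant
#' within a tissue are reported as degenerate and their pairs classified
#' null (they stay in the Bonferroni denominator, which is conservative).
#'
#' @param em numeric log2-CPM matrix (genes x samples), e.g.
#'   `compute_cpm(cm, log2 = TRUE)`.
#' @param annotation a [gene_annotation()] partitioning the rows of `em`.
#' @param st a [sample_table()] matching the columns of `em`.
#' @param de optional `DEResult` with `is_de` set ([call_de()]); without it
#'   the dose-response DE gate cannot fire and only differential calls are
#'   possible.
#' @param family_alpha family-wise error rate (default 0.05).
#' @param alpha per-test threshold override; default
#'   `bonferroni_alpha(n_lncRNA, n_mRNA, family_alpha)` over the pairs
#'   actually scanned.
#' @param dose_b3_max see [classify_pair()].
#' @param keep_fits return the full per-pair fit table (`$fits`)? Off by
#'   default: at transcriptome scale the table has one row per pair.
#' @param max_pairs guard against accidental huge scans when `keep_fits` is
#'   on.
#' @return List of class `ScanResult`: `pairs` (data frame of non-null
#'   classifications with coefficients and p-values), `summary` (pattern
#'   counts, test count, thresholds, degenerate lncRNAs, ambiguous count)
#'   and, when `keep_fits`, `fits` with every scanned pair.
#' @export
scan_all_pairs <- function(em, annotation, st, de = NULL,
                           family_alpha = 0.05, alpha = NULL,
                           dose_b3_max = 0.01, keep_fits = FALSE,
                           max_pairs = 2e7) {
  stopifnot(is.matrix(em), inherits(st, "SampleTable"))
  st <- st[match(colnames(em), st$sample_id), , drop = FALSE]
  if (anyNA(st$sample_id)) stop("sample table does not cover all samples")
  class(st) <- c("SampleTable", "data.frame")
  genes <- intersect(rownames(em), annotation$gene_id)
  bt <- annotation$biotype[match(genes, annotation$gene_id)]
  lnc <- genes[bt == "lncRNA"]
  mrna <- genes[bt == "mRNA"]
  if (!length(lnc) || !length(mrna)) {
    stop("need both lncRNA and mRNA genes in the expression matrix")
  }
  n_pairs <- as.numeric(length(lnc)) * length(mrna)
  if (keep_fits && n_pairs > max_pairs) {
    stop("pair count ", format(n_pairs, big.mark = ","),
         " exceeds max_pairs with keep_fits = TRUE")
  }
  if (is.null(alpha)) {
    alpha <- bonferroni_alpha(length(lnc), length(mrna), family_alpha)
  }
  de_flag <- stats::setNames(rep(FALSE, length(genes)), genes)
  if (!is.null(de)) {
    idx <- match(genes, de$gene_id)
    de_flag[!is.na(idx)] <- de$is_de[idx[!is.na(idx)]] %in% TRUE
  }

  tissue <- st$tissue_type
  Y <- t(em[mrna, , drop = FALSE])              # samples x mRNAs
  hits <- vector("list", length(lnc))
  fits <- if (keep_fits) vector("list", length(lnc)) else NULL
  counts <- c(differential = 0, dose_response = 0, null = 0)
  n_ambiguous <- 0L
  degenerate_lnc <- character()

  for (i in seq_along(lnc)) {
    l <- lnc[i]
    x <- em[l, ]
    if (stats::var(x[tissue == 0]) == 0 || stats::var(x[tissue == 1]) == 0) {
      degenerate_lnc <- c(degenerate_lnc, l)
      counts["null"] <- counts["null"] + length(mrna)
      next
    }
    d <- pair_designs(x, st)
    m2 <- ols_scan(d$X2, Y, "x:tissue")
    m3 <- ols_scan(d$X3, Y, "x")
    jx <- match("x", colnames(d$X2))
    b1 <- m2$coefs["x", ]
    b3 <- m2$coefs["x:tissue", ]
    se_b1 <- sqrt(m2$sigma2 * m2$xtx_inv[jx, jx])
    tab <- data.frame(
      lncRNA = l, mRNA = mrna,
      b1 = unname(b1), b3 = unname(b3),
      se_b1 = unname(se_b1), se_b3 = unname(m2$se),
      slope_normal = unname(b1), slope_tumor = unname(b1 + b3),
      p_interaction = unname(m2$p),
      b1_m3 = unname(m3$coefs["x", ]), se_b1_m3 = unname(m3$se),
      p_b1_m3 = unname(m3$p),
      n_used = nrow(Y), row.names = NULL)
    is_diff <- tab$p_interaction < alpha
    is_dose_crit <- abs(tab$b3) < dose_b3_max & tab$p_b1_m3 < alpha &
      (de_flag[l] | de_flag[mrna])
    tab$pattern <- ifelse(is_diff, "differential",
                          ifelse(is_dose_crit, "dose_response", "null"))
    tab$ambiguous <- is_diff & is_dose_crit
    counts["differential"] <- counts["differential"] + sum(is_diff)
    counts["dose_response"] <- counts["dose_response"] +
      sum(!is_diff & is_dose_crit)
    counts["null"] <- counts["null"] + sum(tab$pattern == "null")
    n_ambiguous <- n_ambiguous + sum(tab$ambiguous)
    keep <- tab$pattern != "null"
    if (any(keep)) hits[[i]] <- tab[keep, , drop = FALSE]
    if (keep_fits) fits[[i]] <- tab
  }

  pairs <- do.call(rbind, hits)
  if (is.null(pairs)) {
    pairs <- data.frame(lncRNA = character(), mRNA = character(),
                        b1 = numeric(), b3 = numeric(), se_b1 = numeric(),
                        se_b3 = numeric(), slope_normal = numeric(),
                        slope_tumor = numeric(), p_interaction = numeric(),
                        b1_m3 = numeric(), se_b1_m3 = numeric(),
                        p_b1_m3 = numeric(), n_used = integer(),
                        pattern = character(), ambiguous = logical())
  }
  rownames(pairs) <- NULL
  out <- list(
    pairs = pairs,
    summary = list(n_lncRNA = length(lnc), n_mRNA = length(mrna),
                   n_tests = n_pairs, alpha = as.numeric(alpha),
                   alpha_display = signif(as.numeric(alpha), 1),
                   dose_b3_max = dose_b3_max,
                   pattern_counts = as.list(counts),
                   n_ambiguous = n_ambiguous,
                   degenerate_lncRNA = degenerate_lnc,
                   test_statistic = "two-sided t (Gaussian on log2-CPM)"))
  if (keep_fits) out$fits <- do.call(rbind, fits)
  class(out) <- "ScanResult"
  out
}

#' @export
print.ScanResult <- function(x, ...) {
  s <- x$summary
  cat(sprintf("ScanResult: %d lncRNA x %d mRNA (%s tests), alpha = %g\n",
              s$n_lncRNA, s$n_mRNA, format(s$n_tests, big.mark = ","),
              s$alpha_display))
  cat(sprintf("  differential: %d, dose-response: %d, ambiguous: %d\n",
              s$pattern_counts$differential, s$pattern_counts$dose_response,
              s$n_ambiguous))
  invisible(x)
}
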