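#' Label pairs as cis- or trans-acting
#'
#' A pair is cis when both genes lie on the same chromosome and trans
#' otherwise (the operational definition used for lncRNA regulatory
#' networks; no distance window by default). Pairs with a missing chromosome
#' on either side are labelled `"unknown"` and excluded from the
#' percentages. An optional window (`max_cis_distance`, base pairs between
#' gene midpoints) restricts cis to nearby same-chromosome pairs.
#'
#' @param pairs data frame with `lncRNA` and `mRNA` id columns (e.g.
#'   `ScanResult$pairs`).
#' @param annotation a [gene_annotation()].
#' @param max_cis_distance optional distance cap for cis calls; `Inf`
#'   (default) means same chromosome suffices.
#' @return `list(pairs, summary)`: the input with a `cis_trans` column, and
#'   counts with percentages (1 decimal) overall and per pattern.
#' @export
classify_cis_trans <- function(pairs, annotation, max_cis_distance = Inf) {
  idx_l <- match(pairs$lncRNA, annotation$gene_id)
  idx_m <- match(pairs$mRNA, annotation$gene_id)
  chr_l <- annotation$chromosome[idx_l]
  chr_m <- annotation$chromosome[idx_m]
  lab <- ifelse(is.na(chr_l) | is.na(chr_m), "unknown",
                ifelse(chr_l == chr_m, "cis", "trans"))
  if (is.finite(max_cis_distance)) {
    mid_l <- (annotation$start[idx_l] + annotation$end[idx_l]) / 2
    mid_m <- (annotation$start[idx_m] + annotation$end[idx_m]) / 2
    lab[lab == "cis" & abs(mid_l - mid_m) > max_cis_distance] <- "trans"
  }
  pairs$cis_trans <- lab
  known <- lab != "unknown"
  pct <- function(k, n) if (n > 0) round(100 * k / n, 1) else NA_real_
  summarise <- function(sel) {
    n <- sum(sel & known)
    list(cis_count = sum(sel & lab == "cis"),
         trans_count = sum(sel & lab == "trans"),
         unknown_count = sum(sel & !known),
         cis_pct = pct(sum(sel & lab == "cis"), n),
         trans_pct = pct(sum(sel & lab == "trans"), n))
  }
  summary <- list(overall = summarise(rep(TRUE, nrow(pairs))))
  if ("pattern" %in% names(pairs)) {
    for (pat in unique(pairs$pattern)) {
      summary[[pat]] <- summarise(pairs$pattern == pat)
    }
  }
  if (nrow(pairs)) {
    n_unknown <- sum(!known)
    if (n_unknown) {
      message(n_unknown, " pair(s) with missing chromosome labelled 'unknown'")
    }
  }
  list(pairs = pairs, summary = summary)
}

#' Node degrees and hub summaries of a co-expression network
#'
#' Degree of a lncRNA is its number of mRNA partners and vice versa. The
#' single-partner percentage is the fraction of unique nodes with degree 1,
#' reported to 1 decimal.
#'
#' @param pairs data frame with `lncRNA` and `mRNA` columns.
#' @param top_k rows kept in the top-degree tables.
#' @return List with `lncRNA` and `mRNA` degree tables (sorted, with a
#'   `top` attribute), unique counts and single-partner percentages. Degree
#'   sums on both sides equal the pair count.
#' @export
hub_degrees <- function(pairs, top_k = 10) {
  if (!nrow(pairs)) stop("empty pair list")
  one_side <- function(ids) {
    tab <- sort(table(ids), decreasing = TRUE)
    df <- data.frame(gene_id = names(tab), degree = as.integer(tab),
                     row.names = NULL)
    list(degrees = df,
         top = utils::head(df, top_k),
         n_unique = nrow(df),
         single_partner_count = sum(df$degree == 1),
         single_partner_pct = round(100 * mean(df$degree == 1), 1))
  }
  list(lncRNA = one_side(pairs$lncRNA), mRNA = one_side(pairs$mRNA),
       n_pairs = nrow(pairs))
}

#' Overlap with the conventional both-members-DE approach
#'
#' Counts, per co-expression pattern, the pairs whose lncRNA and mRNA are
#' both differentially expressed, i.e. the subset a conventional
#' DE-restricted co-expression analysis could have found.
#'
#' @param pairs data frame with `lncRNA`, `mRNA` and optionally `pattern`.
#' @param de a `DEResult` with `is_de` set.
#' @return Data frame with one row per pattern: `n_pairs`, `n_both_de`,
#'   `pct_both_de` (1 decimal).
#' @export
conventional_comparison <- function(pairs, de) {
  de_flag <- stats::setNames(de$is_de %in% TRUE, de$gene_id)
  both <- (de_flag[pairs$lncRNA] %in% TRUE) & (de_flag[pairs$mRNA] %in% TRUE)
  pat <- if ("pattern" %in% names(pairs)) pairs$pattern
         else rep("all", nrow(pairs))
  out <- do.call(rbind, lapply(unique(pat), function(p) {
    sel <- pat == p
    data.frame(pattern = p, n_pairs = sum(sel), n_both_de = sum(both & sel),
               pct_both_de = if (sum(sel)) round(100 * sum(both & sel) /
                                                   sum(sel), 1) else NA_real_)
  }))
  if (is.null(out)) {
    out <- data.frame(pattern = character(), n_pairs = integer(),
                      n_both_de = integer(), pct_both_de = numeric())
  }
  rownames(out) <- NULL
  out
}

#' Read a risk-locus table (snp_id, chrom, position)
#'
#' @param path tab-separated file with columns `snp_id`, `chrom` (or
#'   `chromosome`) and `position` (1-based).
#' @param genome optional genome-build tag carried as an attribute and
#'   checked by [snp_colocalize()].
#' @return Data frame of class `RiskLocus`.
#' @export
read_risk_loci <- function(path, genome = NULL) {
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  if ("chromosome" %in% names(df) && !"chrom" %in% names(df)) {
    names(df)[names(df) == "chromosome"] <- "chrom"
  }
  need <- c("snp_id", "chrom", "position")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("risk-locus table lacks columns: ", paste(missing, collapse = ", "))
  }
  risk_loci(df, genome = genome)
}

#' Construct a risk-locus table
#' @param df data frame with `snp_id`, `chrom`, `position` (1-based).
#' @param genome optional genome-build tag.
#' @return Data frame of class `RiskLocus`.
#' @export
risk_loci <- function(df, genome = NULL) {
  df <- as.data.frame(df)
  df$position <- suppressWarnings(as.numeric(df$position))
  if (anyNA(df$position) || any(df$position < 1) ||
      any(df$position != round(df$position))) {
    stop("malformed position: must be integer >= 1")
  }
  df$position <- as.integer(df$position)
  attr(df, "genome") <- genome
  class(df) <- c("RiskLocus", "data.frame")
  df
}

#' Co-localize risk loci with gene bodies
#'
#' Matches each locus to genes whose body contains it: same chromosome and
#' `start <= position <= end` (1-based inclusive on both boundaries). One
#' locus may hit several genes and one gene several loci. Both inputs may
#' carry a `genome` attribute; if both are set and differ the call is
#' refused, since mixed genome builds silently invalidate containment.
#'
#' @param loci a [risk_loci()] table.
#' @param annotation a [gene_annotation()]; may carry `attr(, "genome")`.
#' @param restrict_biotype biotype(s) to test against (default `"lncRNA"`,
#'   the gene class of interest for regulatory risk loci); `NULL` keeps all.
#' @return `list(matches, summary)`: matches with one row per (locus, gene)
#'   hit, and counts of unique loci and genes hit.
#' @export
snp_colocalize <- function(loci, annotation, restrict_biotype = "lncRNA") {
  g_loci <- attr(loci, "genome")
  g_ann <- attr(annotation, "genome")
  if (!is.null(g_loci) && !is.null(g_ann) && !identical(g_loci, g_ann)) {
    stop("genome build mismatch: loci are '", g_loci, "', annotation is '",
         g_ann, "'")
  }
  ann <- as.data.frame(annotation)
  if (!is.null(restrict_biotype)) {
    ann <- ann[ann$biotype %in% restrict_biotype, , drop = FALSE]
  }
  empty <- data.frame(snp_id = character(), gene_id = character(),
                      chrom = character(), position = integer(),
                      gene_start = integer(), gene_end = integer())
  if (!nrow(ann) || !nrow(loci)) {
    return(list(matches = empty,
                summary = list(n_loci_hit = 0L, n_genes_hit = 0L,
                               n_matches = 0L)))
  }
  gr_genes <- GenomicRanges::GRanges(
    seqnames = ann$chromosome,
    ranges = IRanges::IRanges(start = ann$start, end = ann$end))
  gr_loci <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$position, width = 1))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(gr_loci, gr_genes))
  qi <- S4Vectors::queryHits(ov)
  si <- S4Vectors::subjectHits(ov)
  matches <- data.frame(snp_id = loci$snp_id[qi], gene_id = ann$gene_id[si],
                        chrom = loci$chrom[qi], position = loci$position[qi],
                        gene_start = ann$start[si], gene_end = ann$end[si])
  matches <- matches[order(matches$snp_id, matches$gene_id), , drop = FALSE]
  rownames(matches) <- NULL
  list(matches = matches,
       summary = list(n_loci_hit = length(unique(matches$snp_id)),
                      n_genes_hit = length(unique(matches$gene_id)),
                      n_matches = nrow(matches)))
}

#' Read gene sets from a GMT file
#'
#' GMT lines are tab-separated: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (members), with descriptions as
#'   the `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) stop("malformed GMT line(s): ", paste(bad, collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  attr(sets, "description") <- vapply(parts, `[[`, "", 2)
  sets
}

#' Hypergeometric gene-set enrichment
#'
#' For each set, tests over-representation of the query in the set against a
#' population (background) universe: `p = P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)` with `N` the population size, `K` the set
#' members in the population, `n` the query size and `k` the overlap.
#' P-values are BH-adjusted across the retained sets. The background should
#' match the tested universe (e.g. all genes surviving QC), not the whole
#' annotation.
#'
#' @param query character vector of gene ids; must be a subset of
#'   `population`.
#' @param gene_sets named list of character vectors ([read_gmt()]).
#' @param population character vector, the background universe.
#' @return Data frame of class `EnrichmentResult` with columns `set_name`,
#'   `N`, `K`, `n`, `k`, `p_value`, `fdr_p`, sorted by p-value.
#' @export
hypergeom_enrich <- function(query, gene_sets, population) {
  population <- unique(population)
  if (!length(population)) stop("empty population")
  query <- unique(query)
  outside <- setdiff(query, population)
  if (length(outside)) {
    stop("query genes outside the population: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  N <- length(population)
  n <- length(query)
  K <- vapply(gene_sets, function(s) length(intersect(s, population)), 0L)
  disjoint <- K == 0
  if (any(disjoint)) {
    warning(sum(disjoint), " gene set(s) disjoint from the population; skipped")
  }
  sets <- gene_sets[!disjoint]
  K <- K[!disjoint]
  k <- vapply(sets, function(s) length(intersect(s, query)), 0L)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(set_name = names(sets), N = N, K = unname(K), n = n,
                    k = unname(k), p_value = unname(p),
                    fdr_p = bh_adjust(unname(p)), row.names = NULL)
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Build the post-scan network summary
#'
#' Convenience wrapper: cis/trans classification, hub degrees per pattern,
#' and the conventional-approach comparison in one call.
#'
#' @param scan a `ScanResult` from [scan_all_pairs()].
#' @param annotation a [gene_annotation()].
#' @param de a `DEResult` with `is_de` set.
#' @return List with `pairs` (cis/trans-labelled), `cis_trans` summary,
#'   `degrees` per pattern, and `conventional` comparison table.
#' @export
network_summary <- function(scan, annotation, de) {
  ct <- classify_cis_trans(scan$pairs, annotation)
  degrees <- list()
  for (pat in unique(ct$pairs$pattern)) {
    sub <- ct$pairs[ct$pairs$pattern == pat, , drop = FALSE]
    if (nrow(sub)) degrees[[pat]] <- hub_degrees(sub)
  }
  list(pairs = ct$pairs, cis_trans = ct$summary, degrees = degrees,
       conventional = conventional_comparison(ct$pairs, de))
}
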