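toy_annotation <- function(ids, chroms) {
  gene_annotation(data.frame(
    gene_id = ids, biotype = ifelse(grepl("^L", ids), "lncRNA", "mRNA"),
    chromosome = chroms, start = 1, end = 1000, strand = "+"))
}

test_that("cis/trans percentages reproduce hand counts", {
  # 516 pairs of which 26 share a chromosome -> 5.0% cis / 95.0% trans
  n <- 516; n_cis <- 26
  pairs <- data.frame(lncRNA = sprintf("L%03d", 1:n),
                      mRNA = sprintf("M%03d", 1:n))
  chroms_l <- rep("chr1", n)
  chroms_m <- c(rep("chr1", n_cis), rep("chr2", n - n_cis))
  ann <- toy_annotation(c(pairs$lncRNA, pairs$mRNA), c(chroms_l, chroms_m))
  res <- classify_cis_trans(pairs, ann)
  expect_equal(res$summary$overall$cis_count, 26)
  expect_equal(res$summary$overall$cis_pct, 5.0)
  expect_equal(res$summary$overall$trans_pct, 95.0)

  # all pairs on one chromosome -> 100% cis
  ann2 <- toy_annotation(c(pairs$lncRNA, pairs$mRNA), "chr3")
  expect_equal(classify_cis_trans(pairs, ann2)$summary$overall$cis_pct, 100)
})

test_that("cis/trans labels equal brute-force string comparison on simulator truth", {
  sim <- simulate_dataset(small_sim_config(seed = 14))
  ann <- sim$annotation
  set.seed(14)
  pairs <- data.frame(
    lncRNA = sample(ann$gene_id[ann$biotype == "lncRNA"], 80, replace = TRUE),
    mRNA = sample(ann$gene_id[ann$biotype == "mRNA"], 80, replace = TRUE))
  res <- classify_cis_trans(pairs, ann)
  chr <- stats::setNames(ann$chromosome, ann$gene_id)
  brute <- ifelse(chr[pairs$lncRNA] == chr[pairs$mRNA], "cis", "trans")
  expect_equal(res$pairs$cis_trans, unname(brute))
  # partition is exhaustive and exclusive
  s <- res$summary$overall
  expect_equal(s$cis_count + s$trans_count + s$unknown_count, nrow(pairs))
})

test_that("hub degrees reproduce hand counts and conserve the pair total", {
  pairs <- data.frame(lncRNA = c("L1", "L1", "L2"),
                      mRNA = c("M1", "M2", "M1"))
  h <- hub_degrees(pairs)
  expect_equal(h$lncRNA$degrees$degree[h$lncRNA$degrees$gene_id == "L1"], 2)
  expect_equal(h$mRNA$degrees$degree[h$mRNA$degrees$gene_id == "M1"], 2)
  expect_equal(h$lncRNA$n_unique, 2)
  expect_equal(h$lncRNA$single_partner_pct, 50.0)
  expect_equal(sum(h$lncRNA$degrees$degree), nrow(pairs))
  expect_equal(sum(h$mRNA$degrees$degree), nrow(pairs))

  # 131 unique lncRNAs, 75 at degree 1 -> 57.3% single-partner
  deg <- c(rep(1, 75), rep(2, 55), 516 - 75 - 110)
  pairs2 <- data.frame(
    lncRNA = rep(sprintf("L%03d", seq_along(deg)), deg),
    mRNA = sprintf("M%03d", seq_len(sum(deg))))
  h2 <- hub_degrees(pairs2)
  expect_equal(h2$lncRNA$n_unique, 131)
  expect_equal(h2$lncRNA$single_partner_pct, 57.3)
  expect_equal(sum(h2$lncRNA$degrees$degree), 516)
  expect_equal(h2$lncRNA$top$gene_id[1], "L131")

  expect_error(hub_degrees(pairs[0, ]), "empty")
})

test_that("the conventional both-DE overlap is counted per pattern", {
  pairs <- data.frame(lncRNA = sprintf("L%03d", 1:516),
                      mRNA = sprintf("M%03d", 1:516),
                      pattern = "differential")
  de <- data.frame(gene_id = c(sprintf("L%03d", 1:8), sprintf("M%03d", 1:8),
                               "L999"),
                   is_de = TRUE)
  out <- conventional_comparison(pairs, de)
  expect_equal(out$n_both_de, 8)
  expect_equal(out$pct_both_de, 1.6)  # below the 2% mark
  expect_lt(out$pct_both_de, 2)

  # no DE genes -> zero everywhere
  out0 <- conventional_comparison(pairs, data.frame(gene_id = "X",
                                                    is_de = FALSE))
  expect_equal(out0$n_both_de, 0)
})

test_that("dose-response pairs overlap DE more than differential pairs do", {
  sim <- simulate_dataset(small_sim_config(seed = 16))
  de <- run_de(sim$counts, sim$samples)
  em <- compute_cpm(sim$counts, log2 = TRUE)
  sc <- scan_all_pairs(em, sim$annotation, sim$samples, de = de,
                       dose_b3_max = 0.4)
  conv <- conventional_comparison(sc$pairs, de)
  pd <- conv$pct_both_de[conv$pattern == "differential"]
  po <- conv$pct_both_de[conv$pattern == "dose_response"]
  expect_true(length(po) == 1 && length(pd) == 1)
  expect_gte(po, pd)
})

test_that("SNP containment respects inclusive boundaries", {
  ann <- gene_annotation(data.frame(
    gene_id = "L1", biotype = "lncRNA", chromosome = "chr21",
    start = 16500000, end = 17500000, strand = "+"))
  loci <- risk_loci(data.frame(
    snp_id = c("rs_in", "rs_end", "rs_past", "rs_start", "rs_chrom"),
    chrom = c("chr21", "chr21", "chr21", "chr21", "chr22"),
    position = c(17000000, 17500000, 17500001, 16500000, 17000000)))
  res <- snp_colocalize(loci, ann)
  expect_setequal(res$matches$snp_id, c("rs_in", "rs_end", "rs_start"))
  expect_equal(res$summary$n_genes_hit, 1)
  expect_error(risk_loci(data.frame(snp_id = "x", chrom = "chr1",
                                    position = 0)), "malformed position")
})

test_that("SNP co-localization equals the brute-force double loop", {
  set.seed(45)
  ann <- gene_annotation(data.frame(
    gene_id = sprintf("L%02d", 1:50), biotype = "lncRNA",
    chromosome = sample(paste0("chr", 1:5), 50, replace = TRUE),
    start = s <- sample.int(1e6, 50), end = s + sample.int(2e5, 50),
    strand = "+"))
  loci <- risk_loci(data.frame(
    snp_id = sprintf("rs%02d", 1:50),
    chrom = sample(paste0("chr", 1:5), 50, replace = TRUE),
    position = sample.int(1.2e6, 50)))
  res <- snp_colocalize(loci, ann)
  brute <- character()
  for (i in 1:50) for (j in 1:50) {
    if (loci$chrom[i] == ann$chromosome[j] &&
        loci$position[i] >= ann$start[j] && loci$position[i] <= ann$end[j]) {
      brute <- c(brute, paste(loci$snp_id[i], ann$gene_id[j]))
    }
  }
  expect_setequal(paste(res$matches$snp_id, res$matches$gene_id), brute)

  # permuting input order changes nothing
  res2 <- snp_colocalize(loci[sample(50), ], ann[sample(50), ])
  expect_equal(res2$matches, res$matches)
})

test_that("mismatched genome builds are refused and biotypes restricted", {
  ann <- gene_annotation(data.frame(
    gene_id = c("L1", "M1"), biotype = c("lncRNA", "mRNA"),
    chromosome = "chr1", start = 1, end = 100, strand = "+"))
  loci <- risk_loci(data.frame(snp_id = "rs1", chrom = "chr1", position = 50),
                    genome = "hg19")
  attr(ann, "genome") <- "hg38"
  expect_error(snp_colocalize(loci, ann), "genome build mismatch")
  attr(ann, "genome") <- "hg19"
  expect_equal(snp_colocalize(loci, ann)$matches$gene_id, "L1")
  both <- snp_colocalize(loci, ann, restrict_biotype = NULL)
  expect_setequal(both$matches$gene_id, c("L1", "M1"))
})

test_that("hypergeometric enrichment matches exact combinatorics", {
  sets <- list(empty_overlap = c("X1", "X2"), full = paste0("G", 1:5))
  pop <- paste0("G", 1:10)
  res <- suppressWarnings(hypergeom_enrich(paste0("G", 1:5), sets, pop))
  # k = n = K = 5, N = 10: p = 1/choose(10,5) = 1/252
  expect_equal(res$p_value[res$set_name == "full"], 1 / 252)
  # disjoint set skipped with a warning
  expect_warning(hypergeom_enrich(paste0("G", 1:5), sets, pop), "disjoint")
  expect_false("empty_overlap" %in% res$set_name)

  # k = 0 -> p = 1
  sets2 <- list(s = paste0("G", 6:8))
  res2 <- hypergeom_enrich(paste0("G", 1:3), sets2, pop)
  expect_equal(res2$p_value, 1)

  expect_error(hypergeom_enrich("Z9", sets2, pop), "outside the population")
  expect_error(hypergeom_enrich("G1", sets2, character(0)),
               "empty population")
})

test_that("enrichment p equals the brute-force tail sum and is monotone in k", {
  set.seed(46)
  for (r in 1:100) {
    N <- sample(10:80, 1)
    pop <- sprintf("G%03d", seq_len(N))
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    gene_set <- sample(pop, K)
    query <- sample(pop, n)
    res <- hypergeom_enrich(query, list(s = gene_set), pop)
    k <- length(intersect(gene_set, query))
    expect_equal(res$k, k)
    expect_equal(res$p_value, hyper_brute(N, K, n, k), tolerance = 1e-12)
  }
  # monotone: a larger overlap never increases the p-value
  p_seq <- stats::phyper(0:4 - 1, 5, 15, 8, lower.tail = FALSE)
  expect_true(all(diff(p_seq) <= 0))
})

test_that("GMT files parse into named member lists", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc A\tG1\tG2\tG3", "setB\tdesc B\tG2\tG9"), path)
  sets <- read_gmt(path)
  expect_equal(names(sets), c("setA", "setB"))
  expect_equal(sets$setB, c("G2", "G9"))
  writeLines("broken_line_only_name", path)
  expect_error(read_gmt(path), "malformed GMT")
})
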