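test_that("the Bonferroni threshold follows its closed form", {
  a <- bonferroni_alpha(7450, 22362)
  expect_equal(as.numeric(a), 0.05 / (7450 * 22362))
  expect_equal(as.numeric(a), 3.0013e-10, tolerance = 1e-4)
  expect_equal(attr(a, "display"), 3e-10)
  expect_equal(as.numeric(bonferroni_alpha(1, 1)), 0.05)
  expect_equal(as.numeric(bonferroni_alpha(10, 10)), 5e-4)
  expect_error(bonferroni_alpha(0, 10), ">= 1")
})

test_that("a noiseless piecewise-linear pair is fit exactly", {
  st <- sample_table(data.frame(sample_id = sprintf("S%02d", 1:12),
                                tissue_type = rep(0:1, each = 6),
                                age = 50, batch = "B1"))
  x <- c(1, 2, 3, 4, 5, 6, 1, 2, 3, 4, 5, 6)
  y <- ifelse(st$tissue_type == 0, 2 * x, -x)
  fit <- fit_pair(y, x, st)
  expect_equal(fit$slope_normal, 2, tolerance = 1e-12)
  expect_equal(fit$slope_tumor, -1, tolerance = 1e-12)
  expect_equal(fit$b3, -3, tolerance = 1e-12)
})

test_that("pattern classification applies precedence and the DE gate", {
  base_fit <- structure(list(b1 = 1, b3 = 0.005, se_b1 = 0.1, se_b3 = 0.1,
                             p_interaction = 1e-3, slope_normal = 1,
                             slope_tumor = 1.005, b1_m3 = 1, se_b1_m3 = 0.1,
                             p_b1_m3 = 1e-12, n_used = 36,
                             degenerate = FALSE), class = "PairFit")
  alpha <- 3e-10

  f <- base_fit; f$p_interaction <- 1e-12
  expect_equal(classify_pair(f, FALSE, FALSE, alpha)$pattern, "differential")

  expect_equal(classify_pair(base_fit, TRUE, FALSE, alpha)$pattern,
               "dose_response")
  expect_equal(classify_pair(base_fit, FALSE, FALSE, alpha)$pattern, "null")

  # both rule sets firing -> differential with the ambiguity flag
  g <- base_fit; g$p_interaction <- 1e-12
  cl <- classify_pair(g, TRUE, FALSE, alpha)
  expect_equal(cl$pattern, "differential")
  expect_true(cl$ambiguous)

  # degenerate fits are null with a flag
  d <- base_fit; d$degenerate <- TRUE
  expect_equal(classify_pair(d, TRUE, TRUE, alpha)$pattern, "null")
  expect_true(classify_pair(d, TRUE, TRUE, alpha)$degenerate)
})

test_that("the batched scan equals per-pair lm fits on random instances", {
  set.seed(41)
  for (r in 1:20) {
    st <- rand_sample_table(n = 14, n_batches = 2)
    n_l <- 4; n_m <- 16
    em <- matrix(rnorm((n_l + n_m) * 14, mean = 5), n_l + n_m, 14,
                 dimnames = list(c(sprintf("L%02d", 1:n_l),
                                   sprintf("M%02d", 1:n_m)),
                                 st$sample_id))
    ann <- gene_annotation(data.frame(
      gene_id = rownames(em),
      biotype = rep(c("lncRNA", "mRNA"), c(n_l, n_m)),
      chromosome = "chr1", start = 1, end = 10, strand = "+"))
    sc <- scan_all_pairs(em, ann, st, alpha = 0.01, keep_fits = TRUE)
    for (i in seq_len(nrow(sc$fits))) {
      row <- sc$fits[i, ]
      oracle <- lm_pair_oracle(em[row$mRNA, ], em[row$lncRNA, ], st)
      expect_equal(row$b1, oracle$b1, tolerance = 1e-8)
      expect_equal(row$b3, oracle$b3, tolerance = 1e-8)
      expect_equal(row$p_interaction, oracle$p_interaction, tolerance = 1e-8)
      expect_equal(row$b1_m3, oracle$b1_m3, tolerance = 1e-8)
      expect_equal(row$p_b1_m3, oracle$p_b1_m3, tolerance = 1e-8)
    }
  }
})

test_that("scan results agree with fit_pair and obey the slope identity", {
  set.seed(42)
  sim <- simulate_dataset(small_sim_config(seed = 12))
  em <- compute_cpm(sim$counts, log2 = TRUE)
  sc <- scan_all_pairs(em, sim$annotation, sim$samples, keep_fits = TRUE,
                       alpha = 1e-4)
  expect_true(all(abs((sc$fits$slope_tumor - sc$fits$slope_normal) -
                      sc$fits$b3) < 1e-12))
  # spot-check a handful of pairs against the single-pair path
  idx <- sample(nrow(sc$fits), 5)
  for (i in idx) {
    row <- sc$fits[i, ]
    f <- fit_pair(em[row$mRNA, ], em[row$lncRNA, ], sim$samples)
    expect_equal(row$b1, f$b1, tolerance = 1e-10)
    expect_equal(row$p_interaction, f$p_interaction, tolerance = 1e-10)
  }
})

test_that("relabelling tissue negates b3 and preserves the interaction p", {
  set.seed(43)
  st <- rand_sample_table(n = 16)
  x <- rnorm(16, 5)
  y <- 0.5 * x + st$tissue_type * x * 0.3 + rnorm(16, sd = 0.4)
  f1 <- fit_pair(y, x, st)
  st2 <- st
  st2$tissue_type <- 1L - st2$tissue_type
  f2 <- fit_pair(y, x, st2)
  expect_equal(f2$b3, -f1$b3, tolerance = 1e-10)
  expect_equal(f2$p_interaction, f1$p_interaction, tolerance = 1e-10)
  expect_equal(f2$slope_normal, f1$slope_tumor, tolerance = 1e-10)
})

test_that("within-tissue constant lncRNAs are reported degenerate", {
  st <- rand_sample_table(n = 12)
  x <- ifelse(st$tissue_type == 0, 1, rnorm(12))
  y <- rnorm(12)
  f <- fit_pair(y, x, st)
  expect_true(f$degenerate)
  expect_true(is.na(f$p_interaction))

  em <- rbind(L1 = x, M1 = y, M2 = rnorm(12))
  colnames(em) <- st$sample_id
  ann <- gene_annotation(data.frame(
    gene_id = c("L1", "M1", "M2"), biotype = c("lncRNA", "mRNA", "mRNA"),
    chromosome = "chr1", start = 1, end = 10, strand = "+"))
  sc <- scan_all_pairs(em, ann, st)
  expect_equal(sc$summary$degenerate_lncRNA, "L1")
  expect_equal(sc$summary$pattern_counts$null, 2)
  expect_equal(nrow(sc$pairs), 0)
})

test_that("interaction p-values are calibrated under the null", {
  set.seed(44)
  st <- rand_sample_table(n = 36, n_batches = 2)
  x <- rnorm(36, 5)
  Y <- matrix(rnorm(36 * 1000), 36, 1000)
  em <- rbind(L1 = x, t(Y))
  rownames(em) <- c("L1", sprintf("M%04d", 1:1000))
  colnames(em) <- st$sample_id
  ann <- gene_annotation(data.frame(
    gene_id = rownames(em),
    biotype = c("lncRNA", rep("mRNA", 1000)),
    chromosome = "chr1", start = 1, end = 10, strand = "+"))
  sc <- scan_all_pairs(em, ann, st, keep_fits = TRUE)
  frac <- mean(sc$fits$p_interaction < 0.05)
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(frac - 0.05), 2.5 * se)
  ks <- suppressWarnings(stats::ks.test(sc$fits$p_interaction, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the negative-binomial family recovers the same signal", {
  cfg <- sim_config(n_lncRNA = 10, n_mRNA = 10, n_diff_pairs = 3,
                    n_dose_pairs = 0, n_de_lncRNA = 0, n_de_mRNA = 0,
                    seed = 13)
  sim <- simulate_dataset(cfg)
  em <- compute_cpm(sim$counts, log2 = TRUE)
  tp <- sim$truth$pairs
  for (i in 1:3) {
    g <- fit_pair(em[tp$mRNA[i], ], em[tp$lncRNA[i], ], sim$samples)
    nb <- fit_pair(NULL, em[tp$lncRNA[i], ], sim$samples,
                   family = "negative_binomial",
                   y_counts = sim$counts$counts[tp$mRNA[i], ],
                   lib_sizes = sim$counts$lib_sizes)
    expect_lt(nb$p_interaction, 1e-4)
    expect_equal(sign(nb$b3), sign(g$b3))
    expect_equal(nb$slope_tumor - nb$slope_normal, nb$b3, tolerance = 1e-12)
  }
})

test_that("keep_fits refuses scans above the pair cap", {
  st <- rand_sample_table(n = 8)
  em <- matrix(rnorm(40 * 8, 5), 40, 8,
               dimnames = list(sprintf("G%02d", 1:40), st$sample_id))
  ann <- gene_annotation(data.frame(
    gene_id = rownames(em), biotype = rep(c("lncRNA", "mRNA"), each = 20),
    chromosome = "chr1", start = 1, end = 10, strand = "+"))
  expect_error(scan_all_pairs(em, ann, st, keep_fits = TRUE, max_pairs = 100),
               "max_pairs")
})
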