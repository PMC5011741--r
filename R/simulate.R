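#' Configuration for the synthetic two-tissue RNA-seq generator
#'
#' Defaults emulate the study design the package targets: 18 tumor + 18
#' normal samples (ages 32-80), a desk-scale gene universe of 200 lncRNAs
#' and 600 mRNAs, negative-binomial counts with dispersion `phi = 0.1`
#' (biological CV ~0.32, typical of bulk human tissue across individuals),
#' planted >=2-fold differentially expressed genes, and planted lncRNA-mRNA
#' pairs of two kinds: differential co-expression (tissue-dependent slope,
#' driver not itself DE) and dose-response co-expression (shared slope,
#' driver planted DE). All other pairs are nulls.
#'
#' @param n_tumor,n_normal sample counts per group.
#' @param n_lncRNA,n_mRNA gene counts per biotype.
#' @param n_batches sequencing batches, assigned round-robin within tissue so
#'   batch and tissue are not confounded.
#' @param age_range sampling range (years) for the age covariate, drawn
#'   uniformly and independently of tissue (matched design).
#' @param baseline_log2_mean,baseline_log2_sd per-gene baseline log2 expected
#'   count at reference depth.
#' @param dispersion NB dispersion phi (variance = mu + phi mu^2); 0 gives
#'   Poisson counts.
#' @param n_de_lncRNA,n_de_mRNA planted differentially expressed genes; must
#'   satisfy `n_de_lncRNA >= n_dose_pairs` since every dose-response driver
#'   is planted DE.
#' @param de_log2fc_range magnitude range of planted log2 fold changes
#'   (sign random).
#' @param n_diff_pairs,n_dose_pairs planted pair counts.
#' @param slope_normal_range,slope_tumor_range slope ranges for differential
#'   pairs; defaults give opposite signs so the planted interaction
#'   |b_tumor - b_normal| is bounded away from 0 (>= 1.6).
#' @param shared_slope_range magnitude range of the common slope for
#'   dose-response pairs (sign random); `|b_tumor - b_normal| = 0` by
#'   construction.
#' @param driver_noise_sd per-sample latent biological variation (log2 units)
#'   of driver lncRNAs, the signal the pairwise regressions estimate.
#' @param batch_effect_sd,age_effect_sd nuisance effect scales (log2 units,
#'   age per year).
#' @param depth_log_sd lognormal spread of per-sample depth factors.
#' @param nominal_lib_size library size (total mapped reads) at depth factor
#'   1. The simulated genes are a panel drawn from a larger transcriptome,
#'   so per-sample library sizes are `depth * nominal_lib_size` rather than
#'   panel column sums; this keeps CPM normalisation as stable as it is on
#'   genome-wide data, where no single gene dominates the total.
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return A validated list of class `SimConfig`.
#' @export
sim_config <- function(n_tumor = 18, n_normal = 18,
                       n_lncRNA = 200, n_mRNA = 600,
                       n_batches = 2, age_range = c(32, 80),
                       baseline_log2_mean = 8, baseline_log2_sd = 1.5,
                       dispersion = 0.1,
                       n_de_lncRNA = 30, n_de_mRNA = 60,
                       de_log2fc_range = c(1, 4),
                       n_diff_pairs = 20, n_dose_pairs = 20,
                       slope_normal_range = c(-2, -0.8),
                       slope_tumor_range = c(0.8, 2),
                       shared_slope_range = c(0.8, 2),
                       driver_noise_sd = 1.5,
                       batch_effect_sd = 0.3, age_effect_sd = 0.01,
                       depth_log_sd = 0.2, nominal_lib_size = 2e6,
                       seed = 7) {
  cfg <- as.list(environment())
  if (cfg$dispersion < 0) stop("'dispersion' must be >= 0")
  if (cfg$n_tumor < 1 || cfg$n_normal < 1) stop("need samples in both groups")
  n_drivers <- cfg$n_diff_pairs + cfg$n_dose_pairs
  if (n_drivers > cfg$n_lncRNA) {
    stop("planted pairs exceed available lncRNAs")
  }
  if (n_drivers > cfg$n_mRNA) stop("planted pairs exceed available mRNAs")
  if (cfg$n_de_lncRNA < cfg$n_dose_pairs) {
    stop("n_de_lncRNA must be >= n_dose_pairs (dose drivers are planted DE)")
  }
  if (cfg$n_de_lncRNA > cfg$n_lncRNA - cfg$n_diff_pairs) {
    stop("not enough non-differential lncRNAs to plant DE on")
  }
  if (cfg$n_de_mRNA > cfg$n_mRNA - n_drivers) {
    stop("not enough free mRNAs to plant DE on")
  }
  structure(cfg, class = "SimConfig")
}

#' Draw negative-binomial counts with mean/dispersion parameterisation
#'
#' `variance = mean + dispersion * mean^2`; `dispersion = 0` degenerates to
#' Poisson.
#'
#' @param n number of draws.
#' @param mean positive mean (recycled).
#' @param dispersion NB dispersion phi >= 0.
#' @return Integer vector of draws.
#' @export
nb_sample <- function(n, mean, dispersion = 0) {
  if (any(dispersion < 0)) stop("'dispersion' must be >= 0")
  if (any(mean <= 0)) stop("'mean' must be > 0")
  if (all(dispersion == 0)) {
    stats::rpois(n, lambda = mean)
  } else {
    stats::rnbinom(n, mu = mean, size = 1 / dispersion)
  }
}

#' Simulate a two-tissue count dataset with planted co-expression patterns
#'
#' Generative model, on the latent log2 scale at reference depth:
#' driver lncRNAs get `base + lfc * tissue + batch + age_slope * (age -
#' mean(age)) + N(0, driver_noise_sd)`; for planted pairs the target mRNA's
#' latent mean is `base + b_tissue(s) * (driver_latent - mean(driver_latent))
#' + batch + age` with `b_tissue` equal in both tissues for dose-response
#' pairs and different (opposite signs by default) for differential pairs;
#' all other genes get baseline plus covariate effects (plus `lfc * tissue`
#' for planted DE genes). Counts are `NB(mean = 2^latent * depth_s,
#' dispersion = phi)`. Chromosomes are assigned uniformly at random so
#' cis/trans truth is known.
#'
#' @param cfg a [sim_config()].
#' @return `list(counts = CountMatrix, annotation = GeneAnnotation,
#'   samples = SampleTable, truth = SimTruth)` where `truth` holds per-gene
#'   planted log2 fold changes and DE flags (`genes`) and the planted pair
#'   table with true slopes (`pairs`).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  n <- cfg$n_normal + cfg$n_tumor

  ## samples: normals first, batches round-robin within tissue
  tissue <- c(rep(0L, cfg$n_normal), rep(1L, cfg$n_tumor))
  batch <- unlist(lapply(split(seq_len(n), tissue), function(idx) {
    rep_len(paste0("B", seq_len(cfg$n_batches)), length(idx))
  }), use.names = FALSE)
  depth <- exp(stats::rnorm(n, 0, cfg$depth_log_sd))
  st <- sample_table(data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    tissue_type = tissue,
    age = round(stats::runif(n, cfg$age_range[1], cfg$age_range[2]), 1),
    batch = batch,
    lib_size = round(depth * cfg$nominal_lib_size)))

  ## gene universe and coordinates
  lnc_ids <- sprintf("LNC%04d", seq_len(cfg$n_lncRNA))
  mrna_ids <- sprintf("MRNA%04d", seq_len(cfg$n_mRNA))
  gene_ids <- c(lnc_ids, mrna_ids)
  n_genes <- length(gene_ids)
  chroms <- paste0("chr", c(1:22, "X"))
  chrom <- sample(chroms, n_genes, replace = TRUE)
  start <- sample.int(2e8, n_genes, replace = TRUE)
  width <- sample(2e3:2e5, n_genes, replace = TRUE)
  ann <- gene_annotation(data.frame(
    gene_id = gene_ids,
    biotype = c(rep("lncRNA", cfg$n_lncRNA), rep("mRNA", cfg$n_mRNA)),
    chromosome = chrom, start = start, end = start + width,
    strand = sample(c("+", "-"), n_genes, replace = TRUE)))

  ## plant pairs: drivers/targets drawn without replacement within role
  diff_drivers <- sample(lnc_ids, cfg$n_diff_pairs)
  dose_drivers <- sample(setdiff(lnc_ids, diff_drivers), cfg$n_dose_pairs)
  diff_targets <- sample(mrna_ids, cfg$n_diff_pairs)
  dose_targets <- sample(setdiff(mrna_ids, diff_targets), cfg$n_dose_pairs)

  ## planted DE genes: every dose driver is DE; differential drivers and all
  ## pair targets are kept free of their own tissue effect
  rlfc <- function(k) {
    sample(c(-1, 1), k, replace = TRUE) *
      stats::runif(k, cfg$de_log2fc_range[1], cfg$de_log2fc_range[2])
  }
  free_lnc <- setdiff(lnc_ids, c(diff_drivers, dose_drivers))
  de_lnc <- c(dose_drivers,
              sample(free_lnc, cfg$n_de_lncRNA - cfg$n_dose_pairs))
  free_mrna <- setdiff(mrna_ids, c(diff_targets, dose_targets))
  de_mrna <- sample(free_mrna, cfg$n_de_mRNA)
  true_lfc <- stats::setNames(numeric(n_genes), gene_ids)
  true_lfc[de_lnc] <- rlfc(length(de_lnc))
  true_lfc[de_mrna] <- rlfc(length(de_mrna))

  ## planted slopes
  rsign <- sample(c(-1, 1), cfg$n_dose_pairs, replace = TRUE)
  shared <- rsign * stats::runif(cfg$n_dose_pairs, cfg$shared_slope_range[1],
                                 cfg$shared_slope_range[2])
  pairs <- rbind(
    data.frame(lncRNA = diff_drivers, mRNA = diff_targets,
               label = rep("differential", cfg$n_diff_pairs),
               b_normal = stats::runif(cfg$n_diff_pairs,
                                       cfg$slope_normal_range[1],
                                       cfg$slope_normal_range[2]),
               b_tumor = stats::runif(cfg$n_diff_pairs,
                                      cfg$slope_tumor_range[1],
                                      cfg$slope_tumor_range[2])),
    data.frame(lncRNA = dose_drivers, mRNA = dose_targets,
               label = rep("dose_response", cfg$n_dose_pairs),
               b_normal = shared, b_tumor = shared))

  ## latent log2 expression
  base <- stats::rnorm(n_genes, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  names(base) <- gene_ids
  batch_eff <- matrix(stats::rnorm(n_genes * cfg$n_batches, 0,
                                   cfg$batch_effect_sd),
                      n_genes, cfg$n_batches,
                      dimnames = list(gene_ids, paste0("B",
                                                       seq_len(cfg$n_batches))))
  age_slope <- stats::rnorm(n_genes, 0, cfg$age_effect_sd)
  names(age_slope) <- gene_ids
  age_c <- st$age - mean(st$age)

  covar <- batch_eff[, st$batch, drop = FALSE] +
    outer(age_slope, age_c)                       # genes x samples
  latent <- base + covar +
    outer(true_lfc, as.numeric(st$tissue_type))

  ## driver biological noise, then overwrite planted targets
  drivers <- c(diff_drivers, dose_drivers)
  latent[drivers, ] <- latent[drivers, , drop = FALSE] +
    matrix(stats::rnorm(length(drivers) * n, 0, cfg$driver_noise_sd),
           length(drivers), n)
  b_mat <- matrix(pairs$b_normal, nrow(pairs), n)
  b_mat[, st$tissue_type == 1] <- pairs$b_tumor
  drv_lat <- latent[pairs$lncRNA, , drop = FALSE]
  drv_dev <- drv_lat - rowMeans(drv_lat)
  latent[pairs$mRNA, ] <- base[pairs$mRNA] + covar[pairs$mRNA, , drop = FALSE] +
    b_mat * drv_dev

  mu <- 2^latent * rep(depth, each = n_genes)
  counts <- matrix(nb_sample(length(mu), as.vector(mu), cfg$dispersion),
                   n_genes, n, dimnames = list(gene_ids, st$sample_id))

  truth <- structure(list(
    genes = data.frame(
      gene_id = gene_ids,
      biotype = ann$biotype,
      true_log2fc = unname(true_lfc),
      is_de = gene_ids %in% c(de_lnc, de_mrna),
      role = role_of(gene_ids, diff_drivers, dose_drivers, diff_targets,
                     dose_targets)),
    pairs = pairs,
    seed = cfg$seed,
    config = cfg), class = "SimTruth")

  list(counts = count_matrix(counts, lib_sizes = st$lib_size),
       annotation = ann, samples = st, truth = truth)
}

role_of <- function(ids, diff_drivers, dose_drivers, diff_targets,
                    dose_targets) {
  role <- rep("none", length(ids))
  role[ids %in% diff_drivers] <- "diff_driver"
  role[ids %in% dose_drivers] <- "dose_driver"
  role[ids %in% diff_targets] <- "diff_target"
  role[ids %in% dose_targets] <- "dose_target"
  role
}

#' Write a simulated dataset to a directory as plain TSV
#'
#' Emits `counts.tsv`, `annotation.tsv`, `samples.tsv`, `truth_genes.tsv`
#' and `truth_pairs.tsv`.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  write_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  write_samples(sim$samples, file.path(dir, "samples.tsv"))
  write_table(sim$truth$genes, file.path(dir, "truth_genes.tsv"))
  write_table(sim$truth$pairs, file.path(dir, "truth_pairs.tsv"))
  invisible(dir)
}
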