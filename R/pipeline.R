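#' Pipeline configuration
#'
#' Aggregates every threshold of the analysis chain. Inputs may be given as
#' file paths (TSV/GTF, read with the package readers) or as in-memory
#' objects.
#'
#' @param counts path to a counts TSV or a [count_matrix()].
#' @param samples path to a sample TSV or a [sample_table()].
#' @param annotation path to GTF/TSV annotation or a [gene_annotation()].
#' @param out_dir output directory for the run.
#' @param fdr DE adjusted-p threshold (default 0.01).
#' @param min_abs_log2fc DE fold-change gate on the log2 scale (default 1).
#' @param family_alpha family-wise alpha for the pairwise scan (default
#'   0.05).
#' @param dose_b3_max dose-response interaction gate (default 0.01).
#' @param cpm_threshold,min_samples low-expression gene filter settings.
#' @param min_pct_genes,min_pct_mapped sample filter settings.
#' @param pca_sd PCA outlier cutoff; `Inf` disables.
#' @param seed integer seed recorded in the manifest (the analysis itself is
#'   deterministic; the seed covers any subsampling extensions).
#' @return A validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(counts, samples, annotation, out_dir,
                            fdr = 0.01, min_abs_log2fc = 1.0,
                            family_alpha = 0.05, dose_b3_max = 0.01,
                            cpm_threshold = 1.0, min_samples = NULL,
                            min_pct_genes = 0.50, min_pct_mapped = 0.25,
                            pca_sd = 3.0, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(fdr > 0, fdr <= 1, family_alpha > 0, family_alpha <= 1,
            min_abs_log2fc >= 0, dose_b3_max >= 0, cpm_threshold >= 0,
            pca_sd > 0)
  structure(cfg, class = "PipelineConfig")
}

resolve_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1) {
    list(value = reader(x), path = x, md5 = unname(tools::md5sum(x)))
  } else {
    list(value = x, path = NA_character_, md5 = NA_character_)
  }
}

#' Run the full analysis pipeline
#'
#' Executes QC (sample filters, PCA outliers, gene filter), differential
#' expression, the pairwise co-expression scan, and the network annotation
#' stage, writing each stage's tables plus a `manifest.json` with input
#' checksums, the configuration, package version and stage timings. Reruns
#' with the same inputs and configuration reproduce identical tables.
#'
#' @param cfg a [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results (`qc`, `de`,
#'   `scan`, `network`, `manifest`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(cfg$out_dir, "qc"), showWarnings = FALSE)
  dir.create(file.path(cfg$out_dir, "network"), showWarnings = FALSE)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  inp_counts <- resolve_input(cfg$counts, read_counts)
  inp_samples <- resolve_input(cfg$samples, read_samples)
  inp_ann <- resolve_input(cfg$annotation, read_annotation)
  cm <- inp_counts$value
  st <- inp_samples$value
  ann <- inp_ann$value
  if (!all(colnames(cm$counts) %in% st$sample_id)) {
    stop("samples in counts missing from the sample table")
  }
  unannotated <- setdiff(rownames(cm$counts), ann$gene_id)
  if (length(unannotated)) {
    stop(length(unannotated), " genes in counts lack annotation (first: ",
         utils::head(unannotated, 3)[1], ")")
  }

  qc <- stage("qc", run_qc(cm, st, annotation = ann,
                           min_pct_genes = cfg$min_pct_genes,
                           min_pct_mapped = cfg$min_pct_mapped,
                           pca_sd = cfg$pca_sd,
                           cpm_threshold = cfg$cpm_threshold,
                           min_samples = cfg$min_samples))
  write_table(rbind(qc$report$samples$removed_samples,
                    qc$report$pca$removed_samples),
              file.path(cfg$out_dir, "qc", "removed_samples.tsv"))
  write_table(qc$report$genes$removed_genes,
              file.path(cfg$out_dir, "qc", "removed_genes.tsv"))

  de <- stage("de", run_de(qc$counts, qc$samples,
                           fdr_threshold = cfg$fdr,
                           min_abs_log2fc = cfg$min_abs_log2fc))
  de_out <- de
  de_out$biotype <- ann$biotype[match(de_out$gene_id, ann$gene_id)]
  write_table(de_out, file.path(cfg$out_dir, "de.tsv"))

  em <- compute_cpm(qc$counts, log2 = TRUE)
  scan <- stage("scan", scan_all_pairs(em, ann, qc$samples, de = de,
                                       family_alpha = cfg$family_alpha,
                                       dose_b3_max = cfg$dose_b3_max))

  network <- stage("network", network_summary(scan, ann, de))
  write_table(network$pairs, file.path(cfg$out_dir, "pairs.tsv"))
  write_table(network$conventional,
              file.path(cfg$out_dir, "network", "conventional.tsv"))
  for (pat in names(network$degrees)) {
    write_table(network$degrees[[pat]]$lncRNA$degrees,
                file.path(cfg$out_dir, "network",
                          paste0("degree_lncRNA_", pat, ".tsv")))
    write_table(network$degrees[[pat]]$mRNA$degrees,
                file.path(cfg$out_dir, "network",
                          paste0("degree_mRNA_", pat, ".tsv")))
  }

  manifest <- list(
    package = "coexPatterns",
    version = as.character(utils::packageVersion("coexPatterns")),
    config = cfg[setdiff(names(cfg), c("counts", "samples", "annotation"))],
    inputs = list(
      counts = inp_counts[c("path", "md5")],
      samples = inp_samples[c("path", "md5")],
      annotation = inp_ann[c("path", "md5")]),
    n_samples_retained = ncol(qc$counts$counts),
    n_genes_retained = nrow(qc$counts$counts),
    scan_summary = scan$summary,
    cis_trans = network$cis_trans,
    timings = timings)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null", force = TRUE)

  invisible(list(qc = qc, de = de, scan = scan, network = network,
                 manifest = manifest))
}
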