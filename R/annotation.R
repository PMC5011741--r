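#' Construct a gene annotation table
#'
#' One row per gene with biotype and genomic coordinates. Coordinates are
#' 1-based inclusive (GTF convention) internally; see [read_annotation()] for
#' BED-dialect conversion. The biotype partitions the gene universe into the
#' two classes scanned against each other.
#'
#' @param df data frame with columns `gene_id`, `biotype` (one of
#'   `"lncRNA"`, `"mRNA"`), `chromosome`, `start`, `end`, and optionally
#'   `strand` (`"+"`, `"-"` or `"*"` for unknown).
#' @return A validated data frame of class `GeneAnnotation`.
#' @export
gene_annotation <- function(df) {
  df <- as.data.frame(df)
  need <- c("gene_id", "biotype", "chromosome", "start", "end")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("annotation lacks columns: ", paste(missing, collapse = ", "))
  }
  if (!"strand" %in% names(df)) df$strand <- "*"
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup)) stop("duplicated gene_id: ", paste(dup, collapse = ", "))
  bad_bt <- setdiff(unique(df$biotype), c("lncRNA", "mRNA"))
  if (length(bad_bt)) {
    stop("biotype must be 'lncRNA' or 'mRNA'; found: ",
         paste(bad_bt, collapse = ", "))
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- which(df$start > df$end)
  if (length(bad)) {
    stop("start > end for gene(s): ",
         paste(utils::head(df$gene_id[bad], 5), collapse = ", "))
  }
  if (any(df$start < 1, na.rm = TRUE)) stop("coordinates must be >= 1")
  df$strand[!df$strand %in% c("+", "-")] <- "*"
  df <- df[, c("gene_id", "biotype", "chromosome", "start", "end", "strand")]
  class(df) <- c("GeneAnnotation", "data.frame")
  df
}

#' Default mapping from source biotype strings to the lncRNA/mRNA partition
#'
#' Covers the common GENCODE labels; anything unmapped is an error unless
#' `default = "drop"` is passed to [read_annotation()].
#'
#' @return Named character vector mapping source biotypes to
#'   `"lncRNA"`/`"mRNA"`.
#' @export
default_biotype_rule <- function() {
  c(lncRNA = "lncRNA", lincRNA = "lncRNA", antisense = "lncRNA",
    sense_intronic = "lncRNA", sense_overlapping = "lncRNA",
    processed_transcript = "lncRNA", "3prime_overlapping_ncrna" = "lncRNA",
    protein_coding = "mRNA", mRNA = "mRNA")
}

#' Read gene annotation from GTF or a 6-column TSV
#'
#' GTF input (via rtracklayer) keeps only `type == "gene"` records and reads
#' the biotype from the `gene_type` (GENCODE) or `gene_biotype` attribute.
#' TSV input expects columns `gene_id`, `biotype`, `chromosome` (or `chrom`),
#' `start`, `end`, `strand`. GTF/TSV coordinates are taken as 1-based
#' inclusive; `coords = "bed"` declares 0-based half-open input, converted at
#' the boundary (start + 1).
#'
#' @param path file path; `.gtf`/`.gff` extensions select the GTF parser
#'   unless `format` is given.
#' @param biotype_rule named character vector mapping source biotype strings
#'   to `"lncRNA"`, `"mRNA"` or `"drop"`; see [default_biotype_rule()].
#' @param format `"auto"`, `"gtf"` or `"tsv"`.
#' @param coords coordinate dialect of the input: `"onebased"` (GTF/TSV
#'   default) or `"bed"`.
#' @param default what to do with biotypes absent from `biotype_rule`:
#'   `"error"` (default) or `"drop"`.
#' @return A [gene_annotation()] table.
#' @export
read_annotation <- function(path, biotype_rule = default_biotype_rule(),
                            format = c("auto", "gtf", "tsv"),
                            coords = c("onebased", "bed"),
                            default = c("error", "drop")) {
  format <- match.arg(format)
  coords <- match.arg(coords)
  default <- match.arg(default)
  if (format == "auto") {
    format <- if (grepl("\\.(gtf|gff3?)(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "tsv"
  }
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    md <- as.data.frame(gr)
    if ("type" %in% names(md) && any(md$type == "gene")) {
      md <- md[md$type == "gene", , drop = FALSE]
    }
    bt_col <- intersect(c("gene_type", "gene_biotype"), names(md))[1]
    if (is.na(bt_col)) stop("GTF lacks a gene_type/gene_biotype attribute")
    if (!"gene_id" %in% names(md)) stop("GTF lacks gene_id attributes")
    df <- data.frame(gene_id = md$gene_id, source_biotype = md[[bt_col]],
                     chromosome = as.character(md$seqnames),
                     start = md$start, end = md$end,
                     strand = as.character(md$strand),
                     stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
    if ("chrom" %in% names(df) && !"chromosome" %in% names(df)) {
      names(df)[names(df) == "chrom"] <- "chromosome"
    }
    need <- c("gene_id", "biotype", "chromosome", "start", "end")
    missing <- setdiff(need, names(df))
    if (length(missing)) {
      stop("annotation TSV lacks columns: ", paste(missing, collapse = ", "))
    }
    names(df)[names(df) == "biotype"] <- "source_biotype"
    if (!"strand" %in% names(df)) df$strand <- "*"
  }
  if (coords == "bed") {
    df$start <- df$start + 1L  # 0-based half-open -> 1-based inclusive
  }
  mapped <- unname(biotype_rule[df$source_biotype])
  unmapped <- unique(df$source_biotype[is.na(mapped)])
  if (length(unmapped)) {
    if (default == "error") {
      stop("unmapped biotype(s): ", paste(unmapped, collapse = ", "),
           " (use default = 'drop' or extend biotype_rule)")
    }
    mapped[is.na(mapped)] <- "drop"
  }
  keep <- mapped != "drop"
  df <- df[keep, , drop = FALSE]
  df$biotype <- mapped[keep]
  gene_annotation(df[, c("gene_id", "biotype", "chromosome", "start", "end",
                         "strand")])
}

#' Write annotation as 6-column TSV (1-based inclusive coordinates)
#'
#' @param ann a [gene_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "GeneAnnotation"))
  out <- as.data.frame(ann)
  names(out)[names(out) == "chromosome"] <- "chrom"
  names(out)[names(out) == "biotype"] <- "biotype"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
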