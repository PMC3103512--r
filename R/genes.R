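#' Gene model tables
#'
#' Gene models are plain data.frames with columns `gene_id`, `seq_id`,
#' `start`, `end` (0-based half-open), `strand` ("+"/"-") and `tss` (the
#' transcription start site: `start` on the plus strand, `end - 1` on the
#' minus strand).
#'
#' @param df data.frame with at least `gene_id`, `seq_id`, `start`, `end`,
#'   `strand`; `tss` is derived when absent.
#' @return validated gene-model data.frame.
#' @export
gene_models <- function(df) {
  need <- c("gene_id", "seq_id", "start", "end", "strand")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("gene table lacks columns: ",
                            paste(missing, collapse = ", "))
  if (any(df$start >= df$end)) stop("gene with start >= end")
  if (!all(df$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  if (!"tss" %in% names(df)) {
    df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  }
  if (any(df$tss < df$start | df$tss >= df$end)) {
    stop("tss outside gene span")
  }
  df
}

#' Read gene and CDS features from a GFF3 file
#'
#' Minimal GFF3 reader for the feature subset this package consumes: `gene`
#' rows give the gene models (ID from the `ID=` attribute), `CDS` rows give
#' coding intervals used for scan masking. GFF3 1-based closed coordinates
#' are converted to the package's 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @return list with `genes` (a [gene_models] data.frame) and `cds`
#'   (data.frame `seq_id`, `start`, `end`).
#' @export
read_gff_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9L)
  if (length(bad)) stop("malformed GFF3 row ", bad[1L], " in ", path)
  tab <- as.data.frame(do.call(rbind, f), stringsAsFactors = FALSE)
  names(tab) <- c("seq_id", "source", "type", "start", "end", "score",
                  "strand", "phase", "attr")
  tab$start <- as.integer(tab$start) - 1L   # to 0-based half-open
  tab$end <- as.integer(tab$end)
  gid <- sub(".*ID=([^;]+).*", "\\1", tab$attr)
  g <- tab[tab$type == "gene", , drop = FALSE]
  genes <- gene_models(data.frame(
    gene_id = gid[tab$type == "gene"], seq_id = g$seq_id,
    start = g$start, end = g$end, strand = g$strand,
    stringsAsFactors = FALSE))
  cds <- tab[tab$type == "CDS", c("seq_id", "start", "end"), drop = FALSE]
  rownames(cds) <- NULL
  list(genes = genes, cds = cds)
}

#' Write gene models (and optional CDS) as GFF3
#'
#' @param genes a [gene_models] data.frame.
#' @param path output file.
#' @param cds optional data.frame `seq_id`, `start`, `end` of coding
#'   intervals; defaults to the gene spans.
#' @export
write_gff_genes <- function(genes, path, cds = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    writeLines(sprintf("%s\tcrmpred\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       genes$seq_id[i], genes$start[i] + 1L, genes$end[i],
                       genes$strand[i], genes$gene_id[i]), con)
  }
  if (is.null(cds)) {
    cds <- genes[, c("seq_id", "start", "end")]
    cds$strand <- genes$strand
    cds$gene_id <- genes$gene_id
  }
  for (i in seq_len(nrow(cds))) {
    writeLines(sprintf("%s\tcrmpred\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                       cds$seq_id[i], cds$start[i] + 1L, cds$end[i],
                       if ("strand" %in% names(cds)) cds$strand[i] else "+",
                       paste0("cds_", if ("gene_id" %in% names(cds))
                         cds$gene_id[i] else i)), con)
  }
  invisible(path)
}
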