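#' Pipeline configuration
#'
#' Collects every stage parameter and input path into a validated list.
#' Unknown keys are rejected. Input paths default to the fixture-bundle
#' layout written by [generate_fixture()] under `input_dir`.
#'
#' @param input_dir directory holding the inputs (fixture layout).
#' @param output_dir directory for stage outputs and the manifest.
#' @param seed integer seed driving all randomness.
#' @param ... overrides for any parameter below.
#' @return list of class `crm_config`.
#' @section Parameters:
#' `threshold_fraction` (0.75), `lambda` (0.1), `max_offset` (20),
#' `window_bp` (1000), `K` (5), `min_hits` (3), `score_threshold` (41),
#' `fuse_gap_bp` (500), `flank_bp` (200), `aln_score_threshold` (2600),
#' `identity_threshold` (60), `anchor_pad` (10000), `min_conserved` (20),
#' `fdr` (0.05), `n_rand` (100), `min_specific_rate` (0.5), `min_fish` (10),
#' `species` (tetraodon, stickleback, fugu), `block_format` ("tsv" or
#' "maf").
#' @export
crm_config <- function(input_dir, output_dir, seed = 1L, ...) {
  cfg <- list(
    input_dir = input_dir, output_dir = output_dir, seed = as.integer(seed),
    threshold_fraction = 0.75, lambda = 0.1, max_offset = 20L,
    window_bp = 1000L, K = 5L, min_hits = 3L, score_threshold = 41,
    fuse_gap_bp = 500L, flank_bp = 200L,
    aln_score_threshold = 2600, identity_threshold = 60,
    anchor_pad = 10000L, min_conserved = 20L, fdr = 0.05, n_rand = 100L,
    min_specific_rate = 0.5, min_fish = 10L,
    species = FIXTURE_SPECIES, block_format = "tsv")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  ranges_ok <- cfg$threshold_fraction >= 0 && cfg$threshold_fraction <= 1 &&
    cfg$lambda >= 0 && cfg$max_offset >= 0 && cfg$max_offset <= 20 &&
    cfg$fdr > 0 && cfg$fdr < 1 && cfg$n_rand >= 1
  if (!ranges_ok) stop("config parameter outside its documented range")
  class(cfg) <- "crm_config"
  cfg
}

PIPELINE_STAGES <- c("scan", "conserve", "call", "filter", "context",
                     "enrich", "qc")

#' Run pipeline stages
#'
#' Executes one stage (or `"all"`, chaining every stage in order) against
#' the inputs named in the config, writing fixed-name outputs plus a
#' `manifest.json` (input md5 hashes, parameters, package version) under
#' `output_dir`. Stages read their upstream products from `output_dir`, so
#' running `"all"` is equivalent to running the stages one by one.
#'
#' @param stage one of `"scan"`, `"conserve"`, `"call"`, `"filter"`,
#'   `"context"`, `"enrich"`, `"qc"`, `"all"`.
#' @param config a [crm_config()].
#' @return (invisibly) named list of the output paths written.
#' @export
run_pipeline <- function(stage = c("all", PIPELINE_STAGES), config) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "crm_config"))
  stages <- if (stage == "all") PIPELINE_STAGES else stage
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  for (s in stages) {
    outputs[[s]] <- switch(s,
      scan = stage_scan(config),
      conserve = stage_conserve(config),
      call = stage_call(config),
      filter = stage_filter(config),
      context = stage_context(config),
      enrich = stage_enrich(config),
      qc = stage_qc(config))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("crmpred")),
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("input_dir", "output_dir"))],
    inputs = input_hashes(config),
    outputs = unlist(outputs, use.names = TRUE))
  mpath <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(unlist(outputs, use.names = TRUE), manifest = mpath))
}

input_hashes <- function(config) {
  fs <- list.files(config$input_dir, full.names = TRUE)
  h <- tools::md5sum(fs)
  names(h) <- basename(fs)
  as.list(h)
}

inp <- function(config, name) {
  p <- file.path(config$input_dir, name)
  if (!file.exists(p)) stop("missing input '", name, "' in ",
                            config$input_dir)
  p
}

outp <- function(config, name) file.path(config$output_dir, name)

need_upstream <- function(config, name, produced_by) {
  p <- file.path(config$output_dir, name)
  if (!file.exists(p)) {
    stop("missing upstream output '", name, "': run stage '", produced_by,
         "' first")
  }
  p
}

load_ref <- function(config) {
  ann <- read_gff_genes(inp(config, "genes.gff3"))
  list(genome = read_genome(inp(config, "ref.fa"), cds = ann$cds),
       genes = ann$genes)
}

stage_scan <- function(config) {
  ref <- load_ref(config)
  pwms <- read_jaspar(inp(config, "pwms.pfm"))
  hits <- scan_genome(ref$genome, pwms,
                      threshold_fraction = config$threshold_fraction)
  p <- outp(config, "hits.tsv")
  utils::write.table(hits, p, sep = "\t", quote = FALSE, row.names = FALSE)
  write_hits_bed(hits, outp(config, "hits.bed"))
  c(hits = p)
}

stage_conserve <- function(config) {
  need_upstream(config, "hits.tsv", "scan")
  hits <- utils::read.delim(outp(config, "hits.tsv"),
                            stringsAsFactors = FALSE)
  pwms <- read_jaspar(inp(config, "pwms.pfm"))
  blocks <- if (config$block_format == "maf") {
    read_maf(inp(config, "blocks.maf"))
  } else {
    read_alignment_blocks(inp(config, "blocks.tsv"))
  }
  genomes <- lapply(stats::setNames(nm = config$species), function(sp) {
    read_genome(inp(config, paste0(sp, ".fa")))
  })
  ch <- conserve_hits(hits, pwms, genomes, blocks, lambda = config$lambda,
                      max_offset = config$max_offset,
                      threshold_fraction = config$threshold_fraction)
  p <- outp(config, "conserved_hits.tsv")
  utils::write.table(ch, p, sep = "\t", quote = FALSE, row.names = FALSE)
  write_hits_bed(ch, outp(config, "conserved_hits.bed"))
  c(conserved_hits = p)
}

stage_call <- function(config) {
  need_upstream(config, "conserved_hits.tsv", "conserve")
  ch <- utils::read.delim(outp(config, "conserved_hits.tsv"),
                          stringsAsFactors = FALSE)
  crms <- call_crms(ch, window_bp = config$window_bp, K = config$K,
                    min_hits = config$min_hits,
                    score_threshold = config$score_threshold)
  ref <- load_ref(config)
  regions <- fuse_and_extend(crms, fuse_gap_bp = config$fuse_gap_bp,
                             flank_bp = config$flank_bp,
                             seq_lengths = vapply(ref$genome, function(r)
                               nchar(r$sequence), integer(1L)))
  p <- outp(config, "crms.tsv")
  utils::write.table(crms[, setdiff(names(crms), "hits")], p, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_crms_bed(crms, outp(config, "crms.bed"))
  pr <- outp(config, "test_regions.tsv")
  utils::write.table(regions, pr, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pf <- outp(config, "test_regions.fa")
  extract_region_fasta(regions, ref$genome, pf)
  sm <- summarize_crms(crms)
  jsonlite::write_json(sm, outp(config, "crm_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  c(crms = p, test_regions = pr, region_fasta = pf)
}

stage_filter <- function(config) {
  need_upstream(config, "crms.tsv", "call")
  crms <- utils::read.delim(outp(config, "crms.tsv"),
                            stringsAsFactors = FALSE)
  ref <- load_ref(config)
  orthologs <- utils::read.delim(inp(config, "orthologs_human.tsv"),
                                 stringsAsFactors = FALSE)
  human_genes <- gene_models(utils::read.delim(
    inp(config, "human_genes.tsv"), stringsAsFactors = FALSE))
  human <- read_genome(inp(config, "human.fa"))
  anchors <- anchor_crms(crms, ref$genes, orthologs, human_genes,
                         human_seq_lengths = vapply(human, function(r)
                           nchar(r$sequence), integer(1L)),
                         pad = config$anchor_pad)
  calls <- conservation_calls(crms, anchors, ref$genome, human,
                              score_threshold = config$aln_score_threshold,
                              identity_threshold = config$identity_threshold)
  cand <- select_candidates(calls)
  p <- outp(config, "conservation_calls.tsv")
  utils::write.table(calls, p, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cand$top10, outp(config, "candidates_top10.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cand$spread10, outp(config, "candidates_spread10.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  c(conservation_calls = p)
}

stage_context <- function(config) {
  need_upstream(config, "crms.tsv", "call")
  crms <- utils::read.delim(outp(config, "crms.tsv"),
                            stringsAsFactors = FALSE)
  ref <- load_ref(config)
  seq_lengths <- vapply(ref$genome, function(r) nchar(r$sequence),
                        integer(1L))
  masked <- lapply(ref$genome, `[[`, "masked")
  rr <- randomize_and_test(crms, ref$genes, seq_lengths, masked,
                           n_rand = config$n_rand, seed = config$seed)
  p <- outp(config, "location_summary.json")
  jsonlite::write_json(list(
    n = rr$observed$n,
    tss_bins = as.list(stats::setNames(rr$observed$tss_bins,
                                       attr(rr$observed, "names_tss"))),
    gene_classes = as.list(stats::setNames(rr$observed$gene_classes,
                                           attr(rr$observed, "names_classes"))),
    empirical_p_tss = as.list(rr$p_tss),
    empirical_p_gene = as.list(rr$p_gene),
    n_rand = rr$n_rand), p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(location_summary = p)
}

stage_enrich <- function(config) {
  need_upstream(config, "crms.tsv", "call")
  need_upstream(config, "conservation_calls.tsv", "filter")
  crms <- utils::read.delim(outp(config, "crms.tsv"),
                            stringsAsFactors = FALSE)
  calls <- utils::read.delim(outp(config, "conservation_calls.tsv"),
                             stringsAsFactors = FALSE)
  ref <- load_ref(config)
  oz <- utils::read.delim(inp(config, "orthologs_zebrafish.tsv"),
                          stringsAsFactors = FALSE)
  ann <- utils::read.delim(inp(config, "annotations.tsv"),
                           stringsAsFactors = FALSE)
  parents <- utils::read.delim(inp(config, "term_parents.tsv"),
                               stringsAsFactors = FALSE)
  res <- resolve_orthologs(oz)
  ann$gene_id <- res$ref_gene[match(ann$gene_id, res$source_gene)]
  ann <- ann[!is.na(ann$gene_id), , drop = FALSE]
  ann <- expand_term_closure(ann, parents)
  at <- annotate_crms(crms, ref$genes, ann)
  enr <- tryCatch(
    test_enrichment(at$crm_terms, calls$crm_id[calls$passes], crms$crm_id,
                    min_conserved = config$min_conserved, fdr = config$fdr),
    warning = function(w) {
      data.frame(term = character(), stage = character(), a = integer(),
                 b = integer(), c = integer(), d = integer(), p = numeric(),
                 q = numeric(), significant = logical())
    })
  p <- outp(config, "enrichment.tsv")
  utils::write.table(enr, p, sep = "\t", quote = FALSE, row.names = FALSE)
  c(enrichment = p)
}

stage_qc <- function(config) {
  inj <- read_injection_table(inp(config, "injection.tsv"))
  calls <- call_activity(inj, min_specific_rate = config$min_specific_rate,
                         min_fish = config$min_fish)
  sm <- summarize_screen(calls)
  p <- outp(config, "activity_calls.tsv")
  utils::write.table(calls, p, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sm, outp(config, "screen_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  c(activity_calls = p)
}
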