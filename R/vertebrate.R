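#' The HOXD70 substitution matrix
#'
#' The standard HOXD70 nucleotide substitution scores used by BLASTZ-style
#' local alignment, extended with an `N` row/column scoring -100 against
#' everything.
#'
#' @return 5 x 5 integer matrix with dimnames A,C,G,T,N.
#' @export
hoxd70 <- function() {
  m <- matrix(c(
     91, -114,  -31, -123,
   -114,  100, -125,  -31,
    -31, -125,  100, -114,
   -123,  -31, -114,   91), 4, 4, byrow = TRUE,
   dimnames = list(DNA_BASES, DNA_BASES))
  m <- rbind(cbind(m, N = -100L), N = -100L)
  rownames(m)[5L] <- "N"
  storage.mode(m) <- "integer"
  m
}

#' Anchor CRMs to their human orthologous neighborhood
#'
#' Each CRM is associated with the closest reference gene (by distance from
#' the CRM midpoint to the gene span) that has a human ortholog H; the human
#' search interval spans from the left-flanking to the right-flanking gene
#' of H on its chromosome, padded by `pad` bp and clipped to the chromosome.
#' CRMs on sequences without any ortholog-bearing gene are marked
#' unanchorable with a reason.
#'
#' @param crms CRM data.frame ([call_crms()]).
#' @param genes reference [gene_models].
#' @param orthologs data.frame `ref_gene`, `human_gene` (one row per pair;
#'   when several human genes map to one reference gene the first is used).
#' @param human_genes [gene_models] for the human genes (coordinates on the
#'   human assembly).
#' @param human_seq_lengths named vector of human sequence lengths (for
#'   clipping); `Inf` used when a sequence is absent.
#' @param pad padding beyond the flanking genes, bp (default 10000).
#' @return data.frame: `crm_id`, `ref_gene`, `human_gene`, `human_seq`,
#'   `search_start`, `search_end`, `anchored` (logical), `reason`.
#' @export
anchor_crms <- function(crms, genes, orthologs, human_genes,
                        human_seq_lengths = NULL, pad = 10000L) {
  og <- genes[genes$gene_id %in% orthologs$ref_gene, , drop = FALSE]
  out <- vector("list", nrow(crms))
  for (i in seq_len(nrow(crms))) {
    mid <- (crms$start[i] + crms$end[i]) %/% 2L
    cand <- og[og$seq_id == crms$seq_id[i], , drop = FALSE]
    if (nrow(cand) == 0L) {
      out[[i]] <- data.frame(crm_id = crms$crm_id[i], ref_gene = NA,
                             human_gene = NA, human_seq = NA,
                             search_start = NA, search_end = NA,
                             anchored = FALSE,
                             reason = "no ortholog-bearing gene on sequence",
                             stringsAsFactors = FALSE)
      next
    }
    d <- pmax(0L, pmax(cand$start - mid, mid - (cand$end - 1L)))
    gref <- cand$gene_id[which.min(d)]
    hg <- orthologs$human_gene[match(gref, orthologs$ref_gene)]
    hrow <- human_genes[human_genes$gene_id == hg, , drop = FALSE]
    if (nrow(hrow) == 0L) {
      out[[i]] <- data.frame(crm_id = crms$crm_id[i], ref_gene = gref,
                             human_gene = hg, human_seq = NA,
                             search_start = NA, search_end = NA,
                             anchored = FALSE,
                             reason = "human ortholog not in gene table",
                             stringsAsFactors = FALSE)
      next
    }
    chrom <- human_genes[human_genes$seq_id == hrow$seq_id, , drop = FALSE]
    chrom <- chrom[order(chrom$start), , drop = FALSE]
    pos <- which(chrom$gene_id == hg)
    lo <- if (pos > 1L) chrom$start[pos - 1L] else chrom$start[pos]
    hi <- if (pos < nrow(chrom)) chrom$end[pos + 1L] else chrom$end[pos]
    lo <- min(lo, chrom$start[pos]); hi <- max(hi, chrom$end[pos])
    slen <- if (!is.null(human_seq_lengths) &&
                hrow$seq_id %in% names(human_seq_lengths)) {
      human_seq_lengths[[hrow$seq_id]]
    } else Inf
    out[[i]] <- data.frame(crm_id = crms$crm_id[i], ref_gene = gref,
                           human_gene = hg, human_seq = hrow$seq_id,
                           search_start = max(0, lo - pad),
                           search_end = min(slen, hi + pad),
                           anchored = TRUE, reason = NA_character_,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Local alignment of a CRM against its human search interval
#'
#' Best Smith-Waterman local alignment under HOXD70 with affine gap costs
#' (open 400, extend 30 per bp), checked on both strands of the CRM
#' sequence. A CRM passes the pan-vertebrate conservation filter when the
#' alignment score is strictly greater than `score_threshold` AND the
#' percent identity over aligned columns is strictly greater than
#' `identity_threshold` — a score of exactly 2600 or an identity of exactly
#' 60 does not pass.
#'
#' @param crm_seq CRM DNA sequence (character).
#' @param search_seq human search-interval DNA sequence.
#' @param score_threshold minimum (exclusive) alignment score (default 2600).
#' @param identity_threshold minimum (exclusive) percent identity
#'   (default 60).
#' @param gap_open,gap_extend affine gap costs (default 400 / 30).
#' @return list: `aln_score`, `pct_identity` (matches / aligned columns x
#'   100, gap columns included), `strand`, `passes`.
#' @export
align_to_human <- function(crm_seq, search_seq, score_threshold = 2600,
                           identity_threshold = 60,
                           gap_open = 400, gap_extend = 30) {
  stopifnot(nchar(crm_seq) > 0L, nchar(search_seq) > 0L)
  sm <- hoxd70()
  one <- function(s) {
    Biostrings::pairwiseAlignment(s, search_seq, type = "local",
                                  substitutionMatrix = sm,
                                  gapOpening = gap_open,
                                  gapExtension = gap_extend)
  }
  pf <- one(crm_seq)
  pr <- one(revcomp(crm_seq))
  pa <- if (Biostrings::score(pf) >= Biostrings::score(pr)) pf else pr
  strand <- if (Biostrings::score(pf) >= Biostrings::score(pr)) "+" else "-"
  sc <- Biostrings::score(pa)
  ncol_aln <- Biostrings::nchar(pa)
  pid <- if (ncol_aln > 0L) 100 * Biostrings::nmatch(pa) / ncol_aln else 0
  list(aln_score = sc, pct_identity = pid, strand = strand,
       passes = (sc > score_threshold) && (pid > identity_threshold))
}

#' Conservation calls for a CRM set
#'
#' Runs [align_to_human()] for every anchored CRM, extracting the CRM
#' sequence from the reference genome and the search sequence from the human
#' genome.
#'
#' @param crms CRM data.frame.
#' @param anchors anchor table from [anchor_crms()].
#' @param ref_genome named list of reference [sequence_record]s.
#' @param human_genome named list of human [sequence_record]s.
#' @inheritParams align_to_human
#' @return data.frame: `crm_id`, `score` (CRM score), `seq_id`, `start`,
#'   `end`, `aln_score`, `pct_identity`, `passes` (FALSE with `NA` alignment
#'   fields for unanchorable CRMs).
#' @export
conservation_calls <- function(crms, anchors, ref_genome, human_genome,
                               score_threshold = 2600,
                               identity_threshold = 60) {
  out <- list()
  for (i in seq_len(nrow(crms))) {
    a <- anchors[anchors$crm_id == crms$crm_id[i], , drop = FALSE]
    if (nrow(a) == 0L || !a$anchored) {
      out[[i]] <- data.frame(crm_id = crms$crm_id[i], score = crms$score[i],
                             seq_id = crms$seq_id[i], start = crms$start[i],
                             end = crms$end[i], aln_score = NA_real_,
                             pct_identity = NA_real_, passes = FALSE,
                             stringsAsFactors = FALSE)
      next
    }
    cseq <- subseq0(ref_genome[[crms$seq_id[i]]], crms$start[i], crms$end[i])
    hrec <- human_genome[[a$human_seq]]
    hseq <- subseq0(hrec, as.integer(a$search_start),
                    min(as.integer(a$search_end), nchar(hrec$sequence)))
    call <- align_to_human(cseq, hseq, score_threshold, identity_threshold)
    out[[i]] <- data.frame(crm_id = crms$crm_id[i], score = crms$score[i],
                           seq_id = crms$seq_id[i], start = crms$start[i],
                           end = crms$end[i], aln_score = call$aln_score,
                           pct_identity = call$pct_identity,
                           passes = call$passes, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank vertebrate-conserved CRMs and pick candidate sets
#'
#' Passing CRMs are sorted by CRM score descending (ties broken by genomic
#' position ascending: `seq_id`, then `start`). Two candidate lists are
#' returned: the top 10, and the CRMs at the fixed rank positions
#' 20, 40, 60, 81, 100, 120, 140, 159, 180, 200 of the top 200. Rank
#' positions beyond the number of passing CRMs are dropped with a warning.
#'
#' @param calls data.frame from [conservation_calls()] (needs `crm_id`,
#'   `score`, `seq_id`, `start`, `passes`).
#' @param spread_positions the rank positions of the spread list.
#' @return list with data.frames `top10` and `spread10`, each carrying a
#'   `rank` column.
#' @export
select_candidates <- function(calls,
                              spread_positions = c(20L, 40L, 60L, 81L, 100L,
                                                   120L, 140L, 159L, 180L,
                                                   200L)) {
  p <- calls[calls$passes, , drop = FALSE]
  if (nrow(p) == 0L) {
    e <- p; e$rank <- integer(0)
    return(list(top10 = e, spread10 = e))
  }
  p <- p[order(-p$score, p$seq_id, p$start), , drop = FALSE]
  p$rank <- seq_len(nrow(p))
  rownames(p) <- NULL
  top10 <- p[seq_len(min(10L, nrow(p))), , drop = FALSE]
  keep <- spread_positions[spread_positions <= nrow(p)]
  if (length(keep) < length(spread_positions)) {
    warning("only ", nrow(p), " passing CRMs; spread positions clipped")
  }
  list(top10 = top10, spread10 = p[keep, , drop = FALSE])
}
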