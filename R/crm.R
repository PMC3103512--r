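#' Cluster conserved binding-site hits into CRMs
#'
#' Identifies clusters of conserved homotypic or oligotypic binding sites by
#' a sliding maximal-scoring window over each sequence. Every run of
#' positionally consecutive hits whose span fits within `window_bp` is a
#' candidate window; within a window the CRM score is:
#' \itemize{
#'   \item oligotypic (two or more distinct matrices): the sum of the best
#'     hit per matrix over the top `K` matrices — the contributing hits are
#'     one per tag matrix;
#'   \item homotypic (a single matrix): the sum of the top `K` hits of that
#'     matrix, so single-factor clusters are not starved of score.
#' }
#' Windows holding at least `min_hits` conserved hits and scoring at least
#' `score_threshold` become candidates; candidates are selected greedily by
#' descending score (leftmost wins ties) subject to non-overlap, and each
#' selected CRM is trimmed to the outermost contributing hit boundaries.
#'
#' @param hits conserved-hit data.frame from [conserve_hits()] (columns
#'   `seq_id`, `start`, `end`, `matrix_id`, `combined_score`).
#' @param window_bp maximum cluster span in bp (default 1000).
#' @param K maximum number of tag matrices / homotypic sites scored
#'   (default 5).
#' @param min_hits minimum conserved hits in a window (default 3).
#' @param score_threshold minimum CRM score in bits. The default (41) was
#'   fixed by [calibrate_score_threshold()] at a 1 percent window-level
#'   false-positive rate on the null fixture (zero planted clusters, hit
#'   positions shuffled over the scannable space, pooled over 30 null
#'   genomes).
#' @return data.frame with one row per CRM: `crm_id`, `seq_id`, `start`,
#'   `end` (0-based half-open, pre-extension), `score`, `n_sites` (all
#'   conserved hits in the span), `n_tags`, `tag_matrices`
#'   (comma-separated), and a list-column `hits` holding the contributing
#'   hits of each CRM.
#' @export
call_crms <- function(hits, window_bp = 1000L, K = 5L, min_hits = 3L,
                      score_threshold = 41) {
  empty <- data.frame(crm_id = character(), seq_id = character(),
                      start = integer(), end = integer(), score = numeric(),
                      n_sites = integer(), n_tags = integer(),
                      tag_matrices = character(), stringsAsFactors = FALSE)
  empty$hits <- list()
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  if (!"combined_score" %in% names(hits)) {
    stop("hits must carry a combined_score column (run conserve_hits first)")
  }
  out <- list()
  for (sid in unique(hits$seq_id)) {
    hh <- hits[hits$seq_id == sid, , drop = FALSE]
    hh <- hh[order(hh$start, hh$end), , drop = FALSE]
    rownames(hh) <- NULL
    cands <- enumerate_windows(hh, window_bp, K, min_hits, score_threshold)
    if (length(cands) == 0L) next
    cs <- vapply(cands, `[[`, numeric(1L), "score")
    cstart <- vapply(cands, `[[`, numeric(1L), "start")
    cend <- vapply(cands, `[[`, numeric(1L), "end")
    ord <- order(-cs, cstart)
    taken <- logical(length(cands))
    blocked <- logical(length(cands))
    for (j in ord) {
      if (blocked[j]) next
      taken[j] <- TRUE
      blocked <- blocked | (cstart < cend[j] & cend > cstart[j])
    }
    for (j in which(taken)) {
      cc <- cands[[j]]
      n_sites <- sum(hh$start >= cc$start & hh$end <= cc$end)
      tags <- sort(unique(cc$contrib$matrix_id))
      row <- data.frame(crm_id = NA_character_, seq_id = sid,
                        start = cc$start, end = cc$end, score = cc$score,
                        n_sites = n_sites, n_tags = length(tags),
                        tag_matrices = paste(tags, collapse = ","),
                        stringsAsFactors = FALSE)
      row$hits <- list(cc$contrib)
      out[[length(out) + 1L]] <- row
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$seq_id, res$start), , drop = FALSE]
  res$crm_id <- sprintf("CRM%04d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res[, c("crm_id", setdiff(names(res), "crm_id"))]
}

# enumerate candidate windows: every run of consecutive hits i..j whose span
# fits in window_bp, holds >= min_hits hits and scores >= score_threshold
enumerate_windows <- function(hh, window_bp, K, min_hits, score_threshold) {
  n <- nrow(hh)
  cands <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (hh$end[j] - hh$start[i] > window_bp) break
      if (j - i + 1L < min_hits) next
      ww <- hh[i:j, , drop = FALSE]
      sc <- score_window(ww, K)
      if (sc$score < score_threshold) next
      cands[[length(cands) + 1L]] <- list(
        score = sc$score, contrib = ww[sc$contrib, , drop = FALSE],
        start = min(ww$start[sc$contrib]), end = max(ww$end[sc$contrib]))
    }
  }
  cands
}

# score a window of hits: best-per-matrix over top-K matrices, or top-K hits
# of the single matrix in the homotypic case; returns contributing row indices
score_window <- function(ww, K) {
  mats <- unique(ww$matrix_id)
  if (length(mats) == 1L) {
    ord <- order(-ww$combined_score)
    pick <- ord[seq_len(min(K, length(ord)))]
    return(list(score = sum(ww$combined_score[pick]), contrib = sort(pick)))
  }
  best <- vapply(mats, function(m) {
    ii <- which(ww$matrix_id == m)
    ii[which.max(ww$combined_score[ii])]
  }, integer(1L))
  ord <- best[order(-ww$combined_score[best])]
  pick <- ord[seq_len(min(K, length(ord)))]
  list(score = sum(ww$combined_score[pick]), contrib = sort(unname(pick)))
}

#' Calibrate the CRM score threshold on a null hit set
#'
#' Scores every candidate window (>= `min_hits` hits) over a null hit set —
#' e.g. conserved hits whose positions were shuffled over the scannable
#' space — and returns the score quantile giving a window-level
#' false-positive rate of `fpr`.
#'
#' @param null_hits conserved-hit data.frame drawn under the null.
#' @inheritParams call_crms
#' @param fpr tolerated window-level false-positive rate (default 0.01).
#' @return numeric threshold (bits); `Inf` when no null window reaches
#'   `min_hits`, in which case any window passing `min_hits` is already rarer
#'   than `fpr` under the null.
#' @export
calibrate_score_threshold <- function(null_hits, window_bp = 1000L, K = 5L,
                                      min_hits = 3L, fpr = 0.01) {
  scores <- numeric(0)
  for (sid in unique(null_hits$seq_id)) {
    hh <- null_hits[null_hits$seq_id == sid, , drop = FALSE]
    hh <- hh[order(hh$start), , drop = FALSE]
    cands <- enumerate_windows(hh, window_bp, K, min_hits, -Inf)
    scores <- c(scores, vapply(cands, `[[`, numeric(1L), "score"))
  }
  if (length(scores) == 0L) return(Inf)
  as.numeric(stats::quantile(scores, probs = 1 - fpr, names = FALSE,
                             type = 1L))
}

#' Fuse close-by CRMs and add flanking sequence
#'
#' Merges CRMs on the same sequence whose gap is at most `fuse_gap_bp`, then
#' extends each fused region by `flank_bp` on each side, clipped to the
#' sequence bounds — producing the regions taken into the enhancer assay.
#'
#' @param crms CRM data.frame from [call_crms()].
#' @param fuse_gap_bp maximum gap merged (default 500).
#' @param flank_bp flank added each side (default 200).
#' @param seq_lengths named integer vector of sequence lengths.
#' @return data.frame: `region_id`, `seq_id`, `start`, `end`,
#'   `source_crms` (comma-separated crm ids), `flank`.
#' @export
fuse_and_extend <- function(crms, fuse_gap_bp = 500L, flank_bp = 200L,
                            seq_lengths) {
  out <- list()
  for (sid in unique(crms$seq_id)) {
    cc <- crms[crms$seq_id == sid, , drop = FALSE]
    cc <- cc[order(cc$start), , drop = FALSE]
    ir <- IRanges::IRanges(cc$start + 1L, cc$end)
    red <- IRanges::reduce(ir, min.gapwidth = fuse_gap_bp + 1L)
    ov <- IRanges::findOverlaps(ir, red)
    slen <- seq_lengths[[sid]]
    if (is.null(slen)) stop("no sequence length supplied for '", sid, "'")
    for (j in seq_along(red)) {
      src <- cc$crm_id[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == j]]
      s0 <- IRanges::start(red)[j] - 1L
      e0 <- IRanges::end(red)[j]
      out[[length(out) + 1L]] <- data.frame(
        region_id = NA_character_, seq_id = sid,
        start = max(0L, s0 - flank_bp),
        end = min(slen, e0 + flank_bp),
        source_crms = paste(src, collapse = ","),
        flank = flank_bp, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$seq_id, res$start), , drop = FALSE]
  res$region_id <- sprintf("REG%03d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

#' Summary statistics of a CRM set
#'
#' @param crms CRM data.frame from [call_crms()].
#' @return list with `count`, `mean_length`, `median_length`, `mean_sites`
#'   (lengths from pre-extension boundaries); the summary fields are `NA`
#'   when the set is empty.
#' @export
summarize_crms <- function(crms) {
  if (is.null(crms) || nrow(crms) == 0L) {
    return(list(count = 0L, mean_length = NA_real_, median_length = NA_real_,
                mean_sites = NA_real_))
  }
  len <- crms$end - crms$start
  list(count = nrow(crms), mean_length = mean(len),
       median_length = stats::median(len), mean_sites = mean(crms$n_sites))
}

#' Extract test-region sequences as FASTA
#'
#' Writes the sequence of each region (e.g. from [fuse_and_extend()]) for
#' downstream primer design.
#'
#' @param regions data.frame with `region_id` (or `crm_id`), `seq_id`,
#'   `start`, `end`.
#' @param genome named list of [sequence_record]s.
#' @param path output FASTA path.
#' @export
extract_region_fasta <- function(regions, genome, path) {
  ids <- if ("region_id" %in% names(regions)) regions$region_id else
    regions$crm_id
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(regions))) {
    rec <- genome[[regions$seq_id[i]]]
    if (is.null(rec)) stop("sequence '", regions$seq_id[i], "' not found")
    writeLines(c(paste0(">", ids[i], " ", regions$seq_id[i], ":",
                        regions$start[i], "-", regions$end[i]),
                 subseq0(rec, regions$start[i], regions$end[i])), con)
  }
  invisible(path)
}

#' Write CRMs or test regions as BED6 plus a JSON sidecar
#'
#' @param crms CRM data.frame; a JSON sidecar `<path>.json` records tag
#'   matrices and contributing hits per CRM.
#' @param path BED output path.
#' @export
write_crms_bed <- function(crms, path) {
  bed <- data.frame(crms$seq_id, crms$start, crms$end, crms$crm_id,
                    round(crms$score * 100), ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  side <- lapply(seq_len(nrow(crms)), function(i) {
    list(crm_id = crms$crm_id[i],
         tag_matrices = strsplit(crms$tag_matrices[i], ",")[[1L]],
         n_sites = crms$n_sites[i],
         hits = if ("hits" %in% names(crms)) {
           h <- crms$hits[[i]]
           h[, intersect(c("matrix_id", "start", "end", "strand",
                           "combined_score"), names(h)), drop = FALSE]
         } else NULL)
  })
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
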