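#' Scan a masked sequence for PWM hits
#'
#' Slides the PWM over both strands of the sequence and reports windows whose
#' log-odds score (bits, uniform background) reaches the per-matrix
#' threshold. The reverse strand is scored by scanning with the
#' reverse-complemented matrix, which is equivalent to scoring the
#' reverse-complement of each window. Windows containing `N` or overlapping a
#' masked interval are skipped.
#'
#' The default threshold policy is a fraction of the matrix's maximum
#' achievable score (`threshold_fraction * pwm_max_score(pwm)`); an absolute
#' `min_score` overrides it.
#'
#' @param record a [sequence_record].
#' @param pwm a [pwm] object.
#' @param threshold_fraction fraction of the maximum achievable bit score
#'   required for a hit (default 0.75).
#' @param min_score absolute bit-score threshold; overrides
#'   `threshold_fraction` when non-NULL.
#' @return data.frame of hits: `matrix_id`, `seq_id`, `start`, `end` (0-based
#'   half-open, `end - start == width`), `strand` ("+"/"-"), `score` (bits).
#' @examples
#' r <- sequence_record("s", "ACGTACGTAAAA")
#' p <- pwm(matrix(c(97,1,1,1), 1, 4, byrow = TRUE), "M", "TF", "jaspar")
#' scan_sequence(r, p, threshold_fraction = 0.5)
#' @export
scan_sequence <- function(record, pwm, threshold_fraction = 0.75,
                          min_score = NULL) {
  stopifnot(inherits(record, "sequence_record"), inherits(pwm, "pwm"))
  w <- pwm$width
  n <- nchar(record$sequence)
  empty <- data.frame(matrix_id = character(), seq_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (n < w) return(empty)
  thr <- if (is.null(min_score)) threshold_fraction * pwm_max_score(pwm) else min_score

  idx <- match(strsplit(record$sequence, "")[[1L]], DNA_BASES)  # N -> NA
  bad <- is.na(idx)
  if (length(record$masked)) {
    for (i in seq_along(record$masked)) {
      bad[IRanges::start(record$masked)[i]:IRanges::end(record$masked)[i]] <- TRUE
    }
  }
  nwin <- n - w + 1L
  lo_f <- pwm_log_odds(pwm)
  lo_r <- pwm_log_odds(pwm_reverse_complement(pwm))
  sc_f <- numeric(nwin)
  sc_r <- numeric(nwin)
  ok <- !bad
  valid <- ok[seq_len(nwin)]
  for (j in seq_len(w)) {
    b <- idx[j:(j + nwin - 1L)]
    bi <- ifelse(is.na(b), 1L, b)
    sc_f <- sc_f + lo_f[j, bi]
    sc_r <- sc_r + lo_r[j, bi]
    if (j > 1L) valid <- valid & ok[j:(j + nwin - 1L)]
  }
  hit_f <- which(valid & sc_f >= thr)
  hit_r <- which(valid & sc_r >= thr)
  nh <- length(hit_f) + length(hit_r)
  out <- data.frame(
    matrix_id = rep(pwm$matrix_id, nh),
    seq_id = rep(record$seq_id, nh),
    start = c(hit_f, hit_r) - 1L,
    end = c(hit_f, hit_r) - 1L + w,
    strand = rep(c("+", "-"), c(length(hit_f), length(hit_r))),
    score = c(sc_f[hit_f], sc_r[hit_r]),
    stringsAsFactors = FALSE
  )
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Scan a genome with a PWM collection
#'
#' Applies [scan_sequence()] to every record/matrix pair and concatenates
#' the hits.
#'
#' @param records list of [sequence_record]s.
#' @param pwms list of [pwm]s.
#' @inheritParams scan_sequence
#' @return data.frame of hits (see [scan_sequence()]), sorted by sequence and
#'   position.
#' @export
scan_genome <- function(records, pwms, threshold_fraction = 0.75,
                        min_score = NULL) {
  res <- list()
  for (r in records) {
    for (p in pwms) {
      res[[length(res) + 1L]] <- scan_sequence(r, p, threshold_fraction,
                                               min_score)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(matrix_id = character(), seq_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  out <- out[order(out$seq_id, out$start, out$matrix_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write binding-site hits as BED6
#'
#' Name column holds the matrix id; the BED score is the bit score times 100,
#' rounded.
#'
#' @param hits hit data.frame from [scan_sequence()] or [conserve_hits()];
#'   when a `combined_score` column is present it is used for the BED score
#'   and appended (with support columns) after the strand field.
#' @param path output file.
#' @export
write_hits_bed <- function(hits, path) {
  score_col <- if ("combined_score" %in% names(hits)) "combined_score" else "score"
  bed <- data.frame(hits$seq_id, hits$start, hits$end, hits$matrix_id,
                    round(hits[[score_col]] * 100), hits$strand)
  extra <- intersect(c("score", "combined_score", "support_species",
                       "support_score", "support_offset"), names(hits))
  if (score_col == "combined_score") bed <- cbind(bed, hits[extra])
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
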