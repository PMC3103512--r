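#' Conservation-weighted hit score
#'
#' Combines a reference-genome binding-site score with the best supporting
#' hit among the comparison species:
#' \deqn{combined = ref + \max_s \max(0,\; score_s - \lambda |offset_s|)}
#' Absent species contribute 0, so a strong reference hit can stand alone
#' without conservation, while support from any one comparison species raises
#' the score. Misalignment of the supporting site relative to its projected
#' position is tolerated up to `max_offset` bp and penalized linearly at
#' `lambda` bits per bp.
#'
#' @param ref_score reference hit score in bits (vectorized).
#' @param species_scores numeric vector (or list of vectors, one per input
#'   element) of comparison-species hit scores in bits; `NA` = no hit.
#' @param offsets misalignment offsets in bp, parallel to `species_scores`.
#' @param lambda misalignment penalty, bits per bp (default 0.1).
#' @param max_offset maximum tolerated |offset| (default 20); larger offsets
#'   are rejected as invalid input.
#' @return numeric vector of combined scores (bits).
#' @examples
#' combine_hit_score(5, c(3, 4, 1), c(0, 0, 0))   # 9
#' combine_hit_score(5, numeric(0), numeric(0))   # 5
#' @export
combine_hit_score <- function(ref_score, species_scores, offsets,
                              lambda = 0.1, max_offset = 20L) {
  if (!is.list(species_scores)) {
    species_scores <- list(species_scores)
    offsets <- list(offsets)
    stopifnot(length(ref_score) == 1L)
  }
  vapply(seq_along(ref_score), function(i) {
    s <- species_scores[[i]]; o <- offsets[[i]]
    keep <- !is.na(s)
    s <- s[keep]; o <- o[keep]
    if (any(abs(o) > max_offset)) {
      stop("support offset exceeds the ", max_offset, " bp tolerance")
    }
    ref_score[i] + max(0, s - lambda * abs(o))
  }, numeric(1L))
}

#' Attach cross-species conservation support to reference hits
#'
#' For each reference hit and each comparison species, the hit is projected
#' through the alignment blocks ([map_hit()]), the projected window
#' (+/- `max_offset` bp) is rescanned with the same matrix on both strands at
#' the same threshold policy, and the best penalized supporting hit is
#' recorded. The combined score follows [combine_hit_score()]. When several
#' species tie for the best penalized support, the reported supporting
#' species is the first in `names(comparison_genomes)` order.
#'
#' @param hits reference hit data.frame from [scan_genome()].
#' @param pwms list of [pwm]s covering every `matrix_id` in `hits`.
#' @param comparison_genomes named list (by species, in tie-break order) of
#'   named [sequence_record] lists.
#' @param blocks an [alignment_blocks] table.
#' @param lambda misalignment penalty, bits/bp.
#' @param max_offset misalignment tolerance, bp.
#' @param threshold_fraction per-matrix threshold policy used for the
#'   comparison-species rescans (same default as [scan_sequence()]).
#' @return `hits` with columns added: `combined_score`,
#'   `support_species` (NA when unsupported), `support_score`,
#'   `support_offset`, and one `score_<species>` column per species.
#' @export
conserve_hits <- function(hits, pwms, comparison_genomes, blocks,
                          lambda = 0.1, max_offset = 20L,
                          threshold_fraction = 0.75) {
  species <- names(comparison_genomes)
  pw <- stats::setNames(pwms, vapply(pwms, `[[`, character(1L), "matrix_id"))
  n <- nrow(hits)
  if (n == 0L) {
    hits$combined_score <- numeric(0)
    hits$support_species <- character(0)
    hits$support_score <- numeric(0)
    hits$support_offset <- integer(0)
    for (sp in species) hits[[paste0("score_", sp)]] <- numeric(0)
    return(hits)
  }
  contrib <- matrix(0, n, length(species), dimnames = list(NULL, species))
  raw <- matrix(NA_real_, n, length(species), dimnames = list(NULL, species))
  offs <- matrix(NA_integer_, n, length(species))
  for (i in seq_len(n)) {
    h <- hits[i, , drop = FALSE]
    p <- pw[[h$matrix_id]]
    if (is.null(p)) stop("no PWM supplied for matrix '", h$matrix_id, "'")
    for (k in seq_along(species)) {
      prj <- map_hit(h, blocks, species[k], max_offset)
      if (is.null(prj)) next
      rec <- comparison_genomes[[species[k]]][[prj$other_seq]]
      if (is.null(rec)) next
      win <- sequence_record(prj$other_seq,
                             subseq0(rec, prj$win_start, prj$win_end))
      cand <- scan_sequence(win, p, threshold_fraction = threshold_fraction)
      if (nrow(cand) == 0L) next
      cand_off <- cand$start + prj$win_start - prj$proj_start
      keep <- abs(cand_off) <= max_offset
      if (!any(keep)) next
      pen <- cand$score[keep] - lambda * abs(cand_off[keep])
      j <- which.max(pen)
      raw[i, k] <- cand$score[keep][j]
      offs[i, k] <- cand_off[keep][j]
      contrib[i, k] <- max(0, pen[j])
    }
  }
  best <- apply(contrib, 1L, max)
  best_sp <- apply(contrib, 1L, function(v) {
    if (max(v) <= 0) NA_integer_ else which.max(v)  # first species wins ties
  })
  hits$combined_score <- hits$score + best
  hits$support_species <- ifelse(is.na(best_sp), NA_character_,
                                 species[best_sp])
  hits$support_score <- raw[cbind(seq_len(n),
                                  ifelse(is.na(best_sp), 1L, best_sp))]
  hits$support_score[is.na(best_sp)] <- NA_real_
  hits$support_offset <- offs[cbind(seq_len(n),
                                    ifelse(is.na(best_sp), 1L, best_sp))]
  hits$support_offset[is.na(best_sp)] <- NA_integer_
  for (k in seq_along(species)) {
    hits[[paste0("score_", species[k])]] <- raw[, k]
  }
  hits
}
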