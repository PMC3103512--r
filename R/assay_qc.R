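#' Score enhancer-assay injection experiments
#'
#' The assay injects a candidate region upstream of a minimal promoter whose
#' intrinsic lens expression reports injection success. Per region:
#' `injection_rate = n_lens / n_alive` and
#' `specific_rate = n_specific / n_lens` (reproducible non-lens expression
#' among successfully injected embryos). A region is called positive when
#' the specific rate is strictly above 0.5 AND the consistent pattern was
#' seen in at least 10 individual fish. Experiments with `n_lens == 0` are
#' flagged `"injection_failed"` and receive no positivity verdict.
#'
#' @param experiments data.frame with columns `region_id`, `n_alive`,
#'   `n_lens`, `n_specific` (counts; `0 <= n_specific <= n_lens <= n_alive`).
#' @param min_specific_rate exclusive specific-rate threshold (default 0.5).
#' @param min_fish minimum embryos with the consistent pattern (default 10).
#' @return data.frame: `region_id`, `n_alive`, `n_lens`, `n_specific`,
#'   `injection_rate`, `specific_rate`, `status` ("ok"/"injection_failed"),
#'   `positive` (logical, `NA` on failed injections).
#' @examples
#' call_activity(data.frame(region_id = "r1", n_alive = 100, n_lens = 46,
#'                          n_specific = 30))
#' @export
call_activity <- function(experiments, min_specific_rate = 0.5,
                          min_fish = 10L) {
  e <- experiments
  need <- c("region_id", "n_alive", "n_lens", "n_specific")
  missing <- setdiff(need, names(e))
  if (length(missing)) stop("experiment table lacks columns: ",
                            paste(missing, collapse = ", "))
  if (any(e$n_specific > e$n_lens | e$n_lens > e$n_alive |
          e$n_specific < 0)) {
    stop("counts must satisfy 0 <= n_specific <= n_lens <= n_alive")
  }
  failed <- e$n_lens == 0L
  e$injection_rate <- ifelse(e$n_alive > 0, e$n_lens / e$n_alive, NA_real_)
  e$specific_rate <- ifelse(failed, NA_real_, e$n_specific / e$n_lens)
  e$status <- ifelse(failed, "injection_failed", "ok")
  e$positive <- ifelse(failed, NA,
                       e$specific_rate > min_specific_rate &
                         e$n_specific >= min_fish)
  e
}

#' Summarize an enhancer screen
#'
#' @param calls data.frame from [call_activity()]. Failed injections
#'   (`status == "injection_failed"`) are excluded from the tested count.
#' @return list: `n_tested`, `n_positive`, `pct_positive`
#'   (100 * n_positive / n_tested), `mean_specific_rate`,
#'   `mean_injection_rate`. All zero (with a warning) on empty input.
#' @export
summarize_screen <- function(calls) {
  ok <- calls[!is.na(calls$positive), , drop = FALSE]
  if (nrow(ok) == 0L) {
    warning("no scorable experiments")
    return(list(n_tested = 0L, n_positive = 0L, pct_positive = 0,
                mean_specific_rate = 0, mean_injection_rate = 0))
  }
  list(n_tested = nrow(ok),
       n_positive = sum(ok$positive),
       pct_positive = 100 * sum(ok$positive) / nrow(ok),
       mean_specific_rate = mean(ok$specific_rate),
       mean_injection_rate = mean(ok$injection_rate))
}

#' Ontology coverage of a set of reporter lines
#'
#' Counts how many terms of a controlled vocabulary (e.g. the neuronal
#' structures of an anatomical ontology) are labeled in at least one line.
#' The percentage is floored to an integer. Terms used by lines but absent
#' from the vocabulary are reported back and excluded from the count.
#'
#' @param line_terms list (one element per line) of character term vectors.
#' @param vocabulary character vector of controlled-vocabulary terms.
#' @return list: `n_labeled`, `n_vocabulary`, `pct`
#'   (`floor(100 * n_labeled / n_vocabulary)`), `labeled` (sorted terms),
#'   `unknown_terms` (terms outside the vocabulary).
#' @export
ontology_coverage <- function(line_terms, vocabulary) {
  if (length(vocabulary) == 0L) stop("vocabulary must be non-empty")
  used <- unique(unlist(line_terms))
  unknown <- setdiff(used, vocabulary)
  labeled <- sort(intersect(used, vocabulary))
  list(n_labeled = length(labeled),
       n_vocabulary = length(vocabulary),
       pct = floor(100 * length(labeled) / length(vocabulary)),
       labeled = labeled,
       unknown_terms = sort(unknown))
}

#' Read an injection-experiment table
#'
#' Tab-separated with columns `region_id`, `n_alive`, `n_lens`,
#' `n_specific`.
#'
#' @param path TSV file.
#' @return data.frame suitable for [call_activity()].
#' @export
read_injection_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
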