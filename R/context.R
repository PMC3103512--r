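#' Classify CRM genomic locations
#'
#' Each CRM is summarized by its midpoint. Two classifications are reported:
#' distance to the nearest annotated TSS, binned half-open into
#' `[0,1kb) [1,10kb) [10,100kb) [100kb,Inf)`, and a gene-relative class —
#' intragenic when the midpoint falls within any gene span, otherwise
#' intergenic split at 100 kb from the nearest gene boundary. CRMs on
#' sequences without any annotated gene are counted in the most distal bin
#' of both classifications, with a warning.
#'
#' @param crms CRM data.frame (needs `seq_id`, `start`, `end`).
#' @param genes [gene_models] data.frame.
#' @return object of class `location_summary`: list with `n`, `tss_bins`
#'   (named fractions), `gene_classes` (named fractions), `tss_counts`,
#'   `gene_counts`.
#' @export
classify_locations <- function(crms, genes) {
  bins <- c("lt1kb", "1to10kb", "10to100kb", "gt100kb")
  classes <- c("intragenic", "intergenic_lt100kb", "intergenic_gt100kb")
  n <- nrow(crms)
  tss_bin <- character(n)
  gene_class <- character(n)
  mid <- (crms$start + crms$end) %/% 2L
  for (sid in unique(crms$seq_id)) {
    ii <- which(crms$seq_id == sid)
    gg <- genes[genes$seq_id == sid, , drop = FALSE]
    if (nrow(gg) == 0L) {
      warning("sequence '", sid, "' has no annotated genes; ",
              "its CRMs are counted as >100kb / intergenic >100kb")
      tss_bin[ii] <- "gt100kb"
      gene_class[ii] <- "intergenic_gt100kb"
      next
    }
    m <- mid[ii]
    dtss <- apply(abs(outer(m, gg$tss, `-`)), 1L, min)
    tss_bin[ii] <- bins[findInterval(dtss, c(0, 1e3, 1e4, 1e5))]
    inside <- rowSums(outer(m, gg$start, `>=`) & outer(m, gg$end, `<`)) > 0
    dgene <- apply(pmax(outer(gg$start, m, `-`),
                        outer(gg$end - 1L, m, function(a, b) b - a)),
                   2L, min)
    gene_class[ii] <- ifelse(inside, "intragenic",
                             ifelse(dgene < 1e5, "intergenic_lt100kb",
                                    "intergenic_gt100kb"))
  }
  tss_counts <- table(factor(tss_bin, levels = bins))
  gene_counts <- table(factor(gene_class, levels = classes))
  structure(list(
    n = n,
    tss_bins = as.numeric(tss_counts) / max(1L, n),
    gene_classes = as.numeric(gene_counts) / max(1L, n),
    tss_counts = as.integer(tss_counts),
    gene_counts = as.integer(gene_counts)
  ), names_tss = bins, names_classes = classes, class = "location_summary")
}

#' @export
print.location_summary <- function(x, ...) {
  cat("location summary of", x$n, "regions\n")
  cat("  TSS distance: ",
      paste(sprintf("%s %.1f%%", attr(x, "names_tss"), 100 * x$tss_bins),
            collapse = ", "), "\n")
  cat("  gene context: ",
      paste(sprintf("%s %.1f%%", attr(x, "names_classes"),
                    100 * x$gene_classes), collapse = ", "), "\n")
  invisible(x)
}

#' Draw a size-matched random CRM set
#'
#' Places `nrow(crms)` intervals uniformly over the scannable (unmasked)
#' space of the genome, reusing the observed length multiset (permuted).
#' Draws whose interval would overlap a masked region or run off the
#' sequence end are rejected and redrawn.
#'
#' @param crms observed CRM data.frame.
#' @param seq_lengths named integer vector of sequence lengths.
#' @param masked named list of [IRanges::IRanges] masked intervals (as in
#'   [sequence_record]), or NULL.
#' @return data.frame with `seq_id`, `start`, `end`.
#' @keywords internal
random_locations <- function(crms, seq_lengths, masked = NULL) {
  lens <- sample(crms$end - crms$start)
  seqs <- names(seq_lengths)
  totals <- as.numeric(seq_lengths)
  if (any(lens > max(totals))) {
    stop("a region is longer than every sequence")
  }
  n <- length(lens)
  out_seq <- character(n)
  out_start <- integer(n)
  todo <- seq_len(n)
  guard <- 0L
  while (length(todo)) {
    guard <- guard + 1L
    if (guard > 100000L) stop("random placement failed; mask too dense")
    sid <- sample(seqs, length(todo), replace = TRUE, prob = totals)
    smax <- totals[match(sid, seqs)] - lens[todo]
    ok <- smax >= 0
    s0 <- rep(NA_integer_, length(todo))
    s0[ok] <- as.integer(floor(stats::runif(sum(ok)) * (smax[ok] + 1)))
    if (!is.null(masked)) {
      for (u in unique(sid[ok])) {
        mi <- masked[[u]]
        if (is.null(mi) || length(mi) == 0L) next
        jj <- which(ok & sid == u)
        bad <- IRanges::countOverlaps(
          IRanges::IRanges(s0[jj] + 1L, s0[jj] + lens[todo[jj]]), mi) > 0L
        ok[jj[bad]] <- FALSE
      }
    }
    out_seq[todo[ok]] <- sid[ok]
    out_start[todo[ok]] <- s0[ok]
    todo <- todo[!ok]
  }
  data.frame(seq_id = out_seq, start = out_start, end = out_start + lens,
             stringsAsFactors = FALSE)
}

#' Randomization test for genomic-location bias
#'
#' Compares the observed location summary against `n_rand` random datasets
#' of the same size and length distribution drawn over the scannable genome.
#' Empirical p-values use the add-one rule `(r + 1) / (n_rand + 1)` where
#' `r` counts null replicates as or more extreme than the observation, so
#' the smallest attainable p with 100 randomizations is 1/101 (< 0.01).
#' With `alternative = "auto"` extremeness is taken in the observed
#' direction (one-sided toward the observed deviation from the null mean);
#' `"greater"`/`"less"` fix the direction for every category.
#'
#' @param crms observed CRM data.frame.
#' @param genes [gene_models] data.frame.
#' @param seq_lengths named vector of sequence lengths.
#' @param masked optional named list of masked [IRanges::IRanges].
#' @param n_rand number of randomizations (default 100).
#' @param seed integer seed (required: results are reproducible by
#'   construction).
#' @param alternative `"auto"`, `"greater"` or `"less"`.
#' @return object of class `randomization_result`: list with `observed`
#'   (a `location_summary`), `null_fracs_tss` / `null_fracs_gene`
#'   (`n_rand` x bins matrices), `p_tss`, `p_gene` (named empirical p),
#'   `direction_tss`, `direction_gene`.
#' @export
randomize_and_test <- function(crms, genes, seq_lengths, masked = NULL,
                               n_rand = 100L, seed,
                               alternative = c("auto", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (missing(seed)) stop("a seed is required for reproducibility")
  obs <- classify_locations(crms, genes)
  withr::with_seed(seed, {
    null_tss <- matrix(NA_real_, n_rand, 4L,
                       dimnames = list(NULL, attr(obs, "names_tss")))
    null_gene <- matrix(NA_real_, n_rand, 3L,
                        dimnames = list(NULL, attr(obs, "names_classes")))
    for (r in seq_len(n_rand)) {
      rnd <- random_locations(crms, seq_lengths, masked)
      s <- suppressWarnings(classify_locations(rnd, genes))
      null_tss[r, ] <- s$tss_bins
      null_gene[r, ] <- s$gene_classes
    }
  })
  emp_p <- function(obs_f, null_m) {
    p <- numeric(ncol(null_m)); dir <- character(ncol(null_m))
    for (j in seq_len(ncol(null_m))) {
      d <- switch(alternative,
                  greater = "greater", less = "less",
                  auto = if (obs_f[j] >= mean(null_m[, j])) "greater"
                         else "less")
      r <- if (d == "greater") sum(null_m[, j] >= obs_f[j])
           else sum(null_m[, j] <= obs_f[j])
      p[j] <- (r + 1) / (nrow(null_m) + 1)
      dir[j] <- d
    }
    names(p) <- colnames(null_m)
    list(p = p, dir = dir)
  }
  et <- emp_p(obs$tss_bins, null_tss)
  eg <- emp_p(obs$gene_classes, null_gene)
  structure(list(observed = obs, null_fracs_tss = null_tss,
                 null_fracs_gene = null_gene,
                 p_tss = et$p, p_gene = eg$p,
                 direction_tss = et$dir, direction_gene = eg$dir,
                 n_rand = n_rand, seed = seed),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  print(x$observed)
  cat("  empirical p (", x$n_rand, " randomizations):\n", sep = "")
  cat("    TSS bins: ",
      paste(sprintf("%s %.3f", names(x$p_tss), x$p_tss), collapse = ", "),
      "\n")
  cat("    gene classes: ",
      paste(sprintf("%s %.3f", names(x$p_gene), x$p_gene), collapse = ", "),
      "\n")
  invisible(x)
}
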