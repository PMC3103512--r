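#' Position-weight matrix
#'
#' Constructs a `pwm` object from a width x 4 matrix of base counts or
#' probabilities (columns A, C, G, T). A pseudocount is added to every cell
#' before per-position normalization, so all stored probabilities are strictly
#' positive and every position sums to one. Scores downstream are log-odds in
#' bits against a uniform background (each base at probability 1/4).
#'
#' @param x numeric matrix, width x 4. Columns are taken in A,C,G,T order;
#'   column names, if present, must be a permutation of A,C,G,T.
#' @param matrix_id unique identifier (e.g. "MA0143.1" or "M00982").
#' @param tf_name transcription-factor name the matrix models.
#' @param source one of `"transfac"`, `"jaspar"`, `"chip_derived"`.
#' @param quality optional ordinal quality grade (e.g. "A" better than "B").
#' @param factors optional data.frame with columns `tf`, `species`: the
#'   binding factors annotated on the matrix, used by [curate_pwms()].
#' @param pseudocount value added to each cell before normalization.
#' @return an object of class `pwm` with elements `matrix_id`, `tf_name`,
#'   `width`, `probs` (width x 4, rows summing to 1), `source`, `quality`,
#'   `factors`.
#' @examples
#' m <- pwm(matrix(c(10, 0, 0, 10, 0, 0, 0, 0), 2, 4), "M1", "TF1", "jaspar")
#' pwm_log_odds(m)
#' @export
pwm <- function(x, matrix_id, tf_name, source = c("jaspar", "transfac", "chip_derived"),
                quality = NA_character_, factors = NULL, pseudocount = 0.01) {
  source <- match.arg(source)
  x <- as.matrix(x)
  if (ncol(x) != 4L) stop("PWM matrix must have 4 columns (A, C, G, T)")
  if (nrow(x) < 1L) stop("PWM width must be >= 1")
  if (!is.null(colnames(x))) {
    if (!setequal(colnames(x), DNA_BASES)) {
      stop("PWM column names must be A, C, G, T")
    }
    x <- x[, DNA_BASES, drop = FALSE]
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("PWM '", matrix_id, "': cells must be finite and non-negative")
  }
  x <- x + pseudocount
  probs <- x / rowSums(x)
  dimnames(probs) <- list(NULL, DNA_BASES)
  structure(
    list(matrix_id = as.character(matrix_id), tf_name = as.character(tf_name),
         width = nrow(probs), probs = probs, source = source,
         quality = as.character(quality), factors = factors),
    class = "pwm"
  )
}

DNA_BASES <- c("A", "C", "G", "T")

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (%s, %s) width %d, max score %.2f bits\n",
              x$matrix_id, x$tf_name, x$source, x$width, pwm_max_score(x)))
  invisible(x)
}

#' Log-odds score matrix of a PWM
#'
#' Returns the width x 4 matrix of per-position bit scores against a uniform
#' background: `log2(p(i, b) / 0.25)`. Pseudocounts applied at construction
#' guarantee all entries are finite.
#'
#' @param x a [pwm] object.
#' @return numeric matrix, width x 4, columns A,C,G,T, entries in bits.
#' @export
pwm_log_odds <- function(x) {
  stopifnot(inherits(x, "pwm"))
  log2(x$probs / 0.25)
}

#' Maximum achievable log-odds score of a PWM
#'
#' Sum over positions of the best per-position bit score; the score of the
#' consensus sequence.
#'
#' @param x a [pwm] object.
#' @return scalar, bits.
#' @export
pwm_max_score <- function(x) {
  sum(apply(pwm_log_odds(x), 1L, max))
}

#' Consensus sequence of a PWM (most probable base per position)
#' @param x a [pwm] object.
#' @return character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$probs, 1L, which.max)], collapse = "")
}

#' Reverse-complement a PWM
#' @param x a [pwm] object.
#' @return a [pwm] object scoring the reverse strand.
#' @export
pwm_reverse_complement <- function(x) {
  p <- x$probs[rev(seq_len(x$width)), rev(seq_len(4L)), drop = FALSE]
  colnames(p) <- DNA_BASES
  y <- x
  y$probs <- p
  y
}

# ---- parsers -----------------------------------------------------------

#' Read PWMs from JASPAR PFM files
#'
#' Parses the JASPAR PFM flat format: a `>ID NAME` header followed by four
#' count rows, either bare numbers or the bracketed `A [ ... ]` style. Rows
#' are base-labelled when a leading letter is present, otherwise assumed in
#' A,C,G,T order. Matrices containing a position with zero total count are
#' rejected and listed in the `"report"` attribute of the result.
#'
#' @param path path to a PFM file (may contain several records).
#' @param pseudocount passed to [pwm()].
#' @return list of [pwm] objects; attribute `"report"` is a data.frame of
#'   rejected records (`matrix_id`, `reason`).
#' @export
read_jaspar <- function(path, pseudocount = 0.01) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("malformed JASPAR file (no '>' header): ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  out <- list()
  rej_id <- character(); rej_why <- character()
  for (k in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[k]])
    toks <- strsplit(hdr, "\\s+")[[1L]]
    mid <- toks[1L]
    tf <- if (length(toks) >= 2L) toks[2L] else toks[1L]
    body <- lines[(starts[k] + 1L):ends[k]]
    if (length(body) != 4L) {
      stop("malformed JASPAR record '", mid, "' in ", path,
           ": expected 4 count rows, got ", length(body))
    }
    rows <- lapply(body, function(ln) {
      base <- NA_character_
      m <- regmatches(ln, regexec("^\\s*([ACGTacgt])\\s*[\\[|:]?", ln))[[1L]]
      if (length(m) == 3L) base <- toupper(m[2L])
      nums <- regmatches(ln, gregexpr("[0-9]*\\.?[0-9]+", ln))[[1L]]
      list(base = base, counts = as.numeric(nums))
    })
    counts <- lapply(rows, `[[`, "counts")
    lens <- lengths(counts)
    if (length(unique(lens)) != 1L) {
      stop("malformed JASPAR record '", mid, "' in ", path,
           ": ragged count rows (", paste(lens, collapse = ","), ")")
    }
    mat <- do.call(cbind, counts)  # width x 4
    bases <- vapply(rows, `[[`, character(1L), "base")
    if (!anyNA(bases)) {
      colnames(mat) <- bases
    } else {
      colnames(mat) <- DNA_BASES
    }
    if (any(rowSums(mat) == 0)) {
      rej_id <- c(rej_id, mid)
      rej_why <- c(rej_why, "zero-count column")
      next
    }
    out[[length(out) + 1L]] <- pwm(mat, mid, tf, source = "jaspar",
                                   pseudocount = pseudocount)
  }
  attr(out, "report") <- data.frame(matrix_id = rej_id, reason = rej_why,
                                    stringsAsFactors = FALSE)
  out
}

#' Read PWMs from a TRANSFAC flat file
#'
#' Parses the TRANSFAC matrix flat-file format: records delimited by `//`,
#' with `AC` (accession), `ID`, `NA` (factor name), `BF` (binding factor,
#' "BF  T00000 Name; Species: common, Genus species."), the `P0`-headed count
#' block, and optional `CC quality: X` comments carrying the matrix quality
#' grade. Matrices with a zero-total count position are rejected and reported.
#'
#' @inheritParams read_jaspar
#' @return list of [pwm] objects with `quality` and `factors` populated;
#'   attribute `"report"` lists rejected records.
#' @export
read_transfac <- function(path, pseudocount = 0.01) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  recs <- split(lines, cumsum(c(0L, head(grepl("^//", lines), -1L))))
  out <- list()
  rej_id <- character(); rej_why <- character()
  for (rec in recs) {
    rec <- rec[!grepl("^//", rec)]
    rec <- rec[nzchar(trimws(rec))]
    if (length(rec) == 0L) next
    field <- function(tag) {
      v <- grep(paste0("^", tag, "\\s"), rec, value = TRUE)
      if (length(v) == 0L) NA_character_ else trimws(sub(paste0("^", tag, "\\s+"), "", v[1L]))
    }
    ac <- field("AC"); id <- field("ID"); nm <- field("NA")
    mid <- if (!is.na(ac)) ac else id
    if (is.na(mid)) stop("malformed TRANSFAC record (no AC/ID) in ", path)
    p0 <- grep("^P0", rec)
    if (length(p0) != 1L) {
      stop("malformed TRANSFAC record '", mid, "' in ", path, ": missing P0 header")
    }
    order4 <- strsplit(trimws(sub("^P0\\s+", "", rec[p0])), "\\s+")[[1L]][1:4]
    crow <- grep("^[0-9]+\\s", rec)
    crow <- crow[crow > p0]
    if (length(crow) == 0L) {
      stop("malformed TRANSFAC record '", mid, "' in ", path, ": empty count block")
    }
    mat <- t(vapply(rec[crow], function(ln) {
      as.numeric(strsplit(trimws(ln), "\\s+")[[1L]][2:5])
    }, numeric(4L)))
    colnames(mat) <- toupper(order4)
    bf <- grep("^BF\\s", rec, value = TRUE)
    factors <- NULL
    if (length(bf)) {
      tfs <- vapply(bf, function(ln) {
        body <- sub("^BF\\s+", "", ln)
        trimws(sub(";.*$", "", sub("^T[0-9]+\\s+", "", body)))
      }, character(1L), USE.NAMES = FALSE)
      sp <- vapply(bf, function(ln) {
        m <- regmatches(ln, regexec("Species:\\s*([^.;]+)", ln))[[1L]]
        if (length(m) == 2L) trimws(m[2L]) else NA_character_
      }, character(1L), USE.NAMES = FALSE)
      factors <- data.frame(tf = tfs, species = sp, stringsAsFactors = FALSE)
    }
    qline <- grep("quality:", rec, value = TRUE, ignore.case = TRUE)
    quality <- if (length(qline)) {
      toupper(trimws(sub(".*quality:\\s*", "", qline[1L], ignore.case = TRUE)))
    } else NA_character_
    if (any(rowSums(mat) == 0)) {
      rej_id <- c(rej_id, mid)
      rej_why <- c(rej_why, "zero-count column")
      next
    }
    out[[length(out) + 1L]] <- pwm(mat, mid, if (is.na(nm)) mid else nm,
                                   source = "transfac", quality = quality,
                                   factors = factors, pseudocount = pseudocount)
  }
  attr(out, "report") <- data.frame(matrix_id = rej_id, reason = rej_why,
                                    stringsAsFactors = FALSE)
  out
}

#' Parse one or more PWM collections
#'
#' Dispatches to the JASPAR or TRANSFAC parser per file and concatenates the
#' results, merging rejection reports.
#'
#' @param paths character vector of file paths.
#' @param dialect `"jaspar"` or `"transfac"`, recycled along `paths`.
#' @param pseudocount passed to the parsers.
#' @return list of [pwm] objects with a combined `"report"` attribute.
#' @export
parse_matrices <- function(paths, dialect = c("jaspar", "transfac"),
                           pseudocount = 0.01) {
  dialect <- match.arg(dialect, several.ok = TRUE)
  dialect <- rep_len(dialect, length(paths))
  out <- list()
  rep <- list()
  for (i in seq_along(paths)) {
    r <- switch(dialect[i],
                jaspar = read_jaspar(paths[i], pseudocount),
                transfac = read_transfac(paths[i], pseudocount))
    rep[[i]] <- attr(r, "report")
    out <- c(out, r)
  }
  attr(out, "report") <- do.call(rbind, rep)
  out
}

# ---- curation ----------------------------------------------------------

#' Vertebrate species keywords used by default in curation
#' @keywords internal
.vertebrate_species <- c(
  "human", "homo sapiens", "mouse", "mus musculus", "rat", "rattus",
  "chick", "gallus", "xenopus", "frog", "zebrafish", "danio", "medaka",
  "oryzias", "fugu", "takifugu", "tetraodon", "gasterosteus", "stickleback",
  "bovine", "bos taurus", "pig", "sus scrofa", "rabbit", "oryctolagus",
  "hamster", "cricetulus", "monkey", "macaca", "dog", "canis", "vertebrata"
)

#' Curate a PWM collection
#'
#' Applies the curation rules used to build a non-redundant vertebrate matrix
#' set from TRANSFAC-style collections:
#' \enumerate{
#'   \item matrices whose annotated binding-factor species are all
#'     non-vertebrate are dropped, unless their id is on `allow_list`
#'     (standing in for a hand-picked set of invertebrate matrices for
#'     factors with vertebrate developmental roles);
#'   \item matrices linked to more than two distinct TFs of one species are
#'     dropped;
#'   \item among several matrices for the same TF, only the one with the
#'     highest quality grade is kept (earlier in `quality_levels` is better;
#'     missing quality ranks last, ties keep the first encountered).
#' }
#' Matrices without factor metadata (JASPAR, ChIP-derived) are not subject to
#' rules 1-2. Rule 3 keys on `tf_name` case-insensitively.
#'
#' @param pwms list of [pwm] objects.
#' @param allow_list matrix ids exempt from the non-vertebrate filter.
#' @param vertebrate_species lowercase keywords identifying vertebrate
#'   species strings.
#' @param quality_levels ordinal quality grades, best first.
#' @return curated list of [pwm]s; attribute `"report"` is a data.frame
#'   (`matrix_id`, `reason`) of exclusions.
#' @export
curate_pwms <- function(pwms, allow_list = character(),
                        vertebrate_species = .vertebrate_species,
                        quality_levels = c("A", "B", "C", "D", "E")) {
  keep <- rep(TRUE, length(pwms))
  why <- rep(NA_character_, length(pwms))
  is_vert <- function(sp) {
    sp <- tolower(sp)
    any(vapply(vertebrate_species, function(v) grepl(v, sp, fixed = TRUE),
               logical(1L)))
  }
  for (i in seq_along(pwms)) {
    p <- pwms[[i]]
    f <- p$factors
    if (is.null(f) || nrow(f) == 0L) next
    sp <- f$species[!is.na(f$species)]
    if (length(sp) && !any(vapply(sp, is_vert, logical(1L))) &&
        !(p$matrix_id %in% allow_list)) {
      keep[i] <- FALSE; why[i] <- "non-vertebrate"
      next
    }
    ntf <- tapply(toupper(f$tf), toupper(f$species),
                  function(x) length(unique(x)))
    if (length(ntf) && any(ntf > 2L, na.rm = TRUE)) {
      keep[i] <- FALSE; why[i] <- "linked to >2 TFs of one species"
    }
  }
  # rule 3: one matrix per TF, highest quality
  idx <- which(keep)
  tf_key <- vapply(pwms[idx], function(p) toupper(p$tf_name), character(1L))
  qrank <- vapply(pwms[idx], function(p) {
    r <- match(p$quality, quality_levels)
    if (is.na(r)) length(quality_levels) + 1L else r
  }, integer(1L))
  best <- tapply(seq_along(idx), tf_key, function(ii) ii[which.min(qrank[ii])])
  drop_dup <- setdiff(seq_along(idx), unlist(best))
  keep[idx[drop_dup]] <- FALSE
  why[idx[drop_dup]] <- "redundant matrix for TF (lower quality)"
  out <- pwms[keep]
  attr(out, "report") <- data.frame(
    matrix_id = vapply(pwms[!keep], `[[`, character(1L), "matrix_id"),
    reason = why[!keep], stringsAsFactors = FALSE)
  out
}
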