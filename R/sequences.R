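#' Masked sequence record
#'
#' A genome sequence together with the intervals excluded from scanning
#' (repeats from soft-masking, coding sequence from annotation). All
#' coordinates in this package are 0-based half-open; masked intervals are
#' stored as an [IRanges::IRanges] in the same convention via
#' `IRanges(start0 + 1, end0)`.
#'
#' @param seq_id sequence name.
#' @param sequence DNA string over A,C,G,T,N; lowercase accepted and recorded
#'   as masked.
#' @param masked an [IRanges::IRanges] of additional masked intervals,
#'   0-based half-open encoded as `IRanges(start0 + 1, end0)`.
#' @return object of class `sequence_record`: list with `seq_id`, `sequence`
#'   (uppercase character), `masked` (reduced IRanges).
#' @export
sequence_record <- function(seq_id, sequence, masked = IRanges::IRanges()) {
  sequence <- as.character(sequence)
  lc <- lowercase_runs(sequence)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence '", seq_id, "' contains characters outside A,C,G,T,N")
  }
  masked <- IRanges::reduce(c(masked, lc))
  n <- nchar(sequence)
  if (length(masked) && (min(IRanges::start(masked)) < 1L ||
                         max(IRanges::end(masked)) > n)) {
    stop("masked intervals outside [0, length) for '", seq_id, "'")
  }
  structure(list(seq_id = as.character(seq_id), sequence = sequence,
                 masked = masked),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("sequence_record %s: %d bp, %d bp masked (%d intervals)\n",
              x$seq_id, nchar(x$sequence), sum(IRanges::width(x$masked)),
              length(x$masked)))
  invisible(x)
}

lowercase_runs <- function(s) {
  m <- gregexpr("[acgtn]+", s)[[1L]]
  if (m[1L] == -1L) return(IRanges::IRanges())
  IRanges::IRanges(start = as.integer(m),
                   end = as.integer(m) + attr(m, "match.length") - 1L)
}

#' Read a soft-masked genome FASTA into sequence records
#'
#' Lowercase runs in the FASTA become masked intervals; an optional gene
#' annotation adds CDS intervals to the mask, so scanning is restricted to
#' non-coding, non-repetitive sequence.
#'
#' @param path FASTA file (soft-masked).
#' @param cds optional data.frame with columns `seq_id`, `start`, `end`
#'   (0-based half-open), e.g. the `cds` element of [read_gff_genes()].
#' @return named list of [sequence_record]s.
#' @export
read_genome <- function(path, cds = NULL) {
  ss <- Biostrings::readBStringSet(path)
  out <- lapply(seq_along(ss), function(i) {
    id <- sub("\\s.*$", "", names(ss)[i])
    extra <- IRanges::IRanges()
    if (!is.null(cds)) {
      ci <- cds[cds$seq_id == id, , drop = FALSE]
      if (nrow(ci)) extra <- IRanges::IRanges(ci$start + 1L, ci$end)
    }
    sequence_record(id, as.character(ss[[i]]), masked = extra)
  })
  names(out) <- vapply(out, `[[`, character(1L), "seq_id")
  out
}

#' Write sequence records as a soft-masked FASTA
#'
#' Masked intervals are emitted lowercase so the mask round-trips through
#' [read_genome()].
#'
#' @param records list of [sequence_record]s.
#' @param path output file.
#' @param width line width.
#' @export
write_genome <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    s <- r$sequence
    if (length(r$masked)) {
      ch <- strsplit(s, "")[[1L]]
      for (i in seq_along(r$masked)) {
        ix <- IRanges::start(r$masked)[i]:IRanges::end(r$masked)[i]
        ch[ix] <- tolower(ch[ix])
      }
      s <- paste(ch, collapse = "")
    }
    writeLines(paste0(">", r$seq_id), con)
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Reverse complement of a DNA string
#' @param s character scalar over A,C,G,T,N.
#' @return character scalar.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Extract a subsequence (0-based half-open)
#' @param record a [sequence_record] or character string.
#' @param start,end 0-based half-open bounds.
#' @return character scalar.
#' @export
subseq0 <- function(record, start, end) {
  s <- if (inherits(record, "sequence_record")) record$sequence else record
  substr(s, start + 1L, end)
}
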