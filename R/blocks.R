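#' Pairwise alignment block tables
#'
#' Alignment blocks link an interval of the reference genome to an interval
#' of one comparison species through a per-base offset map encoded as a
#' CIGAR-like string over the operations `M` (both advance), `D` (gap in the
#' comparison sequence, reference advances) and `I` (gap in the reference,
#' comparison advances). Blocks are stored as a data.frame with columns
#' `ref_seq`, `ref_start`, `ref_end`, `species`, `other_seq`, `other_start`,
#' `other_end`, `cigar`; all coordinates 0-based half-open.
#'
#' @param df data.frame with the columns above.
#' @return validated data.frame of class `c("alignment_blocks", "data.frame")`.
#' @export
alignment_blocks <- function(df) {
  need <- c("ref_seq", "ref_start", "ref_end", "species", "other_seq",
            "other_start", "other_end", "cigar")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("alignment block table lacks columns: ",
                            paste(missing, collapse = ", "))
  for (i in seq_len(nrow(df))) {
    ops <- parse_cigar(df$cigar[i])
    rlen <- sum(ops$len[ops$op %in% c("M", "D")])
    olen <- sum(ops$len[ops$op %in% c("M", "I")])
    if (rlen != df$ref_end[i] - df$ref_start[i] ||
        olen != df$other_end[i] - df$other_start[i]) {
      stop("block ", i, ": cigar '", df$cigar[i],
           "' inconsistent with interval lengths")
    }
  }
  class(df) <- c("alignment_blocks", "data.frame")
  df
}

parse_cigar <- function(cig) {
  m <- gregexpr("[0-9]+[MDI]", cig)[[1L]]
  if (m[1L] == -1L) stop("malformed cigar: ", cig)
  toks <- regmatches(cig, gregexpr("[0-9]+[MDI]", cig))[[1L]]
  if (sum(nchar(toks)) != nchar(cig)) stop("malformed cigar: ", cig)
  list(len = as.integer(sub("[MDI]", "", toks)),
       op = sub("[0-9]+", "", toks))
}

#' Per-base offset map of a block
#'
#' @param block one row of an [alignment_blocks] table.
#' @return integer vector of length `ref_end - ref_start`; element `k` is the
#'   0-based comparison-genome position aligned to reference position
#'   `ref_start + k - 1`, or `NA` where the reference base falls in a
#'   comparison-sequence gap. The map is monotone non-decreasing over
#'   non-`NA` entries.
#' @export
block_map <- function(block) {
  ops <- parse_cigar(block$cigar)
  ref_len <- block$ref_end - block$ref_start
  map <- integer(0)
  opos <- block$other_start
  for (i in seq_along(ops$op)) {
    L <- ops$len[i]
    switch(ops$op[i],
           M = { map <- c(map, opos + seq_len(L) - 1L); opos <- opos + L },
           D = { map <- c(map, rep(NA_integer_, L)) },
           I = { opos <- opos + L })
  }
  stopifnot(length(map) == ref_len)
  map
}

#' Project a reference hit into a comparison genome
#'
#' Looks up the block containing the hit, projects its interval through the
#' per-base offset map, and returns the projection together with the
#' misalignment search window (projection start +/- `max_offset`, clipped to
#' the block's comparison interval). Returns `NULL` when the hit lies outside
#' every block of the species, or when its footprint maps entirely into a
#' gap.
#'
#' @param hit one-row hit data.frame (needs `seq_id`, `start`, `end`).
#' @param blocks an [alignment_blocks] table.
#' @param species comparison species name.
#' @param max_offset misalignment tolerance in bp (default 20).
#' @return `NULL`, or a list with `other_seq`, `proj_start`, `proj_end`,
#'   `win_start`, `win_end` (all 0-based half-open).
#' @export
map_hit <- function(hit, blocks, species, max_offset = 20L) {
  b <- blocks[blocks$species == species & blocks$ref_seq == hit$seq_id, ,
              drop = FALSE]
  if (nrow(b) == 0L) return(NULL)
  b <- b[order(b$ref_start), , drop = FALSE]
  if (nrow(b) > 1L && any(b$ref_start[-1L] < b$ref_end[-nrow(b)])) {
    stop("alignment blocks overlap on the reference for species '", species,
         "'; block table is misconfigured")
  }
  sel <- which(b$ref_start <= hit$start & b$ref_end >= hit$end)
  if (length(sel) == 0L) return(NULL)
  blk <- b[sel[1L], , drop = FALSE]
  map <- block_map(blk)
  span <- map[(hit$start - blk$ref_start + 1L):(hit$end - blk$ref_start)]
  span <- span[!is.na(span)]
  if (length(span) == 0L) return(NULL)
  proj_start <- min(span)
  proj_end <- max(span) + 1L
  list(other_seq = blk$other_seq,
       proj_start = proj_start, proj_end = proj_end,
       win_start = max(blk$other_start, proj_start - max_offset),
       win_end = min(blk$other_end, proj_end + max_offset))
}

# ---- TSV dialect -------------------------------------------------------

#' Read/write the TSV alignment-block dialect
#'
#' Tab-separated with a header matching the [alignment_blocks] columns.
#'
#' @param path file path.
#' @return an [alignment_blocks] table.
#' @export
read_alignment_blocks <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  alignment_blocks(df)
}

#' @rdname read_alignment_blocks
#' @param blocks an [alignment_blocks] table.
#' @export
write_alignment_blocks <- function(blocks, path) {
  utils::write.table(as.data.frame(blocks), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- MAF dialect -------------------------------------------------------

#' Read pairwise alignment blocks from a MAF file
#'
#' Each MAF block must contain the reference row first followed by one row
#' per comparison species; `src` fields are `species.seq_id`. Gapped texts
#' are converted to the CIGAR encoding of [alignment_blocks]. Only
#' forward-strand rows are supported (the fixture generator emits forward
#' blocks; strandedness of binding-site support is handled at scan time).
#'
#' @param path MAF file.
#' @param ref_species name of the reference species (first `s` row).
#' @return an [alignment_blocks] table.
#' @export
read_maf <- function(path, ref_species = "ref") {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  starts <- grep("^a", lines)
  rows <- list()
  for (k in seq_along(starts)) {
    from <- starts[k] + 1L
    to <- if (k < length(starts)) starts[k + 1L] - 1L else length(lines)
    srows <- grep("^s ", lines[from:to], value = TRUE)
    if (length(srows) < 2L) next
    parse_s <- function(ln) {
      f <- strsplit(trimws(ln), "\\s+")[[1L]]
      sp <- sub("\\..*$", "", f[2L])
      sq <- sub("^[^.]*\\.", "", f[2L])
      if (f[5L] != "+") stop("MAF reader supports forward-strand rows only")
      list(species = sp, seq = sq, start = as.integer(f[3L]),
           size = as.integer(f[4L]), text = f[7L])
    }
    ref <- parse_s(srows[1L])
    if (ref$species != ref_species) {
      stop("first MAF row of block ", k, " is '", ref$species,
           "', expected reference '", ref_species, "'")
    }
    for (j in 2L:length(srows)) {
      oth <- parse_s(srows[j])
      rows[[length(rows) + 1L]] <- data.frame(
        ref_seq = ref$seq, ref_start = ref$start,
        ref_end = ref$start + ref$size,
        species = oth$species, other_seq = oth$seq,
        other_start = oth$start, other_end = oth$start + oth$size,
        cigar = texts_to_cigar(ref$text, oth$text),
        stringsAsFactors = FALSE)
    }
  }
  alignment_blocks(do.call(rbind, rows))
}

texts_to_cigar <- function(ref_text, oth_text) {
  r <- strsplit(ref_text, "")[[1L]] != "-"
  o <- strsplit(oth_text, "")[[1L]] != "-"
  if (length(r) != length(o)) stop("MAF rows of unequal aligned length")
  op <- ifelse(r & o, "M", ifelse(r, "D", "I"))
  rl <- rle(op)
  paste0(rl$lengths, rl$values, collapse = "")
}

#' Write alignment blocks as MAF
#'
#' Reconstructs gapped row texts from the genomes, so a round trip through
#' [read_maf()] recovers the block table.
#'
#' @param blocks an [alignment_blocks] table.
#' @param ref_genome named list of reference [sequence_record]s.
#' @param other_genomes named list (by species) of named record lists.
#' @param path output file.
#' @param ref_species reference species label used in `src` fields.
#' @export
write_maf <- function(blocks, ref_genome, other_genomes, path,
                      ref_species = "ref") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, , drop = FALSE]
    ops <- parse_cigar(b$cigar)
    rseq <- subseq0(ref_genome[[b$ref_seq]], b$ref_start, b$ref_end)
    oseq <- subseq0(other_genomes[[b$species]][[b$other_seq]],
                    b$other_start, b$other_end)
    rt <- character(); ot <- character(); rp <- 0L; op_ <- 0L
    for (j in seq_along(ops$op)) {
      L <- ops$len[j]
      if (ops$op[j] == "M") {
        rt <- c(rt, substr(rseq, rp + 1L, rp + L))
        ot <- c(ot, substr(oseq, op_ + 1L, op_ + L))
        rp <- rp + L; op_ <- op_ + L
      } else if (ops$op[j] == "D") {
        rt <- c(rt, substr(rseq, rp + 1L, rp + L))
        ot <- c(ot, strrep("-", L)); rp <- rp + L
      } else {
        rt <- c(rt, strrep("-", L))
        ot <- c(ot, substr(oseq, op_ + 1L, op_ + L)); op_ <- op_ + L
      }
    }
    rlen <- nchar(ref_genome[[b$ref_seq]]$sequence)
    olen <- nchar(other_genomes[[b$species]][[b$other_seq]]$sequence)
    writeLines(c("a score=0",
                 sprintf("s %s.%s %d %d + %d %s", ref_species, b$ref_seq,
                         b$ref_start, b$ref_end - b$ref_start, rlen,
                         paste(rt, collapse = "")),
                 sprintf("s %s.%s %d %d + %d %s", b$species, b$other_seq,
                         b$other_start, b$other_end - b$other_start, olen,
                         paste(ot, collapse = "")),
                 ""), con)
  }
  invisible(path)
}
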