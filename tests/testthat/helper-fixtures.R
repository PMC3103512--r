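# shared helpers: tiny constructors and a cached default fixture bundle

.fixture_cache <- new.env(parent = emptyenv())

# default study-conditions fixture (seed 1), generated once per test run
default_fixture <- function() {
  if (is.null(.fixture_cache$bundle)) {
    .fixture_cache$bundle <- generate_fixture(fixture_spec(seed = 1L))
  }
  .fixture_cache$bundle
}

# reference records with CDS masking applied, as the pipeline scans them
fixture_ref <- function(bundle) {
  ref <- lapply(bundle$ref_genome, function(r) {
    ci <- bundle$cds[bundle$cds$seq_id == r$seq_id, , drop = FALSE]
    sequence_record(r$seq_id, r$sequence,
                    masked = c(r$masked, IRanges::IRanges(ci$start + 1L,
                                                          ci$end)))
  })
  names(ref) <- names(bundle$ref_genome)
  ref
}

# conserved hits of the default fixture, cached
default_conserved_hits <- function() {
  if (is.null(.fixture_cache$chits)) {
    bun <- default_fixture()
    ref <- fixture_ref(bun)
    hits <- scan_genome(ref, bun$pwms)
    .fixture_cache$chits <- conserve_hits(hits, bun$pwms,
                                          bun$species_genomes, bun$blocks)
  }
  .fixture_cache$chits
}

# a simple informative PWM: one dominant base per position
make_pwm <- function(consensus, id = "TST", tf = "tst", dominant = 85,
                     other = 5) {
  ch <- strsplit(consensus, "")[[1L]]
  m <- matrix(other, length(ch), 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  m[cbind(seq_along(ch), match(ch, c("A", "C", "G", "T")))] <- dominant
  pwm(m, id, tf, source = "jaspar")
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

overlaps0 <- function(a1, a2, b1, b2) a1 < b2 & b1 < a2

# independent brute-force scanner: explicit per-window log-odds lookup,
# reverse strand scored on the reverse-complemented window text
brute_scan <- function(record, p, frac) {
  lo <- log2(p$probs / 0.25)
  w <- p$width
  n <- nchar(record$sequence)
  thr <- frac * sum(apply(lo, 1, max))
  res <- list()
  bad <- rep(FALSE, n)
  if (length(record$masked) > 0) {
    for (k in seq_along(record$masked)) {
      bad[IRanges::start(record$masked)[k]:IRanges::end(record$masked)[k]] <- TRUE
    }
  }
  for (s in seq_len(max(0, n - w + 1L))) {
    win <- substr(record$sequence, s, s + w - 1L)
    if (grepl("N", win) || any(bad[s:(s + w - 1L)])) next
    for (strand in c("+", "-")) {
      txt <- if (strand == "+") win else revcomp(win)
      ch <- strsplit(txt, "")[[1L]]
      sc <- sum(lo[cbind(seq_len(w), match(ch, c("A", "C", "G", "T")))])
      if (sc >= thr) {
        res[[length(res) + 1L]] <- data.frame(start = s - 1L,
                                              end = s - 1L + w,
                                              strand = strand, score = sc)
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), score = numeric()))
  }
  out <- do.call(rbind, res)
  out[order(out$start, out$strand), , drop = FALSE]
}
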