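identity_block <- function(len = 100L, species = "tetraodon") {
  alignment_blocks(data.frame(
    ref_seq = "chr", ref_start = 0L, ref_end = len, species = species,
    other_seq = "oc", other_start = 0L, other_end = len,
    cigar = paste0(len, "M"), stringsAsFactors = FALSE))
}

test_that("map_hit projects through an identity block with a +/-20 window", {
  hit <- data.frame(seq_id = "chr", start = 10L, end = 18L)
  prj <- map_hit(hit, identity_block(), "tetraodon")
  expect_equal(prj$proj_start, 10L)
  expect_equal(prj$proj_end, 18L)
  expect_equal(prj$win_start, 0L)   # 10 - 20 clipped to block start
  expect_equal(prj$win_end, 38L)
  # hit outside every block maps nowhere
  expect_null(map_hit(data.frame(seq_id = "chr", start = 200L, end = 208L),
                      identity_block(), "tetraodon"))
  expect_null(map_hit(hit, identity_block(), "fugu"))
})

test_that("map_hit shifts projections across alignment gaps", {
  # 5 bp insertion in the comparison sequence before the hit: walk the
  # cigar ops by hand as the oracle
  blk <- alignment_blocks(data.frame(
    ref_seq = "chr", ref_start = 0L, ref_end = 100L, species = "fugu",
    other_seq = "oc", other_start = 0L, other_end = 105L,
    cigar = "5M5I95M", stringsAsFactors = FALSE))
  map <- block_map(blk[1L, ])
  oracle <- c(0:4, 10:104)  # 5 matched, then shifted by the insertion
  expect_equal(map, oracle)
  prj <- map_hit(data.frame(seq_id = "chr", start = 10L, end = 18L), blk,
                 "fugu")
  expect_equal(prj$proj_start, 15L)
  expect_equal(prj$proj_end, 23L)
  # deletion in the comparison sequence: gap positions are NA
  blk2 <- alignment_blocks(data.frame(
    ref_seq = "chr", ref_start = 0L, ref_end = 20L, species = "fugu",
    other_seq = "oc", other_start = 0L, other_end = 15L,
    cigar = "5M5D10M", stringsAsFactors = FALSE))
  expect_equal(block_map(blk2[1L, ]), c(0:4, rep(NA_integer_, 5L), 5:14))
})

test_that("overlapping reference blocks are rejected", {
  blks <- alignment_blocks(data.frame(
    ref_seq = "chr", ref_start = c(0L, 50L), ref_end = c(60L, 100L),
    species = "fugu", other_seq = "oc", other_start = c(0L, 50L),
    other_end = c(60L, 100L), cigar = c("60M", "50M"),
    stringsAsFactors = FALSE))
  expect_error(map_hit(data.frame(seq_id = "chr", start = 10L, end = 18L),
                       blks, "fugu"), "overlap")
})

test_that("combine_hit_score follows the conservation-weighted formula", {
  expect_equal(combine_hit_score(5, c(3, 4, 1), c(0, 0, 0)), 9)
  expect_equal(combine_hit_score(5, numeric(0), numeric(0)), 5)
  expect_equal(combine_hit_score(5, NA_real_, NA_integer_), 5)
  # penalty: 5 + (4 - 0.1 * 10) = 8; brute force over candidate offsets
  expect_equal(combine_hit_score(5, 4, 10), 8)
  cand <- expand.grid(s = c(2, 4), o = c(-10, 0, 10))
  best <- max(pmax(0, cand$s - 0.1 * abs(cand$o)))
  expect_equal(combine_hit_score(5, cand$s, cand$o), 5 + best)
  expect_error(combine_hit_score(5, 4, 25), "tolerance")
})

test_that("combined score is monotone and bounded below by the ref score", {
  set.seed(23)
  for (k in 1:200) {
    ref <- stats::runif(1, 0, 20)
    s <- stats::runif(3, 0, 15)
    o <- sample(0:20, 3L, replace = TRUE)
    base <- combine_hit_score(ref, s, o)
    expect_gte(base, ref)
    # raising any species score never lowers the result
    s2 <- s; s2[1L] <- s2[1L] + 1
    expect_gte(combine_hit_score(ref, s2, o), base)
    # growing any |offset| never raises it
    o2 <- o; o2[2L] <- min(20L, o2[2L] + 3L)
    expect_lte(combine_hit_score(ref, s, o2), base)
    # lambda = 0, perfect alignment: closed form ref + best support
    expect_equal(combine_hit_score(ref, s, rep(0L, 3L), lambda = 0),
                 ref + max(0, max(s)))
  }
})

test_that("conserve_hits recovers planted support with the planted offset", {
  p <- make_pwm("ACGTACGTTA")
  site <- "ACGTACGTTA"
  set.seed(31)
  left <- random_seq(60)
  ref <- sequence_record("chr", paste0(left, site, random_seq(60)))
  # species copy shifted +7 bp relative to the projected position
  oth <- sequence_record("chr", paste0(left, "GGTCTAG", site,
                                       random_seq(53)))
  blocks <- alignment_blocks(data.frame(
    ref_seq = "chr", ref_start = 0L, ref_end = 130L, species = "tetraodon",
    other_seq = "chr", other_start = 0L, other_end = 130L, cigar = "130M",
    stringsAsFactors = FALSE))
  hits <- scan_sequence(ref, p)
  hits$seq_id <- "chr"
  ch <- conserve_hits(hits, list(p), list(tetraodon = list(chr = oth)),
                      blocks)
  i <- which(ch$start == 60L & ch$strand == "+")
  expect_equal(ch$support_species[i], "tetraodon")
  expect_equal(ch$support_offset[i], 7L)
  expect_equal(ch$combined_score[i],
               combine_hit_score(ch$score[i], ch$support_score[i], 7L))
})

test_that("unsupported hits keep their reference score", {
  p <- make_pwm("ACGTACGTTA")
  set.seed(37)
  ref <- sequence_record("chr", paste0(random_seq(40), "ACGTACGTTA",
                                       random_seq(40)))
  oth <- sequence_record("chr", random_seq(90))
  blocks <- identity_block(90L)
  blocks$ref_seq <- "chr"; blocks$other_seq <- "chr"
  hits <- scan_sequence(ref, p)
  hits$seq_id <- "chr"
  ch <- conserve_hits(hits, list(p), list(tetraodon = list(chr = oth)),
                      blocks)
  expect_true(all(is.na(ch$support_species)))
  expect_equal(ch$combined_score, ch$score)
})

test_that("alignment blocks round-trip through the TSV and MAF dialects", {
  bun <- default_fixture()
  td <- withr::local_tempdir()
  tsv <- file.path(td, "b.tsv")
  write_alignment_blocks(bun$blocks, tsv)
  expect_equal(as.data.frame(read_alignment_blocks(tsv)),
               as.data.frame(bun$blocks))
  maf <- file.path(td, "b.maf")
  write_maf(bun$blocks, bun$ref_genome, bun$species_genomes, maf)
  back <- read_maf(maf)
  cols <- c("ref_seq", "ref_start", "ref_end", "species", "other_seq",
            "other_start", "other_end", "cigar")
  a <- as.data.frame(bun$blocks)[cols]
  b <- as.data.frame(back)[cols]
  a <- a[order(a$species, a$ref_seq, a$ref_start), ]
  b <- b[order(b$species, b$ref_seq, b$ref_start), ]
  expect_equal(b, a, ignore_attr = TRUE)
})

test_that("gapped MAF texts are converted to the cigar encoding", {
  f <- tempfile(fileext = ".maf")
  writeLines(c("##maf version=1", "a score=0",
               "s ref.chr1 5 8 + 100 ACGT--ACGT",
               "s fugu.sc2 3 9 + 50 ACGTGGAC-T",
               ""), f)
  b <- read_maf(f)
  expect_equal(b$cigar, "4M2I2M1D1M")
  expect_equal(b$ref_start, 5L)
  expect_equal(b$other_end, 12L)
})
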