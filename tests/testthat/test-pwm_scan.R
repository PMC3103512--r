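test_that("JASPAR parsing normalizes counts with pseudocounts", {
  f <- tempfile(fileext = ".pfm")
  writeLines(c(">M1 tfA",
               "A [ 10  0 ]",
               "C [  0 10 ]",
               "G [  0  0 ]",
               "T [  0  0 ]"), f)
  ps <- read_jaspar(f)
  expect_length(ps, 1L)
  p <- ps[[1L]]
  expect_equal(p$width, 2L)
  expect_equal(rowSums(p$probs), c(1, 1), tolerance = 1e-12)
  expect_gt(p$probs[1L, "A"], 0.99)       # ~1 after pseudocount
  expect_true(all(p$probs > 0))
  expect_equal(p$tf_name, "tfA")
})

test_that("JASPAR parser rejects malformed and zero-count records", {
  f <- tempfile(fileext = ".pfm")
  writeLines(c(">BAD three rows only", "A [ 1 ]", "C [ 1 ]", "G [ 1 ]"), f)
  expect_error(read_jaspar(f), "malformed")
  writeLines(c(">MZERO tfz",
               "A [ 1 0 ]", "C [ 1 0 ]", "G [ 1 0 ]", "T [ 1 0 ]"), f)
  out <- read_jaspar(f)
  expect_length(out, 0L)
  expect_equal(attr(out, "report")$matrix_id, "MZERO")
  expect_equal(attr(out, "report")$reason, "zero-count column")
})

transfac_fixture <- function() {
  system.file("extdata", "transfac_synthetic.dat", package = "crmpred")
}

test_that("TRANSFAC parsing extracts factors, species and quality", {
  ps <- read_transfac(transfac_fixture())
  ids <- vapply(ps, `[[`, character(1L), "matrix_id")
  expect_setequal(ids, c("M90001", "M90002", "M90003", "M90004", "M90005"))
  expect_equal(attr(ps, "report")$matrix_id, "M90006")  # zero-count column
  p1 <- ps[[match("M90001", ids)]]
  expect_equal(p1$quality, "B")
  expect_equal(p1$tf_name, "AP1syn")
  expect_match(p1$factors$species, "Homo sapiens")
})

test_that("curation drops non-vertebrates, multi-TF and redundant matrices", {
  ps <- read_transfac(transfac_fixture())
  cur <- curate_pwms(ps, allow_list = "M90004")
  ids <- vapply(cur, `[[`, character(1L), "matrix_id")
  # drosophila matrix not allow-listed is removed, allow-listed one kept
  expect_false("M90003" %in% ids)
  expect_true("M90004" %in% ids)
  # >2 TFs of one species removed
  expect_false("M90005" %in% ids)
  # of the two AP1syn matrices, the quality-A one is kept
  expect_true("M90002" %in% ids)
  expect_false("M90001" %in% ids)
  rep <- attr(cur, "report")
  expect_setequal(rep$matrix_id, c("M90003", "M90005", "M90001"))
})

test_that("log-odds follows the uniform-background definition", {
  # uniform matrix scores zero everywhere
  u <- pwm(matrix(1, 3, 4), "U", "u", pseudocount = 0)
  expect_equal(pwm_log_odds(u), matrix(0, 3, 4, dimnames = list(NULL, c("A","C","G","T"))))
  # a certain base scores log2(1/0.25) = 2 bits without pseudocount
  one <- pwm(matrix(c(1, 0, 0, 0), 1, 4), "O", "o", pseudocount = 0)
  expect_equal(unname(pwm_log_odds(one)[1L, "A"]), 2)
  # random matrix equals per-cell recomputation
  set.seed(42)
  m <- matrix(stats::runif(16, 1, 20), 4, 4)
  p <- pwm(m, "R", "r")
  probs <- (m + 0.01) / rowSums(m + 0.01)
  expect_equal(pwm_log_odds(p), log2(probs / 0.25), ignore_attr = TRUE)
  expect_equal(pwm_max_score(p), sum(apply(log2(probs / 0.25), 1, max)))
})

test_that("scan finds forward hits on a poly-A sequence and skips masks", {
  p <- pwm(matrix(c(97, 1, 1, 1), 1, 4), "A1", "a", pseudocount = 0)
  r <- sequence_record("s", "AAAA")
  h <- scan_sequence(r, p, threshold_fraction = 0.5)
  expect_equal(h$start[h$strand == "+"], 0:3)
  expect_equal(sum(h$strand == "-"), 0L)
  expect_true(all(h$end - h$start == 1L))
  # fully masked sequence yields no hits
  rm <- sequence_record("s", "aaaa")
  expect_equal(nrow(scan_sequence(rm, p, threshold_fraction = 0.5)), 0L)
  # windows containing N are skipped
  rn <- sequence_record("s", "AANA")
  hn <- scan_sequence(rn, p, threshold_fraction = 0.5)
  expect_equal(hn$start[hn$strand == "+"], c(0L, 1L, 3L))
})

test_that("palindromic matrices score both strands equally", {
  p <- make_pwm("ACGT")  # reverse complement of ACGT is ACGT
  set.seed(7)
  r <- sequence_record("s", random_seq(100))
  h <- scan_sequence(r, p, threshold_fraction = 0)
  fwd <- h[h$strand == "+", ]
  rev <- h[h$strand == "-", ]
  expect_equal(fwd$start, rev$start)
  expect_equal(fwd$score, rev$score)
})

test_that("scan equals exhaustive window scoring on short sequences", {
  set.seed(11)
  for (k in 1:20) {
    w <- sample(4:9, 1L)
    p <- make_pwm(random_seq(w), dominant = sample(c(40, 85), 1L))
    n <- sample(20:200, 1L)
    s <- random_seq(n)
    # random mask and N injection
    ch <- strsplit(s, "")[[1L]]
    ch[sample(n, n %/% 20)] <- "N"
    mstart <- sample(n - 5L, 1L)
    rec <- sequence_record("s", paste(ch, collapse = ""),
                           masked = IRanges::IRanges(mstart, mstart + 4L))
    frac <- stats::runif(1L, 0.3, 0.8)
    got <- scan_sequence(rec, p, threshold_fraction = frac)
    want <- brute_scan(rec, p, frac)
    expect_equal(got[, c("start", "end", "strand")],
                 want[, c("start", "end", "strand")], ignore_attr = TRUE)
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }
})

test_that("raising the threshold fraction never increases hit count", {
  set.seed(13)
  p <- make_pwm(random_seq(8), dominant = 40)
  r <- sequence_record("s", random_seq(500))
  counts <- vapply(c(0.2, 0.4, 0.8), function(f)
    nrow(scan_sequence(r, p, threshold_fraction = f)), integer(1L))
  expect_true(all(diff(counts) <= 0L))
})

test_that("scanning the reverse complement mirrors hits with swapped strands", {
  set.seed(17)
  p <- make_pwm(random_seq(7))
  s <- random_seq(300)
  r <- sequence_record("s", s)
  rc <- sequence_record("s", revcomp(s))
  h <- scan_sequence(r, p, threshold_fraction = 0.25)
  hrc <- scan_sequence(rc, p, threshold_fraction = 0.25)
  expect_gt(nrow(h), 0L)
  n <- nchar(s)
  mirrored <- data.frame(start = n - h$end, end = n - h$start,
                         strand = as.character(ifelse(h$strand == "+",
                                                      "-", "+")),
                         score = h$score)
  mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
  expect_equal(hrc[, c("start", "end", "strand", "score")], mirrored,
               ignore_attr = TRUE)
})

test_that("soft-masked FASTA round-trips through read_genome/write_genome", {
  r <- sequence_record("sq", "ACGTACGTACGTacgtACGTNNACGT")
  f <- tempfile(fileext = ".fa")
  write_genome(list(r), f)
  back <- read_genome(f)
  expect_equal(back$sq$sequence, toupper(r$sequence))
  expect_equal(IRanges::start(back$sq$masked), 13L)
  expect_equal(IRanges::end(back$sq$masked), 16L)
})
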