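test_that("anchoring picks the nearest ortholog-bearing gene", {
  genes <- gene_models(data.frame(
    gene_id = c("gA", "gB"), seq_id = "chr1",
    start = c(1000L, 9000L), end = c(3000L, 11000L), strand = "+"))
  orth <- data.frame(ref_gene = "gA", human_gene = "H_gA")
  hg <- gene_models(data.frame(
    gene_id = c("H_left", "H_gA", "H_right"), seq_id = "hchr",
    start = c(1000L, 5000L, 9000L), end = c(2000L, 7000L, 10000L),
    strand = "+"))
  crm <- data.frame(crm_id = "c1", seq_id = "chr1", start = 4000L,
                    end = 4200L)
  a <- anchor_crms(crm, genes, orth, hg)
  # gB is nearer to the CRM but has no ortholog; gA anchors
  expect_true(a$anchored)
  expect_equal(a$ref_gene, "gA")
  expect_equal(a$human_gene, "H_gA")
  expect_equal(a$search_start, 0)       # 1000 - 10000 pad, clipped at 0
  expect_equal(a$search_end, 20000)     # 10000 + pad
})

test_that("anchors at chromosome ends use the single available flank", {
  genes <- gene_models(data.frame(
    gene_id = "gA", seq_id = "chr1", start = 100L, end = 300L, strand = "+"))
  orth <- data.frame(ref_gene = "gA", human_gene = "H_gA")
  hg <- gene_models(data.frame(
    gene_id = c("H_gA", "H_right"), seq_id = "hchr",
    start = c(100L, 5000L), end = c(300L, 6000L), strand = "+"))
  crm <- data.frame(crm_id = "c1", seq_id = "chr1", start = 400L, end = 500L)
  a <- anchor_crms(crm, genes, orth, hg, pad = 1000L)
  expect_equal(a$search_start, 0)       # 100 - 1000 clipped
  expect_equal(a$search_end, 7000)      # right flank end + pad
  # CRMs on sequences without ortholog-bearing genes are excluded with reason
  crm2 <- data.frame(crm_id = "c2", seq_id = "chr9", start = 0L, end = 100L)
  a2 <- anchor_crms(crm2, genes, orth, hg)
  expect_false(a2$anchored)
  expect_match(a2$reason, "no ortholog")
})

test_that("gapless identical alignment scores length times the match score", {
  set.seed(41)
  s <- random_seq(100)
  call <- align_to_human(s, s)
  sm <- hoxd70()
  ch <- strsplit(s, "")[[1L]]
  expect_equal(call$aln_score, sum(sm[cbind(ch, ch)]))
  expect_equal(call$pct_identity, 100)
  # reverse-complement embedding is found on the minus strand, same score
  set.seed(43)
  emb <- paste0(random_seq(50), revcomp(s), random_seq(50))
  rcall <- align_to_human(s, emb)
  expect_equal(rcall$strand, "-")
  expect_equal(rcall$aln_score, call$aln_score)
})

test_that("the conservation thresholds are strict inequalities", {
  # 26 C matches against an identical sequence: score exactly 26 x 100
  s26 <- strrep("C", 26)
  b <- align_to_human(s26, s26)
  expect_equal(b$aln_score, 2600)
  expect_equal(b$pct_identity, 100)
  expect_false(b$passes)
  # one more match clears the bar
  s27 <- strrep("C", 27)
  expect_true(align_to_human(s27, s27)$passes)
  # 33 matches / 22 mismatches: score 2618 > 2600, identity exactly 60%
  mlen <- c(2, 2, 2, 2, 2, 2, 2, 2, 3, 3)
  pat <- paste0("CCC", paste(vapply(seq_along(mlen), function(i)
    paste0(strrep("A", mlen[i]), "CCC"), character(1L)), collapse = ""))
  sub <- gsub("A", "G", pat)
  call <- align_to_human(pat, sub)
  expect_equal(call$aln_score, 33 * 100 - 22 * 31)
  expect_gt(call$aln_score, 2600)
  expect_equal(call$pct_identity, 60)
  expect_false(call$passes)
})

test_that("passing is monotone in score and identity", {
  pass <- function(sc, pid) (sc > 2600) && (pid > 60)
  grid <- expand.grid(sc = c(2000, 2600, 2601, 5000),
                      pid = c(50, 60, 60.01, 90))
  for (i in seq_len(nrow(grid))) {
    for (j in seq_len(nrow(grid))) {
      if (grid$sc[j] >= grid$sc[i] && grid$pid[j] >= grid$pid[i]) {
        expect_false(pass(grid$sc[i], grid$pid[i]) &&
                       !pass(grid$sc[j], grid$pid[j]))
      }
    }
  }
})

mk_calls <- function(n, scores = rev(seq_len(n))) {
  data.frame(crm_id = sprintf("c%03d", seq_len(n)), score = scores,
             seq_id = "chr1", start = seq_len(n) * 100L,
             end = seq_len(n) * 100L + 50L, passes = TRUE,
             stringsAsFactors = FALSE)
}

test_that("candidate selection returns the printed rank positions", {
  calls <- mk_calls(491, scores = 1000 - seq_len(491))
  sel <- select_candidates(calls)
  expect_equal(sel$top10$rank, 1:10)
  expect_equal(sel$spread10$rank,
               c(20L, 40L, 60L, 81L, 100L, 120L, 140L, 159L, 180L, 200L))
  expect_equal(sel$top10$crm_id, calls$crm_id[1:10])
  # permuting the input changes nothing
  perm <- calls[sample(nrow(calls)), ]
  sel2 <- select_candidates(perm)
  expect_equal(sel2$top10, sel$top10)
  expect_equal(sel2$spread10, sel$spread10)
})

test_that("candidate selection clips short lists and breaks ties leftmost", {
  few <- mk_calls(5)
  sel <- NULL
  expect_warning(sel <- select_candidates(few), "clipped")
  expect_equal(nrow(sel$top10), 5L)
  expect_equal(nrow(sel$spread10), 0L)
  # tie at ranks 10/11: the genomically leftmost CRM takes rank 10
  calls <- mk_calls(12, scores = c(100:92, 50, 50, 40))
  calls$start[10:11] <- c(900L, 700L)   # c011 is leftmost of the tied pair
  sel2 <- suppressWarnings(select_candidates(calls))
  ord <- calls[order(-calls$score, calls$seq_id, calls$start), ]
  expect_equal(sel2$top10$crm_id[10L], ord$crm_id[10L])
  expect_equal(sel2$top10$crm_id[10L], "c011")
  # no passing CRMs: empty lists
  none <- mk_calls(3); none$passes <- FALSE
  sel3 <- select_candidates(none)
  expect_equal(nrow(sel3$top10), 0L)
})
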