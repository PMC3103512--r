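test_that("the same spec produces a byte-identical bundle on disk", {
  spec <- fixture_spec(seed = 4L, n_sequences = 1L, sequence_length = 30000L,
                       n_genes = 6L, n_planted = 3L, n_human_conserved = 1L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- generate_fixture(spec, dir = d1)
  b2 <- generate_fixture(spec, dir = d2)
  for (f in list.files(d1)) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  expect_equal(b1$truth, b2$truth)
})

test_that("ground truth records the planted clusters within bounds", {
  bun <- default_fixture()
  tr <- bun$truth$planted
  expect_length(tr, 10L)
  expect_equal(sum(vapply(tr, `[[`, logical(1L), "human_conserved")), 4L)
  for (t in tr) {
    expect_true(all(unlist(t$offsets) >= 0 & unlist(t$offsets) <= 20))
    expect_length(t$conserved_species, 2L)
    rec <- bun$ref_genome[[t$seq_id]]
    # planted clusters sit in unmasked, intergenic space
    expect_equal(sum(IRanges::countOverlaps(
      IRanges::IRanges(t$start + 1L, t$end), rec$masked)), 0L)
    gg <- bun$genes[bun$genes$seq_id == t$seq_id, ]
    expect_false(any(overlaps0(t$start, t$end, gg$start, gg$end)))
  }
})

test_that("comparison species carry the planted copies at their offsets", {
  bun <- default_fixture()
  for (t in bun$truth$planted) {
    for (sp in t$conserved_species) {
      o <- t$offsets[[sp]]
      copy <- subseq0(bun$species_genomes[[sp]][[t$seq_id]],
                      t$start + o, t$end + o)
      orig <- subseq0(bun$ref_genome[[t$seq_id]], t$start, t$end)
      mism <- sum(strsplit(copy, "")[[1L]] != strsplit(orig, "")[[1L]])
      # 5% extra divergence: far closer than background identity
      expect_lt(mism / nchar(orig), 0.2)
    }
  }
})

# exact P(window score >= threshold) for a PWM scanned over i.i.d. GC-biased
# background: full enumeration by per-position convolution of score sums
tail_prob_oracle <- function(p, gc, frac) {
  lo <- pwm_log_odds(p)
  base_p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sums <- 0; probs <- 1
  for (j in seq_len(p$width)) {
    sums <- as.vector(outer(sums, lo[j, ], `+`))
    probs <- as.vector(outer(probs, base_p, `*`))
  }
  thr <- frac * pwm_max_score(p)
  sum(probs[sums >= thr])
}

test_that("a zero-planted fixture has background-level hit density", {
  spec <- fixture_spec(seed = 8L, n_planted = 0L, n_human_conserved = 0L,
                       masked_fraction = 0)
  bun <- generate_fixture(spec)
  ref <- fixture_ref(bun)
  p <- bun$pwms[[1L]]
  hits <- scan_genome(ref, list(p))
  # scannable windows: both strands, excluding CDS-masked positions
  nscan <- sum(vapply(ref, function(r) {
    nchar(r$sequence) - sum(IRanges::width(r$masked))
  }, numeric(1L)))
  nwin <- 2 * nscan
  pr <- tail_prob_oracle(p, spec$gc_content, 0.75)
  expected <- nwin * pr
  sd <- sqrt(nwin * pr * (1 - pr))
  expect_lte(abs(nrow(hits) - expected), max(2 * sd, 3))
})

test_that("fixture files parse back into the bundle's tables", {
  spec <- fixture_spec(seed = 4L, n_sequences = 1L, sequence_length = 30000L,
                       n_genes = 6L, n_planted = 3L, n_human_conserved = 1L)
  d <- withr::local_tempdir()
  bun <- generate_fixture(spec, dir = d)
  ref <- read_genome(file.path(d, "ref.fa"))
  expect_equal(names(ref), names(bun$ref_genome))
  expect_equal(ref$chr1$sequence, bun$ref_genome$chr1$sequence)
  expect_equal(ref$chr1$masked, bun$ref_genome$chr1$masked)
  gg <- read_gff_genes(file.path(d, "genes.gff3"))
  expect_equal(gg$genes$gene_id, bun$genes$gene_id)
  expect_equal(gg$genes$tss, bun$genes$tss)
  truth <- jsonlite::read_json(file.path(d, "ground_truth.json"),
                               simplifyVector = FALSE)
  expect_length(truth$planted, 3L)
  inj <- read_injection_table(file.path(d, "injection.tsv"))
  expect_equal(nrow(inj), 3L)
  expect_true(all(inj$n_specific <= inj$n_lens))
})

test_that("the enrichment simulator reproduces its target frequencies", {
  sim <- simulate_enrichment_dataset(n_conserved = 4000L,
                                     n_background = 4000L, seed = 9L)
  tab <- table(sim$crm_terms$term[sim$crm_terms$crm_id %in%
                                    sim$conserved_ids])
  f_brain <- tab[["brain"]] / 4000
  expect_lt(abs(f_brain - 0.4), 0.03)
  tabb <- table(sim$crm_terms$term[!sim$crm_terms$crm_id %in%
                                     sim$conserved_ids])
  expect_lt(abs(tabb[["brain"]] / 4000 - 0.2), 0.03)
  # deterministic under its seed
  sim2 <- simulate_enrichment_dataset(n_conserved = 4000L,
                                      n_background = 4000L, seed = 9L)
  expect_identical(sim, sim2)
})
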