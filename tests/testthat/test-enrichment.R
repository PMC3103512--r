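test_that("the ortholog resolver keeps the highest-identity pair", {
  om <- data.frame(source_gene = c("zf1", "zf1", "zf2"),
                   ref_gene = c("gA", "gB", "gC"),
                   pct_identity = c(80, 60, 70))
  r <- resolve_orthologs(om)
  expect_equal(nrow(r), 2L)
  expect_equal(r$ref_gene[r$source_gene == "zf1"], "gA")
  expect_error(resolve_orthologs(om[, 1:2]), "lacks columns")
})

test_that("term closure annotates every ancestor", {
  ann <- data.frame(gene_id = "g1", term = "forebrain", stage = "st20")
  parents <- data.frame(term = c("forebrain", "brain", "spinal_cord"),
                        parent = c("brain", "nervous_system",
                                   "nervous_system"))
  out <- expand_term_closure(ann, parents)
  expect_setequal(out$term, c("forebrain", "brain", "nervous_system"))
  expect_equal(unique(out$gene_id), "g1")
  # no parent table: unchanged
  expect_equal(expand_term_closure(ann, NULL), ann)
})

test_that("CRMs inherit the closest gene's terms regardless of distance", {
  genes <- gene_models(data.frame(
    gene_id = c("gA", "gB"), seq_id = "chr1",
    start = c(1000L, 52000L), end = c(2000L, 53000L), strand = "+"))
  ann <- data.frame(gene_id = c("gA", "gB"), term = c("brain", "somite"),
                    stage = "st20")
  # 1 kb from gA, 50 kb from gB: gA's terms transfer
  crm <- data.frame(crm_id = "c1", seq_id = "chr1", start = 2400L,
                    end = 2600L)
  at <- annotate_crms(crm, genes, ann)
  expect_equal(at$links$gene_id, "gA")
  expect_equal(at$crm_terms$term, "brain")
  # equidistant: the upstream (left) gene wins the tie
  mid_between <- (1500L + 52500L) %/% 2L
  crm2 <- data.frame(crm_id = "c2", seq_id = "chr1",
                     start = mid_between - 100L, end = mid_between + 100L)
  at2 <- annotate_crms(crm2, genes, ann)
  expect_equal(at2$links$gene_id, "gA")
  # a gene without annotation yields a valid empty term set
  crm3 <- data.frame(crm_id = "c3", seq_id = "chr1", start = 52400L,
                     end = 52600L)
  at3 <- annotate_crms(crm3, genes, ann[ann$gene_id == "gA", ])
  expect_equal(nrow(at3$crm_terms), 0L)
})

# exact one-sided Fisher p by explicit hypergeometric summation
fisher_oracle <- function(a, b, c, d) {
  N <- a + b + c + d; K <- a + c; n <- a + b
  ks <- a:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

mk_terms <- function(conserved_ids, background_ids, a, c) {
  data.frame(crm_id = c(conserved_ids[seq_len(a)],
                        background_ids[seq_len(c)]),
             term = "brain", stage = "st20", stringsAsFactors = FALSE)
}

test_that("enrichment p equals the exact hypergeometric tail", {
  cons <- sprintf("V%02d", 1:20)
  bg <- sprintf("B%02d", 1:100)
  ct <- mk_terms(cons, bg, a = 15L, c = 30L)
  res <- test_enrichment(ct, cons, c(cons, bg), min_conserved = 1L)
  expect_equal(res$a, 15L)
  expect_equal(res$b, 5L)
  expect_equal(res$c, 30L)
  expect_equal(res$d, 70L)
  expect_equal(res$p, fisher_oracle(15, 5, 30, 70), tolerance = 1e-12)
  # a term annotating everything cannot be enriched
  all_term <- data.frame(crm_id = c(cons, bg), term = "everything",
                         stage = "st20")
  res2 <- test_enrichment(all_term, cons, c(cons, bg), min_conserved = 1L)
  expect_equal(res2$p, 1)
})

test_that("terms below the conserved-support floor are dropped", {
  cons <- sprintf("V%02d", 1:30)
  bg <- sprintf("B%02d", 1:60)
  ct <- rbind(mk_terms(cons, bg, a = 25L, c = 10L),
              within(mk_terms(cons, bg, a = 5L, c = 40L),
                     term <- "rare_term"))
  res <- test_enrichment(ct, cons, c(cons, bg), min_conserved = 20L)
  expect_equal(res$term, "brain")
  expect_warning(
    empty <- test_enrichment(ct, cons, c(cons, bg), min_conserved = 29L),
    "no term")
  expect_equal(nrow(empty), 0L)
  expect_error(test_enrichment(ct, c(cons, "V99"), cons, 1L), "subset")
})

test_that("q values respect BH and dominate raw p", {
  sim <- simulate_enrichment_dataset(seed = 5L)
  res <- test_enrichment(sim$crm_terms, sim$conserved_ids, sim$all_ids,
                         min_conserved = 5L)
  expect_true(all(res$q >= res$p))
  # BH never rejects fewer than Bonferroni at the same level
  bonf <- sum(stats::p.adjust(res$p, "bonferroni") <= 0.05)
  expect_gte(sum(res$significant), bonf)
  # BH matches the step-up definition on the realized p vector
  m <- nrow(res); o <- order(res$p)
  k <- max(c(0L, which(res$p[o] <= 0.05 * seq_len(m) / m)))
  rejected <- if (k > 0L) res$term[o][seq_len(k)] else character(0)
  expect_setequal(res$term[res$significant], rejected)
})

test_that("planted neuronal enrichment is detected and parity is not", {
  hits_neuro <- 0L
  hits_other <- 0L
  n_sim <- 100L
  for (s in seq_len(n_sim)) {
    sim <- simulate_enrichment_dataset(seed = 1000L + s)
    res <- test_enrichment(sim$crm_terms, sim$conserved_ids, sim$all_ids,
                           min_conserved = 20L)
    neuro <- res$significant[res$term %in% c("brain", "spinal_cord")]
    other <- res$significant[!res$term %in% c("brain", "spinal_cord")]
    if (length(neuro) == 2L && all(neuro)) hits_neuro <- hits_neuro + 1L
    if (!any(other)) hits_other <- hits_other + 1L
  }
  expect_gte(hits_neuro / n_sim, 0.95)
  expect_gte(hits_other / n_sim, 0.95)
})
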