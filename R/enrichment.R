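#' Resolve an ortholog map to one reference gene per source gene
#'
#' When a source-species gene (e.g. zebrafish) has several candidate
#' orthologs in the reference genome, only the pair with the highest percent
#' identity is kept (ties keep the first row).
#'
#' @param orthomap data.frame `source_gene`, `ref_gene`, `pct_identity`.
#' @return data.frame with one row per `source_gene`.
#' @export
resolve_orthologs <- function(orthomap) {
  need <- c("source_gene", "ref_gene", "pct_identity")
  missing <- setdiff(need, names(orthomap))
  if (length(missing)) stop("ortholog map lacks columns: ",
                            paste(missing, collapse = ", "))
  orthomap <- orthomap[order(orthomap$source_gene,
                             -orthomap$pct_identity), , drop = FALSE]
  out <- orthomap[!duplicated(orthomap$source_gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expand tissue annotations through the ontology term closure
#'
#' A gene annotated to a term is implicitly annotated to every ancestor of
#' the term ("a tissue and its subparts"): annotating `forebrain` also
#' annotates `brain` and `nervous_system`. The closure is given as an
#' explicit parent table.
#'
#' @param annotations data.frame `gene_id`, `term`, `stage`.
#' @param parents data.frame `term`, `parent` (direct parents; the closure
#'   is taken transitively). NULL leaves annotations unchanged.
#' @return annotation data.frame including ancestor terms (deduplicated).
#' @export
expand_term_closure <- function(annotations, parents = NULL) {
  if (is.null(parents) || nrow(parents) == 0L) return(annotations)
  anc <- function(term) {
    seen <- character()
    frontier <- term
    while (length(frontier)) {
      nxt <- unique(parents$parent[parents$term %in% frontier])
      nxt <- setdiff(nxt, c(seen, term))
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  closure <- lapply(unique(annotations$term), anc)
  names(closure) <- unique(annotations$term)
  extra <- list()
  for (i in seq_len(nrow(annotations))) {
    up <- closure[[annotations$term[i]]]
    if (length(up)) {
      extra[[length(extra) + 1L]] <- data.frame(
        gene_id = annotations$gene_id[i], term = up,
        stage = annotations$stage[i], stringsAsFactors = FALSE)
    }
  }
  out <- rbind(annotations, do.call(rbind, extra))
  out <- out[!duplicated(out[, c("gene_id", "term", "stage")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attach tissue annotations to CRMs via the closest gene
#'
#' Each CRM is associated with the closest of its flanking genes by midpoint
#' distance, independently of how far away that gene is; an equidistant tie
#' goes to the upstream (left) gene. The CRM then inherits the
#' (closure-expanded, ortholog-transferred) annotation terms of that gene.
#'
#' @param crms CRM data.frame.
#' @param genes reference [gene_models].
#' @param annotations reference-gene annotation data.frame `gene_id`,
#'   `term`, `stage` — e.g. zebrafish terms transferred through
#'   [resolve_orthologs()] and expanded with [expand_term_closure()].
#' @return list with `links` (data.frame `crm_id`, `gene_id`, `distance`)
#'   and `crm_terms` (data.frame `crm_id`, `term`, `stage`; CRMs whose gene
#'   has no annotation are absent, which is a valid empty term set).
#' @export
annotate_crms <- function(crms, genes, annotations) {
  links <- vector("list", nrow(crms))
  for (i in seq_len(nrow(crms))) {
    mid <- (crms$start[i] + crms$end[i]) %/% 2L
    gg <- genes[genes$seq_id == crms$seq_id[i], , drop = FALSE]
    if (nrow(gg) == 0L) {
      links[[i]] <- data.frame(crm_id = crms$crm_id[i],
                               gene_id = NA_character_, distance = NA_real_,
                               stringsAsFactors = FALSE)
      next
    }
    gmid <- (gg$start + gg$end) %/% 2L
    d <- abs(mid - gmid)
    best <- which(d == min(d))
    if (length(best) > 1L) best <- best[which.min(gmid[best])]  # upstream
    links[[i]] <- data.frame(crm_id = crms$crm_id[i],
                             gene_id = gg$gene_id[best],
                             distance = d[best], stringsAsFactors = FALSE)
  }
  links <- do.call(rbind, links)
  crm_terms <- merge(links[!is.na(links$gene_id), c("crm_id", "gene_id")],
                     annotations, by = "gene_id")
  crm_terms <- crm_terms[, c("crm_id", "term", "stage")]
  crm_terms <- crm_terms[!duplicated(crm_terms), , drop = FALSE]
  rownames(crm_terms) <- NULL
  list(links = links, crm_terms = crm_terms)
}

# one-sided Fisher p for enrichment of `a` in the conserved margin:
# upper hypergeometric tail P(X >= a) with X ~ Hyper(K=a+c, N=a+b+c+d, n=a+b)
fisher_p_greater <- function(a, b, c, d) {
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Tissue-enrichment test of conserved CRMs against the background set
#'
#' For every term x stage pair annotating at least `min_conserved`
#' conserved CRMs, builds the 2x2 table (conserved vs background x
#' annotated vs not), computes a one-sided Fisher exact p (enrichment
#' direction), and controls the false-discovery rate with Benjamini-Hochberg
#' across all retained pairs jointly. The background set is the full CRM set
#' minus the conserved subset.
#'
#' @param crm_terms data.frame `crm_id`, `term`, `stage` from
#'   [annotate_crms()].
#' @param conserved_ids crm ids of the vertebrate-conserved subset.
#' @param all_ids crm ids of the whole predicted set (superset of
#'   `conserved_ids`).
#' @param min_conserved minimum conserved CRMs annotated with the term
#'   (default 20).
#' @param fdr false-discovery rate for the `significant` flag (default
#'   0.05).
#' @return data.frame `term`, `stage`, `a`, `b`, `c`, `d`, `p`, `q`,
#'   `significant`, sorted by `p`; zero rows (with a warning) when no term
#'   reaches `min_conserved`.
#' @export
test_enrichment <- function(crm_terms, conserved_ids, all_ids,
                            min_conserved = 20L, fdr = 0.05) {
  if (!all(conserved_ids %in% all_ids)) {
    stop("conserved_ids must be a subset of all_ids")
  }
  background_ids <- setdiff(all_ids, conserved_ids)
  key <- unique(crm_terms[, c("term", "stage")])
  rows <- list()
  for (i in seq_len(nrow(key))) {
    ann <- crm_terms$crm_id[crm_terms$term == key$term[i] &
                            crm_terms$stage == key$stage[i]]
    a <- sum(conserved_ids %in% ann)
    if (a < min_conserved) next
    b <- length(conserved_ids) - a
    c_ <- sum(background_ids %in% ann)
    d <- length(background_ids) - c_
    rows[[length(rows) + 1L]] <- data.frame(
      term = key$term[i], stage = key$stage[i], a = a, b = b, c = c_, d = d,
      p = fisher_p_greater(a, b, c_, d), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    warning("no term annotates at least ", min_conserved, " conserved CRMs")
    return(data.frame(term = character(), stage = character(), a = integer(),
                      b = integer(), c = integer(), d = integer(),
                      p = numeric(), q = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$q <= fdr
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  res
}
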