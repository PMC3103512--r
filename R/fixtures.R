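#' Specification of a synthetic multi-species fixture
#'
#' Describes a deterministic toy dataset carrying the statistical structure
#' every pipeline stage assumes: a soft-masked reference genome with genes
#' and planted conserved binding-site clusters, three comparison teleost
#' genomes holding (possibly misaligned, up to 20 bp) copies of the planted
#' sites, whole-sequence alignment blocks, a human neighborhood with
#' high-identity copies of a subset of the planted clusters, ortholog maps,
#' tissue annotations, and an injection-screen table.
#'
#' Defaults define the package's reference study conditions: a 100 kb
#' reference (2 x 50 kb) across 4 species with 10 planted clusters; planted
#' sites are matrix consensus with a 0.05 per-base mutation rate and
#' comparison-species copies carry 0.05 additional divergence, so planted
#' sites clear the default hit threshold with margin; 4 clusters carry an
#' 85 percent identity human copy.
#'
#' @param seed integer seed; the whole bundle is a deterministic function of
#'   the spec.
#' @param n_sequences,sequence_length reference genome shape.
#' @param gc_content background GC fraction.
#' @param n_genes genes in the reference genome (split over sequences).
#' @param gene_length gene span in bp.
#' @param masked_fraction fraction of each sequence covered by repeat masks.
#' @param n_planted planted binding-site clusters.
#' @param sites_per_crm binding sites per planted cluster.
#' @param oligotypic_matrices distinct matrices used by oligotypic clusters
#'   (every other cluster is homotypic, using a single matrix).
#' @param mutation_rate per-base mutation rate of planted consensus sites.
#' @param species_divergence additional per-base divergence of
#'   comparison-species site copies.
#' @param n_conserved_species comparison species carrying each cluster.
#' @param max_plant_offset largest misalignment offset planted (<= 20).
#' @param n_human_conserved clusters with a human copy.
#' @param human_identity per-base identity of human copies.
#' @param zf_coverage fraction of reference genes with a zebrafish ortholog.
#' @param neuronal_terms,other_terms tissue terms assigned to genes.
#' @param neuronal_freq_conserved,neuronal_freq_background per-gene
#'   probability of each neuronal term for genes nearest to human-conserved
#'   clusters vs all other genes (non-neuronal terms use the background
#'   frequency everywhere).
#' @param pwm_file JASPAR-format PWM file; default is the matrix set shipped
#'   with the package.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         n_sequences = 2L,
                         sequence_length = 50000L,
                         gc_content = 0.4,
                         n_genes = 12L,
                         gene_length = 2000L,
                         masked_fraction = 0.1,
                         n_planted = 10L,
                         sites_per_crm = 6L,
                         oligotypic_matrices = 5L,
                         mutation_rate = 0.05,
                         species_divergence = 0.05,
                         n_conserved_species = 2L,
                         max_plant_offset = 15L,
                         n_human_conserved = 4L,
                         human_identity = 0.85,
                         zf_coverage = 0.9,
                         neuronal_terms = c("brain", "spinal_cord"),
                         other_terms = c("pronephros", "somite", "heart"),
                         neuronal_freq_conserved = 0.8,
                         neuronal_freq_background = 0.3,
                         pwm_file = NULL) {
  if (max_plant_offset > 20L) stop("planted offsets must be <= 20 bp")
  spec <- as.list(environment())
  class(spec) <- "fixture_spec"
  spec
}

FIXTURE_SPECIES <- c("tetraodon", "stickleback", "fugu")

random_dna <- function(n, gc) {
  sample(DNA_BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

mutate_bases <- function(ch, rate) {
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
  ch
}

# sample a start for a len-bp interval avoiding `occupied` (IRanges, 1-based)
# with `pad` bp clearance, within [lo, hi) 0-based
place_interval <- function(len, lo, hi, occupied, pad = 0L,
                           max_tries = 10000L) {
  for (t in seq_len(max_tries)) {
    s0 <- lo + sample.int(hi - lo - len + 1L, 1L) - 1L
    cand <- IRanges::IRanges(s0 + 1L - pad, s0 + len + pad)
    if (length(occupied) == 0L ||
        sum(IRanges::countOverlaps(cand, occupied)) == 0L) {
      return(s0)
    }
  }
  stop("could not place a ", len, " bp interval; fixture too crowded")
}

#' Generate a synthetic multi-species fixture bundle
#'
#' Builds the full bundle described by a [fixture_spec()], optionally
#' writing it to disk as the plain-text formats the pipeline reads (FASTA,
#' GFF3, MAF + TSV blocks, TSV tables, ground-truth JSON). The same spec
#' always produces a byte-identical bundle.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional output directory (created if missing).
#' @return list with elements `ref_genome`, `species_genomes`, `blocks`,
#'   `genes`, `cds`, `pwms`, `human_genome`, `human_genes`,
#'   `orthologs_human`, `orthologs_zebrafish`, `annotations`,
#'   `term_parents`, `injection`, `truth` (planted ground truth), `spec`,
#'   and `files` (named paths when `dir` is given).
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  pwm_file <- spec$pwm_file
  if (is.null(pwm_file)) {
    pwm_file <- system.file("extdata", "fixture_pwms.pfm", package = "crmpred")
  }
  pwms <- read_jaspar(pwm_file)
  mids <- vapply(pwms, `[[`, character(1L), "matrix_id")
  bundle <- withr::with_seed(spec$seed, {
    .generate_fixture_inner(spec, pwms, mids)
  })
  bundle$spec <- spec
  bundle$pwms <- pwms
  if (!is.null(dir)) {
    bundle$files <- write_fixture(bundle, dir, pwm_file)
  }
  bundle
}

.generate_fixture_inner <- function(spec, pwms, mids) {
  nseq <- spec$n_sequences
  slen <- spec$sequence_length
  seq_ids <- sprintf("chr%d", seq_len(nseq))
  genes_per_seq <- diff(round(seq(0, spec$n_genes, length.out = nseq + 1L)))
  plant_per_seq <- diff(round(seq(0, spec$n_planted, length.out = nseq + 1L)))

  ref_chars <- list(); genes <- list(); repeats <- list(); truth <- list()
  occupied <- list()
  for (si in seq_len(nseq)) {
    sid <- seq_ids[si]
    ch <- random_dna(slen, spec$gc_content)
    occ <- IRanges::IRanges()
    # genes
    for (gi in seq_len(genes_per_seq[si])) {
      s0 <- place_interval(spec$gene_length, 0L, slen, occ, pad = 200L)
      occ <- c(occ, IRanges::IRanges(s0 + 1L, s0 + spec$gene_length))
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = sprintf("g%s_%02d", si, gi), seq_id = sid, start = s0,
        end = s0 + spec$gene_length,
        strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
    }
    # repeat masks
    target <- spec$masked_fraction * slen
    got <- 0L
    while (got < target) {
      rl <- sample(200:800, 1L)
      s0 <- place_interval(rl, 0L, slen, occ, pad = 50L)
      occ <- c(occ, IRanges::IRanges(s0 + 1L, s0 + rl))
      repeats[[length(repeats) + 1L]] <- data.frame(
        seq_id = sid, start = s0, end = s0 + rl, stringsAsFactors = FALSE)
      got <- got + rl
    }
    ref_chars[[sid]] <- ch
    occupied[[sid]] <- occ
  }
  genes <- gene_models(do.call(rbind, genes))
  repeats <- if (length(repeats)) do.call(rbind, repeats) else
    data.frame(seq_id = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)

  # planted clusters: intergenic, unmasked, inside the gene-covered span so
  # the human anchor's flanking-gene interval contains them
  plant_idx <- 0L
  for (si in seq_len(nseq)) {
    sid <- seq_ids[si]
    gg <- genes[genes$seq_id == sid, , drop = FALSE]
    lo <- min(gg$start) + 1L
    hi <- max(gg$end) - 1L
    for (pi in seq_len(plant_per_seq[si])) {
      plant_idx <- plant_idx + 1L
      homotypic <- plant_idx %% 2L == 1L
      mm <- if (homotypic) sample(mids, 1L) else
        sample(mids, min(spec$oligotypic_matrices, length(mids)))
      # realize the cluster sequence
      site_mat <- rep(mm, length.out = spec$sites_per_crm)
      pieces <- character(); site_rel <- integer(); site_w <- integer()
      pos <- 0L
      for (k in seq_len(spec$sites_per_crm)) {
        p <- pwms[[match(site_mat[k], mids)]]
        site <- mutate_bases(strsplit(pwm_consensus(p), "")[[1L]],
                             spec$mutation_rate)
        site <- paste(site, collapse = "")
        if (sample(c(TRUE, FALSE), 1L)) site <- revcomp(site)
        gap <- if (k == 1L) 0L else sample(2:20, 1L)
        pieces <- c(pieces, strrep("N", 0L), random_dna(gap, spec$gc_content),
                    site)
        pos <- pos + gap
        site_rel <- c(site_rel, pos)
        site_w <- c(site_w, p$width)
        pos <- pos + p$width
      }
      crm_seq <- paste(unlist(pieces), collapse = "")
      clen <- nchar(crm_seq)
      s0 <- place_interval(clen, lo, hi, occupied[[sid]], pad = 600L)
      occupied[[sid]] <- c(occupied[[sid]],
                           IRanges::IRanges(s0 + 1L, s0 + clen))
      ref_chars[[sid]][(s0 + 1L):(s0 + clen)] <- strsplit(crm_seq, "")[[1L]]
      consv <- sample(FIXTURE_SPECIES, spec$n_conserved_species)
      offs <- stats::setNames(
        sample(0:spec$max_plant_offset, length(consv), replace = TRUE),
        consv)
      truth[[plant_idx]] <- list(
        planted_id = sprintf("planted%02d", plant_idx), seq_id = sid,
        start = s0, end = s0 + clen, matrix_ids = mm,
        n_sites = spec$sites_per_crm, homotypic = homotypic,
        conserved_species = consv, offsets = as.list(offs),
        crm_seq = crm_seq, human_conserved = FALSE)
    }
  }
  # mark the human-conserved subset (spread over the list deterministically)
  hc <- unique(round(seq(1L, spec$n_planted,
                         length.out = max(0L, spec$n_human_conserved))))
  for (i in hc) truth[[i]]$human_conserved <- TRUE

  # reference records with repeat masks (CDS masking handled by the caller)
  ref_genome <- lapply(seq_ids, function(sid) {
    rr <- repeats[repeats$seq_id == sid, , drop = FALSE]
    sequence_record(sid, paste(ref_chars[[sid]], collapse = ""),
                    masked = IRanges::IRanges(rr$start + 1L, rr$end))
  })
  names(ref_genome) <- seq_ids

  # comparison species: independent backgrounds + planted (offset) copies
  species_genomes <- list()
  for (sp in FIXTURE_SPECIES) {
    gg <- list()
    for (sid in seq_ids) {
      ch <- random_dna(slen, spec$gc_content)
      for (tr in truth) {
        if (tr$seq_id != sid || !(sp %in% tr$conserved_species)) next
        o <- tr$offsets[[sp]]
        copy <- mutate_bases(strsplit(tr$crm_seq, "")[[1L]],
                             spec$species_divergence)
        ix <- (tr$start + o + 1L):(tr$start + o + length(copy))
        ch[ix] <- copy
      }
      gg[[sid]] <- sequence_record(sid, paste(ch, collapse = ""))
    }
    species_genomes[[sp]] <- gg
  }

  # whole-sequence identity alignment blocks
  blocks <- alignment_blocks(do.call(rbind, lapply(FIXTURE_SPECIES,
    function(sp) data.frame(
      ref_seq = seq_ids, ref_start = 0L, ref_end = slen, species = sp,
      other_seq = seq_ids, other_start = 0L, other_end = slen,
      cigar = paste0(slen, "M"), stringsAsFactors = FALSE))))

  # human: one chromosome per reference sequence, genes mirrored, copies of
  # the human-conserved clusters at the mirrored coordinates
  human_genome <- list(); human_genes <- list()
  for (si in seq_len(nseq)) {
    sid <- seq_ids[si]; hid <- paste0("h", sid)
    ch <- random_dna(slen, spec$gc_content)
    for (tr in truth) {
      if (tr$seq_id != sid || !tr$human_conserved) next
      copy <- mutate_bases(strsplit(tr$crm_seq, "")[[1L]],
                           1 - spec$human_identity)
      ch[(tr$start + 1L):(tr$start + length(copy))] <- copy
    }
    human_genome[[hid]] <- sequence_record(hid, paste(ch, collapse = ""))
    gg <- genes[genes$seq_id == sid, , drop = FALSE]
    human_genes[[si]] <- data.frame(
      gene_id = paste0("H_", gg$gene_id), seq_id = hid, start = gg$start,
      end = gg$end, strand = gg$strand, stringsAsFactors = FALSE)
  }
  human_genes <- gene_models(do.call(rbind, human_genes))
  orthologs_human <- data.frame(ref_gene = genes$gene_id,
                                human_gene = paste0("H_", genes$gene_id),
                                stringsAsFactors = FALSE)

  # zebrafish orthologs: highest-identity pair is the true one; two genes
  # get a second, lower-identity candidate to exercise the resolver
  has_zf <- stats::runif(nrow(genes)) < spec$zf_coverage
  oz <- data.frame(source_gene = paste0("zf_", genes$gene_id[has_zf]),
                   ref_gene = genes$gene_id[has_zf],
                   pct_identity = round(stats::runif(sum(has_zf), 65, 95), 1),
                   stringsAsFactors = FALSE)
  if (nrow(oz) >= 2L) {
    dup <- oz[1:2, ]
    dup$ref_gene <- rev(oz$ref_gene[1:2])
    dup$pct_identity <- dup$pct_identity - 20
    oz <- rbind(oz, dup)
  }

  # tissue annotations on zebrafish genes (transferred downstream): genes
  # nearest to a human-conserved cluster draw neuronal terms at the
  # conserved frequency
  cons_genes <- character()
  for (tr in truth) {
    if (!tr$human_conserved) next
    gg <- genes[genes$seq_id == tr$seq_id, , drop = FALSE]
    mid <- (tr$start + tr$end) %/% 2L
    gmid <- (gg$start + gg$end) %/% 2L
    cons_genes <- c(cons_genes, gg$gene_id[which.min(abs(mid - gmid))])
  }
  ann <- list()
  for (i in seq_len(nrow(oz))) {
    g <- oz$ref_gene[i]
    pn <- if (g %in% cons_genes) spec$neuronal_freq_conserved else
      spec$neuronal_freq_background
    for (tm in spec$neuronal_terms) {
      if (stats::runif(1L) < pn) {
        ann[[length(ann) + 1L]] <- data.frame(
          gene_id = oz$source_gene[i], term = tm, stage = "st20",
          stringsAsFactors = FALSE)
      }
    }
    for (tm in spec$other_terms) {
      if (stats::runif(1L) < spec$neuronal_freq_background) {
        ann[[length(ann) + 1L]] <- data.frame(
          gene_id = oz$source_gene[i], term = tm, stage = "st20",
          stringsAsFactors = FALSE)
      }
    }
  }
  annotations <- if (length(ann)) do.call(rbind, ann) else
    data.frame(gene_id = character(), term = character(),
               stage = character(), stringsAsFactors = FALSE)
  term_parents <- data.frame(
    term = c(spec$neuronal_terms, "forebrain"),
    parent = c(rep("nervous_system", length(spec$neuronal_terms)), "brain"),
    stringsAsFactors = FALSE)

  # injection screen table for the planted regions: conserved clusters are
  # active (specific rate above the QC bar), the rest fail it
  inj <- list()
  for (i in seq_along(truth)) {
    n_alive <- sample(80:120, 1L)
    n_lens <- round(n_alive * stats::runif(1L, 0.4, 0.7))
    active <- truth[[i]]$human_conserved
    rate <- if (active) stats::runif(1L, 0.6, 0.8) else stats::runif(1L, 0, 0.3)
    inj[[i]] <- data.frame(region_id = truth[[i]]$planted_id,
                           n_alive = n_alive, n_lens = n_lens,
                           n_specific = round(n_lens * rate),
                           stringsAsFactors = FALSE)
  }
  injection <- if (length(inj)) do.call(rbind, inj) else
    data.frame(region_id = character(), n_alive = integer(),
               n_lens = integer(), n_specific = integer(),
               stringsAsFactors = FALSE)

  cds <- genes[, c("seq_id", "start", "end")]
  list(ref_genome = ref_genome, species_genomes = species_genomes,
       blocks = blocks, genes = genes, cds = cds,
       human_genome = human_genome, human_genes = human_genes,
       orthologs_human = orthologs_human, orthologs_zebrafish = oz,
       annotations = annotations, term_parents = term_parents,
       injection = injection,
       truth = list(planted = lapply(truth, function(t) t[names(t) != "crm_seq"]),
                    conserved_genes = cons_genes))
}

write_fixture <- function(bundle, dir, pwm_file) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(dir, x)
  files <- c(ref = f("ref.fa"), genes = f("genes.gff3"),
             blocks_tsv = f("blocks.tsv"), blocks_maf = f("blocks.maf"),
             pwms = f("pwms.pfm"), human = f("human.fa"),
             human_genes = f("human_genes.tsv"),
             orthologs_human = f("orthologs_human.tsv"),
             orthologs_zebrafish = f("orthologs_zebrafish.tsv"),
             annotations = f("annotations.tsv"),
             term_parents = f("term_parents.tsv"),
             injection = f("injection.tsv"),
             truth = f("ground_truth.json"))
  write_genome(bundle$ref_genome, files["ref"])
  for (sp in names(bundle$species_genomes)) {
    files[[sp]] <- f(paste0(sp, ".fa"))
    write_genome(bundle$species_genomes[[sp]], files[[sp]])
  }
  write_gff_genes(bundle$genes, files["genes"])
  write_alignment_blocks(bundle$blocks, files["blocks_tsv"])
  write_maf(bundle$blocks, bundle$ref_genome, bundle$species_genomes,
            files["blocks_maf"])
  file.copy(pwm_file, files["pwms"], overwrite = TRUE)
  write_genome(bundle$human_genome, files["human"])
  tsv <- function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  tsv(bundle$human_genes, files["human_genes"])
  tsv(bundle$orthologs_human, files["orthologs_human"])
  tsv(bundle$orthologs_zebrafish, files["orthologs_zebrafish"])
  tsv(bundle$annotations, files["annotations"])
  tsv(bundle$term_parents, files["term_parents"])
  tsv(bundle$injection, files["injection"])
  jsonlite::write_json(bundle$truth, files["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files
}

#' Simulate an annotated CRM set with controlled tissue enrichment
#'
#' A lightweight generator for the enrichment statistics: draws term
#' annotations for a conserved and a background CRM set at specified
#' per-term frequencies, without any sequence machinery. Used to verify
#' that planted relative enrichment is detected and parity is not.
#'
#' @param n_conserved,n_background set sizes (defaults 150/450, keeping the
#'   roughly 1:3 conserved-to-background ratio at desk scale).
#' @param term_freqs data.frame `term`, `freq_conserved`,
#'   `freq_background`.
#' @param stage stage label.
#' @param seed integer seed.
#' @return list: `crm_terms` (data.frame `crm_id`, `term`, `stage`),
#'   `conserved_ids`, `all_ids`, `term_freqs`.
#' @export
simulate_enrichment_dataset <- function(
    n_conserved = 150L, n_background = 450L,
    term_freqs = data.frame(
      term = c("brain", "spinal_cord", "pronephros", "somite",
               "cardiovascular_system"),
      freq_conserved = c(0.4, 0.4, 0.2, 0.2, 0.2),
      freq_background = c(0.2, 0.2, 0.2, 0.2, 0.2)),
    stage = "st20", seed = 1L) {
  conserved_ids <- sprintf("VC%04d", seq_len(n_conserved))
  background_ids <- sprintf("BG%04d", seq_len(n_background))
  all_ids <- c(conserved_ids, background_ids)
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(term_freqs))) {
      hit_c <- conserved_ids[stats::runif(n_conserved) <
                               term_freqs$freq_conserved[i]]
      hit_b <- background_ids[stats::runif(n_background) <
                                term_freqs$freq_background[i]]
      ids <- c(hit_c, hit_b)
      if (length(ids)) {
        rows[[length(rows) + 1L]] <- data.frame(
          crm_id = ids, term = term_freqs$term[i], stage = stage,
          stringsAsFactors = FALSE)
      }
    }
    crm_terms <- do.call(rbind, rows)
  })
  list(crm_terms = crm_terms, conserved_ids = conserved_ids,
       all_ids = all_ids, term_freqs = term_freqs)
}
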