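#' Specification of a synthetic whitening time-course dataset
#'
#' Collects every knob of the generator, with defaults stating the emulated
#' world: a 4-stage (D0 < D15 < D85 < Y2) x 3-replicate bulk RNA-seq design
#' over a compact two-chromosome genome of 200 protein-coding genes, 30
#' annotated lncRNAs and 120 planted novel transcripts spread over the four
#' positional categories plus exact copies of known models, NB counts with
#' dispersion 0.05, eight planted stage-pattern archetypes, planted
#' lncRNA-gene correlations, and a D0 ("classical BAT") top-10 expression
#' dominance share of 0.80.
#'
#' @param seed Integer seed; mandatory. Every generator output is a pure
#'   function of (spec, seed).
#' @param n_chromosomes,n_genes Genome layout.
#' @param exons_per_gene,exon_length,intron_length,intergenic_gap Integer
#'   ranges (length-2 vectors) for gene structure and spacing, in bp.
#' @param n_annotated_lnc Number of annotated (reference) lncRNA genes.
#' @param novel_counts Named integer vector of planted novel transcripts
#'   per category (`lincRNA`, `antisense`, `intronic`, `sense_overlapping`,
#'   `rejected_known`).
#' @param stages,replicates Design.
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2).
#' @param de_fraction Fraction of novel lncRNAs given a DE archetype.
#' @param n_pos_pairs,n_neg_pairs Planted positively/negatively correlated
#'   (lncRNA, cis-gene) pairs.
#' @param dominance,n_dominant,dominance_stage Share of total lncRNA
#'   expression carried by the `n_dominant` most-expressed lncRNAs at the
#'   classical-BAT stage.
#' @param coding_flip_fraction Fraction of novel lncRNAs whose coding calls
#'   are flipped to coding (exercises the consensus filter).
#' @param lnc_meanlog,lnc_sdlog,gene_meanlog,gene_sdlog Log-normal base
#'   count means.
#' @return Object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(seed,
                           n_chromosomes = 2,
                           n_genes = 200,
                           exons_per_gene = c(3, 8),
                           exon_length = c(200, 500),
                           intron_length = c(2500, 6000),
                           intergenic_gap = c(20000, 80000),
                           n_annotated_lnc = 30,
                           novel_counts = c(lincRNA = 50, antisense = 25,
                                            intronic = 25,
                                            sense_overlapping = 15,
                                            rejected_known = 5),
                           stages = c("D0", "D15", "D85", "Y2"),
                           replicates = 3,
                           dispersion = 0.05,
                           de_fraction = 0.4,
                           n_pos_pairs = 20,
                           n_neg_pairs = 10,
                           dominance = 0.8,
                           n_dominant = 10,
                           dominance_stage = "D0",
                           coding_flip_fraction = 0,
                           lnc_meanlog = 2.5, lnc_sdlog = 1,
                           gene_meanlog = 6, gene_sdlog = 1) {
  if (missing(seed)) stop("seed is mandatory")
  spec <- list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
               n_genes = n_genes, exons_per_gene = exons_per_gene,
               exon_length = exon_length, intron_length = intron_length,
               intergenic_gap = intergenic_gap,
               n_annotated_lnc = n_annotated_lnc,
               novel_counts = novel_counts, stages = stages,
               replicates = replicates, dispersion = dispersion,
               de_fraction = de_fraction, n_pos_pairs = n_pos_pairs,
               n_neg_pairs = n_neg_pairs, dominance = dominance,
               n_dominant = n_dominant, dominance_stage = dominance_stage,
               coding_flip_fraction = coding_flip_fraction,
               lnc_meanlog = lnc_meanlog, lnc_sdlog = lnc_sdlog,
               gene_meanlog = gene_meanlog, gene_sdlog = gene_sdlog)
  stopifnot(all(novel_counts >= 0), dispersion >= 0,
            dominance > 0, dominance < 1,
            dominance_stage %in% stages, replicates >= 2,
            de_fraction >= 0, de_fraction <= 1)
  cats <- c("lincRNA", "antisense", "intronic", "sense_overlapping",
            "rejected_known")
  if (!all(cats %in% names(novel_counts))) {
    stop("novel_counts must name all five categories")
  }
  structure(spec, class = "synthetic_spec")
}

#' The eight planted stage-pattern archetypes
#'
#' Stage-mean multipliers over (D0, D15, D85, Y2) emulating the recurring
#' whitening-course patterns: early-peak, biphasic, monotone decline or
#' rise, and the late Y2 burst.
#'
#' @return A named list of 8 numeric multiplier vectors of length 4.
#' @export
de_archetypes <- function() {
  list(A1 = c(1, 8, 1, 1), A2 = c(1, 6, 6, 1), A3 = c(8, 1, 1, 1),
       A4 = c(8, 8, 1, 1), A5 = c(1, 2, 8, 8), A6 = c(1, 4, 8, 4),
       A7 = c(1, 1, 1, 10), A8 = c(4, 1, 8, 1))
}

rint <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(seq.int(range[1L], range[2L]), n, replace = TRUE)
}

#' Generate a synthetic reference annotation
#'
#' Places non-overlapping multi-exon protein-coding genes with alternating
#' strands and the spec's intergenic gaps on each chromosome, and drops
#' annotated lncRNA genes (2-exon, biotype `lncRNA`) into a subset of the
#' gaps. Deterministic given the spec seed.
#'
#' @param spec A [synthetic_spec].
#' @return A `reference` [transcript_set] (protein-coding plus annotated
#'   lncRNA transcripts).
#' @export
generate_annotation <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  chroms <- paste0("chr", seq_len(spec$n_chromosomes))
  per_chrom <- rep(floor(spec$n_genes / spec$n_chromosomes),
                   spec$n_chromosomes)
  if (spec$n_genes > 0) {
    per_chrom[1L] <- per_chrom[1L] + spec$n_genes - sum(per_chrom)
  }
  rows <- list()
  gap_rows <- list()
  gidx <- 0L
  for (ci in seq_along(chroms)) {
    pos <- 0L  # last occupied coordinate
    for (g in seq_len(per_chrom[ci])) {
      gidx <- gidx + 1L
      gap <- rint(1L, spec$intergenic_gap)
      gstart <- pos + gap + 1L
      n_ex <- rint(1L, spec$exons_per_gene)
      elens <- rint(n_ex, spec$exon_length)
      ilens <- if (n_ex > 1L) rint(n_ex - 1L, spec$intron_length) else
        integer()
      starts <- gstart + cumsum(c(0L, elens[-n_ex] + ilens))
      ends <- starts + elens - 1L
      strand <- if (gidx %% 2L == 0L) "-" else "+"
      rows[[gidx]] <- data.frame(
        chrom = chroms[ci], start = starts, end = ends, strand = strand,
        transcript_id = sprintf("REFT%04d", gidx),
        gene_id = sprintf("REFG%04d", gidx),
        biotype = "protein_coding", stringsAsFactors = FALSE)
      gap_rows[[length(gap_rows) + 1L]] <- data.frame(
        chrom = chroms[ci], start = pos + 1L, end = gstart - 1L,
        stringsAsFactors = FALSE)
      pos <- ends[n_ex]
    }
  }
  ex <- do.call(rbind, rows)
  gaps <- do.call(rbind, gap_rows)
  # annotated lncRNAs at the right end of randomly chosen wide gaps
  if (spec$n_annotated_lnc > 0) {
    wide <- which(gaps$end - gaps$start + 1L >= 20000L & gaps$start > 1L)
    if (length(wide) < spec$n_annotated_lnc) {
      stop("infeasible spec: not enough intergenic room for annotated ",
           "lncRNAs")
    }
    pick <- sort(sample(wide, spec$n_annotated_lnc))
    ann <- do.call(rbind, lapply(seq_along(pick), function(k) {
      ge <- gaps$end[pick[k]]
      e2e <- ge - 2000L
      e2s <- e2e - 299L
      e1e <- e2s - 401L
      e1s <- e1e - 299L
      data.frame(chrom = gaps$chrom[pick[k]],
                 start = c(e1s, e2s), end = c(e1e, e2e),
                 strand = if (k %% 2L == 0L) "-" else "+",
                 transcript_id = sprintf("ALNC%03d", k),
                 gene_id = sprintf("ALNCG%03d", k),
                 biotype = "lncRNA", stringsAsFactors = FALSE)
    }))
    ex <- rbind(ex, ann)
  }
  if (nrow(ex) == 0L) {
    return(transcript_set(GenomicRanges::GRanges(
      transcript_id = character(), gene_id = character()),
      source = "reference"))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom, ranges = IRanges::IRanges(ex$start, ex$end),
    strand = ex$strand, transcript_id = ex$transcript_id,
    gene_id = ex$gene_id)
  bt <- stats::setNames(ex$biotype, ex$transcript_id)
  bt <- bt[!duplicated(names(bt))]
  transcript_set(gr, source = "reference", biotype = bt)
}

#' Plant novel transcripts of known positional category
#'
#' Constructs novel transcripts that satisfy, by construction, the defining
#' predicate of each requested category under the classifier's documented
#' precedence: lincRNAs in intergenic gaps (within 100 kb of a flanking
#' gene), antisense models overlapping a gene exon on the opposite strand,
#' intronic models contained in a single intron, sense-overlapping models
#' sharing exonic sequence on the same strand with a novel intron chain,
#' and exact intron-chain copies of reference transcripts
#' (`rejected_known`). All planted transcripts are >= 200 nt with >= 2
#' exons.
#'
#' @param reference The [transcript_set] from [generate_annotation].
#' @param spec The [synthetic_spec].
#' @return List with `novel` (a [transcript_set]) and `truth` (a
#'   `data.frame`: `transcript_id`, `category`, `primary_target` gene id,
#'   `target_distance` bp).
#' @export
plant_novel_transcripts <- function(reference, spec) {
  stopifnot(inherits(reference, "transcript_set"),
            inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 2L)
  idx <- build_annotation_index(reference)
  pc <- idx$genes[S4Vectors::mcols(idx$genes)$biotype == "protein_coding"]
  nc <- spec$novel_counts
  rows <- list()
  truth <- list()
  nid <- 0L
  add <- function(chrom, starts, ends, strand, category, target, dist) {
    nid <<- nid + 1L
    tid <- sprintf("NV%04d", nid)
    rows[[nid]] <<- data.frame(
      chrom = chrom, start = starts, end = ends, strand = strand,
      transcript_id = tid, gene_id = sprintf("NVG%04d", nid),
      stringsAsFactors = FALSE)
    truth[[nid]] <<- data.frame(
      transcript_id = tid, category = category, primary_target = target,
      target_distance = dist, stringsAsFactors = FALSE)
  }

  # intergenic gaps between consecutive reference gene bodies per chromosome
  gaps <- list()
  for (ch in unique(as.character(GenomicRanges::seqnames(idx$genes)))) {
    gg <- idx$genes[as.character(GenomicRanges::seqnames(idx$genes)) == ch]
    gg <- gg[order(GenomicRanges::start(gg))]
    if (length(gg) < 2L) next
    gs <- GenomicRanges::start(gg)
    ge <- GenomicRanges::end(gg)
    for (i in seq_len(length(gg) - 1L)) {
      w <- gs[i + 1L] - ge[i] - 1L
      if (w >= 6000L) {
        # right neighbour is the recorded flank target when protein-coding,
        # else the left one
        tgt_r <- S4Vectors::mcols(gg)$biotype[i + 1L] == "protein_coding"
        tgt_l <- S4Vectors::mcols(gg)$biotype[i] == "protein_coding"
        if (!tgt_r && !tgt_l) next
        gaps[[length(gaps) + 1L]] <- data.frame(
          chrom = ch, start = ge[i] + 1L, end = gs[i + 1L] - 1L,
          left_gene = S4Vectors::mcols(gg)$gene_id[i],
          right_gene = S4Vectors::mcols(gg)$gene_id[i + 1L],
          left_pc = tgt_l, right_pc = tgt_r, stringsAsFactors = FALSE)
      }
    }
  }
  gaps <- do.call(rbind, gaps)
  if (nc[["lincRNA"]] > 0) {
    if (is.null(gaps) || nrow(gaps) < nc[["lincRNA"]]) {
      stop("infeasible spec for category lincRNA: not enough gaps")
    }
    pick <- sort(sample(nrow(gaps), nc[["lincRNA"]]))
    for (i in pick) {
      s1 <- gaps$start[i] + 2000L
      # 2 exons of 300 nt separated by a 400 nt intron
      add(gaps$chrom[i], c(s1, s1 + 700L), c(s1 + 299L, s1 + 999L),
          sample(c("+", "-"), 1L), "lincRNA",
          if (gaps$left_pc[i]) gaps$left_gene[i] else gaps$right_gene[i],
          if (gaps$left_pc[i]) 2000L else gaps$end[i] - (s1 + 999L))
    }
  }

  # genic categories draw distinct host genes; all generated genes have
  # first introns >= 2500 bp by construction
  pc_tx <- reference$tx[reference$tx$biotype == "protein_coding" &
                          reference$tx$n_exons >= 2L, ]
  need <- nc[["antisense"]] + nc[["intronic"]] + nc[["sense_overlapping"]] +
    nc[["rejected_known"]]
  if (nrow(pc_tx) < need) {
    stop("infeasible spec for genic categories: too few multi-exon genes")
  }
  hosts <- sample(nrow(pc_tx), need)
  ref_exons <- reference$exons
  host_k <- 0L
  next_host <- function() {
    host_k <<- host_k + 1L
    pc_tx[hosts[host_k], ]
  }
  host_exons <- function(ht) {
    e <- ref_exons[as.character(
      S4Vectors::mcols(ref_exons)$transcript_id) == ht$transcript_id]
    e[order(GenomicRanges::start(e))]
  }
  flip <- function(s) if (s == "+") "-" else "+"

  for (k in seq_len(nc[["antisense"]])) {
    ht <- next_host()
    e <- host_exons(ht)
    e1s <- GenomicRanges::start(e)[1L] + 20L
    e1e <- e1s + 180L
    e2s <- GenomicRanges::end(e)[1L] + 500L
    e2e <- e2s + 180L
    add(ht$chrom, c(e1s, e2s), c(e1e, e2e), flip(ht$strand), "antisense",
        ht$gene_id, 0L)
  }
  for (k in seq_len(nc[["intronic"]])) {
    ht <- next_host()
    e <- host_exons(ht)
    i1s <- GenomicRanges::end(e)[1L] + 1L
    i1e <- GenomicRanges::start(e)[2L] - 1L
    s1 <- i1s + 100L
    e2e <- i1e - 100L
    e2s <- e2e - 149L
    add(ht$chrom, c(s1, e2s), c(s1 + 149L, e2e),
        sample(c(ht$strand, flip(ht$strand)), 1L), "intronic",
        ht$gene_id, 0L)
  }
  for (k in seq_len(nc[["sense_overlapping"]])) {
    ht <- next_host()
    e <- host_exons(ht)
    e1s <- GenomicRanges::start(e)[1L] - 150L
    e1e <- GenomicRanges::start(e)[1L] + 100L
    e2s <- GenomicRanges::end(e)[1L] + 700L
    e2e <- e2s + 200L
    add(ht$chrom, c(e1s, e2s), c(e1e, e2e), ht$strand,
        "sense_overlapping", ht$gene_id, 0L)
  }
  for (k in seq_len(nc[["rejected_known"]])) {
    ht <- next_host()
    e <- host_exons(ht)
    add(ht$chrom, GenomicRanges::start(e), GenomicRanges::end(e),
        ht$strand, "rejected_known", ht$gene_id, 0L)
  }

  if (nid == 0L) {
    novel <- transcript_set(GenomicRanges::GRanges(
      transcript_id = character(), gene_id = character()))
    return(list(novel = novel, truth = data.frame(
      transcript_id = character(), category = character(),
      primary_target = character(), target_distance = integer(),
      stringsAsFactors = FALSE)))
  }
  ex <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom, ranges = IRanges::IRanges(ex$start, ex$end),
    strand = ex$strand, transcript_id = ex$transcript_id,
    gene_id = ex$gene_id)
  list(novel = transcript_set(gr, source = "novel"),
       truth = do.call(rbind, truth))
}

#' Simulate NB counts and TPM for a planted feature table
#'
#' Every feature (novel transcript, annotated lncRNA, protein-coding gene)
#' gets per-stage expected counts: a log-normal base mean times its
#' archetype's stage multipliers. Planted correlation pairs additionally
#' share (positive) or invert (negative) the stage profile and a mild
#' per-sample latent multiplier (15% log-normal co-fluctuation) so the
#' lncRNA and its cis gene co-vary across all samples without drowning the
#' planted differential expression in replicate noise. The
#' classical-BAT stage means of the `n_dominant` strongest lncRNAs are then
#' rescaled so those lncRNAs carry exactly the configured dominance share of
#' length-normalized lncRNA output. Replicate counts are drawn
#' NB(mean * library factor, alpha); TPM is computed from the counts by
#' length normalization and per-sample scaling to 1e6.
#'
#' @param spec A [synthetic_spec].
#' @param features `data.frame` with columns `feature_id`, `ftype` (one of
#'   `lnc_novel`, `lnc_annotated`, `pc_gene`, `novel_rejected`), `length`,
#'   `category`, `primary_target`.
#' @return List with `counts` and `tpm` (`expr_matrix`es), `metadata`, and
#'   ledger components `profiles` (feature_id, archetype, per-stage expected
#'   mean), `true_lfc` (feature, comparison, true log2 ratio of stage
#'   means), `pairs` (lncrna_id, gene_id, sign) and `dominant_ids`.
#' @export
simulate_counts <- function(spec, features) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 3L)
  stages <- spec$stages
  nrep <- spec$replicates
  samples <- paste0(rep(stages, each = nrep), "_r", seq_len(nrep))
  stage_of <- rep(stages, each = nrep)
  meta <- data.frame(sample_id = samples, stage = stage_of,
                     replicate = rep(seq_len(nrep), length(stages)),
                     stringsAsFactors = FALSE)
  nfeat <- nrow(features)
  arche <- de_archetypes()

  is_lnc <- features$ftype %in% c("lnc_novel", "lnc_annotated")
  is_novel_lnc <- features$ftype == "lnc_novel"

  base <- numeric(nfeat)
  base[is_lnc | features$ftype == "novel_rejected"] <-
    stats::rlnorm(sum(is_lnc | features$ftype == "novel_rejected"),
                  spec$lnc_meanlog, spec$lnc_sdlog)
  base[features$ftype == "pc_gene"] <-
    stats::rlnorm(sum(features$ftype == "pc_gene"),
                  spec$gene_meanlog, spec$gene_sdlog)

  # archetype assignment: a fraction of novel lncRNAs, cycling the 8 patterns
  profile_name <- rep("flat", nfeat)
  de_pool <- which(is_novel_lnc)
  n_de <- round(spec$de_fraction * length(de_pool))
  de_idx <- if (n_de > 0) sample(de_pool, n_de) else integer()
  profile_name[de_idx] <- rep(names(arche), length.out = length(de_idx))
  # archetyped features get a base-mean floor so the planted patterns are
  # detectable at the default sequencing depth (the generator's contract is
  # that planted DE is recoverable end-to-end)
  base[de_idx] <- pmax(base[de_idx], 30)

  prof_mult <- function(nm) {
    if (nm == "flat") rep(1, length(stages)) else arche[[nm]]
  }
  stage_mu <- t(vapply(profile_name, prof_mult, numeric(length(stages))))
  stage_mu <- stage_mu * base
  dimnames(stage_mu) <- list(features$feature_id, stages)

  # planted correlation pairs among DE lncRNAs that have a protein-coding
  # primary target present in the feature table
  pairable <- de_idx[!is.na(features$primary_target[de_idx]) &
                       features$primary_target[de_idx] %in%
                         features$feature_id]
  # one planted pair per target gene, else later pairs would overwrite the
  # shared latent of earlier ones
  pairable <- pairable[!duplicated(features$primary_target[pairable])]
  n_pairs <- spec$n_pos_pairs + spec$n_neg_pairs
  if (length(pairable) < n_pairs) {
    n_pairs <- length(pairable)
  }
  pair_idx <- if (n_pairs > 0) sample(pairable, n_pairs) else integer()
  n_pos <- min(spec$n_pos_pairs, n_pairs)
  pairs <- data.frame(
    lncrna_id = features$feature_id[pair_idx],
    gene_id = features$primary_target[pair_idx],
    sign = rep(c("pos", "neg"), c(n_pos, n_pairs - n_pos)),
    stringsAsFactors = FALSE)

  # per-(feature, sample) expected counts
  mu <- stage_mu[, match(stage_of, stages), drop = FALSE]
  colnames(mu) <- samples

  # correlated pairs: gene adopts the lncRNA's stage profile (or its
  # inversion) and both share a per-sample log-normal latent factor
  if (nrow(pairs) > 0) {
    for (i in seq_len(nrow(pairs))) {
      l <- pairs$lncrna_id[i]
      g <- pairs$gene_id[i]
      u <- stats::rlnorm(length(samples), 0, 0.15)
      prof <- stage_mu[l, ] / base[match(l, features$feature_id)]
      gbase <- base[match(g, features$feature_id)]
      if (pairs$sign[i] == "pos") {
        gprof <- prof
        mu[g, ] <- gbase * gprof[match(stage_of, stages)] * u
        mu[l, ] <- mu[l, ] * u
      } else {
        gprof <- max(prof) + min(prof) - prof
        mu[g, ] <- gbase * gprof[match(stage_of, stages)] / u
        mu[l, ] <- mu[l, ] * u
      }
      stage_mu[g, ] <- gbase * gprof
    }
  }

  # dominance: rescale the classical-BAT stage of the strongest lncRNAs so
  # they carry `dominance` of length-normalized lncRNA output at that stage
  dom_stage <- spec$dominance_stage
  retained_lnc <- which(is_lnc)
  dominant_ids <- character()
  if (spec$n_dominant > 0 && length(retained_lnc) > spec$n_dominant) {
    rate <- stage_mu[retained_lnc, dom_stage] /
      features$length[retained_lnc]
    cand <- setdiff(retained_lnc, pair_idx)
    cand <- cand[order(stage_mu[cand, dom_stage] / features$length[cand],
                       decreasing = TRUE)]
    dom <- cand[seq_len(spec$n_dominant)]
    s_dom <- sum(stage_mu[dom, dom_stage] / features$length[dom])
    s_rest <- sum(rate) - s_dom
    scale <- (spec$dominance / (1 - spec$dominance)) * s_rest / s_dom
    in_dom_stage <- stage_of == dom_stage
    mu[dom, in_dom_stage] <- mu[dom, in_dom_stage] * scale
    stage_mu[dom, dom_stage] <- stage_mu[dom, dom_stage] * scale
    dominant_ids <- features$feature_id[dom]
  }

  lib <- stats::rlnorm(length(samples), 0, 0.15)
  mu_eff <- sweep(mu, 2L, lib, "*")
  counts <- matrix(0, nfeat, length(samples),
                   dimnames = list(features$feature_id, samples))
  if (spec$dispersion > 0) {
    counts[] <- stats::rnbinom(length(mu_eff), mu = mu_eff,
                               size = 1 / spec$dispersion)
  } else {
    counts[] <- stats::rpois(length(mu_eff), lambda = mu_eff)
  }

  rate <- counts / features$length
  tpm <- sweep(rate, 2L, colSums(rate), "/") * 1e6

  comps <- character()
  tl <- list()
  for (i in seq_along(stages)[-length(stages)]) {
    for (j in (i + 1L):length(stages)) {
      nm <- paste0(stages[j], "_vs_", stages[i])
      tl[[nm]] <- data.frame(
        feature_id = features$feature_id,
        comparison = nm,
        true_lfc = log2(stage_mu[, stages[j]] / stage_mu[, stages[i]]),
        stringsAsFactors = FALSE)
    }
  }
  true_lfc <- do.call(rbind, tl)
  rownames(true_lfc) <- NULL

  profiles <- data.frame(feature_id = features$feature_id,
                         archetype = profile_name,
                         stage_mu, check.names = FALSE,
                         stringsAsFactors = FALSE)
  list(
    counts = expression_matrix(counts, "counts", meta,
                               stage_order = stages),
    tpm = expression_matrix(tpm, "TPM", meta, stage_order = stages),
    metadata = meta,
    profiles = profiles,
    true_lfc = true_lfc,
    pairs = pairs,
    dominant_ids = dominant_ids
  )
}

#' Generate a complete synthetic dataset bundle
#'
#' One call producing everything the pipeline consumes — reference and novel
#' transcript sets, coding-potential call tables (all planted lncRNAs called
#' non-coding by all four predictors, minus an optional flipped fraction), NB
#' count and TPM matrices, sample metadata, a synthetic GMT pathway file
#' whose designated pathway collects the cis-targets of the late-burst (A7)
#' archetype — plus the ground-truth ledger every test surface compares
#' against.
#'
#' @param spec A [synthetic_spec].
#' @return List of class `synthetic_bundle` with elements `reference`,
#'   `novel`, `calls`, `counts`, `tpm`, `metadata`, `gmt`, `ledger`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  reference <- generate_annotation(spec)
  planted <- plant_novel_transcripts(reference, spec)
  novel <- planted$novel
  truth <- planted$truth

  ftype <- c(lincRNA = "lnc_novel", antisense = "lnc_novel",
             intronic = "lnc_novel", sense_overlapping = "lnc_novel",
             rejected_known = "novel_rejected")
  ref_tx <- reference$tx
  pc <- ref_tx[ref_tx$biotype == "protein_coding", ]
  ann <- ref_tx[ref_tx$biotype == "lncRNA", ]
  features <- rbind(
    data.frame(feature_id = truth$transcript_id,
               ftype = unname(ftype[truth$category]),
               length = novel$tx$length[match(truth$transcript_id,
                                              novel$tx$transcript_id)],
               category = truth$category,
               primary_target = truth$primary_target,
               stringsAsFactors = FALSE),
    data.frame(feature_id = ann$transcript_id,
               ftype = rep("lnc_annotated", nrow(ann)),
               length = ann$length,
               category = rep("lincRNA", nrow(ann)),
               primary_target = rep(NA_character_, nrow(ann)),
               stringsAsFactors = FALSE),
    data.frame(feature_id = pc$gene_id,
               ftype = rep("pc_gene", nrow(pc)),
               length = pc$length,
               category = rep(NA_character_, nrow(pc)),
               primary_target = rep(NA_character_, nrow(pc)),
               stringsAsFactors = FALSE)
  )
  sim <- simulate_counts(spec, features)

  set.seed(spec$seed + 4L)
  lnc_ids <- features$feature_id[features$ftype %in%
                                   c("lnc_novel", "novel_rejected")]
  calls_df <- data.frame(transcript_id = lnc_ids,
                         CPC2 = rep("noncoding", length(lnc_ids)),
                         CPAT = rep("noncoding", length(lnc_ids)),
                         CNCI = rep("noncoding", length(lnc_ids)),
                         Pfam = rep("noncoding", length(lnc_ids)),
                         stringsAsFactors = FALSE)
  flipped <- character()
  n_flip <- round(spec$coding_flip_fraction *
                    sum(features$ftype == "lnc_novel"))
  if (n_flip > 0) {
    flipped <- sample(features$feature_id[features$ftype == "lnc_novel"],
                      n_flip)
    calls_df$CNCI[calls_df$transcript_id %in% flipped] <- "coding"
  }
  calls <- coding_calls(calls_df)

  # synthetic pathways over protein-coding genes; the designated pathway
  # collects the cis-targets of A7 (late-burst) lncRNAs
  genes <- pc$gene_id
  a7_lnc <- sim$profiles$feature_id[sim$profiles$archetype == "A7"]
  a7_targets <- unique(stats::na.omit(
    truth$primary_target[truth$transcript_id %in% a7_lnc]))
  gmt <- list()
  pw_sizes <- 20L
  other_genes <- setdiff(genes, a7_targets)
  for (k in seq_len(9L)) {
    gmt[[sprintf("PW%02d", k)]] <- sample(other_genes, pw_sizes)
  }
  gmt[["PW_PLANTED"]] <- unique(c(
    a7_targets, sample(other_genes, max(0L, pw_sizes - length(a7_targets)))))

  ledger <- list(
    transcripts = truth,
    annotated_lnc = ann$transcript_id,
    profiles = sim$profiles,
    true_lfc = sim$true_lfc,
    pairs = sim$pairs,
    dominance = list(stage = spec$dominance_stage,
                     share = spec$dominance,
                     dominant_ids = sim$dominant_ids),
    flipped_calls = flipped,
    enriched_pathway = "PW_PLANTED"
  )
  structure(list(reference = reference, novel = novel, calls = calls,
                 counts = sim$counts, tpm = sim$tpm,
                 metadata = sim$metadata, gmt = gmt, ledger = ledger,
                 spec = spec),
            class = "synthetic_bundle")
}

#' Write a synthetic bundle to files in the standard formats
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gtf(bundle$reference, file.path(dir, "reference.gtf"))
  write_gtf(bundle$novel, file.path(dir, "novel.gtf"))
  write_expression_matrix(bundle$counts, file.path(dir, "counts.tsv"),
                          file.path(dir, "metadata.tsv"))
  write_expression_matrix(bundle$tpm, file.path(dir, "tpm.tsv"))
  for (p in c("CPC2", "CPAT", "CNCI", "Pfam")) {
    utils::write.table(
      data.frame(transcript_id = bundle$calls$transcript_id,
                 call = bundle$calls[[p]]),
      file.path(dir, paste0(tolower(p), "_calls.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_gmt(bundle$gmt, file.path(dir, "pathways.gmt"))
  utils::write.table(bundle$ledger$transcripts,
                     file.path(dir, "truth_transcripts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
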