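# a compact spec keeps generator tests fast; contracts are size-independent
small_spec <- function(seed, ...) {
  synthetic_spec(seed = seed, n_genes = 60, n_annotated_lnc = 6,
                 novel_counts = c(lincRNA = 12, antisense = 6, intronic = 6,
                                  sense_overlapping = 4, rejected_known = 2),
                 n_pos_pairs = 6, n_neg_pairs = 3, ...)
}

test_that("generation is a pure function of the spec seed", {
  b1 <- generate_dataset(small_spec(5))
  b2 <- generate_dataset(small_spec(5))
  p1 <- tempfile(); p2 <- tempfile()
  write_gtf(b1$reference, p1); write_gtf(b2$reference, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(b1$counts$values, b2$counts$values)
  expect_identical(b1$tpm$values, b2$tpm$values)
  expect_identical(b1$ledger$pairs, b2$ledger$pairs)
  # a different seed actually changes the data
  b3 <- generate_dataset(small_spec(6))
  expect_false(identical(b1$counts$values, b3$counts$values))
})

test_that("generated annotation is valid and gene bodies are disjoint", {
  b <- generate_dataset(small_spec(8))
  idx <- build_annotation_index(b$reference)
  g <- idx$genes
  # pairwise overlap scan
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
                   start = GenomicRanges::start(g),
                   end = GenomicRanges::end(g))
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, ]
    d <- d[order(d$start), ]
    expect_true(all(d$start[-1] > d$end[-nrow(d)]))
  }
  # every intron lies inside its gene body
  introns <- idx$introns
  h <- GenomicRanges::findOverlaps(introns, g, type = "within",
                                   ignore.strand = TRUE)
  expect_equal(length(unique(S4Vectors::queryHits(h))), length(introns))
})

test_that("planting honors the classifier's own predicates", {
  b <- generate_dataset(small_spec(13))
  got <- classify_position(b$novel, build_annotation_index(b$reference))
  truth <- b$ledger$transcripts
  expect_equal(unname(got[truth$transcript_id]), truth$category)
  # all planted transcripts satisfy the structural filter
  expect_true(all(b$novel$tx$length >= 200))
  expect_true(all(b$novel$tx$n_exons >= 2))
  # ledger covers every generated feature exactly once
  feats <- rownames(b$counts$values)
  expect_true(all(truth$transcript_id %in% feats))
  expect_false(anyDuplicated(feats) > 0)
  prof <- b$ledger$profiles
  expect_setequal(prof$feature_id, feats)
})

test_that("requesting zero transcripts yields empty layers", {
  spec <- synthetic_spec(seed = 3, n_genes = 20, n_annotated_lnc = 0,
                         novel_counts = c(lincRNA = 0, antisense = 0,
                                          intronic = 0,
                                          sense_overlapping = 0,
                                          rejected_known = 0),
                         n_pos_pairs = 0, n_neg_pairs = 0,
                         de_fraction = 0)
  b <- generate_dataset(spec)
  expect_equal(nrow(b$novel$tx), 0L)
  expect_equal(nrow(b$ledger$transcripts), 0L)
  expect_equal(nrow(b$counts$values), 20L)  # protein-coding genes only
})

test_that("counts follow the planted means and TPM sums to 1e6", {
  spec <- small_spec(17, dispersion = 0)
  b <- generate_dataset(spec)
  expect_equal(unname(colSums(b$tpm$values)), rep(1e6, 12),
               tolerance = 1e-9)
  # alpha = 0: Poisson counts; stage-mean of high-mean features tracks the
  # planted expectation within a few relative percent
  prof <- b$ledger$profiles
  sm <- stage_means(b$counts)
  hi <- prof$feature_id[prof$D0 > 200]
  if (length(hi) >= 3) {
    rel <- abs(sm[hi, "D0"] / prof$D0[match(hi, prof$feature_id)] - 1)
    # library factors add ~15% spread per sample, averaged over 3 reps
    expect_lt(median(rel), 0.25)
  }
})

test_that("flipping coding calls removes exactly those lncRNAs", {
  b0 <- generate_dataset(small_spec(19))
  b1 <- generate_dataset(small_spec(19, coding_flip_fraction = 0.1))
  l0 <- identify_lncrnas(b0$novel, b0$reference, b0$tpm, b0$calls)
  l1 <- identify_lncrnas(b1$novel, b1$reference, b1$tpm, b1$calls)
  flipped <- b1$ledger$flipped_calls
  expect_gt(length(flipped), 0)
  lost <- setdiff(l0$transcript_id, l1$transcript_id)
  expect_setequal(lost, intersect(flipped, l0$transcript_id))
})

test_that("the planted pathway is the most enriched for its cluster", {
  b <- generate_dataset(synthetic_spec(seed = 23))
  prof <- b$ledger$profiles
  a7 <- prof$feature_id[prof$archetype == "A7"]
  truth <- b$ledger$transcripts
  q <- unique(na.omit(truth$primary_target[truth$transcript_id %in% a7]))
  universe <- unique(unlist(b$gmt))
  res <- hypergeom_enrich(intersect(q, universe), b$gmt, universe)
  expect_equal(res$pathway_id[1], "PW_PLANTED")
  expect_true(res$significant[1])
})
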