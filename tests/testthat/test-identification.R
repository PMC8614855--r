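ref_small <- function() {
  # one protein-coding gene on chr1 (+): exons 1001-1400, 5001-5400,
  # intron 1401-5000
  make_ts(list(
    pc1 = list(chrom = "chr1", strand = "+", gene = "G1",
               exons = list(c(1001, 1400), c(5001, 5400)))),
    source = "reference", biotype = "protein_coding")
}

test_that("structural filter applies the length, exon and TPM rules", {
  ts <- make_ts(list(
    short = list(chrom = "c1", strand = "+",
                 exons = list(c(1, 75), c(200, 274))),       # 150 nt
    mono = list(chrom = "c1", strand = "+", exons = list(c(1, 500))),
    low = list(chrom = "c1", strand = "+",
               exons = list(c(1, 250), c(400, 649))),        # 500 nt
    edge = list(chrom = "c1", strand = "+",
                exons = list(c(1, 100), c(300, 399)))))      # 200 nt
  tpm <- matrix(5, 4, 12, dimnames = list(
    c("short", "mono", "low", "edge"), sprintf("s%02d", 1:12)))
  tpm["low", ] <- 0.05
  tpm["edge", ] <- 0
  tpm["edge", 1] <- 0.2
  kept <- filter_structural(ts, make_expr(tpm))
  expect_equal(kept$tx$transcript_id, "edge")
  summ <- attr(kept, "filter_summary")
  expect_equal(summ$n[summ$rule == "retained"], 1)
})

test_that("positional categories follow the documented cascade", {
  idx <- build_annotation_index(ref_small())
  nov <- make_ts(list(
    # entirely inside the intron
    intr = list(chrom = "chr1", strand = "+",
                exons = list(c(2000, 2200), c(3000, 3200))),
    # exon overlaps gene exon, opposite strand
    anti = list(chrom = "chr1", strand = "-",
                exons = list(c(1200, 1500), c(2000, 2200))),
    # same strand, partial exon overlap, novel intron chain
    so = list(chrom = "chr1", strand = "+",
              exons = list(c(900, 1100), c(2000, 2200))),
    # exact structure copy
    known = list(chrom = "chr1", strand = "+",
                 exons = list(c(1001, 1400), c(5001, 5400))),
    # far away on the same chromosome
    linc = list(chrom = "chr1", strand = "+",
                exons = list(c(50000, 50300), c(51000, 51300))),
    # overlapping the gene body but neither exon nor single intron
    resid = list(chrom = "chr1", strand = "-",
                 exons = list(c(1450, 1600), c(5500, 5700)))))
  got <- classify_position(nov, idx)
  expect_equal(got[["intr"]], "intronic")
  expect_equal(got[["anti"]], "antisense")
  expect_equal(got[["so"]], "sense_overlapping")
  expect_equal(got[["known"]], "rejected_known")
  expect_equal(got[["linc"]], "lincRNA")
  expect_equal(got[["resid"]], "rejected_known")

  # a chromosome with no annotated genes is intergenic by definition
  lonely <- make_ts(list(x = list(chrom = "chrZ", strand = "+",
                                  exons = list(c(1, 300), c(500, 800)))))
  expect_warning(got2 <- classify_position(lonely, idx), "absent")
  expect_equal(unname(got2), "lincRNA")
  expect_error(classify_position(lonely, idx, strict = TRUE), "absent")
})

test_that("classification is invariant under renaming and translation", {
  set.seed(31)
  ref <- random_annotation_df(40)
  nov <- random_transcripts_df(60)
  idx <- build_annotation_index(
    df_to_ts(ref, "reference", "protein_coding"))
  base <- suppressWarnings(classify_position(df_to_ts(nov), idx))

  shift <- 7777L
  ref2 <- ref; ref2$start <- ref2$start + shift; ref2$end <- ref2$end + shift
  ref2$chrom <- paste0("X", ref2$chrom)
  nov2 <- nov; nov2$start <- nov2$start + shift; nov2$end <- nov2$end + shift
  nov2$chrom <- paste0("X", nov2$chrom)
  idx2 <- build_annotation_index(
    df_to_ts(ref2, "reference", "protein_coding"))
  moved <- suppressWarnings(classify_position(df_to_ts(nov2), idx2))
  expect_equal(unname(moved[names(base)]), unname(base))
})

test_that("non-coding consensus is an intersection and is monotone", {
  df <- data.frame(
    transcript_id = c("t1", "t2", "t3"),
    CPC2 = "noncoding", CPAT = "noncoding",
    CNCI = c("noncoding", "coding", "noncoding"),
    Pfam = c("noncoding", "noncoding", "missing"),
    stringsAsFactors = FALSE)
  calls <- coding_calls(df)
  expect_true(consensus_noncoding(calls, "t1")[["t1"]])
  expect_false(consensus_noncoding(calls, "t2")[["t2"]])
  expect_warning(r3 <- consensus_noncoding(calls, "t3"), "missing")
  expect_false(r3[["t3"]])
  expect_error(consensus_noncoding(calls, "absent"), "absent")

  # monotonicity: flipping any call to coding never turns FALSE into TRUE
  set.seed(5)
  preds <- c("CPC2", "CPAT", "CNCI", "Pfam")
  for (k in 1:20) {
    row <- data.frame(transcript_id = "t",
                      CPC2 = sample(c("coding", "noncoding"), 1),
                      CPAT = sample(c("coding", "noncoding"), 1),
                      CNCI = sample(c("coding", "noncoding"), 1),
                      Pfam = sample(c("coding", "noncoding"), 1),
                      stringsAsFactors = FALSE)
    before <- consensus_noncoding(coding_calls(row), "t")[["t"]]
    worse <- row
    worse[[sample(preds, 1)]] <- "coding"
    after <- consensus_noncoding(coding_calls(worse), "t")[["t"]]
    expect_true(before || !after)
  }
})

test_that("longest_orf matches the exhaustive start/stop scan", {
  expect_equal(longest_orf("ATGAAATAG"), 2L)
  expect_equal(longest_orf("CCCCCCCCC"), 0L)
  expect_error(longest_orf("ATGXXX"), "ACGTN")
  set.seed(12)
  for (k in 1:50) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(30:200, 1),
                      replace = TRUE), collapse = "")
    expect_equal(longest_orf(s), oracle_orf(s))
  }
})

test_that("identify_lncrnas composes filters and recovers planted counts", {
  spec <- synthetic_spec(seed = 77, novel_counts = c(
    lincRNA = 20, antisense = 10, intronic = 15, sense_overlapping = 5,
    rejected_known = 3), n_genes = 80, n_annotated_lnc = 8)
  b <- generate_dataset(spec)
  lnc <- identify_lncrnas(b$novel, b$reference, b$tpm, b$calls)
  counts <- attr(lnc, "category_counts")
  expect_equal(as.integer(counts[c("lincRNA", "antisense", "intronic",
                                   "sense_overlapping")]),
               c(20 + 8, 10, 15, 5))
  # partition identity: categories sum to the total
  expect_equal(sum(counts), nrow(lnc))
  # rejected copies are not in the output
  rej <- b$ledger$transcripts$transcript_id[
    b$ledger$transcripts$category == "rejected_known"]
  expect_false(any(rej %in% lnc$transcript_id))

  # empty novel set leaves only annotated lncRNAs
  empty <- subset_transcripts(b$novel, character())
  only_ann <- identify_lncrnas(empty, b$reference, b$tpm, b$calls)
  expect_true(all(only_ann$origin == "annotated"))
  expect_equal(nrow(only_ann), 8)
})
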