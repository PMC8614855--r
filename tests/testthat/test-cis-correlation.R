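# helper: lncrna_set rows built directly
fake_lncset <- function(df) {
  structure(df, class = c("lncrna_set", "data.frame"))
}

test_that("cis targets honor host vs 100-kb flank semantics", {
  # genes at known distances from a lincRNA spanning 200000-201000
  ref <- make_ts(list(
    near = list(chrom = "c1", strand = "+", gene = "Gnear",
                exons = list(c(251001, 252000))),   # gap 50000
    far = list(chrom = "c1", strand = "+", gene = "Gfar",
               exons = list(c(351002, 352000))),    # gap 150001
    edge = list(chrom = "c1", strand = "-", gene = "Gedge",
                exons = list(c(50000, 99999)))      # gap exactly 100000
  ), source = "reference", biotype = "protein_coding")
  idx <- build_annotation_index(ref)
  lnc <- fake_lncset(data.frame(
    transcript_id = c("L1", "I1"), gene_id = c("gl1", "gi1"),
    chrom = "c1", strand = "+",
    start = c(200000L, 251100L), end = c(201000L, 251300L),
    length = c(1000L, 200L), n_exons = 2L,
    category = c("lincRNA", "intronic"), origin = "novel",
    max_tpm = 1, stringsAsFactors = FALSE))
  tg <- assign_cis_targets(lnc, idx, window = 1e5)
  l1 <- tg[tg$lncrna_id == "L1", ]
  expect_setequal(l1$gene_id, c("Gnear", "Gedge"))
  expect_equal(l1$distance[l1$gene_id == "Gnear"], 50000L)
  expect_equal(l1$distance[l1$gene_id == "Gedge"], 100000L)
  expect_true(all(l1$relationship == "flank"))
  # the intronic record is hosted by the gene containing it
  i1 <- tg[tg$lncrna_id == "I1", ]
  expect_equal(i1$gene_id, "Gnear")
  expect_equal(i1$relationship, "host")
  expect_equal(i1$distance, 0L)
})

test_that("pearson_with_p matches the product-moment formula", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_with_p(x, x)$r, 1)
  expect_equal(pearson_with_p(x, -x)$r, -1)
  got <- pearson_with_p(x, c(1, 2, 3, 5))
  expect_equal(got$r, 0.9827076, tolerance = 1e-6)
  want <- oracle_pearson(x, c(1, 2, 3, 5))
  expect_equal(got$r, want$r)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_warning(z <- pearson_with_p(rep(1, 4), x), "zero variance")
  expect_true(is.na(z$r))
  expect_error(pearson_with_p(1:2, 1:2), "at least 3")

  # antisymmetry of r, invariance of p, under negation; permutation
  # invariance under a shared reordering
  set.seed(9)
  for (k in 1:10) {
    a <- rnorm(12); b <- rnorm(12)
    r1 <- pearson_with_p(a, b)
    r2 <- pearson_with_p(a, -b)
    expect_equal(r1$r, -r2$r)
    expect_equal(r1$p, r2$p)
    o <- sample(12)
    r3 <- pearson_with_p(a[o], b[o])
    expect_equal(r1$r, r3$r)
  }
})

test_that("correlation screen recovers planted signal at t-test power", {
  # Monte-Carlo oracle for the power of the Pearson t-test at n = 12,
  # true r = 0.9, computed with the longhand formula
  set.seed(101)
  n <- 12
  rho <- 0.9
  mc <- replicate(1000, {
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    oracle_pearson(x, y)$p < 0.05
  })
  power <- mean(mc)

  # screen 300 planted pairs through the package path
  n_pairs <- 300
  vals <- matrix(0, 2 * n_pairs, n)
  rownames(vals) <- c(sprintf("l%03d", 1:n_pairs),
                      sprintf("g%03d", 1:n_pairs))
  for (i in 1:n_pairs) {
    x <- rnorm(n)
    vals[i, ] <- x + 10
    vals[n_pairs + i, ] <- rho * x + sqrt(1 - rho^2) * rnorm(n) + 10
  }
  tpm <- make_expr(vals)
  targets <- data.frame(
    lncrna_id = sprintf("l%03d", 1:n_pairs),
    gene_id = sprintf("g%03d", 1:n_pairs),
    relationship = "flank", distance = 1000L,
    category = "lincRNA", stringsAsFactors = FALSE)
  recs <- correlation_screen(targets, tpm)
  rate <- mean(recs$klass == "pos")
  se <- sqrt(power * (1 - power) / n_pairs) +
    sqrt(power * (1 - power) / 1000)
  expect_lt(abs(rate - power), 4 * se + 0.02)

  # pos/neg/ns partition is exhaustive and exclusive
  expect_true(all(recs$klass %in% c("pos", "neg", "ns")))
})

test_that("per-category summary counts lncRNAs once and pools correctly", {
  recs <- data.frame(
    lncrna_id = c("a", "a", "b", "c", "d"),
    gene_id = paste0("g", 1:5),
    category = c("antisense", "antisense", "antisense", "lincRNA",
                 "intronic"),
    r = c(0.9, 0.8, -0.7, 0.6, 0.1),
    p = c(0.01, 0.02, 0.03, 0.04, 0.9),
    klass = c("pos", "pos", "neg", "pos", "ns"),
    stringsAsFactors = FALSE)
  s <- summarize_correlation(recs, n_total = 10)
  per <- s$per_category
  expect_equal(per$pos[per$category == "antisense"], 1) # "a" counted once
  expect_equal(per$neg[per$category == "antisense"], 1)
  expect_equal(per$pos[per$category == "lincRNA"], 1)
  expect_equal(per$ns[per$category == "intronic"], 1)
  expect_equal(s$fraction_significant, 3 / 10)

  all_ns <- recs; all_ns$klass <- "ns"
  expect_equal(summarize_correlation(all_ns, 10)$fraction_significant, 0)
})
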