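test_that("median-of-ratios size factors match hand computation", {
  m <- matrix(c(2, 8, 2, 2), 2, 2, byrow = TRUE,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(0.75, 1.5))

  ident <- matrix(c(5, 5, 9, 9), 2, 2, byrow = TRUE,
                  dimnames = list(c("f1", "f2"), c("s1", "s2")))
  expect_equal(unname(size_factors(ident)), c(1, 1))

  # doubling one sample's library doubles its factor
  set.seed(22)
  big <- matrix(rpois(200 * 4, 50), 200, 4,
                dimnames = list(sprintf("f%03d", 1:200), paste0("s", 1:4)))
  sf1 <- size_factors(big)
  big2 <- big; big2[, 2] <- big2[, 2] * 2
  sf2 <- size_factors(big2)
  # equivariance holds up to the overall renormalization through the
  # geometric means, so compare the doubled sample against a reference one
  expect_equal((sf2[["s2"]] / sf1[["s2"]]) / (sf2[["s1"]] / sf1[["s1"]]),
               2, tolerance = 1e-9)

  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2, 2,
                                   dimnames = list(c("a", "b"),
                                                   c("x", "y")))),
               "nonzero")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(23)
  m <- matrix(rnbinom(500 * 6, mu = 80, size = 10), 500, 6,
              dimnames = list(sprintf("f%03d", 1:500), paste0("s", 1:6)))
  m[, 3] <- m[, 3] * 3L
  ours <- size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-5)
})

test_that("moment dispersion is zero for constant data, recovers alpha", {
  const <- matrix(10, 20, 6,
                  dimnames = list(sprintf("f%02d", 1:20), paste0("s", 1:6)))
  a0 <- estimate_dispersion(const, list(1:3, 4:6))
  expect_true(all(a0 == 0))
  expect_error(estimate_dispersion(const, list(1:1, 2:6)), "2 replicates")

  # Poisson data: mean alpha-hat near 0 relative to squared-mean scale
  set.seed(24)
  pois <- matrix(rpois(1000 * 20, 50), 1000, 20)
  ap <- estimate_dispersion(pois, list(1:10, 11:20))
  expect_lt(mean(ap), 0.01)

  # NB alpha = 0.2 at n = 50 per group: mean within 20%
  nb <- matrix(rnbinom(1000 * 100, mu = 100, size = 5), 1000, 100)
  an <- estimate_dispersion(nb, list(1:50, 51:100))
  expect_lt(abs(mean(an) - 0.2) / 0.2, 0.2)
})

test_that("nb_wald is symmetric, null-calibrated and recovers planted lfc", {
  set.seed(25)
  m <- matrix(rnbinom(2000 * 6, mu = 100, size = 10), 2000, 6,
              dimnames = list(sprintf("f%04d", 1:2000), paste0("s", 1:6)))
  a <- paste0("s", 1:3); b <- paste0("s", 4:6)
  res <- nb_wald(m, a, b)
  # identical groups in expectation: type-I error near nominal
  rate <- mean(res$p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  # swapping labels negates lfc and keeps p
  swap <- nb_wald(m, b, a)
  expect_equal(swap$log2fc, -res$log2fc)
  expect_equal(swap$p, res$p, tolerance = 1e-9)

  # identical groups literally: lfc 0, p 1
  dup <- cbind(m[, 1:3], m[, 1:3])
  colnames(dup) <- paste0("s", 1:6)
  res0 <- nb_wald(dup, a, b, sf = setNames(rep(1, 6), paste0("s", 1:6)))
  expect_true(all(abs(res0$log2fc) < 1e-12))
  expect_true(all(res0$p > 1 - 1e-9))

  # planted 4-fold changes at moderate depth: median estimate within 0.25
  set.seed(26)
  mu <- rep(100, 1000)
  planted <- matrix(c(rnbinom(1000 * 3, mu = mu, size = 20),
                      rnbinom(1000 * 3, mu = 4 * mu, size = 20)),
                    1000, 6, dimnames = list(sprintf("p%04d", 1:1000),
                                             paste0("s", 1:6)))
  resp <- nb_wald(planted, a, b,
                  sf = setNames(rep(1, 6), paste0("s", 1:6)))
  expect_lt(abs(median(resp$log2fc) - 2), 0.25)
})

test_that("BH adjustment equals the step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(27)
  for (k in 1:25) {
    p <- runif(sample(1:4, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
  }
})

test_that("DEL calling uses strict thresholds and unions correctly", {
  res <- data.frame(
    feature_id = c("a", "b", "c"),
    log2fc = c(1.6, 1.5, -2.0),
    fdr = c(0.005, 0.001, 0.5))
  got <- call_dels(res)
  expect_equal(got$status, c("up", "ns", "ns"))
  expect_equal(call_dels(data.frame(feature_id = "d", log2fc = -1.9,
                                    fdr = 0.009))$status, "down")

  de <- list(
    c1 = data.frame(feature_id = c("a", "b", "x"),
                    status = c("up", "down", "ns")),
    c2 = data.frame(feature_id = c("b", "c", "d"),
                    status = c("up", "up", "up")))
  u <- del_union(de, categories = c(a = "lincRNA", b = "lincRNA",
                                    c = "antisense", d = "intronic"))
  expect_setequal(u$ids, c("a", "b", "c", "d"))
  expect_equal(sum(u$breakdown), length(u$ids))
  expect_equal(u$per_comparison$up, c(1, 3))
  # random overlapping sets match base set union
  set.seed(28)
  for (k in 1:10) {
    s1 <- sample(letters, 8); s2 <- sample(letters, 8)
    de2 <- list(one = data.frame(feature_id = s1, status = "up"),
                two = data.frame(feature_id = s2, status = "down"))
    expect_setequal(del_union(de2)$ids, union(s1, s2))
  }
})
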