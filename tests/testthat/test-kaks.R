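test_that("site counts match the enumeration oracle for every sense codon", {
  expect_equal(count_sites("GGT"), c(S = 1, N = 2))
  expect_equal(count_sites("TTT"), c(S = 1 / 3, N = 8 / 3))
  expect_error(count_sites("TAA"), "domain error")
  expect_error(count_sites("ATN"), "skip signal")
  for (cd in sense_codons_t5()) {
    sn <- count_sites(cd)
    expect_equal(unname(sum(sn)), 3, info = cd)
    expect_equal(sn, oracle_count_sites(cd), info = cd)
  }
})

test_that("pathway-averaged differences match a brute-force enumerator", {
  expect_equal(count_differences("ATG", "ATG"), c(sd = 0, nd = 0))
  expect_equal(count_differences("TTT", "TTC"), c(sd = 1, nd = 0))
  expect_equal(count_differences("TTT", "GTT"), c(sd = 0, nd = 1))
  set.seed(19)
  sense <- sense_codons_t5()
  for (i in 1:400) {
    a <- sample(sense, 1); b <- sample(sense, 1)
    got <- count_differences(a, b)
    ora <- oracle_count_differences(a, b)
    if (is.null(ora)) {
      expect_true(isTRUE(attr(got, "stop_pathways_used")))
    } else {
      expect_equal(unname(got), unname(ora), info = paste(a, b))
    }
    ndiff <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(unname(sum(got)), ndiff, info = paste(a, b))
  }
})

test_that("pairwise Ka/Ks is symmetric, zero on identity, and separable", {
  set.seed(23)
  sense <- sense_codons_t5()
  a <- paste(c("ATG", sample(sense, 60, TRUE)), collapse = "")
  same <- pairwise_kaks(a, a)
  expect_equal(same$Ka, 0)
  expect_equal(same$Ks, 0)
  expect_true(same$undefined)
  # synonymous-only divergence: third positions of 4-fold codons
  b4 <- paste(rep("GGT", 50), collapse = "")
  b4m <- paste(rep(c("GGA", "GGT"), 25), collapse = "")
  r <- pairwise_kaks(b4, b4m)
  expect_equal(r$Ka, 0)
  expect_gt(r$Ks, 0)
  # nonsynonymous-only divergence
  c1 <- paste(rep("TTT", 50), collapse = "")
  c2 <- paste(rep(c("GTT", "TTT"), 25), collapse = "")
  r2 <- pairwise_kaks(c1, c2)
  expect_equal(r2$Sd, 0)
  expect_gt(r2$Ka, 0)
  for (i in 1:10) {
    cx <- sample(sense, 40, TRUE)
    cy <- cx
    flip <- sample(40, 10)
    cy[flip] <- sample(sense, 10, TRUE)
    x <- paste(cx, collapse = ""); y <- paste(cy, collapse = "")
    fx <- pairwise_kaks(x, y); fy <- pairwise_kaks(y, x)
    expect_equal(fx$Ka, fy$Ka)
    expect_equal(fx$Ks, fy$Ks)
    expect_equal(fx$Sd, fy$Sd)
  }
  expect_error(pairwise_kaks("ATGAAA", "ATG"), "unequal")
})

test_that("pairwise totals agree with per-codon oracle sums", {
  set.seed(29)
  sense <- sense_codons_t5()
  for (rep in 1:20) {
    ca <- sample(sense, 30, TRUE)
    cb <- ca
    flip <- sample(30, 8)
    cb[flip] <- sample(sense, 8, TRUE)
    r <- pairwise_kaks(paste(ca, collapse = ""), paste(cb, collapse = ""))
    ora <- rowSums(vapply(seq_along(ca), function(i) {
      d <- oracle_count_differences(ca[i], cb[i])
      if (is.null(d)) unname(count_differences(ca[i], cb[i])) else unname(d)
    }, c(0, 0)))
    expect_equal(c(r$Sd, r$Nd), unname(ora))
  }
})

test_that("gaps and ambiguity codons are deleted pairwise", {
  a <- "ATGGGTNNNAAA"
  b <- "ATGGGA---AAA"
  r <- pairwise_kaks(a, b)
  expect_identical(r$n_codons, 3L)   # the N/gap codon dropped
  expect_equal(r$Sd, 1)              # GGT -> GGA, synonymous
})

test_that("gene aggregation needs two taxa and is zero on identical input", {
  seqs <- rep("ATGGGTAAACCCTAA", 4)
  s <- gene_mean_kaks(as.list(seqs), gene = "g")
  expect_equal(s$mean_ka, 0)
  expect_equal(s$mean_ks, 0)
  expect_identical(s$n_pairs, 0L)    # all ratios undefined at Ks = 0
  expect_error(gene_mean_kaks(list("ATGAAA")), "insufficient-data")
  # the alternative aggregation is exposed behind a flag
  set.seed(5)
  sense <- sense_codons_t5()
  base_codons <- sample(sense, 80, TRUE)
  seqs2 <- lapply(1:4, function(i) {
    cx <- base_codons
    flip <- sample(80, 12)
    cx[flip] <- sample(sense, 12, TRUE)
    paste(cx, collapse = "")
  })
  s1 <- gene_mean_kaks(seqs2, method = "mean_ratio")
  s2 <- gene_mean_kaks(seqs2, method = "ratio_of_means")
  expect_false(identical(s1$mean_ratio, s2$mean_ratio))
  expect_identical(s1$mean_ka, s2$mean_ka)
})

test_that("saturated proportions raise a saturation error", {
  # force pS near 1: 4-fold third positions all different
  a <- paste(rep("GGA", 60), collapse = "")
  b <- paste(rep("GGC", 60), collapse = "")
  expect_error(pairwise_kaks(a, b), "saturation")
})
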