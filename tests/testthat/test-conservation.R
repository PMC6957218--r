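test_that("a fully conserved column scores the maximum index", {
  set.seed(5)
  m <- makeMSA(n_seqs = 20, L = 50, rlm_columns = integer(), p_in = 0.3,
               p_out = 0.3, seed = 5)
  m[, 10] <- "W"
  p <- conservationIndex(m)
  expect_equal(which.max(p@values), 10L)
  expect_equal(max(p@values, na.rm = TRUE), p@values[10])
})

test_that("a 50/50 two-state column has raw index -ln 2", {
  m <- rbind(rep("A", 10), rep("A", 10))
  m[1, 4] <- "V"   # column 4: frequencies (0.5, 0.5)
  p <- conservationIndex(m, normalize = FALSE)
  expect_equal(p@values[4], -log(2), tolerance = 1e-12)
  expect_equal(p@values[1], 0)
})

test_that("degenerate alignments raise the documented errors", {
  allgap <- matrix("-", 3, 5)
  expect_error(conservationIndex(allgap), "all-gap")
  const <- matrix("A", 4, 6)    # every column identical composition
  expect_error(conservationIndex(const), "constant profile")
  expect_error(conservationIndex(matrix("A", 1, 5)), "at least 2")
})

test_that("columns with more than half gaps are unscored", {
  m <- matrix(sample(c("A", "V", "L"), 40, TRUE), 4, 10)
  m[1:3, 7] <- "-"
  p <- conservationIndex(m)
  expect_true(is.na(p@values[7]))
  v <- p@values[!is.na(p@values)]
  expect_lt(abs(mean(v)), 1e-9)
  expect_lt(abs(stats::sd(v) - 1), 1e-9)
})

test_that("binning is the identity when L equals B, for all L up to 50", {
  for (L in 1:50) {
    v <- stats::rnorm(L)
    expect_equal(rlmscan:::.bin_values(v, L), v)
  }
})

test_that("partition and stretch follow the bin-centre floor rule", {
  a <- 1.5; b <- -2.5; cc <- 0.25; d <- 4
  expect_equal(rlmscan:::.bin_values(c(a, b), 4L), c(a, a, b, b))
  expect_equal(rlmscan:::.bin_values(c(a, b, cc, d), 2L), c(b, d))
  # general agreement with the independent centre-evaluation oracle
  set.seed(8)
  for (k in 1:25) {
    L <- sample(1:40, 1); B <- sample(1:40, 1)
    v <- stats::rnorm(L)
    expect_equal(rlmscan:::.bin_values(v, B), bin_oracle(v, B))
  }
})

test_that("profiles bin onto motif elements through the reference mapping", {
  scan <- scan_of("ideal")
  m <- scan$matches[[1]]
  n <- nrow(rlmscan:::.residue_table(scan$structure))
  msa <- makeMSA(n_seqs = 25, L = n, rlm_columns = unlist(m@elements),
                 p_in = 0.95, p_out = 0.3, seed = 3)
  p <- conservationIndex(msa)
  bins <- c(I = 5, II = 9, III = 5, IV = 7, V = 4)
  bp <- binProfile(p, m, bins)
  expect_equal(bp@binCounts, vapply(bins, as.integer, integer(1)))
  for (e in names(bins))
    expect_length(bp@means[[e]], bins[[e]])
  expect_error(binProfile(p, m, unname(bins)), "named")
})

test_that("aggregation averages bins with the SE of the mean", {
  mk <- function(vals) new("BinnedProfile", binCounts = c(I = length(vals)),
                           means = list(I = vals),
                           se = list(I = rep(0, length(vals))), n = 1L)
  agg <- aggregateBins(list(mk(c(1, 1)), mk(c(3, 3))))
  expect_equal(agg@means$I, c(2, 2))
  expect_equal(agg@se$I, c(1, 1))   # sd sqrt(2), n = 2 -> SE 1
  single <- aggregateBins(list(mk(c(5, 7))))
  expect_equal(single@se$I, c(0, 0))
  same <- aggregateBins(list(mk(c(2, 4)), mk(c(2, 4)), mk(c(2, 4))))
  expect_equal(same@se$I, c(0, 0))
  # order invariance
  a <- aggregateBins(list(mk(c(1, 5)), mk(c(2, 2)), mk(c(6, -1))))
  b <- aggregateBins(list(mk(c(6, -1)), mk(c(1, 5)), mk(c(2, 2))))
  expect_equal(a@means, b@means)
  expect_equal(a@se, b@se)
  expect_error(aggregateBins(list(mk(c(1, 2)), mk(c(1, 2, 3)))),
               "mismatched")
})

test_that("the KS comparison behaves at its degenerate limits", {
  x <- stats::rnorm(50)
  same <- insideOutsideTest(inside = x, outside = x)
  expect_equal(same$D, 0)
  expect_equal(same$p.value, 1)
  sep <- insideOutsideTest(inside = 0:9, outside = 10:19)
  expect_equal(sep$D, 1)
  expect_error(insideOutsideTest(inside = numeric(), outside = x), "empty")
})

test_that("KS statistics agree with an independent implementation", {
  set.seed(21)
  for (k in 1:10) {
    x <- stats::rnorm(60, 0.3); y <- stats::rnorm(80)
    got <- insideOutsideTest(inside = x, outside = y)
    ref <- ks_asymptotic(x, y)
    expect_equal(got$D, ref$D, tolerance = 1e-12)
    # p evaluated by a different summation of the Kolmogorov series
    expect_equal(got$p.value, ref$p, tolerance = 1e-4)
  }
})

test_that("planted conservation contrast is detected on a motif", {
  scan <- scan_of("ideal")
  m <- scan$matches[[1]]
  n <- nrow(rlmscan:::.residue_table(scan$structure))
  msa <- makeMSA(n_seqs = 40, L = max(100, n),
                 rlm_columns = unlist(m@elements), p_in = 0.9, p_out = 0.3,
                 seed = 17)
  p <- conservationIndex(msa)
  res <- insideOutsideTest(p, m)
  expect_gt(res$mean_in, res$mean_out)
  expect_lt(res$p.value, 0.05)
})

test_that("default bin counts are rounded mean element lengths", {
  m <- scan_of("ideal")$matches[[1]]
  bc <- defaultBinCounts(list(m, m))
  for (e in c("I", "II", "III", "IV", "V"))
    expect_equal(bc[[e]], round(length(m@elements[[e]])))
})
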