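rand_counts <- function(g = 50, n = 6, seed = 1, lambda = 80) {
  set.seed(seed)
  m <- matrix(rpois(g * n, lambda), g, n,
              dimnames = list(paste0("m", seq_len(g)), paste0("s", seq_len(n))))
  m
}

test_that("CPM identities hold", {
  m <- matrix(c(5, 5), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(cpm(m)[, 1]), c(5e5, 5e5))
  m2 <- rand_counts(seed = 2)
  expect_equal(unname(colSums(cpm(m2))), rep(1e6, ncol(m2)))
  # identical columns give identical CPM columns
  m3 <- matrix(rep(c(3, 7, 10), 3), 3, 3,
               dimnames = list(letters[1:3], paste0("s", 1:3)))
  expect_equal(cpm(m3)[, 1], cpm(m3)[, 2])
  m4 <- m2; m4[, 1] <- 0
  expect_error(cpm(m4), "library size")
})

test_that("low-expressor filter requires the CPM threshold in >= 2 samples", {
  sheet <- toy_sheet(3, treatments = "CTL")[1:3, ]
  sheet$compartment <- "MB"; sheet$subject <- paste0("S", 1:3)
  base <- matrix(1e6 / 3, 3, 3)  # fill so each library is ~1e6
  mk <- function(v) {
    m <- rbind(test_mir = v, filler1 = 4e5, filler2 = 6e5 - v / 3)
    colnames(m) <- sheet$sample_id
    mir_counts(round(m), sheet)
  }
  # CPM >= 0.5 in one sample only: dropped
  r1 <- filter_low_expressors(mk(c(1, 0, 0)))
  expect_true("test_mir" %in% r1$dropped)
  # in two samples: kept
  r2 <- filter_low_expressors(mk(c(1, 1, 0)))
  expect_true("test_mir" %in% rownames(r2$kept$counts))
  # degenerate threshold 0 keeps everything
  r3 <- filter_low_expressors(mk(c(0, 0, 0)), cpm_threshold = 0)
  expect_equal(r3$dropped, character(0))
  # monotone in the threshold
  x <- mir_counts(matrix(rpois(30, 10), 10, 3,
                         dimnames = list(paste0("m", 1:10), sheet$sample_id)),
                  sheet)
  k1 <- rownames(filter_low_expressors(x, 0.5)$kept$counts)
  k2 <- rownames(filter_low_expressors(x, 5e5)$kept$counts)
  expect_true(all(k2 %in% k1))
  expect_error(filter_low_expressors(x, min_samples = 4), "exceeds")
})

test_that("TMM factors: proportional samples give unit factors", {
  m <- rand_counts(30, 2, seed = 3)
  m[, 2] <- m[, 1] * 2
  f <- tmm_factors(m)
  expect_equal(unname(f$factors), c(1, 1))
})

test_that("TMM agrees with the direct trimmed-weighted-mean oracle", {
  set.seed(11)
  for (rep in 1:20) {
    m <- matrix(rpois(50 * 6, rlnorm(50, 4, 1)), 50, 6)
    dimnames(m) <- list(paste0("g", 1:50), paste0("s", 1:6))
    m[sample(length(m), 20)] <- 0
    got <- tmm_factors(m)
    expect_equal(unname(got$factors), unname(oracle_tmm(m)),
                 tolerance = 1e-10)
    expect_equal(exp(mean(log(got$factors))), 1, tolerance = 1e-9)
  }
  # a single 50x inflated gene must not distort the factors much
  m <- rand_counts(20, 2, seed = 4, lambda = 200)
  m[1, 2] <- m[1, 2] * 50
  expect_equal(unname(tmm_factors(m)$factors), unname(oracle_tmm(m)),
               tolerance = 1e-10)
})

test_that("TMM cross-checks against the reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(2)
  for (i in 1:5) {
    m <- matrix(rpois(200 * 6, rlnorm(200, 4, 1)), 200, 6)
    dimnames(m) <- list(paste0("g", 1:200), paste0("s", 1:6))
    m[sample(length(m), 80)] <- 0
    m <- m[rowSums(m) > 0, ]
    mine <- tmm_factors(m)$factors
    ref <- edgeR::calcNormFactors(edgeR::DGEList(m),
                                  method = "TMM")$samples$norm.factors
    expect_equal(unname(mine), ref, tolerance = 5e-3)
  }
})

test_that("TMM is invariant to whole-sample scaling", {
  m <- rand_counts(40, 4, seed = 6, lambda = 150)
  f1 <- tmm_factors(m, reference = 1)
  m2 <- m; m2[, 3] <- m[, 3] * 4
  f2 <- tmm_factors(m2, reference = 1)
  # weights depend weakly on absolute counts, so invariance is approximate
  expect_equal(f1$factors, f2$factors, tolerance = 5e-3)
})

test_that("median-of-ratios matches its closed form and is equivariant", {
  m <- rand_counts(25, 2, seed = 7, lambda = 100) + 1
  m[, 2] <- m[, 1] * 2
  f <- median_of_ratios_factors(m)
  expect_equal(unname(f$factors), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # identical samples -> unit factors
  m3 <- cbind(s1 = m[, 1], s2 = m[, 1], s3 = m[, 1])
  expect_equal(unname(median_of_ratios_factors(m3)$factors), rep(1, 3))
  # permutation equivariance
  m4 <- rand_counts(30, 3, seed = 8) + 1
  f4 <- median_of_ratios_factors(m4)$factors
  perm <- c(3, 1, 2)
  f5 <- median_of_ratios_factors(m4[, perm])$factors
  expect_equal(unname(f5), unname(f4[perm]))
  # scaling one sample by c scales its factor by c (up to the geometric
  # mean rescale shared by all samples)
  m5 <- m4; m5[, 2] <- m5[, 2] * 3
  r <- median_of_ratios_factors(m5)$factors / f4
  expect_equal(unname(r), c(1, 3, 1) / 3^(1 / 3), tolerance = 1e-12)
  expect_error(median_of_ratios_factors(diag(3)), "positive")
})

test_that("TPM normalization matches the per-column oracle", {
  counts <- c(10, 10, 10)
  lengths <- c(g1 = 20, g2 = 22, g3 = 24)
  m <- matrix(counts, 3, 1, dimnames = list(names(lengths), "s1"))
  expect_equal(unname(tpm_normalize(m, lengths)[, 1]),
               unname(oracle_tpm_col(counts, lengths)))
  expect_equal(sum(tpm_normalize(m, lengths)), 1e6)
  # equal lengths: TPM == CPM
  leq <- setNames(rep(22, 3), names(lengths))
  expect_equal(tpm_normalize(m, leq), cpm(m))
  # single gene
  m1 <- matrix(7, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(unname(tpm_normalize(m1, c(g1 = 22))[, 1]), 1e6)
  expect_error(tpm_normalize(m, c(g1 = 0, g2 = 22, g3 = 24)), "length")
})
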