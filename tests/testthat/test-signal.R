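track_from_bins <- function(values, bin = 20L, chrom = "c") {
  cov <- list(S4Vectors::Rle(as.numeric(values), rep(bin, length(values))))
  names(cov) <- chrom
  signal_track(cov)
}

test_that("BPM normalization scales bins to a fixed total", {
  tr <- track_from_bins(c(1, 1, 2))
  bpm <- bpm_normalize(tr, bin_size = 20L)
  vals <- as.numeric(bpm$cov$c)[c(1, 21, 41)]    # one value per 20-bp bin
  expect_equal(vals, c(250000, 250000, 500000))
  expect_equal(sum(as.numeric(bpm$cov$c)) / 20, 1e6, tolerance = 1e-6)
  expect_equal(bpm$normalization, "BPM")
  expect_error(bpm_normalize(track_from_bins(c(0, 0))), "empty coverage")
  expect_error(bpm_normalize(bpm), "already normalized")
})

test_that("percentile extraction interpolates order statistics", {
  # per-base values 1..100 -> 95.05 at q = 95 under linear interpolation
  cov <- list(c = S4Vectors::Rle(as.numeric(1:100), rep(1, 100)))
  tr <- signal_track(cov)
  locus <- bed_gr("c", 0, 100)
  expect_equal(percentile_signal(tr, locus, q = 95)$values, 95.05)
  expect_equal(percentile_signal(tr, locus, q = 100)$values, 100)  # max
  expect_equal(percentile_signal(tr, locus, q = 0)$values, 1)      # min
  # constant signal returns the constant; uncovered locus returns 0
  tr2 <- track_from_bins(c(0, 7, 0, 0, 0))
  expect_equal(percentile_signal(tr2, bed_gr("c", 20, 40))$values, 7)
  expect_equal(percentile_signal(tr2, bed_gr("c", 60, 90))$values, 0)
  expect_error(percentile_signal(tr2, GRanges("c", IRanges(5, 4))),
               "zero-length")
})

test_that("input normalization produces standardized log-ratios", {
  s <- signal_vector("chip", c(100, 400, 900, 1600), "raw95")
  i <- signal_vector("inp", c(100, 100, 100, 100), "raw95")
  z <- input_normalize_log_z(s, i, eps = 1)
  expect_equal(mean(z$values), 0, tolerance = 1e-12)
  expect_equal(sd(z$values), 1, tolerance = 1e-12)
  expect_equal(z$state, "logZ")
  # scale invariance: doubling both signal and input leaves z unchanged
  s2 <- signal_vector("chip", 2 * s$values, "raw95")
  i2 <- signal_vector("inp", 2 * i$values, "raw95")
  z2 <- input_normalize_log_z(s2, i2, eps = 1)
  expect_equal(z2$values, z$values, tolerance = 1e-3)
  # signal identical to input -> zero variance
  expect_error(input_normalize_log_z(i, i), "zero variance")
})

test_that("pearson_matrix matches a brute-force covariance computation", {
  expect_equal(cor(c(1, 2, 3), c(1, 2, 4)), 3 / sqrt(2 * 14 / 3),
               tolerance = 1e-4)
  mkv <- function(id, x) signal_vector(id, x, "logZ")
  m <- pearson_matrix(list(mkv("a", c(1, 2, 3)), mkv("b", c(3, 2, 1)),
                           mkv("c", c(1, 2, 4))))
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_equal(m["a", "b"], -1)
  expect_equal(m["a", "c"], 0.9820, tolerance = 1e-4)
  expect_true(isSymmetric(m))

  set.seed(9)
  xs <- lapply(1:4, function(i) rnorm(50))
  m2 <- pearson_matrix(lapply(seq_along(xs), function(i)
    mkv(paste0("s", i), xs[[i]])))
  brute <- function(x, y) {
    mean((x - mean(x)) * (y - mean(y))) /
      sqrt(mean((x - mean(x))^2) * mean((y - mean(y))^2))
  }
  for (i in 1:4) for (j in 1:4)
    expect_equal(m2[i, j], brute(xs[[i]], xs[[j]]), tolerance = 1e-12)
  expect_error(pearson_matrix(list(mkv("a", 1:3),
                                   signal_vector("b", 1:3, "raw95"))),
               "logZ")
})

test_that("complete-linkage clustering is deterministic and orders merges", {
  corr <- matrix(c(1, 1, 0.1,
                   1, 1, 0.1,
                   0.1, 0.1, 1), 3, 3,
                 dimnames = list(c("s1", "s2", "s3"), c("s1", "s2", "s3")))
  cl <- hcluster_samples(corr)
  expect_equal(cl$tree$height[1], 0)                # identical pair first
  expect_true(all(cl$tree$merge[1, ] %in% c(-1, -2)))
  cl2 <- hcluster_samples(corr)
  expect_identical(cl$leaf_order, cl2$leaf_order)   # stable leaf order
  f <- tempfile(fileext = ".nwk")
  write_newick(cl, f)
  expect_true(grepl("s3", readLines(f)))
  bad <- corr; bad[1, 2] <- 0.5
  expect_error(hcluster_samples(bad), "non-symmetric")
})

test_that("coupled readers correlate more strongly than independent ones", {
  r_coupled <- numeric(0); r_indep <- numeric(0)
  for (s in 1:8) {
    cfg <- synthetic_config(seed = 100 + s,
                            chrom_lengths = c(chrA = 4e5),
                            het_rate_arm = 8 / 88e3, n_genes = 60L)
    b <- simulate_experiment(cfg,
      marks = list(H3K9me2 = list(type = "het"),
                   H3K4me3 = list(type = "eu")),
      readers = list(r1 = list(target = "H3K9me2", theta = 0.85, n = 60),
                     r2 = list(target = "H3K9me2", theta = 0.85, n = 60),
                     r3 = list(target = "H3K4me3", theta = 0, n = 60)))
    loci <- merge_intervals(lapply(b$readers, `[[`, "peaks"))
    inp <- percentile_signal(bpm_normalize(b$input), loci, sample_id = "i")
    z <- lapply(names(b$readers), function(n) {
      input_normalize_log_z(
        percentile_signal(bpm_normalize(b$readers[[n]]$track), loci,
                          sample_id = n), inp)
    })
    m <- pearson_matrix(z)
    r_coupled <- c(r_coupled, m[1, 2])
    r_indep <- c(r_indep, m[1, 3])
  }
  expect_true(all(r_coupled > r_indep))
  expect_lt(wilcox.test(r_coupled, r_indep, paired = TRUE,
                        alternative = "greater")$p.value, 0.01)
})
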