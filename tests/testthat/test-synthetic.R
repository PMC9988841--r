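test_that("genome simulation tiles domains and is seed-deterministic", {
  cfg <- synthetic_config(seed = 5, chrom_lengths = c(chrA = 1e6),
                          arm_fraction = 0.25)
  g <- simulate_genome(cfg)
  expect_equal(g$domains$arm_end, 250000)
  expect_equal(g$domains$center_end, 750000)
  segs <- c(domain_segments(g$domains, "arm"),
            domain_segments(g$domains, "center"))
  expect_equal(sum(width(segs)), 1e6)              # exact tiling
  expect_equal(sum(width(GenomicRanges::reduce(segs))), 1e6)  # no overlap

  g2 <- simulate_genome(cfg)
  expect_identical(serialize(g, NULL), serialize(g2, NULL))
  expect_error(simulate_genome(synthetic_config(
    seed = 1, chrom_lengths = c(chrA = 1e4))), "shorter than 10x")
  expect_error(synthetic_config(seed = 1, not_a_field = 2), "unknown config")
})

test_that("mark placement follows the arm/center rates", {
  # zero center rate puts every domain on an arm
  cfg <- synthetic_config(seed = 7, chrom_lengths = c(chrA = 5e5),
                          het_rate_center_ratio = 0)
  g <- simulate_genome(cfg)
  mk <- simulate_marks(g, list(m = list(type = "het")))$m
  arms <- domain_segments(g$domains, "arm")
  expect_true(all(IRanges::overlapsAny(mk$peaks, arms)))
  expect_true(all(S4Vectors::runValue(mk$track$cov$chrA) >= 0))

  # arm share of mark bp close to the closed-form expectation
  cfgs <- lapply(1:6, function(s) synthetic_config(
    seed = 40 + s, chrom_lengths = c(chrA = 1e6)))
  shares <- vapply(cfgs, function(cf) {
    gg <- simulate_genome(cf)
    mm <- simulate_marks(gg, list(m = list(type = "het")))$m
    arm_bp <- sum(width(IRanges::intersect(
      GenomicRanges::reduce(mm$peaks),
      GenomicRanges::reduce(domain_segments(gg$domains, "arm")))))
    arm_bp / sum(width(mm$peaks))
  }, numeric(1))
  rho <- 0.1                                  # center/arm rate ratio
  arm_bp <- 2 * 0.22; cen_bp <- 1 - arm_bp
  expected <- arm_bp / (arm_bp + rho * cen_bp)
  se <- sd(shares) / sqrt(length(shares))
  expect_lt(abs(mean(shares) - expected), 3 * se + 0.02)
})

test_that("reader coupling hits its target rate", {
  cfg <- synthetic_config(seed = 9, chrom_lengths = c(chrA = 1e6))
  g <- simulate_genome(cfg)
  mk <- simulate_marks(g, list(m = list(type = "het")))$m
  r1 <- simulate_reader(g, mk, theta = 1, n = 200, name = "r1")
  expect_equal(r1$truth$realized_in_mark, 1)     # degenerate coupling
  expect_length(r1$peaks, 200)                   # count conservation

  # theta = 0: in-mark fraction matches the mark's genome share
  mark_frac <- sum(width(GenomicRanges::reduce(mk$peaks))) / 1e6
  fr0 <- vapply(1:6, function(s) {
    cf <- synthetic_config(seed = 60 + s, chrom_lengths = c(chrA = 1e6))
    gg <- simulate_genome(cf)
    mm <- simulate_marks(gg, list(m = list(type = "het")))$m
    simulate_reader(gg, mm, theta = 0, n = 300,
                    name = "r")$truth$realized_in_mark
  }, numeric(1))
  expect_lt(abs(mean(fr0) - mark_frac), 3 * sd(fr0) / sqrt(6) + 0.02)
  expect_error(simulate_reader(g, list(peaks = GRanges()), theta = 0.5,
                               n = 10), "zero domains")
})

test_that("read simulation respects strand balance and locality", {
  cfg <- synthetic_config(seed = 13, chrom_lengths = c(chrQ = 4e5),
                          background_rate = 0)
  g <- simulate_genome(cfg)
  mk <- simulate_marks(g, list(m = list(type = "het")))$m
  rd <- simulate_reader(g, mk, theta = 1, n = 10, name = "r")
  rr <- simulate_reads(g, rd$peaks)
  # strand counts are each ~half of emitted ends
  tab <- table(rr$chip$strand)
  n <- sum(tab)
  expect_lt(abs(tab[["+"]] - n / 2), 4 * sqrt(n / 4))
  # with zero background every read lies near a peak
  near <- GenomicRanges::resize(rd$peaks,
                                width = width(rd$peaks) + 2 * (200 + 150),
                                fix = "center")
  pts <- GRanges(rr$chip$chrom, IRanges(rr$chip$pos, width = 1))
  expect_true(all(IRanges::overlapsAny(pts, near)))
  # same seed, same reads
  rr2 <- simulate_reads(g, rd$peaks)
  expect_identical(rr, rr2)
})

test_that("bundles round-trip losslessly through the readers", {
  b <- tiny_bundle()
  dir <- file.path(tempdir(), "bundle_rt")
  write_bundle(b, dir)
  pk <- read_intervals(file.path(dir, "rdrA.bed"), "bed")
  expect_equal(ranges(pk), ranges(b$readers$rdrA$peaks))
  dom <- read_domains(file.path(dir, "domains.tsv"))
  expect_equal(dom, b$genome$domains)
  tr <- read_bedgraph(file.path(dir, "H3K9me2.bedgraph"),
                      seqlengths = b$genome$seqlengths)
  expect_identical(as.numeric(tr$cov$chrA),
                   as.numeric(b$marks$H3K9me2$track$cov$chrA))
  fp <- read_fpkm(file.path(dir, "fpkm.tsv"))
  expect_equal(fp, b$genome$fpkm)
  reps <- read_repeats(file.path(dir, "repeats.bed"))
  expect_equal(length(reps), length(b$genome$repeats))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$rdrA$theta, 0.9)
})
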