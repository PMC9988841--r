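test_that("BED and narrowPeak parsing honours coordinates, summits and rejection", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chrI\t0\t10\tp1", "chrI\t20\t35\tp2"), bed)
  ps <- read_intervals(bed, "bed")
  expect_equal(start(ps), c(1L, 21L))
  expect_equal(end(ps), c(10L, 35L))
  expect_equal(mcols(ps)$name, c("p1", "p2"))

  np <- tempfile(fileext = ".narrowPeak")
  writeLines(c(paste(c("chrI", 0, 10, "p1", 100, ".", 5, 3, 2, 4),
                     collapse = "\t"),
               paste(c("chrI", 50, 80, "p2", 10, ".", 5, 3, 2, -1),
                     collapse = "\t")), np)
  pn <- read_intervals(np, "narrowPeak")
  # summit offset 4 on [0,10) -> absolute reference point 4 (0-based)
  expect_equal(reference_points(pn)[1], 5L)      # 1-based internal
  # -1 summit falls back to the midpoint
  expect_equal(reference_points(pn)[2], floor((50 + 80) / 2) + 1L)

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chrI\t10\t5\tbad", "chrI\t0\t10\tok"), bad)
  expect_message(pb <- read_intervals(bad, "bed"), "rejected")
  expect_length(pb, 1)

  unparseable <- tempfile(fileext = ".bed")
  writeLines("chrI\tfoo\tbar", unparseable)
  expect_error(read_intervals(unparseable, "bed"), "line")
})

test_that("merge_intervals unions, merges book-ended runs, and is idempotent", {
  expect_equal(ranges(merge_intervals(bed_gr("c", c(0, 5), c(10, 15)))),
               ranges(bed_gr("c", 0, 15)))
  expect_equal(ranges(merge_intervals(bed_gr("c", c(0, 10), c(10, 20)))),
               ranges(bed_gr("c", 0, 20)))
  disj <- bed_gr("c", c(0, 10), c(5, 15))
  expect_equal(ranges(merge_intervals(disj)), ranges(disj))
  expect_length(merge_intervals(list()), 0)

  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    st <- sample(0:5000, n)
    gr <- bed_gr("c", st, st + sample(10:300, n, replace = TRUE))
    m1 <- merge_intervals(gr)
    expect_identical(m1, merge_intervals(m1))           # idempotent
    expect_equal(sum(width(m1)),                         # covered bp preserved
                 sum(width(reduce(gr))))
    expect_true(all(start(m1)[-1] > end(m1)[-length(m1)] + 1))  # disjoint
  }
})

test_that("domain partition assigns by midpoint and conserves counts", {
  dom <- chromosome_domains("chrI", 1000, 3000, 4000)
  # midpoint inside left arm
  expect_equal(partition_by_domain(bed_gr("chrI", 100, 200), dom)$class, "arm")
  # peak spanning the boundary with midpoint exactly at a -> center
  expect_equal(partition_by_domain(bed_gr("chrI", 990, 1010), dom)$class,
               "center")
  # 10 peaks, 6 arm midpoints -> 0.6
  st <- c(0, 100, 200, 3200, 3300, 3400, 1500, 1600, 1700, 1800)
  pt <- partition_by_domain(bed_gr("chrI", st, st + 50), dom)
  expect_equal(pt$arm_fraction, 0.6)
  expect_error(partition_by_domain(bed_gr("chrX", 0, 10), dom), "chrX")

  set.seed(1)
  for (i in 1:10) {
    st <- sample(0:3900, 50)
    pk <- bed_gr("chrI", st, st + sample(5:80, 50, replace = TRUE))
    pt <- partition_by_domain(pk, dom)
    expect_equal(length(pt$arm) + length(pt$center), length(pk))
  }
  expect_error(chromosome_domains("c", 0, 10, 20), "0 < a < b < L")
})

test_that("feature assignment follows the promoter > exon > intron priority", {
  genes <- bed_gr("chrI", 2000, 5000, gene_id = "g1")
  strand(genes) <- "+"
  exons <- bed_gr("chrI", c(2000, 3000, 4500), c(2500, 3500, 5000),
                  gene_id = "g1")
  strand(exons) <- "+"
  gm <- gene_models(genes, exons)
  # promoter window is [TSS-1000, TSS+100): a point at 2050 is both exon and
  # promoter; promoter wins
  pk <- bed_gr("chrI", c(2040, 3100, 2700, 9000), c(2060, 3120, 2720, 9020))
  af <- assign_feature(pk, gm)
  expect_equal(af$labels, c("promoter", "exon", "intron", "intergenic"))
  expect_equal(sum(af$fractions), 1, tolerance = 1e-12)
  expect_named(af$fractions, c("promoter", "exon", "intron", "intergenic"))
})

test_that("gene activity classification matches the full truth table", {
  combos <- expand.grid(f = c(2, 0.5), eu = c(TRUE, FALSE),
                        het = c(TRUE, FALSE))
  ids <- sprintf("g%d", seq_len(nrow(combos)))
  got <- classify_gene_activity(ids, setNames(combos$f, ids),
                                setNames(combos$eu, ids),
                                setNames(combos$het, ids))
  # independent re-derivation of the rule
  want <- ifelse(combos$f >= 1 & combos$eu, "active",
                 ifelse(combos$f < 1 & combos$het, "silent", "unclassified"))
  expect_equal(got$label, want)
  expect_error(classify_gene_activity("g", c(g = -1), c(g = TRUE),
                                      c(g = FALSE)), "negative")
  expect_message(classify_gene_activity("missing", c(other = 1),
                                        c(missing = TRUE), c(missing = TRUE)),
                 "missing")
})

test_that("repeat-family overlap uses per-family and any-family set semantics", {
  pk <- bed_gr("c", seq(0, 1900, by = 100), seq(0, 1900, by = 100) + 50)  # 20
  reps <- bed_gr("c", c(10, 110, 210, 310, 320), c(30, 130, 230, 330, 340),
                 family = c("DNA", "DNA", "LTR", "DNA", "LTR"))
  ro <- repeat_family_overlap(pk, reps)
  expect_equal(ro$fraction, 4 / 20)
  expect_equal(ro$per_family[["DNA"]], 3L)
  # the peak at [300,350) touches both DNA and LTR: counted once per family,
  # once at peak level
  expect_equal(ro$per_family[["LTR"]], 2L)
  empty <- repeat_family_overlap(pk, GRanges())
  expect_equal(empty$fraction, 0)
})

test_that("interval, track and domain files round-trip losslessly", {
  pk <- peak_set(bed_gr("chrI", c(0, 100), c(50, 180)), sample = "s1")
  f <- tempfile(fileext = ".bed")
  write_intervals(pk, f)
  back <- read_intervals(f, "bed")
  expect_equal(ranges(back), ranges(pk))

  dom <- chromosome_domains(c("chrI", "chrII"), c(100, 150), c(300, 350),
                            c(400, 500))
  fd <- tempfile(fileext = ".tsv")
  write_domains(dom, fd)
  expect_equal(read_domains(fd), dom)

  tr <- signal_track(bed_gr("chrI", c(0, 40), c(20, 60), score = c(2, 5)),
                     seqlengths = c(chrI = 100))
  ft <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, ft)
  tr2 <- read_bedgraph(ft, seqlengths = c(chrI = 100))
  expect_identical(as.numeric(tr2$cov$chrI), as.numeric(tr$cov$chrI))
})
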