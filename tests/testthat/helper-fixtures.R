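suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
})

# quick GRanges builder from BED-style (0-based half-open) triples
bed_gr <- function(chrom, start, end, ...) {
  gr <- GRanges(chrom, IRanges(start + 1L, end))
  extra <- list(...)
  for (nm in names(extra)) mcols(gr)[[nm]] <- extra[[nm]]
  gr
}

# independent brute-force proximity oracle: enumerate every placement of a
# length-L query inside the 0-based half-open domain [d0, d1) and count the
# placements whose bp gap to the nearest of the refs (parallel 0-based
# vectors r0, r1) is <= the observed gap of the query at start qs.
brute_prox_p <- function(d0, d1, L, r0, r1, qs) {
  ss <- d0:(d1 - L)
  gap_at <- function(s) min(pmax(r0 - (s + L), s - r1, 0))
  ds <- vapply(ss, gap_at, numeric(1))
  mean(ds <= gap_at(qs))
}

# enumerate all set partitions of n elements (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, mx) {
    k <- length(prefix)
    if (k == n) { out[[length(out) + 1]] <<- prefix; return(invisible()) }
    for (v in 1:(mx + 1)) rec(c(prefix, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# a small shared synthetic bundle for pipeline-level tests (built once)
.tiny_bundle_cache <- new.env()
tiny_bundle <- function(seed = 11) {
  key <- as.character(seed)
  if (!is.null(.tiny_bundle_cache[[key]])) return(.tiny_bundle_cache[[key]])
  cfg <- synthetic_config(seed = seed,
                          chrom_lengths = c(chrA = 1e6, chrB = 1e6),
                          n_genes = 120L, n_repeats = 150L)
  b <- simulate_experiment(cfg,
    marks = list(H3K9me2 = list(type = "het"), H3K4me3 = list(type = "eu")),
    readers = list(rdrA = list(target = "H3K9me2", theta = 0.9, n = 100),
                   rdrA2 = list(target = "H3K9me2", theta = 0.9, n = 100),
                   rdrB = list(target = "H3K4me3", theta = 0.9, n = 100),
                   rdrB2 = list(target = "H3K4me3", theta = 0.9, n = 100)))
  .tiny_bundle_cache[[key]] <- b
  b
}

# two triangles {a,b,c} and {d,e,f} joined by the bridge c-d, unit weights
two_triangle_network <- function() {
  ed <- data.frame(
    factor_a = c("a", "a", "b", "d", "d", "e", "c"),
    factor_b = c("b", "c", "c", "e", "f", "f", "d"),
    overlap_ab = 1, overlap_ba = 1, weight = 1,
    stringsAsFactors = FALSE)
  build_network(ed, strong = 0.5, moderate = 0.25)
}
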