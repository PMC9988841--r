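#' Synthetic experiment configuration
#'
#' Default study conditions for the synthetic genome: five 2-Mb chromosomes
#' (10 Mb total) partitioned so that the two arms jointly hold 44% of each
#' chromosome; heterochromatin-type marks as dispersed small domains (median
#' 2 kb, log-normal) laid down on arms at ~8 domains per arm with a 10x lower
#' rate in centers; euchromatin-type marks at promoters/bodies of active
#' genes; reader peak sets coupled to a chosen mark with strength theta
#' (a peak sits uniformly inside a random target-mark domain with probability
#' theta, else uniformly in the genome); peak lengths log-normal with median
#' 300 bp. Read simulation uses 200-bp fragments, 50-bp single-end reads,
#' and a block-structured background emulating regional
#' accessibility/mappability variation.
#'
#' @param seed master seed; every sub-generator derives an independent
#'   stream from it, so adding a reader never perturbs mark placement
#' @param ... overrides for any default listed above
#' @return a named list (class \code{synthetic_config})
#' @export
synthetic_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    chrom_lengths = setNames(rep(2e6, 5), paste0("chr", as.roman(1:5))),
    arm_fraction = 0.22,          # per side; arms jointly 44% of the genome
    n_genes = 300L,
    gene_center_prob = 0.8,
    n_repeats = 400L,
    repeat_families = c("DNAtransposon", "LTR", "LINE", "satellite",
                        "unknown"),
    repeat_arm_prob = 0.8,
    # marks
    het_rate_arm = 8 / 440e3,     # expected domains per arm bp
    het_rate_center_ratio = 0.1,
    het_len_meanlog = log(2000), het_len_sdlog = 0.4,
    # reader peaks
    peak_len_meanlog = log(300), peak_len_sdlog = 0.5,
    # tracks
    track_bin = 20L,
    track_depth = 10,
    track_background = 1,
    # reads
    frag_len = 200L, read_len = 50L, reads_per_peak = 200L,
    jitter_sd = 50, background_rate = 0.2, frag_len_bg = c(100L, 300L),
    block_size = 10e3, block_sdlog = 1.2,
    active_fraction = 0.6)
  ovr <- list(...)
  unknown <- setdiff(names(ovr), names(cfg))
  if (length(unknown)) stopf("unknown config field(s): %s",
                             paste(unknown, collapse = ", "))
  structure(modifyList(cfg, ovr), class = c("synthetic_config", "list"))
}

#' Simulate a genome with domains, genes, repeats and expression
#'
#' Builds the chromosome manifest, the arm/center domain table, gene models
#' (placed preferentially in centers), a repeat annotation (preferentially on
#' arms), an FPKM table, and per-block background-rate multipliers used by
#' the read simulator. Deterministic under the config seed.
#'
#' @param config a [synthetic_config()]
#' @return list(config, seqlengths, domains, genes, repeats, fpkm, blocks)
#' @export
simulate_genome <- function(config = synthetic_config()) {
  sl <- config$chrom_lengths
  mean_mark_len <- exp(config$het_len_meanlog + config$het_len_sdlog^2 / 2)
  if (any(sl < 10 * mean_mark_len))
    stopf("chromosome shorter than 10x mean mark domain length")
  a <- floor(sl * config$arm_fraction)
  b <- sl - a
  domains <- chromosome_domains(names(sl), a, b, sl)

  set.seed(stream_seed(config$seed, 1L))
  # genes: preferentially in centers, 2-6 exons
  n <- config$n_genes
  g_chr <- sample(names(sl), n, replace = TRUE, prob = sl / sum(sl))
  in_center <- runif(n) < config$gene_center_prob
  g_len <- pmin(round(rlnorm(n, log(2500), 0.4)), 2e4)
  g_start <- integer(n)
  for (i in seq_len(n)) {
    ch <- g_chr[i]
    rng <- if (in_center[i]) c(a[[ch]] + 1, b[[ch]] - g_len[i]) else
      c(1, a[[ch]] - g_len[i])
    g_start[i] <- sample(seq(rng[1], max(rng[1] + 1, rng[2])), 1)
  }
  g_strand <- sample(c("+", "-"), n, replace = TRUE)
  genes_gr <- GenomicRanges::GRanges(g_chr,
               IRanges::IRanges(g_start, width = g_len), strand = g_strand)
  mcols(genes_gr)$gene_id <- sprintf("gene%04d", seq_len(n))
  ex_rows <- lapply(seq_len(n), function(i) {
    k <- sample(2:6, 1)
    cuts <- sort(sample(seq(50, g_len[i] - 50), 2 * (k - 1)))
    bounds <- c(0, cuts, g_len[i])
    st <- bounds[seq(1, length(bounds) - 1, by = 2)]
    en <- bounds[seq(2, length(bounds), by = 2)]
    data.frame(chrom = g_chr[i], start = g_start[i] + st,
               end = g_start[i] + en - 1, gene_id = sprintf("gene%04d", i),
               strand = g_strand[i])
  })
  exd <- do.call(rbind, ex_rows)
  exons_gr <- GenomicRanges::GRanges(exd$chrom,
                IRanges::IRanges(exd$start, exd$end), strand = exd$strand)
  mcols(exons_gr)$gene_id <- exd$gene_id
  models <- gene_models(genes_gr, exons_gr)

  set.seed(stream_seed(config$seed, 2L))
  # repeats: short elements, preferentially on arms
  m <- config$n_repeats
  r_chr <- sample(names(sl), m, replace = TRUE, prob = sl / sum(sl))
  on_arm <- runif(m) < config$repeat_arm_prob
  r_len <- pmax(50L, round(rlnorm(m, log(400), 0.6)))
  r_start <- integer(m)
  for (i in seq_len(m)) {
    ch <- r_chr[i]
    r_start[i] <- if (on_arm[i]) {
      left <- runif(1) < 0.5
      if (left) sample.int(max(2, a[[ch]] - r_len[i]), 1)
      else b[[ch]] + sample.int(max(2, sl[[ch]] - b[[ch]] - r_len[i]), 1)
    } else a[[ch]] + sample.int(max(2, b[[ch]] - a[[ch]] - r_len[i]), 1)
  }
  repeats <- GenomicRanges::GRanges(r_chr,
               IRanges::IRanges(r_start, width = r_len))
  mcols(repeats)$family <- sample(config$repeat_families, m, replace = TRUE)
  repeats <- GenomicRanges::sort(repeats)

  set.seed(stream_seed(config$seed, 3L))
  active <- runif(n) < config$active_fraction
  fpkm <- ifelse(active, rlnorm(n, log(20), 1), runif(n, 0, 0.9))
  names(fpkm) <- mcols(genes_gr)$gene_id

  set.seed(stream_seed(config$seed, 4L))
  blocks <- lapply(sl, function(L) {
    nb <- ceiling(L / config$block_size)
    rlnorm(nb, -config$block_sdlog^2 / 2, config$block_sdlog)  # mean 1
  })

  list(config = config, seqlengths = sl, domains = domains,
       genes = models, repeats = repeats, fpkm = fpkm,
       active = setNames(active, names(fpkm)), blocks = blocks)
}

# Piecewise-constant track: bin-level value = depth * indicator(bin overlaps
# an interval) + Poisson(background). Bin resolution keeps simulation and
# downstream BPM bins aligned.
simulate_track_from <- function(intervals, seqlengths, seed, depth = 10,
                                background = 1, bin = 20L) {
  set.seed(seed)
  cov <- lapply(names(seqlengths), function(ch) {
    L <- seqlengths[[ch]]
    nb <- ceiling(L / bin)
    lam <- rep(background, nb)
    sel <- intervals[as.character(seqnames(intervals)) == ch]
    val <- rpois(nb, lam)
    if (length(sel)) {
      bins_hit <- unique(unlist(lapply(seq_along(sel), function(i) {
        seq(floor((GenomicRanges::start(sel)[i] - 1) / bin),
            floor((GenomicRanges::end(sel)[i] - 1) / bin)) + 1L
      })))
      bins_hit <- bins_hit[bins_hit >= 1 & bins_hit <= nb]
      val[bins_hit] <- val[bins_hit] + depth
    }
    w <- rep(bin, nb); w[nb] <- L - bin * (nb - 1)
    Rle(as.numeric(val), w)
  })
  names(cov) <- names(seqlengths)
  signal_track(cov)
}

#' Simulate histone-mark domains and signal tracks
#'
#' Heterochromatin-type marks: domain counts per arm/center segment are
#' Poisson with per-bp rates (arm rate >> center rate), lengths log-normal,
#' positions uniform within the segment. Euchromatin-type marks cover the
#' promoters (and optionally bodies) of genes labelled active. Each mark also
#' gets a raw signal track (indicator x depth + Poisson background at bin
#' resolution).
#'
#' @param genome output of [simulate_genome()]
#' @param marks named list describing each mark:
#'   \code{list(H3K9me2 = list(type = "het"), H3K4me3 = list(type = "eu"))};
#'   het marks accept \code{rate_arm}, \code{rate_center} overrides
#' @return named list per mark: list(peaks, track)
#' @export
simulate_marks <- function(genome,
                           marks = list(H3K9me2 = list(type = "het"))) {
  cfg <- genome$config
  out <- list()
  for (k in seq_along(marks)) {
    nm <- names(marks)[k]
    spec <- marks[[k]]
    seed <- stream_seed(cfg$seed, 10L + k)
    set.seed(seed)
    if (identical(spec$type, "het")) {
      rate_arm <- spec$rate_arm %||% cfg$het_rate_arm
      rate_center <- spec$rate_center %||%
        (rate_arm * cfg$het_rate_center_ratio)
      segs <- c(domain_segments(genome$domains, "arm"),
                domain_segments(genome$domains, "center"))
      doms <- list()
      for (i in seq_along(segs)) {
        L <- IRanges::width(segs)[i]
        rate <- if (mcols(segs)$class[i] == "arm") rate_arm else rate_center
        nd <- rpois(1, rate * L)
        if (!nd) next
        len <- pmax(200, round(rlnorm(nd, cfg$het_len_meanlog,
                                      cfg$het_len_sdlog)))
        len <- pmin(len, L - 1)
        st <- GenomicRanges::start(segs)[i] +
          floor(runif(nd) * (L - len))
        doms[[length(doms) + 1]] <- GenomicRanges::GRanges(
          seqnames(segs)[i], IRanges::IRanges(st, width = len))
      }
      peaks <- if (length(doms)) GenomicRanges::reduce(
        GenomicRanges::sort(do.call(c, doms))) else GenomicRanges::GRanges()
    } else {
      act <- names(genome$active)[genome$active]
      gsel <- genome$genes$genes[mcols(genome$genes$genes)$gene_id %in% act]
      prom <- GenomicRanges::promoters(gsel, upstream = 500, downstream = 500)
      body <- if (isTRUE(spec$body)) gsel else NULL
      peaks <- GenomicRanges::reduce(GenomicRanges::sort(
        GenomicRanges::`strand<-`(c(GenomicRanges::granges(prom),
                                    if (!is.null(body))
                                      GenomicRanges::granges(body)),
                                  value = "*")))
      peaks <- GenomicRanges::trim(peaks)
    }
    peaks <- peak_set(peaks, sample = nm)
    track <- simulate_track_from(peaks, genome$seqlengths,
                                 seed = stream_seed(cfg$seed, 40L + k),
                                 depth = cfg$track_depth,
                                 background = cfg$track_background,
                                 bin = cfg$track_bin)
    out[[nm]] <- list(peaks = peaks, track = track)
  }
  out
}

#' Simulate a reader peak set coupled to a mark
#'
#' Each of n peaks independently sits, with probability theta, uniformly
#' inside a uniformly chosen target-mark domain; otherwise uniformly in the
#' genome. Peak lengths are log-normal (median 300 bp by default). The truth
#' record carries theta and the realized fraction of peak centers inside
#' mark domains (which exceeds theta by the chance placement rate
#' (1 - theta) x mark genome fraction, in expectation).
#'
#' @param genome output of [simulate_genome()]
#' @param mark a mark entry from [simulate_marks()] (list with \code{peaks})
#' @param theta coupling strength in [0, 1]
#' @param n number of peaks
#' @param name sample name
#' @param stream RNG sub-stream index (vary per reader)
#' @return list(peaks, track, truth = list(target, theta, realized_in_mark))
#' @export
simulate_reader <- function(genome, mark, theta, n, name = "reader",
                            stream = 20L) {
  stopifnot(theta >= 0, theta <= 1)
  cfg <- genome$config
  doms <- mark$peaks
  if (theta > 0 && !length(doms)) stopf("target mark has zero domains")
  sl <- genome$seqlengths
  set.seed(stream_seed(cfg$seed, stream))
  len <- pmax(50L, round(rlnorm(n, cfg$peak_len_meanlog, cfg$peak_len_sdlog)))
  coupled <- runif(n) < theta
  chr <- character(n); ctr <- numeric(n)
  n_doms <- length(doms)
  for (i in seq_len(n)) {
    if (coupled[i]) {
      j <- sample.int(n_doms, 1)
      chr[i] <- as.character(seqnames(doms))[j]
      ctr[i] <- GenomicRanges::start(doms)[j] +
        floor(runif(1) * IRanges::width(doms)[j])
    } else {
      chr[i] <- sample(names(sl), 1, prob = sl / sum(sl))
      ctr[i] <- 1 + floor(runif(1) * sl[[chr[i]]])
    }
  }
  st <- pmax(1, round(ctr - len / 2))
  en <- pmin(sl[chr], st + len - 1)
  gr <- GenomicRanges::GRanges(chr, IRanges::IRanges(st, en))
  mcols(gr)$summit <- as.integer(pmin(pmax(ctr, st), en))
  peaks <- peak_set(gr, sample = name)
  centers <- GenomicRanges::GRanges(chr, IRanges::IRanges(as.integer(ctr),
                                                          width = 1L))
  realized <- if (length(doms))
    mean(IRanges::overlapsAny(centers, doms, ignore.strand = TRUE))
  else 0
  track <- simulate_track_from(peaks, sl,
                               seed = stream_seed(cfg$seed, stream + 1000L),
                               depth = cfg$track_depth,
                               background = cfg$track_background,
                               bin = cfg$track_bin)
  list(peaks = peaks, track = track,
       truth = list(target = metadata(mark$peaks)$sample, theta = theta,
                    realized_in_mark = realized))
}

#' Simulate a matched input track
#'
#' Background-only track (Poisson around the configured background depth).
#'
#' @param genome output of [simulate_genome()]
#' @return a raw \code{signal_track}
#' @export
simulate_input_track <- function(genome) {
  cfg <- genome$config
  simulate_track_from(GenomicRanges::GRanges(), genome$seqlengths,
                      seed = stream_seed(cfg$seed, 99L),
                      depth = 0, background = cfg$track_background,
                      bin = cfg$track_bin)
}

#' Simulate stranded ChIP reads and a matched input
#'
#' Signal: per peak, \code{reads_per_peak} fragments of length
#' \code{frag_len} centered at the peak reference point with Gaussian jitter;
#' each fragment emits a plus-strand read at its left end and/or a
#' minus-strand read at its right end, each with probability 0.5
#' independently. Background: fragments at \code{background_rate} per bp with
#' broad (uniform) lengths, placed proportionally to per-block accessibility
#' multipliers; the input read set is background-only at matched depth.
#'
#' @param genome output of [simulate_genome()]
#' @param peaks peak set to seed signal fragments (NULL for input-only)
#' @param stream RNG sub-stream index
#' @return list(chip = read_set, input = read_set)
#' @export
simulate_reads <- function(genome, peaks, stream = 60L) {
  cfg <- genome$config
  if (cfg$frag_len <= cfg$read_len) stopf("fragment length must exceed read length")
  sl <- genome$seqlengths
  sample_bg <- function(seed) {
    set.seed(seed)
    out <- list()
    for (ch in names(sl)) {
      L <- sl[[ch]]
      nfrag <- rpois(1, cfg$background_rate * L)
      if (!nfrag) next
      wts <- genome$blocks[[ch]]
      blk <- sample.int(length(wts), nfrag, replace = TRUE, prob = wts)
      left <- (blk - 1) * cfg$block_size +
        floor(runif(nfrag) * pmin(cfg$block_size,
                                  L - (blk - 1) * cfg$block_size)) + 1
      flen <- sample(seq(cfg$frag_len_bg[1], cfg$frag_len_bg[2]),
                     nfrag, replace = TRUE)
      out[[ch]] <- data.frame(chrom = ch, left = left,
                              right = pmin(left + flen - 1, L))
    }
    do.call(rbind, out)
  }
  sample_signal <- function(seed) {
    if (is.null(peaks) || !length(peaks)) return(NULL)
    set.seed(seed)
    rp <- reference_points(peaks)
    chr <- as.character(seqnames(peaks))
    nf <- cfg$reads_per_peak
    ctr <- rep(rp, each = nf) + round(rnorm(length(peaks) * nf, 0,
                                            cfg$jitter_sd))
    ch <- rep(chr, each = nf)
    left <- pmax(1, round(ctr - cfg$frag_len / 2))
    right <- pmin(sl[ch], left + cfg$frag_len - 1)
    data.frame(chrom = ch, left = left, right = right)
  }
  emit <- function(frags, seed) {
    if (is.null(frags) || !nrow(frags)) return(NULL)
    set.seed(seed)
    p <- runif(nrow(frags)) < 0.5
    m <- runif(nrow(frags)) < 0.5
    data.frame(chrom = c(frags$chrom[p], frags$chrom[m]),
               pos = c(frags$left[p], frags$right[m]),
               strand = c(rep("+", sum(p)), rep("-", sum(m))))
  }
  chip_fr <- rbind(sample_signal(stream_seed(cfg$seed, stream)),
                   sample_bg(stream_seed(cfg$seed, stream + 1L)))
  input_fr <- sample_bg(stream_seed(cfg$seed, stream + 2L))
  chip_rd <- emit(chip_fr, stream_seed(cfg$seed, stream + 3L))
  input_rd <- emit(input_fr, stream_seed(cfg$seed, stream + 4L))
  list(chip = read_set(chip_rd$chrom, chip_rd$pos, chip_rd$strand,
                       cfg$read_len, sl),
       input = read_set(input_rd$chrom, input_rd$pos, input_rd$strand,
                        cfg$read_len, sl))
}

#' Simulate a complete experiment bundle
#'
#' One call producing everything the pipeline consumes: genome, marks with
#' tracks, readers coupled per the specs, an input track, and the
#' ground-truth manifest.
#'
#' @param config a [synthetic_config()]
#' @param marks mark specification, see [simulate_marks()]
#' @param readers named list: \code{list(readerA = list(target = "H3K9me2",
#'   theta = 0.9, n = 500))}
#' @return list(genome, marks, readers, input, truth)
#' @export
simulate_experiment <- function(config = synthetic_config(),
                                marks = list(H3K9me2 = list(type = "het")),
                                readers = list(readerA = list(
                                  target = "H3K9me2", theta = 0.9, n = 500))) {
  genome <- simulate_genome(config)
  mk <- simulate_marks(genome, marks)
  rd <- list()
  for (k in seq_along(readers)) {
    spec <- readers[[k]]
    rd[[names(readers)[k]]] <- simulate_reader(
      genome, mk[[spec$target]], theta = spec$theta, n = spec$n,
      name = names(readers)[k], stream = 20L + 2L * k)
  }
  truth <- lapply(rd, function(r) r$truth)
  list(genome = genome, marks = mk, readers = rd,
       input = simulate_input_track(genome), truth = truth)
}

#' Write a simulated bundle to disk
#'
#' Emits narrowPeak/BED peak files, bedGraph tracks, the domain table, the
#' FPKM table, the repeat BED and a truth manifest JSON into a directory.
#'
#' @param bundle output of [simulate_experiment()]
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  write_domains(bundle$genome$domains, fp("domains.tsv"))
  fwrite(data.table(gene_id = names(bundle$genome$fpkm),
                    fpkm = as.numeric(bundle$genome$fpkm)),
         fp("fpkm.tsv"), sep = "\t")
  rep_dt <- data.table(chrom = as.character(seqnames(bundle$genome$repeats)),
                       start = GenomicRanges::start(bundle$genome$repeats) - 1L,
                       end = GenomicRanges::end(bundle$genome$repeats),
                       family = mcols(bundle$genome$repeats)$family)
  fwrite(rep_dt, fp("repeats.bed"), sep = "\t", col.names = FALSE)
  for (nm in names(bundle$marks)) {
    write_intervals(bundle$marks[[nm]]$peaks, fp(paste0(nm, ".bed")))
    write_bedgraph(bundle$marks[[nm]]$track, fp(paste0(nm, ".bedgraph")))
  }
  for (nm in names(bundle$readers)) {
    write_intervals(bundle$readers[[nm]]$peaks, fp(paste0(nm, ".bed")))
    write_bedgraph(bundle$readers[[nm]]$track, fp(paste0(nm, ".bedgraph")))
  }
  write_bedgraph(bundle$input, fp("input.bedgraph"))
  jsonlite::write_json(bundle$truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
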