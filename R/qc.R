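#' Construct a read set
#'
#' Single-end reads reduced to their 5' positions: chromosome, 1-based
#' position, and strand, plus the read length and chromosome lengths needed
#' for cross-correlation.
#'
#' @param chrom,pos,strand per-read vectors; strand in {"+", "-"}
#' @param read_length read length in bp
#' @param seqlengths named chromosome lengths
#' @return object of class \code{read_set}
#' @export
read_set <- function(chrom, pos, strand, read_length, seqlengths) {
  stopifnot(all(strand %in% c("+", "-")))
  chrom <- as.character(chrom)
  bad <- pos < 1 | pos > seqlengths[chrom]
  if (any(bad)) stopf("%d read position(s) outside chromosome bounds", sum(bad))
  structure(list(chrom = chrom, pos = as.integer(pos), strand = strand,
                 read_length = as.integer(read_length),
                 seqlengths = seqlengths),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads (%d +, %d -), read length %d bp\n",
              length(x$pos), sum(x$strand == "+"), sum(x$strand == "-"),
              x$read_length))
  invisible(x)
}

#' Read a BED6 file of reads
#'
#' Each record is one read interval; the 5' position is the left end for "+"
#' reads and the right end for "-" reads.
#'
#' @param path file path
#' @param read_length read length in bp (default: modal interval width)
#' @param seqlengths named chromosome lengths (default: max end per chrom)
#' @return a \code{read_set}
#' @export
read_reads_bed <- function(path, read_length = NULL, seqlengths = NULL) {
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 6) stopf("%s: BED6 required for reads", path)
  strand <- as.character(dt[[6]])
  if (!all(strand %in% c("+", "-"))) stopf("reads must be stranded")
  pos <- ifelse(strand == "+", dt[[2]] + 1L, dt[[3]])
  w <- dt[[3]] - dt[[2]]
  rl <- read_length %||% as.integer(names(sort(table(w), decreasing = TRUE))[1])
  sl <- seqlengths %||% tapply(dt[[3]], as.character(dt[[1]]), max)
  read_set(dt[[1]], pos, strand, rl, sl)
}

#' Fraction of reads in peaks (FRiP)
#'
#' @param reads a \code{read_set}
#' @param peaks a peak set
#' @return fraction of reads whose 5' position falls inside any peak
#' @export
frip <- function(reads, peaks) {
  if (!length(reads$pos)) stopf("empty read set")
  if (!length(peaks)) return(0)
  pts <- GenomicRanges::GRanges(reads$chrom,
                                IRanges::IRanges(reads$pos, width = 1L))
  mean(IRanges::overlapsAny(pts, peaks, ignore.strand = TRUE))
}

# Exact Pearson cross-correlation between the two strand-specific 5'-end
# occupancy vectors, computed sparsely. For shift d, the correlation is over
# positions i = 1..L-d of x[i] (plus strand) vs y[i+d] (minus strand).
# With binarized vectors this reduces to pair counts:
#   M11(d) = #{(a, b): a in P+, b in P-, b - a = d}
# plus boundary-corrected marginal counts, all obtainable from sorted
# positions, avoiding any length-L dense vector.
.cc_one_chrom <- function(p_plus, p_minus, L, max_shift, binarize) {
  if (binarize) { p_plus <- unique(p_plus); p_minus <- unique(p_minus) }
  else stopf("raw-count cross-correlation not implemented; use binarize=TRUE")
  shifts <- 0:max_shift
  # pair counts per difference
  ir_q <- IRanges::IRanges(start = p_plus, end = pmin(p_plus + max_shift, L))
  ir_s <- IRanges::IRanges(start = p_minus, width = 1L)
  ov <- IRanges::findOverlaps(ir_q, ir_s)
  diffs <- p_minus[subjectHits(ov)] - p_plus[queryHits(ov)]
  M11 <- tabulate(diffs + 1L, nbins = max_shift + 1L)
  # marginal counts restricted to the overlap window:
  # n1x(d) = #{a <= L - d} = |P+| - #{L - a < d};  n1y(d) = #{b > d}
  t_x <- L - p_plus                      # >= 0
  tb_x <- tabulate(t_x[t_x <= max_shift] + 1L, nbins = max_shift + 1L)
  exc_x <- c(0, cumsum(tb_x))[seq_len(max_shift + 1L)]
  tb_y <- tabulate(p_minus[p_minus <= max_shift], nbins = max_shift)
  exc_y <- c(0, cumsum(tb_y))
  n1x <- length(p_plus) - exc_x
  n1y <- length(p_minus) - exc_y
  n <- L - shifts
  num <- n * M11 - n1x * n1y
  den <- sqrt(n1x * (n - n1x)) * sqrt(n1y * (n - n1y))
  r <- ifelse(den > 0, num / den, 0)
  data.frame(shift = shifts, cc = r)
}

#' Strand cross-correlation profile
#'
#' Pearson correlation between the plus-strand 5'-end occupancy vector and
#' the minus-strand vector shifted left by d, for d = 0..max_shift, averaged
#' over chromosomes weighted by length. Occupancy vectors are binarized
#' (position holds >= 1 read end), matching common cross-correlation
#' practice. In a ChIP library the profile peaks near the fragment length;
#' mappability artefacts add a "phantom" peak at the read length.
#'
#' @param reads a \code{read_set} with reads on both strands
#' @param max_shift largest shift in bp (must be < chromosome length)
#' @param binarize binarize occupancy (default TRUE)
#' @return data.frame(shift, cc) with attribute \code{read_length}
#' @export
cross_correlation_profile <- function(reads, max_shift = 400L,
                                      binarize = TRUE) {
  if (!any(reads$strand == "+") || !any(reads$strand == "-"))
    stopf("cross-correlation needs reads on both strands")
  sl <- reads$seqlengths
  if (any(max_shift >= sl)) stopf("max_shift >= chromosome length")
  acc <- rep(0, max_shift + 1L); wsum <- 0
  for (ch in names(sl)) {
    sel <- reads$chrom == ch
    if (!any(sel)) next
    pp <- reads$pos[sel & reads$strand == "+"]
    pm <- reads$pos[sel & reads$strand == "-"]
    if (!length(pp) || !length(pm)) next
    prof <- .cc_one_chrom(pp, pm, as.numeric(sl[[ch]]), max_shift, binarize)
    acc <- acc + prof$cc * as.numeric(sl[[ch]])
    wsum <- wsum + as.numeric(sl[[ch]])
  }
  out <- data.frame(shift = 0:max_shift, cc = acc / wsum)
  attr(out, "read_length") <- reads$read_length
  out
}

#' NSC, RSC and fragment-length estimate from a cross-correlation profile
#'
#' Background b is the profile minimum; the fragment-length peak cc_frag is
#' the profile maximum outside an exclusion zone of +/- \code{exclusion} bp
#' around the read length (the phantom peak); cc_read is the profile at the
#' read-length shift. NSC = cc_frag / b and RSC = (cc_frag - b) /
#' (cc_read - b), the background-subtracted form; the raw peak ratio
#' cc_frag / cc_read is reported alongside as \code{rsc_raw}.
#'
#' @param profile data.frame(shift, cc) from [cross_correlation_profile()]
#' @param read_length read length in bp (default: profile attribute)
#' @param exclusion half-width of the phantom-peak exclusion zone (bp)
#' @return list(nsc, rsc, rsc_raw, frag_len_estimate, cc_frag, cc_read,
#'   background)
#' @export
nsc_rsc <- function(profile, read_length = attr(profile, "read_length"),
                    exclusion = 10L) {
  if (max(profile$shift) <= read_length)
    stopf("profile must extend past the read length")
  b <- min(profile$cc)
  outside <- abs(profile$shift - read_length) > exclusion
  i_frag <- which(outside)[which.max(profile$cc[outside])]
  cc_frag <- profile$cc[i_frag]
  frag_len <- profile$shift[i_frag]
  i_read <- which(profile$shift == read_length)
  cc_read <- if (length(i_read)) profile$cc[i_read] else
    stats::approx(profile$shift, profile$cc, xout = read_length)$y
  rsc <- if (abs(cc_read - b) < .Machine$double.eps * 8) {
    ca_log("warn", "cc at read length equals background; RSC = +Inf")
    Inf
  } else (cc_frag - b) / (cc_read - b)
  list(nsc = cc_frag / b, rsc = rsc, rsc_raw = cc_frag / cc_read,
       frag_len_estimate = frag_len, cc_frag = cc_frag, cc_read = cc_read,
       background = b)
}

#' Full QC report for one ChIP dataset
#'
#' @param reads ChIP \code{read_set}
#' @param peaks called peaks for FRiP
#' @param max_shift see [cross_correlation_profile()]
#' @return list(frip, profile, nsc, rsc, rsc_raw, frag_len_estimate)
#' @export
chip_qc_report <- function(reads, peaks, max_shift = 400L) {
  prof <- cross_correlation_profile(reads, max_shift = max_shift)
  m <- nsc_rsc(prof)
  c(list(frip = frip(reads, peaks), profile = prof), m)
}
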