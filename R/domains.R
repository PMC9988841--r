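#' Chromosome arm/center domain table
#'
#' In holocentric nematode chromosomes, heterochromatin is not pericentric but
#' concentrated on the distal chromosome arms; most association analyses in
#' this package are therefore stratified into arm vs center domains. A domain
#' table holds, per chromosome, the 0-based half-open boundaries
#' \code{[0, a)} (left arm), \code{[a, b)} (center) and \code{[b, L)} (right
#' arm), which tile the chromosome exactly.
#'
#' @param chrom chromosome ids
#' @param arm_end left-arm end \code{a} (0-based, exclusive)
#' @param center_end center end \code{b}
#' @param length chromosome length \code{L}
#' @return a data.frame of class \code{chrom_domains}
#' @export
chromosome_domains <- function(chrom, arm_end, center_end, length) {
  d <- data.frame(chrom = as.character(chrom),
                  arm_end = as.numeric(arm_end),
                  center_end = as.numeric(center_end),
                  length = as.numeric(length),
                  stringsAsFactors = FALSE)
  bad <- with(d, !(arm_end > 0 & center_end > arm_end & length > center_end))
  if (any(bad))
    stopf("invalid domain boundaries (need 0 < a < b < L) for: %s",
          paste(d$chrom[bad], collapse = ", "))
  if (anyDuplicated(d$chrom)) stopf("duplicated chromosome in domain table")
  class(d) <- c("chrom_domains", "data.frame")
  d
}

#' Read / write a domain boundary table (TSV with header)
#'
#' Columns: chrom, arm_end, center_end, length.
#' @param path file path
#' @return a \code{chrom_domains} table
#' @export
read_domains <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t")
  chromosome_domains(dt$chrom, dt$arm_end, dt$center_end, dt$length)
}

#' @rdname read_domains
#' @param domains a \code{chrom_domains} table
#' @export
write_domains <- function(domains, path) {
  fwrite(as.data.table(unclass(domains)[c("chrom", "arm_end", "center_end",
                                          "length")]),
         path, sep = "\t")
  invisible(path)
}

#' Domain segments as GRanges
#'
#' @param domains a \code{chrom_domains} table
#' @param class "arm" (left and right arms as separate segments), "center",
#'   or "whole" (entire chromosomes)
#' @return GRanges with mcols \code{segment} (unique id) and \code{class}
#' @export
domain_segments <- function(domains, class = c("arm", "center", "whole")) {
  class <- match.arg(class)
  d <- domains
  gr <- switch(class,
    arm = GenomicRanges::GRanges(
      rep(d$chrom, 2),
      IRanges::IRanges(start = c(rep(1, nrow(d)), d$center_end + 1),
                       end = c(d$arm_end, d$length))),
    center = GenomicRanges::GRanges(
      d$chrom, IRanges::IRanges(d$arm_end + 1, d$center_end)),
    whole = GenomicRanges::GRanges(
      d$chrom, IRanges::IRanges(1, d$length)))
  side <- switch(class,
                 arm = rep(c("L", "R"), each = nrow(d)),
                 center = rep("C", nrow(d)),
                 whole = rep("W", nrow(d)))
  mcols(gr)$segment <- paste0(as.character(seqnames(gr)), ":", side)
  mcols(gr)$class <- class
  GenomicRanges::sort(gr)
}

#' Assign peaks to arm or center domains
#'
#' Each peak is assigned by its midpoint (0-based position
#' \code{floor((start+end)/2)}; a midpoint exactly at a boundary falls in the
#' right-hand, half-open domain). Counts are conserved exactly:
#' |arm| + |center| = |input|.
#'
#' @param peaks a peak set
#' @param domains a \code{chrom_domains} table
#' @return list with elements \code{arm}, \code{center} (peak subsets),
#'   \code{arm_fraction}, and per-peak \code{class} vector
#' @export
partition_by_domain <- function(peaks, domains) {
  chr <- as.character(seqnames(peaks))
  missing_chr <- setdiff(unique(chr), domains$chrom)
  if (length(missing_chr))
    stopf("no domain coordinates for chromosome(s): %s",
          paste(missing_chr, collapse = ", "))
  idx <- match(chr, domains$chrom)
  mid0 <- floor((GenomicRanges::start(peaks) - 1 + GenomicRanges::end(peaks)) / 2)
  is_arm <- mid0 < domains$arm_end[idx] | mid0 >= domains$center_end[idx]
  cls <- ifelse(is_arm, "arm", "center")
  list(arm = peaks[is_arm],
       center = peaks[!is_arm],
       arm_fraction = if (length(peaks)) mean(is_arm) else NA_real_,
       class = cls)
}
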