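#' Construct a peak set
#'
#' A peak set is a \link[GenomicRanges]{GRanges} (1-based, closed, the
#' Bioconductor convention; converted from 0-based half-open BED on import)
#' carrying the sample name and developmental-stage tag in its metadata and,
#' optionally, a per-peak summit (mcol \code{summit}, absolute 1-based
#' position) used as the reference point.
#'
#' @param gr a GRanges (or a data.frame with chrom/start/end in BED
#'   coordinates)
#' @param sample sample (factor) name
#' @param stage developmental stage tag, one of "E" (embryo), "L" (larval),
#'   "A" (adult), or NA
#' @param sort sort by (chrom, start)? Default TRUE.
#' @return a GRanges with metadata \code{sample}, \code{stage}
#' @export
peak_set <- function(gr, sample = "sample", stage = NA_character_, sort = TRUE) {
  if (is.data.frame(gr)) {
    gr <- GenomicRanges::GRanges(gr$chrom,
                                 IRanges::IRanges(gr$start + 1L, gr$end))
  }
  if (!is.na(stage) && !stage %in% c("E", "L", "A"))
    stopf("stage must be one of E, L, A (got '%s')", stage)
  if (sort) gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  metadata(gr)$sample <- sample
  metadata(gr)$stage <- stage
  gr
}

#' Read a peak file (BED or narrowPeak)
#'
#' Coordinates on disk are 0-based half-open (BED convention) and converted to
#' 1-based GRanges. Records with start >= end are rejected with a logged
#' warning; otherwise malformed lines raise a parse error naming the line.
#' For narrowPeak input the summit column (10th, 0-based offset from start) is
#' retained as the per-peak reference point when >= 0.
#'
#' @param path file path
#' @param format "bed" or "narrowPeak"
#' @param sample,stage passed to [peak_set()]; sample defaults to the file
#'   base name
#' @return a peak set (GRanges)
#' @export
read_intervals <- function(path, format = c("bed", "narrowPeak"),
                           sample = NULL, stage = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("peak file not found: %s", path)
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
              colClasses = list(character = 1))
  min_cols <- if (format == "narrowPeak") 10L else 3L
  if (ncol(dt) < min_cols)
    stopf("%s: expected >= %d tab-separated columns for %s", path, min_cols, format)
  start <- suppressWarnings(as.integer(dt[[2]]))
  end <- suppressWarnings(as.integer(dt[[3]]))
  bad_parse <- which(is.na(start) | is.na(end))
  if (length(bad_parse))
    stopf("%s: non-numeric coordinates at line %d", path, bad_parse[1])
  bad <- which(start >= end | start < 0)
  if (length(bad)) {
    ca_log("warn", "%s: rejected %d record(s) with start >= end or start < 0 (first at line %d)",
           path, length(bad), bad[1])
    dt <- dt[-bad]; start <- start[-bad]; end <- end[-bad]
  }
  gr <- GenomicRanges::GRanges(dt[[1]], IRanges::IRanges(start + 1L, end))
  if (ncol(dt) >= 4) mcols(gr)$name <- as.character(dt[[4]])
  if (ncol(dt) >= 5) mcols(gr)$score <- suppressWarnings(as.numeric(dt[[5]]))
  if (ncol(dt) >= 6) {
    str <- as.character(dt[[6]])
    str[!str %in% c("+", "-")] <- "*"
    GenomicRanges::strand(gr) <- str
  }
  if (format == "narrowPeak") {
    summit_off <- suppressWarnings(as.integer(dt[[10]]))
    summit <- ifelse(!is.na(summit_off) & summit_off >= 0,
                     start + summit_off + 1L, NA_integer_)
    mcols(gr)$summit <- summit
  }
  peak_set(gr, sample = sample %||% sub("\\.[^.]*$", "", basename(path)),
           stage = stage)
}

#' Write a peak set as BED (0-based half-open)
#'
#' @param peaks a peak set (GRanges)
#' @param path output path
#' @export
write_intervals <- function(peaks, path) {
  dt <- data.table(chrom = as.character(seqnames(peaks)),
                   start = GenomicRanges::start(peaks) - 1L,
                   end = GenomicRanges::end(peaks),
                   name = mcols(peaks)$name %||%
                     paste0("peak_", seq_along(peaks)),
                   score = mcols(peaks)$score %||% 0,
                   strand = as.character(GenomicRanges::strand(peaks)))
  dt$strand[dt$strand == "*"] <- "."
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Merge one or more interval sets into a disjoint union
#'
#' Returns the minimal sorted set of disjoint intervals covering exactly the
#' union of the inputs. Book-ended intervals (end of one equals start of the
#' next in BED coordinates) are merged, mirroring standard interval-union
#' semantics.
#'
#' @param ... GRanges objects (or a single list of them)
#' @return a sorted GRanges; empty input gives an empty GRanges
#' @export
merge_intervals <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "GRanges"))
    sets <- sets[[1]]
  sets <- Filter(Negate(is.null), sets)
  if (!length(sets)) return(GenomicRanges::GRanges())
  gr <- do.call(c, unname(lapply(sets, function(g) {
    g <- GenomicRanges::granges(g)
    GenomicRanges::strand(g) <- "*"
    g
  })))
  GenomicRanges::reduce(GenomicRanges::sort(gr), min.gapwidth = 1L)
}

#' Per-peak reference points
#'
#' The reference point is the narrowPeak summit when present (and not NA),
#' otherwise the interval midpoint, matching center-anchored profile
#' semantics. Positions are 1-based.
#'
#' @param peaks a peak set
#' @return integer vector of positions, one per peak
#' @export
reference_points <- function(peaks) {
  s0 <- GenomicRanges::start(peaks) - 1L   # 0-based
  e0 <- GenomicRanges::end(peaks)
  mid <- as.integer(floor((s0 + e0) / 2)) + 1L
  summit <- mcols(peaks)$summit
  if (is.null(summit)) return(mid)
  ifelse(is.na(summit), mid, as.integer(summit))
}
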