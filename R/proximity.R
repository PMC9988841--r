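#' Distance from a query interval to the nearest reference interval
#'
#' Distance is the bp gap between interval bounds: 0 when the query overlaps
#' or exactly abuts a reference, otherwise the smallest gap. Returns +Inf when
#' no reference lies on the query's chromosome.
#'
#' @param q a single-range GRanges (or a peak set; vectorised over queries)
#' @param refs reference GRanges
#' @return numeric vector of distances (bp), one per query
#' @export
nearest_distance <- function(q, refs) {
  out <- rep(Inf, length(q))
  if (!length(refs)) return(out)
  hits <- suppressWarnings(
    GenomicRanges::distanceToNearest(q, refs, ignore.strand = TRUE))
  out[queryHits(hits)] <- mcols(hits)$distance
  out
}

# Number of integer points in the union of closed intervals [lo_i, hi_i].
.int_union_len <- function(lo, hi) {
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  tot <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] > cur_hi) {
      tot <- tot + cur_hi - cur_lo + 1
      cur_lo <- lo[i]; cur_hi <- hi[i]
    } else if (hi[i] > cur_hi) cur_hi <- hi[i]
  }
  tot + cur_hi - cur_lo + 1
}

# Exact p-value for one query, all coordinates 0-based half-open.
# domain [d0, d1); query length L; refs as parallel vectors r0, r1 (clipped
# to the domain). Null: the query start s is uniform on the integers
# d0 .. d1 - L; p = #(placements with nearest gap <= d_obs) / #placements.
# A placement is within gap d of ref [r0, r1) iff s in [r0 - d - L, r1 + d];
# the favorable count is the size of the union of those integer ranges
# clipped to the feasible placements.
.prox_p_one <- function(d0, d1, L, r0, r1, d_obs) {
  total <- d1 - L - d0 + 1
  if (total <= 0) stopf("domain shorter than query")
  if (!length(r0)) return(1)
  if (!is.finite(d_obs)) return(1)
  lo <- pmax(r0 - d_obs - L, d0)
  hi <- pmin(r1 + d_obs, d1 - L)
  keep <- lo <= hi
  if (!any(keep)) return(1 / total)  # observed placement itself qualifies
  min(1, .int_union_len(lo[keep], hi[keep]) / total)
}

#' Proximity p-value of a query peak relative to a reference peak set
#'
#' The null model places the query uniformly over all integer start positions
#' that keep it inside its domain segment; the p-value is the fraction of
#' placements whose distance to the nearest reference is at most the observed
#' distance. Overlapping or book-ended placements have distance 0. p lies in
#' (0, 1], is an exact rational reported as a float, and is monotone
#' non-decreasing in the observed distance. No multiple-testing correction is
#' applied; downstream thresholds use raw p.
#'
#' @param q single-range GRanges, fully inside \code{domain}
#' @param refs reference GRanges (clipped to the domain internally)
#' @param domain single-range GRanges: the containing arm/center segment
#' @return p-value in (0, 1]
#' @export
proximity_pvalue <- function(q, refs, domain) {
  stopifnot(length(q) == 1, length(domain) == 1)
  d0 <- GenomicRanges::start(domain) - 1
  d1 <- GenomicRanges::end(domain)
  qs <- GenomicRanges::start(q) - 1; qe <- GenomicRanges::end(q)
  if (qs < d0 || qe > d1) stopf("query not contained in its domain segment")
  L <- qe - qs
  if (d1 - d0 <= L) stopf("domain shorter than query")
  refs <- refs[as.character(seqnames(refs)) == as.character(seqnames(domain))]
  refs <- IRanges::subsetByOverlaps(refs, domain, ignore.strand = TRUE)
  if (!length(refs)) {
    ca_log("warn", "no reference peaks in domain segment; p = 1")
    return(1)
  }
  r0 <- pmax(GenomicRanges::start(refs) - 1, d0)
  r1 <- pmin(GenomicRanges::end(refs), d1)
  gap <- pmax(r0 - qe, qs - r1, 0)
  .prox_p_one(d0, d1, L, r0, r1, min(gap))
}

#' Fraction of query peaks significantly proximal to a reference set
#'
#' Restricts the query set to the chosen domain class (arm, center, or whole
#' chromosome; assignment by peak midpoint), tests every query peak within
#' its own containing domain segment against the references in that segment,
#' and reports the fraction with p < alpha. Swap query and reference to get
#' the other direction.
#'
#' @param query,refs peak sets (GRanges)
#' @param domains a \code{chrom_domains} table
#' @param alpha significance level on the raw per-peak p-value
#' @param domain_class "arm", "center" or "whole"
#' @return list(fraction, results = data.frame(chrom, start, end, segment,
#'   distance, p, significant))
#' @export
significant_fraction <- function(query, refs, domains, alpha = 0.05,
                                 domain_class = c("arm", "center", "whole")) {
  domain_class <- match.arg(domain_class)
  segs <- domain_segments(domains, domain_class)
  mid0 <- floor((GenomicRanges::start(query) - 1 + GenomicRanges::end(query)) / 2)
  mid_pts <- GenomicRanges::GRanges(seqnames(query),
                                    IRanges::IRanges(mid0 + 1, width = 1L))
  hit <- GenomicRanges::findOverlaps(mid_pts, segs, ignore.strand = TRUE)
  keep <- queryHits(hit)
  if (!length(keep)) stopf("empty query class '%s'", domain_class)
  q <- query[keep]
  seg_of <- subjectHits(hit)

  n <- length(q)
  p <- numeric(n); dist <- numeric(n)
  qs_all <- GenomicRanges::start(q) - 1
  qe_all <- GenomicRanges::end(q)
  ref_chr <- as.character(seqnames(refs))
  ref_s <- GenomicRanges::start(refs) - 1
  ref_e <- GenomicRanges::end(refs)
  seg_chr <- as.character(seqnames(segs))
  seg_s <- GenomicRanges::start(segs) - 1
  seg_e <- GenomicRanges::end(segs)
  for (si in unique(seg_of)) {
    d0 <- seg_s[si]; d1 <- seg_e[si]
    in_seg <- which(seg_of == si)
    rsel <- ref_chr == seg_chr[si] & ref_e > d0 & ref_s < d1
    if (!any(rsel)) {
      p[in_seg] <- 1; dist[in_seg] <- Inf
      next
    }
    r0 <- pmax(ref_s[rsel], d0)
    r1 <- pmin(ref_e[rsel], d1)
    for (i in in_seg) {
      qs <- max(qs_all[i], d0)
      qe <- min(qe_all[i], d1)   # clip boundary-spanning query
      L <- qe - qs
      gap <- pmax(r0 - qe, qs - r1, 0)
      dist[i] <- min(gap)
      p[i] <- .prox_p_one(d0, d1, L, r0, r1, dist[i])
    }
  }
  res <- data.frame(chrom = as.character(seqnames(q)),
                    start = GenomicRanges::start(q) - 1L,
                    end = GenomicRanges::end(q),
                    segment = mcols(segs)$segment[seg_of],
                    distance = dist, p = p,
                    significant = p < alpha,
                    stringsAsFactors = FALSE)
  list(fraction = mean(res$significant), results = res)
}
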