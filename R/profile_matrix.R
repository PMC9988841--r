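#' Reference-point profile matrix
#'
#' One row per peak, centered on its reference point (summit, else midpoint),
#' spanning +/- \code{flank} bp in \code{bin_size}-bp bins (default 300
#' columns of 20 bp across +/- 3 kb). Bin values are the mean signal over the
#' bin; windows truncated at chromosome edges are zero-padded and flagged.
#' Optional smoothing replaces each bin by the mean of itself and its two
#' neighbours (60 bp at the defaults).
#'
#' @param track a \code{signal_track} (typically BPM-normalized)
#' @param peaks a peak set with reference points
#' @param flank half-window in bp (default 3000)
#' @param bin_size bin width in bp (default 20)
#' @param smooth apply 3-bin smoothing? default FALSE
#' @return numeric matrix of class \code{profile_matrix} with attributes
#'   \code{bin_size}, \code{flank}, \code{truncated} (logical per row)
#' @export
compute_matrix <- function(track, peaks, flank = 3000L, bin_size = 20L,
                           smooth = FALSE) {
  ncols <- as.integer(2 * flank / bin_size)
  n <- length(peaks)
  mat <- matrix(0, nrow = n, ncol = ncols)
  truncated <- logical(n)
  rp <- reference_points(peaks)
  chr <- as.character(seqnames(peaks))
  off <- seq(0L, ncols - 1L) * bin_size
  for (ch in unique(chr)) {
    if (!ch %in% names(track$cov)) stopf("track lacks chromosome %s", ch)
    r <- track$cov[[ch]]
    L <- length(r)
    rows <- which(chr == ch)
    win_start <- rp[rows] - flank          # 1-based start of first bin
    bin_start <- rep(win_start, each = ncols) + rep(off, times = length(rows))
    bin_end <- bin_start + bin_size - 1L
    truncated[rows] <- win_start < 1 | (win_start + 2 * flank - 1) > L
    cs <- pmax(bin_start, 1L); ce <- pmin(bin_end, L)
    ok <- cs <= ce
    sums <- numeric(length(bin_start))
    if (any(ok)) {
      v <- IRanges::Views(r, start = cs[ok], end = ce[ok])
      sums[ok] <- IRanges::viewSums(v)
    }
    mat[rows, ] <- matrix(sums / bin_size, ncol = ncols, byrow = TRUE)
  }
  if (smooth && ncols >= 3) {
    sm <- mat
    sm[, 2:(ncols - 1)] <- (mat[, 1:(ncols - 2)] + mat[, 2:(ncols - 1)] +
                              mat[, 3:ncols]) / 3
    sm[, 1] <- (mat[, 1] + mat[, 2]) / 2
    sm[, ncols] <- (mat[, ncols - 1] + mat[, ncols]) / 2
    mat <- sm
  }
  structure(mat, bin_size = bin_size, flank = flank, truncated = truncated,
            class = c("profile_matrix", "matrix", "array"))
}

# mean pairwise cosine similarity among unit-normalised rows; 1-row clusters
# count as perfectly homogeneous, zero rows are excluded.
.mean_pairwise_cosine <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  m <- m[nrm > 0, , drop = FALSE]
  n <- nrow(m)
  if (n <= 1) return(1)
  u <- m / sqrt(rowSums(m^2))
  s <- colSums(u)
  (sum(s^2) - n) / (n * (n - 1))
}

#' Minimal-k homogeneity clustering of profile rows
#'
#' Runs k-means for each candidate k (fixed seed, 10 restarts, Euclidean on
#' rows scaled by their maximum so shape rather than amplitude drives the
#' clusters). A clustering is "homogeneous" when every cluster's mean
#' pairwise cosine similarity of row profiles is >= \code{theta_h}; the
#' chosen k is the smallest homogeneous one, else the largest candidate with
#' a warning. The homogeneity rule is a quantitative proxy for visual
#' "no heterogeneity within clusters" selection.
#'
#' @param mat a \code{profile_matrix} (>= 10 rows)
#' @param ks candidate cluster numbers (default 1:3)
#' @param theta_h within-cluster homogeneity threshold (default 0.8)
#' @param seed RNG seed for the k-means restarts
#' @return list(k, clusters = integer per row, homogeneous = logical per k)
#' @export
kmeans_min_k <- function(mat, ks = 1:3, theta_h = 0.8, seed = 1L) {
  if (nrow(mat) < 10) stopf("need >= 10 rows")
  mx <- apply(mat, 1, max)
  scaled <- mat / ifelse(mx > 0, mx, 1)
  res <- list(); homog <- logical(0)
  for (k in ks) {
    if (k > nrow(mat)) { ca_log("warn", "skipping k=%d > rows", k); next }
    n_distinct <- nrow(unique(scaled))
    if (k > n_distinct) { ca_log("warn", "skipping k=%d > distinct rows", k); next }
    cl <- if (k == 1) rep(1L, nrow(mat)) else {
      set.seed(seed)
      kmeans(scaled, centers = k, nstart = 10, iter.max = 50)$cluster
    }
    h <- all(vapply(split(seq_len(nrow(mat)), cl), function(i) {
      .mean_pairwise_cosine(scaled[i, , drop = FALSE]) >= theta_h
    }, logical(1)))
    res[[as.character(k)]] <- cl
    homog[as.character(k)] <- h
  }
  pick <- names(homog)[homog][1]
  if (is.na(pick)) {
    ca_log("warn", "no homogeneous clustering among ks; using max k")
    pick <- tail(names(res), 1)
  }
  list(k = as.integer(pick), clusters = res[[pick]], homogeneous = homog)
}

#' Genome-wide background signal level
#'
#' Median of per-bin values across the whole track, used as the background
#' for coverage calls.
#'
#' @param track a \code{signal_track}
#' @param bin_size bin width in bp
#' @return scalar background level
#' @export
track_background <- function(track, bin_size = 20L) {
  vals <- unlist(lapply(track$cov, function(r) {
    starts <- seq(1L, length(r), by = bin_size)
    v <- IRanges::Views(r, start = starts,
                        end = pmin(starts + bin_size - 1L, length(r)))
    IRanges::viewMeans(v)
  }), use.names = FALSE)
  median(vals)
}

#' Per-row coverage calls from a profile matrix
#'
#' A row (peak) is "covered" by the mark when its mean signal over the
#' central +/- \code{center_bp} (default 500 bp, i.e. 50 bins at 20 bp)
#' exceeds \code{fold} times the genome-wide background; the pair-level
#' heatmap-overlap flag fires when at least \code{tau} of rows are covered.
#' Raising every row's center signal can never turn covered rows uncovered.
#'
#' @param mat a \code{profile_matrix}
#' @param background scalar background level (see [track_background()])
#' @param fold fold over background required (default 2)
#' @param tau row fraction required for the pair-level flag (default 0.5)
#' @param center_bp half-width of the central window in bp
#' @return list(covered = logical per row, covered_count, fraction,
#'   heatmap_overlap_detected)
#' @export
coverage_call <- function(mat, background, fold = 2, tau = 0.5,
                          center_bp = 500L) {
  bin_size <- attr(mat, "bin_size")
  ncols <- ncol(mat)
  k <- max(1L, as.integer(center_bp / bin_size))
  ctr <- ncols / 2
  cols <- max(1L, ctr - k + 1L):min(ncols, ctr + k)
  center_mean <- rowMeans(mat[, cols, drop = FALSE])
  covered <- center_mean > background * fold
  frac <- if (nrow(mat)) mean(covered) else 0
  list(covered = covered, covered_count = sum(covered), fraction = frac,
       heatmap_overlap_detected = frac >= tau)
}
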