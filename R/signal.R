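#' Construct a signal track
#'
#' A signal track is a per-chromosome run-length encoded, piecewise-constant,
#' non-negative coverage (uncovered bases are implicitly 0) together with its
#' normalization state ("raw" or "BPM").
#'
#' @param cov a named \code{RleList}-like list of per-chromosome
#'   \code{S4Vectors::Rle} vectors spanning the full chromosome, or a GRanges
#'   with a \code{score} mcol (bedGraph style) plus \code{seqlengths}
#' @param seqlengths named chromosome lengths (required for GRanges input
#'   lacking them)
#' @param normalization "raw" or "BPM"
#' @return object of class \code{signal_track}
#' @export
signal_track <- function(cov, seqlengths = NULL, normalization = "raw") {
  if (inherits(cov, "GRanges")) {
    sl <- seqlengths %||% seqlengths(cov)
    if (anyNA(sl) || is.null(sl) || !length(sl))
      stopf("seqlengths required to build a track from GRanges")
    score <- mcols(cov)$score %||% rep(1, length(cov))
    if (any(score < 0)) stopf("track values must be >= 0")
    cov <- GenomicRanges::coverage(cov, weight = score)
    cov <- cov[names(sl)]
    for (ch in names(sl)) {
      if (length(cov[[ch]]) < sl[[ch]])
        cov[[ch]] <- c(cov[[ch]], Rle(0, sl[[ch]] - length(cov[[ch]])))
    }
  }
  structure(list(cov = cov, normalization = normalization),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track (%s): %d chromosome(s), %.0f bp\n",
              x$normalization, length(x$cov),
              sum(vapply(x$cov, length, numeric(1)))))
  invisible(x)
}

track_seqlengths <- function(track) {
  vapply(track$cov, length, numeric(1))
}

#' Read / write bedGraph tracks
#'
#' bedGraph is 0-based half-open; values of uncovered bases are 0.
#'
#' @param path file path
#' @param seqlengths named chromosome lengths; defaults to the last covered
#'   position per chromosome
#' @return a \code{signal_track}
#' @export
read_bedgraph <- function(path, seqlengths = NULL) {
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "start", "end", "value"))
  if (any(dt$value < 0)) stopf("%s: negative bedGraph values", path)
  gr <- GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$start + 1L, dt$end))
  mcols(gr)$score <- dt$value
  sl <- seqlengths %||% tapply(dt$end, dt$chrom, max)
  signal_track(gr, seqlengths = sl[unique(dt$chrom)])
}

#' @rdname read_bedgraph
#' @param track a \code{signal_track}
#' @export
write_bedgraph <- function(track, path) {
  rows <- lapply(names(track$cov), function(ch) {
    r <- track$cov[[ch]]
    ends <- cumsum(runLength(r))
    data.table(chrom = ch, start = c(0, head(ends, -1)), end = ends,
               value = runValue(r))
  })
  dt <- data.table::rbindlist(rows)
  fwrite(dt[dt$value != 0], path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Bins-per-million (BPM) normalization
#'
#' Averages the track into fixed-size bins and rescales so the bin values sum
#' to 1e6 genome-wide, the standard BPM track normalization. The result is a
#' piecewise-constant track at bin resolution.
#'
#' @param track a raw \code{signal_track}
#' @param bin_size bin width in bp (default 20)
#' @return a \code{signal_track} with normalization "BPM"
#' @export
bpm_normalize <- function(track, bin_size = 20L) {
  if (track$normalization != "raw") stopf("track already normalized")
  binned <- lapply(track$cov, function(r) {
    L <- length(r)
    starts <- seq(1L, L, by = bin_size)
    v <- IRanges::Views(r, start = starts,
                        end = pmin(starts + bin_size - 1L, L))
    IRanges::viewMeans(v)
  })
  tot <- sum(vapply(binned, sum, numeric(1)))
  if (tot <= 0) stopf("empty coverage")
  cov <- lapply(names(binned), function(ch) {
    L <- length(track$cov[[ch]])
    w <- rep(bin_size, length(binned[[ch]]))
    w[length(w)] <- L - bin_size * (length(w) - 1L)
    Rle(binned[[ch]] * 1e6 / tot, w)
  })
  names(cov) <- names(binned)
  structure(list(cov = cov, normalization = "BPM", bin_size = bin_size),
            class = "signal_track")
}

#' Percentile signal over loci
#'
#' Extracts, for each locus, the q-th percentile of the per-base signal
#' (linear interpolation between order statistics, the common numerics
#' default). Bases outside covered runs count as 0; q = 100 gives the locus
#' maximum and q = 0 the minimum.
#'
#' @param track a \code{signal_track}
#' @param loci GRanges (e.g. merged peaks)
#' @param q percentile in [0, 100]; default 95
#' @param sample_id label recorded on the result
#' @return a \code{signal_vector} (see [signal_vector()]) in state "raw95"
#' @export
percentile_signal <- function(track, loci, q = 95, sample_id = "sample") {
  if (any(IRanges::width(loci) < 1)) stopf("zero-length locus")
  vals <- numeric(length(loci))
  chr <- as.character(seqnames(loci))
  for (ch in unique(chr)) {
    if (!ch %in% names(track$cov)) stopf("track lacks chromosome %s", ch)
    r <- track$cov[[ch]]
    idx <- which(chr == ch)
    st <- pmax(GenomicRanges::start(loci)[idx], 1L)
    en <- pmin(GenomicRanges::end(loci)[idx], length(r))
    v <- IRanges::Views(r, start = st, end = en)
    vals[idx] <- IRanges::viewApply(v, function(x) {
      quantile(as.numeric(x), q / 100, names = FALSE, type = 7)
    }, simplify = TRUE)
  }
  signal_vector(sample_id, vals, state = "raw95")
}

#' Per-sample signal vector over a fixed locus list
#'
#' Tracks the processing state: "raw95" (percentile extraction) ->
#' "inputNorm" (input ratio) -> "logZ" (log-transformed, Z-scored). State
#' transitions are enforced in that order.
#'
#' @param sample_id sample label
#' @param values numeric vector, one value per locus
#' @param state processing state
#' @return object of class \code{signal_vector}
#' @export
signal_vector <- function(sample_id, values,
                          state = c("raw95", "inputNorm", "logZ")) {
  state <- match.arg(state)
  structure(list(sample = sample_id, values = as.numeric(values),
                 state = state),
            class = "signal_vector")
}

#' @export
print.signal_vector <- function(x, ...) {
  cat(sprintf("signal_vector '%s' (%s): %d loci\n", x$sample, x$state,
              length(x$values)))
  invisible(x)
}

#' Input normalization, log transform and Z-scoring
#'
#' Computes x_i = log2((s_i + eps) / (i_i + eps)) over the shared locus list
#' and standardizes to mean 0, sd 1. The pseudocount eps (default 1 coverage
#' unit) guards zero-input loci; log base 2 is pinned for reproducibility
#' (the base cancels after Z-scoring up to the sd rescaling).
#'
#' @param signal,input \code{signal_vector}s in state "raw95" over the same
#'   loci
#' @param eps pseudocount, > 0
#' @return a \code{signal_vector} in state "logZ"
#' @export
input_normalize_log_z <- function(signal, input, eps = 1) {
  stopifnot(inherits(signal, "signal_vector"), inherits(input, "signal_vector"))
  if (length(signal$values) != length(input$values))
    stopf("signal and input cover different locus lists")
  if (eps <= 0) stopf("eps must be > 0")
  x <- log2((signal$values + eps) / (input$values + eps))
  s <- sd(x)
  if (!is.finite(s) || s == 0) stopf("degenerate signal (zero variance)")
  signal_vector(signal$sample, (x - mean(x)) / s, state = "logZ")
}

#' Pairwise Pearson correlation matrix of signal vectors
#'
#' @param vectors list of \code{signal_vector}s in state "logZ" over the same
#'   loci (>= 3 loci)
#' @return symmetric correlation matrix with unit diagonal, dimnames from the
#'   sample labels
#' @export
pearson_matrix <- function(vectors) {
  states <- vapply(vectors, function(v) v$state, character(1))
  if (!all(states == "logZ")) stopf("all vectors must be in logZ state")
  lens <- vapply(vectors, function(v) length(v$values), integer(1))
  if (length(unique(lens)) != 1) stopf("locus-list length mismatch")
  if (lens[1] < 3) stopf("need >= 3 loci")
  m <- vapply(vectors, function(v) v$values, numeric(lens[1]))
  colnames(m) <- vapply(vectors, function(v) v$sample, character(1))
  cor(m, method = "pearson")
}

#' Complete-linkage hierarchical clustering of a correlation matrix
#'
#' Distance is 1 - r; the agglomeration method is "complete" (maximum
#' pairwise distance between clusters). Returns the merge tree and the
#' deterministic leaf order.
#'
#' @param corr symmetric correlation matrix
#' @return list(tree = hclust object, leaf_order = character labels)
#' @export
hcluster_samples <- function(corr) {
  if (!isSymmetric(unname(corr), tol = 1e-8)) stopf("non-symmetric matrix")
  tree <- hclust(as.dist(1 - corr), method = "complete")
  list(tree = tree, leaf_order = tree$labels[tree$order])
}

#' Export a clustering dendrogram as Newick
#'
#' @param clust result of [hcluster_samples()]
#' @param path output path
#' @export
write_newick <- function(clust, path) {
  phy <- ape::as.phylo(clust$tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
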