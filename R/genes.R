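#' Gene models
#'
#' A light container for gene structures: the gene span (with strand and
#' TSS), its exons, and derived introns (the gaps between consecutive exons).
#'
#' @param genes GRanges with mcol \code{gene_id} and proper strand; the TSS is
#'   the strand-aware 5' end
#' @param exons GRanges with mcol \code{gene_id}; exons of one gene must be
#'   non-overlapping
#' @return object of class \code{gene_models} with elements \code{genes},
#'   \code{exons}, \code{introns}
#' @export
gene_models <- function(genes, exons) {
  if (is.null(mcols(genes)$gene_id) || is.null(mcols(exons)$gene_id))
    stopf("genes and exons need a gene_id metadata column")
  exons <- GenomicRanges::sort(exons, ignore.strand = TRUE)
  ex_by <- GenomicRanges::split(GenomicRanges::granges(exons),
                                mcols(exons)$gene_id)
  red <- GenomicRanges::reduce(ex_by)
  if (!all(S4Vectors::elementNROWS(red) == S4Vectors::elementNROWS(ex_by)))
    stopf("overlapping exons within a gene")
  span_by <- unlist(range(ex_by))
  introns <- unlist(GenomicRanges::psetdiff(span_by, ex_by))
  mcols(introns)$gene_id <- names(introns)
  names(introns) <- NULL
  structure(list(genes = GenomicRanges::sort(genes, ignore.strand = TRUE),
                 exons = exons, introns = introns),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exons, %d introns\n",
              length(x$genes), length(x$exons), length(x$introns)))
  invisible(x)
}

#' Transcription start sites
#' @param models a \code{gene_models} object
#' @return GRanges of width-1 TSS positions (strand-aware 5' ends)
#' @export
tss_positions <- function(models) {
  GenomicRanges::resize(models$genes, width = 1L, fix = "start")
}

#' Promoter windows
#'
#' Strand-aware window \code{[TSS - upstream, TSS + downstream)} (BED
#' coordinates). The defaults (1000 bp upstream, 100 bp downstream) are
#' configurable; histone-mark overlap elsewhere in the package ignores
#' strand, but promoters honour it.
#'
#' @param models a \code{gene_models} object
#' @param upstream,downstream window extent in bp
#' @return GRanges with mcol \code{gene_id}
#' @export
promoter_windows <- function(models, upstream = 1000L, downstream = 100L) {
  p <- GenomicRanges::promoters(models$genes, upstream = upstream,
                                downstream = downstream)
  GenomicRanges::trim(p)
}

#' Read gene models from BED12 or GFF3
#'
#' BED12 blocks become exons (0-based half-open on disk). GFF3 (1-based
#' inclusive) is converted on read; features of type "gene" define spans and
#' "exon" features are attached to their gene via the Parent/ID chain or a
#' \code{gene_id} attribute.
#'
#' @param path file path
#' @param format "bed12" or "gff3"
#' @return a \code{gene_models} object
#' @export
read_gene_models <- function(path, format = c("bed12", "gff3")) {
  format <- match.arg(format)
  if (format == "bed12") {
    dt <- fread(path, header = FALSE, sep = "\t")
    if (ncol(dt) < 12) stopf("%s: BED12 needs 12 columns", path)
    chrom <- as.character(dt[[1]]); start0 <- as.integer(dt[[2]])
    gid <- as.character(dt[[4]]); strand <- as.character(dt[[6]])
    genes <- GenomicRanges::GRanges(chrom,
                IRanges::IRanges(start0 + 1L, as.integer(dt[[3]])),
                strand = ifelse(strand %in% c("+", "-"), strand, "*"))
    mcols(genes)$gene_id <- gid
    sizes <- lapply(strsplit(as.character(dt[[11]]), ","), as.integer)
    offs <- lapply(strsplit(as.character(dt[[12]]), ","), as.integer)
    nblk <- lengths(sizes)
    ex <- GenomicRanges::GRanges(rep(chrom, nblk),
            IRanges::IRanges(rep(start0, nblk) + unlist(offs) + 1L,
                             width = unlist(sizes)),
            strand = rep(GenomicRanges::strand(genes), nblk))
    mcols(ex)$gene_id <- rep(gid, nblk)
    gene_models(genes, ex)
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stopf("GFF3 input requires the rtracklayer package")
    g <- rtracklayer::import(path, format = "gff3")
    genes <- g[g$type == "gene"]
    mcols(genes) <- S4Vectors::DataFrame(
      gene_id = as.character(genes$ID %||% genes$gene_id))
    ex <- g[g$type == "exon"]
    parent <- if (!is.null(ex$Parent)) as.character(unlist(ex$Parent))
              else as.character(ex$gene_id)
    mcols(ex) <- S4Vectors::DataFrame(gene_id = parent)
    gene_models(genes, ex)
  }
}

#' Annotate peaks with genomic features
#'
#' Labels every peak's reference point (summit, else midpoint) as promoter,
#' exon, intron, or intergenic with priority promoter > exon > intron;
#' the summary fractions sum to 1.
#'
#' @param peaks a peak set
#' @param models a \code{gene_models} object
#' @param upstream,downstream promoter window, see [promoter_windows()]
#' @return list(labels = per-peak character, fractions = named numeric)
#' @export
assign_feature <- function(peaks, models, upstream = 1000L, downstream = 100L) {
  pts <- GenomicRanges::GRanges(seqnames(peaks),
                                IRanges::IRanges(reference_points(peaks),
                                                 width = 1L))
  lab <- rep("intergenic", length(peaks))
  hit <- function(subject) {
    IRanges::overlapsAny(pts, subject, ignore.strand = TRUE)
  }
  lab[hit(models$introns)] <- "intron"
  lab[hit(models$exons)] <- "exon"
  lab[hit(promoter_windows(models, upstream, downstream))] <- "promoter"
  lv <- c("promoter", "exon", "intron", "intergenic")
  frac <- if (length(peaks)) as.numeric(table(factor(lab, lv)) / length(peaks))
          else rep(NA_real_, 4)
  list(labels = lab, fractions = setNames(frac, lv))
}

#' Classify genes as actively transcribed or silent
#'
#' A gene is \emph{active} iff FPKM >= 1 and it is occupied by a euchromatin
#' mark (H3K4me3, H3K36me3 or H3K79me3); \emph{silent} iff FPKM < 1 and
#' occupied by a heterochromatin mark (H3K9me2/3, H3K27me3); otherwise
#' unclassified. Genes missing from the FPKM table are treated as FPKM 0 and
#' logged.
#'
#' @param gene_ids character vector of genes to classify
#' @param fpkm named numeric vector (gene id -> FPKM)
#' @param eu_occupied,het_occupied named or parallel logical vectors
#' @return data.frame(gene_id, fpkm, label)
#' @export
classify_gene_activity <- function(gene_ids, fpkm, eu_occupied, het_occupied) {
  f <- fpkm[gene_ids]
  if (anyNA(f)) {
    ca_log("warn", "%d gene(s) missing from FPKM table; treated as 0",
           sum(is.na(f)))
    f[is.na(f)] <- 0
  }
  if (any(f < 0)) stopf("negative FPKM values")
  pick <- function(v) {
    if (!is.null(names(v))) v <- v[gene_ids]
    v[is.na(v)] <- FALSE
    as.logical(v)
  }
  eu <- pick(eu_occupied); het <- pick(het_occupied)
  label <- ifelse(f >= 1 & eu, "active",
                  ifelse(f < 1 & het, "silent", "unclassified"))
  data.frame(gene_id = gene_ids, fpkm = as.numeric(f), label = label,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Overlap of peaks with repeat families
#'
#' A peak counts toward family f when it overlaps >= 1 bp of any repeat of
#' that family (a peak touching two families counts once per family). The
#' peak-level fraction is the share of peaks overlapping at least one repeat
#' of any family.
#'
#' @param peaks a peak set
#' @param repeats GRanges with mcol \code{family}
#' @return list(per_family = named counts, fraction = scalar)
#' @export
repeat_family_overlap <- function(peaks, repeats) {
  fams <- unique(as.character(mcols(repeats)$family %||% character()))
  if (!length(repeats) || !length(fams))
    return(list(per_family = setNames(integer(0), character(0)),
                fraction = 0))
  ov <- GenomicRanges::findOverlaps(peaks, repeats, ignore.strand = TRUE)
  fam_hit <- as.character(mcols(repeats)$family)[subjectHits(ov)]
  per_family <- vapply(fams, function(f) {
    length(unique(queryHits(ov)[fam_hit == f]))
  }, integer(1))
  frac <- if (length(peaks)) length(unique(queryHits(ov))) / length(peaks) else 0
  list(per_family = per_family, fraction = frac)
}

#' Read an FPKM table (TSV: gene_id, fpkm)
#' @param path file path
#' @return named numeric vector
#' @export
read_fpkm <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t")
  setNames(as.numeric(dt[[2]]), as.character(dt[[1]]))
}

#' Read a repeat annotation BED with family labels in column 4
#' @param path file path
#' @return GRanges with mcol \code{family}
#' @export
read_repeats <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  gr <- GenomicRanges::GRanges(dt[[1]], IRanges::IRanges(dt[[2]] + 1L, dt[[3]]))
  mcols(gr)$family <- if (ncol(dt) >= 4) as.character(dt[[4]]) else "repeat"
  GenomicRanges::sort(gr)
}
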