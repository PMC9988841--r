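#' Grade one reader x mark pair within a domain class
#'
#' Runs the three association read-outs for a single pair: (1) Pearson
#' correlation of input-normalized, log-transformed, Z-scored 95th-percentile
#' signals over the merged reader+mark peaks of the chosen domain class;
#' (2) the fraction of the reader's peaks significantly proximal to the mark
#' (raw p < alpha under the domain-restricted uniform-placement null);
#' (3) the heatmap coverage flag from the reference-point profile matrix of
#' mark signal over reader peaks. The three are combined by
#' [grade_association()].
#'
#' @param reader,mark lists with elements \code{peaks} (peak set) and
#'   \code{track} (raw \code{signal_track})
#' @param input_track matched input \code{signal_track} (raw)
#' @param domains a \code{chrom_domains} table
#' @param domain_class "arm" or "center"
#' @param alpha per-peak significance level
#' @param r0,f0 grading thresholds
#' @param fold,tau coverage-call parameters
#' @param q percentile for signal extraction
#' @param eps pseudocount for input normalization
#' @param flank,bin_size profile-matrix geometry
#' @param loci optional GRanges of combined peaks over which the correlation
#'   is computed. The correlation procedure merges peaks called from
#'   \emph{any} dataset in the panel and correlates signals over that union,
#'   so when grading one pair out of a panel, pass the panel-wide merged
#'   peaks here; the default falls back to the union of the pair's own peaks
#' @return one-row data.frame as returned by [grade_association()]
#' @export
grade_pair <- function(reader, mark, input_track, domains,
                       domain_class = "arm", alpha = 0.05,
                       r0 = 0.300, f0 = 0.30, fold = 2, tau = 0.5,
                       q = 95, eps = 1, flank = 3000L, bin_size = 20L,
                       loci = NULL) {
  reader_bpm <- bpm_normalize(reader$track, bin_size)
  mark_bpm <- bpm_normalize(mark$track, bin_size)
  input_bpm <- bpm_normalize(input_track, bin_size)

  if (is.null(loci)) loci <- merge_intervals(reader$peaks, mark$peaks)
  loci <- partition_by_domain(loci, domains)[[domain_class]]
  r <- if (length(loci) >= 3) {
    sv <- lapply(list(reader = reader_bpm, mark = mark_bpm,
                      input = input_bpm), percentile_signal,
                 loci = loci, q = q)
    z_reader <- input_normalize_log_z(sv$reader, sv$input, eps = eps)
    z_mark <- input_normalize_log_z(sv$mark, sv$input, eps = eps)
    cor(z_reader$values, z_mark$values)
  } else NA_real_

  sig <- significant_fraction(reader$peaks, mark$peaks, domains,
                              alpha = alpha, domain_class = domain_class)

  rpk <- partition_by_domain(reader$peaks, domains)[[domain_class]]
  pm <- compute_matrix(mark_bpm, rpk, flank = flank, bin_size = bin_size)
  bg <- track_background(mark_bpm, bin_size)
  cc <- coverage_call(pm, background = bg, fold = fold, tau = tau)

  grade_association(r = if (is.na(r)) 0 else r,
                    sig_fraction = sig$fraction,
                    heatmap_flag = cc$heatmap_overlap_detected,
                    r0 = r0, f0 = f0,
                    reader = metadata(reader$peaks)$sample %||% "reader",
                    mark = metadata(mark$peaks)$sample %||% "mark",
                    domain_class = domain_class)
}

.resolve_peaks <- function(x, nm) {
  if (inherits(x, "GRanges")) return(x)
  if (is.character(x)) {
    fmt <- if (grepl("narrowPeak$", x)) "narrowPeak" else "bed"
    return(read_intervals(x, format = fmt, sample = nm))
  }
  stopf("cannot resolve peak set '%s'", nm)
}

.resolve_track <- function(x, nm, seqlengths = NULL) {
  if (inherits(x, "signal_track")) return(x)
  if (is.character(x)) return(read_bedgraph(x, seqlengths = seqlengths))
  stopf("cannot resolve track '%s'", nm)
}

#' Run the full association pipeline
#'
#' Executes, in order: arm/center partitioning of every factor; pairwise
#' reader x mark grading in both domain classes; the percentile-signal
#' correlation matrix and complete-linkage clustering across all factors;
#' the colocalization network with Louvain communities; feature/repeat
#' annotation summaries (when gene models / repeats are supplied); gene
#' activity calls (when an FPKM table is supplied); and ChIP QC (when read
#' sets are supplied). All stage tables are written as TSV next to a JSON
#' summary that embeds the fully resolved parameter set and a config hash;
#' identical inputs, parameters and seed reproduce the summary byte for
#' byte.
#'
#' @param config list with fields: \code{peaks} (named list of peak sets or
#'   paths), \code{tracks} (named list, same names), \code{input_track},
#'   \code{domains} (table or path), \code{readers}, \code{marks} (character
#'   vectors naming entries of \code{peaks}), optional \code{genes},
#'   \code{repeats}, \code{fpkm}, \code{mark_types} (named "het"/"eu"),
#'   \code{reads} (named list of \code{read_set}s), and a \code{params} list
#'   overriding \code{alpha}, \code{r0}, \code{f0}, \code{fold}, \code{tau},
#'   \code{strong}, \code{moderate}, \code{q}, \code{eps}, \code{seed}
#' @param out_dir output directory
#' @return the summary list, invisibly; side effect: files under out_dir
#' @export
run_pipeline <- function(config, out_dir) {
  par <- modifyList(list(alpha = 0.05, r0 = 0.300, f0 = 0.30, fold = 2,
                         tau = 0.5, strong = 0.5, moderate = 0.25, q = 95,
                         eps = 1, seed = 1L, flank = 3000L, bin_size = 20L),
                    config$params %||% list())
  # fail fast: every referenced path must exist before any computation
  paths <- as.character(c(unlist(Filter(is.character, config$peaks)),
                          unlist(Filter(is.character, config$tracks)),
                          if (is.character(config$input_track))
                            config$input_track,
                          if (is.character(config$domains)) config$domains))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stopf("missing input file(s): %s",
                             paste(missing, collapse = ", "))
  domains <- if (is.character(config$domains)) read_domains(config$domains)
             else config$domains
  sl <- setNames(domains$length, domains$chrom)  # chrom sizes for bedGraphs
  nms <- names(config$peaks)
  peaks <- setNames(lapply(nms, function(n)
    .resolve_peaks(config$peaks[[n]], n)), nms)
  tracks <- setNames(lapply(nms, function(n)
    .resolve_track(config$tracks[[n]], n, sl)), nms)
  input_track <- .resolve_track(config$input_track, "input", sl)
  readers <- config$readers %||% nms
  marks <- config$marks %||% character(0)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  stage_log <- function(stage, n) {
    ca_log("info", "stage %-12s done (%d records, %.1fs elapsed)", stage, n,
           proc.time()[["elapsed"]] - t0)
  }

  partition <- do.call(rbind, lapply(nms, function(n) {
    pt <- partition_by_domain(peaks[[n]], domains)
    data.frame(factor = n, n_peaks = length(peaks[[n]]),
               n_arm = length(pt$arm), n_center = length(pt$center),
               arm_fraction = pt$arm_fraction, stringsAsFactors = FALSE)
  }))
  fwrite(as.data.table(partition), file.path(out_dir, "partition.tsv"),
         sep = "\t")
  stage_log("partition", nrow(partition))

  assoc <- NULL
  if (length(readers) && length(marks)) {
    loci_all <- merge_intervals(peaks)
    rows <- list()
    for (rd in readers) for (mk in marks) for (cls in c("arm", "center")) {
      rows[[length(rows) + 1]] <- tryCatch(
        grade_pair(list(peaks = peaks[[rd]], track = tracks[[rd]]),
                   list(peaks = peaks[[mk]], track = tracks[[mk]]),
                   input_track, domains, domain_class = cls,
                   alpha = par$alpha, r0 = par$r0, f0 = par$f0,
                   fold = par$fold, tau = par$tau, q = par$q, eps = par$eps,
                   flank = par$flank, bin_size = par$bin_size,
                   loci = loci_all),
        error = function(e) {
          ca_log("warn", "grading %s x %s (%s) failed: %s", rd, mk, cls,
                 conditionMessage(e))
          NULL
        })
    }
    assoc <- do.call(rbind, rows)
    if (!is.null(assoc))
      fwrite(as.data.table(assoc), file.path(out_dir, "association.tsv"),
             sep = "\t")
    stage_log("grading", NROW(assoc))
  }

  corr <- NULL; leaf_order <- NULL
  if (length(nms) >= 2) {
    loci <- merge_intervals(peaks)
    if (length(loci) >= 3) {
      input_bpm <- bpm_normalize(input_track, par$bin_size)
      sv_in <- percentile_signal(input_bpm, loci, q = par$q, "input")
      vecs <- lapply(nms, function(n) {
        input_normalize_log_z(
          percentile_signal(bpm_normalize(tracks[[n]], par$bin_size), loci,
                            q = par$q, sample_id = n),
          sv_in, eps = par$eps)
      })
      corr <- pearson_matrix(vecs)
      cl <- hcluster_samples(corr)
      leaf_order <- cl$leaf_order
      fwrite(data.table(sample = rownames(corr),
                        as.data.table(corr)),
             file.path(out_dir, "correlation.tsv"), sep = "\t")
      write_newick(cl, file.path(out_dir, "dendrogram.nwk"))
    }
    stage_log("correlate", length(nms))
  }

  network <- NULL; communities <- NULL; Q <- NA_real_
  if (length(nms) >= 2) {
    cand <- pairwise_overlap_stats(peaks, domains, alpha = par$alpha)
    roles <- setNames(ifelse(nms %in% marks, "mark",
                             ifelse(nms %in% readers, "reader", "other")),
                      nms)
    network <- build_network(cand, strong = par$strong,
                             moderate = par$moderate, roles = roles)
    lp <- louvain_partition(network, seed = par$seed)
    communities <- lp$membership; Q <- lp$Q
    write_network(network, file.path(out_dir, "network_edges.tsv"))
    stage_log("network", nrow(network$edges))
  }

  annotation <- NULL
  if (!is.null(config$genes)) {
    models <- if (is.character(config$genes))
      read_gene_models(config$genes) else config$genes
    annotation <- do.call(rbind, lapply(nms, function(n) {
      fr <- assign_feature(peaks[[n]], models)$fractions
      data.frame(factor = n, t(fr), stringsAsFactors = FALSE)
    }))
    fwrite(as.data.table(annotation), file.path(out_dir, "features.tsv"),
           sep = "\t")
    stage_log("annotate", NROW(annotation))
  }

  repeats_tbl <- NULL
  if (!is.null(config$repeats)) {
    reps <- if (is.character(config$repeats)) read_repeats(config$repeats)
            else config$repeats
    repeats_tbl <- do.call(rbind, lapply(nms, function(n) {
      ro <- repeat_family_overlap(peaks[[n]], reps)
      data.frame(factor = n, repeat_fraction = ro$fraction,
                 stringsAsFactors = FALSE)
    }))
    fwrite(as.data.table(repeats_tbl), file.path(out_dir, "repeats.tsv"),
           sep = "\t")
  }

  activity <- NULL
  if (!is.null(config$fpkm) && !is.null(config$genes) &&
      !is.null(config$mark_types)) {
    models <- if (is.character(config$genes))
      read_gene_models(config$genes) else config$genes
    fpkm <- if (is.character(config$fpkm)) read_fpkm(config$fpkm)
            else config$fpkm
    occ <- function(type) {
      sel <- names(config$mark_types)[config$mark_types == type]
      if (!length(sel)) return(setNames(
        rep(FALSE, length(models$genes)), mcols(models$genes)$gene_id))
      hits <- Reduce(`|`, lapply(sel, function(m)
        IRanges::overlapsAny(models$genes, peaks[[m]],
                                   ignore.strand = TRUE)))
      setNames(hits, mcols(models$genes)$gene_id)
    }
    activity <- classify_gene_activity(mcols(models$genes)$gene_id, fpkm,
                                       occ("eu"), occ("het"))
    fwrite(as.data.table(activity), file.path(out_dir, "activity.tsv"),
           sep = "\t")
  }

  qc <- NULL
  if (!is.null(config$reads)) {
    qc <- lapply(names(config$reads), function(n) {
      rep <- chip_qc_report(config$reads[[n]], peaks[[n]] %||%
                              GenomicRanges::GRanges())
      fwrite(as.data.table(rep$profile),
             file.path(out_dir, paste0("cc_profile_", n, ".tsv")), sep = "\t")
      list(sample = n, frip = rep$frip, nsc = rep$nsc, rsc = rep$rsc,
           frag_len_estimate = rep$frag_len_estimate)
    })
    names(qc) <- names(config$reads)
    stage_log("qc", length(qc))
  }

  resolved <- par[order(names(par))]
  summary <- list(
    params = resolved,
    config_hash = fnv1a32(paste(names(resolved),
                                vapply(resolved, format, character(1)),
                                collapse = ";")),
    partition = partition,
    association = assoc,
    correlation = if (!is.null(corr)) as.data.frame(corr) else NULL,
    leaf_order = leaf_order,
    network = if (!is.null(network)) list(
      edges = network$edges,
      communities = as.list(communities),
      modularity = Q) else NULL,
    annotation = annotation,
    repeats = repeats_tbl,
    activity_counts = if (!is.null(activity))
      as.list(table(activity$label)) else NULL,
    qc = qc)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  invisible(summary)
}
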