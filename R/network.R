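#' Pairwise colocalization statistics for a set of factors
#'
#' For every unordered pair of peak sets, computes both directional
#' significant-overlap fractions (via [significant_fraction()], raw p < alpha)
#' and a symmetric specificity weight, the minimum of the two directions:
#' the minimum penalizes one-sided engulfment of a small peak set by a large
#' one, so the weight reflects how specifically two factors co-bind.
#'
#' @param peak_sets named list of peak sets (>= 2)
#' @param domains a \code{chrom_domains} table
#' @param alpha per-peak significance level
#' @param domain_class stratum for the null model ("whole" by default:
#'   network edges are genome-wide)
#' @return data.frame(factor_a, factor_b, overlap_ab, overlap_ba, weight)
#' @export
pairwise_overlap_stats <- function(peak_sets, domains, alpha = 0.05,
                                   domain_class = "whole") {
  if (length(peak_sets) < 2) stopf("need >= 2 peak sets")
  if (is.null(names(peak_sets))) stopf("peak_sets must be named")
  nm <- names(peak_sets)
  pairs <- utils::combn(nm, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ab <- significant_fraction(peak_sets[[a]], peak_sets[[b]], domains,
                               alpha = alpha, domain_class = domain_class)$fraction
    ba <- significant_fraction(peak_sets[[b]], peak_sets[[a]], domains,
                               alpha = alpha, domain_class = domain_class)$fraction
    data.frame(factor_a = a, factor_b = b, overlap_ab = ab, overlap_ba = ba,
               weight = min(ab, ba), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build a tiered colocalization network
#'
#' Edges with specificity weight >= \code{strong} are tier "strong", >=
#' \code{moderate} are "moderate", weaker candidate pairs are omitted.
#' Factors without any retained edge stay in the node set as isolated nodes.
#'
#' @param candidates output of [pairwise_overlap_stats()]
#' @param strong,moderate tier thresholds on the specificity weight
#'   (strong > moderate)
#' @param roles optional named character vector tagging each factor
#'   (e.g. "reader", "mark")
#' @return object of class \code{coloc_network}: list(nodes, roles, edges)
#' @export
build_network <- function(candidates, strong = 0.5, moderate = 0.25,
                          roles = NULL) {
  if (strong <= moderate) stopf("need strong > moderate")
  nodes <- sort(unique(c(candidates$factor_a, candidates$factor_b)))
  e <- candidates[candidates$weight >= moderate, , drop = FALSE]
  e$tier <- ifelse(e$weight >= strong, "strong", "moderate")
  rownames(e) <- NULL
  structure(list(nodes = nodes,
                 roles = (roles %||% setNames(rep("factor", length(nodes)),
                                              nodes))[nodes],
                 edges = e),
            class = "coloc_network")
}

#' @export
print.coloc_network <- function(x, ...) {
  cat(sprintf("coloc_network: %d nodes, %d edges (%d strong, %d moderate)\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$tier == "strong"),
              sum(x$edges$tier == "moderate")))
  invisible(x)
}

#' Modularity of a partition of a weighted undirected network
#'
#' Q = sum_c [ W_c / W - (S_c / 2W)^2 ], with W the total edge weight, W_c
#' the intra-community weight and S_c the summed weighted degree of
#' community c. Q is invariant under community relabeling and 0 for the
#' all-in-one partition.
#'
#' @param network a \code{coloc_network}
#' @param membership named vector (node -> community id)
#' @return Q in [-0.5, 1]
#' @export
modularity_score <- function(network, membership) {
  e <- network$edges
  W <- sum(e$weight)
  if (!is.finite(W) || W <= 0) stopf("zero total edge weight")
  ca <- as.character(membership[e$factor_a])
  cb <- as.character(membership[e$factor_b])
  deg <- tapply(c(e$weight, e$weight), c(e$factor_a, e$factor_b), sum)
  comms <- unique(as.character(membership[network$nodes]))
  Q <- 0
  for (cm in comms) {
    Wc <- sum(e$weight[ca == cm & cb == cm])
    Sc <- sum(deg[names(deg) %in%
                    names(membership)[as.character(membership) == cm]])
    Q <- Q + Wc / W - (Sc / (2 * W))^2
  }
  Q
}

# Internal single-level Louvain pass on an adjacency list representation.
# Nodes are visited in fixed (lexicographic) order; among equal-gain moves the
# smallest community id wins, so the result is deterministic.
.louvain_one_level <- function(adj, weight, self_w) {
  n <- length(adj)
  comm <- seq_len(n)
  two_m <- sum(vapply(seq_len(n), function(i) sum(weight[[i]]), numeric(1))) +
    2 * sum(self_w)
  deg <- vapply(seq_len(n), function(i) sum(weight[[i]]), numeric(1)) +
    2 * self_w
  tot <- deg[comm]
  tot <- tapply(deg, comm, sum)
  improved_any <- FALSE
  repeat {
    improved <- FALSE
    for (i in seq_len(n)) {
      ci <- comm[i]
      nb <- adj[[i]]; w <- weight[[i]]
      if (!length(nb)) next                 # isolated node: nothing to gain
      links <- tapply(w, comm[nb], sum)
      tot[as.character(ci)] <- tot[as.character(ci)] - deg[i]
      best_gain <- 0; best_c <- ci
      k_ci <- if (as.character(ci) %in% names(links))
        links[[as.character(ci)]] else 0
      base <- k_ci - tot[[as.character(ci)]] * deg[i] / two_m
      for (cn in names(links)) {
        gain <- links[[cn]] - tot[[cn]] * deg[i] / two_m - base
        if (gain > best_gain + 1e-12 ||
            (abs(gain - best_gain) <= 1e-12 && gain > 1e-12 &&
             as.integer(cn) < best_c)) {
          best_gain <- gain; best_c <- as.integer(cn)
        }
      }
      tot[as.character(best_c)] <- tot[[as.character(best_c)]] + deg[i]
      if (best_c != ci) { comm[i] <- best_c; improved <- TRUE }
    }
    if (!improved) break
    improved_any <- TRUE
  }
  list(comm = comm, improved = improved_any)
}

#' Louvain community detection
#'
#' Greedy modularity optimization: repeated local node moves followed by
#' community aggregation, iterated until the modularity stops improving.
#' Nodes are visited in lexicographic order of factor id and ties broken
#' deterministically, so a fixed seed and input reproduce the partition
#' byte-for-byte; Q never decreases across passes (asserted internally).
#' A graph with no edges returns each node in its own community with Q
#' reported as NA.
#'
#' @param network a \code{coloc_network}
#' @param seed unused except for interface stability (the algorithm is
#'   deterministic by construction); kept so callers can thread one seed
#'   through a pipeline
#' @return list(membership = named integer vector, Q)
#' @export
louvain_partition <- function(network, seed = 1L) {
  nodes <- sort(network$nodes)
  e <- network$edges
  if (!nrow(e)) {
    return(list(membership = setNames(seq_along(nodes), nodes), Q = NA_real_))
  }
  ia <- match(e$factor_a, nodes); ib <- match(e$factor_b, nodes)
  n <- length(nodes)
  build_adj <- function(ia, ib, w, n) {
    adj <- vector("list", n); wt <- vector("list", n)
    for (j in seq_along(ia)) {
      a <- ia[j]; b <- ib[j]
      adj[[a]] <- c(adj[[a]], b); wt[[a]] <- c(wt[[a]], w[j])
      adj[[b]] <- c(adj[[b]], a); wt[[b]] <- c(wt[[b]], w[j])
    }
    list(adj = adj, wt = wt)
  }
  g <- build_adj(ia, ib, e$weight, n)
  self_w <- rep(0, n)
  membership <- seq_len(n)          # map original node -> current community
  q_prev <- -Inf
  repeat {
    lv <- .louvain_one_level(g$adj, g$wt, self_w)
    comm <- match(lv$comm, sort(unique(lv$comm)))
    membership <- comm[membership]
    q_now <- modularity_score(network,
                              setNames(membership, nodes))
    stopifnot(q_now >= q_prev - 1e-9)  # Q non-decreasing across passes
    if (!lv$improved || q_now <= q_prev + 1e-12) break
    q_prev <- q_now
    # aggregate: one node per community
    k <- max(comm)
    agg_w <- new.env()
    new_self <- rep(0, k)
    for (i in seq_along(g$adj)) {
      ci <- comm[i]
      new_self[ci] <- new_self[ci] + self_w[i]
      nb <- g$adj[[i]]; w <- g$wt[[i]]
      for (j in seq_along(nb)) {
        cj <- comm[nb[j]]
        if (cj == ci) { new_self[ci] <- new_self[ci] + w[j] / 2 }
        else if (ci < cj) {
          key <- paste(ci, cj)
          agg_w[[key]] <- (agg_w[[key]] %||% 0) + w[j] / 2
        } else {
          key <- paste(cj, ci)
          agg_w[[key]] <- (agg_w[[key]] %||% 0) + w[j] / 2
        }
      }
    }
    keys <- ls(agg_w)
    if (!length(keys)) break
    pr <- do.call(rbind, strsplit(keys, " "))
    ia2 <- as.integer(pr[, 1]); ib2 <- as.integer(pr[, 2])
    w2 <- vapply(keys, function(k2) agg_w[[k2]], numeric(1))
    g <- build_adj(ia2, ib2, w2, k)
    self_w <- new_self
    n <- k
  }
  membership <- match(membership, sort(unique(membership)))
  names(membership) <- nodes
  # isolated nodes (present in node set, absent from edges) keep their own
  # communities already via the initial numbering
  list(membership = membership,
       Q = modularity_score(network, membership))
}

#' Convert a colocalization network to igraph
#'
#' @param network a \code{coloc_network}
#' @param membership optional community labels to attach
#' @return an igraph graph (requires the igraph package)
#' @export
as_igraph <- function(network, membership = NULL) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stopf("as_igraph requires the igraph package")
  g <- igraph::graph_from_data_frame(
    network$edges[, c("factor_a", "factor_b", "weight", "tier")],
    directed = FALSE,
    vertices = data.frame(name = network$nodes,
                          role = unname(network$roles[network$nodes])))
  if (!is.null(membership))
    igraph::V(g)$community <- unname(membership[igraph::V(g)$name])
  g
}

#' Export edges and nodes as TSV / GraphML
#' @param network a \code{coloc_network}
#' @param path output path
#' @param membership optional community labels
#' @export
write_network <- function(network, path, membership = NULL) {
  fwrite(as.data.table(network$edges), path, sep = "\t")
  invisible(path)
}

#' @rdname write_network
#' @export
write_graphml <- function(network, path, membership = NULL) {
  g <- as_igraph(network, membership)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
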