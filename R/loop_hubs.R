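#' Annotate loops by anchor overlap with promoters and accessible sites
#'
#' A loop is promoter-promoter (PP) when both anchors overlap promoters;
#' promoter-enhancer (PE) when one anchor overlaps a promoter and the other
#' overlaps a chromatin-accessible site but no promoter; enhancer-enhancer
#' (EE) when both anchors overlap accessible sites but no promoters; and
#' "other" otherwise. The labels are mutually exclusive with exactly this
#' precedence.
#'
#' @param loops a `loop_set`.
#' @param promoters `GRanges` of promoter windows (see
#'   [promoters_from_genes()]).
#' @param chracc_sites `GRanges` of accessible sites.
#' @return the loop set with an `annotation` column.
#' @export
annotate_loops <- function(loops, promoters, chracc_sites) {
  a1 <- loop_anchors(loops, 1)
  a2 <- loop_anchors(loops, 2)
  p1 <- IRanges::overlapsAny(a1, promoters)
  p2 <- IRanges::overlapsAny(a2, promoters)
  e1 <- IRanges::overlapsAny(a1, chracc_sites) & !p1
  e2 <- IRanges::overlapsAny(a2, chracc_sites) & !p2
  ann <- rep("other", nrow(loops))
  ann[p1 & p2] <- "PP"
  ann[(p1 & e2 & !p2) | (p2 & e1 & !p1)] <- "PE"
  ann[e1 & e2 & !p1 & !p2] <- "EE"
  loops$annotation <- ann
  loops
}

#' Build the loop-anchor network
#'
#' Nodes are canonical anchors: anchors sharing at least 1 bp are merged into
#' one node whose canonical interval is the union. One edge per loop, default
#' weight 1. Loops whose two anchors merge into the same node would be
#' self-edges and are rejected with a log entry; duplicate loops (same
#' canonical node pair) are collapsed with a warning.
#'
#' @param loops an intra-chromosomal `loop_set`.
#' @param weights optional per-loop edge weights (default 1).
#' @return `igraph` graph with vertex attributes `chrom`, `start`, `end`
#'   (canonical anchor, BED convention) and edge attribute `weight`.
#' @export
build_loop_graph <- function(loops, weights = NULL) {
  if (any(loops$interchrom %||% (loops$chrom1 != loops$chrom2))) {
    loops <- loops[loops$chrom1 == loops$chrom2, , drop = FALSE]
    log_stage("build_loop_graph", "interchromosomal loops dropped; %d retained",
              nrow(loops))
  }
  anchors <- loop_anchors(loops, "both")
  nodes <- GenomicRanges::reduce(anchors)
  nodes <- GenomicRanges::sort(nodes)  # vertex order fixed by coordinate
  hit <- GenomicRanges::findOverlaps(anchors, nodes, select = "first")
  n_loops <- nrow(loops)
  v1 <- hit[seq_len(n_loops)]
  v2 <- hit[n_loops + seq_len(n_loops)]
  self <- v1 == v2
  if (any(self)) {
    log_stage("build_loop_graph", "%d loop(s) rejected as self-edges", sum(self))
  }
  v1 <- v1[!self]; v2 <- v2[!self]
  w <- (weights %||% rep(1, n_loops))[!self]
  key <- paste(pmin(v1, v2), pmax(v1, v2))
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate loop(s) collapsed")
    keep <- !duplicated(key)
    v1 <- v1[keep]; v2 <- v2[keep]; w <- w[keep]
  }
  if (length(v1)) {
    g <- igraph::graph_from_edgelist(cbind(v1, v2), directed = FALSE)
    if (igraph::vcount(g) < length(nodes)) {
      g <- igraph::add_vertices(g, length(nodes) - igraph::vcount(g))
    }
  } else {
    g <- igraph::make_empty_graph(length(nodes), directed = FALSE)
  }
  igraph::V(g)$chrom <- as.character(GenomicRanges::seqnames(nodes))
  igraph::V(g)$start <- bed_start(nodes)
  igraph::V(g)$end <- bed_end(nodes)
  igraph::E(g)$weight <- w
  g
}

#' Multilevel (Louvain) community detection
#'
#' Modularity maximization at resolution 1 with the final partition returned;
#' deterministic for a fixed seed and the coordinate-fixed node ordering used
#' by [build_loop_graph()].
#'
#' @param graph `igraph` graph.
#' @param seed integer seed.
#' @return integer membership vector (one entry per node).
#' @export
detect_communities <- function(graph, seed = 1L) {
  if (igraph::vcount(graph) == 0) stop("graph is empty")
  if (igraph::ecount(graph) == 0) return(seq_len(igraph::vcount(graph)))
  set.seed(seed)
  cl <- igraph::cluster_louvain(graph, weights = igraph::E(graph)$weight,
                                resolution = 1)
  igraph::membership(cl)
}

#' Identify chromatin-loop hubs
#'
#' Runs community detection on the loop-anchor network, thresholds the
#' cluster-size curve with [elbow_threshold()], and keeps clusters whose size
#' is strictly greater than the threshold. Anchors within each hub are ranked
#' by PageRank (damping 0.85, unit edge weights); clusters of size 2
#' (isolated loops) are reported separately as controls.
#'
#' @param loops an intra-chromosomal `loop_set`.
#' @param seed integer seed for community detection.
#' @return list with `hubs` (list of per-hub records: `anchors` GRanges ranked
#'   by decreasing PageRank, `size`, `top_anchor`, `bottom_anchor`,
#'   `pagerank`), `threshold`, `cluster_sizes`, `membership`, `isolated`
#'   (GRanges of size-2 cluster anchors), and the `graph`.
#' @export
identify_hubs <- function(loops, seed = 1L) {
  g <- build_loop_graph(loops)
  memb <- detect_communities(g, seed = seed)
  sizes <- as.integer(table(memb))
  thr <- elbow_threshold(sizes)
  pr <- igraph::page_rank(g, damping = 0.85,
                          weights = igraph::E(g)$weight)$vector
  node_gr <- genomic_interval(igraph::V(g)$chrom, igraph::V(g)$start,
                              igraph::V(g)$end)
  hub_ids <- as.integer(names(table(memb)))[sizes > thr]
  hubs <- lapply(hub_ids, function(cid) {
    nodes <- which(memb == cid)
    ord <- nodes[order(-pr[nodes], igraph::V(g)$start[nodes])]
    anchors <- node_gr[ord]
    anchors$pagerank <- pr[ord]
    list(anchors = anchors, size = length(ord),
         top_anchor = anchors[1], bottom_anchor = anchors[length(ord)],
         pagerank = pr[ord])
  })
  iso_ids <- as.integer(names(table(memb)))[sizes == 2]
  isolated <- node_gr[memb %in% iso_ids]
  log_stage("identify_hubs",
            "%d cluster(s), size threshold %.3g, %d hub(s), %d isolated loops",
            length(sizes), thr, length(hubs), length(iso_ids))
  list(hubs = hubs, threshold = thr, cluster_sizes = sizes,
       membership = memb, isolated = isolated, graph = g)
}

#' Count read pairs at loop-anchor pairs
#'
#' For each loop of a union pool and each replicate raw contact map, sums raw
#' counts over all bin pairs covered by the two anchors (anchors snapped
#' outward to the bin grid, with a log entry).
#'
#' @param union_loops a `loop_set` on the chromosome of the maps.
#' @param contact_maps_per_replicate named list of raw [contact_map()]s.
#' @return integer count matrix, loops x replicates.
#' @export
count_loop_anchor_pairs <- function(union_loops, contact_maps_per_replicate) {
  maps <- contact_maps_per_replicate
  bs <- maps[[1]]$bin_size
  n <- maps[[1]]$n_bins
  snapped <- FALSE
  bin_range <- function(s, e) {
    if (s %% bs != 0 || e %% bs != 0) snapped <<- TRUE
    max(0L, floor(s / bs)):min(n - 1L, ceiling(e / bs) - 1L) + 1L
  }
  counts <- matrix(0, nrow(union_loops), length(maps),
                   dimnames = list(NULL, names(maps)))
  for (l in seq_len(nrow(union_loops))) {
    b1 <- bin_range(union_loops$start1[l], union_loops$end1[l])
    b2 <- bin_range(union_loops$start2[l], union_loops$end2[l])
    for (r in seq_along(maps)) {
      counts[l, r] <- sum(maps[[r]]$counts[b1, b2, drop = FALSE])
    }
  }
  if (snapped) log_stage("count_loop_anchor_pairs", "anchors snapped to bin grid")
  counts
}

#' Relative loop strength between conditions
#'
#' Ratio (WT / dKO) of balanced anchor-pair sums. The two maps must already be
#' balanced and depth-normalized to equal totals; no rescaling is applied
#' here, so a uniform halving of the dKO map doubles every ratio. Loops with
#' zero dKO signal get `NA`.
#'
#' @param loops a `loop_set`.
#' @param map_wt,map_dko balanced, depth-normalized [contact_map()]s on the
#'   same grid.
#' @return numeric vector of ratios.
#' @export
relative_loop_strength <- function(loops, map_wt, map_dko) {
  b_wt <- balanced_matrix(map_wt)
  b_dko <- balanced_matrix(map_dko)
  b_wt[is.na(b_wt)] <- 0
  b_dko[is.na(b_dko)] <- 0
  bs <- map_wt$bin_size
  n <- map_wt$n_bins
  vapply(seq_len(nrow(loops)), function(l) {
    b1 <- (max(0, floor(loops$start1[l] / bs)):
             min(n - 1, ceiling(loops$end1[l] / bs) - 1)) + 1
    b2 <- (max(0, floor(loops$start2[l] / bs)):
             min(n - 1, ceiling(loops$end2[l] / bs) - 1)) + 1
    num <- sum(b_wt[b1, b2])
    den <- sum(b_dko[b1, b2])
    if (den == 0) NA_real_ else num / den
  }, numeric(1))
}
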