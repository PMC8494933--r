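#' Select directional differential edges between two contact maps
#'
#' Compares balanced, depth-normalized maps bin pair by bin pair. Same-bin
#' (diagonal) pairs and weak interactions, `(WT + dKO) <= weak_sum`, are
#' excluded; the remaining pairs are kept when the chosen direction holds
#' strictly (`wt > dko` for WT-specific, `dko > wt` for dKO-specific). The
#' dKO map is scaled so its total balanced signal matches the WT map before
#' comparison.
#'
#' @param map_wt,map_dko balanced [contact_map()]s on the same grid.
#' @param direction `"wt"` (decreased in dKO) or `"dko"` (increased in dKO).
#' @param weak_sum weak-interaction filter (default 10).
#' @param max_dist optional cap on |i - j| in bins (memory control; default
#'   none).
#' @return data.frame with 0-based `bin_i < bin_j`, `wt`, `dko` values.
#' @export
select_directional_edges <- function(map_wt, map_dko,
                                     direction = c("wt", "dko"),
                                     weak_sum = 10, max_dist = NULL) {
  direction <- match.arg(direction)
  if (map_wt$n_bins != map_dko$n_bins || map_wt$bin_size != map_dko$bin_size) {
    stop("contact maps must share the same bin grid")
  }
  b_wt <- balanced_matrix(map_wt)
  b_dko <- balanced_matrix(map_dko)
  b_wt[is.na(b_wt)] <- 0
  b_dko[is.na(b_dko)] <- 0
  b_dko <- b_dko * sum(b_wt) / sum(b_dko)
  keep <- upper.tri(b_wt) & (b_wt + b_dko) > weak_sum
  if (direction == "wt") keep <- keep & b_wt > b_dko else keep <- keep & b_dko > b_wt
  idx <- which(keep, arr.ind = TRUE)
  if (!is.null(max_dist)) {
    within <- abs(idx[, 2] - idx[, 1]) <= max_dist
    idx <- idx[within, , drop = FALSE]
  }
  edges <- data.frame(bin_i = idx[, 1] - 1L, bin_j = idx[, 2] - 1L,
                      wt = b_wt[idx], dko = b_dko[idx])
  log_stage("select_directional_edges", "%d %s-direction edge(s) retained",
            nrow(edges), direction)
  edges
}

#' Cluster the differential-interaction network
#'
#' Louvain communities on the edge graph with edge weights equal to the
#' reference-condition balanced values (WT values for WT-specific hubs, dKO
#' values for dKO-specific). Per-node degree (number of incident edges,
#' unweighted) and PageRank (damping 0.85 on the weighted graph) are computed
#' on the same graph. Nodes exist only via edges; singletons never appear.
#'
#' @param edges data.frame from [select_directional_edges()].
#' @param reference_condition `"wt"` or `"dko"`.
#' @param seed integer seed.
#' @return list with `bins` (0-based bin per node), `membership`, `degree`,
#'   `pagerank`, and the `graph`.
#' @export
cluster_diff_network <- function(edges, reference_condition = c("wt", "dko"),
                                 seed = 1L) {
  reference_condition <- match.arg(reference_condition)
  if (!nrow(edges)) stop("no edges to cluster")
  bins <- sort(unique(c(edges$bin_i, edges$bin_j)))
  v1 <- match(edges$bin_i, bins)
  v2 <- match(edges$bin_j, bins)
  g <- igraph::graph_from_edgelist(cbind(v1, v2), directed = FALSE)
  if (igraph::vcount(g) < length(bins)) {
    g <- igraph::add_vertices(g, length(bins) - igraph::vcount(g))
  }
  igraph::E(g)$weight <- edges[[reference_condition]]
  igraph::V(g)$bin <- bins
  memb <- detect_communities(g, seed = seed)
  list(bins = bins, membership = memb,
       degree = igraph::degree(g),
       pagerank = igraph::page_rank(g, damping = 0.85,
                                    weights = igraph::E(g)$weight)$vector,
       graph = g)
}

#' Project a network cluster onto the genome
#'
#' The seed is the bin of the node with the highest PageRank (ties to the
#' smaller bin). Every other node's bin is included if and only if
#' `degree / distance_in_bins^2` satisfies the configured comparator against
#' `ratio` (default `< 0.5`, as printed; `">="` selects the inverted reading).
#' The projected region is the contiguous bin interval from the smallest to
#' the largest included-or-seed bin. Non-seed nodes at distance 0 (duplicate
#' bins) are skipped with a log entry.
#'
#' @param cluster_bins 0-based bins of the cluster's nodes.
#' @param degrees,pagerank_scores parallel per-node vectors.
#' @param ratio projection cutoff (default 0.5).
#' @param comparator `"<"` or `">="`.
#' @return list with `seed_bin`, `member_bins`, `region` = c(first, last) bins.
#' @export
project_cluster <- function(cluster_bins, degrees, pagerank_scores,
                            ratio = 0.5, comparator = c("<", ">=")) {
  comparator <- match.arg(comparator)
  stopifnot(length(cluster_bins) > 0)
  ord <- order(-pagerank_scores, cluster_bins)
  seed <- cluster_bins[ord[1]]
  rest <- setdiff(seq_along(cluster_bins), ord[1])
  dist <- abs(cluster_bins[rest] - seed)
  if (any(dist == 0)) {
    log_stage("project_cluster", "%d duplicate-bin node(s) skipped",
              sum(dist == 0))
    rest <- rest[dist > 0]
    dist <- dist[dist > 0]
  }
  ratio_val <- degrees[rest] / dist^2
  included <- if (comparator == "<") ratio_val < ratio else ratio_val >= ratio
  member_bins <- sort(c(seed, cluster_bins[rest][included]))
  list(seed_bin = seed, member_bins = member_bins,
       region = c(min(member_bins), max(member_bins)))
}

#' Wilcoxon significance of a projected region
#'
#' Paired one-sided Wilcoxon signed-rank test on the balanced WT vs dKO values
#' of all internal bin pairs (i < j) of the region, with the alternative
#' matching the direction (`wt`: WT greater).
#'
#' @param region c(first, last) 0-based bins, spanning >= 2 bins.
#' @param b_wt,b_dko balanced (depth-normalized) matrices.
#' @param direction `"wt"` or `"dko"`.
#' @return p-value.
#' @export
test_region_significance <- function(region, b_wt, b_dko,
                                     direction = c("wt", "dko")) {
  direction <- match.arg(direction)
  bins <- (region[1]:region[2]) + 1L
  if (length(bins) < 2) stop("region must span at least 2 bins")
  ut <- upper.tri(matrix(0, length(bins), length(bins)))
  x <- b_wt[bins, bins][ut]
  y <- b_dko[bins, bins][ut]
  keep <- !is.na(x) & !is.na(y)
  wilcox_signed_rank(x[keep], y[keep],
                     alternative = if (direction == "wt") "greater" else "less")
}

#' Call differential chromatin-interaction hubs
#'
#' Full pipeline on pooled balanced maps: directional edge selection ->
#' Louvain clustering (weights = reference-condition values) -> 1D genomic
#' projection (PageRank seed, degree/distance^2 rule) -> one-sided Wilcoxon
#' signed-rank test on the internal interactions of each projected region.
#' Regions with `p < hub_pvalue` (default 1e-7) are reported.
#'
#' @param map_wt,map_dko pooled balanced [contact_map()]s.
#' @param direction `"wt"` for WT-specific hubs, `"dko"` for dKO-specific.
#' @param seed integer seed.
#' @param config an [analysis_config()].
#' @return data.frame with one row per hub: `chrom`, `start`, `end` (BED
#'   convention), `direction`, `seed_bin`, `n_bins` (projected members),
#'   `n_internal_pairs`, `p_value`.
#' @export
call_diff_hubs <- function(map_wt, map_dko, direction = c("wt", "dko"),
                           seed = 1L, config = analysis_config()) {
  direction <- match.arg(direction)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      direction = character(), seed_bin = integer(),
                      n_bins = integer(), n_internal_pairs = integer(),
                      p_value = numeric())
  edges <- select_directional_edges(map_wt, map_dko, direction,
                                    weak_sum = config$weak_interaction_sum)
  if (!nrow(edges)) return(empty)
  cl <- cluster_diff_network(edges, reference_condition = direction, seed = seed)
  b_wt <- balanced_matrix(map_wt)
  b_dko <- balanced_matrix(map_dko)
  b_dko[is.na(b_dko)] <- 0
  b_wt[is.na(b_wt)] <- 0
  b_dko <- b_dko * sum(b_wt) / sum(b_dko)
  bs <- map_wt$bin_size
  rows <- list()
  for (cid in unique(cl$membership)) {
    nodes <- which(cl$membership == cid)
    proj <- project_cluster(cl$bins[nodes], cl$degree[nodes],
                            cl$pagerank[nodes],
                            ratio = config$projection_ratio,
                            comparator = config$projection_comparator)
    if (proj$region[2] - proj$region[1] < 1) next
    p <- test_region_significance(proj$region, b_wt, b_dko, direction)
    if (p < config$hub_pvalue) {
      nb <- proj$region[2] - proj$region[1] + 1
      rows[[length(rows) + 1]] <- data.frame(
        chrom = map_wt$chrom,
        start = proj$region[1] * bs,
        end = (proj$region[2] + 1) * bs,
        direction = direction,
        seed_bin = proj$seed_bin,
        n_bins = length(proj$member_bins),
        n_internal_pairs = nb * (nb - 1) / 2,
        p_value = p)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  log_stage("call_diff_hubs", "%d %s-specific hub(s) at p < %g",
            nrow(out), direction, config$hub_pvalue)
  out
}

#' Associate genes with differential hubs
#'
#' A gene is listed for every hub whose region overlaps its promoter
#' (TSS +/- flank) by at least 1 bp.
#'
#' @param hubs data.frame from [call_diff_hubs()].
#' @param gene_models gene-model data.frame (see [read_gene_models()]).
#' @param flank promoter half-width in bp.
#' @return data.frame with columns `gene`, `hub` (row index), `chrom`,
#'   `start`, `end`, `direction`.
#' @export
associate_genes_to_hubs <- function(hubs, gene_models, flank = 1000L) {
  if (!nrow(hubs)) {
    return(data.frame(gene = character(), hub = integer(), chrom = character(),
                      start = numeric(), end = numeric(),
                      direction = character()))
  }
  prom <- promoters_from_genes(gene_models, flank = flank)
  hub_gr <- genomic_interval(hubs$chrom, hubs$start, hubs$end)
  hits <- GenomicRanges::findOverlaps(prom, hub_gr)
  data.frame(gene = prom$gene[S4Vectors::queryHits(hits)],
             hub = S4Vectors::subjectHits(hits),
             chrom = hubs$chrom[S4Vectors::subjectHits(hits)],
             start = hubs$start[S4Vectors::subjectHits(hits)],
             end = hubs$end[S4Vectors::subjectHits(hits)],
             direction = hubs$direction[S4Vectors::subjectHits(hits)])
}
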