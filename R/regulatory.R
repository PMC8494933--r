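#' Stitch acetylation islands into super-enhancer candidates and call SEs
#'
#' Neighboring islands separated by at most `stitch_distance` are merged
#' (ROSE-style stitching, default 12.5 kb). Stitched regions are ranked by
#' their summed island signal; regions whose signal strictly exceeds the
#' [elbow_threshold()] of the ranked signal curve are super-enhancers.
#' Stitching is idempotent: stitching the stitched regions changes nothing.
#'
#' @param islands `GRanges` with a numeric `score` column (island signal).
#' @param stitch_distance maximum merged gap in bp.
#' @return data.frame with one row per stitched region: `chrom`, `start`,
#'   `end` (BED convention), `n_islands`, `rank_signal`, `is_se`; the elbow
#'   threshold is attached as attribute `"threshold"`.
#' @export
stitch_superenhancers <- function(islands, stitch_distance = 12500L) {
  if (!length(islands)) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_islands = integer(), rank_signal = numeric(),
                      is_se = logical())
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  stopifnot(!is.null(islands$score))
  stitched <- GenomicRanges::reduce(islands,
                                    min.gapwidth = stitch_distance + 1L)
  hit <- factor(GenomicRanges::findOverlaps(islands, stitched, select = "first"),
                levels = seq_along(stitched))
  signal <- as.vector(tapply(islands$score, hit, sum, default = 0))
  n_members <- as.vector(table(hit))
  thr <- if (length(signal) >= 3 && length(unique(signal)) >= 2) {
    elbow_threshold(signal)
  } else {
    suppressWarnings(elbow_threshold(signal))
  }
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(stitched)),
                    start = bed_start(stitched), end = bed_end(stitched),
                    n_islands = n_members, rank_signal = signal,
                    is_se = signal > thr)
  attr(out, "threshold") <- thr
  log_stage("stitch_superenhancers",
            "%d island(s) -> %d stitched region(s), %d SE(s)",
            length(islands), nrow(out), sum(out$is_se))
  out
}

#' Signal-to-noise ratio of a super-enhancer
#'
#' Island-filtered reads divided by total reads within the SE span; stitching
#' brings background reads between islands into an SE, and this ratio checks
#' that differential SE activity is not driven by that background.
#'
#' @param island_read_count reads falling on member islands.
#' @param total_read_count all reads within the SE span (>= island count).
#' @return fraction in `[0, 1]`, `NA` when the total is zero.
#' @export
se_signal_to_noise <- function(island_read_count, total_read_count) {
  stopifnot(all(island_read_count <= total_read_count | total_read_count == 0))
  ifelse(total_read_count == 0, NA_real_,
         island_read_count / total_read_count)
}

#' Associate regulatory elements to genes
#'
#' Window rule first: an element is linked to every gene for which it lies
#' within `[TSS - upstream, TES]` (strand-aware upstream). Elements matching
#' no window get exactly one closest-gene link, measured from the element
#' midpoint to the nearest TSS-or-TES boundary; ties are reported to all tied
#' genes and flagged. Loop links are added on top for every element whose
#' interval shares a chromatin loop with a gene promoter (TSS +/- flank).
#'
#' @param elements `GRanges` (a `name` column, if present, is used as the
#'   element id; otherwise the row index).
#' @param gene_models gene-model data.frame (see [read_gene_models()]).
#' @param loops optional `loop_set` for loop-mediated links.
#' @param upstream upstream window in bp (default 50 kb).
#' @param flank promoter half-width for loop links (default 1 kb).
#' @return data.frame with `element`, `gene`, `rule` in
#'   `{window, closest, loop}` and a `tied` flag for closest links.
#' @export
associate_elements_to_genes <- function(elements, gene_models, loops = NULL,
                                        upstream = 50000L, flank = 1000L) {
  if (!nrow(gene_models)) stop("empty gene set")
  ids <- elements$name %||% as.character(seq_along(elements))
  plus <- gene_models$strand == "+"
  win_start <- ifelse(plus, pmin(gene_models$tss, gene_models$tes) - upstream,
                      pmin(gene_models$tss, gene_models$tes))
  win_end <- ifelse(plus, pmax(gene_models$tss, gene_models$tes),
                    pmax(gene_models$tss, gene_models$tes) + upstream)
  windows <- genomic_interval(gene_models$chrom, pmax(0, win_start), win_end)
  windows$gene <- gene_models$gene
  hits <- GenomicRanges::findOverlaps(elements, windows)
  qh <- S4Vectors::queryHits(hits)
  links <- data.frame(element = ids[qh],
                      gene = windows$gene[S4Vectors::subjectHits(hits)],
                      rule = rep("window", length(qh)),
                      tied = rep(FALSE, length(qh)),
                      stringsAsFactors = FALSE)
  # closest gene for the remainder: element midpoint to nearest TSS/TES
  unmatched <- setdiff(seq_along(elements), S4Vectors::queryHits(hits))
  for (i in unmatched) {
    chrom <- as.character(GenomicRanges::seqnames(elements[i]))
    same <- gene_models$chrom == chrom
    if (!any(same)) next
    mid <- (bed_start(elements[i]) + bed_end(elements[i])) / 2
    d <- pmin(abs(gene_models$tss[same] - mid), abs(gene_models$tes[same] - mid))
    best <- which(d == min(d))
    links <- rbind(links, data.frame(element = ids[i],
                                     gene = gene_models$gene[same][best],
                                     rule = "closest",
                                     tied = length(best) > 1,
                                     stringsAsFactors = FALSE))
  }
  # loop-mediated links, additive
  if (!is.null(loops) && nrow(loops)) {
    prom <- promoters_from_genes(gene_models, flank = flank)
    a1 <- loop_anchors(loops, 1)
    a2 <- loop_anchors(loops, 2)
    loop_links <- rbind(anchor_gene_links(elements, ids, a1, a2, prom),
                        anchor_gene_links(elements, ids, a2, a1, prom))
    links <- rbind(links, loop_links)
  }
  links <- unique(links)
  rownames(links) <- NULL
  log_stage("associate_elements_to_genes",
            "%d link(s): %d window, %d closest, %d loop",
            nrow(links), sum(links$rule == "window"),
            sum(links$rule == "closest"), sum(links$rule == "loop"))
  links
}

# elements on anchor_a linked to promoters overlapping the paired anchor_b
anchor_gene_links <- function(elements, ids, anchor_a, anchor_b, prom) {
  eh <- GenomicRanges::findOverlaps(elements, anchor_a)
  if (!length(eh)) {
    return(data.frame(element = character(), gene = character(),
                      rule = character(), tied = logical()))
  }
  out <- list()
  for (k in seq_along(eh)) {
    loop_idx <- anchor_a$loop[S4Vectors::subjectHits(eh)[k]]
    other <- anchor_b[anchor_b$loop == loop_idx]
    genes <- unique(prom$gene[IRanges::overlapsAny(prom, other)])
    if (length(genes)) {
      out[[length(out) + 1]] <- data.frame(
        element = ids[S4Vectors::queryHits(eh)[k]], gene = genes,
        rule = "loop", tied = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(element = character(), gene = character(),
               rule = character(), tied = logical())
}

#' Concordance classes of accessibility versus expression changes
#'
#' Every (element, gene) pair for which both the element's accessibility
#' direction and the linked gene's expression direction (in dKO relative to
#' WT) are defined is assigned to exactly one class: C1 = expression up +
#' accessibility up, C2 = expression up + accessibility down, C3 = expression
#' down + accessibility up, C4 = expression down + accessibility down.
#'
#' @param diff_elements data.frame with `element` and `acc_direction`
#'   (`"up"`/`"down"`, in dKO).
#' @param element_gene_links data.frame with `element`, `gene` (see
#'   [associate_elements_to_genes()]).
#' @param diff_genes data.frame with `gene` and `expr_direction`
#'   (`"up"`/`"down"`, in dKO).
#' @return list with `pairs` (per-pair class table) and `counts` (named C1-C4
#'   totals).
#' @export
classify_concordance <- function(diff_elements, element_gene_links, diff_genes) {
  m <- merge(element_gene_links[, c("element", "gene")], diff_elements,
             by = "element")
  m <- merge(m, diff_genes, by = "gene")
  m <- unique(m)
  stopifnot(all(m$acc_direction %in% c("up", "down")),
            all(m$expr_direction %in% c("up", "down")))
  m$class <- ifelse(m$expr_direction == "up",
                    ifelse(m$acc_direction == "up", "C1", "C2"),
                    ifelse(m$acc_direction == "up", "C3", "C4"))
  counts <- vapply(paste0("C", 1:4), function(cl) sum(m$class == cl),
                   integer(1))
  list(pairs = m, counts = counts)
}
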