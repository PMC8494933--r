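#' Genomic interval construction
#'
#' All region-type inputs (peaks, TADs, accessible sites, super-enhancers,
#' hubs) are handled as [GenomicRanges::GRanges]. File formats use BED
#' conventions (0-based, half-open); the conversion to the 1-based closed
#' GRanges representation happens at the reader/writer boundary and nowhere
#' else.
#'
#' @param chrom chromosome name(s).
#' @param start,end 0-based half-open coordinates, `0 <= start < end`.
#' @param name,score,strand optional BED columns (`strand` in `+`, `-`, `*`).
#' @return A `GRanges` object.
#' @export
genomic_interval <- function(chrom, start, end, name = NULL, score = NULL,
                             strand = NULL) {
  if (any(start < 0) || any(end <= start)) {
    stop("malformed coordinates: require 0 <= start < end")
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = strand %||% "*"
  )
  if (!is.null(name)) gr$name <- name
  if (!is.null(score)) gr$score <- score
  gr
}

bed_start <- function(gr) GenomicRanges::start(gr) - 1L
bed_end <- function(gr) GenomicRanges::end(gr)

#' Read/write BED intervals
#'
#' 3-6 column BED. Coordinates are validated (`end > start`); the returned
#' `GRanges` round-trips identically through [write_bed()].
#'
#' @param path file path.
#' @return `GRanges` with optional `name` and `score` metadata columns.
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           colClasses = c("character", "numeric", "numeric",
                                          rep(NA, 3))[seq_len(max(3, ncol_tsv(path)))])
  if (ncol(tab) < 3) stop("BED requires at least 3 columns")
  genomic_interval(tab[[1]], tab[[2]], tab[[3]],
                   name = if (ncol(tab) >= 4) as.character(tab[[4]]),
                   score = if (ncol(tab) >= 5) as.numeric(tab[[5]]),
                   strand = if (ncol(tab) >= 6) as.character(tab[[6]]))
}

ncol_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) 0L else length(strsplit(first, "\t", fixed = TRUE)[[1]])
}

#' @rdname read_bed
#' @param gr intervals to write.
#' @export
write_bed <- function(gr, path) {
  cols <- list(as.character(GenomicRanges::seqnames(gr)), bed_start(gr), bed_end(gr))
  if (!is.null(gr$name)) {
    cols <- c(cols, list(gr$name))
    if (!is.null(gr$score)) {
      cols <- c(cols, list(gr$score))
      st <- as.character(GenomicRanges::strand(gr))
      if (any(st != "*")) cols <- c(cols, list(sub("\\*", ".", st)))
    }
  }
  utils::write.table(as.data.frame(cols, col.names = seq_along(cols)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write a loop list (BEDPE)
#'
#' Rows are anchor pairs. Anchors are canonicalized so anchor1 starts before
#' anchor2 (on the same chromosome). Interchromosomal rows are retained but
#' flagged in the `interchrom` column, since all downstream loop analyses are
#' intra-chromosomal.
#'
#' @param path file path.
#' @return data.frame of class `"loop_set"` with BED-convention columns
#'   `chrom1,start1,end1,chrom2,start2,end2` plus optional `name`, `score`.
#' @export
read_bedpe <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, quote = "")
  if (ncol(tab) < 6) stop("BEDPE requires at least 6 columns")
  loops <- data.frame(chrom1 = as.character(tab[[1]]),
                      start1 = as.numeric(tab[[2]]), end1 = as.numeric(tab[[3]]),
                      chrom2 = as.character(tab[[4]]),
                      start2 = as.numeric(tab[[5]]), end2 = as.numeric(tab[[6]]),
                      stringsAsFactors = FALSE)
  if (ncol(tab) >= 7) loops$name <- as.character(tab[[7]])
  if (ncol(tab) >= 8) loops$score <- as.numeric(tab[[8]])
  as_loop_set(loops)
}

#' @rdname read_bedpe
#' @param loops a `loop_set`.
#' @export
write_bedpe <- function(loops, path) {
  keep <- intersect(c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                      "name", "score"), names(loops))
  out <- loops[, keep, drop = FALSE]
  if ("score" %in% keep && !"name" %in% keep) out$name <- "."
  utils::write.table(out[, intersect(c("chrom1", "start1", "end1", "chrom2",
                                       "start2", "end2", "name", "score"),
                                     names(out))],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Coerce a data.frame into a canonical loop set
#'
#' Validates coordinates, sorts the two anchors of each intra-chromosomal loop
#' by start position, and flags interchromosomal rows.
#'
#' @param loops data.frame with the six BEDPE coordinate columns.
#' @return data.frame of class `"loop_set"`.
#' @export
as_loop_set <- function(loops) {
  stopifnot(all(c("chrom1", "start1", "end1", "chrom2", "start2", "end2") %in%
                  names(loops)))
  if (any(loops$end1 <= loops$start1) || any(loops$end2 <= loops$start2) ||
      any(loops$start1 < 0) || any(loops$start2 < 0)) {
    stop("malformed anchor coordinates: require 0 <= start < end")
  }
  swap <- loops$chrom1 == loops$chrom2 & loops$start2 < loops$start1
  if (any(swap)) {
    tmp <- loops[swap, c("start1", "end1")]
    loops[swap, c("start1", "end1")] <- loops[swap, c("start2", "end2")]
    loops[swap, c("start2", "end2")] <- tmp
  }
  loops$interchrom <- loops$chrom1 != loops$chrom2
  if (any(loops$interchrom)) {
    log_stage("read_bedpe", "%d interchromosomal loop(s) flagged",
              sum(loops$interchrom))
  }
  class(loops) <- c("loop_set", "data.frame")
  loops
}

#' Anchors of a loop set as GRanges
#'
#' @param loops a `loop_set`.
#' @param which `1`, `2`, or `"both"` (anchor1 rows then anchor2 rows).
#' @return `GRanges` with a `loop` metadata column giving the row index.
#' @export
loop_anchors <- function(loops, which = "both") {
  a1 <- genomic_interval(loops$chrom1, loops$start1, loops$end1)
  a1$loop <- seq_len(nrow(loops))
  a2 <- genomic_interval(loops$chrom2, loops$start2, loops$end2)
  a2$loop <- seq_len(nrow(loops))
  switch(as.character(which), "1" = a1, "2" = a2, both = c(a1, a2))
}

#' Read/write a bedGraph signal track
#'
#' @param path file path.
#' @return `GRanges` with a numeric `score` column.
#' @export
read_bedgraph <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE, quote = "")
  if (ncol(tab) < 4) stop("bedGraph requires 4 columns")
  genomic_interval(as.character(tab[[1]]), tab[[2]], tab[[3]],
                   score = as.numeric(tab[[4]]))
}

#' @rdname read_bedgraph
#' @param gr intervals with a `score` column.
#' @export
write_bedgraph <- function(gr, path) {
  utils::write.table(
    data.frame(as.character(GenomicRanges::seqnames(gr)), bed_start(gr),
               bed_end(gr), gr$score),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write gene sets (GMT)
#'
#' One set per line: name, description, then tab-separated gene symbols.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' @rdname read_gmt
#' @param gene_sets named list of character vectors.
#' @param descriptions optional character vector parallel to `gene_sets`.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(gene_sets))
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(gene_sets), descriptions, gene_sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read a tab-delimited gene model table
#'
#' Columns: gene, chrom, tss, tes, strand. TSS/TES are 0-based positions; for
#' minus-strand genes the TSS is numerically larger than the TES.
#'
#' @param path file path.
#' @return data.frame with those five columns.
#' @export
read_gene_models <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "chrom", "tss", "tes", "strand") %in% names(tab)))
  if (!all(tab$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  tab
}

#' Promoter windows from gene models
#'
#' Promoter = `[TSS - flank, TSS + flank]`.
#'
#' @param genes gene-model data.frame (see [read_gene_models()]).
#' @param flank half-width in bp (default 1 kb).
#' @return `GRanges` with `gene` metadata column.
#' @export
promoters_from_genes <- function(genes, flank = 1000L) {
  gr <- genomic_interval(genes$chrom,
                         pmax(0, genes$tss - flank),
                         genes$tss + flank,
                         strand = genes$strand)
  gr$gene <- genes$gene
  gr
}

#' Read/write an expression matrix with its sample-metadata sidecar
#'
#' The matrix is genes x samples TSV with a header and gene ids in the first
#' column. The sidecar (`<path>.meta`, or `meta_path`) maps sample -> lineage
#' and replicate.
#'
#' @param path matrix file path.
#' @param meta_path sidecar path; defaults to `paste0(path, ".meta")`.
#' @return list with `counts` (numeric matrix) and `meta` (data.frame with
#'   columns sample, lineage, replicate).
#' @export
read_expression <- function(path, meta_path = paste0(path, ".meta")) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           check.names = FALSE, row.names = 1)
  meta <- utils::read.table(meta_path, sep = "\t", header = TRUE, quote = "",
                            stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "lineage", "replicate") %in% names(meta)))
  counts <- as.matrix(tab)
  if (!identical(colnames(counts), meta$sample)) {
    stop("expression columns and metadata samples do not match")
  }
  list(counts = counts, meta = meta)
}

#' @rdname read_expression
#' @param expr list as returned by [read_expression()] or
#'   [simulate_expression()].
#' @export
write_expression <- function(expr, path, meta_path = paste0(path, ".meta")) {
  out <- data.frame(gene = rownames(expr$counts), expr$counts,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
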