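#' Pairwise differential expression between two lineages
#'
#' Delegates to the shared negative-binomial count test
#' ([test_differential_counts()]) on the replicate columns of the two
#' lineages. A gene is called up in a lineage when its fold-change is at
#' least `fc` and its BH-FDR is at most `fdr`.
#'
#' @param expr list with `counts` (genes x samples) and `meta` (sample,
#'   lineage, replicate), as from [read_expression()] or
#'   [simulate_expression()].
#' @param lineage_a,lineage_b lineage labels present in `expr$meta$lineage`.
#' @param fc fold-change requirement (default 5).
#' @param fdr FDR cutoff (default 0.01).
#' @return character vector per gene: `"up_a"`, `"up_b"`, or `"ns"`.
#' @export
pairwise_de <- function(expr, lineage_a, lineage_b, fc = 5, fdr = 0.01) {
  sel_a <- expr$meta$lineage == lineage_a
  sel_b <- expr$meta$lineage == lineage_b
  if (sum(sel_a) < 2 || sum(sel_b) < 2) {
    stop("each lineage needs at least 2 replicates")
  }
  counts <- expr$counts[, c(which(sel_a), which(sel_b)), drop = FALSE]
  group <- factor(rep(c("a", "b"), c(sum(sel_a), sum(sel_b))),
                  levels = c("a", "b"))
  res <- test_differential_counts(counts, group, fc_threshold = fc,
                                  sig_threshold = fdr, sig_mode = "fdr",
                                  fc_strict = FALSE)
  calls <- ifelse(res$call == "a", "up_a",
                  ifelse(res$call == "b", "up_b", "ns"))
  stats::setNames(calls, res$feature)
}

# coefficient of variation per gene within one lineage; NA when the mean is 0
lineage_cv <- function(counts) {
  m <- rowMeans(counts)
  s <- apply(counts, 1, stats::sd)
  ifelse(m > 0, s / m, NA_real_)
}

#' Identify lineage-enriched genes (LEGs)
#'
#' A gene is a LEG for lineage L when it is called significantly upregulated
#' in L in at least `min_wins` of the pairwise comparisons against the other
#' lineages (5 of 6 for the seven-lineage pan-immune analysis), and its
#' within-L coefficient of variation (sd/mean across replicates) is strictly
#' below `cv_max`.
#'
#' @param expr expression list (see [pairwise_de()]).
#' @param lineages lineage labels to analyze; defaults to all in the metadata.
#' @param fc,fdr pairwise test cutoffs (defaults 5-fold, FDR 0.01).
#' @param min_wins minimum number of won comparisons (default 5).
#' @param cv_max coefficient-of-variation ceiling (default 1).
#' @return named list, one element per lineage: data.frame with `gene`,
#'   `wins`, `cv` for every LEG.
#' @export
identify_legs <- function(expr, lineages = NULL, fc = 5, fdr = 0.01,
                          min_wins = 5L, cv_max = 1.0) {
  lineages <- lineages %||% unique(expr$meta$lineage)
  n_lin <- length(lineages)
  if (n_lin < 2) stop("need at least 2 lineages")
  wins <- matrix(0L, nrow(expr$counts), n_lin,
                 dimnames = list(rownames(expr$counts), lineages))
  for (i in seq_len(n_lin - 1)) {
    for (j in seq(i + 1, n_lin)) {
      calls <- pairwise_de(expr, lineages[i], lineages[j], fc = fc, fdr = fdr)
      wins[, i] <- wins[, i] + (calls == "up_a")
      wins[, j] <- wins[, j] + (calls == "up_b")
    }
  }
  out <- lapply(lineages, function(L) {
    cv <- lineage_cv(expr$counts[, expr$meta$lineage == L, drop = FALSE])
    ok <- wins[, L] >= min_wins & !is.na(cv) & cv < cv_max
    data.frame(gene = rownames(expr$counts)[ok],
               wins = wins[ok, L], cv = cv[ok], row.names = NULL)
  })
  names(out) <- lineages
  log_stage("identify_legs", "LEGs per lineage: %s",
            paste(sprintf("%s=%d", lineages, vapply(out, nrow, integer(1))),
                  collapse = ", "))
  out
}

#' LEGs within the T-cell subsets
#'
#' Same procedure as [identify_legs()] restricted to the T subsets (naive
#' CD4, naive CD8, Treg, gamma-delta T), with the win rule relaxed to at
#' least 2 of 3 comparisons.
#'
#' @param expr expression list.
#' @param subsets the T-subset lineage labels (default: all in the metadata).
#' @param ... passed to [identify_legs()].
#' @return named list of per-subset LEG tables.
#' @export
identify_t_subset_legs <- function(expr, subsets = NULL, ...) {
  subsets <- subsets %||% unique(expr$meta$lineage)
  identify_legs(expr, lineages = subsets, min_wins = 2L, ...)
}

#' Two-genotype differentially expressed genes with an expression floor
#'
#' DEG call requires fold >= `fc`, BH-FDR < `fdr`, and a mean expression of at
#' least `min_level` in the higher group (the FPKM >= 1 style floor).
#'
#' @param expr_wt,expr_ko genes x replicates matrices (same genes).
#' @param fc,fdr,min_level thresholds (defaults 2, 0.05, 1).
#' @return data.frame with per-gene statistics and `call` in
#'   `{up_in_ko, down_in_ko, ns}`.
#' @export
flag_degs <- function(expr_wt, expr_ko, fc = 2, fdr = 0.05, min_level = 1) {
  stopifnot(nrow(expr_wt) == nrow(expr_ko))
  counts <- cbind(expr_wt, expr_ko)
  group <- factor(rep(c("wt", "ko"), c(ncol(expr_wt), ncol(expr_ko))),
                  levels = c("wt", "ko"))
  res <- test_differential_counts(counts, group, fc_threshold = fc,
                                  sig_threshold = fdr, sig_mode = "fdr",
                                  fc_strict = FALSE)
  hi_mean <- ifelse(res$higher_group == "ko",
                    rowMeans(expr_ko), rowMeans(expr_wt))
  res$call <- ifelse(res$call == "ns" | hi_mean < min_level, "ns",
                     ifelse(res$call == "ko", "up_in_ko", "down_in_ko"))
  res
}

#' Flag divergent replicates within lineages
#'
#' Generic outlier screen: within each lineage, each replicate's mean Pearson
#' correlation with the remaining replicates (log scale with pseudocount 1)
#' is computed; while the worst replicate falls below `min_cor` and at least
#' 3 replicates remain, it is flagged and removed before re-evaluating. The
#' iterative exclusion matters because a single divergent replicate also
#' depresses the leave-one-out correlations of its well-behaved lineage
#' mates. Flagged samples can then be excluded before LEG calling.
#'
#' @param expr expression list.
#' @param min_cor correlation floor (default 0.8).
#' @return character vector of flagged sample names.
#' @export
flag_outlier_replicates <- function(expr, min_cor = 0.8) {
  lx <- log1p(expr$counts)
  flagged <- character()
  for (L in unique(expr$meta$lineage)) {
    cols <- which(expr$meta$lineage == L)
    while (length(cols) >= 3) {
      cm <- stats::cor(lx[, cols])
      mean_cor <- (rowSums(cm) - 1) / (length(cols) - 1)
      worst <- which.min(mean_cor)
      if (mean_cor[worst] >= min_cor) break
      flagged <- c(flagged, expr$meta$sample[cols[worst]])
      cols <- cols[-worst]
    }
  }
  if (length(flagged)) {
    log_stage("flag_outlier_replicates", "flagged: %s",
              paste(flagged, collapse = ", "))
  }
  flagged
}

#' Export LEG sets as GMT
#'
#' @param leg_sets named list from [identify_legs()].
#' @param path output file.
#' @export
write_leg_gmt <- function(leg_sets, path) {
  write_gmt(lapply(leg_sets, function(df) df$gene), path,
            descriptions = paste0(names(leg_sets), "_LEG"))
}
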