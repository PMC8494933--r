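#' Elbow (tangent-line) threshold on a ranked value curve
#'
#' Values are sorted ascending and both the rank axis and the value axis are
#' scaled to `[0, 1]`. The threshold is the value at the tangency point of a
#' unit-slope line with the curve, i.e. the point of maximum distance below
#' the `y = x` diagonal; ties are broken to the largest index (conservative:
#' fewer calls pass). Degenerate input (fewer than 3 values, or all values
#' equal) returns `max(values)` with a warning, so that nothing passes a
#' strict `>` comparison.
#'
#' @param values numeric vector (cluster sizes, stitched-enhancer signals...).
#' @return threshold on the original value scale.
#' @export
elbow_threshold <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 3 || length(unique(values)) < 2) {
    warning("degenerate input to elbow_threshold; returning max(values)")
    return(max(values))
  }
  v <- sort(values)
  n <- length(v)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (v - v[1]) / (v[n] - v[1])
  d <- x - y
  idx <- max(which(d == max(d)))
  v[idx]
}

#' Paired one-sided Wilcoxon signed-rank test
#'
#' Standard signed-rank convention: zero differences are dropped and ties are
#' mid-ranked. The exact null distribution of the signed-rank sum (computed by
#' dynamic programming over the tied mid-ranks, so ties are handled exactly)
#' is used for up to 25 non-zero differences; the normal approximation with
#' continuity correction and tie-corrected variance is used above that.
#'
#' @param x,y paired observations.
#' @param alternative `"greater"` tests whether `x` tends to exceed `y`.
#' @return p-value (1, with a warning, when all differences are zero).
#' @export
wilcox_signed_rank <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  d <- x - y
  d <- d[d != 0]
  if (!length(d)) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  if (alternative == "less") d <- -d
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  n <- length(d)
  if (n <= 25) {
    # exact: distribution of the signed-rank sum over all 2^n sign
    # assignments, via convolution on doubled (integer) mid-ranks
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    probs <- c(1, numeric(total))
    for (w in r2) {
      shifted <- c(numeric(w), probs[seq_len(total + 1 - w)])
      probs <- (probs + shifted) / 2
    }
    v2 <- as.integer(round(2 * v))
    return(sum(probs[(v2 + 1):(total + 1)]))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  stats::pnorm(v - 0.5, mean = mu, sd = sqrt(sigma2), lower.tail = FALSE)
}

#' Binomial enrichment of point events in regions
#'
#' Expected count = total region length x genome-wide event density. The
#' one-sided binomial upper tail uses the total number of events as the number
#' of trials and expected/total as the success probability.
#'
#' @param features `GRanges` of point events (peak summits) or a numeric
#'   vector of 0-based positions (then `regions` must be a 2-column matrix of
#'   0-based half-open intervals).
#' @param regions `GRanges` (merged before counting) or a 2-column matrix.
#' @param genome_length total genome length in bp.
#' @return list with `observed`, `expected`, `ratio`, `p`.
#' @export
enrichment_score <- function(features, regions, genome_length) {
  if (inherits(features, "GRanges")) {
    n_feat <- length(features)
    regions <- GenomicRanges::reduce(regions)
    observed <- sum(IRanges::overlapsAny(features, regions))
    region_len <- sum(GenomicRanges::width(regions))
  } else {
    regions <- as.matrix(regions)
    n_feat <- length(features)
    observed <- sum(vapply(features, function(p)
      any(p >= regions[, 1] & p < regions[, 2]), logical(1)))
    region_len <- sum(regions[, 2] - regions[, 1])
  }
  expected <- region_len * n_feat / genome_length
  if (expected == 0) {
    if (observed > 0) {
      warning("expected count is zero with observed > 0; p = 0 sentinel")
      return(list(observed = observed, expected = 0, ratio = Inf, p = 0))
    }
    return(list(observed = 0, expected = 0, ratio = NA_real_, p = 1))
  }
  prob <- expected / n_feat
  p <- stats::pbinom(observed - 1, size = n_feat, prob = prob,
                     lower.tail = FALSE)
  list(observed = observed, expected = expected,
       ratio = observed / expected, p = p)
}

#' One-sided Poisson enrichment tail
#'
#' `P(X >= observed | lambda = expected)`.
#'
#' @param observed observed count.
#' @param expected expected count (> 0).
#' @return p-value.
#' @export
poisson_enrichment <- function(observed, expected) {
  if (expected <= 0) stop("expected must be positive")
  stats::ppois(observed - 1, lambda = expected, lower.tail = FALSE)
}

#' Composition of motif classes across strata
#'
#' Pearson chi-squared test (no continuity correction) on the contingency
#' table of Motif+/MotifInt/Motif- counts per stratum. A warning is attached
#' when any expected cell is below 1.
#'
#' @param motif_class character vector of per-peak classes.
#' @param strata parallel vector of stratum labels (at least 2 strata).
#' @return list with `table`, `statistic`, `p`, and `low_expected` flag.
#' @export
motif_class_composition <- function(motif_class, strata) {
  if (length(unique(strata)) < 2) stop("need at least 2 strata to test")
  tab <- table(strata, motif_class)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  low <- any(ct$expected < 1)
  if (low) warning("some expected cell counts are below 1")
  list(table = tab, statistic = unname(ct$statistic), p = ct$p.value,
       low_expected = low)
}

#' Negative-binomial differential count test
#'
#' The shared test behind differential loops, accessible sites,
#' super-enhancers, and pairwise lineage comparisons: an edgeR
#' quasi-likelihood F-test (robust) with TMM library scaling. A feature is
#' called when its fold-change (computed on TMM-normalized group means with a
#' 0.5 pseudocount) exceeds `fc_threshold` and its raw p-value or BH-FDR
#' (per `sig_mode`) falls below `sig_threshold`.
#'
#' @param count_matrix features x samples, non-negative.
#' @param group_labels factor-like vector of length `ncol(count_matrix)` with
#'   exactly two levels and at least 2 replicates each.
#' @param fc_threshold fold-change requirement (set to 1 to disable).
#' @param sig_threshold significance cutoff.
#' @param sig_mode `"p"` (raw p-value, as for differential loops) or `"fdr"`.
#' @param fc_strict require fold strictly greater than the threshold (loops
#'   use `> 2.0`); when `FALSE`, `>=` is used (lineage DE uses `>= 5`).
#' @return data.frame with per-feature `log2_fc`, `fold`, `higher_group`,
#'   `p`, `fdr`, `call` (one of the two group names or `"ns"`), and
#'   `excluded` for all-zero features.
#' @export
test_differential_counts <- function(count_matrix, group_labels,
                                     fc_threshold = 2, sig_threshold = 0.05,
                                     sig_mode = c("p", "fdr"),
                                     fc_strict = TRUE) {
  sig_mode <- match.arg(sig_mode)
  group <- factor(group_labels)
  if (nlevels(group) != 2) stop("exactly two groups are required")
  if (any(table(group) < 2)) stop("need >= 2 replicates per group")
  count_matrix <- as.matrix(count_matrix)
  if (any(count_matrix < 0)) stop("counts must be non-negative")
  if (is.null(rownames(count_matrix))) {
    rownames(count_matrix) <- paste0("f", seq_len(nrow(count_matrix)))
  }
  nonzero <- rowSums(count_matrix) > 0
  if (any(!nonzero)) {
    log_stage("test_differential_counts", "%d all-zero feature(s) excluded",
              sum(!nonzero))
  }
  out <- data.frame(feature = rownames(count_matrix),
                    log2_fc = NA_real_, fold = NA_real_,
                    higher_group = NA_character_,
                    p = NA_real_, fdr = NA_real_, call = "ns",
                    excluded = !nonzero, stringsAsFactors = FALSE)
  if (sum(nonzero) == 0) return(out)
  y <- edgeR::DGEList(counts = count_matrix[nonzero, , drop = FALSE],
                      group = group)
  y <- edgeR::calcNormFactors(y)
  design <- stats::model.matrix(~group)
  y <- edgeR::estimateDisp(y, design)
  fit <- edgeR::glmQLFit(y, design, robust = TRUE)
  qlf <- edgeR::glmQLFTest(fit, coef = 2)
  p <- qlf$table$PValue
  fdr <- stats::p.adjust(p, method = "BH")
  # fold-change from TMM-normalized group means, pseudocount 0.5
  eff_lib <- y$samples$lib.size * y$samples$norm.factors
  norm <- sweep(y$counts, 2, mean(eff_lib) / eff_lib, "*")
  m1 <- rowMeans(norm[, group == levels(group)[1], drop = FALSE])
  m2 <- rowMeans(norm[, group == levels(group)[2], drop = FALSE])
  log2fc <- log2((m2 + 0.5) / (m1 + 0.5))
  fold <- 2^abs(log2fc)
  higher <- ifelse(log2fc >= 0, levels(group)[2], levels(group)[1])
  sig <- if (sig_mode == "p") p < sig_threshold else fdr <= sig_threshold
  fc_ok <- if (fc_strict) fold > fc_threshold else fold >= fc_threshold
  call <- ifelse(sig & fc_ok, higher, "ns")
  out$log2_fc[nonzero] <- log2fc
  out$fold[nonzero] <- fold
  out$higher_group[nonzero] <- higher
  out$p[nonzero] <- p
  out$fdr[nonzero] <- fdr
  out$call[nonzero] <- call
  log_stage("test_differential_counts", "%d/%d feature(s) called differential",
            sum(call != "ns"), sum(nonzero))
  out
}
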