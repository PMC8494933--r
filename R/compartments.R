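#' A/B compartment scores
#'
#' Computes per-bin compartment scores at coarse (typically 100-kb) resolution:
#' the contact matrix is distance-normalized (observed over the per-distance
#' expected mean), the Pearson correlation matrix of the normalized map is
#' formed over unmasked bins, and the first principal component (leading
#' eigenvector of the correlation matrix) is the score, up to a sign. The
#' global sign is fixed against an activity track (e.g. H3K27ac coverage per
#' bin) so that positive-score (A compartment) bins have mean activity at
#' least that of negative-score (B) bins.
#'
#' Per-distance expected values with fewer than 3 unmasked observations are
#' pooled with the neighboring (shorter) distance.
#'
#' @param map a [contact_map()] at compartment resolution.
#' @param activity_track non-negative numeric vector, one value per bin.
#' @param use_weights use balanced values when weights are present.
#' @return list of class `"compartment_track"` with `chrom`, `bin_size`, and
#'   `scores` (NA at masked bins).
#' @export
compartment_scores <- function(map, activity_track, use_weights = TRUE) {
  stopifnot(length(activity_track) == map$n_bins)
  if (any(activity_track < 0)) stop("activity track must be non-negative")
  m <- if (use_weights) balanced_matrix(map) else map$counts
  mask <- map$mask | rowSums(map$counts) == 0
  keep <- which(!mask)
  if (length(keep) < 3) stop("degenerate input: fewer than 3 usable bins")
  sub <- m[keep, keep, drop = FALSE]
  oe <- oe_normalize(sub, abs(outer(keep, keep, "-")))
  if (max(oe) - min(oe) < .Machine$double.eps) {
    stop("degenerate input: constant contact matrix")
  }
  cm <- suppressWarnings(stats::cor(oe))
  if (any(!is.finite(cm))) {
    # constant columns yield undefined correlations
    bad <- apply(oe, 2, stats::sd) == 0
    if (all(bad)) stop("degenerate input: constant contact matrix")
    keep <- keep[!bad]
    cm <- stats::cor(oe[!bad, !bad, drop = FALSE])
    if (any(!is.finite(cm))) stop("degenerate input: undefined correlations")
  }
  ev <- eigen(cm, symmetric = TRUE)$vectors[, 1]
  scores <- rep(NA_real_, map$n_bins)
  scores[keep] <- ev
  pos <- which(scores > 0)
  neg <- which(scores < 0)
  if (length(pos) && length(neg) &&
      mean(activity_track[pos]) < mean(activity_track[neg])) {
    scores <- -scores
  }
  structure(list(chrom = map$chrom, bin_size = map$bin_size, scores = scores),
            class = "compartment_track")
}

# observed / per-distance expected; distances with < min_obs observations are
# pooled with the next shorter distance
oe_normalize <- function(m, dist, min_obs = 3) {
  n <- nrow(m)
  maxd <- n - 1
  sums <- counts <- numeric(maxd + 1)
  for (d in 0:maxd) {
    vals <- m[dist == d]
    sums[d + 1] <- sum(vals)
    counts[d + 1] <- length(vals)
  }
  # pool sparse distances backwards onto their shorter neighbor
  expected <- numeric(maxd + 1)
  d <- 0
  while (d <= maxd) {
    s <- sums[d + 1]; k <- counts[d + 1]; dd <- d
    while (k < min_obs && dd < maxd) {
      dd <- dd + 1
      s <- s + sums[dd + 1]
      k <- k + counts[dd + 1]
    }
    expected[(d:dd) + 1] <- if (k > 0) s / k else 0
    d <- dd + 1
  }
  e <- expected[dist + 1]
  oe <- ifelse(e > 0, m / e, 0)
  dim(oe) <- dim(m)
  oe
}

#' @export
print.compartment_track <- function(x, ...) {
  cat(sprintf("compartment_track: %s, %d bins of %d bp (%d A / %d B)\n",
              x$chrom, length(x$scores), x$bin_size,
              sum(x$scores > 0, na.rm = TRUE), sum(x$scores < 0, na.rm = TRUE)))
  invisible(x)
}

#' Write per-bin scores as bedGraph
#'
#' Shared exporter for interaction-score and compartment tracks.
#'
#' @param scores numeric vector, one value per bin (NA bins skipped).
#' @param chrom chromosome name.
#' @param bin_size bin size in bp.
#' @param path output file.
#' @export
write_score_bedgraph <- function(scores, chrom, bin_size, path) {
  keep <- which(!is.na(scores))
  gr <- genomic_interval(rep(chrom, length(keep)),
                         (keep - 1) * bin_size, keep * bin_size,
                         score = scores[keep])
  write_bedgraph(gr, path)
}
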