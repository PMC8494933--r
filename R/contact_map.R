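#' Binned intra-chromosomal contact map
#'
#' Symmetric non-negative matrix of raw read-pair counts at a fixed bin size,
#' with optional Knight-Ruiz balancing weights and a mask of excluded
#' (low-coverage) bins. Bin `b` covers `[b * bin_size, (b + 1) * bin_size)` in
#' 0-based genomic coordinates.
#'
#' @param counts symmetric non-negative numeric matrix.
#' @param chrom chromosome name.
#' @param bin_size bin size in bp.
#' @param weights optional per-bin balancing weights (NA at masked bins).
#' @param mask optional logical vector marking excluded bins.
#' @return object of class `"contact_map"`.
#' @export
contact_map <- function(counts, chrom, bin_size, weights = NULL, mask = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(counts))) {
    stop("counts must be symmetric")
  }
  n <- nrow(counts)
  map <- list(chrom = chrom, bin_size = as.integer(bin_size), n_bins = n,
              counts = counts,
              weights = weights,
              mask = mask %||% rep(FALSE, n))
  class(map) <- "contact_map"
  map
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %s, %d bins of %d bp, %s counts, %s\n",
              x$chrom, x$n_bins, x$bin_size,
              format(sum(x$counts)),
              if (is.null(x$weights)) "unbalanced" else "KR-balanced"))
  invisible(x)
}

#' Read a contact map from sparse triplet text
#'
#' Rows are `bin_i<TAB>bin_j<TAB>count` (0-based bins, upper triangle or any
#' order); missing pairs are zero. The matrix is symmetrized by construction.
#'
#' @param path triplet file (one chromosome per file).
#' @param bin_size bin size in bp.
#' @param chrom_length chromosome length in bp (fixes the bin count).
#' @param chrom chromosome name.
#' @return a [contact_map()].
#' @export
read_contact_triplets <- function(path, bin_size, chrom_length, chrom = "chr") {
  n <- as.integer(ceiling(chrom_length / bin_size))
  m <- matrix(0, n, n)
  info <- file.info(path)
  if (!is.na(info$size) && info$size > 0) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("i", "j", "count"))
    if (any(tab$i != floor(tab$i)) || any(tab$j != floor(tab$j))) {
      stop("malformed input: bin indices must be integers")
    }
    if (any(tab$i < 0) || any(tab$j < 0) || any(tab$i >= n) || any(tab$j >= n)) {
      stop("malformed input: bin index out of range")
    }
    if (any(tab$count < 0)) stop("validation error: negative count")
    idx1 <- cbind(tab$i + 1L, tab$j + 1L)
    m[idx1] <- m[idx1] + tab$count
    off <- tab$i != tab$j
    idx2 <- cbind(tab$j[off] + 1L, tab$i[off] + 1L)
    m[idx2] <- m[idx2] + tab$count[off]
  }
  contact_map(m, chrom = chrom, bin_size = bin_size)
}

#' @rdname read_contact_triplets
#' @param map a `contact_map`.
#' @export
write_contact_triplets <- function(map, path) {
  ut <- which(upper.tri(map$counts, diag = TRUE) & map$counts != 0,
              arr.ind = TRUE)
  tab <- data.frame(i = ut[, 1] - 1L, j = ut[, 2] - 1L,
                    count = map$counts[ut])
  tab <- tab[order(tab$i, tab$j), ]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Knight-Ruiz balancing (inner-outer Newton with CG), following the standard
# bnewt formulation. Returns the weight vector solving diag(x) A diag(x) 1 = 1,
# or NULL on non-convergence.
kr_bnewt <- function(A, tol = 1e-8, delta = 0.1, Delta = 3, max_outer = 50) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  g <- 0.9
  etamax <- 0.1
  eta <- etamax
  stop_tol <- tol * 0.5
  rt <- tol^2
  v <- x * as.vector(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1
  rold <- rout
  mvp <- 0
  i <- 0
  while (rout > rt) {
    i <- i + 1
    if (i > max_outer) return(NULL)
    k <- 0
    y <- e
    innertol <- max(eta^2 * rout, rt)
    rho_km2 <- rho_km1
    Z <- p <- NULL
    while (rho_km1 > innertol) {
      k <- k + 1
      if (k == 1) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.vector(A %*% (x * p)) + v * p
      denom <- sum(p * w)
      if (!is.finite(denom) || denom == 0) return(NULL)
      alpha <- rho_km1 / denom
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        ind <- which(ap < 0)
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- which(ynew > Delta)
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      mvp <- mvp + 1
      if (mvp > 100000) return(NULL)
    }
    x <- x * y
    if (any(!is.finite(x)) || any(x <= 0)) return(NULL)
    v <- x * as.vector(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    mvp <- mvp + k + 1
    rat <- rout / rold
    rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / res_norm)
  }
  x
}

# symmetric Sinkhorn-Knopp iteration: w <- w / sqrt(w * (A w)) drives the
# balanced row sums to 1
sinkhorn_balance <- function(A, tol = 1e-8, max_iter = 5000) {
  w <- rep(1, nrow(A))
  for (it in seq_len(max_iter)) {
    s <- w * as.vector(A %*% w)
    if (any(!is.finite(s)) || any(s <= 0)) return(NULL)
    if (max(abs(s - 1)) < tol) return(w)
    w <- w / sqrt(s)
  }
  NULL
}

#' Knight-Ruiz balancing of a contact map
#'
#' Fills the per-bin weight vector so that the balanced value
#' `w_i * counts[i, j] * w_j` has equal row sums over all unmasked bins.
#' Bins whose raw marginal count falls below `mask_floor` (or is zero) are
#' masked before balancing and receive `NA` weights. Weights are rescaled so
#' the total balanced signal equals the total raw signal of the unmasked
#' submatrix, keeping balanced values on the read-count scale. If the
#' Knight-Ruiz Newton iteration fails to converge, a symmetric Sinkhorn-Knopp
#' iteration is used; if that also fails, an error is raised.
#'
#' @param map a [contact_map()].
#' @param tolerance maximum relative deviation of balanced row sums.
#' @param max_iter outer-iteration budget for the Newton solver.
#' @param mask_floor raw marginal-count floor below which a bin is masked.
#' @return the map with `weights` and `mask` filled.
#' @export
kr_balance <- function(map, tolerance = 1e-6, max_iter = 50, mask_floor = 10) {
  marg <- rowSums(map$counts)
  mask <- marg < max(mask_floor, .Machine$double.eps)
  if (all(mask)) stop("no unmasked bins to balance")
  A <- map$counts[!mask, !mask, drop = FALSE]
  w <- kr_bnewt(A, tol = tolerance * 0.1, max_outer = max_iter)
  if (is.null(w)) {
    log_stage("kr_balance", "Newton solver did not converge; Sinkhorn fallback")
    w <- sinkhorn_balance(A, tol = tolerance * 0.1)
  }
  if (is.null(w)) stop("balancing did not converge")
  # rescale: sum of balanced == sum of raw over unmasked bins
  bal_total <- sum(w * A %*% w)
  w <- w * sqrt(sum(A) / bal_total)
  weights <- rep(NA_real_, map$n_bins)
  weights[!mask] <- w
  map$weights <- weights
  map$mask <- mask
  log_stage("kr_balance", "%d/%d bins unmasked", sum(!mask), map$n_bins)
  map
}

#' Balanced matrix of a contact map
#'
#' `w_i * counts[i, j] * w_j`; rows/columns of masked bins are `NA`. For an
#' unbalanced map the raw counts are returned.
#'
#' @param map a [contact_map()].
#' @return numeric matrix.
#' @export
balanced_matrix <- function(map) {
  if (is.null(map$weights)) return(map$counts)
  b <- map$counts * outer(map$weights, map$weights)
  b
}

#' Per-bin interaction score
#'
#' The row sum of the (balanced, if weights are present) contact matrix,
#' excluding the diagonal element. Masked bins get `NA`, not zero.
#'
#' @param map a [contact_map()].
#' @param bins bin indices (0-based); default all bins.
#' @param use_weights use balanced values when available (default) or raw
#'   counts.
#' @return numeric vector of scores (named by 0-based bin index).
#' @export
interaction_score <- function(map, bins = NULL, use_weights = TRUE) {
  m <- if (use_weights) balanced_matrix(map) else map$counts
  diag(m) <- 0
  s <- rowSums(m)
  s[map$mask] <- NA_real_
  names(s) <- as.character(seq_len(map$n_bins) - 1L)
  if (!is.null(bins)) s <- s[as.character(bins)]
  s
}

#' Reproducibility of two replicate maps
#'
#' Pearson correlation of the per-bin interaction scores (diagonal-excluded
#' row sums) of two replicates, over the union-unmasked bins.
#'
#' @param map_rep1,map_rep2 [contact_map()]s on the same chromosome and grid.
#' @return Pearson r.
#' @export
replicate_reproducibility <- function(map_rep1, map_rep2) {
  if (map_rep1$n_bins != map_rep2$n_bins ||
      map_rep1$bin_size != map_rep2$bin_size ||
      !identical(map_rep1$chrom, map_rep2$chrom)) {
    stop("replicate maps must share chromosome, bin size and grid")
  }
  s1 <- interaction_score(map_rep1)
  s2 <- interaction_score(map_rep2)
  keep <- !is.na(s1) & !is.na(s2)
  if (sum(keep) < 3) stop("insufficient data: fewer than 3 shared unmasked bins")
  stats::cor(s1[keep], s2[keep], method = "pearson")
}

#' TAD score of an interval
#'
#' Intra-domain read pairs divided by all read pairs that overlap the domain,
#' on RAW counts, with same-bin (diagonal) pairs excluded from both counts.
#' The interval is snapped outward to the bin grid.
#'
#' @param map a [contact_map()] with raw counts.
#' @param tad a single `GRanges` interval or a `c(start, end)` 0-based bp pair.
#' @return fraction in `[0, 1]`, or `NA` when no read pair overlaps the TAD.
#' @export
tad_score <- function(map, tad) {
  if (inherits(tad, "GRanges")) {
    tad <- c(bed_start(tad)[1], bed_end(tad)[1])
  }
  bs <- map$bin_size
  first <- max(0L, as.integer(floor(tad[1] / bs)))
  last <- min(map$n_bins - 1L, as.integer(ceiling(tad[2] / bs)) - 1L)
  if (last < first) return(NA_real_)
  idx <- (first:last) + 1L
  m <- map$counts
  diag(m) <- 0
  intra <- sum(m[idx, idx, drop = FALSE]) / 2
  cross <- sum(m[idx, -idx, drop = FALSE])
  denom <- intra + cross
  if (denom == 0) return(NA_real_)
  intra / denom
}

#' Stratify regions by peak density
#'
#' Labels each region with its peak count per `length_unit` and assigns a
#' density group using the supplied bounds.
#'
#' @param regions `GRanges`.
#' @param peaks `GRanges` of peaks.
#' @param length_unit length unit in bp (default 100 kb).
#' @param bounds increasing left bounds of the density groups (default
#'   `c(0, 1, 2)`, i.e. groups `[0,1)`, `[1,2)`, `[2,Inf)`).
#' @return data.frame with `n_peaks`, `density`, and `group` per region.
#' @export
stratify_regions_by_peak_density <- function(regions, peaks,
                                             length_unit = 100000,
                                             bounds = c(0, 1, 2)) {
  n <- GenomicRanges::countOverlaps(regions, peaks)
  density <- n / (GenomicRanges::width(regions) / length_unit)
  grp <- cut(density, breaks = c(bounds, Inf), right = FALSE,
             labels = paste0("g", bounds))
  data.frame(n_peaks = n, density = density, group = as.character(grp))
}

#' Differential region score
#'
#' Per-region difference (default, `dko - wt`) or ratio (`dko / wt`) of paired
#' scores. Regions with an undefined score in either condition, or a zero
#' denominator in ratio mode, are dropped with a log entry.
#'
#' @param score_wt,score_dko paired numeric vectors.
#' @param mode `"difference"` or `"ratio"`.
#' @return numeric vector with `NA` at dropped positions.
#' @export
differential_region_score <- function(score_wt, score_dko,
                                      mode = c("difference", "ratio")) {
  mode <- match.arg(mode)
  stopifnot(length(score_wt) == length(score_dko))
  bad <- is.na(score_wt) | is.na(score_dko)
  if (mode == "ratio") bad <- bad | score_wt == 0
  out <- rep(NA_real_, length(score_wt))
  out[!bad] <- if (mode == "difference") {
    score_dko[!bad] - score_wt[!bad]
  } else {
    score_dko[!bad] / score_wt[!bad]
  }
  if (any(bad)) {
    log_stage("differential_region_score", "%d/%d region(s) dropped",
              sum(bad), length(bad))
  }
  out
}
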