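# Independent oracles, implemented as directly as possible from the
# definitions, against which the package's vectorized/optimized routines are
# checked.

# Symmetric Sinkhorn-Knopp balancing run to high precision. Returns weights w
# with all balanced row sums equal to 1.
oracle_sinkhorn <- function(A, tol = 1e-10, max_iter = 1e5) {
  w <- rep(1, nrow(A))
  for (it in seq_len(max_iter)) {
    s <- w * as.vector(A %*% w)
    if (max(abs(s - 1)) < tol) return(w)
    w <- w / sqrt(s)
  }
  stop("oracle did not converge")
}

# Exhaustive sign-assignment enumeration for the one-sided signed-rank test
# (zero differences dropped, ties mid-ranked). Feasible for n <= 15.
oracle_signed_rank <- function(x, y, alternative = "greater") {
  d <- x - y
  d <- d[d != 0]
  if (alternative == "less") d <- -d
  n <- length(d)
  stopifnot(n >= 1, n <= 15)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  hits <- 0
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m))[1:n]
    w <- sum(r[signs == 1])
    if (w >= v - 1e-9) hits <- hits + 1
  }
  hits / 2^n
}

# Brute-force tangency scan: sort ascending, scale both axes to [0, 1], find
# the point of maximum distance below the y = x diagonal by an explicit loop;
# ties broken to the largest index.
oracle_elbow <- function(values) {
  v <- sort(values)
  n <- length(v)
  d <- numeric(n)
  for (i in seq_len(n)) {
    x <- (i - 1) / (n - 1)
    y <- (v[i] - v[1]) / (v[n] - v[1])
    d[i] <- x - y
  }
  v[max(which(d >= max(d) - 1e-12))]
}

# Best modularity over all bipartitions of a small graph (exhaustive).
oracle_best_bipartition <- function(graph) {
  n <- igraph::vcount(graph)
  stopifnot(n <= 12)
  best_q <- -Inf
  best_m <- NULL
  for (m in 0:(2^(n - 1) - 1)) {
    memb <- c(1L, as.integer(intToBits(m))[seq_len(n - 1)] + 1L)
    q <- igraph::modularity(graph, memb, weights = igraph::E(graph)$weight)
    if (q > best_q) {
      best_q <- q
      best_m <- memb
    }
  }
  list(membership = best_m, modularity = best_q)
}

# All set partitions of n elements (n small), as membership vectors.
oracle_all_partitions <- function(n) {
  out <- list()
  recur <- function(memb, k) {
    if (length(memb) == n) {
      out[[length(out) + 1]] <<- memb
      return(invisible())
    }
    for (g in seq_len(k + 1)) recur(c(memb, g), max(k, g))
  }
  recur(integer(), 0L)
  out
}

# Brute-force PWM scan: score every offset on both strands with explicit
# per-position loops.
oracle_score_window <- function(p, sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  lom <- rbind(p$log_odds, N = 0)
  rc_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  score_strand <- function(cv) {
    best <- -Inf
    for (off in seq_len(length(cv) - p$length + 1)) {
      s <- 0
      for (pos in seq_len(p$length)) {
        s <- s + lom[cv[off + pos - 1], pos]
      }
      best <- max(best, s)
    }
    best
  }
  max(score_strand(chars), score_strand(rev(unname(rc_map[chars]))))
}

# Jaccard index of two GRanges interpreted as anchor sets (by exact match).
oracle_anchor_jaccard <- function(a, b) {
  key <- function(gr) {
    paste(as.character(GenomicRanges::seqnames(gr)),
          GenomicRanges::start(gr), GenomicRanges::end(gr))
  }
  ka <- unique(key(a))
  kb <- unique(key(b))
  length(intersect(ka, kb)) / length(union(ka, kb))
}

# Jaccard of two bp intervals c(start, end), half-open.
oracle_interval_jaccard <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  uni <- max(a[2], b[2]) - min(a[1], b[1])
  inter / uni
}

# Pearson correlation from raw sums (independent of stats::cor).
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Small symmetric contact map from an upper-triangle triplet list.
toy_map <- function(n, triplets, bin_size = 10, chrom = "chrT") {
  m <- matrix(0, n, n)
  for (t in triplets) {
    m[t[1] + 1, t[2] + 1] <- t[3]
    m[t[2] + 1, t[1] + 1] <- t[3]
  }
  contact_map(m, chrom = chrom, bin_size = bin_size)
}
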