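#' Position weight matrix
#'
#' Per-position base probabilities over A, C, G, T. A pseudocount is added and
#' columns renormalized at construction so log-odds are always finite. The
#' default background is uniform; log-odds use the natural log (the 7/3
#' classification thresholds are on that scale).
#'
#' @param probs 4 x L numeric matrix with rownames A, C, G, T (or L x 4, which
#'   is transposed); columns must each sum to 1 (to 1e-9) before pseudocount.
#' @param background length-4 base probabilities summing to 1.
#' @param pseudocount added to every probability before renormalization.
#' @return object of class `"pwm"` with elements `probs`, `background`,
#'   `log_odds` (4 x L, natural log), `length`.
#' @export
pwm <- function(probs, background = rep(0.25, 4), pseudocount = 1e-3) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4 && ncol(probs) == 4) probs <- t(probs)
  if (nrow(probs) != 4) stop("PWM must have 4 base rows")
  if (is.null(rownames(probs))) rownames(probs) <- c("A", "C", "G", "T")
  probs <- probs[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(abs(colSums(probs) - 1) > 1e-9)) {
    stop("each PWM position must sum to 1")
  }
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  p <- sweep(probs + pseudocount, 2, colSums(probs + pseudocount), "/")
  structure(list(probs = p, background = background,
                 log_odds = log(p / background), length = ncol(p)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cons <- paste(rownames(x$probs)[apply(x$probs, 2, which.max)], collapse = "")
  cat(sprintf("pwm: %d positions, consensus %s, max score %.3f\n",
              x$length, cons, sum(apply(x$log_odds, 2, max))))
  invisible(x)
}

#' Read/write a PWM as a tab-delimited probability matrix
#'
#' Four columns A, C, G, T with a header, one row per motif position.
#'
#' @param path file path.
#' @param ... passed to [pwm()]. The stored probabilities already include any
#'   pseudocount applied at construction, so `pseudocount` defaults to 0 here
#'   (avoiding double smoothing on a round trip).
#' @return a [pwm()].
#' @export
read_pwm <- function(path, ...) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE)
  args <- list(...)
  if (is.null(args$pseudocount)) args$pseudocount <- 0
  do.call(pwm, c(list(t(as.matrix(tab[, c("A", "C", "G", "T")]))), args))
}

#' @rdname read_pwm
#' @param x a `pwm`.
#' @export
write_pwm <- function(x, path) {
  utils::write.table(as.data.frame(t(x$probs)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tcf/Lef core-motif PWM
#'
#' A sharp 7-position matrix with consensus ATCAAAG, the core recognition
#' sequence of the Tcf/Lef HMG family, used as the default for scanning and
#' for planting motif instances in synthetic peaks.
#'
#' @param dominant probability of the consensus base at each position.
#' @return a [pwm()].
#' @export
tcf_lef_pwm <- function(dominant = 0.997) {
  consensus <- c("A", "T", "C", "A", "A", "A", "G")
  bases <- c("A", "C", "G", "T")
  probs <- vapply(consensus, function(b) {
    p <- rep((1 - dominant) / 3, 4)
    p[bases == b] <- dominant
    p
  }, numeric(4))
  rownames(probs) <- bases
  pwm(probs)
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Best PWM log-odds hit in a sequence window
#'
#' Scans every offset on both strands and returns the maximum sum of
#' per-position natural-log odds. `N` bases contribute 0 (background) at their
#' position.
#'
#' @param pwm a [pwm()].
#' @param sequence character string over A/C/G/T/N, at least as long as the
#'   motif.
#' @return best log-odds score.
#' @export
score_window <- function(pwm, sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- pwm$length
  if (length(chars) < L) stop("sequence shorter than the motif")
  if (!all(chars %in% c("A", "C", "G", "T", "N"))) {
    stop("sequence alphabet must be A/C/G/T/N")
  }
  lom <- rbind(pwm$log_odds, N = 0)
  scan <- function(cv) {
    idx <- match(cv, rownames(lom))
    n_off <- length(cv) - L + 1
    scores <- numeric(n_off)
    for (pos in seq_len(L)) {
      scores <- scores + lom[cbind(idx[pos:(pos + n_off - 1)], pos)]
    }
    max(scores)
  }
  rc <- rev(unname(REVCOMP[chars]))
  max(scan(chars), scan(rc))
}

#' Classify a peak by its best motif hit
#'
#' The sequence of the +/- 100 bp window around the peak summit (clipped to
#' the contig, with a warning) is scanned with [score_window()]. Motif+ when
#' the best hit strictly exceeds `pos_threshold` (default 7); Motif- when all
#' hits (equivalently, the best hit) fall strictly below `neg_threshold`
#' (default 3); MotifInt otherwise.
#'
#' @param pwm a [pwm()].
#' @param genome named character vector or `Biostrings::DNAStringSet` of
#'   contig sequences.
#' @param peaks data.frame with `chrom`, `start`, `end`, `summit` (0-based bp;
#'   summit inside the peak).
#' @param flank window half-width (default 100 bp).
#' @param pos_threshold,neg_threshold classification cutoffs.
#' @return the peaks with `best_score` and `motif_class` columns.
#' @export
classify_peaks <- function(pwm, genome, peaks, flank = 100L,
                           pos_threshold = 7, neg_threshold = 3) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  stopifnot(all(peaks$summit >= peaks$start & peaks$summit < peaks$end))
  n <- nrow(peaks)
  best <- numeric(n)
  clipped <- FALSE
  for (i in seq_len(n)) {
    contig <- genome[[peaks$chrom[i]]]
    clen <- nchar(contig)
    s <- peaks$summit[i] - flank
    e <- peaks$summit[i] + flank + 1  # half-open end
    if (s < 0 || e > clen) {
      clipped <- TRUE
      s <- max(0, s)
      e <- min(clen, e)
    }
    best[i] <- score_window(pwm, substr(contig, s + 1, e))
  }
  if (clipped) warning("some windows were clipped to the contig")
  peaks$best_score <- best
  peaks$motif_class <- ifelse(best > pos_threshold, "Motif+",
                              ifelse(best < neg_threshold, "Motif-", "MotifInt"))
  peaks
}
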