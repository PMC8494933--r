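# Shared deterministic test-case builders (used by the motif, lineage, and
# acceptance suites).

# A PWM whose consensus scores an exact target (pseudocount disabled so the
# closed form holds): each position has consensus probability
# 0.25 * exp(target / L).
pwm_with_consensus_score <- function(target, consensus = "AAAAAAA") {
  bases <- c("A", "C", "G", "T")
  cons <- strsplit(consensus, "")[[1]]
  L <- length(cons)
  p <- 0.25 * exp(target / L)
  stopifnot(p < 1)
  probs <- vapply(cons, function(b) {
    v <- rep((1 - p) / 3, 4)
    v[bases == b] <- p
    v
  }, numeric(4))
  rownames(probs) <- bases
  pwm(probs, pseudocount = 0)
}

# Hand-built, near-noiseless seven-lineage matrix exercising the win and CV
# rules deterministically. Lineage A's third replicate is sequenced at 10x
# depth, so raw-count CVs can exceed 1 for genes whose normalized expression
# is perfectly consistent.
build_leg_matrix <- function() {
  lineages <- c("A", "B", "C", "D", "E", "F", "G")
  reps <- 3L
  samples <- paste(rep(lineages, each = reps), 1:reps, sep = "_r")
  meta <- data.frame(sample = samples, lineage = rep(lineages, each = reps),
                     replicate = rep(1:reps, length(lineages)))
  set.seed(55)
  n_filler <- 120
  filler <- matrix(rep(round(runif(n_filler, 100, 1000)), length(samples)),
                   n_filler, length(samples))
  filler <- filler + matrix(rep(c(0L, 1L, 2L), each = 1),
                            n_filler, length(samples), byrow = TRUE)
  counts <- rbind(
    filler,
    g_only_B   = ifelse(meta$lineage == "B", 300, 0),
    g_high_cv  = ifelse(meta$lineage == "A", 200, 0),
    g_5of6     = ifelse(meta$lineage %in% c("C", "G"), 1200, 150),
    g_4of6     = ifelse(meta$lineage %in% c("C", "F", "G"), 1200, 150),
    g_49fold   = ifelse(meta$lineage == "D", 490, 100))
  rownames(counts)[seq_len(n_filler)] <- sprintf("filler%03d", seq_len(n_filler))
  # depth factor: lineage A replicate 3 at 10x
  hi <- which(meta$lineage == "A" & meta$replicate == 3)
  counts[, hi] <- counts[, hi] * 10
  list(counts = counts, meta = meta)
}
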