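#' Simulation specification for synthetic Hi-C contact maps
#'
#' Defines a distance-decay expected matrix (contact frequency proportional to
#' `(1 + d)^-decay_exponent` in bins) with optional planted structure: an
#' alternating compartment checkerboard, TAD blocks, focal loops, and a
#' differential-interaction region whose internal expectations are multiplied
#' by `fold` in one condition. Replicates are independent Poisson draws.
#'
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp.
#' @param bin_size bin size in bp.
#' @param decay_exponent distance-decay exponent (default 1, the canonical
#'   intra-chromosomal scaling).
#' @param depth total expected read pairs per replicate.
#' @param compartments `NULL` or `list(block_size =, factor =)`: alternating
#'   A/B blocks; same-label bin pairs are enriched by `factor`, cross-label
#'   pairs depleted by `1/factor`.
#' @param tads `NULL` or data.frame with `start`, `end` (bp) and `factor`.
#' @param loops `NULL` or data.frame with `anchor1`, `anchor2` (bp of anchor
#'   bins) and `intensity` (added expected counts at the anchor bin pair).
#' @param diff_hub `NULL` or `list(start =, end = (bp), condition = "wt" or
#'   "dko", fold =)`.
#' @param replicates replicates per condition.
#' @param seed integer seed.
#' @return list of class `"sim_contact_spec"`.
#' @export
sim_contact_spec <- function(chrom = "chrS", chrom_length = 2e7,
                             bin_size = 1e4, decay_exponent = 1,
                             depth = 2e6, compartments = NULL, tads = NULL,
                             loops = NULL, diff_hub = NULL, replicates = 1L,
                             seed = 1L) {
  spec <- list(chrom = chrom, chrom_length = chrom_length,
               bin_size = bin_size, decay_exponent = decay_exponent,
               depth = depth, compartments = compartments, tads = tads,
               loops = loops, diff_hub = diff_hub,
               replicates = as.integer(replicates), seed = as.integer(seed))
  stopifnot(spec$decay_exponent > 0, spec$depth > 0, spec$replicates >= 1)
  for (part in c("compartments", "tads", "loops", "diff_hub")) {
    p <- spec[[part]]
    if (!is.null(p)) {
      f <- if (is.data.frame(p)) p$factor %||% p$intensity else p$factor %||% p$fold
      if (any(f <= 0)) stop(part, ": all factors must be positive")
    }
  }
  class(spec) <- "sim_contact_spec"
  spec
}

bins_of <- function(start, end, bin_size, n) {
  (max(0L, floor(start / bin_size)):min(n - 1L, ceiling(end / bin_size) - 1L)) + 1L
}

# expected matrix for one condition ("wt"/"dko"), total scaled to spec$depth
sim_expected_matrix <- function(spec, condition) {
  n <- as.integer(ceiling(spec$chrom_length / spec$bin_size))
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- (1 + d)^(-spec$decay_exponent)
  if (!is.null(spec$compartments)) {
    block_bins <- max(1L, round(spec$compartments$block_size / spec$bin_size))
    lab <- ((seq_len(n) - 1) %/% block_bins) %% 2
    same <- outer(lab, lab, "==")
    E <- E * ifelse(same, spec$compartments$factor, 1 / spec$compartments$factor)
  }
  if (!is.null(spec$tads)) {
    for (k in seq_len(nrow(spec$tads))) {
      idx <- bins_of(spec$tads$start[k], spec$tads$end[k], spec$bin_size, n)
      E[idx, idx] <- E[idx, idx] * spec$tads$factor[k]
    }
  }
  E <- E * spec$depth / ((sum(E) + sum(diag(E))) / 2)
  if (!is.null(spec$loops)) {
    for (k in seq_len(nrow(spec$loops))) {
      i <- bins_of(spec$loops$anchor1[k], spec$loops$anchor1[k] + 1,
                   spec$bin_size, n)[1]
      j <- bins_of(spec$loops$anchor2[k], spec$loops$anchor2[k] + 1,
                   spec$bin_size, n)[1]
      E[i, j] <- E[i, j] + spec$loops$intensity[k]
      E[j, i] <- E[i, j]
    }
  }
  if (!is.null(spec$diff_hub) && condition == spec$diff_hub$condition) {
    idx <- bins_of(spec$diff_hub$start, spec$diff_hub$end, spec$bin_size, n)
    off <- outer(idx, idx, function(a, b) a != b)
    E[idx, idx][off] <- E[idx, idx][off] * spec$diff_hub$fold
  }
  if (any(!is.finite(E))) stop("expected value overflow")
  E
}

poisson_symmetric_draw <- function(E) {
  n <- nrow(E)
  ut <- upper.tri(E, diag = TRUE)
  x <- numeric(n * n)
  dim(x) <- c(n, n)
  x[ut] <- stats::rpois(sum(ut), E[ut])
  x + t(x) - diag(diag(x))
}

#' Simulate two-condition replicate contact maps with planted truth
#'
#' Expected matrix = depth-scaled distance decay x compartment checkerboard x
#' TAD blocks + focal loop additions; the differential-hub region's internal
#' expectations are multiplied by `fold` in one condition. Each replicate is
#' an independent Poisson draw; the same seed reproduces identical output.
#'
#' @param spec a [sim_contact_spec()].
#' @return list with `maps` (`$wt`, `$dko`: lists of [contact_map()]s, one per
#'   replicate) and `truth` (the planted compartment labels, TADs, loops, and
#'   differential region).
#' @export
simulate_contact_maps <- function(spec) {
  stopifnot(inherits(spec, "sim_contact_spec"))
  set.seed(spec$seed)
  n <- as.integer(ceiling(spec$chrom_length / spec$bin_size))
  maps <- list()
  for (cond in c("wt", "dko")) {
    E <- sim_expected_matrix(spec, cond)
    maps[[cond]] <- lapply(seq_len(spec$replicates), function(r) {
      # symmetric by construction; skip the validating constructor
      structure(list(chrom = spec$chrom, bin_size = as.integer(spec$bin_size),
                     n_bins = n, counts = poisson_symmetric_draw(E),
                     weights = NULL, mask = rep(FALSE, n)),
                class = "contact_map")
    })
  }
  truth <- list(
    compartment_labels = if (!is.null(spec$compartments)) {
      block_bins <- max(1L, round(spec$compartments$block_size / spec$bin_size))
      ((seq_len(n) - 1) %/% block_bins) %% 2
    },
    tads = spec$tads, loops = spec$loops, diff_hub = spec$diff_hub)
  list(maps = maps, truth = truth)
}

#' Simulate TF peaks with planted motif instances
#'
#' Builds one synthetic contig of uniform random sequence carrying `n_peaks`
#' non-overlapping peaks. A `fraction_direct` subset of peaks (the planted
#' direct-binding sites) receives one motif instance sampled from the PWM,
#' placed on a random strand within +/- `plant_offset` bp of the summit;
#' indirect peaks keep background sequence only. Planted instances are
#' rejection-sampled until their own log-odds score exceeds
#' `min_instance_score`: a direct-binding site is by definition one carrying
#' a functional (high-affinity) motif occurrence, so low-affinity draws from
#' the PWM's tail are not planted as direct sites.
#'
#' @param n_peaks number of peaks.
#' @param pwm a [pwm()] (default [tcf_lef_pwm()]).
#' @param fraction_direct fraction of peaks receiving a motif instance.
#' @param seed integer seed.
#' @param peak_width peak width in bp.
#' @param spacing distance between peak starts in bp.
#' @param plant_offset maximum |offset| of the planted instance from the
#'   summit (must keep the instance inside the scanned +/- 100 bp window).
#' @param min_instance_score minimum log-odds score of a planted instance
#'   (default 7, the direct-binding threshold).
#' @return list with `genome` (named character vector), `peaks` (data.frame
#'   with chrom/start/end/summit/name), and `truth` (logical: planted direct).
#' @export
simulate_peaks_and_sequences <- function(n_peaks, pwm = tcf_lef_pwm(),
                                         fraction_direct = 0.5, seed = 1L,
                                         peak_width = 300L, spacing = 1000L,
                                         plant_offset = 80L,
                                         min_instance_score = 7) {
  stopifnot(fraction_direct >= 0, fraction_direct <= 1)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  contig_len <- n_peaks * spacing + spacing
  contig <- sample(bases, contig_len, replace = TRUE)
  starts <- (seq_len(n_peaks) - 1L) * spacing + spacing %/% 4L
  summits <- starts + peak_width %/% 2L
  n_direct <- round(n_peaks * fraction_direct)
  direct <- rep(FALSE, n_peaks)
  if (n_direct > 0) direct[sample.int(n_peaks, n_direct)] <- TRUE
  L <- pwm$length
  inst_score <- function(inst) {
    sum(pwm$log_odds[cbind(match(inst, rownames(pwm$log_odds)), seq_len(L))])
  }
  max_score <- sum(apply(pwm$log_odds, 2, max))
  if (max_score <= min_instance_score && n_direct > 0) {
    stop("the PWM's consensus cannot reach min_instance_score")
  }
  for (i in which(direct)) {
    repeat {
      inst <- vapply(seq_len(L), function(p) {
        sample(bases, 1, prob = pwm$probs[, p])
      }, character(1))
      if (inst_score(inst) > min_instance_score) break
    }
    if (stats::runif(1) < 0.5) inst <- rev(unname(REVCOMP[inst]))
    off <- sample.int(2L * plant_offset + 1L, 1) - plant_offset - 1L
    pos <- summits[i] + off  # 0-based start of the instance
    contig[(pos + 1):(pos + L)] <- inst
  }
  genome <- stats::setNames(paste(contig, collapse = ""), "chrS")
  peaks <- data.frame(chrom = "chrS", start = starts,
                      end = starts + peak_width, summit = summits,
                      name = sprintf("peak%04d", seq_len(n_peaks)))
  list(genome = genome, peaks = peaks, truth = direct)
}

#' Simulate a multi-lineage expression matrix with planted LEGs
#'
#' Negative-binomial counts for `n_lineages` lineages with `replicates`
#' replicates each. Baseline per-gene means are log-normal and shared across
#' lineages; each lineage receives `legs_per_lineage` planted marker genes
#' whose mean in that lineage is `fold` times the baseline.
#'
#' @param n_genes total genes.
#' @param lineages lineage names (default the seven pan-immune cell types).
#' @param replicates replicates per lineage.
#' @param legs_per_lineage planted markers per lineage.
#' @param fold planted enrichment (>= 5).
#' @param dispersion NB dispersion (default 0.1).
#' @param base_meanlog,base_sdlog log-normal parameters of baseline means.
#' @param seed integer seed.
#' @return list with `counts`, `meta`, and `truth` (data.frame gene/lineage).
#' @export
simulate_expression <- function(n_genes = 2000L,
                                lineages = c("panT", "B", "NK", "cDC", "pDC",
                                             "mono", "granulo"),
                                replicates = 3L, legs_per_lineage = 10L,
                                fold = 10, dispersion = 0.1,
                                base_meanlog = log(100), base_sdlog = 0.7,
                                seed = 1L) {
  if (fold < 5) stop("planted LEG folds must be >= 5")
  set.seed(seed)
  n_lin <- length(lineages)
  base <- stats::rlnorm(n_genes, base_meanlog, base_sdlog)
  mu <- matrix(base, n_genes, n_lin)
  colnames(mu) <- lineages
  genes <- sprintf("gene%05d", seq_len(n_genes))
  leg_idx <- sample.int(n_genes, legs_per_lineage * n_lin)
  truth <- data.frame(gene = genes[leg_idx],
                      lineage = rep(lineages, each = legs_per_lineage))
  for (k in seq_along(leg_idx)) {
    mu[leg_idx[k], truth$lineage[k]] <- base[leg_idx[k]] * fold
  }
  samples <- paste(rep(lineages, each = replicates),
                   rep(seq_len(replicates), n_lin), sep = "_r")
  counts <- matrix(0L, n_genes, length(samples),
                   dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    L <- rep(lineages, each = replicates)[j]
    counts[, j] <- stats::rnbinom(n_genes, size = 1 / dispersion, mu = mu[, L])
  }
  meta <- data.frame(sample = samples,
                     lineage = rep(lineages, each = replicates),
                     replicate = rep(seq_len(replicates), n_lin))
  list(counts = counts, meta = meta, truth = truth)
}

#' Simulate a loop universe with planted anchor hubs
#'
#' Planted hubs are dense near-cliques of anchors (every pair looped with
#' probability `density`, plus a random spanning tree so each hub is
#' connected); isolated loops connect otherwise-unused anchor pairs. Anchors
#' are non-overlapping fixed-width windows along one synthetic chromosome.
#'
#' @param n_hubs planted hubs.
#' @param hub_size_range inclusive range of anchors per hub (>= 3).
#' @param n_isolated isolated loops.
#' @param seed integer seed.
#' @param density within-hub loop probability.
#' @param anchor_width anchor width in bp.
#' @param chrom chromosome name.
#' @return list with `loops` (a `loop_set`) and `truth` (list of per-hub
#'   anchor index sets into the `anchors` GRanges, also returned).
#' @export
simulate_loop_universe <- function(n_hubs = 1L, hub_size_range = c(10L, 14L),
                                   n_isolated = 50L, seed = 1L,
                                   density = 0.8, anchor_width = 10000L,
                                   chrom = "chrS") {
  stopifnot(hub_size_range[1] >= 3)
  set.seed(seed)
  size_vals <- seq(hub_size_range[1], hub_size_range[2])
  sizes <- if (n_hubs > 0) {
    size_vals[sample.int(length(size_vals), n_hubs, replace = TRUE)]
  } else integer()
  n_anchor <- sum(sizes) + 2L * n_isolated
  gap <- 2L * anchor_width
  starts <- sample(seq_len(n_anchor)) * (anchor_width + gap)
  anchors <- genomic_interval(rep(chrom, n_anchor), starts,
                              starts + anchor_width)
  pairs <- NULL
  truth <- list()
  used <- 0L
  for (h in seq_len(n_hubs)) {
    members <- used + seq_len(sizes[h])
    used <- used + sizes[h]
    truth[[h]] <- members
    all_pairs <- t(utils::combn(members, 2))
    keep <- stats::runif(nrow(all_pairs)) < density
    # random spanning tree guarantees connectivity
    perm <- sample(members)
    tree <- cbind(perm[-length(perm)], perm[-1])
    hub_pairs <- unique(rbind(all_pairs[keep, , drop = FALSE],
                              t(apply(tree, 1, sort))))
    pairs <- rbind(pairs, hub_pairs)
  }
  if (n_isolated > 0) {
    iso <- matrix(used + seq_len(2L * n_isolated), ncol = 2, byrow = TRUE)
    pairs <- rbind(pairs, iso)
  }
  s <- bed_start(anchors)
  e <- bed_end(anchors)
  loops <- as_loop_set(data.frame(
    chrom1 = chrom, start1 = s[pairs[, 1]], end1 = e[pairs[, 1]],
    chrom2 = chrom, start2 = s[pairs[, 2]], end2 = e[pairs[, 2]]))
  list(loops = loops, anchors = anchors, truth = truth)
}
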