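#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline in one validated object.
#' Defaults are the values used throughout the analyses: 10-kb working
#' resolution, 100-kb compartment resolution, motif log-odds cutoffs of 7
#' (direct binding) and 3 (indirect), the weak-interaction sum filter of 10,
#' the degree/distance^2 projection ratio of 0.5, the 1e-7 differential-hub
#' p-value, fold-change/significance cutoffs for loops, accessible sites,
#' super-enhancers and lineage-enriched genes, and the promoter/upstream
#' association windows.
#'
#' @param bin_size working Hi-C bin size in bp.
#' @param compartment_bin_size bin size for compartment scoring in bp.
#' @param motif_pos_threshold log-odds above which a peak is Motif+.
#' @param motif_neg_threshold log-odds below which all hits must fall for Motif-.
#' @param weak_interaction_sum bin pairs with (WT + dKO) balanced signal at or
#'   below this value are excluded from differential-hub networks.
#' @param projection_ratio cutoff for the degree/distance^2 projection rule.
#' @param projection_comparator `"<"` (as printed) or `">="`; see
#'   [project_cluster()].
#' @param hub_pvalue Wilcoxon p-value cutoff for reported differential hubs.
#' @param loop_fc,loop_p fold-change and p-value cutoffs for differential loops.
#' @param chracc_fc,chracc_fdr cutoffs for differential accessible sites.
#' @param se_fdr FDR cutoff for differential super-enhancers.
#' @param leg_fc,leg_fdr,leg_min_wins,leg_cv_max lineage-enriched gene rules:
#'   pairwise fold/FDR, minimum wins out of (n lineages - 1), and the maximum
#'   within-lineage coefficient of variation.
#' @param deg_fc,deg_fdr,deg_min_level two-genotype DEG rules (fold, FDR, and
#'   the minimum expression required in the higher group).
#' @param promoter_flank promoter half-width around the TSS in bp.
#' @param upstream_assoc upstream window for element-to-gene association in bp.
#' @param stitch_distance maximum gap merged when stitching enhancer islands.
#' @param mask_floor bins with raw marginal counts below this are masked before
#'   balancing.
#' @param rng_seed integer seed used by stochastic steps.
#' @return A list of class `"chromhubs_config"`.
#' @export
analysis_config <- function(bin_size = 10000L,
                            compartment_bin_size = 100000L,
                            motif_pos_threshold = 7,
                            motif_neg_threshold = 3,
                            weak_interaction_sum = 10,
                            projection_ratio = 0.5,
                            projection_comparator = c("<", ">="),
                            hub_pvalue = 1e-7,
                            loop_fc = 2.0,
                            loop_p = 0.05,
                            chracc_fc = 2.0,
                            chracc_fdr = 0.05,
                            se_fdr = 0.05,
                            leg_fc = 5.0,
                            leg_fdr = 0.01,
                            leg_min_wins = 5L,
                            leg_cv_max = 1.0,
                            deg_fc = 2.0,
                            deg_fdr = 0.05,
                            deg_min_level = 1,
                            promoter_flank = 1000L,
                            upstream_assoc = 50000L,
                            stitch_distance = 12500L,
                            mask_floor = 10,
                            rng_seed = 1L) {
  projection_comparator <- match.arg(projection_comparator)
  cfg <- list(
    bin_size = as.integer(bin_size),
    compartment_bin_size = as.integer(compartment_bin_size),
    motif_pos_threshold = motif_pos_threshold,
    motif_neg_threshold = motif_neg_threshold,
    weak_interaction_sum = weak_interaction_sum,
    projection_ratio = projection_ratio,
    projection_comparator = projection_comparator,
    hub_pvalue = hub_pvalue,
    loop_fc = loop_fc, loop_p = loop_p,
    chracc_fc = chracc_fc, chracc_fdr = chracc_fdr,
    se_fdr = se_fdr,
    leg_fc = leg_fc, leg_fdr = leg_fdr,
    leg_min_wins = as.integer(leg_min_wins), leg_cv_max = leg_cv_max,
    deg_fc = deg_fc, deg_fdr = deg_fdr, deg_min_level = deg_min_level,
    promoter_flank = as.integer(promoter_flank),
    upstream_assoc = as.integer(upstream_assoc),
    stitch_distance = as.integer(stitch_distance),
    mask_floor = mask_floor,
    rng_seed = as.integer(rng_seed)
  )
  num <- cfg[!names(cfg) %in% "projection_comparator"]
  if (any(!vapply(num, is.numeric, logical(1))) ||
      any(vapply(num, function(x) any(x <= 0), logical(1)) &
          !names(num) %in% "rng_seed")) {
    stop("all configuration thresholds must be positive numbers")
  }
  if (cfg$motif_neg_threshold >= cfg$motif_pos_threshold) {
    stop("motif_neg_threshold must be smaller than motif_pos_threshold")
  }
  class(cfg) <- "chromhubs_config"
  cfg
}

#' @export
print.chromhubs_config <- function(x, ...) {
  cat("chromhubs analysis configuration\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read/write a configuration file
#'
#' Plain `key<TAB>value` text; unknown keys are rejected so typos surface early.
#'
#' @param path file path.
#' @param overrides named list applied on top of the file values.
#' @return [analysis_config()] object.
#' @export
read_config <- function(path, overrides = list()) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("key", "value"),
                           colClasses = "character", quote = "")
  args <- stats::setNames(as.list(tab$value), tab$key)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(args), known)
  if (length(bad)) stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  args[names(args) != "projection_comparator"] <-
    lapply(args[names(args) != "projection_comparator"], as.numeric)
  args[names(overrides)] <- overrides
  do.call(analysis_config, args)
}

#' @rdname read_config
#' @param config a `chromhubs_config` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "chromhubs_config"))
  lines <- vapply(names(config), function(nm) {
    paste(nm, format(config[[nm]], scientific = FALSE), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# stage-granularity logging: counts in/out of every filter are reported via
# message() so "N survived"-style numbers are inspectable but suppressible
log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
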