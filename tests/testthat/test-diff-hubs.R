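# Balanced toy pair on a shared grid; values are used directly (no weights).
diff_pair <- function(wt_vals, dko_vals, n = 4, bin_size = 10) {
  sym <- function(m) {
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  list(wt = contact_map(sym(wt_vals), "chrD", bin_size),
       dko = contact_map(sym(dko_vals), "chrD", bin_size))
}

test_that("directional edge selection honors the weak-sum and strictness rules", {
  wt <- matrix(0, 4, 4)
  dko <- matrix(0, 4, 4)
  # totals are equal by construction, so the internal depth normalization is
  # the identity and the stated values are compared as-is
  wt[1, 2] <- 6;   dko[1, 2] <- 4    # sum 10, excluded (boundary)
  wt[1, 3] <- 7;   dko[1, 3] <- 4    # sum 11, wt > dko, kept
  wt[2, 3] <- 5;   dko[2, 3] <- 15   # dko-direction edge
  wt[3, 4] <- 8;   dko[3, 4] <- 8    # tie: kept by neither direction
  wt[1, 4] <- 7.5; dko[1, 4] <- 2.5  # sum 10, excluded despite wt > dko
  maps <- diff_pair(wt, dko)
  expect_equal(sum(maps$wt$counts), sum(maps$dko$counts))

  e_wt <- suppressMessages(select_directional_edges(maps$wt, maps$dko, "wt"))
  expect_equal(nrow(e_wt), 1)
  expect_equal(c(e_wt$bin_i, e_wt$bin_j), c(0, 2))
  e_dko <- suppressMessages(select_directional_edges(maps$wt, maps$dko, "dko"))
  expect_equal(c(e_dko$bin_i, e_dko$bin_j), c(1, 2))

  # direction disjointness on random maps
  set.seed(31)
  r1 <- matrix(rpois(100, 12), 10, 10)
  r2 <- matrix(rpois(100, 12), 10, 10)
  m1 <- contact_map(r1 + t(r1), "chrD", 10)
  m2 <- contact_map(r2 + t(r2), "chrD", 10)
  a <- suppressMessages(select_directional_edges(m1, m2, "wt"))
  b <- suppressMessages(select_directional_edges(m1, m2, "dko"))
  key <- function(e) paste(e$bin_i, e$bin_j)
  expect_equal(length(intersect(key(a), key(b))), 0)

  # wt = dko everywhere -> empty edge list
  z <- suppressMessages(select_directional_edges(m1, m1, "wt"))
  expect_equal(nrow(z), 0)

  # mismatched grids error
  m3 <- contact_map(matrix(0, 5, 5), "chrD", 10)
  expect_error(select_directional_edges(m1, m3, "wt"), "grid")

  # max_dist cap drops long-range pairs
  capped <- suppressMessages(select_directional_edges(m1, m2, "wt",
                                                      max_dist = 2))
  expect_true(all(capped$bin_j - capped$bin_i <= 2))
})

test_that("diff-network clustering uses reference weights and emits no singletons", {
  # two disjoint edge sets -> 2 clusters
  edges <- data.frame(bin_i = c(0, 1, 10, 11), bin_j = c(1, 2, 11, 12),
                      wt = c(5, 5, 5, 5), dko = c(1, 1, 1, 1))
  cl <- cluster_diff_network(edges, "wt", seed = 1)
  expect_equal(length(unique(cl$membership)), 2)
  expect_equal(cl$bins, c(0, 1, 2, 10, 11, 12))  # nodes exist only via edges

  # chain A-B-C with weights 10, 1: the clustering reaches the best
  # modularity found by exhaustive partition scoring
  chain <- data.frame(bin_i = c(0, 1), bin_j = c(1, 2),
                      wt = c(10, 1), dko = c(1, 1))
  cc <- cluster_diff_network(chain, "wt", seed = 1)
  g <- cc$graph
  parts <- oracle_all_partitions(3)
  q <- vapply(parts, function(p)
    igraph::modularity(g, p, weights = igraph::E(g)$weight), numeric(1))
  expect_equal(igraph::modularity(g, cc$membership,
                                  weights = igraph::E(g)$weight), max(q))

  # degree is the unweighted incident-edge count
  expect_equal(unname(cc$degree), c(1, 2, 1))
  expect_error(cluster_diff_network(edges[0, ], "wt"), "no edges")
})

test_that("cluster projection applies the printed degree/distance^2 rule", {
  # singleton cluster -> region = the seed bin alone
  p <- project_cluster(5L, degrees = 3, pagerank_scores = 1)
  expect_equal(p$seed_bin, 5L)
  expect_equal(p$region, c(5L, 5L))

  # printed example: degree 4 at distance 3 -> 4/9 < 0.5 -> included;
  # degree 4 at distance 2 -> 1.0 -> excluded
  bins <- c(10L, 13L, 12L)
  deg <- c(9, 4, 4)
  pr <- c(0.5, 0.3, 0.2)
  p2 <- project_cluster(bins, deg, pr, ratio = 0.5, comparator = "<")
  expect_equal(p2$seed_bin, 10L)
  expect_equal(p2$member_bins, c(10L, 13L))
  expect_equal(p2$region, c(10L, 13L))

  # the alternative comparator inverts the inclusion
  p3 <- project_cluster(bins, deg, pr, ratio = 0.5, comparator = ">=")
  expect_equal(p3$member_bins, c(10L, 12L))

  # all non-seed nodes excluded -> region = seed bin only
  p4 <- project_cluster(c(10L, 11L), c(5, 9), c(0.9, 0.1), comparator = "<")
  expect_equal(p4$region, c(10L, 10L))

  # PageRank ties break to the smaller bin; duplicate bins skipped with log
  p5 <- project_cluster(c(20L, 7L), c(1, 1), c(0.5, 0.5))
  expect_equal(p5$seed_bin, 7L)
  expect_message(p6 <- project_cluster(c(4L, 4L, 9L), c(1, 1, 30),
                                       c(0.9, 0.1, 0.1)), "duplicate")
  expect_equal(p6$seed_bin, 4L)

  # projection regions are contiguous and contain their seed
  set.seed(15)
  for (k in 1:10) {
    nb <- sample(2:8, 1)
    bins <- sort(sample(0:50, nb))
    pp <- project_cluster(bins, sample(1:10, nb, TRUE), runif(nb))
    expect_true(pp$seed_bin >= pp$region[1] && pp$seed_bin <= pp$region[2])
    expect_true(all(pp$member_bins >= pp$region[1] &
                      pp$member_bins <= pp$region[2]))
  }
})

test_that("region significance matches the exact signed-rank oracle", {
  # wt = dko internally -> p = 1 (all differences zero)
  b <- matrix(5, 6, 6)
  expect_warning(p <- test_region_significance(c(0, 3), b, b, "wt"), "zero")
  expect_equal(p, 1)

  # 10 internal pairs (5 bins), wt = dko + 1 -> p = 1/2^10
  b_wt <- matrix(6, 5, 5)
  b_dko <- matrix(5, 5, 5)
  p2 <- test_region_significance(c(0, 4), b_wt, b_dko, "wt")
  expect_equal(p2, 1 / 2^10)

  # direction flipped on the same data -> p >= 0.5
  p3 <- test_region_significance(c(0, 4), b_wt, b_dko, "dko")
  expect_gte(p3, 0.5)

  # random balanced values agree with exhaustive enumeration
  set.seed(44)
  bw <- matrix(runif(25, 4, 8), 5, 5)
  bd <- matrix(runif(25, 4, 8), 5, 5)
  ut <- upper.tri(bw)
  expect_equal(test_region_significance(c(0, 4), bw, bd, "wt"),
               oracle_signed_rank(bw[ut], bd[ut], "greater"))
  expect_error(test_region_significance(c(2, 2), bw, bd, "wt"), "2 bins")
})

test_that("gene-hub association uses 1-bp promoter overlap on hub regions", {
  hubs <- data.frame(chrom = "chrD", start = 100000, end = 200000,
                     direction = "wt", seed_bin = 12L, n_bins = 5L,
                     n_internal_pairs = 10L, p_value = 1e-9)
  genes <- data.frame(
    gene = c("inside", "boundary_out", "edge_touch", "dup", "dup"),
    chrom = "chrD",
    tss = c(150000, 201001, 199999, 150000, 150000),
    tes = c(151000, 202000, 201000, 151000, 151000),
    strand = "+")
  out <- associate_genes_to_hubs(hubs, genes, flank = 1000L)
  # promoter inside -> associated; promoter starting 1 bp past the end -> not
  expect_true("inside" %in% out$gene)
  expect_false("boundary_out" %in% out$gene)
  # promoter straddling the boundary still overlaps by >= 1 bp
  expect_true("edge_touch" %in% out$gene)
  # duplicate TSS records give duplicate rows
  expect_equal(sum(out$gene == "dup"), 2)
  empty <- associate_genes_to_hubs(hubs[0, ], genes)
  expect_equal(nrow(empty), 0)
})

planted_diff_run <- function(seed, fold, start = 1e7, end = 1.03e7,
                             condition = "wt") {
  spec <- sim_contact_spec(diff_hub = list(start = start, end = end,
                                           condition = condition, fold = fold),
                           seed = seed)
  sim <- simulate_contact_maps(spec)
  list(wt = suppressMessages(kr_balance(sim$maps$wt[[1]])),
       dko = suppressMessages(kr_balance(sim$maps$dko[[1]])))
}

test_that("the full diff-hub pipeline recovers a planted region", {
  maps <- planted_diff_run(seed = 1, fold = 3)
  hubs <- suppressMessages(call_diff_hubs(maps$wt, maps$dko, "wt"))
  expect_equal(nrow(hubs), 1)
  expect_gte(oracle_interval_jaccard(c(hubs$start, hubs$end), c(1e7, 1.03e7)),
             0.6)
  expect_lt(hubs$p_value, 1e-7)
  # the seed bin lies inside the reported region
  expect_gte(hubs$seed_bin * 1e4, hubs$start)
  expect_lt(hubs$seed_bin * 1e4, hubs$end)

  # swapping WT/dKO converts the call to dKO-specific with the same region
  swapped <- suppressMessages(call_diff_hubs(maps$dko, maps$wt, "dko"))
  expect_equal(nrow(swapped), 1)
  expect_equal(swapped$start, hubs$start)
  expect_equal(swapped$end, hubs$end)
  expect_equal(swapped$direction, "dko")

  # determinism: the same seeded inputs give identical calls
  again <- suppressMessages(call_diff_hubs(maps$wt, maps$dko, "wt"))
  expect_identical(again, hubs)

  # monotonicity at the fixed planted region: a larger fold never increases
  # the Wilcoxon p (the projected region itself may shrink as degrees grow,
  # so the comparison is made at the planted region)
  maps5 <- planted_diff_run(seed = 1, fold = 5)
  norm_pair <- function(m) {
    b_wt <- balanced_matrix(m$wt)
    b_dko <- balanced_matrix(m$dko)
    b_wt[is.na(b_wt)] <- 0
    b_dko[is.na(b_dko)] <- 0
    list(wt = b_wt, dko = b_dko * sum(b_wt) / sum(b_dko))
  }
  region <- c(1e7 / 1e4, 1.03e7 / 1e4 - 1)
  b3 <- norm_pair(maps)
  b5 <- norm_pair(maps5)
  p3 <- test_region_significance(region, b3$wt, b3$dko, "wt")
  p5 <- test_region_significance(region, b5$wt, b5$dko, "wt")
  expect_lte(p5, p3)
})

test_that("null maps produce calibrated, non-significant region p-values", {
  cfg <- analysis_config(hub_pvalue = 1)  # keep every region to inspect p
  ps <- c()
  for (s in 1:2) {
    maps <- planted_diff_run(seed = s, fold = 1)
    h <- suppressMessages(call_diff_hubs(maps$wt, maps$dko, "wt",
                                         config = cfg))
    ps <- c(ps, h$p_value)
    # at the reporting threshold nothing is called
    strict <- suppressMessages(call_diff_hubs(maps$wt, maps$dko, "wt"))
    expect_equal(nrow(strict), 0)
  }
  expect_gt(length(ps), 5)
  for (alpha in c(0.05, 0.01)) {
    bound <- alpha + 3 * sqrt(alpha * (1 - alpha) / length(ps))
    expect_lte(mean(ps < alpha), bound)
  }
})
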