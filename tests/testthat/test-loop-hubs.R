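make_loops <- function(pairs, anchors) {
  # pairs: 2-column matrix of anchor indices; anchors: list of c(start, end)
  df <- data.frame(
    chrom1 = "chrL",
    start1 = vapply(pairs[, 1], function(i) anchors[[i]][1], numeric(1)),
    end1 = vapply(pairs[, 1], function(i) anchors[[i]][2], numeric(1)),
    chrom2 = "chrL",
    start2 = vapply(pairs[, 2], function(i) anchors[[i]][1], numeric(1)),
    end2 = vapply(pairs[, 2], function(i) anchors[[i]][2], numeric(1)))
  as_loop_set(df)
}

test_that("loop annotation follows the PP/PE/EE precedence exactly", {
  anchors <- list(c(0, 100), c(1000, 1100), c(2000, 2100), c(3000, 3100))
  loops <- make_loops(rbind(c(1, 2), c(1, 3), c(3, 4), c(2, 3)), anchors)
  promoters <- genomic_interval(c("chrL", "chrL"), c(50, 1050), c(80, 1080))
  chracc <- genomic_interval(c("chrL", "chrL", "chrL"),
                             c(60, 2050, 3050), c(70, 2080, 3080))
  ann <- annotate_loops(loops, promoters, chracc)
  # both anchors overlap promoters (anchor1 also overlaps ChrAcc) -> PP
  expect_equal(ann$annotation[1], "PP")
  # promoter-only anchor + ChrAcc-only anchor -> PE
  expect_equal(ann$annotation[2], "PE")
  # both anchors ChrAcc, no promoter -> EE
  expect_equal(ann$annotation[3], "EE")
  expect_equal(ann$annotation[4], "PE")
  # neither anchor overlaps anything -> other
  far <- make_loops(rbind(c(1, 2)), list(c(9e5, 9e5 + 100), c(8e5, 8e5 + 100)))
  expect_equal(annotate_loops(far, promoters, chracc)$annotation, "other")
})

test_that("loop graph merges overlapping anchors and rejects self-edges", {
  # 2 loops sharing an identical anchor -> 3 nodes, 2 edges
  anchors <- list(c(0, 100), c(1000, 1100), c(2000, 2100))
  loops <- make_loops(rbind(c(1, 2), c(2, 3)), anchors)
  g <- build_loop_graph(loops)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  # node order fixed by coordinate
  expect_equal(igraph::V(g)$start, c(0, 1000, 2000))

  # anchors overlapping by 1 bp merge into a shared node
  ov <- as_loop_set(data.frame(
    chrom1 = "chrL", start1 = c(0, 1099), end1 = c(100, 1200),
    chrom2 = "chrL", start2 = c(1000, 2000), end2 = c(1100, 2100)))
  g2 <- build_loop_graph(ov)
  expect_equal(igraph::vcount(g2), 3)  # [0,100), [1000,1200), [2000,2100)
  expect_equal(igraph::ecount(g2), 2)
  # the merged node carries the union interval
  expect_true(any(igraph::V(g2)$start == 1000 & igraph::V(g2)$end == 1200))

  # loop whose anchors merge into one node -> rejected as self-edge
  self <- as_loop_set(data.frame(
    chrom1 = "chrL", start1 = c(0, 5000), end1 = c(100, 5100),
    chrom2 = "chrL", start2 = c(50, 6000), end2 = c(150, 6100)))
  g3 <- suppressMessages(build_loop_graph(self))
  expect_equal(igraph::ecount(g3), 1)

  # duplicate loops collapse with a warning
  dup <- make_loops(rbind(c(1, 2), c(1, 2)), anchors)
  expect_warning(g4 <- build_loop_graph(dup), "duplicate")
  expect_equal(igraph::ecount(g4), 1)
})

test_that("community detection maximizes modularity on reference graphs", {
  # two 5-cliques joined by a single edge -> the clique bipartition,
  # verified against exhaustive 2-partition modularity
  clique_edges <- function(members) t(utils::combn(members, 2))
  el <- rbind(clique_edges(1:5), clique_edges(6:10), c(5, 6))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$weight <- 1
  memb <- detect_communities(g, seed = 1)
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[1:5])), 1)
  expect_equal(length(unique(memb[6:10])), 1)
  oracle <- oracle_best_bipartition(g)
  expect_equal(igraph::modularity(g, memb, weights = igraph::E(g)$weight),
               oracle$modularity)

  # edgeless graph -> n singleton clusters
  g0 <- igraph::make_empty_graph(5, directed = FALSE)
  expect_equal(detect_communities(g0), 1:5)
  expect_error(detect_communities(igraph::make_empty_graph(0)), "empty")

  # single triangle -> one cluster
  tri <- igraph::graph_from_edgelist(rbind(c(1, 2), c(2, 3), c(1, 3)),
                                     directed = FALSE)
  igraph::E(tri)$weight <- 1
  expect_equal(length(unique(detect_communities(tri))), 1)
})

test_that("hub calling recovers a planted dense cluster", {
  sim <- simulate_loop_universe(n_hubs = 1, hub_size_range = c(12L, 12L),
                                n_isolated = 50L, seed = 5)
  res <- suppressWarnings(suppressMessages(identify_hubs(sim$loops, seed = 1)))
  expect_equal(length(res$hubs), 1)
  planted <- sim$anchors[sim$truth[[1]]]
  jac <- oracle_anchor_jaccard(res$hubs[[1]]$anchors, planted)
  expect_gte(jac, 0.8)
  # the elbow threshold equals the brute-force tangency oracle
  expect_equal(res$threshold, oracle_elbow(res$cluster_sizes))
  # hub size strictly above the threshold; isolated loops reported separately
  expect_gt(res$hubs[[1]]$size, res$threshold)
  expect_equal(length(res$isolated), 100)
  # PageRank scores decrease down the ranked anchor list
  expect_true(all(diff(res$hubs[[1]]$pagerank) <= 1e-12))

  # all loops isolated -> 0 hubs
  iso <- simulate_loop_universe(n_hubs = 0, n_isolated = 30, seed = 2)
  res0 <- suppressWarnings(suppressMessages(identify_hubs(iso$loops)))
  expect_equal(length(res0$hubs), 0)

  # hub calling is invariant to loop input order
  shuf <- sim$loops[sample(nrow(sim$loops)), ]
  res_shuf <- suppressWarnings(suppressMessages(identify_hubs(shuf, seed = 1)))
  expect_equal(oracle_anchor_jaccard(res_shuf$hubs[[1]]$anchors,
                                     res$hubs[[1]]$anchors), 1)
})

test_that("a star hub's top PageRank anchor is the star center", {
  center <- c(0, 100)
  spokes <- lapply(1:6, function(i) c(i * 1000, i * 1000 + 100))
  loops <- make_loops(cbind(1, 2:7), c(list(center), spokes))
  g <- build_loop_graph(loops)
  pr <- igraph::page_rank(g, damping = 0.85)$vector
  expect_equal(igraph::V(g)$start[which.max(pr)], 0)
  # community partition covers all nodes exactly once
  memb <- detect_communities(g)
  expect_equal(length(memb), igraph::vcount(g))
  expect_true(all(!is.na(memb)))
})

test_that("loop anchor-pair counting matches exhaustive enumeration", {
  map <- toy_map(6, list(c(0, 3, 7), c(1, 3, 2), c(0, 4, 5), c(1, 4, 1),
                         c(2, 5, 9)), bin_size = 10)
  # single-bin anchors: count = the single entry
  l1 <- as_loop_set(data.frame(chrom1 = "chrT", start1 = 0, end1 = 10,
                               chrom2 = "chrT", start2 = 30, end2 = 40))
  expect_equal(unname(count_loop_anchor_pairs(l1, list(r1 = map))[1, 1]), 7)

  # 2-bin anchors: sum over the 4 bin pairs, vs explicit enumeration
  l2 <- as_loop_set(data.frame(chrom1 = "chrT", start1 = 0, end1 = 20,
                               chrom2 = "chrT", start2 = 30, end2 = 50))
  manual <- sum(map$counts[1:2, 4:5])
  expect_equal(unname(count_loop_anchor_pairs(l2, list(r1 = map))[1, 1]),
               manual)

  # zero map -> 0; off-grid anchors snap outward with a log entry
  zmap <- contact_map(matrix(0, 6, 6), "chrT", 10)
  expect_equal(unname(count_loop_anchor_pairs(l2, list(r1 = zmap))[1, 1]), 0)
  l3 <- as_loop_set(data.frame(chrom1 = "chrT", start1 = 2, end1 = 18,
                               chrom2 = "chrT", start2 = 31, end2 = 49))
  expect_message(cnt <- count_loop_anchor_pairs(l3, list(r1 = map)), "snapped")
  expect_equal(unname(cnt[1, 1]), manual)
})

test_that("relative loop strength is the depth-normalized balanced ratio", {
  set.seed(6)
  r <- matrix(rpois(36, 30), 6, 6)
  A <- r + t(r)
  wt <- contact_map(A, "chrT", 10)
  loops <- as_loop_set(data.frame(chrom1 = "chrT", start1 = 0, end1 = 20,
                                  chrom2 = "chrT", start2 = 30, end2 = 50))
  # identical maps -> 1.0; dKO = WT/2 everywhere -> 2.0
  expect_equal(relative_loop_strength(loops, wt, wt), 1)
  half <- contact_map(A / 2, "chrT", 10)
  expect_equal(relative_loop_strength(loops, wt, half), 2)

  # toy maps with unequal anchors: hand-enumerated ratio
  B <- A
  B[1:2, 4:5] <- B[1:2, 4:5] / 2
  B[4:5, 1:2] <- t(B[1:2, 4:5])
  dko <- contact_map(B, "chrT", 10)
  manual <- sum(A[1:2, 4:5]) / sum(B[1:2, 4:5])
  expect_equal(relative_loop_strength(loops, wt, dko), manual)
  expect_equal(manual, 2)

  # zero denominator -> NA sentinel
  C <- A
  C[1:2, 4:5] <- 0
  C[4:5, 1:2] <- 0
  expect_true(is.na(relative_loop_strength(loops, wt,
                                           contact_map(C, "chrT", 10))))
})
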