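# Spatial clustering of tumor cells, k-NN graph, and barrier scoring.

test_that("DBSCAN chains collinear cells within eps and leaves far pairs as noise", {
  cells <- make_cells(c(0, 20, 40), c(0, 0, 0), rep("epithelial", 3))
  cl <- cluster_tumor_cells(cells, eps = 25, min_cells = 3)
  expect_equal(cl$cluster, c(1L, 1L, 1L))
  cells2 <- make_cells(c(0, 100), c(0, 0), rep("epithelial", 2))
  cl2 <- cluster_tumor_cells(cells2, eps = 25, min_cells = 3)
  expect_true(all(cl2$cluster == 0L))
  expect_length(cl2$areas_um2, 0)
})

test_that("DBSCAN labels match the brute-force oracle on random blobs", {
  set.seed(55)
  x <- c(rnorm(50, 100, 15), rnorm(40, 300, 15), runif(20, 0, 400))
  y <- c(rnorm(50, 100, 15), rnorm(40, 300, 15), runif(20, 0, 400))
  mine <- dbscan_labels(x, y, eps = 25, min_pts = 3)
  want <- brute_dbscan(x, y, eps = 25, min_pts = 3)
  # same partition up to label permutation, same noise set
  expect_equal(mine == 0L, want == 0L)
  keep <- mine != 0L
  expect_equal(adjusted_rand_index(mine[keep], want[keep]), 1)
})

test_that("cluster areas are convex-hull shoelace areas", {
  # 50x40 um rectangle of tumor cells
  g <- expand.grid(x = seq(0, 50, 10), y = seq(0, 40, 10))
  cells <- make_cells(g$x, g$y, rep("epithelial", nrow(g)))
  cl <- cluster_tumor_cells(cells, eps = 15, min_cells = 3)
  expect_equal(length(cl$areas_um2), 1L)
  expect_equal(cl$areas_um2, 2000)
})

test_that("k-NN graph equals brute force and is mutualized", {
  cells <- csr_cells(300, "A", seed = 77)
  g <- build_knn_graph(cells, k = 5)
  nn <- brute_knn(cells$x_um, cells$y_um, 5)
  for (i in c(1, 50, 150, 300)) {
    expect_true(all(nn[i, ] %in% g$adj[[i]]))
    for (j in g$adj[[i]]) expect_true(i %in% g$adj[[j]])
  }
  expect_true(all(lengths(g$adj) >= 5))
  # 6 cells on a line with k = 5 form the complete graph
  line <- make_cells(1:6, rep(0, 6), rep("A", 6))
  gl <- build_knn_graph(line, k = 5)
  expect_true(all(lengths(gl$adj) == 5))
})

test_that("BFS hop distances match igraph on random graphs", {
  set.seed(13)
  for (rep in 1:10) {
    cells <- csr_cells(60, "A", seed = rep, side = 200)
    g <- build_knn_graph(cells, k = 3)
    edges <- do.call(rbind, lapply(seq_along(g$adj), function(i) {
      up <- g$adj[[i]][g$adj[[i]] > i]
      if (length(up)) cbind(i, up) else NULL
    }))
    ig <- igraph::graph_from_edgelist(edges, directed = FALSE)
    dmat <- igraph::distances(ig)
    targets <- rep(FALSE, 60); targets[sample(60, 5)] <- TRUE
    src <- sample(which(!targets), 1)
    res <- spatialTME:::.bfs_nearest(g$adj, src, targets)
    want <- min(dmat[src, targets])
    if (is.finite(want)) {
      expect_equal(res$dist, unname(want))
      expect_equal(res$targets, sort(which(targets)[dmat[src, targets] == want]))
    } else {
      expect_null(res)
    }
  }
})

test_that("canonical BFS paths are valid shortest paths with smallest-id predecessors", {
  fix <- chain_graph_fixture()
  res <- spatialTME:::.bfs_nearest(fix$graph$adj, 1L, fix$cells$tumor_cell)
  for (t in res$targets) {
    path <- spatialTME:::.bfs_path(res$pred, 1L, t)
    expect_equal(length(path) - 1L, res$dist)
    for (s in seq_len(length(path) - 1L)) {
      expect_true(path[s + 1L] %in% fix$graph$adj[[path[s]]])
    }
  }
})

test_that("three 6-hop paths with fibroblasts on two score 2/3 per cell", {
  fix <- chain_graph_fixture(n_chains = 3, hops = 6, fibro_chains = 1:2)
  b <- barrier_score(fix$cells, fix$graph, fix$clusters)
  expect_equal(b$per_cell$score, 2 / 3)
  expect_equal(b$per_cell$hops, 6L)
  expect_equal(b$score, 2 / 3)
})

test_that("single path scores 1 with a counted fibroblast and 0 without", {
  with_f <- chain_graph_fixture(n_chains = 1, fibro_chains = 1)
  expect_equal(barrier_score(with_f$cells, with_f$graph, with_f$clusters)$score, 1)
  no_f <- chain_graph_fixture(n_chains = 1, fibro_chains = integer(0))
  expect_equal(barrier_score(no_f$cells, no_f$graph, no_f$clusters)$score, 0)
})

test_that("count mode counts fibroblasts while indicator caps at 1", {
  fix <- chain_graph_fixture(n_chains = 1, fibro_chains = 1)
  # make the 4th node a second tumor-adjacent fibroblast? place another
  # fibroblast adjacent to the tumor cell by retyping node 5 (hop 4)
  fix$cells$cell_type[5] <- "aSMA+ fibroblast"
  # node 5 is adjacent to node 6 (fibro) and node 4; not adjacent to tumor 7
  ind <- barrier_score(fix$cells, fix$graph, fix$clusters, mode = "indicator")
  cnt <- barrier_score(fix$cells, fix$graph, fix$clusters, mode = "count")
  expect_equal(ind$score, 1)
  expect_equal(cnt$score, 1)  # node 5 not tumor-adjacent, so not counted
})

test_that("fibroblasts not adjacent to eligible tumor cells contribute 0", {
  fix <- chain_graph_fixture(n_chains = 1, fibro_chains = integer(0))
  fix$cells$cell_type[4] <- "aSMA+ fibroblast"  # mid-path, not tumor-adjacent
  expect_equal(barrier_score(fix$cells, fix$graph, fix$clusters)$score, 0)
})

test_that("perivascular CD8 and fibroblasts are excluded; small clusters are ineligible", {
  fix <- chain_graph_fixture(n_chains = 1, fibro_chains = 1)
  # perivascular fibroblast no longer counted
  fix2 <- fix; fix2$cells$perivascular[6] <- TRUE
  expect_equal(barrier_score(fix2$cells, fix2$graph, fix2$clusters)$score, 0)
  # cluster below 2000 um^2: no eligible tumor cells
  fix3 <- fix; fix3$clusters$areas_um2 <- 1500
  expect_warning(b <- barrier_score(fix3$cells, fix3$graph, fix3$clusters),
                 "no eligible tumor")
  expect_true(is.na(b$score))
})

test_that("indicator scores stay in [0,1] and are invariant under rigid transforms", {
  cfg <- fast_core_config(barrier = list(coverage = 0.6, thickness_um = 10),
                          emit_markers = FALSE)
  res <- generate_core(cfg, seed = 19)
  b1 <- barrier_score(res$cells)
  expect_true(b1$score >= 0 && b1$score <= 1)
  # rotate by 90 degrees and translate
  rot <- res$cells
  rot$x_um2 <- -res$cells$y_um + 2000
  rot$y_um <- res$cells$x_um + 500
  rot$x_um <- rot$x_um2; rot$x_um2 <- NULL
  b2 <- barrier_score(rot)
  expect_equal(b2$score, b1$score)
})
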