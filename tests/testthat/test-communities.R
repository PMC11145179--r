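# Windowed composition, k-means communities, elbow selection, concordance,
# enrichment.

test_that("single-type cores give unit-vector windows; W=2 is center plus nearest neighbor", {
  cells <- csr_cells(40, "A", seed = 1)
  win <- build_windows(cells, W = 10)
  expect_true(all(win$composition[, "A"] == 1))
  expect_equal(rowSums(win$composition), rep(1, 40), ignore_attr = TRUE)

  cells2 <- make_cells(c(0, 1, 50), c(0, 0, 0), c("A", "B", "A"))
  win2 <- build_windows(cells2, W = 2)
  # cell 1's window = {1, 2} -> half A half B; cell 3's nearest is cell 2 (49 vs 50)
  expect_equal(unname(win2$composition[1, ]), c(0.5, 0.5))
  expect_equal(unname(win2$composition[2, ]), c(0.5, 0.5))
  expect_equal(unname(win2$composition[3, ]), c(0.5, 0.5))
})

test_that("windows from the k-d style search equal brute-force neighbor windows", {
  cells <- csr_cells(200, c("A", "B", "C"), seed = 33)
  win <- build_windows(cells, W = 10)
  nn <- brute_knn(cells$x_um, cells$y_um, 9, ids = rank(cells$cell_id))
  types <- win$types
  for (i in c(1, 42, 200)) {
    w <- c(i, nn[i, ])
    want <- as.vector(table(factor(cells$cell_type[w], types))) / 10
    expect_equal(unname(win$composition[i, ]), want)
  }
})

test_that("cores with too few eligible cells are skipped with a warning", {
  cells <- rbind(csr_cells(30, "A", seed = 2, image_id = "BIG"),
                 csr_cells(4, "A", seed = 3, image_id = "TINY"))
  expect_warning(win <- build_windows(cells, W = 10), "TINY")
  expect_true(all(win$image_id == "BIG"))
})

test_that("k-means recovers two spatially segregated planted compositions", {
  spec <- list(
    list(id = 1, xfrac = c(0, 0.5),
         densities = c("CD8 T cells" = 500, "CD163+CD206+ macrophage" = 80)),
    list(id = 2, xfrac = c(0.5, 1),
         densities = c("B cell" = 500, "neutrophil" = 80))
  )
  cfg <- fast_core_config(community_spec = spec, emit_markers = FALSE)
  cfg$densities[] <- cfg$densities / 10   # faint background everywhere
  res <- generate_core(cfg, seed = 41)
  win <- build_windows(res$cells, W = 10)
  fit <- fit_communities(win, k = 2, seed = 5)
  planted <- res$truth$cells$community_id[match(win$cell_id, res$truth$cells$cell_id)]
  keep <- planted > 0
  ari <- adjusted_rand_index(fit$assignment[keep], planted[keep])
  expect_gte(ari, 0.9)
})

test_that("k=1 puts all cells in one community; same seed gives identical fits", {
  cells <- csr_cells(60, c("A", "B"), seed = 6)
  win <- build_windows(cells, W = 5)
  f1 <- fit_communities(win, k = 1, seed = 1)
  expect_true(all(f1$assignment == 1L))
  f2 <- fit_communities(win, k = 4, seed = 7)
  f3 <- fit_communities(win, k = 4, seed = 7)
  expect_identical(f2$assignment, f3$assignment)
  expect_error(fit_communities(win, k = 100, seed = 1), "exceeds")
  expect_equal(rowSums(f2$centroids), rep(1, 4), tolerance = 1e-8)
})

test_that("select_k finds the elbow at three well-separated planted profiles", {
  set.seed(9)
  proto <- diag(3)[, ]  # three pure compositions over 3 types
  X <- proto[sample(1:3, 600, replace = TRUE), ] +
    matrix(abs(rnorm(1800, 0, 0.03)), 600, 3)
  X <- X / rowSums(X)
  colnames(X) <- c("A", "B", "C")
  sel <- select_k(X, k_range = 1:8, seed = 2, method = "lloyd")
  expect_equal(sel$k_star, 3)
  # distortion nonincreasing (within stochastic tolerance)
  d <- sel$distortion
  expect_true(all(diff(d) <= 1e-8 + 0.05 * d[-length(d)]))
})

test_that("distortion at k = n windows is zero", {
  X <- matrix(runif(20), 10, 2)
  X <- X / rowSums(X)
  colnames(X) <- c("A", "B")
  f <- fit_communities(X, k = 10, seed = 3, method = "lloyd")
  expect_equal(f$distortion, 0, tolerance = 1e-10)
})

test_that("concordance is 1 for perfectly separated communities and reports per-rep values", {
  X <- rbind(matrix(rep(c(1, 0), each = 150), 150), matrix(rep(c(0, 1), each = 150), 150))
  X <- X + abs(matrix(rnorm(600, 0, 0.01), 300, 2))
  X <- X / rowSums(X)
  colnames(X) <- c("A", "B")
  fit <- fit_communities(X, k = 2, seed = 1)
  cc <- concordance(X, fit, reps = 3, seed = 2)
  expect_length(cc$per_rep, 3)
  expect_true(all(cc$per_rep > 0.99))
  expect_equal(cc$median, median(cc$per_rep))
})

test_that("label matching used by concordance is optimal on known confusions", {
  a <- rep(1:3, each = 20)
  b <- rep(c(30, 10, 20), each = 20)  # permuted labels
  m <- match_labels(a, b)
  expect_equal(m$agreement, 1)
  expect_equal(unname(m$map[c("10", "20", "30")]), c(2, 3, 1))
})

test_that("planted enrichment is detected and absent communities contribute zeros", {
  set.seed(10)
  cores <- list()
  for (p in 1:4) for (cc in 1:2) {
    img <- sprintf("P%d_C%d", p, cc)
    cells <- csr_cells(150, c("CD8 T cells", "B cell"), seed = p * 10 + cc,
                       image_id = img, patient_id = sprintf("P%d", p))
    # community 1 = left half, heavily CD8-enriched
    cells$community <- ifelse(cells$x_um < 200, 1L, 2L)
    left <- cells$x_um < 200
    cells$cell_type[left] <- sample(c("CD8 T cells", "B cell"), sum(left),
                                    replace = TRUE, prob = c(0.9, 0.1))
    cores[[img]] <- cells
  }
  cells <- do.call(rbind, cores)
  areas <- data.frame(image_id = unique(cells$image_id),
                      patient_id = sub("_C\\d", "", unique(cells$image_id)),
                      area_tumor_nest_mm2 = 0.05, area_stroma_mm2 = 0.11)
  enr <- community_enrichment(cells, community = 1, type = "CD8 T cells", areas)
  expect_gt(enr$effect, 0)
  expect_lt(enr$p_value, 0.05)
  # a core without community 1 still contributes (density 0), not dropped
  cells2 <- cells
  cells2$community[cells2$image_id == "P1_C1"] <- 2L
  enr2 <- community_enrichment(cells2, community = 1, type = "CD8 T cells", areas)
  expect_equal(enr2$n_cores, 8)
})

test_that("single-patient enrichment falls back to a fixed-effect test with a warning", {
  cells <- rbind(csr_cells(200, c("A", "B"), seed = 3, image_id = "IMG1"),
                 csr_cells(200, c("A", "B"), seed = 4, image_id = "IMG2"),
                 csr_cells(200, c("A", "B"), seed = 5, image_id = "IMG3"))
  set.seed(6)
  cells$community <- sample(1:2, nrow(cells), replace = TRUE)
  areas <- data.frame(image_id = c("IMG1", "IMG2", "IMG3"), patient_id = "P1",
                      area_tumor_nest_mm2 = 0.05, area_stroma_mm2 = 0.11)
  expect_warning(enr <- community_enrichment(cells, 1, "A", areas), "single patient")
  expect_true(is.finite(enr$p_value))
})

test_that("community assignment is invariant to translation and rotation of a core", {
  cells <- csr_cells(120, c("A", "B", "C"), seed = 44)
  win1 <- build_windows(cells, W = 8)
  rot <- cells
  th <- pi / 5
  rot$x_um <- cos(th) * cells$x_um - sin(th) * cells$y_um + 300
  rot$y_um <- sin(th) * cells$x_um + cos(th) * cells$y_um - 100
  win2 <- build_windows(rot, W = 8)
  expect_equal(win1$composition, win2$composition)
  f1 <- fit_communities(win1, k = 3, seed = 9)
  f2 <- fit_communities(win2, k = 3, seed = 9)
  expect_identical(f1$assignment, f2$assignment)
})
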