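# ITH statistics, bootstrap class-homogeneity, distances, TAN/TMB/subclonal
# expansion scores.

test_that("ith_score matches hand-computed spreadsheet arithmetic", {
  # 2 patients x 2 cores, 2 features (asymmetric so the final z is defined)
  m <- rbind(c(10, 1), c(20, 1), c(30, 5), c(31, 9))
  colnames(m) <- c("f1", "f2")
  patient <- c("A", "A", "B", "B")
  # manual: z-score columns, per-patient SD, mean over patients, z over features
  z <- scale(m)
  sd_a <- apply(z[1:2, ], 2, sd); sd_b <- apply(z[3:4, ], 2, sd)
  raw <- (sd_a + sd_b) / 2
  want <- as.vector(scale(raw))
  got <- ith_score(m, patient)
  expect_equal(unname(got), want)
  # z-transform contract
  expect_equal(mean(got), 0, tolerance = 1e-12)
  expect_equal(sd(got), 1, tolerance = 1e-12)
})

test_that("identical densities across a patient's cores give zero patient SD", {
  m <- cbind(f1 = c(5, 5, 1, 9), f2 = c(2, 2, 2, 2))
  patient <- c("A", "A", "B", "B")
  z <- scale(m)
  expect_equal(sd(z[1:2, 1]), 0)
  expect_silent(ith_score(m, patient))
})

test_that("ith_score is invariant to feature ordering", {
  set.seed(4)
  m <- matrix(rnorm(40, 10), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  patient <- rep(c("A", "B", "C", "D", "E"), each = 2)
  s1 <- ith_score(m, patient)
  s2 <- ith_score(m[, c(3, 1, 4, 2)], patient)
  expect_equal(s1[names(s2)], s2)
})

test_that("bootstrap homogeneity probability converges to the exact 4/9 on an XXY tumor", {
  labels <- c("X", "X", "Y")
  tumor <- c("T1", "T1", "T1")
  res <- class_homogeneity_probability(labels, tumor, n_samples = 2,
                                       reps = 1000, seed = 11)
  p <- res$p_same[res$class == "X"]
  sigma <- sqrt(4 / 9 * 5 / 9 / 1000)
  expect_lt(abs(p - 4 / 9), 3 * sigma)
  expect_equal(res$p_ith[res$class == "X"], 1 - p)
})

test_that("homogeneous tumors give probability 1; enumeration reproduces small cases", {
  res <- class_homogeneity_probability(c("X", "X"), c("T1", "T1"),
                                       n_samples = c(2, 3), reps = 50, seed = 2)
  expect_equal(res$p_same[res$class == "X"], 1)
  # two tumors: T1 = [X, Y], T2 = [X, X]; exact P(all X | n=2):
  # per iteration: T1 contributes (1/2)^2, T2 contributes 1; denominator 2
  labels <- c("X", "Y", "X", "X")
  tumor <- c("T1", "T1", "T2", "T2")
  res2 <- class_homogeneity_probability(labels, tumor, n_samples = 2,
                                        reps = 4000, seed = 3)
  want <- (0.25 + 1) / 2
  p <- res2$p_same[res2$class == "X"]
  expect_lt(abs(p - want), 3 * sqrt(want * (1 - want) / 4000))
  expect_true(all(res2$p_same >= 0 & res2$p_same <= 1))
})

test_that("median distance to a target type matches brute force and its contracts", {
  cells <- make_cells(c(0, 30), c(0, 0), c("epithelial", "endothelial"))
  out <- median_distance_to_type(cells, "epithelial", "endothelial")
  expect_equal(out$median_distance_um, 30)
  # brute-force oracle on random cells
  cells2 <- csr_cells(300, c("epithelial", "endothelial"), seed = 8)
  out2 <- median_distance_to_type(cells2, "epithelial", "endothelial")
  si <- which(cells2$cell_type == "epithelial")
  ti <- which(cells2$cell_type == "endothelial")
  D <- as.matrix(dist(cbind(cells2$x_um, cells2$y_um)))
  want <- median(apply(D[si, ti, drop = FALSE], 1, min))
  expect_equal(out2$median_distance_um, want)
  # monotonicity: adding a farther target never increases the median
  far <- make_cells(10000, 10000, "endothelial")
  far$cell_id <- "far_1"
  out3 <- median_distance_to_type(rbind(cells2, far), "epithelial", "endothelial")
  expect_lte(out3$median_distance_um, out2$median_distance_um)
  # missing target type
  expect_warning(
    out4 <- median_distance_to_type(cells2, "epithelial", "neutrophil"),
    "absent")
  expect_true(is.na(out4$median_distance_um))
})

test_that("TAN classification applies histology cutoffs with OR logic", {
  expect_equal(tan_classify(5, 0, "LUAD"), "high")
  expect_equal(tan_classify(0, 0, "LUAD"), "low")
  expect_equal(tan_classify(0, 1.5, "LUAD"), "high")   # sTAN above LUAD cutoff 1
  expect_equal(tan_classify(2.5, 0, "LUSC"), "low")    # below LUSC tTAN cutoff 3
  expect_equal(tan_classify(2.5, 0, "LUAD"), "high")
  expect_error(tan_classify(1, 1, "SCLC"), "unknown histology")
  expect_error(tan_classify(150, 0, "LUAD"), "within")
})

test_that("TAN cutoff derivation recovers a planted separating threshold", {
  set.seed(21)
  neut_high <- runif(20, 4, 9)    # tTAN scores in the neutrophil-high class
  others <- runif(40, 0, 2)
  cut <- derive_cutoff(c(neut_high, others), rep(c(TRUE, FALSE), c(20, 40)))
  expect_gt(cut$cutoff, 2)
  expect_lt(cut$cutoff, 4)
  expect_equal(cut$direction, 1)
})

test_that("TMB boundary is inclusive at 10 muts/Mb", {
  out <- tmb_status(c(300, 299, 0), c(30, 30, 30))
  expect_equal(out$status, c("high", "low", "low"))
  expect_equal(out$muts_per_mb, c(10, 299 / 30, 0))
  expect_error(tmb_status(5, 0), "coding_mb")
})

test_that("subclonal expansion score is the max leaf CCF, root included when terminal", {
  ccf <- rbind(clonal = c(R1 = 1, R2 = 1), s1 = c(0.2, 0.6), s2 = c(0.5, 0.1))
  tr <- phylo_tree(c("clonal", "s1", "s2"), c(NA, "clonal", "clonal"), ccf)
  expect_equal(sort(tree_leaves(tr)), c("s1", "s2"))
  expect_equal(subclonal_expansion_score(tr, "R1"), 0.5)
  expect_equal(subclonal_expansion_score(tr, "R2"), 0.6)
  single <- phylo_tree("clonal", NA_character_,
                       matrix(1, 1, 1, dimnames = list("clonal", "R1")))
  expect_equal(subclonal_expansion_score(single, "R1"), 1.0)
  expect_error(subclonal_expansion_score(tr, "R9"), "absent")
})

test_that("random clone trees: score equals brute-force max over enumerated leaves", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    nodes <- paste0("c", seq_len(n))
    parents <- c(NA, nodes[sapply(2:n, function(j) sample(j - 1, 1))])
    ccf <- matrix(runif(n * 2), n, 2, dimnames = list(nodes, c("R1", "R2")))
    tr <- phylo_tree(nodes, parents, ccf)
    leaves <- setdiff(nodes, na.omit(parents))
    expect_equal(subclonal_expansion_score(tr, "R2"),
                 max(ccf[leaves, "R2"]))
  }
})

test_that("phylo trees round-trip through JSON and reject malformed input", {
  ccf <- rbind(clonal = c(R1 = 1), s1 = c(R1 = 0.4))
  tr <- phylo_tree(c("clonal", "s1"), c(NA, "clonal"), ccf)
  path <- tempfile(fileext = ".json")
  write_phylo_tree(tr, path)
  tr2 <- read_phylo_tree(path)
  expect_equal(tr2$nodes, tr$nodes)
  expect_equal(unname(tr2$ccf), unname(tr$ccf))
  expect_error(phylo_tree(c("a", "b"), c("b", "a"), rbind(a = 1, b = 1)),
               "root|cycle")
  expect_error(phylo_tree(c("a", "b"), c(NA, "zz"), rbind(a = 1, b = 1)),
               "unknown parent")
})
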