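# Rule-based phenotyping: positivity calling, lineage scoring, subtype rules,
# pathology-mask relabeling.

test_that("two-component positivity separates a clearly bimodal marker", {
  intens <- cbind(CD3 = c(0, 0, 0, 10, 10))
  pos <- call_positivity(intens)
  expect_equal(unname(pos$positive[, "CD3"]), c(FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("constant and all-zero marker columns are called all-negative with a warning", {
  intens <- cbind(CD3 = rep(2, 5), CD4 = rep(0, 5))
  w <- capture_warnings(pos <- call_positivity(intens))
  expect_length(w, 2)
  expect_match(w, "constant", all = TRUE)
  expect_false(any(pos$positive))
  expect_equal(unname(pos$method), c("degenerate", "degenerate"))
})

test_that("positivity is monotone in intensity (single threshold per marker)", {
  set.seed(42)
  intens <- cbind(CD8a = c(rlnorm(150, log(0.3), 0.4), rlnorm(80, log(3), 0.4)))
  pos <- call_positivity(intens)
  v <- log1p(intens[, 1])
  called <- pos$positive[, 1]
  # every positive cell is brighter than every negative cell boundary
  expect_true(min(v[called]) > max(v[!called]) ||
                all(v[called] > pos$threshold[1]) && all(v[!called] <= pos$threshold[1]))
})

test_that("positivity recovers generating flags on synthetic cells", {
  res <- generate_core(fast_core_config(), seed = 101)
  markers <- colnames(res$truth$flags)
  pos <- call_positivity(as.matrix(res$cells[, markers]))
  acc <- mean(pos$positive == res$truth$flags)
  expect_gt(acc, 0.95)
})

test_that("lineage scoring matches the marker-set definitions", {
  pos <- pos_fixture(
    CD45 = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    CD3 = c(TRUE, FALSE, FALSE, FALSE, TRUE),
    CD8a = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    CD4 = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    CD79a = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    CD20 = c(FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  lin <- assign_major_lineage(pos)
  expect_equal(lin, c("CD8 T cells",      # CD45+CD3+CD8a+
                      "unassigned",       # all negative
                      "leukocytes - other", # CD45+ only
                      "B cells",          # CD45+CD79a+CD20+
                      "CD4 T cells"))     # CD45+CD3+CD4+
})

test_that("subtype rules reproduce the published definitions", {
  cases <- list(
    list(on = c("CD45", "CD11b", "MPO"), want = "neutrophil"),
    list(on = c("CD45", "CD79a", "CD38"), want = "plasma cell"),
    list(on = c("CD45", "CD79a", "CD20"), want = "B cell"),
    list(on = c("CD45", "CD79a"), want = "B cell lineage - other"),
    list(on = c("CD45", "CD11b", "CD14", "CD68", "CD206", "CD163"),
         want = "CD163+CD206+ macrophage"),
    list(on = c("CD45", "CD11b", "CD14", "CD68"), want = "CD163- macrophage"),
    list(on = c("CD45", "CD3", "CD4", "FOXP3"), want = "Treg"),
    list(on = c("CD45", "CD3", "CD8a", "GZMB"), want = "cytotoxic T"),
    list(on = c("CD45", "CD3", "CD8a", "CD103"), want = "tissue-resident memory T"),
    list(on = c("CD45", "CD3", "CD4", "CD45RA"), want = "naive T"),
    list(on = c("CD45", "CD3", "CD8a", "CD57", "CD39"), want = "exhausted TDT"),
    list(on = c("CD45", "CD3", "CD8a", "CD57"), want = "CD57+ T"),
    list(on = c("CD45", "CD3", "CD4", "CD27", "CCR7"), want = "Tcm"),
    list(on = c("CD45", "CD3", "CD4", "CD27"), want = "Tem"),
    list(on = c("CD45", "CD3", "TCRd"), want = "Tgd"),
    list(on = "aSMA", want = "aSMA+ fibroblast"),
    # CD11b+ without MPO/CD14/CD68 keeps the myeloid-other lineage label
    list(on = c("CD45", "CD11b"), want = "myeloid cells - other")
  )
  panel <- default_panel()
  m <- do.call(rbind, lapply(cases, function(cs) marker_row(cs$on)))
  pos <- structure(list(positive = m), class = "positivity_matrix")
  lin <- assign_major_lineage(pos, panel)
  sub <- assign_subtype(lin, pos, panel)
  expect_equal(sub, vapply(cases, `[[`, character(1), "want"))
})

test_that("every cell gets exactly one final label (partition invariant)", {
  res <- generate_core(fast_core_config(), seed = 7)
  ph <- phenotype_cells(res$cells)
  expect_false(anyNA(ph$cell_type))
  expect_equal(length(ph$cell_type), nrow(res$cells))
})

test_that("contradictory rule tables are rejected", {
  panel <- default_panel()
  panel$subtypes$neg[panel$subtypes$subtype == "neutrophil"] <- "MPO"
  expect_error(validate_panel(panel), "requires and forbids")
})

test_that("pathology masks set perivascular, alveolar and tumor labels from cell centers", {
  cells <- make_cells(c(5, 25, 5, 25), c(5, 5, 25, 25),
                      c("aSMA+ fibroblast", "aSMA+ fibroblast",
                        "CD163+CD206+ macrophage", "epithelial"))
  blank <- matrix(0L, 40, 40)
  vessels <- blank; vessels[1:15, 1:15] <- 1L          # covers (5,5)
  alveolar <- blank; alveolar[20:40, 1:15] <- 1L       # covers (5,25)
  tumor <- blank; tumor[20:40, 20:40] <- 1L            # covers (25,25)
  out <- apply_pathology_labels(cells, list(vessels = vessels,
                                            alveolar = alveolar, tumor = tumor))
  expect_true(out$perivascular[1])
  expect_equal(out$cell_type[1], "perivascular aSMA+")
  expect_false(out$perivascular[2])                    # aSMA+ outside vessels
  expect_equal(out$cell_type[3], "alveolar macrophage")
  expect_true(out$tumor_cell[4])                       # epithelial inside tumor mask
  expect_equal(sum(out$tumor_cell), 1L)
})

test_that("cells outside the mask frame raise a frame-mismatch error", {
  cells <- make_cells(100, 100, "epithelial")
  expect_error(apply_pathology_labels(cells, list(tumor = matrix(0L, 40, 40))),
               "outside the mask")
})
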