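# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the default suite stays fast.

# Minimal cell table from coordinate/type vectors (one image).
make_cells <- function(x, y, type, image_id = "IMG1", patient_id = "P1",
                       tumor = type == "epithelial", perivascular = FALSE) {
  n <- length(x)
  data.frame(
    cell_id = sprintf("%s_%04d", image_id, seq_len(n)),
    image_id = image_id, patient_id = patient_id,
    x_um = x, y_um = y, cell_type = type,
    tumor_cell = tumor, perivascular = perivascular,
    stringsAsFactors = FALSE
  )
}

# Uniform random cells in a box under complete spatial randomness.
csr_cells <- function(n, types, side = 400, seed = 1, image_id = "IMG1",
                      patient_id = "P1") {
  set.seed(seed)
  make_cells(runif(n, 0, side), runif(n, 0, side),
             sample(types, n, replace = TRUE),
             image_id = image_id, patient_id = patient_id)
}

# Small synthetic core config for fast tests: 0.8 mm core, one nest.
fast_core_config <- function(...) {
  synthetic_config(
    core_diameter_um = 800,
    nest_geometry = list(n_nests = 1, radius_um = 180, radius_sd_um = 20,
                         irregularity = 0.2),
    ...
  )
}

# Hand-built graph fixture: one CD8 T cell with `n_chains` disjoint chains of
# `hops` edges each ending at a tumor cell; chains listed in `fibro_chains`
# carry a tumor-adjacent aSMA+ fibroblast just before the tumor cell.
chain_graph_fixture <- function(n_chains = 3, hops = 6, fibro_chains = 1:2,
                                cluster_area = 2500) {
  n <- 1 + n_chains * hops
  type <- c("CD8 T cells", rep("stroma-other", n - 1))
  tumor <- rep(FALSE, n)
  adj <- vector("list", n)
  link <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
    adj[[b]] <<- c(adj[[b]], a)
  }
  node <- 1L
  for (chain in seq_len(n_chains)) {
    prev <- 1L
    for (h in seq_len(hops)) {
      node <- node + 1L
      link(prev, node)
      prev <- node
    }
    tumor[node] <- TRUE
    type[node] <- "epithelial"
    if (chain %in% fibro_chains) type[node - 1L] <- "aSMA+ fibroblast"
  }
  cells <- make_cells(seq_len(n), rep(0, n), type, tumor = tumor)
  graph <- structure(list(adj = lapply(adj, sort), k = NA_integer_, n = n),
                     class = "spatial_graph")
  clusters <- structure(list(cluster = ifelse(tumor, 1L, 0L),
                             areas_um2 = cluster_area, polygons = list(NULL)),
                        class = "tumor_clusters")
  list(cells = cells, graph = graph, clusters = clusters)
}

# Brute-force k-NN oracle (all-pairs distances, ties by id rank).
brute_knn <- function(x, y, k, ids = seq_along(x)) {
  n <- length(x)
  D <- as.matrix(stats::dist(cbind(x, y)))
  t(vapply(seq_len(n), function(i) {
    d <- D[i, ]; d[i] <- Inf
    as.integer(order(d, rank(ids))[seq_len(k)])
  }, integer(k)))
}

# Brute-force textbook DBSCAN oracle (min_pts includes the point itself).
brute_dbscan <- function(x, y, eps, min_pts) {
  n <- length(x)
  D <- as.matrix(stats::dist(cbind(x, y)))
  nb <- lapply(seq_len(n), function(i) setdiff(which(D[i, ] <= eps), i))
  core <- vapply(nb, length, integer(1)) + 1L >= min_pts
  labels <- rep(0L, n); cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  labels
}

# Positivity matrix fixture from explicit logical columns.
pos_fixture <- function(...) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  structure(list(positive = m,
                 threshold = stats::setNames(rep(0, ncol(m)), colnames(m)),
                 method = stats::setNames(rep("fixture", ncol(m)), colnames(m))),
            class = "positivity_matrix")
}

# Logical marker row helper: all panel markers FALSE except `on`.
marker_row <- function(on, markers = default_panel()$markers) {
  stats::setNames(markers %in% on, markers)
}
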