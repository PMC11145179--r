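# aSMA+ fibroblast barrier score: DBSCAN spatial clusters of tumor cells,
# a 5-nearest-neighbor cell graph, BFS shortest paths from each CD8 T cell to
# its nearest eligible tumor cells, and scoring of tumor-adjacent aSMA+
# fibroblasts interposed on those paths.

#' Spatial clustering of tumor cells
#'
#' DBSCAN over tumor-cell coordinates (eps 25 um, minimum 3 cells), with a
#' boundary polygon (convex hull) and area per cluster. Noise cells belong
#' to no cluster.
#'
#' @param cells cell table with `tumor_cell` logical column.
#' @param eps DBSCAN radius (um), default 25.
#' @param min_cells minimum cluster size, default 3.
#' @return object of class `tumor_clusters`: `cluster` (integer per cell of
#'   `cells`, 0 = noise or non-tumor), `areas_um2` (per cluster), `polygons`
#'   (list of hull vertex matrices).
#' @export
cluster_tumor_cells <- function(cells, eps = 25, min_cells = 3) {
  stopifnot("tumor_cell" %in% names(cells))
  idx <- which(cells$tumor_cell)
  labels_all <- rep(0L, nrow(cells))
  areas <- numeric(0)
  polys <- list()
  if (length(idx) >= min_cells) {
    lab <- dbscan_labels(cells$x_um[idx], cells$y_um[idx], eps, min_cells)
    labels_all[idx] <- lab
    ncl <- max(lab)
    if (ncl > 0) {
      areas <- numeric(ncl)
      polys <- vector("list", ncl)
      for (c in seq_len(ncl)) {
        sel <- idx[lab == c]
        poly <- .hull_polygon(cells$x_um[sel], cells$y_um[sel])
        polys[[c]] <- poly
        areas[c] <- .polygon_area(poly)
      }
    }
  }
  structure(list(cluster = labels_all, areas_um2 = areas, polygons = polys),
            class = "tumor_clusters")
}

#' @export
print.tumor_clusters <- function(x, ...) {
  cat("tumor spatial clusters:", length(x$areas_um2), "cluster(s),",
      sum(x$cluster > 0), "clustered cells,", sum(x$cluster == 0),
      "noise/non-tumor\n")
  if (length(x$areas_um2)) {
    cat("areas (um^2):", paste(round(sort(x$areas_um2, decreasing = TRUE)),
                               collapse = ", "), "\n")
  }
  invisible(x)
}

#' Build the k-nearest-neighbor cell graph
#'
#' Connects each cell to its k nearest neighbors; the union of directed
#' edges is taken as an undirected graph (so interior nodes have degree
#' >= k). Duplicate coordinates are tolerated: ties break by cell id, with a
#' warning.
#'
#' @param cells cell table (`x_um`, `y_um`, `cell_id`).
#' @param k neighbors per cell, default 5.
#' @return object of class `spatial_graph`: `adj` (list of sorted integer
#'   neighbor vectors, indices into `cells`), `k`, `n`.
#' @export
build_knn_graph <- function(cells, k = 5) {
  n <- nrow(cells)
  if (n < k + 1) stop("need at least k + 1 cells")
  if (anyDuplicated(cbind(cells$x_um, cells$y_um))) {
    warning("duplicate coordinates; k-NN ties broken by cell id")
  }
  nn <- knn_index(cells$x_um, cells$y_um, k, ids = rank(cells$cell_id))
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- nn[i, ]
  # mutualize: union of directed edges
  rev_edges <- split(rep(seq_len(n), each = k), as.vector(t(nn)))
  for (j in names(rev_edges)) {
    jj <- as.integer(j)
    adj[[jj]] <- c(adj[[jj]], rev_edges[[j]])
  }
  adj <- lapply(adj, function(v) sort(unique(v)))
  structure(list(adj = adj, k = k, n = n), class = "spatial_graph")
}

#' @export
print.spatial_graph <- function(x, ...) {
  deg <- lengths(x$adj)
  cat("spatial k-NN graph: n =", x$n, ", k =", x$k,
      ", mean degree", round(mean(deg), 2), "\n")
  invisible(x)
}

#' aSMA+ fibroblast barrier score
#'
#' For each non-perivascular CD8 T cell, finds the hop distance to the
#' nearest eligible tumor cells (tumor cells belonging to a spatial cluster
#' of at least `min_cluster_area_um2`) on the k-NN graph, takes one canonical
#' BFS shortest path per tied nearest tumor cell (smallest-id predecessor),
#' and scores each path by the counted fibroblasts on it: non-perivascular
#' aSMA+ fibroblasts that are graph neighbors of at least one eligible tumor
#' cell. In `indicator` mode a path scores 1 if it carries any counted
#' fibroblast, 0 otherwise; in `count` mode it scores the number of counted
#' fibroblasts. The per-cell score is the mean over tied paths and the
#' per-core score the mean over CD8 T cells.
#'
#' @param cells cell table (`cell_type`, `tumor_cell`, `perivascular`).
#' @param graph a `spatial_graph` from [build_knn_graph()].
#' @param clusters a `tumor_clusters` from [cluster_tumor_cells()].
#' @param mode `"indicator"` (default) or `"count"`.
#' @param min_cluster_area_um2 eligibility threshold, default 2000.
#' @param eps,knn_k DBSCAN radius and graph k used when `clusters`/`graph`
#'   are built internally.
#' @param cd8_type,fibroblast_type cell-type labels used for CD8 T cells and
#'   aSMA+ fibroblasts.
#' @return list `score` (per-core mean; NA if no CD8 or no eligible tumor
#'   cell), `per_cell` (data.frame: cell_id, hops, score), `n_cd8`,
#'   `n_eligible_tumor`.
#' @export
barrier_score <- function(cells, graph = NULL, clusters = NULL,
                          mode = c("indicator", "count"),
                          min_cluster_area_um2 = 2000,
                          cd8_type = "CD8 T cells",
                          fibroblast_type = "aSMA+ fibroblast",
                          eps = 25, knn_k = 5) {
  mode <- match.arg(mode)
  if (is.null(graph)) graph <- build_knn_graph(cells, k = knn_k)
  if (is.null(clusters)) clusters <- cluster_tumor_cells(cells, eps = eps)
  n <- nrow(cells)
  periv <- if ("perivascular" %in% names(cells)) cells$perivascular else rep(FALSE, n)
  big <- which(clusters$areas_um2 >= min_cluster_area_um2)
  eligible_tumor <- cells$tumor_cell & clusters$cluster %in% big & clusters$cluster > 0
  cd8 <- which(cells$cell_type == cd8_type & !periv)
  if (!any(eligible_tumor) || !length(cd8)) {
    warning("no eligible tumor cells or no CD8 T cells; core score missing")
    return(list(score = NA_real_, per_cell = NULL, n_cd8 = length(cd8),
                n_eligible_tumor = sum(eligible_tumor)))
  }
  # counted fibroblasts: non-perivascular aSMA+ fibroblasts adjacent to an
  # eligible tumor cell
  is_fibro <- cells$cell_type == fibroblast_type & !periv
  counted <- rep(FALSE, n)
  for (i in which(is_fibro)) {
    if (any(eligible_tumor[graph$adj[[i]]])) counted[i] <- TRUE
  }
  per_cell <- data.frame(cell_id = cells$cell_id[cd8],
                         hops = NA_integer_, score = NA_real_,
                         stringsAsFactors = FALSE)
  for (s in seq_along(cd8)) {
    res <- .bfs_nearest(graph$adj, cd8[s], eligible_tumor)
    if (is.null(res)) next
    path_scores <- vapply(res$targets, function(t) {
      path <- .bfs_path(res$pred, cd8[s], t)
      inner <- path[-c(1L, length(path))]
      nf <- sum(counted[inner])
      if (mode == "indicator") as.numeric(nf > 0) else as.numeric(nf)
    }, numeric(1))
    per_cell$hops[s] <- res$dist
    per_cell$score[s] <- mean(path_scores)
  }
  list(score = mean(per_cell$score, na.rm = TRUE), per_cell = per_cell,
       n_cd8 = length(cd8), n_eligible_tumor = sum(eligible_tumor))
}

#' Barrier scores for every core of a cohort
#'
#' @param cells multi-core cell table.
#' @param ... passed to [barrier_score()].
#' @return data.frame: image_id, barrier_score, n_cd8, n_eligible_tumor.
#' @export
barrier_score_by_core <- function(cells, ...) {
  imgs <- unique(cells$image_id)
  rows <- lapply(imgs, function(img) {
    sub <- cells[cells$image_id == img, , drop = FALSE]
    b <- suppressWarnings(barrier_score(sub, ...))
    data.frame(image_id = img, barrier_score = b$score, n_cd8 = b$n_cd8,
               n_eligible_tumor = b$n_eligible_tumor,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
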