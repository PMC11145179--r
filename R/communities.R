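# Recurrent cellular community detection: every cell's local window (the W
# nearest cells including itself) is summarized as a composition vector over
# cell types; windows are pooled across cores and clustered by k-means.

#' Build windowed composition matrix
#'
#' For every eligible cell, the window is the cell plus its W-1 nearest
#' eligible neighbors within the same core; the row is the fraction of each
#' type among the W window cells. Distance ties are broken by cell id. Cores
#' with fewer than W eligible cells are skipped with a warning.
#'
#' @param cells cell table (`image_id`, `x_um`, `y_um`, `cell_type`).
#' @param W window size in cells, center included (default 10).
#' @param eligible_types types to include; default: all types except
#'   `"unassigned"` and `"ambiguous"`.
#' @return list: `composition` (cells x types fraction matrix, rows named by
#'   cell id), `cell_id`, `image_id`, `types`.
#' @export
build_windows <- function(cells, W = 10, eligible_types = NULL) {
  if (is.null(eligible_types)) {
    eligible_types <- setdiff(sort(unique(cells$cell_type)),
                              c("unassigned", "ambiguous"))
  }
  el <- cells[cells$cell_type %in% eligible_types, , drop = FALSE]
  rows <- list(); ids <- list(); imgs <- list()
  for (img in unique(el$image_id)) {
    sub <- el[el$image_id == img, , drop = FALSE]
    if (nrow(sub) < W) {
      warning("core ", img, " has fewer than W eligible cells; skipped")
      next
    }
    type_f <- factor(sub$cell_type, levels = eligible_types)
    if (W >= 2L) {
      nn <- knn_index(sub$x_um, sub$y_um, W - 1L, ids = rank(sub$cell_id))
      idx <- cbind(seq_len(nrow(sub)), nn)
    } else {
      idx <- matrix(seq_len(nrow(sub)), ncol = 1)
    }
    compo <- vapply(seq_len(nrow(idx)), function(r) {
      tabulate(type_f[idx[r, ]], length(eligible_types))
    }, integer(length(eligible_types)))
    rows[[img]] <- t(matrix(compo, nrow = length(eligible_types))) / W
    ids[[img]] <- sub$cell_id
    imgs[[img]] <- rep(img, nrow(sub))
  }
  if (!length(rows)) stop("no core has enough eligible cells")
  composition <- do.call(rbind, rows)
  colnames(composition) <- eligible_types
  rownames(composition) <- unlist(ids, use.names = FALSE)
  list(composition = composition,
       cell_id = unlist(ids, use.names = FALSE),
       image_id = unlist(imgs, use.names = FALSE),
       types = eligible_types, W = W)
}

# Mini-batch k-means (sampled batches, streaming centroid updates), then a
# final full assignment pass. Deterministic under the caller's RNG state.
.minibatch_kmeans <- function(X, k, batch = 1024L, iters = 100L) {
  n <- nrow(X)
  centers <- X[sample.int(n, k), , drop = FALSE]
  counts <- rep(0, k)
  for (it in seq_len(iters)) {
    b <- X[sample.int(n, min(batch, n)), , drop = FALSE]
    d <- .sqdist(b, centers)
    a <- max.col(-d, ties.method = "first")
    for (c in unique(a)) {
      rows <- which(a == c)
      counts[c] <- counts[c] + length(rows)
      eta <- length(rows) / counts[c]
      centers[c, ] <- (1 - eta) * centers[c, ] + eta * colMeans(b[rows, , drop = FALSE])
    }
  }
  centers
}

# Squared Euclidean distances between rows of A and rows of B.
.sqdist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d <- outer(an, bn, "+") - 2 * A %*% t(B)
  d[d < 0] <- 0
  d
}

#' Fit cellular communities by k-means on window compositions
#'
#' @param windows output of [build_windows()] (or a plain numeric matrix).
#' @param k number of communities (default 10).
#' @param seed integer seed; assignments are identical under the same seed.
#' @param method `"minibatch"` (default; streaming mini-batch updates) or
#'   `"lloyd"` (exact full-batch via [stats::kmeans()]).
#' @param nstart restarts for the lloyd method.
#' @return object of class `community_model`: `centroids` (k x types, rows
#'   sum to 1), `assignment` (1..k per window row), `k`, `W`, `types`,
#'   `distortion` (total within-cluster sum of squares), `seed`, plus the
#'   window bookkeeping (`cell_id`, `image_id`).
#' @export
fit_communities <- function(windows, k = 10, seed = 1L,
                            method = c("minibatch", "lloyd"), nstart = 5L) {
  method <- match.arg(method)
  X <- if (is.list(windows)) windows$composition else windows
  if (!nrow(X)) stop("windows are empty")
  if (k > nrow(X)) stop("k exceeds the number of windows")
  set.seed(seed)
  if (k == 1L) {
    centers <- matrix(colMeans(X), 1, ncol(X), dimnames = list(NULL, colnames(X)))
    assignment <- rep(1L, nrow(X))
  } else if (k == nrow(X)) {
    centers <- X
    assignment <- seq_len(nrow(X))
  } else if (method == "minibatch") {
    centers <- .minibatch_kmeans(X, k)
    assignment <- max.col(-.sqdist(X, centers), ties.method = "first")
    # empty clusters: reseed on the farthest points, one pass
    empty <- setdiff(seq_len(k), unique(assignment))
    if (length(empty)) {
      d <- .sqdist(X, centers)
      far <- order(apply(d, 1, min), decreasing = TRUE)[seq_along(empty)]
      centers[empty, ] <- X[far, , drop = FALSE]
      assignment <- max.col(-.sqdist(X, centers), ties.method = "first")
    }
    for (c in seq_len(k)) {            # final centroid refresh
      rows <- which(assignment == c)
      if (length(rows)) centers[c, ] <- colMeans(X[rows, , drop = FALSE])
    }
  } else {
    km <- stats::kmeans(X, centers = k, nstart = nstart, iter.max = 100)
    centers <- km$centers
    assignment <- km$cluster
  }
  dimnames(centers) <- list(NULL, colnames(X))
  distortion <- sum((X - centers[assignment, , drop = FALSE])^2)
  structure(list(
    centroids = centers, assignment = as.integer(assignment), k = k,
    W = if (is.list(windows)) windows$W else NA,
    types = colnames(X), distortion = distortion, seed = seed,
    cell_id = if (is.list(windows)) windows$cell_id else NULL,
    image_id = if (is.list(windows)) windows$image_id else NULL
  ), class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat("community model: k =", x$k, ", window W =", x$W, ",",
      length(x$assignment), "cells\n")
  cat("community sizes:\n")
  print(table(x$assignment))
  invisible(x)
}

#' Predict community membership for new window compositions
#' @param object a `community_model`.
#' @param newdata windows (list or matrix) with the same type columns.
#' @param ... unused.
#' @return integer community assignments.
#' @export
predict.community_model <- function(object, newdata, ...) {
  X <- if (is.list(newdata)) newdata$composition else newdata
  max.col(-.sqdist(X[, object$types, drop = FALSE], object$centroids),
          ties.method = "first")
}

#' Select the number of communities by the distortion elbow
#'
#' Fits k-means over a range of k and computes the distortion (total sum of
#' squared distances of windows to their assigned centers). The selected k*
#' is the elbow: the k with the maximum second difference (discrete
#' curvature) of the distortion curve.
#'
#' @param windows output of [build_windows()].
#' @param k_range candidate k values (default 1:20).
#' @param seed integer seed.
#' @param method clustering method passed to [fit_communities()].
#' @return list `distortion` (named numeric over k), `k_star`.
#' @export
select_k <- function(windows, k_range = 1:20, seed = 1L,
                     method = "minibatch") {
  X <- if (is.list(windows)) windows$composition else windows
  k_range <- sort(unique(k_range))
  k_range <- k_range[k_range <= nrow(X)]
  distortion <- vapply(k_range, function(k) {
    fit_communities(windows, k = k, seed = seed, method = method)$distortion
  }, numeric(1))
  names(distortion) <- k_range
  k_star <- if (length(k_range) >= 3L) {
    curv <- diff(diff(distortion))      # second difference at interior ks
    k_range[which.max(curv) + 1L]
  } else k_range[length(k_range)]
  list(distortion = distortion, k_star = k_star)
}

#' Subsampling concordance of a community model
#'
#' Refits the clustering on random subsamples of the windows, optimally
#' matches the subsample labels to the full-model labels (assignment-problem
#' matching on the confusion matrix) and reports the fraction of cells
#' assigned to the same community.
#'
#' @param windows output of [build_windows()].
#' @param model fitted `community_model`.
#' @param fraction subsample fraction (default 1/3).
#' @param reps number of subsamples (default 3).
#' @param seed integer seed.
#' @param method clustering method for the refits.
#' @return list `per_rep` (concordance fraction per repetition) and `median`.
#' @export
concordance <- function(windows, model, fraction = 1/3, reps = 3, seed = 1L,
                        method = "minibatch") {
  X <- if (is.list(windows)) windows$composition else windows
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  per_rep <- numeric(reps)
  for (r in seq_len(reps)) {
    idx <- sample.int(nrow(X), max(model$k, round(fraction * nrow(X))))
    sub_fit <- fit_communities(X[idx, , drop = FALSE], k = model$k,
                               seed = rep_seeds[r], method = method)
    m <- match_labels(model$assignment[idx], sub_fit$assignment)
    per_rep[r] <- m$agreement
  }
  list(per_rep = per_rep, median = stats::median(per_rep))
}

#' Cell-type enrichment of a community
#'
#' Tests whether the per-core density of a cell type is higher inside the
#' community of interest than in all other communities combined, using a
#' linear mixed-effects model with patient as a random intercept and an
#' ANOVA-style p-value (Satterthwaite). With a single patient the model
#' falls back to a fixed-effect comparison with a warning. Cores where the
#' community is absent contribute density 0 (they are not dropped).
#'
#' @param cells cell table with `community` assignments (integer column),
#'   `image_id`, `patient_id`, `cell_type`.
#' @param community community id of interest.
#' @param type cell type tested for enrichment.
#' @param areas per-core areas data.frame (as in [compute_densities()]).
#' @return list `effect` (difference of in-community vs out-of-community
#'   mean density, cells/mm^2 equivalents), `p_value`, `n_cores`.
#' @export
community_enrichment <- function(cells, community, type, areas) {
  stopifnot("community" %in% names(cells))
  cores <- areas$image_id
  tot_area <- areas$area_tumor_nest_mm2 + areas$area_stroma_mm2
  pat <- areas$patient_id
  rows <- list()
  for (i in seq_along(cores)) {
    sub <- cells[cells$image_id == cores[i], ]
    for (grp in c(TRUE, FALSE)) {
      sel <- if (grp) sub$community == community else sub$community != community
      cnt <- sum(sel & sub$cell_type == type, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = cores[i], patient_id = pat[i],
        in_community = grp, density = cnt / tot_area[i])
    }
  }
  d <- do.call(rbind, rows)
  single_patient <- length(unique(d$patient_id)) < 2L
  if (single_patient) {
    warning("single patient: falling back to a fixed-effect comparison")
    fit <- stats::lm(density ~ in_community, data = d)
    p <- stats::anova(fit)["in_community", "Pr(>F)"]
    eff <- stats::coef(fit)[["in_communityTRUE"]]
  } else {
    fit <- lmerTest::lmer(density ~ in_community + (1 | patient_id), data = d)
    a <- stats::anova(fit)
    p <- a["in_community", "Pr(>F)"]
    eff <- lme4::fixef(fit)[["in_communityTRUE"]]
  }
  list(effect = eff, p_value = p, n_cores = length(cores))
}
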