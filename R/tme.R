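# Four-class TME classification: consensus clustering of compartment-wise
# immune cell densities, then explicit per-class decision criteria with
# automatically derived cutoffs and an "undefined" label for cores that fail
# their cluster's criteria.

# Cell-type groups feeding the TME feature matrix.
.tme_groups <- function() {
  list(
    CD8 = "CD8 T cells",
    CD4 = "CD4 T cells",
    B = c("B cell", "plasma cell", "B cell lineage - other", "B cells"),
    mac163p = c("CD163+CD206+ macrophage", "alveolar macrophage"),
    mac163n = "CD163- macrophage",
    neutrophil = "neutrophil",
    myeloid_other = c("myeloid cells - other", "monocytes", "mDCs")
  )
}

#' TME feature matrix from a region density object
#'
#' Builds the default classification features: densities of CD8 T cells,
#' CD4 T cells, B lineage, CD163+CD206+ and CD163- macrophages, neutrophils
#' and other myeloid cells per compartment, with B lineage and myeloid-other
#' restricted to the stroma (they are essentially absent from the tumor
#' nest). Also computes the per-core neutrophil proportion of all cells in
#' each compartment, used by the neutrophil-class criterion.
#'
#' @param rd a `region_density` from [compute_densities()].
#' @return list: `density` (cores x features), `z` (robust z of `density`),
#'   `neut_prop` (cores x c(tumor_nest, stroma) proportions), `meta`.
#' @export
tme_features <- function(rd) {
  stopifnot(inherits(rd, "region_density"))
  groups <- .tme_groups()
  counts <- rd$counts
  have <- colnames(counts)
  grp_count <- function(members, comp) {
    cols <- intersect(paste(members, comp, sep = "__"), have)
    if (!length(cols)) return(rep(0, nrow(counts)))
    rowSums(counts[, cols, drop = FALSE])
  }
  feats <- list()
  for (g in names(groups)) {
    for (comp in c("tumor_nest", "stroma")) {
      if (comp == "tumor_nest" && g %in% c("B", "myeloid_other")) next
      feats[[paste(g, comp, sep = "__")]] <-
        grp_count(groups[[g]], comp) / rd$areas[, comp]
    }
  }
  density <- do.call(cbind, feats)
  rownames(density) <- rownames(rd$density)
  all_nest <- rowSums(counts[, grep("__tumor_nest$", have), drop = FALSE])
  all_stroma <- rowSums(counts[, grep("__stroma$", have), drop = FALSE])
  neut_prop <- cbind(
    tumor_nest = ifelse(all_nest > 0, grp_count("neutrophil", "tumor_nest") / all_nest, 0),
    stroma = ifelse(all_stroma > 0, grp_count("neutrophil", "stroma") / all_stroma, 0)
  )
  rownames(neut_prop) <- rownames(rd$density)
  list(density = density, z = robust_z(density), neut_prop = neut_prop,
       meta = rd$meta)
}

#' Consensus clustering of cores
#'
#' Hierarchical clustering (Chebyshev/maximum distance, Ward linkage) of row
#' subsamples; the consensus value of a pair of cores is the fraction of
#' co-sampled iterations in which the pair co-clusters. Final labels per k
#' come from Ward clustering of 1 - consensus as a dissimilarity. The
#' cumulative distribution function of consensus values and its area under
#' the curve (AUC) are reported per k, with delta-AUC(k) = AUC(k) - AUC(k-1)
#' for successive k.
#'
#' @param z numeric matrix (cores x features), typically robust z-scores.
#' @param k_range candidate numbers of clusters (default 2:6).
#' @param subsample row subsample fraction per iteration (default 0.75).
#' @param reps subsampling iterations (default 1000).
#' @param seed integer seed.
#' @return object of class `consensus_result`: `consensus` (list of matrices
#'   per k), `labels` (matrix cores x k), `auc`, `delta_auc` (NA for the
#'   first k), `k_range`.
#' @export
consensus_cluster <- function(z, k_range = 2:6, subsample = 0.75, reps = 1000,
                              seed = 1L) {
  n <- nrow(z)
  if (n < 2 * max(k_range)) stop("need at least 2*k cores")
  # canonical row order (by core id) so results don't depend on input order
  ids <- rownames(z) %||% as.character(seq_len(n))
  ord <- order(ids)
  back <- order(ord)                    # inverse permutation
  z <- z[ord, , drop = FALSE]
  rownames(z) <- ids[ord]
  set.seed(seed)
  m <- max(2L, round(subsample * n))
  k_range <- sort(unique(k_range))
  co_sample <- matrix(0, n, n)
  co_cluster <- lapply(k_range, function(k) matrix(0, n, n))
  names(co_cluster) <- k_range
  for (r in seq_len(reps)) {
    idx <- sort(sample.int(n, m))
    hc <- stats::hclust(stats::dist(z[idx, , drop = FALSE], method = "maximum"),
                        method = "ward.D")
    co_sample[idx, idx] <- co_sample[idx, idx] + 1
    for (k in k_range) {
      lab <- stats::cutree(hc, k)
      same <- outer(lab, lab, "==")
      co_cluster[[as.character(k)]][idx, idx] <-
        co_cluster[[as.character(k)]][idx, idx] + same
    }
  }
  never <- co_sample == 0 & upper.tri(co_sample)
  if (any(never)) {
    warning(sum(never), " core pair(s) never co-sampled; consensus set to 0.5")
  }
  consensus <- lapply(co_cluster, function(cc) {
    cons <- ifelse(co_sample > 0, cc / pmax(co_sample, 1), 0.5)
    diag(cons) <- 1
    dimnames(cons) <- list(rownames(z), rownames(z))
    cons
  })
  labels <- matrix(NA_integer_, n, length(k_range),
                   dimnames = list(rownames(z), k_range))
  auc <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    cons <- consensus[[as.character(k)]]
    hc <- stats::hclust(stats::as.dist(1 - cons), method = "ward.D")
    labels[, i] <- stats::cutree(hc, k)
    v <- sort(cons[upper.tri(cons)])
    cdf <- seq_along(v) / length(v)
    auc[i] <- sum(diff(c(v, 1)) * cdf) + v[1] * 0   # CDF integral over [min, 1]
  }
  delta_auc <- c(NA, diff(auc))
  names(auc) <- names(delta_auc) <- k_range
  # restore the caller's row order
  consensus <- lapply(consensus, function(cm) cm[back, back, drop = FALSE])
  labels <- labels[back, , drop = FALSE]
  structure(list(consensus = consensus, labels = labels, auc = auc,
                 delta_auc = delta_auc, k_range = k_range, reps = reps,
                 subsample = subsample),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus clustering over k =", paste(range(x$k_range), collapse = "-"),
      "(", x$reps, "iterations at", x$subsample, "subsampling)\n")
  cat("CDF AUC:\n"); print(round(x$auc, 3))
  cat("delta AUC:\n"); print(round(x$delta_auc, 3))
  invisible(x)
}

#' Plot consensus CDF curves
#' @param x a `consensus_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.consensus_result <- function(x, ...) {
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "consensus value", ylab = "CDF", ...)
  for (i in seq_along(x$k_range)) {
    cons <- x$consensus[[i]]
    v <- sort(cons[upper.tri(cons)])
    graphics::lines(stats::ecdf(v), col = i, do.points = FALSE)
  }
  graphics::legend("bottomright", legend = paste("k =", x$k_range),
                   col = seq_along(x$k_range), lty = 1, bty = "n")
}

#' Derive a decision cutoff from class membership and a score
#'
#' Fits a binomial GLM of membership on the score (the coefficient sign
#' gives the criterion direction) and picks the threshold where sensitivity
#' and specificity curves intersect: the candidate threshold (midpoint
#' between consecutive distinct scores) minimizing |sensitivity -
#' specificity|; ties resolve to the midpoint of the optimal interval.
#'
#' @param score per-core numeric score.
#' @param membership per-core logical class membership.
#' @return list `cutoff`, `direction` (+1: members above the cutoff, -1:
#'   members below), `glm_coef`.
#' @export
derive_cutoff <- function(score, membership) {
  membership <- as.logical(membership)
  if (!any(membership) || all(membership)) stop("both classes must be nonempty")
  if (length(unique(score)) < 2L) stop("score is constant; cutoff undefined")
  fit <- suppressWarnings(stats::glm(membership ~ score, family = stats::binomial()))
  beta <- stats::coef(fit)[["score"]]
  direction <- if (is.na(beta) || beta >= 0) 1 else -1
  u <- sort(unique(score))
  thr <- (u[-1] + u[-length(u)]) / 2
  sens <- spec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    hi <- score > thr[i]
    if (direction > 0) {
      sens[i] <- mean(hi[membership])
      spec[i] <- mean(!hi[!membership])
    } else {
      sens[i] <- mean(!hi[membership])
      spec[i] <- mean(hi[!membership])
    }
  }
  d <- abs(sens - spec)
  best <- which(d == min(d))
  cutoff <- mean(range(thr[best]))
  list(cutoff = cutoff, direction = direction, glm_coef = beta)
}

# Group scores used by the class criteria: row-wise max over the robust-z
# features of a group ("TIL or macrophage" OR-phrasing).
.tme_scores <- function(feats) {
  z <- feats$z
  gmax <- function(cols) {
    cols <- intersect(cols, colnames(z))
    apply(z[, cols, drop = FALSE], 1, max)
  }
  list(
    tilmphi_nest = gmax(c("CD8__tumor_nest", "CD4__tumor_nest",
                          "mac163p__tumor_nest", "mac163n__tumor_nest")),
    tilmphi_stroma = gmax(c("CD8__stroma", "CD4__stroma", "B__stroma",
                            "mac163p__stroma", "mac163n__stroma")),
    immune_nest = gmax(grep("__tumor_nest$", colnames(z), value = TRUE)),
    neut_prop_nest = feats$neut_prop[, "tumor_nest"],
    neut_prop_stroma = feats$neut_prop[, "stroma"]
  )
}

#' Fit the four-class TME model
#'
#' Consensus-clusters the robust-z density features at k = 4, maps the
#' clusters onto the four named classes by their centroid profiles
#' (neutrophil proportion -> "TS:Neutrophil high"; then highest tumor-nest
#' TIL/macrophage z -> "TS:TIL+MP high"; of the remaining two, higher
#' stromal TIL/macrophage -> "T:TIL+MP excluded", the other "TS:Immune
#' low"), then derives each class's decision criteria and cutoffs with
#' [derive_cutoff()]. Cores failing their cluster's criteria are labeled
#' `"undefined"`.
#'
#' @param rd a `region_density`.
#' @param k number of consensus clusters kept (default 4).
#' @param k_range diagnostic range for the consensus CDF/delta-AUC.
#' @param reps,subsample consensus-clustering parameters.
#' @param seed integer seed.
#' @return object of class `tme_model`: `features`, `consensus`, `clusters`
#'   (per-core cluster id), `class_of_cluster`, `criteria`, `labels`
#'   (per-core final class incl. "undefined"), `meta`.
#' @export
tme_model <- function(rd, k = 4, k_range = 2:6, reps = 1000, subsample = 0.75,
                      seed = 1L) {
  feats <- tme_features(rd)
  cons <- consensus_cluster(feats$z, k_range = unique(sort(c(k_range, k))),
                            subsample = subsample, reps = reps, seed = seed)
  clusters <- cons$labels[, as.character(k)]
  if (k != 4) {
    # the four named classes require four clusters; otherwise keep generic
    # cluster labels with no criteria
    class_of <- stats::setNames(paste0("cluster_", sort(unique(clusters))),
                                sort(unique(clusters)))
    model <- structure(list(features = feats, consensus = cons,
                            clusters = clusters, class_of_cluster = class_of,
                            criteria = list(), k = k, meta = feats$meta,
                            seed = seed),
                       class = "tme_model")
    model$labels <- stats::setNames(unname(class_of[as.character(clusters)]),
                                    names(clusters))
    return(model)
  }
  scores <- .tme_scores(feats)
  cl_ids <- sort(unique(clusters))
  cmean <- function(v) vapply(cl_ids, function(c) mean(v[clusters == c]), numeric(1))
  neut_score <- pmax(scores$neut_prop_nest, scores$neut_prop_stroma)
  class_of <- rep(NA_character_, length(cl_ids)); names(class_of) <- cl_ids
  take <- function(v, avail) avail[which.max(v[match(avail, cl_ids)])]
  avail <- cl_ids
  c_neut <- take(cmean(neut_score), avail)
  class_of[as.character(c_neut)] <- "TS:Neutrophil high"
  avail <- setdiff(avail, c_neut)
  c_high <- take(cmean(scores$tilmphi_nest), avail)
  class_of[as.character(c_high)] <- "TS:TIL+MP high"
  avail <- setdiff(avail, c_high)
  c_excl <- take(cmean(scores$tilmphi_stroma), avail)
  class_of[as.character(c_excl)] <- "T:TIL+MP excluded"
  avail <- setdiff(avail, c_excl)
  class_of[as.character(avail)] <- "TS:Immune low"
  c_low <- avail[1]

  criteria <- list(
    "TS:TIL+MP high" = list(list(score = "tilmphi_nest",
                                 cut = derive_cutoff(scores$tilmphi_nest,
                                                     clusters == c_high))),
    "TS:Immune low" = list(list(score = "immune_nest",
                                cut = derive_cutoff(scores$immune_nest,
                                                    clusters == c_low))),
    "T:TIL+MP excluded" = list(
      list(score = "tilmphi_nest",
           cut = derive_cutoff(scores$tilmphi_nest[clusters %in% c(c_excl, c_high)],
                               (clusters == c_excl)[clusters %in% c(c_excl, c_high)]),
           subset = "vs_high"),
      list(score = "tilmphi_stroma",
           cut = derive_cutoff(scores$tilmphi_stroma[clusters %in% c(c_excl, c_low)],
                               (clusters == c_excl)[clusters %in% c(c_excl, c_low)]),
           subset = "vs_low")),
    "TS:Neutrophil high" = list(
      list(score = "neut_prop_nest",
           cut = derive_cutoff(scores$neut_prop_nest, clusters == c_neut),
           combine = "or"),
      list(score = "neut_prop_stroma",
           cut = derive_cutoff(scores$neut_prop_stroma, clusters == c_neut),
           combine = "or"))
  )
  model <- structure(list(features = feats, consensus = cons,
                          clusters = clusters, class_of_cluster = class_of,
                          criteria = criteria, k = k, meta = feats$meta,
                          seed = seed),
                     class = "tme_model")
  model$labels <- assign_tme(model)
  model
}

.criterion_pass <- function(crit, scores, i) {
  s <- scores[[crit$score]][i]
  if (is.na(s)) return(NA)
  if (crit$cut$direction > 0) s > crit$cut$cutoff else s < crit$cut$cutoff
}

#' Assign TME class labels
#'
#' Each core keeps its consensus cluster's class only if it passes that
#' class's criteria; otherwise it is labeled `"undefined"`. Criteria marked
#' `combine = "or"` pass if any of them passes (the neutrophil class);
#' otherwise all must pass.
#'
#' @param model a fitted `tme_model`.
#' @param rd optional new `region_density`; when given, cores are assigned
#'   to the nearest cluster centroid (Chebyshev distance on robust z) before
#'   the criteria are applied.
#' @return character vector of per-core labels.
#' @export
assign_tme <- function(model, rd = NULL) {
  if (is.null(rd)) {
    feats <- model$features
    clusters <- model$clusters
  } else {
    feats <- tme_features(rd)
    cl_ids <- sort(unique(model$clusters))
    cent <- t(vapply(cl_ids, function(c) {
      colMeans(model$features$z[model$clusters == c, , drop = FALSE])
    }, numeric(ncol(model$features$z))))
    common <- intersect(colnames(feats$z), colnames(cent))
    d <- vapply(seq_len(nrow(cent)), function(j) {
      apply(abs(sweep(feats$z[, common, drop = FALSE], 2, cent[j, common])), 1, max)
    }, numeric(nrow(feats$z)))
    clusters <- cl_ids[max.col(-d, ties.method = "first")]
    names(clusters) <- rownames(feats$z)
  }
  scores <- .tme_scores(feats)
  out <- rep("undefined", length(clusters))
  names(out) <- names(clusters)
  for (i in seq_along(clusters)) {
    cls <- model$class_of_cluster[[as.character(clusters[i])]]
    crits <- model$criteria[[cls]]
    res <- vapply(crits, .criterion_pass, scores = scores, i = i, logical(1))
    if (anyNA(res)) {
      warning("core ", names(clusters)[i], " is missing a criterion feature")
      next
    }
    or_mode <- any(vapply(crits, function(cr) identical(cr$combine, "or"), logical(1)))
    if ((or_mode && any(res)) || (!or_mode && all(res))) out[i] <- cls
  }
  out
}

#' @export
print.tme_model <- function(x, ...) {
  cat("TME model: k =", x$k, "consensus clusters over",
      nrow(x$features$z), "cores\n")
  cat("class labels:\n")
  print(table(x$labels))
  cat("delta AUC by k:\n")
  print(round(x$consensus$delta_auc, 3))
  invisible(x)
}
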