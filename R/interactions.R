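# Per-image cell-cell interaction/avoidance permutation testing and
# cross-core aggregation with a patient-aware logistic model.

#' Neighbor lists for interaction testing
#'
#' Centroid-distance adjacency: two cells are neighbors if their centers are
#' within `radius_um` plus both equivalent radii (from per-cell `area_um2`
#' if present, else a fixed `cell_radius_um` each). This approximates the
#' mask-dilation neighborhood (5 px) used on segmentation masks.
#'
#' @param cells cell table of one image.
#' @param radius_um gap radius, default 5.
#' @param cell_radius_um fallback equivalent radius per cell, default 5.
#' @return list of integer neighbor index vectors (symmetric, self excluded).
#' @export
interaction_neighbors <- function(cells, radius_um = 5, cell_radius_um = 5) {
  r_cell <- if ("area_um2" %in% names(cells)) sqrt(cells$area_um2 / pi)
            else rep(cell_radius_um, nrow(cells))
  thr <- radius_um + 2 * max(r_cell)
  nb <- radius_neighbors(cells$x_um, cells$y_um, thr)
  # refine per pair with the actual radii
  for (i in seq_along(nb)) {
    j <- nb[[i]]
    if (!length(j)) next
    d <- sqrt((cells$x_um[j] - cells$x_um[i])^2 + (cells$y_um[j] - cells$y_um[i])^2)
    nb[[i]] <- j[d <= radius_um + r_cell[i] + r_cell[j]]
  }
  nb
}

#' Permutation test of pairwise spatial relationships in one image
#'
#' For each ordered type pair (A center, B neighbor), the statistic is the
#' mean number of B neighbors per A cell. Type labels are permuted over the
#' fixed cell positions; `p_high = (1 + #{perm >= obs}) / (n_perm + 1)` and
#' `p_low` analogously. The relation is `interaction` if `p_high <= alpha`,
#' `avoidance` if `p_low <= alpha`, else `ns`.
#'
#' @param cells cell table of one image (`cell_type`, coordinates).
#' @param pairs optional 2-column character matrix of (A, B) pairs; default
#'   all ordered pairs of observed types.
#' @param n_perm permutations, default 1000.
#' @param alpha significance level per tail, default 0.05.
#' @param seed integer seed.
#' @param neighbors precomputed neighbor lists (else computed with
#'   defaults).
#' @param ... passed to [interaction_neighbors()].
#' @return data.frame: image_id, type_a, type_b, obs, p_high, p_low,
#'   relation.
#' @export
permutation_relations <- function(cells, pairs = NULL, n_perm = 1000,
                                  alpha = 0.05, seed = 1L, neighbors = NULL,
                                  ...) {
  set.seed(seed)
  types <- sort(unique(cells$cell_type))
  if (is.null(pairs)) {
    pairs <- as.matrix(expand.grid(type_a = types, type_b = types,
                                   stringsAsFactors = FALSE))
  }
  if (is.null(neighbors)) neighbors <- interaction_neighbors(cells, ...)
  n <- nrow(cells)
  lab <- factor(cells$cell_type, levels = types)
  # flattened neighbor pairs (i, j): counts per type via one tabulate pass
  src <- rep(seq_len(n), lengths(neighbors))
  dst <- unlist(neighbors, use.names = FALSE)
  nt <- length(types)
  stat_all <- function(lab_int) {
    # mean B-neighbor count per A cell, all pairs at once (nt x nt matrix)
    cnt <- matrix(0, n, nt)
    if (length(dst)) {
      ix <- src + (lab_int[dst] - 1L) * n
      tb <- tabulate(ix, nbins = n * nt)
      cnt <- matrix(tb, n, nt)
    }
    na <- tabulate(lab_int, nbins = nt)
    out <- matrix(NA_real_, nt, nt)
    for (a in seq_len(nt)) {
      if (na[a] > 0) out[a, ] <- colMeans(cnt[lab_int == a, , drop = FALSE])
    }
    out
  }
  lab_int <- as.integer(lab)
  obs <- stat_all(lab_int)
  ge <- matrix(0L, nt, nt); le <- matrix(0L, nt, nt)
  for (p in seq_len(n_perm)) {
    s <- stat_all(sample(lab_int))
    ge <- ge + (s >= obs)
    le <- le + (s <= obs)
  }
  res <- data.frame(image_id = cells$image_id[1],
                    type_a = pairs[, 1], type_b = pairs[, 2],
                    obs = NA_real_, p_high = NA_real_, p_low = NA_real_,
                    relation = NA_character_, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(res))) {
    a <- match(res$type_a[r], types); b <- match(res$type_b[r], types)
    if (is.na(a) || is.na(b) || is.na(obs[a, b])) next  # type absent: skipped
    res$obs[r] <- obs[a, b]
    res$p_high[r] <- (1 + ge[a, b]) / (n_perm + 1)
    res$p_low[r] <- (1 + le[a, b]) / (n_perm + 1)
    res$relation[r] <- if (res$p_high[r] <= alpha) "interaction"
                       else if (res$p_low[r] <= alpha) "avoidance" else "ns"
  }
  res[!is.na(res$relation), , drop = FALSE]
}

#' Aggregate per-core relations across groups
#'
#' For each type pair, models the per-core presence of a relation (binary)
#' on the group indicator with a patient random intercept (binomial GLMM)
#' and reports Benjamini-Hochberg adjusted p-values. Pairs are reported only
#' if both constituent types are present in at least `presence_min` of the
#' cores. Degenerate pairs (all-0/all-1 outcome) are flagged without an
#' estimate.
#'
#' @param results row-bound output of [permutation_relations()] over cores.
#' @param groups data.frame: image_id, patient_id, group (logical or
#'   2-level).
#' @param relation which relation to model, default `"interaction"`.
#' @param type_presence data.frame image_id x type presence (cell table
#'   derived): columns `image_id`, `cell_type`; default derived from
#'   `results` obs availability.
#' @param presence_min fraction of cores in which both types must be
#'   present, default 0.9.
#' @return data.frame: type_a, type_b, estimate, p_value, p_adj, n_cores,
#'   degenerate.
#' @export
aggregate_relations <- function(results, groups, relation = "interaction",
                                type_presence = NULL, presence_min = 0.9) {
  stopifnot(all(c("image_id", "patient_id", "group") %in% names(groups)))
  if (length(unique(groups$group)) < 2) stop("need at least two groups")
  n_cores <- length(unique(groups$image_id))
  if (is.null(type_presence)) {
    type_presence <- unique(rbind(
      data.frame(image_id = results$image_id, cell_type = results$type_a),
      data.frame(image_id = results$image_id, cell_type = results$type_b)))
  }
  pres_frac <- table(type_presence$cell_type) / n_cores
  pairs <- unique(results[, c("type_a", "type_b")])
  keep <- pres_frac[pairs$type_a] >= presence_min &
          pres_frac[pairs$type_b] >= presence_min
  pairs <- pairs[!is.na(keep) & keep, , drop = FALSE]
  out <- list()
  for (r in seq_len(nrow(pairs))) {
    sub <- results[results$type_a == pairs$type_a[r] &
                   results$type_b == pairs$type_b[r], ]
    d <- merge(sub, groups, by = "image_id")
    d$y <- as.integer(d$relation == relation)
    row <- data.frame(type_a = pairs$type_a[r], type_b = pairs$type_b[r],
                      estimate = NA_real_, p_value = NA_real_,
                      n_cores = nrow(d), degenerate = FALSE,
                      stringsAsFactors = FALSE)
    if (length(unique(d$y)) < 2) {
      row$degenerate <- TRUE
    } else {
      fit <- try(suppressMessages(suppressWarnings(
        lme4::glmer(y ~ group + (1 | patient_id), data = d,
                    family = stats::binomial()))), silent = TRUE)
      fit0 <- try(suppressMessages(suppressWarnings(
        lme4::glmer(y ~ 1 + (1 | patient_id), data = d,
                    family = stats::binomial()))), silent = TRUE)
      if (!inherits(fit, "try-error") && !inherits(fit0, "try-error")) {
        row$estimate <- unname(lme4::fixef(fit)[2])
        # likelihood-ratio p: robust to separation, unlike the Wald z
        lrt <- suppressMessages(suppressWarnings(stats::anova(fit0, fit)))
        row$p_value <- lrt[2, "Pr(>Chisq)"]
      } else {
        row$degenerate <- TRUE
      }
    }
    out[[r]] <- row
  }
  if (!length(out)) {
    out <- data.frame(type_a = character(0), type_b = character(0),
                      estimate = numeric(0), p_value = numeric(0),
                      n_cores = integer(0), degenerate = logical(0))
  } else {
    out <- do.call(rbind, out)
  }
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out
}
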