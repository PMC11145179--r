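# Intratumor heterogeneity (ITH) statistics over multi-region tumors, plus
# TAN scoring, tumor mutational burden and recent-subclonal-expansion scores.

#' Spatial ITH score of per-core features
#'
#' For each feature: z-score the per-core values across the cohort, compute
#' the standard deviation across each patient's cores (patients with two or
#' more cores), average those SDs over patients, then z-score the resulting
#' per-feature means across features. Higher scores mean more region-to-
#' region variability within tumors.
#'
#' @param densities numeric matrix, cores x features.
#' @param patient per-core patient ids (same length as `nrow(densities)`).
#' @return named numeric vector of per-feature ITH scores (mean 0, sd 1
#'   across features).
#' @export
ith_score <- function(densities, patient) {
  densities <- as.matrix(densities)
  stopifnot(nrow(densities) == length(patient))
  multi <- names(which(table(patient) >= 2))
  if (!length(multi)) stop("no patient has two or more cores")
  z <- scale(densities)
  sd_by_pat <- vapply(multi, function(p) {
    apply(z[patient == p, , drop = FALSE], 2, stats::sd)
  }, numeric(ncol(z)))
  sd_by_pat <- matrix(sd_by_pat, nrow = ncol(z))
  raw <- rowMeans(sd_by_pat, na.rm = TRUE)
  out <- as.vector(scale(raw))
  names(out) <- colnames(densities)
  out
}

#' Bootstrap probability of TME-class homogeneity across regions
#'
#' For each bootstrap iteration and each number of sampled regions n, draws
#' n cores with replacement from every multi-core tumor and, for each class,
#' computes the ratio of tumors whose sampled cores all carry that class to
#' the tumors having the class in any core. The reported probability is the
#' mean of this ratio over iterations and over the values of n; the ITH
#' probability is its complement.
#'
#' @param labels per-core class labels.
#' @param tumor per-core tumor (patient) ids.
#' @param n_samples numbers of regions drawn per tumor, default `c(2, 3, 4)`.
#' @param reps bootstrap iterations, default 1000.
#' @param seed integer seed.
#' @param classes classes to report (default: all observed).
#' @return data.frame: class, p_same (homogeneity probability), p_ith
#'   (1 - p_same), n_tumors (denominator).
#' @export
class_homogeneity_probability <- function(labels, tumor,
                                          n_samples = c(2, 3, 4),
                                          reps = 1000, seed = 1L,
                                          classes = NULL) {
  stopifnot(length(labels) == length(tumor))
  set.seed(seed)
  by_tumor <- split(as.character(labels), tumor)
  by_tumor <- by_tumor[lengths(by_tumor) >= 2]
  if (!length(by_tumor)) stop("no tumor has two or more cores")
  if (is.null(classes)) classes <- sort(unique(unlist(by_tumor)))
  has_class <- vapply(classes, function(cl) {
    vapply(by_tumor, function(v) cl %in% v, logical(1))
  }, logical(length(by_tumor)))
  has_class <- matrix(has_class, ncol = length(classes),
                      dimnames = list(names(by_tumor), classes))
  denom <- colSums(has_class)
  acc <- matrix(0, length(n_samples), length(classes),
                dimnames = list(n_samples, classes))
  for (r in seq_len(reps)) {
    for (ni in seq_along(n_samples)) {
      n <- n_samples[ni]
      all_same <- vapply(by_tumor, function(v) {
        s <- v[sample.int(length(v), n, replace = TRUE)]
        if (length(unique(s)) == 1L) s[1] else NA_character_
      }, character(1))
      for (ci in seq_along(classes)) {
        if (denom[ci] == 0) next
        num <- sum(!is.na(all_same) & all_same == classes[ci] &
                     has_class[, ci])
        acc[ni, ci] <- acc[ni, ci] + num / denom[ci]
      }
    }
  }
  p_same <- colMeans(acc / reps)
  p_same[denom == 0] <- NA_real_
  data.frame(class = classes, p_same = unname(p_same),
             p_ith = unname(1 - p_same), n_tumors = unname(denom),
             stringsAsFactors = FALSE)
}

#' Median nearest-neighbor distance from one cell type to another
#'
#' Per source cell of type `source`, the Euclidean distance to the nearest
#' cell of type `target` within the same core; the per-core value is the
#' median. Cores missing the target type return NA with a warning.
#'
#' @param cells cell table.
#' @param source,target cell-type labels.
#' @return data.frame: image_id, median_distance_um, n_source, n_target.
#' @export
median_distance_to_type <- function(cells, source, target) {
  imgs <- unique(cells$image_id)
  rows <- lapply(imgs, function(img) {
    sub <- cells[cells$image_id == img, ]
    si <- which(sub$cell_type == source)
    ti <- which(sub$cell_type == target)
    if (!length(ti) || !length(si)) {
      warning("core ", img, ": source or target type absent; distance missing")
      return(data.frame(image_id = img, median_distance_um = NA_real_,
                        n_source = length(si), n_target = length(ti)))
    }
    d <- vapply(si, function(i) {
      sqrt(min((sub$x_um[ti] - sub$x_um[i])^2 + (sub$y_um[ti] - sub$y_um[i])^2))
    }, numeric(1))
    data.frame(image_id = img, median_distance_um = stats::median(d),
               n_source = length(si), n_target = length(ti))
  })
  do.call(rbind, rows)
}

#' Classify a TAN record as high or low
#'
#' A record is TAN-high if either the tumor-compartment neutrophil area
#' percentage (tTAN) exceeds the tumor cutoff or the stromal percentage
#' (sTAN) exceeds the stroma cutoff, with histology-specific cutoffs. The
#' default cutoffs are the diagnostic-slide values: tTAN 2%/3% and sTAN
#' 1%/2% in LUAD/LUSC.
#'
#' @param ttan,stan neutrophil area percentages (0-100) in the tumor and
#'   stromal compartments.
#' @param histology `"LUAD"` or `"LUSC"` (must appear in `cutoffs`).
#' @param cutoffs named list: histology -> c(ttan, stan) cutoff percentages.
#' @return `"high"` or `"low"` (vectorized over records).
#' @export
tan_classify <- function(ttan, stan, histology,
                         cutoffs = list(LUAD = c(ttan = 2, stan = 1),
                                        LUSC = c(ttan = 3, stan = 2))) {
  stopifnot(length(ttan) == length(stan), length(histology) %in% c(1, length(ttan)))
  histology <- rep(histology, length.out = length(ttan))
  if (any(ttan < 0 | ttan > 100 | stan < 0 | stan > 100)) {
    stop("TAN percentages must be within [0, 100]")
  }
  unknown <- setdiff(unique(histology), names(cutoffs))
  if (length(unknown)) stop("unknown histology: ", paste(unknown, collapse = ", "))
  out <- character(length(ttan))
  for (i in seq_along(ttan)) {
    ct <- cutoffs[[histology[i]]]
    out[i] <- if (ttan[i] > ct[["ttan"]] || stan[i] > ct[["stan"]]) "high" else "low"
  }
  out
}

#' Tumor mutational burden status
#'
#' Mutations per coding megabase; high at >= 10 muts/Mb (boundary
#' inclusive).
#'
#' @param mutations somatic mutation count(s) in coding regions.
#' @param coding_mb coding megabases covered (> 0).
#' @return data.frame: muts_per_mb, status ("high"/"low").
#' @export
tmb_status <- function(mutations, coding_mb) {
  if (any(coding_mb <= 0)) stop("coding_mb must be > 0")
  rate <- mutations / coding_mb
  data.frame(muts_per_mb = rate,
             status = ifelse(rate >= 10, "high", "low"),
             stringsAsFactors = FALSE)
}

#' Construct a clone phylogeny
#'
#' A clone tree with per-region cancer cell fractions (CCF). The root is the
#' clonal cluster (parent NA); leaves are nodes without children.
#'
#' @param nodes character vector of clone ids.
#' @param parents parent clone id per node (NA for the root).
#' @param ccf numeric matrix clones x regions of CCFs in `[0, 1]` (rownames
#'   must match `nodes`).
#' @return object of class `phylo_tree`.
#' @export
phylo_tree <- function(nodes, parents, ccf) {
  stopifnot(length(nodes) == length(parents), !anyDuplicated(nodes))
  ccf <- as.matrix(ccf)
  stopifnot(identical(sort(rownames(ccf)), sort(nodes)))
  if (any(ccf < 0 | ccf > 1, na.rm = TRUE)) stop("CCF values must be in [0, 1]")
  root <- nodes[is.na(parents)]
  if (length(root) != 1) stop("tree must have exactly one root")
  bad <- setdiff(stats::na.omit(parents), nodes)
  if (length(bad)) stop("unknown parent(s): ", paste(bad, collapse = ", "))
  # acyclicity: walking up from each node must reach the root
  for (i in seq_along(nodes)) {
    seen <- character(0); v <- nodes[i]
    while (!is.na(v)) {
      if (v %in% seen) stop("cycle detected at clone ", nodes[i])
      seen <- c(seen, v)
      v <- parents[match(v, nodes)]
    }
  }
  structure(list(nodes = nodes, parents = parents, ccf = ccf),
            class = "phylo_tree")
}

#' Leaf clones of a phylogeny
#' @param tree a `phylo_tree`.
#' @return character vector of clones with no children (the root if it is
#'   the only node).
#' @export
tree_leaves <- function(tree) {
  setdiff(tree$nodes, stats::na.omit(tree$parents))
}

#' Recent subclonal expansion score
#'
#' The maximum cancer cell fraction over the leaf (terminal) clones of the
#' tumor phylogeny in a given region; a single-node tree's root counts as
#' terminal.
#'
#' @param tree a `phylo_tree`.
#' @param region region (column) id.
#' @return numeric score in `[0, 1]`.
#' @export
subclonal_expansion_score <- function(tree, region) {
  stopifnot(inherits(tree, "phylo_tree"))
  if (!region %in% colnames(tree$ccf)) {
    stop("region '", region, "' absent from the tree's CCF table")
  }
  leaves <- tree_leaves(tree)
  max(tree$ccf[leaves, region], na.rm = TRUE)
}

#' Read/write a clone phylogeny as JSON
#' @param path file path.
#' @param tree a `phylo_tree` (for writing).
#' @return for reading, a `phylo_tree`.
#' @export
read_phylo_tree <- function(path) {
  x <- jsonlite::fromJSON(path)
  ccf <- as.matrix(as.data.frame(x$ccf, check.names = FALSE))
  rownames(ccf) <- x$nodes
  parents <- unlist(x$parents)
  parents[parents == ""] <- NA_character_
  phylo_tree(x$nodes, parents, ccf)
}

#' @rdname read_phylo_tree
#' @export
write_phylo_tree <- function(tree, path) {
  parents <- tree$parents
  parents[is.na(parents)] <- ""
  jsonlite::write_json(
    list(nodes = tree$nodes, parents = parents,
         ccf = as.data.frame(tree$ccf, check.names = FALSE)),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
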