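# Compartment assignment and compartment-wise cell density matrices.
# Densities are cell counts normalized by imaged tissue area (mm^2); the
# total imaged area is the sum of the tumor-nest and stroma compartment areas
# (background, e.g. air space, contributes no area).

#' Assign tissue compartments to cells
#'
#' Labels every cell `tumor_nest`, `stroma` or `background`, either from a
#' compartment label mask (0 background, 1 tumor nest, 2 stroma; row = y px,
#' col = x px, 1 um/px) sampled at the cell center, or from an existing
#' per-cell column.
#'
#' @param cells cell table with `x_um`, `y_um`.
#' @param mask optional label mask matrix.
#' @param column optional name of an existing per-cell compartment column.
#' @return the cell table with a `compartment` column.
#' @export
assign_compartment <- function(cells, mask = NULL, column = NULL) {
  if (is.null(mask) && is.null(column)) {
    if (!"compartment" %in% names(cells)) {
      stop("no compartment mask and no per-cell compartment column available")
    }
    return(cells)
  }
  if (!is.null(mask)) {
    v <- .mask_at(mask, cells$x_um, cells$y_um)
    cells$compartment <- c("background", "tumor_nest", "stroma")[v + 1L]
  } else {
    cells$compartment <- cells[[column]]
  }
  cells
}

#' Per-core compartment-wise cell densities
#'
#' Computes a cores x (cell class, compartment) density matrix in cells/mm^2.
#' Background cells are excluded. The `total` compartment uses the summed
#' tumor-nest + stroma area. Compartments with zero area yield `NA` densities
#' for that core (e.g. a core not resolved into an epithelial compartment);
#' a zero-area compartment containing cells is an error.
#'
#' @param cells cell table with `image_id`, `cell_type`, `compartment`.
#' @param areas data.frame with `image_id`, `area_tumor_nest_mm2`,
#'   `area_stroma_mm2` (one row per core); may carry extra metadata columns
#'   (e.g. `patient_id`) which are retained.
#' @param classes cell classes to tabulate (default: all observed).
#' @return object of class `region_density`: list with `density` (numeric
#'   matrix, columns named `<class>__<compartment>`), `counts`, `areas`,
#'   `meta`.
#' @export
compute_densities <- function(cells, areas, classes = NULL) {
  stopifnot(all(c("image_id", "area_tumor_nest_mm2", "area_stroma_mm2") %in% names(areas)))
  if (is.null(classes)) classes <- sort(unique(cells$cell_type))
  cores <- areas$image_id
  keep <- cells$compartment %in% c("tumor_nest", "stroma") &
    cells$cell_type %in% classes & cells$image_id %in% cores
  cc <- cells[keep, c("image_id", "cell_type", "compartment")]
  compartments <- c("tumor_nest", "stroma", "total")
  cols <- as.vector(outer(classes, compartments, paste, sep = "__"))
  counts <- matrix(0, length(cores), length(cols),
                   dimnames = list(cores, cols))
  if (nrow(cc)) {
    tab <- table(factor(cc$image_id, cores), factor(cc$cell_type, classes),
                 factor(cc$compartment, c("tumor_nest", "stroma")))
    for (comp in c("tumor_nest", "stroma")) {
      counts[, paste(classes, comp, sep = "__")] <- tab[, , comp]
    }
    counts[, paste(classes, "total", sep = "__")] <-
      counts[, paste(classes, "tumor_nest", sep = "__"), drop = FALSE] +
      counts[, paste(classes, "stroma", sep = "__"), drop = FALSE]
  }
  area_mat <- cbind(tumor_nest = areas$area_tumor_nest_mm2,
                    stroma = areas$area_stroma_mm2)
  area_mat <- cbind(area_mat, total = rowSums(area_mat))
  rownames(area_mat) <- cores
  dens <- counts
  for (comp in compartments) {
    a <- area_mat[, comp]
    sel <- paste(classes, comp, sep = "__")
    bad <- a <= 0 & rowSums(counts[, sel, drop = FALSE]) > 0
    if (any(bad)) {
      stop("zero compartment area with nonzero cell count in core(s): ",
           paste(cores[bad], collapse = ", "))
    }
    dens[, sel] <- sweep(counts[, sel, drop = FALSE], 1,
                         ifelse(a > 0, a, NA_real_), "/")
  }
  meta_cols <- setdiff(names(areas), c("area_tumor_nest_mm2", "area_stroma_mm2"))
  structure(list(density = dens, counts = counts, areas = area_mat,
                 meta = areas[, meta_cols, drop = FALSE]),
            class = "region_density")
}

#' @export
print.region_density <- function(x, ...) {
  cat("region density matrix:", nrow(x$density), "cores x",
      ncol(x$density), "(class, compartment) columns\n")
  cat("total imaged area (mm^2): median",
      round(stats::median(x$areas[, "total"]), 3), "\n")
  invisible(x)
}

#' Robust z-score normalization of a density matrix
#'
#' Per-column centering and scaling. Robust mode uses the median and the
#' median absolute deviation; by default the MAD is used raw (no 1.4826
#' normal-consistency factor), with the factor available as an option.
#' Columns with zero scale are flagged, scaled by a small epsilon, and a
#' warning is raised.
#'
#' @param m numeric matrix, or a `region_density` (its `density` is used).
#' @param mode `"robust"` (median/MAD) or `"standard"` (mean/sd).
#' @param mad_constant multiplier applied to the MAD (default 1; use 1.4826
#'   for normal consistency).
#' @return numeric matrix of normalized values; attribute `degenerate` names
#'   zero-scale columns.
#' @export
robust_z <- function(m, mode = c("robust", "standard"), mad_constant = 1) {
  mode <- match.arg(mode)
  if (inherits(m, "region_density")) m <- m$density
  m <- as.matrix(m)
  if (nrow(m) < 2L) stop("need at least two cores to normalize")
  center <- if (mode == "robust") apply(m, 2, stats::median, na.rm = TRUE)
            else colMeans(m, na.rm = TRUE)
  scale <- if (mode == "robust") {
    apply(m, 2, function(v) stats::mad(v, constant = 1, na.rm = TRUE)) * mad_constant
  } else {
    apply(m, 2, stats::sd, na.rm = TRUE)
  }
  degenerate <- colnames(m)[!is.na(scale) & scale == 0]
  if (length(degenerate)) {
    warning("zero scale in column(s): ", paste(degenerate, collapse = ", "),
            "; scaled by epsilon")
    scale[scale == 0] <- .Machine$double.eps^0.5
  }
  out <- sweep(sweep(m, 2, center, "-"), 2, scale, "/")
  attr(out, "degenerate") <- degenerate
  out
}
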