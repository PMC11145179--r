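# Rule-based cell phenotyping: marker positivity -> major lineage -> subtype.
# Replaces probabilistic assignment pipelines with a deterministic rule table;
# downstream spatial analyses consume labels only.

#' Default antibody panel and phenotyping rule table
#'
#' Marker panel modeled on a pan-immune NSCLC IMC panel (with aSMA added so
#' that fibroblast-dependent analyses run from a single table). Lineages are
#' defined by marker sets; subtypes by required-positive / required-negative
#' marker combinations within parent lineages.
#'
#' Lineage assignment scores each lineage as
#' (number of its markers positive) - (number of positive markers outside it);
#' ties are broken by the fraction of lineage markers matched, then by panel
#' order. Subtype precedence: the rule with the largest required-positive set
#' wins; remaining ties resolve in table order.
#'
#' @return a `panel_definition` list with elements `markers`, `lineages`
#'   (named list of marker sets, in precedence order) and `subtypes`
#'   (data.frame: subtype, parents, pos, neg; list-columns are
#'   comma-separated strings).
#' @export
default_panel <- function() {
  markers <- c("CD31", "panCK", "CD45", "CD3", "CD4", "CD8a", "CD79a", "CD20",
               "CD38", "CD11b", "CD14", "CD68", "CD206", "CD163", "MPO",
               "CLEC9a", "aSMA", "CD45RA", "GZMB", "CD103", "CD57", "CD39",
               "FOXP3", "CD27", "CCR7", "TCRd")
  lineages <- list(
    "endothelial"        = c("CD31"),
    "epithelial"         = c("panCK"),
    "CD4 T cells"        = c("CD45", "CD3", "CD4"),
    "CD8 T cells"        = c("CD45", "CD3", "CD8a"),
    "T cells - other"    = c("CD45", "CD3"),
    "B cells"            = c("CD45", "CD79a", "CD20"),
    "monocytes"          = c("CD45", "CD11b", "CD14"),
    "macrophages"        = c("CD45", "CD11b", "CD14", "CD68", "CD206", "CD163"),
    "myeloid cells - other" = c("CD45", "CD11b"),
    "mDCs"               = c("CD45", "CLEC9a"),
    "leukocytes - other" = c("CD45"),
    "aSMA+ cells"        = c("aSMA")
  )
  t_par <- "CD4 T cells,CD8 T cells,T cells - other"
  subtypes <- data.frame(
    subtype = c("CD163+CD206+ macrophage", "CD163- macrophage",
                "neutrophil",
                "plasma cell", "B cell", "B cell lineage - other",
                "Tgd", "exhausted TDT", "Treg", "cytotoxic T",
                "tissue-resident memory T", "naive T", "Tem", "Tcm", "CD57+ T",
                "aSMA+ fibroblast"),
    parents = c("macrophages", "macrophages",
                "myeloid cells - other",
                "B cells", "B cells", "B cells",
                t_par, t_par, t_par, t_par, t_par, t_par, t_par, t_par, t_par,
                "aSMA+ cells"),
    pos = c("CD68,CD206,CD163", "CD68",
            "CD11b,MPO",
            "CD79a,CD38", "CD79a,CD20", "CD79a",
            "CD3,TCRd", "CD57,CD39", "FOXP3", "GZMB",
            "CD103", "CD45RA", "CD27", "CCR7", "CD57",
            "aSMA"),
    neg = c("", "CD163",
            "CD14,CD68,CD163,CD206",
            "", "", "CD20,CD38",
            "", "", "", "",
            "", "", "CCR7", "", "",
            ""),
    stringsAsFactors = FALSE
  )
  structure(list(markers = markers, lineages = lineages, subtypes = subtypes),
            class = "panel_definition")
}

.split_csv <- function(s) if (identical(s, "")) character(0) else strsplit(s, ",", fixed = TRUE)[[1]]

#' Validate a panel definition
#'
#' Checks that every marker referenced by a lineage or subtype rule exists in
#' the panel and that no rule requires and forbids the same marker.
#'
#' @param panel a `panel_definition`.
#' @return the panel, invisibly; errors on an inconsistent table.
#' @export
validate_panel <- function(panel) {
  refd <- unique(c(unlist(panel$lineages),
                   unlist(lapply(panel$subtypes$pos, .split_csv)),
                   unlist(lapply(panel$subtypes$neg, .split_csv))))
  missing <- setdiff(refd, panel$markers)
  if (length(missing)) {
    stop("rule table references markers absent from panel: ",
         paste(missing, collapse = ", "))
  }
  for (i in seq_len(nrow(panel$subtypes))) {
    both <- intersect(.split_csv(panel$subtypes$pos[i]), .split_csv(panel$subtypes$neg[i]))
    if (length(both)) {
      stop("subtype '", panel$subtypes$subtype[i],
           "' requires and forbids marker(s): ", paste(both, collapse = ", "))
    }
    unk <- setdiff(.split_csv(panel$subtypes$parents[i]), names(panel$lineages))
    if (length(unk)) {
      stop("subtype '", panel$subtypes$subtype[i], "' names unknown parent lineage: ",
           paste(unk, collapse = ", "))
    }
  }
  invisible(panel)
}

# Two-component Gaussian mixture EM on a numeric vector; returns the
# posterior-0.5 crossing between the component means, or NULL when the fit
# is degenerate.
.mix2_threshold <- function(v, max_iter = 200, tol = 1e-8) {
  u <- unique(v)
  if (length(u) < 2L) return(NULL)
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
  mu <- c(q[1], q[2])
  if (mu[1] == mu[2]) mu <- range(v)
  s2 <- rep(max(stats::var(v) / 4, 1e-6), 2)
  pi1 <- 0.5
  for (it in seq_len(max_iter)) {
    d1 <- pi1 * stats::dnorm(v, mu[1], sqrt(s2[1]))
    d2 <- (1 - pi1) * stats::dnorm(v, mu[2], sqrt(s2[2]))
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d2 / tot                      # responsibility of the upper component
    n2 <- sum(g); n1 <- length(v) - n2
    if (n1 < 1e-8 || n2 < 1e-8) return(NULL)
    mu_new <- c(sum((1 - g) * v) / n1, sum(g * v) / n2)
    s2_new <- c(sum((1 - g) * (v - mu_new[1])^2) / n1,
                sum(g * (v - mu_new[2])^2) / n2)
    s2_new <- pmax(s2_new, 1e-8)
    pi1_new <- n1 / length(v)
    done <- max(abs(mu_new - mu)) < tol
    mu <- mu_new; s2 <- s2_new; pi1 <- pi1_new
    if (done) break
  }
  if (mu[2] < mu[1]) {                  # relabel so component 2 is the bright one
    mu <- rev(mu); s2 <- rev(s2); pi1 <- 1 - pi1
  }
  if ((mu[2] - mu[1]) < 1e-6) return(NULL)
  # grid search for the posterior-0.5 crossing between the means: monotone
  # threshold by construction; component sds floored so a collapsed
  # (zero-variance) mode still yields an interior boundary
  sd_t <- pmax(sqrt(s2), (mu[2] - mu[1]) / 8)
  grid <- seq(mu[1], mu[2], length.out = 512)
  post <- (1 - pi1) * stats::dnorm(grid, mu[2], sd_t[2])
  post <- post / (post + pi1 * stats::dnorm(grid, mu[1], sd_t[1]))
  cross <- which(post >= 0.5)
  if (!length(cross) || length(cross) == length(grid)) return(NULL)
  grid[cross[1L]]
}

#' Call per-marker positivity
#'
#' Converts a cells x markers intensity matrix into boolean positivity calls.
#' The default method fits a two-component mixture (negative/positive) on
#' log1p intensities per marker and thresholds at the posterior-0.5 crossing;
#' degenerate fits fall back to an upper-quantile threshold. Positivity is
#' monotone in intensity: each marker reduces to a single threshold.
#'
#' @param intensities nonnegative numeric matrix, columns named by marker.
#' @param method `"two_component"` (default) or `"quantile"`.
#' @param quantile fallback/quantile threshold level (default 0.9).
#' @return object of class `positivity_matrix`: list with `positive` (logical
#'   matrix), `threshold` (per-marker, on the log1p scale) and `method`
#'   (per-marker method actually used).
#' @export
call_positivity <- function(intensities, method = c("two_component", "quantile"),
                            quantile = 0.9) {
  method <- match.arg(method)
  intensities <- as.matrix(intensities)
  if (nrow(intensities) < 1L) stop("need at least one cell")
  if (any(intensities < 0)) stop("intensities must be nonnegative")
  lv <- log1p(intensities)
  m <- ncol(lv)
  thr <- stats::setNames(rep(NA_real_, m), colnames(lv))
  used <- stats::setNames(rep(NA_character_, m), colnames(lv))
  pos <- matrix(FALSE, nrow(lv), m, dimnames = dimnames(lv))
  for (j in seq_len(m)) {
    v <- lv[, j]
    if (length(unique(v)) < 2L) {
      warning("marker '", colnames(lv)[j],
              "' is constant; threshold undefined, all cells called negative")
      used[j] <- "degenerate"
      next
    }
    t <- if (method == "two_component") .mix2_threshold(v) else NULL
    if (is.null(t)) {
      t <- stats::quantile(v, quantile, names = FALSE)
      used[j] <- "quantile"
    } else {
      used[j] <- "two_component"
    }
    thr[j] <- t
    pos[, j] <- v > t
  }
  structure(list(positive = pos, threshold = thr, method = used),
            class = "positivity_matrix")
}

#' @export
print.positivity_matrix <- function(x, ...) {
  cat("positivity calls:", nrow(x$positive), "cells x", ncol(x$positive), "markers\n")
  cat("positive fraction per marker:\n")
  print(round(colMeans(x$positive), 3))
  invisible(x)
}

#' Assign major cell lineage from positivity calls
#'
#' Each cell receives the lineage whose marker set best matches its positive
#' markers; see [default_panel()] for the scoring rule. Cells with no
#' positively scoring lineage are `"unassigned"`.
#'
#' @param positivity a `positivity_matrix` or a logical cells x markers matrix.
#' @param panel a `panel_definition`.
#' @return character vector of lineage labels.
#' @export
assign_major_lineage <- function(positivity, panel = default_panel()) {
  pos <- if (inherits(positivity, "positivity_matrix")) positivity$positive else positivity
  validate_panel(panel)
  if (!length(panel$lineages)) stop("panel lineage map is empty")
  lin_names <- names(panel$lineages)
  n <- nrow(pos)
  score <- matrix(0, n, length(lin_names))
  frac <- matrix(0, n, length(lin_names))
  npos <- rowSums(pos)
  for (l in seq_along(lin_names)) {
    mk <- intersect(panel$lineages[[l]], colnames(pos))
    matched <- if (length(mk) == 1L) as.numeric(pos[, mk]) else rowSums(pos[, mk, drop = FALSE])
    violated <- npos - matched
    score[, l] <- matched - violated
    frac[, l] <- matched / length(panel$lineages[[l]])
  }
  out <- rep("unassigned", n)
  for (i in seq_len(n)) {
    best <- max(score[i, ])
    if (best <= 0) next
    cand <- which(score[i, ] == best)
    cand <- cand[frac[i, cand] == max(frac[i, cand])]
    out[i] <- lin_names[cand[1L]]      # remaining ties: panel order
  }
  out
}

#' Assign cell subtype from the rule table
#'
#' Applies the panel's subtype rules within each cell's lineage. The most
#' specific applicable rule (largest required-positive set) wins; cells
#' failing every rule keep their lineage label.
#'
#' @param lineage character vector of lineage labels.
#' @param positivity a `positivity_matrix` or logical matrix.
#' @param panel a `panel_definition`.
#' @return character vector of final cell-type labels.
#' @export
assign_subtype <- function(lineage, positivity, panel = default_panel()) {
  pos <- if (inherits(positivity, "positivity_matrix")) positivity$positive else positivity
  validate_panel(panel)
  stopifnot(length(lineage) == nrow(pos))
  rules <- panel$subtypes
  sizes <- vapply(rules$pos, function(s) length(.split_csv(s)), integer(1))
  ord <- order(-sizes, seq_len(nrow(rules)))  # most specific first, then table order
  out <- lineage
  assigned <- rep(FALSE, length(lineage))
  for (r in ord) {
    par <- .split_csv(rules$parents[r])
    req <- .split_csv(rules$pos[r])
    if (!all(req %in% colnames(pos))) next  # rule untestable without its markers
    fbd <- intersect(.split_csv(rules$neg[r]), colnames(pos))
    ok <- !assigned & lineage %in% par
    if (length(req)) ok <- ok & rowSums(pos[, req, drop = FALSE]) == length(req)
    if (length(fbd)) ok <- ok & rowSums(pos[, fbd, drop = FALSE]) == 0L
    out[ok] <- rules$subtype[r]
    assigned <- assigned | ok
  }
  out
}

# Sample a label mask at cell centers. Masks are integer/logical matrices in
# pixel space, row = y, col = x, 1 um = 1 px, origin top-left.
.mask_at <- function(mask, x, y) {
  ix <- floor(x) + 1L
  iy <- floor(y) + 1L
  if (any(ix < 1L | iy < 1L | ix > ncol(mask) | iy > nrow(mask))) {
    stop("cell centers fall outside the mask extent; coordinate frames disagree")
  }
  mask[cbind(iy, ix)]
}

#' Relabel cells using pathology annotation masks
#'
#' Applies the pathology-mask rules: aSMA+ cells centered in the large-vessel
#' mask become perivascular (flag set, excluded from barrier scoring);
#' CD163+CD206+ macrophages centered in the alveolar-macrophage mask are
#' relabeled alveolar macrophages; epithelial cells centered in the tumor
#' mask receive `tumor_cell = TRUE`. Point-in-mask tests use the cell center.
#'
#' @param cells a cell table with `x_um`, `y_um` and `cell_type` columns.
#' @param masks named list of matrices (any of `tumor`, `vessels`,
#'   `alveolar`, `airways`, `necrosis`); row = y px, col = x px, nonzero =
#'   inside.
#' @return the cell table with `perivascular`, `tumor_cell` (and relabeled
#'   `cell_type`) columns.
#' @export
apply_pathology_labels <- function(cells, masks) {
  stopifnot(is.list(masks))
  if (!"perivascular" %in% names(cells)) cells$perivascular <- FALSE
  if (!is.null(masks$vessels)) {
    in_vessel <- .mask_at(masks$vessels, cells$x_um, cells$y_um) > 0
    is_asma <- cells$cell_type %in% c("aSMA+ fibroblast", "aSMA+ cells")
    cells$perivascular <- cells$perivascular | (is_asma & in_vessel)
    cells$cell_type[is_asma & in_vessel] <- "perivascular aSMA+"
  }
  if (!is.null(masks$alveolar)) {
    in_alv <- .mask_at(masks$alveolar, cells$x_um, cells$y_um) > 0
    relabel <- in_alv & cells$cell_type == "CD163+CD206+ macrophage"
    cells$cell_type[relabel] <- "alveolar macrophage"
  }
  if (!is.null(masks$tumor)) {
    in_tum <- .mask_at(masks$tumor, cells$x_um, cells$y_um) > 0
    cells$tumor_cell <- cells$cell_type %in% c("epithelial", "tumor") & in_tum
  }
  cells
}
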