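# Synthetic tissue-core generator. Emulates IMC-style single-cell tables from
# 1.5 mm circular tumor-microarray cores at 1 um/px: irregular tumor nests in
# stroma, per-class target densities (cells/mm^2), two-component log-normal
# marker intensities, planted communities, planted aSMA+ fibroblast barriers
# and planted per-core TME classes, with full ground truth for recovery tests.

.SPATIALTME_CLASSES <- c("epithelial", "endothelial", "aSMA+ fibroblast",
                         "CD4 T cells", "CD8 T cells", "B cell",
                         "CD163+CD206+ macrophage", "CD163- macrophage",
                         "neutrophil", "myeloid cells - other")

# Minimal positive-marker set per generator class, consistent with the
# default panel's rule table so phenotyping can recover the classes.
.class_marker_sets <- function() {
  list(
    "epithelial"              = "panCK",
    "endothelial"             = "CD31",
    "aSMA+ fibroblast"        = "aSMA",
    "CD4 T cells"             = c("CD45", "CD3", "CD4"),
    "CD8 T cells"             = c("CD45", "CD3", "CD8a"),
    "B cell"                  = c("CD45", "CD79a", "CD20"),
    "CD163+CD206+ macrophage" = c("CD45", "CD11b", "CD14", "CD68", "CD206", "CD163"),
    "CD163- macrophage"       = c("CD45", "CD11b", "CD14", "CD68"),
    "neutrophil"              = c("CD45", "CD11b", "MPO"),
    "myeloid cells - other"   = c("CD45", "CD11b")
  )
}

.synthetic_markers <- function() {
  unique(unlist(.class_marker_sets(), use.names = FALSE))
}

#' Density archetypes of the four TME classes
#'
#' Per-class target densities (cells/mm^2) in the tumor nest and stroma for
#' the four tumor-microenvironment archetypes: TIL/macrophage-rich in nest and
#' stroma ("TS:TIL+MP high"), TIL/macrophage-rich stroma with an excluded nest
#' ("T:TIL+MP excluded"), immune-cold ("TS:Immune low") and neutrophil-rich
#' TIL-cold ("TS:Neutrophil high"). `effect` in (0, 1] shrinks the log-scale
#' contrast between archetypes toward the cohort mean profile (1 = full
#' contrast).
#'
#' @param class one of the four class names (see [tme_class_names()]).
#' @param effect effect-size multiplier in (0, 1].
#' @return named list: class -> matrix classes x c(tumor_nest, stroma).
#' @export
tme_archetypes <- function(class = NULL, effect = 1) {
  stopifnot(effect > 0, effect <= 1)
  base <- list(
    "TS:TIL+MP high" = c(
      epithelial = 1500, endothelial = 80, `aSMA+ fibroblast` = 0,
      `CD4 T cells` = 60, `CD8 T cells` = 60, `B cell` = 0,
      `CD163+CD206+ macrophage` = 48, `CD163- macrophage` = 30,
      neutrophil = 20, `myeloid cells - other` = 25,
      s.epithelial = 0, s.endothelial = 120, `s.aSMA+ fibroblast` = 150,
      `s.CD4 T cells` = 350, `s.CD8 T cells` = 350, `s.B cell` = 50,
      `s.CD163+CD206+ macrophage` = 250, `s.CD163- macrophage` = 160,
      s.neutrophil = 25, `s.myeloid cells - other` = 40),
    "T:TIL+MP excluded" = c(
      epithelial = 1500, endothelial = 80, `aSMA+ fibroblast` = 0,
      `CD4 T cells` = 25, `CD8 T cells` = 25, `B cell` = 0,
      `CD163+CD206+ macrophage` = 25, `CD163- macrophage` = 15,
      neutrophil = 20, `myeloid cells - other` = 25,
      s.epithelial = 0, s.endothelial = 120, `s.aSMA+ fibroblast` = 150,
      `s.CD4 T cells` = 350, `s.CD8 T cells` = 350, `s.B cell` = 100,
      `s.CD163+CD206+ macrophage` = 250, `s.CD163- macrophage` = 160,
      s.neutrophil = 25, `s.myeloid cells - other` = 90),
    "TS:Immune low" = c(
      epithelial = 1500, endothelial = 80, `aSMA+ fibroblast` = 0,
      `CD4 T cells` = 12, `CD8 T cells` = 12, `B cell` = 0,
      `CD163+CD206+ macrophage` = 12, `CD163- macrophage` = 10,
      neutrophil = 8, `myeloid cells - other` = 10,
      s.epithelial = 0, s.endothelial = 120, `s.aSMA+ fibroblast` = 150,
      `s.CD4 T cells` = 25, `s.CD8 T cells` = 25, `s.B cell` = 25,
      `s.CD163+CD206+ macrophage` = 25, `s.CD163- macrophage` = 20,
      s.neutrophil = 12, `s.myeloid cells - other` = 20),
    "TS:Neutrophil high" = c(
      epithelial = 1500, endothelial = 80, `aSMA+ fibroblast` = 0,
      `CD4 T cells` = 20, `CD8 T cells` = 20, `B cell` = 0,
      `CD163+CD206+ macrophage` = 25, `CD163- macrophage` = 20,
      neutrophil = 160, `myeloid cells - other` = 20,
      s.epithelial = 0, s.endothelial = 120, `s.aSMA+ fibroblast` = 150,
      `s.CD4 T cells` = 30, `s.CD8 T cells` = 30, `s.B cell` = 30,
      `s.CD163+CD206+ macrophage` = 40, `s.CD163- macrophage` = 30,
      s.neutrophil = 240, `s.myeloid cells - other` = 40)
  )
  to_mat <- function(v) {
    cls <- .SPATIALTME_CLASSES
    m <- cbind(tumor_nest = v[cls], stroma = v[paste0("s.", cls)])
    rownames(m) <- cls
    m
  }
  mats <- lapply(base, to_mat)
  if (effect < 1) {
    logm <- lapply(mats, function(m) log1p(m))
    mean_log <- Reduce(`+`, logm) / length(logm)
    mats <- lapply(logm, function(lm) expm1(mean_log + effect * (lm - mean_log)))
    mats <- lapply(mats, function(m) pmax(m, 0))
  }
  if (is.null(class)) mats else {
    stopifnot(class %in% names(mats))
    mats[[class]]
  }
}

#' Names of the four TME classes
#' @return character vector of length 4.
#' @export
tme_class_names <- function() {
  c("TS:TIL+MP high", "T:TIL+MP excluded", "TS:Immune low", "TS:Neutrophil high")
}

#' Configuration for the synthetic tissue generator
#'
#' @param n_patients number of patients (tumors) for [generate_cohort()].
#' @param cores_per_patient integer range `c(min, max)` of cores per tumor
#'   (1-8).
#' @param core_diameter_um core diameter, default 1500 (1.5 mm TMA core).
#' @param nest_geometry list: `n_nests`, `radius_um` (mean nest radius),
#'   `radius_sd_um`, `irregularity` (boundary-jitter amplitude, 0-0.5).
#' @param densities classes x c(tumor_nest, stroma) matrix of target
#'   densities (cells/mm^2); default immune-moderate profile.
#' @param planted_tme `NULL`, or one of [tme_class_names()]: replaces
#'   `densities` with the archetype profile at `tme_effect`.
#' @param tme_effect archetype effect size in (0, 1].
#' @param barrier list `coverage` (fraction of nest perimeter, 0-1) and
#'   `thickness_um` of a planted aSMA+ fibroblast ring.
#' @param community_spec `NULL`, or list of planted communities, each a list
#'   with `id`, `xfrac = c(lo, hi)` (horizontal band of the core, fractions),
#'   and `densities` (named class -> cells/mm^2, placed in both compartments).
#' @param class_proportions cohort proportions of the four planted classes.
#'   The default keeps the two TIL-rich classes just under half the cohort so
#'   that the median/MAD normalization of every stromal feature is anchored
#'   in the immune-cold mode, which keeps all four archetypes recoverable.
#' @param density_jitter_sd per-core log-normal density jitter (sd on log
#'   scale).
#' @param patient_jitter_sd per-patient log-normal density jitter.
#' @param marker_separation fold separation between negative and positive
#'   marker intensity components.
#' @param marker_sdlog log-sd of each intensity component.
#' @param emit_markers emit marker intensity columns (disable for speed when
#'   only cell types are needed).
#' @param min_spacing_um hard minimum inter-cell spacing (nuclear exclusion).
#' @return validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 4,
                             cores_per_patient = c(2, 3),
                             core_diameter_um = 1500,
                             nest_geometry = list(n_nests = 3, radius_um = 220,
                                                  radius_sd_um = 15,
                                                  irregularity = 0.25),
                             densities = NULL,
                             planted_tme = NULL,
                             tme_effect = 1,
                             barrier = list(coverage = 0, thickness_um = 10),
                             community_spec = NULL,
                             class_proportions = c(0.26, 0.23, 0.10, 0.41),
                             density_jitter_sd = 0.08,
                             patient_jitter_sd = 0.06,
                             marker_separation = 10,
                             marker_sdlog = 0.35,
                             emit_markers = TRUE,
                             min_spacing_um = 4) {
  if (is.null(densities)) {
    densities <- if (!is.null(planted_tme)) {
      tme_archetypes(planted_tme, tme_effect)
    } else {
      tme_archetypes("TS:TIL+MP high", tme_effect)
    }
  }
  cfg <- list(n_patients = n_patients, cores_per_patient = cores_per_patient,
              core_diameter_um = core_diameter_um, nest_geometry = nest_geometry,
              densities = densities, planted_tme = planted_tme,
              tme_effect = tme_effect, barrier = barrier,
              community_spec = community_spec,
              class_proportions = class_proportions,
              density_jitter_sd = density_jitter_sd,
              patient_jitter_sd = patient_jitter_sd,
              marker_separation = marker_separation,
              marker_sdlog = marker_sdlog, emit_markers = emit_markers,
              min_spacing_um = min_spacing_um)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

#' Validate a synthetic generator configuration
#' @param cfg a `synthetic_config` (or plain list with the same fields).
#' @return the config, invisibly; errors on invalid values.
#' @export
validate_synthetic_config <- function(cfg) {
  if (cfg$core_diameter_um <= 0) stop("core_diameter_um must be > 0")
  if (any(cfg$densities < 0)) stop("densities must be >= 0")
  if (cfg$barrier$coverage < 0 || cfg$barrier$coverage > 1) {
    stop("barrier coverage must be in [0, 1]")
  }
  if (any(cfg$cores_per_patient < 1) || any(cfg$cores_per_patient > 8)) {
    stop("cores_per_patient must be within 1-8")
  }
  # sequential packing limit at the hard-core spacing
  packing <- 0.5 / (pi * (cfg$min_spacing_um / 2)^2 * 1e-6)
  if (any(cfg$densities > packing)) {
    stop("infeasible density: target exceeds the packing limit (",
         round(packing), " cells/mm^2) at min spacing ", cfg$min_spacing_um, " um")
  }
  invisible(cfg)
}

# --- geometry ---------------------------------------------------------------

.sample_nests <- function(cfg) {
  ng <- cfg$nest_geometry
  R <- cfg$core_diameter_um / 2
  nests <- list()
  if (ng$n_nests < 1) return(nests)
  for (i in seq_len(ng$n_nests)) {
    for (try in 1:200) {
      r_nest <- max(40, stats::rnorm(1, ng$radius_um, ng$radius_sd_um))
      max_off <- R - r_nest * (1 + ng$irregularity) - 20
      if (max_off <= 0) next
      rho <- sqrt(stats::runif(1)) * max_off
      th <- stats::runif(1, 0, 2 * pi)
      cand <- list(cx = R + rho * cos(th), cy = R + rho * sin(th), r = r_nest,
                   amp = stats::runif(2, 0, ng$irregularity / 2),
                   phase = stats::runif(2, 0, 2 * pi))
      sep_ok <- all(vapply(nests, function(n) {
        sqrt((n$cx - cand$cx)^2 + (n$cy - cand$cy)^2) > (n$r + cand$r) * 1.05
      }, logical(1)))
      if (sep_ok || try == 200) { nests[[i]] <- cand; break }
    }
  }
  nests
}

# Angular radius of a nest blob: r(theta) = r (1 + a1 sin(2t+p1) + a2 sin(3t+p2))
.nest_radius <- function(nest, theta) {
  nest$r * (1 + nest$amp[1] * sin(2 * theta + nest$phase[1]) +
              nest$amp[2] * sin(3 * theta + nest$phase[2]))
}

.in_nest <- function(geom, x, y) {
  inside <- rep(FALSE, length(x))
  for (nest in geom$nests) {
    dx <- x - nest$cx; dy <- y - nest$cy
    rho <- sqrt(dx^2 + dy^2)
    theta <- atan2(dy, dx)
    inside <- inside | rho <= .nest_radius(nest, theta)
  }
  inside
}

# Compartment at exact coordinates, snapped to the pixel center so that cell
# labels and the rasterized mask agree exactly.
.compartment_at <- function(geom, x, y) {
  px <- floor(x) + 0.5; py <- floor(y) + 0.5
  R <- geom$radius
  in_disc <- (px - geom$center[1])^2 + (py - geom$center[2])^2 <= R^2
  nest <- .in_nest(geom, px, py)
  out <- ifelse(!in_disc, "background", ifelse(nest, "tumor_nest", "stroma"))
  out
}

#' Rasterize the compartment label mask of a synthetic core
#'
#' @param geom per-core geometry from the generator's ground truth
#'   (`truth$geometry[[image_id]]`).
#' @return integer matrix (row = y px, col = x px, 1 um/px): 0 background,
#'   1 tumor nest, 2 stroma.
#' @export
compartment_mask <- function(geom) {
  side <- ceiling(2 * geom$radius)
  xs <- seq_len(side) - 0.5
  ys <- seq_len(side) - 0.5
  # disc membership row by row (analytic), nests only inside their boxes
  out <- matrix(0L, side, side)
  dy2 <- (ys - geom$center[2])^2
  half <- sqrt(pmax(geom$radius^2 - dy2, 0))
  for (iy in seq_len(side)) {
    if (geom$radius^2 < dy2[iy]) next
    lo <- max(1L, ceiling(geom$center[1] - half[iy] + 0.5))
    hi <- min(side, floor(geom$center[1] + half[iy] + 0.5))
    if (lo <= hi) out[iy, lo:hi] <- 2L
  }
  for (nest in geom$nests) {
    rmax <- nest$r * (1 + sum(nest$amp))
    ix <- which(xs >= nest$cx - rmax & xs <= nest$cx + rmax)
    iy <- which(ys >= nest$cy - rmax & ys <= nest$cy + rmax)
    if (!length(ix) || !length(iy)) next
    xm <- rep(xs[ix], times = length(iy))
    ym <- rep(ys[iy], each = length(ix))
    dx <- xm - nest$cx; dyv <- ym - nest$cy
    rho <- sqrt(dx^2 + dyv^2)
    inside <- rho <= .nest_radius(nest, atan2(dyv, dx))
    sub <- out[iy, ix, drop = FALSE]
    sub_t <- t(sub)
    sub_t[inside & sub_t == 2L] <- 1L
    out[iy, ix] <- t(sub_t)
  }
  out
}

# Compartment areas in mm^2 by pixel counting (consistent with the mask).
.compartment_areas <- function(geom) {
  m <- compartment_mask(geom)
  c(tumor_nest = sum(m == 1L) * 1e-6, stroma = sum(m == 2L) * 1e-6)
}

# --- hard-core point placement ----------------------------------------------

# Occupancy index for min-spacing rejection; bins of side `spacing`.
.new_occupancy <- function(side, spacing, capacity = 4096L) {
  env <- new.env(parent = emptyenv())
  env$bins <- new.env(hash = TRUE, parent = emptyenv())  # key -> point indices
  env$nb <- ceiling(side / spacing) + 2L
  env$spacing <- spacing
  env$x <- numeric(capacity)
  env$y <- numeric(capacity)
  env$n <- 0L
  env
}

.occ_key <- function(occ, x, y) {
  bx <- as.integer(x / occ$spacing)
  by <- as.integer(y / occ$spacing)
  as.character(bx + by * occ$nb)
}

.occ_free <- function(occ, x, y, spacing = occ$spacing) {
  bx <- as.integer(x / occ$spacing)
  by <- as.integer(y / occ$spacing)
  for (dx in -1L:1L) for (dy in -1L:1L) {
    key <- as.character((bx + dx) + (by + dy) * occ$nb)
    idx <- get0(key, envir = occ$bins, inherits = FALSE)
    if (!is.null(idx) &&
        any((occ$x[idx] - x)^2 + (occ$y[idx] - y)^2 < spacing^2)) {
      return(FALSE)
    }
  }
  TRUE
}

.occ_add <- function(occ, x, y) {
  if (occ$n == length(occ$x)) {        # grow capacity geometrically
    occ$x <- c(occ$x, numeric(length(occ$x)))
    occ$y <- c(occ$y, numeric(length(occ$y)))
  }
  i <- occ$n + 1L
  occ$n <- i
  occ$x[i] <- x
  occ$y[i] <- y
  key <- .occ_key(occ, x, y)
  assign(key, c(get0(key, envir = occ$bins, inherits = FALSE), i),
         envir = occ$bins)
  i
}

# Place n points uniformly in {disc} x {compartment} x {optional x-band},
# respecting the hard-core spacing. Returns a 2-column matrix (possibly fewer
# rows if space runs out after max tries; errors only if badly infeasible).
.place_points <- function(n, geom, compartment, occ, xfrac = NULL,
                          max_tries = 400) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  R <- geom$radius
  out <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  while (placed < n && tries < max_tries * n) {
    m <- min(4L * (n - placed) + 16L, 4096L)
    tries <- tries + m
    rho <- sqrt(stats::runif(m)) * R
    th <- stats::runif(m, 0, 2 * pi)
    x <- geom$center[1] + rho * cos(th)
    y <- geom$center[2] + rho * sin(th)
    keep <- .compartment_at(geom, x, y) == compartment
    if (!is.null(xfrac)) {
      keep <- keep & x >= xfrac[1] * 2 * R & x < xfrac[2] * 2 * R
    }
    x <- x[keep]; y <- y[keep]
    for (j in seq_along(x)) {
      if (placed >= n) break
      if (.occ_free(occ, x[j], y[j])) {
        .occ_add(occ, x[j], y[j])
        placed <- placed + 1L
        out[placed, ] <- c(x[j], y[j])
      }
    }
  }
  if (placed < n * 0.98 && placed < n - 5L) {
    stop("infeasible density: could only place ", placed, " of ", n,
         " cells in compartment '", compartment, "'")
  }
  out[seq_len(placed), , drop = FALSE]
}

# --- marker intensities -----------------------------------------------------

.emit_markers <- function(classes, cfg) {
  sets <- .class_marker_sets()
  markers <- .synthetic_markers()
  n <- length(classes)
  neg_meanlog <- log(0.3)
  pos_meanlog <- neg_meanlog + log(cfg$marker_separation)
  flags <- matrix(FALSE, n, length(markers), dimnames = list(NULL, markers))
  for (cl in unique(classes)) {
    idx <- which(classes == cl)
    flags[idx, sets[[cl]]] <- TRUE
  }
  mean_log <- ifelse(flags, pos_meanlog, neg_meanlog)
  intens <- matrix(stats::rlnorm(n * length(markers),
                                 meanlog = as.vector(mean_log),
                                 sdlog = cfg$marker_sdlog),
                   n, length(markers), dimnames = list(NULL, markers))
  list(intensities = intens, flags = flags)
}

# --- core generation --------------------------------------------------------

#' Generate one synthetic tissue core
#'
#' Samples nest geometry, places cells per (class, compartment) with Poisson
#' counts around area x target density under a hard minimum spacing, draws
#' two-component log-normal marker intensities consistent with each cell's
#' generating class, and plants communities and an aSMA+ fibroblast barrier
#' if configured.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed; identical seed and config give identical output.
#' @param image_id,patient_id identifiers stamped on the cells.
#' @return list with `cells` (the cell table) and `truth` (ground truth:
#'   `cells` per-cell truth, `flags` marker ground truth, `cores` per-core
#'   record, `geometry`).
#' @export
generate_core <- function(config, seed = 1L, image_id = "C1", patient_id = "P1") {
  validate_synthetic_config(config)
  set.seed(seed)
  R <- config$core_diameter_um / 2
  geom <- list(center = c(R, R), radius = R, nests = .sample_nests(config))
  areas <- .compartment_areas(geom)
  occ <- .new_occupancy(2 * R, config$min_spacing_um)

  dens <- config$densities
  jit <- matrix(exp(stats::rnorm(length(dens), 0, config$density_jitter_sd)),
                nrow(dens), ncol(dens))
  dens <- dens * jit

  xs <- numeric(0); ys <- numeric(0); cls <- character(0); comp <- character(0)
  comm <- integer(0)
  for (compartment in c("tumor_nest", "stroma")) {
    a <- areas[[compartment]]
    if (a <= 0) next
    for (k in rownames(dens)) {
      lambda <- a * dens[k, compartment]
      n <- stats::rpois(1, lambda)
      if (n == 0L) next
      pts <- .place_points(n, geom, compartment, occ)
      xs <- c(xs, pts[, 1]); ys <- c(ys, pts[, 2])
      cls <- c(cls, rep(k, nrow(pts)))
      comp <- c(comp, rep(compartment, nrow(pts)))
      comm <- c(comm, rep(0L, nrow(pts)))
    }
  }
  # planted communities: extra cells in horizontal bands with set compositions
  if (!is.null(config$community_spec)) {
    core_area <- areas[["tumor_nest"]] + areas[["stroma"]]
    for (spec in config$community_spec) {
      band_frac <- spec$xfrac[2] - spec$xfrac[1]
      for (k in names(spec$densities)) {
        for (compartment in c("tumor_nest", "stroma")) {
          a_comp <- areas[[compartment]] * band_frac  # approximate band area
          n <- stats::rpois(1, a_comp * spec$densities[[k]])
          if (n == 0L) next
          pts <- .place_points(n, geom, compartment, occ, xfrac = spec$xfrac)
          xs <- c(xs, pts[, 1]); ys <- c(ys, pts[, 2])
          cls <- c(cls, rep(k, nrow(pts)))
          comp <- c(comp, rep(compartment, nrow(pts)))
          comm <- c(comm, rep(as.integer(spec$id), nrow(pts)))
        }
      }
    }
  }

  n <- length(xs)
  cell_id <- if (n) sprintf("%s_%05d", image_id, seq_len(n)) else character(0)
  cells <- data.frame(
    cell_id = cell_id, image_id = rep(image_id, n), patient_id = rep(patient_id, n),
    x_um = xs, y_um = ys,
    compartment = comp, cell_type = cls,
    tumor_cell = cls == "epithelial" & comp == "tumor_nest",
    perivascular = rep(FALSE, n),
    stringsAsFactors = FALSE
  )
  truth_cells <- data.frame(
    cell_id = cell_id, image_id = rep(image_id, n),
    true_class = cls, community_id = comm,
    barrier_member = rep(FALSE, n), stringsAsFactors = FALSE
  )
  flags <- NULL
  if (config$emit_markers && n > 0) {
    mk <- .emit_markers(cls, config)
    cells <- cbind(cells, as.data.frame(mk$intensities))
    flags <- mk$flags
    rownames(flags) <- cell_id
  }
  truth <- list(
    cells = truth_cells,
    flags = flags,
    cores = data.frame(image_id = image_id, patient_id = patient_id,
                       planted_tme = config$planted_tme %||% NA_character_,
                       area_tumor_nest_mm2 = unname(areas[["tumor_nest"]]),
                       area_stroma_mm2 = unname(areas[["stroma"]]),
                       stringsAsFactors = FALSE),
    geometry = stats::setNames(list(geom), image_id)
  )
  out <- list(cells = cells, truth = truth)
  if (config$barrier$coverage > 0 && length(geom$nests)) {
    out <- plant_barrier(out$cells, out$truth, config$barrier$coverage,
                         config$barrier$thickness_um, config = config)
  }
  out
}

#' Plant an aSMA+ fibroblast barrier along tumor-nest boundaries
#'
#' Adds aSMA+ fibroblasts in a band of the given thickness immediately
#' outside each nest boundary, over a contiguous random arc covering the
#' requested fraction of the perimeter. Planted cells carry
#' `barrier_member = TRUE` in the ground truth. Uses the RNG stream of the
#' caller (seed it upstream for reproducibility).
#'
#' @param cells cell table of one core (from [generate_core()]).
#' @param truth matching ground-truth object (needs `geometry`).
#' @param coverage fraction of each nest perimeter covered, in `[0, 1]`.
#' @param thickness_um radial thickness of the fibroblast band (um).
#' @param config the generator config (marker emission settings).
#' @return list `cells`, `truth` with barrier fibroblasts appended.
#' @export
plant_barrier <- function(cells, truth, coverage, thickness_um = 10,
                          config = synthetic_config()) {
  if (coverage < 0 || coverage > 1) stop("coverage must be in [0, 1]")
  image_id <- truth$cores$image_id[1]
  geom <- truth$geometry[[image_id]]
  if (!length(geom$nests)) stop("core has no tumor nest")
  if (coverage == 0) {
    attr(truth, "barrier_coverage") <- 0
    return(list(cells = cells, truth = truth))
  }
  # rebuild occupancy from existing cells (relaxed spacing for the ring)
  spacing <- max(2, config$min_spacing_um / 2)
  occ <- .new_occupancy(2 * geom$radius, spacing)
  for (i in seq_len(nrow(cells))) .occ_add(occ, cells$x_um[i], cells$y_um[i])

  bx <- numeric(0); by <- numeric(0)
  arc_step <- 4 / mean(vapply(geom$nests, function(n) n$r, numeric(1)))
  for (nest in geom$nests) {
    phi0 <- stats::runif(1, 0, 2 * pi)
    arc <- coverage * 2 * pi
    thetas <- seq(phi0, phi0 + arc, by = 4 / nest$r)
    offsets <- seq(2, max(thickness_um - 2, 2), by = 4)
    for (th in thetas) {
      rb <- .nest_radius(nest, th)
      for (off in offsets) {
        x <- nest$cx + (rb + off) * cos(th) + stats::rnorm(1, 0, 0.5)
        y <- nest$cy + (rb + off) * sin(th) + stats::rnorm(1, 0, 0.5)
        d2c <- sqrt((x - geom$center[1])^2 + (y - geom$center[2])^2)
        if (d2c > geom$radius - 1) next
        if (.occ_free(occ, x, y, spacing)) {
          .occ_add(occ, x, y)
          bx <- c(bx, x); by <- c(by, y)
        }
      }
    }
  }
  n_new <- length(bx)
  if (n_new == 0L) {
    attr(truth, "barrier_coverage") <- coverage
    return(list(cells = cells, truth = truth))
  }
  new_ids <- sprintf("%s_B%05d", image_id, seq_len(n_new))
  comp <- .compartment_at(geom, bx, by)
  new_cells <- data.frame(
    cell_id = new_ids, image_id = image_id, patient_id = cells$patient_id[1],
    x_um = bx, y_um = by, compartment = comp,
    cell_type = "aSMA+ fibroblast", tumor_cell = FALSE, perivascular = FALSE,
    stringsAsFactors = FALSE
  )
  if (!is.null(truth$flags)) {
    mk <- .emit_markers(rep("aSMA+ fibroblast", n_new), config)
    new_cells <- cbind(new_cells, as.data.frame(mk$intensities))
    rownames(mk$flags) <- new_ids
    truth$flags <- rbind(truth$flags, mk$flags)
  }
  cells <- rbind(cells, new_cells[, names(cells)])
  truth$cells <- rbind(truth$cells, data.frame(
    cell_id = new_ids, image_id = image_id,
    true_class = "aSMA+ fibroblast", community_id = 0L,
    barrier_member = TRUE, stringsAsFactors = FALSE
  ))
  attr(truth, "barrier_coverage") <- coverage
  list(cells = cells, truth = truth)
}

#' Generate a synthetic multi-patient cohort
#'
#' Concatenates cores across patients with unique ids. Each patient receives
#' a planted TME class (sampled by `class_proportions`, or given explicitly)
#' applied to all of that patient's cores, plus per-patient and per-core
#' density jitter.
#'
#' @param config a [synthetic_config()].
#' @param seed integer master seed; all per-core seeds derive from it.
#' @param planted_classes optional list: one character vector of per-core
#'   classes per patient (recycled across that patient's cores).
#' @return list `cells` (row-bound cell table) and `truth` (merged ground
#'   truth; `truth$cores$planted_tme` holds per-core classes).
#' @export
generate_cohort <- function(config, seed = 1L, planted_classes = NULL) {
  validate_synthetic_config(config)
  set.seed(seed)
  n_pat <- config$n_patients
  rng <- config$cores_per_patient
  n_cores <- if (rng[1] == rng[2]) rep(rng[1], n_pat)
             else sample(rng[1]:rng[2], n_pat, replace = TRUE)
  if (is.null(planted_classes)) {
    cls <- sample(tme_class_names(), n_pat, replace = TRUE,
                  prob = config$class_proportions)
    planted_classes <- as.list(cls)
  }
  stopifnot(length(planted_classes) == n_pat)
  core_seeds <- sample.int(.Machine$integer.max - 1L, sum(n_cores))
  pat_jit <- replicate(n_pat, exp(stats::rnorm(length(config$densities), 0,
                                               config$patient_jitter_sd)),
                       simplify = FALSE)
  all_cells <- list(); all_truth_cells <- list(); all_cores <- list()
  all_flags <- list(); geoms <- list()
  idx <- 0L
  for (p in seq_len(n_pat)) {
    pid <- sprintf("P%02d", p)
    classes_p <- rep(planted_classes[[p]], length.out = n_cores[p])
    for (cc in seq_len(n_cores[p])) {
      idx <- idx + 1L
      iid <- sprintf("%s_C%d", pid, cc)
      cfg_i <- config
      cfg_i$planted_tme <- classes_p[cc]
      dens <- tme_archetypes(classes_p[cc], config$tme_effect)
      cfg_i$densities <- dens * matrix(pat_jit[[p]], nrow(dens), ncol(dens))
      res <- generate_core(cfg_i, seed = core_seeds[idx],
                           image_id = iid, patient_id = pid)
      all_cells[[idx]] <- res$cells
      all_truth_cells[[idx]] <- res$truth$cells
      all_cores[[idx]] <- res$truth$cores
      if (!is.null(res$truth$flags)) all_flags[[idx]] <- res$truth$flags
      geoms[[iid]] <- res$truth$geometry[[iid]]
    }
  }
  cells <- do.call(rbind, all_cells)
  if (anyDuplicated(cells$cell_id)) stop("duplicate cell ids in cohort")
  truth <- list(
    cells = do.call(rbind, all_truth_cells),
    flags = if (length(all_flags)) do.call(rbind, all_flags) else NULL,
    cores = do.call(rbind, all_cores),
    geometry = geoms
  )
  rownames(cells) <- NULL
  rownames(truth$cells) <- NULL
  list(cells = cells, truth = truth)
}
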