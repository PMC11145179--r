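# Readers/writers and the pipeline driver. CSV is the interchange format for
# cell tables, JSON for models and ground truth, TIFF for label masks.

#' Read and validate a cell table CSV
#'
#' Required columns: `cell_id`, `image_id`, `patient_id`, `x_um`, `y_um`,
#' plus either marker intensity columns or a `cell_type` column. Errors are
#' descriptive (missing columns, non-numeric coordinates, duplicate ids).
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_cell_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("cell_id", "image_id", "patient_id", "x_um", "y_um")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("cell table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!is.numeric(x$x_um) || !is.numeric(x$y_um)) {
    stop("coordinates x_um/y_um must be numeric")
  }
  if (anyNA(x$x_um) || anyNA(x$y_um)) stop("coordinates contain missing values")
  dup <- x$cell_id[duplicated(x$cell_id)]
  if (length(dup)) {
    stop("duplicate cell_id(s): ", paste(utils::head(unique(dup), 5), collapse = ", "))
  }
  extra <- setdiff(names(x), required)
  if (!("cell_type" %in% names(x)) && !length(extra)) {
    stop("cell table needs marker columns or a cell_type column")
  }
  x
}

#' Write a cell table CSV
#' @param cells data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' Write/read generator ground truth as JSON
#' @param truth ground-truth object from the generator.
#' @param path file path.
#' @return for reading, the ground-truth list (without geometry closures).
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(cells = truth$cells, cores = truth$cores,
              flags = if (!is.null(truth$flags)) {
                list(cell_id = rownames(truth$flags),
                     markers = colnames(truth$flags),
                     values = unname(as.data.frame(truth$flags)))
              })
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::fromJSON(path)
  if (!is.null(x$cores$planted_tme)) {
    x$cores$planted_tme <- as.character(x$cores$planted_tme)
  }
  if (!is.null(x$flags)) {
    flags <- as.matrix(x$flags$values)
    dimnames(flags) <- list(x$flags$cell_id, x$flags$markers)
    x$flags <- flags
  }
  x
}

#' Write a label mask as TIFF
#'
#' @param mask integer matrix (0 background, 1 tumor nest, 2 stroma).
#' @param path output path.
#' @return the path, invisibly; requires the `tiff` package.
#' @export
write_mask_tiff <- function(mask, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to write TIFF masks")
  }
  tiff::writeTIFF(mask / 255, path)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to read TIFF masks")
  }
  m <- tiff::readTIFF(path)
  round(m * 255)
}

#' Phenotype a cell table end to end
#'
#' Positivity calling on the panel's marker columns, lineage assignment and
#' subtype rules; returns the table with `cell_type` (final label),
#' `lineage` and positivity columns attached.
#'
#' @param cells cell table with marker intensity columns.
#' @param panel a `panel_definition`.
#' @param method positivity method, see [call_positivity()].
#' @return the annotated cell table.
#' @export
phenotype_cells <- function(cells, panel = default_panel(),
                            method = "two_component") {
  markers <- intersect(panel$markers, names(cells))
  if (!length(markers)) stop("no panel marker columns found in the cell table")
  pos <- call_positivity(as.matrix(cells[, markers, drop = FALSE]), method = method)
  lineage <- assign_major_lineage(pos, panel)
  subtype <- assign_subtype(lineage, pos, panel)
  cells$lineage <- lineage
  cells$cell_type <- subtype
  attr(cells, "positivity") <- pos
  cells
}

#' Pipeline configuration
#'
#' @param out_dir artifact directory.
#' @param seed master seed; all stage seeds derive from it.
#' @param synthetic a [synthetic_config()] (the pipeline runs on synthetic
#'   data unless `cells_csv` is given).
#' @param cells_csv optional path to an existing cell table.
#' @param window_w,community_k community-stage parameters.
#' @param knn_k,dbscan_eps,min_cluster_area_um2,barrier_mode barrier-stage
#'   parameters.
#' @param interaction_radius_um,n_perm,alpha interaction-stage parameters.
#' @param tme_k,tme_reps,tme_subsample TME-stage parameters.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = "spatialtme_out", seed = 1L,
                            synthetic = synthetic_config(),
                            cells_csv = NULL,
                            window_w = 10, community_k = 10,
                            knn_k = 5, dbscan_eps = 25,
                            min_cluster_area_um2 = 2000,
                            barrier_mode = "indicator",
                            interaction_radius_um = 5, n_perm = 1000,
                            alpha = 0.05,
                            tme_k = 4, tme_reps = 1000, tme_subsample = 0.75) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

# Stable hash of a configuration (content-addressed output stamping).
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(config, digits.d = 12)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Generates (or loads) a cohort, then runs phenotyping, compartment
#' densities, TME classification, community detection, barrier scoring and
#' heterogeneity statistics in order, writing every artifact (CSV/JSON) to
#' the output directory stamped with the config hash and seed. Any stage
#' failure aborts with the stage name and cause.
#'
#' @param config a [pipeline_config()].
#' @return the artifact directory path, invisibly; the `manifest.json` file
#'   lists the outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 8)
  artifacts <- character(0)
  emit_csv <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    artifacts <<- c(artifacts, name)
    p
  }
  emit_json <- function(x, name) {
    p <- file.path(config$out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, na = "null",
                         force = TRUE)
    artifacts <<- c(artifacts, name)
    p
  }

  # data
  if (!is.null(config$cells_csv)) {
    cells <- stage("load", read_cell_table(config$cells_csv))
    truth <- NULL
  } else {
    sim <- stage("simulate", generate_cohort(config$synthetic, seed = seeds[1]))
    cells <- sim$cells
    truth <- sim$truth
    emit_csv(cells, "cells.csv")
    stage("simulate", write_ground_truth(truth, file.path(config$out_dir, "ground_truth.json")))
    artifacts <- c(artifacts, "ground_truth.json")
  }

  # phenotyping (only when marker columns are present)
  panel <- default_panel()
  if (any(panel$markers %in% names(cells))) {
    cells <- stage("phenotype", phenotype_cells(cells, panel))
    emit_csv(cells[, c("cell_id", "lineage", "cell_type")], "phenotypes.csv")
  }

  # densities
  areas <- if (!is.null(truth)) truth$cores else
    stop("pipeline stage 'densities' failed: no compartment areas available")
  rd <- stage("densities", compute_densities(cells, areas))
  emit_csv(data.frame(image_id = rownames(rd$density), rd$density,
                      check.names = FALSE), "densities.csv")

  # TME classification
  tme <- stage("tme", {
    k_max <- max(config$tme_k, min(6, floor(nrow(rd$density) / 2)))
    tme_model(rd, k = config$tme_k, k_range = seq(2, k_max),
              reps = config$tme_reps, subsample = config$tme_subsample,
              seed = seeds[2])
  })
  emit_csv(data.frame(image_id = names(tme$labels), tme_class = tme$labels),
           "tme_labels.csv")
  emit_json(list(class_of_cluster = as.list(tme$class_of_cluster),
                 criteria = lapply(tme$criteria, function(cl) {
                   lapply(cl, function(cr) list(score = cr$score,
                                                cutoff = cr$cut$cutoff,
                                                direction = cr$cut$direction))
                 }),
                 delta_auc = as.list(tme$consensus$delta_auc)),
            "tme_model.json")

  # communities
  win <- stage("communities", build_windows(cells, W = config$window_w))
  cm <- stage("communities", fit_communities(win, k = config$community_k,
                                             seed = seeds[3]))
  comm_df <- data.frame(cell_id = cm$cell_id, community = cm$assignment)
  cells$community <- comm_df$community[match(cells$cell_id, comm_df$cell_id)]
  emit_csv(comm_df, "communities.csv")
  emit_json(list(k = cm$k, W = cm$W, seed = cm$seed,
                 centroids = as.data.frame(cm$centroids)), "community_model.json")

  # barrier
  bar <- stage("barrier", barrier_score_by_core(
    cells, mode = config$barrier_mode,
    min_cluster_area_um2 = config$min_cluster_area_um2))
  emit_csv(bar, "barrier_scores.csv")

  # interactions (per core)
  inter <- stage("interactions", {
    do.call(rbind, lapply(unique(cells$image_id), function(img) {
      sub <- cells[cells$image_id == img, ]
      permutation_relations(sub, n_perm = config$n_perm, alpha = config$alpha,
                            seed = seeds[4], radius_um = config$interaction_radius_um)
    }))
  })
  emit_csv(inter, "interactions.csv")

  # heterogeneity
  het <- stage("heterogeneity", {
    pat <- rd$meta$patient_id[match(rownames(rd$density), rd$meta$image_id)]
    feats <- tme_features(rd)
    ith <- ith_score(feats$density, pat)
    hom <- class_homogeneity_probability(tme$labels, pat, seed = seeds[5])
    list(ith = ith, homogeneity = hom)
  })
  emit_csv(data.frame(feature = names(het$ith), ith_score = het$ith),
           "ith_scores.csv")
  emit_csv(het$homogeneity, "tme_homogeneity.csv")

  emit_json(list(config_hash = hash, seed = config$seed,
                 artifacts = artifacts), "manifest.json")
  invisible(config$out_dir)
}
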