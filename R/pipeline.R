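#' Pipeline configuration
#'
#' Collects every tunable of the per-brain workflow. `brains` is a named
#' list; each brain has `channels`, itself a named list with entries
#' `vessel`, `extravasation`, `hypoxia` that are either file paths or
#' in-memory [voxel_grid()]s, and optionally `spacing_um` used when loading
#' files without spacing metadata.
#'
#' The per-analysis downsampling factors default to the resolution policy of
#' the source workflow (coarse for lesion masking, medium for the diffuse
#' signal channels, fine for vessels); desk-scale phantoms run with all
#' factors at 1.
#'
#' @param brains Named list as described above.
#' @param factors Named list of integer downsampling factors: `lesion`,
#'   `signals`, `vessels`.
#' @param tissue_threshold Intensity or `"auto"` (Otsu) for tissue
#'   segmentation.
#' @param closing_radius_um Surface solidification radius.
#' @param lr_axis Left-right grid axis (1-3).
#' @param ipsilateral_side `+1` or `-1`.
#' @param registration_search_voxels Mirror-registration translation search
#'   radius.
#' @param lesion_min_component_mm3 Minimum lesion component volume.
#' @param layers A [layer_spec()].
#' @param vesselness A [vesselness_params()].
#' @param vessel_threshold Vesselness cut in (0, 1).
#' @param vessel_min_component_mm3 Minimum vessel component volume.
#' @param signal_percentile Contralateral background percentile.
#' @param contralateral_distal_fraction Fraction of the contralateral tissue
#'   (far side first) used as background reference; see
#'   [contralateral_mask()].
#' @param signal_min_component_mm3 Minimum signal component volume.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @param seed Integer recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(brains,
                            factors = list(lesion = 32L, signals = 4L,
                                           vessels = 2L),
                            tissue_threshold = "auto",
                            closing_radius_um = 300,
                            lr_axis = 3L,
                            ipsilateral_side = 1L,
                            registration_search_voxels = 10L,
                            lesion_min_component_mm3 = 1e-3,
                            layers = layer_spec(),
                            vesselness = vesselness_params(),
                            vessel_threshold = 0.2,
                            vessel_min_component_mm3 = 1e-5,
                            signal_percentile = 99.9,
                            contralateral_distal_fraction = 0.5,
                            signal_min_component_mm3 = 1e-4,
                            out_dir = NULL,
                            seed = 1L) {
  stopifnot(is.list(brains), length(brains) >= 1, !is.null(names(brains)))
  stopifnot(all(vapply(factors, function(f) f >= 1, logical(1))))
  cfg <- structure(list(
    brains = brains, factors = factors,
    tissue_threshold = tissue_threshold,
    closing_radius_um = closing_radius_um, lr_axis = as.integer(lr_axis),
    ipsilateral_side = as.integer(ipsilateral_side),
    registration_search_voxels = as.integer(registration_search_voxels),
    lesion_min_component_mm3 = lesion_min_component_mm3,
    layers = layers, vesselness = vesselness,
    vessel_threshold = vessel_threshold,
    vessel_min_component_mm3 = vessel_min_component_mm3,
    signal_percentile = signal_percentile,
    contralateral_distal_fraction = contralateral_distal_fraction,
    signal_min_component_mm3 = signal_min_component_mm3,
    out_dir = out_dir, seed = as.integer(seed)
  ), class = "pipeline_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(config) {
  for (id in names(config$brains)) {
    ch <- config$brains[[id]]$channels
    if (is.null(ch)) stop("brain '", id, "' has no channels")
    for (nm in names(ch)) {
      x <- ch[[nm]]
      if (is.character(x) && !file.exists(x))
        stop("brain '", id, "' channel '", nm, "': file not found: ", x)
    }
  }
  invisible(config)
}

get_channel <- function(config, brain_id, channel) {
  x <- config$brains[[brain_id]]$channels[[channel]]
  if (is.null(x)) stop("brain '", brain_id, "' lacks channel '", channel, "'")
  if (inherits(x, "voxel_grid")) return(x)
  load_grid(x, config$brains[[brain_id]]$spacing_um, channel)
}

# nearest-neighbor resampling of a mask onto a target frame (same physical
# extent, different spacing), used to carry lesion-scale masks to the signal
# and vessel analysis resolutions
resample_mask_nn <- function(mask, target_dim, target_spacing) {
  src_idx <- lapply(1:3, function(a) {
    i <- round(((seq_len(target_dim[a]) - 0.5) * target_spacing[a]) /
                 mask$spacing[a] + 0.5)
    pmin(pmax(i, 1L), dim(mask$values)[a])
  })
  out <- mask$values[src_idx[[1]], src_idx[[2]], src_idx[[3]]]
  binary_mask(out, target_spacing, mask$channel)
}

#' Run the full per-brain quantification workflow
#'
#' Executes tissue segmentation, surface solidification, midsagittal
#' splitting, mirror-subtraction lesion masking, boundary extraction, depth
#' layering, vessel quantification (Frangi segmentation, skeleton metrics),
#' and contralateral-thresholded hypoxia/extravasation fractions, each at its
#' configured analysis resolution.
#'
#' @param config A [pipeline_config()].
#' @param brain_id Name of the brain in `config$brains`.
#' @return A list: `metrics` (tidy per-layer data.frame with columns
#'   `brain_id`, `metric`, `d_min_um`, `d_max_um`, `value`,
#'   `tissue_volume_mm3`), `lesion_report` (lesion volume, plane, threshold),
#'   `layers`, and `manifest`. With `config$out_dir` set, writes
#'   `<brain_id>_metrics.csv`, `<brain_id>_lesion.json`, and
#'   `<brain_id>_manifest.json`.
#' @export
run_brain <- function(config, brain_id) {
  stopifnot(inherits(config, "pipeline_config"),
            brain_id %in% names(config$brains))
  validate_config(config)
  f <- config$factors

  extrav_full <- get_channel(config, brain_id, "extravasation")
  ext_lesion <- downsample_grid(extrav_full, f$lesion)
  ext_sig <- downsample_grid(extrav_full, f$signals)
  hyp_sig <- downsample_grid(get_channel(config, brain_id, "hypoxia"),
                             f$signals)
  ves_fine <- downsample_grid(get_channel(config, brain_id, "vessel"),
                              f$vessels)

  # lesion geometry at coarse resolution
  tissue_l <- segment_tissue(ext_lesion, config$tissue_threshold)
  solid <- solidify_surface(tissue_l, config$closing_radius_um)
  plane <- find_midsagittal(solid, config$lr_axis)
  lesion <- mirror_subtract_lesion(
    solid, plane, config$ipsilateral_side,
    config$registration_search_voxels, config$lesion_min_component_mm3,
    tissue = tissue_l)
  lesion_volume <- mask_volume_mm3(lesion)

  # tissue always comes from the autofluorescence (extravasation) channel,
  # regridded to the analysis resolution
  run_resolution <- function(tissue_grid) {
    d <- dim(tissue_grid$values)
    tis <- segment_tissue(tissue_grid, config$tissue_threshold)
    les <- resample_mask_nn(lesion, d, tissue_grid$spacing)
    sol <- resample_mask_nn(solid, d, tissue_grid$spacing)
    bnd <- lesion_boundary(les, sol)
    lay <- if (any(bnd$values | les$values))
      build_layers(bnd, tis, les, config$layers) else NULL
    pln <- structure(list(axis = plane$axis,
                          plane_position = plane$plane_position /
                            dim(lesion$values)[plane$axis] * d[plane$axis]),
                     class = "midsagittal_plane")
    list(tissue = tis, lesion = les, boundary = bnd, layers = lay,
         plane = pln)
  }

  sig <- run_resolution(ext_sig)
  rows <- list()
  add_rows <- function(metric, d_min, d_max, value, tvol) {
    rows[[length(rows) + 1L]] <<- data.frame(
      brain_id = brain_id, metric = metric, d_min_um = d_min,
      d_max_um = d_max, value = value, tissue_volume_mm3 = tvol,
      stringsAsFactors = FALSE)
  }

  thresholds <- list()
  if (!is.null(sig$layers)) {
    contra <- contralateral_mask(sig$tissue, sig$plane,
                                 config$ipsilateral_side,
                                 config$contralateral_distal_fraction)
    for (ch in c("extravasation", "hypoxia")) {
      g <- if (ch == "extravasation") ext_sig else hyp_sig
      thr <- background_threshold(g, contra, config$signal_percentile)
      thresholds[[ch]] <- thr
      sm <- segment_signal(g, thr, sig$tissue,
                           config$signal_min_component_mm3)
      tab <- signal_fraction_per_layer(sm, sig$layers)
      add_rows(paste0(ch, "_fraction"), tab$d_min_um, tab$d_max_um,
               tab$signal_fraction, tab$tissue_volume_mm3)
    }
  }

  ves <- run_resolution(downsample_grid(extrav_full, f$vessels))
  if (!is.null(ves$layers)) {
    vness <- frangi_vesselness(ves_fine, config$vesselness)
    vmask <- segment_vessels(vness, config$vessel_threshold,
                             config$vessel_min_component_mm3)
    # restrict vessel analysis to the layered perilesional region
    region <- Reduce(`|`, lapply(ves$layers$layers, `[[`, "values"))
    vmask$values <- vmask$values & region
    skel <- skeletonize_vessels(vmask)
    vtab <- vessel_metrics_per_layer(skel, ves$layers)
    add_rows("vessel_length_density", vtab$d_min_um, vtab$d_max_um,
             vtab$length_density_mm_per_mm3, vtab$tissue_volume_mm3)
    add_rows("vessel_volume_fraction", vtab$d_min_um, vtab$d_max_um,
             vtab$volume_fraction, vtab$tissue_volume_mm3)
  } else {
    skel <- NULL
  }

  metrics <- if (length(rows)) do.call(rbind, rows) else
    data.frame(brain_id = character(), metric = character(),
               d_min_um = numeric(), d_max_um = numeric(), value = numeric(),
               tissue_volume_mm3 = numeric())

  lesion_report <- list(
    brain_id = brain_id,
    lesion_volume_mm3 = lesion_volume,
    plane_axis = plane$axis,
    plane_position = plane$plane_position,
    tissue_threshold = config$tissue_threshold,
    signal_thresholds = thresholds
  )
  manifest <- list(
    brain_id = brain_id,
    package_version = as.character(utils::packageVersion("tbi3d")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("brains", "out_dir"))]
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(metrics,
                     file.path(config$out_dir,
                               paste0(brain_id, "_metrics.csv")),
                     row.names = FALSE)
    jsonlite::write_json(lesion_report,
                         file.path(config$out_dir,
                                   paste0(brain_id, "_lesion.json")),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir,
                                   paste0(brain_id, "_manifest.json")),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }

  list(metrics = metrics, lesion_report = lesion_report,
       layers = sig$layers, skeleton = skel, manifest = manifest)
}

#' Run a cohort and compare treatment groups
#'
#' Runs every brain, then for each metric and depth layer removes per-group
#' 1.5 x IQR outliers and applies one-way ANOVA with Fisher's LSD post hoc
#' comparisons across groups.
#'
#' @param config A [pipeline_config()] containing all brains.
#' @param groups Named character vector mapping brain id to group label; at
#'   least two groups with at least two brains each.
#' @return A list: `metrics` (all per-brain rows), `anova` (tidy data.frame
#'   with `metric`, `d_min_um`, `d_max_um`, `F`, `df_between`, `df_within`,
#'   `p`), `lsd` (pairwise rows with the same keys plus `group1`, `group2`,
#'   `mean_diff`, `p`), `lesions` (per-brain lesion volumes).
#' @export
run_cohort <- function(config, groups) {
  stopifnot(inherits(config, "pipeline_config"))
  ids <- names(config$brains)
  stopifnot(all(ids %in% names(groups)))
  tab <- table(groups[ids])
  keep_groups <- names(tab)[tab >= 2]
  if (any(tab < 2))
    warning("excluding group(s) with < 2 brains: ",
            paste(names(tab)[tab < 2], collapse = ", "))
  if (length(keep_groups) < 2)
    stop("need at least 2 groups with >= 2 brains each")
  ids <- ids[groups[ids] %in% keep_groups]

  res <- list()
  lesions <- list()
  for (id in ids) {
    out <- tryCatch(run_brain(config, id), error = function(e) e)
    if (inherits(out, "error")) {
      warning("brain '", id, "' failed: ", conditionMessage(out))
      next
    }
    res[[id]] <- out$metrics
    lesions[[id]] <- data.frame(brain_id = id, group = unname(groups[id]),
                                lesion_volume_mm3 =
                                  out$lesion_report$lesion_volume_mm3,
                                stringsAsFactors = FALSE)
  }
  metrics <- do.call(rbind, res)
  metrics$group <- unname(groups[metrics$brain_id])
  lesions <- do.call(rbind, lesions)
  rownames(metrics) <- rownames(lesions) <- NULL

  anova_rows <- list()
  lsd_rows <- list()
  for (m in unique(metrics$metric)) {
    sub_m <- metrics[metrics$metric == m, ]
    for (dmin in unique(sub_m$d_min_um)) {
      sub <- sub_m[sub_m$d_min_um == dmin & !is.na(sub_m$value), ]
      gl <- split(sub$value, sub$group)
      gl <- lapply(gl, remove_outliers_iqr)
      gl <- gl[vapply(gl, length, integer(1)) >= 2]
      if (length(gl) < 2) next
      an <- tryCatch(oneway_anova(gl), error = function(e) NULL)
      if (is.null(an)) next
      anova_rows[[length(anova_rows) + 1L]] <- data.frame(
        metric = m, d_min_um = dmin, d_max_um = sub$d_max_um[1],
        F = an$F, df_between = an$df_between, df_within = an$df_within,
        p = an$p, stringsAsFactors = FALSE)
      lsd <- fisher_lsd(gl, an)
      if (!is.null(lsd) && nrow(lsd)) {
        lsd$metric <- m
        lsd$d_min_um <- dmin
        lsd$d_max_um <- sub$d_max_um[1]
        lsd_rows[[length(lsd_rows) + 1L]] <- lsd
      }
    }
  }
  list(metrics = metrics,
       anova = if (length(anova_rows)) do.call(rbind, anova_rows) else NULL,
       lsd = if (length(lsd_rows)) do.call(rbind, lsd_rows) else NULL,
       lesions = lesions)
}
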