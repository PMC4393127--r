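# Formats, configuration, and pipeline orchestration.
#
# Coordinate convention: everything in memory is 1-based R matrix indexing
# (row, col); every CSV written by the package uses 0-based (row, col)
# pixel coordinates, with micrometre columns alongside where meaningful.

default_config <- function() {
  list(
    pixel_size_um = 0.32,
    filters = list(dapi_curvature = 5, em48_curvature = 20,
                   rim = list(width_px = 3, gap_px = 2)),
    nuclei = list(min_area_px = 280, threshold = "otsu", split_touching = FALSE),
    cells = list(max_radius_px = 15),
    markers = list(DARPP32 = 1.1, NeuN = 2.0, GFP = 1.5),
    spots = list(grow_factor = 2, connectivity = 4, min_area_px2 = 5,
                 roundness_min = 0.5, roundness_max = 1.2, min_ratio = 0.4,
                 intensity_factor = 2, ring_width_px = 9,
                 spot_mean_reference = "spots"),
    granularity = list(scale_px = 1),
    intensity = list(floor_at_zero = TRUE),
    restrict_to = "DARPP32"
  )
}

#' Read and resolve a YAML run configuration
#'
#' Loads a YAML configuration and merges it over the package defaults
#' (curvatures 5/20, rim 3/2 px, nucleus area gate 280 px, positivity
#' factors 1.1/2.0/1.5, spot gates 5 px² / roundness 0.5–1.2 / ratio 0.4,
#' 9-px ring, 0.32 um/px). Unknown top-level keys are rejected so typos
#' fail fast rather than silently using a default.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  extra <- setdiff(names(user), c(names(cfg), "channels", "output", "seed"))
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "), call. = FALSE)
  modifyList(cfg, user)
}

#' Read one image channel from TIFF
#'
#' Reads a single- or multi-page TIFF as a numeric matrix in original
#' sample units (integer TIFFs are not rescaled to \[0, 1\]).
#'
#' @param path TIFF file.
#' @param page Page index for multi-page files (default 1).
#' @return Numeric matrix.
#' @export
read_channel_tiff <- function(path, page = 1) {
  img <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  m <- img[[page]]
  if (length(dim(m)) == 3) m <- m[, , 1]
  storage.mode(m) <- "double"
  m
}

#' Write an intensity or label image to TIFF
#'
#' Writes a matrix as 16-bit grayscale TIFF (values clipped to 0..65535).
#'
#' @param img Numeric or integer matrix.
#' @param path Output file.
#' @export
write_channel_tiff <- function(img, path) {
  m <- pmin(pmax(img, 0), 65535) / 65535
  tiff::writeTIFF(m, path, bits.per.sample = 16)
  invisible(path)
}

#' Rasterize a polygon to a pixel mask
#'
#' Even-odd (ray casting) point-in-polygon fill over pixel centers, used to
#' turn polygon-JSON region annotations into label masks.
#'
#' @param vertices Two-column matrix of polygon vertices as (row, col).
#' @param shape `c(nrow, ncol)` of the target mask.
#' @return Logical matrix.
#' @export
rasterize_polygon <- function(vertices, shape) {
  nrv <- nrow(vertices)
  vr <- vertices[, 1]; vc <- vertices[, 2]
  out <- matrix(FALSE, shape[1], shape[2])
  px_r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  px_c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  inside <- matrix(FALSE, shape[1], shape[2])
  j <- nrv
  for (i in seq_len(nrv)) {
    cross <- ((vr[i] > px_r) != (vr[j] > px_r)) &
      (px_c < (vc[j] - vc[i]) * (px_r - vr[i]) / (vr[j] - vr[i]) + vc[i])
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Read region masks from a label TIFF or polygon JSON
#'
#' Label-image TIFFs map each positive label to `region_<label>` (or names
#' given in `names`); polygon JSON files hold an object of region name ->
#' list of \[row, col\] vertices (0-based), rasterized by
#' [rasterize_polygon()].
#'
#' @param path `.tif`/`.tiff` or `.json` file.
#' @param shape Image shape, required for JSON input.
#' @param names Optional region names for label input.
#' @return Named list of logical masks.
#' @export
read_region_masks <- function(path, shape = NULL, names = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (is.null(shape)) stop("shape required for polygon masks", call. = FALSE)
    polys <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(lapply(polys, function(v) {
      v <- matrix(unlist(v), ncol = 2, byrow = is.list(v))
      rasterize_polygon(v + 1, shape)  # stored 0-based
    }))
  }
  lab <- round(read_channel_tiff(path))
  labs <- sort(unique(lab[lab > 0]))
  masks <- lapply(labs, function(l) lab == l)
  names(masks) <- if (!is.null(names)) names else paste0("region_", labs)
  masks
}

#' Run the full quantification pipeline on one scene or image bundle
#'
#' Executes filters -> nuclei -> cells -> spots -> granularity -> intensity
#' -> endpoints on a set of co-registered channels, optionally writing
#' per-cell, per-spot and per-region CSVs, spot/nucleus label TIFFs, the
#' resolved configuration, and a per-stage count log. Deterministic:
#' identical inputs and configuration give byte-identical outputs.
#'
#' @param channels Named list of matrices (needs `dapi`; `em48`, marker and
#'   `mab2174` channels used when present), or an `htt_scene`.
#' @param config Configuration list from [read_run_config()].
#' @param masks Optional named region masks.
#' @param out_dir Output directory; `NULL` skips writing.
#' @param animal,group,section Identifiers stamped onto output rows.
#' @return List with `nuclei`, `cells` (`cell_set`), `spots` (`spot_set`),
#'   `granularity`, `intensity`, `endpoints`, `log`.
#' @export
run_pipeline <- function(channels, config = read_run_config(), masks = NULL,
                         out_dir = NULL, animal = "a1", group = "g1",
                         section = "s1") {
  if (inherits(channels, "htt_scene")) channels <- channels$channels
  if (!"dapi" %in% names(channels))
    stop("missing channel: dapi", call. = FALSE)
  shapes <- unique(vapply(channels, function(m) paste(dim(m), collapse = "x"), ""))
  if (length(shapes) > 1)
    stop("channels are not co-registered: ", paste(shapes, collapse = " vs "),
         call. = FALSE)
  cfg <- config
  rim <- cfg$filters$rim
  nuclei <- detect_nuclei(channels$dapi,
                          curvature = cfg$filters$dapi_curvature,
                          min_area_px = cfg$nuclei$min_area_px,
                          threshold = cfg$nuclei$threshold,
                          split_touching = isTRUE(cfg$nuclei$split_touching),
                          pixel_size_um = cfg$pixel_size_um)
  marker_names <- intersect(names(cfg$markers), names(channels))
  cells <- if (length(marker_names)) {
    classify_cells(channels[marker_names], nuclei,
                   factors = unlist(cfg$markers[marker_names]),
                   max_radius_px = cfg$cells$max_radius_px,
                   width_px = rim$width_px, gap_px = rim$gap_px)
  } else NULL
  spots <- if ("em48" %in% names(channels)) {
    detect_inclusions(channels$em48, nuclei,
                      curvature = cfg$filters$em48_curvature,
                      grow_factor = cfg$spots$grow_factor,
                      connectivity = cfg$spots$connectivity,
                      ring_width_px = cfg$spots$ring_width_px,
                      min_area_px2 = cfg$spots$min_area_px2,
                      roundness_range = c(cfg$spots$roundness_min,
                                          cfg$spots$roundness_max),
                      min_ratio = cfg$spots$min_ratio,
                      intensity_factor = cfg$spots$intensity_factor,
                      spot_mean_reference = cfg$spots$spot_mean_reference)
  } else NULL
  gran <- if ("em48" %in% names(channels) && nrow(nuclei$cells)) {
    granularity_index(channels$em48, nuclei, scale_px = cfg$granularity$scale_px)
  } else NULL
  intens <- if ("mab2174" %in% names(channels) && !is.null(cells)) {
    measure_intensity(channels$mab2174, cells, "cytoplasm",
                      width_px = rim$width_px, gap_px = rim$gap_px,
                      floor_at_zero = isTRUE(cfg$intensity$floor_at_zero))
  } else NULL
  ctab <- if (!is.null(cells)) cells else
    list(cells = dplyr::mutate(nuclei$cells, cell_area_um2 = .data$area_um2),
         calls = NULL)
  if (!is.null(masks)) {
    ann <- assign_regions(if (is.null(cells)) ctab$cells else cells, spots, masks)
    cells_tab <- ann$cells; spots_tab <- ann$spots
  } else {
    cells_tab <- if (is.null(cells)) ctab$cells else cells$cells
    spots_tab <- if (is.null(spots)) NULL else spots$spots
  }
  endpoints <- endpoint_table(cells_tab, spots_tab, granularity = gran,
                              calls = if (is.null(cells)) NULL else cells$calls,
                              restrict_to = cfg$restrict_to,
                              animal = animal, group = group, section = section)
  log <- tibble::tibble(
    stage = c("nuclei", "cells_positive", "spots", "spots_nuclear"),
    count = c(nrow(nuclei$cells),
              if (is.null(cells)) NA_integer_ else
                sum(cells$calls$positive[cells$calls$marker == cfg$restrict_to]),
              if (is.null(spots)) NA_integer_ else nrow(spots$spots),
              if (is.null(spots)) NA_integer_ else
                sum(spots$spots$compartment == "nuclear")))
  res <- list(nuclei = nuclei, cells = cells, spots = spots,
              granularity = gran, intensity = intens,
              endpoints = endpoints, log = log, config = cfg)
  if (!is.null(out_dir)) write_outputs(res, out_dir, channels)
  res
}

#' Write pipeline outputs to a directory
#'
#' Emits `cells.csv`, `calls.csv`, `spots.csv`, `granularity.csv`,
#' `intensity.csv`, `endpoints.csv`, `log.csv`, label TIFFs for nuclei and
#' spot masks, and the resolved configuration as `config.yaml`. Pixel
#' coordinates in CSVs are 0-based (row, col).
#'
#' @param res Result of [run_pipeline()].
#' @param out_dir Directory (created if missing).
#' @param channels Channel list (for the spot label image shape).
#' @export
write_outputs <- function(res, out_dir, channels = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  zero_base <- function(df) {
    for (nm in grep("(_row|_col)$", names(df), value = TRUE)) df[[nm]] <- df[[nm]] - 1
    df
  }
  cells_tab <- if (is.null(res$cells)) res$nuclei$cells else res$cells$cells
  readr::write_csv(zero_base(cells_tab), file.path(out_dir, "cells.csv"))
  if (!is.null(res$cells))
    readr::write_csv(res$cells$calls, file.path(out_dir, "calls.csv"))
  if (!is.null(res$spots))
    readr::write_csv(zero_base(dplyr::select(res$spots$spots, -"pixels")),
                     file.path(out_dir, "spots.csv"))
  if (!is.null(res$granularity))
    readr::write_csv(res$granularity, file.path(out_dir, "granularity.csv"))
  if (!is.null(res$intensity))
    readr::write_csv(res$intensity, file.path(out_dir, "intensity.csv"))
  readr::write_csv(res$endpoints, file.path(out_dir, "endpoints.csv"))
  readr::write_csv(res$log, file.path(out_dir, "log.csv"))
  write_channel_tiff(res$nuclei$label_image, file.path(out_dir, "nuclei_labels.tif"))
  if (!is.null(res$spots)) {
    shp <- dim(res$nuclei$label_image)
    sl <- matrix(0L, shp[1], shp[2])
    for (i in seq_len(nrow(res$spots$spots)))
      sl[res$spots$spots$pixels[[i]]] <- res$spots$spots$spot_id[i]
    write_channel_tiff(sl, file.path(out_dir, "spot_labels.tif"))
  }
  yaml::write_yaml(res$config, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
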