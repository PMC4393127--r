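# Background-corrected pan-HTT (MAB2174) intensity per cell and
# percent-of-control summaries.

#' Background-corrected compartment intensity
#'
#' Measures the mean raw intensity over a cell compartment (cytoplasm or
#' nucleus) and corrects it by subtracting the mean local background from an
#' extracellular rim around the cell border (other cells excluded), floored
#' at zero so corrected intensities stay nonnegative. Cells with an empty
#' compartment are emitted with a QC flag and an `NA` corrected value so
#' they can be excluded downstream rather than silently dropped.
#'
#' @param img Numeric matrix (e.g. the MAB2174 channel).
#' @param cells A `cell_set` from [classify_cells()].
#' @param compartment `"cytoplasm"` or `"nucleus"`.
#' @param width_px,gap_px Rim geometry (defaults 3 and 2).
#' @param floor_at_zero Floor corrected values at 0 (default `TRUE`).
#' @return Tibble per cell: `label`, `compartment`, `raw_mean`,
#'   `local_bg_mean`, `corrected`, `qc`.
#' @export
measure_intensity <- function(img, cells, compartment = c("cytoplasm", "nucleus"),
                              width_px = 3, gap_px = 2, floor_at_zero = TRUE) {
  compartment <- match.arg(compartment)
  assert_image(img)
  lab <- cells$nuclei$label_image
  cyto <- cells$cytoplasm_image
  all_cells <- lab > 0L | cyto > 0L
  purrr::map_dfr(cells$cells$label, function(li) {
    nuc <- lab == li
    own <- nuc | cyto == li
    comp_mask <- if (compartment == "nucleus") nuc else (cyto == li)
    if (!any(comp_mask)) {
      return(tibble::tibble(label = li, compartment = compartment,
                            raw_mean = NA_real_, local_bg_mean = NA_real_,
                            corrected = NA_real_, qc = "empty_compartment"))
    }
    bg <- local_background_mean(img, own, width_px, gap_px,
                                exclusion_mask = all_cells & !own)
    raw <- mean(img[comp_mask])
    corr <- raw - bg$mean
    if (floor_at_zero) corr <- max(corr, 0)
    tibble::tibble(label = li, compartment = compartment, raw_mean = raw,
                   local_bg_mean = bg$mean, corrected = corr,
                   qc = if (bg$used_fallback) "rim_fallback" else NA_character_)
  })
}

#' Express corrected intensities as percent of a control group
#'
#' Divides every cell's corrected intensity by the control group's mean
#' corrected intensity and multiplies by 100, then summarises per group.
#' The control group's own mean is exactly 100. Cells with `NA` corrected
#' values (empty compartments) are excluded.
#'
#' @param records Tibble with columns `group` and `corrected` (e.g. rows
#'   from [measure_intensity()] joined with a condition label).
#' @param control_group Name of the control level; must be present with a
#'   positive mean corrected intensity.
#' @return Tibble per group: `group`, `mean_pct`, `sd_pct`, `n`.
#' @export
percent_of_control <- function(records, control_group) {
  records <- dplyr::filter(records, !is.na(.data$corrected))
  ctrl <- records$corrected[records$group == control_group]
  if (!length(ctrl)) stop("control group '", control_group, "' is empty", call. = FALSE)
  m <- mean(ctrl)
  if (m <= 0) stop("control group mean must be positive", call. = FALSE)
  records |>
    dplyr::mutate(pct = .data$corrected / m * 100) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_pct = mean(.data$pct), sd_pct = sd(.data$pct),
                     n = dplyr::n(), .groups = "drop")
}
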