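# Background estimation and local-background measurement shared by all
# detection stages.

#' Sliding-parabola background estimate
#'
#' Estimates the smooth background of a fluorescence image as the grayscale
#' opening of the image with a paraboloid structuring function
#' \eqn{s(r) = -c\,r^2}, where `curvature` is \eqn{c} in intensity units per
#' squared pixel. This is the standard reading of a rolling/sliding-parabola
#' filter: a paraboloid of the given curvature is slid under the intensity
#' surface and the background is the upper envelope of all positions it can
#' reach. Bright structures narrower than the paraboloid (nuclei, puncta,
#' inclusions) are excluded from the background; smooth shading is followed.
#' The mapping from the Acapella vendor "curvature" setting is approximate:
#' only the morphological contract is guaranteed, not bit-level parity.
#'
#' The quadratic structuring function is separable, so the opening is
#' computed as 1-D min/max passes over rows then columns. At image borders
#' the structuring-function support is truncated at the edge; no padding
#' values are invented.
#'
#' @param img Numeric matrix of finite, nonnegative intensities.
#' @param curvature Positive curvature in intensity units per px^2. The
#'   defaults used by the pipeline are 5 for DAPI and 20 for EM48.
#' @return Numeric matrix of the same shape, everywhere `<= img`.
#' @seealso [subtract_background()]
#' @examples
#' img <- matrix(0, 16, 16); img[8, 8] <- 50
#' bg <- sliding_parabola_background(img, curvature = 5)
#' max(bg) # the isolated spike is not background
#' @export
sliding_parabola_background <- function(img, curvature) {
  assert_image(img)
  if (!is.numeric(curvature) || length(curvature) != 1 || curvature <= 0)
    stop("curvature must be a positive scalar", call. = FALSE)
  rng <- max(img) - min(img)
  if (rng == 0) return(img)
  ero <- quad_pass(quad_pass(img, curvature, 0L, byrow = TRUE),
                   curvature, 0L)
  quad_pass(quad_pass(ero, curvature, 1L, byrow = TRUE), curvature, 1L)
}

# one separable erosion (op = 0) / dilation (op = 1) pass with the
# quadratic structuring function, along columns (or rows with byrow)
quad_pass <- function(m, curvature, op, byrow = FALSE) {
  storage.mode(m) <- "double"
  if (byrow) t(.Call(quad_pass_c, t(m), as.numeric(curvature), as.integer(op)))
  else .Call(quad_pass_c, m, as.numeric(curvature), as.integer(op))
}

#' Remove background with the sliding-parabola filter
#'
#' Subtracts the [sliding_parabola_background()] estimate from the image,
#' clipping at zero. The result keeps compact bright structure (nuclei,
#' EM48-ir inclusions) on a near-zero baseline.
#'
#' @inheritParams sliding_parabola_background
#' @return Nonnegative numeric matrix, `img - background`.
#' @export
subtract_background <- function(img, curvature) {
  bg <- sliding_parabola_background(img, curvature)
  pmax(img - bg, 0)
}

#' Mean intensity in an extracellular background rim
#'
#' Measures the local ("extracellular") background around a cell: the rim is
#' the set of pixels reached by dilating the region by `gap_px + width_px`
#' chessboard steps but not by `gap_px` steps (defaults: 3 px width, 2 px
#' gap), minus any excluded pixels (typically other cells) and out-of-field
#' pixels. If exclusions empty the rim entirely, the image-wide median is
#' returned and the record is flagged so one crowded cell cannot abort a run.
#'
#' @param img Numeric intensity matrix.
#' @param region_mask Logical matrix, the cell region (nonempty).
#' @param width_px,gap_px Rim width and gap from the region border, pixels.
#' @param exclusion_mask Optional logical matrix of pixels to exclude.
#' @return List with `mean` (numeric), `n_px` and `used_fallback` (logical).
#' @export
local_background_mean <- function(img, region_mask, width_px = 3, gap_px = 2,
                                  exclusion_mask = NULL) {
  assert_image(img)
  if (!any(region_mask)) stop("region_mask is empty", call. = FALSE)
  bb <- mask_bbox(region_mask, pad = gap_px + width_px)
  sub <- region_mask[bb["r0"]:bb["r1"], bb["c0"]:bb["c1"], drop = FALSE]
  inner <- dilate_k(sub, gap_px)
  outer <- dilate_k(inner, width_px)
  ring <- outer & !inner
  if (!is.null(exclusion_mask))
    ring <- ring & !exclusion_mask[bb["r0"]:bb["r1"], bb["c0"]:bb["c1"], drop = FALSE]
  vals <- img[bb["r0"]:bb["r1"], bb["c0"]:bb["c1"], drop = FALSE][ring]
  if (!length(vals)) {
    return(list(mean = median(img), n_px = 0L, used_fallback = TRUE))
  }
  list(mean = mean(vals), n_px = length(vals), used_fallback = FALSE)
}
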