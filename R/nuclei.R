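# Nuclei detection from the DAPI channel.

#' Detect cell nuclei in a DAPI image
#'
#' Segments individual nuclei from the DAPI channel: sliding-parabola
#' background removal (curvature 5 by default), a global threshold on the
#' filtered image, hole filling, optional distance-transform watershed
#' splitting of touching nuclei, 8-connected labeling, and a strict area
#' gate — nuclei with an area smaller than `min_area_px` (default 280 px)
#' are excluded, so a 279-px object is rejected and a 280-px object kept.
#'
#' The global threshold defaults to Otsu's method on the background-
#' subtracted image (`threshold = "otsu"`); passing a number `k` uses
#' `k * median` of the filtered image instead.
#'
#' @param dapi_img Numeric matrix, the DAPI channel.
#' @param curvature Sliding-parabola curvature for DAPI (default 5).
#' @param min_area_px Minimum nucleus area in raw pixels (default 280),
#'   applied after any splitting.
#' @param threshold `"otsu"` or a positive multiple of the filtered-image
#'   median.
#' @param split_touching If `TRUE`, split touching nuclei by a watershed on
#'   the distance transform of the foreground mask.
#' @param pixel_size_um Pixel edge length in micrometres (default 0.32).
#' @return A `nucleus_set`: list with `cells` (tibble: `label`, `area_px`,
#'   `area_um2`, `centroid_row`, `centroid_col`), `label_image` (integer
#'   matrix, 0 = background), and `pixel_size_um`. Labels are consecutive
#'   from 1; an empty image yields zero rows, not an error.
#' @examples
#' sc <- render_scene(scene_spec(n_nuclei = 6, shape = c(160, 160)), seed = 1)
#' nuc <- detect_nuclei(sc$channels$dapi)
#' nuc$cells
#' @export
detect_nuclei <- function(dapi_img, curvature = 5, min_area_px = 280,
                          threshold = "otsu", split_touching = FALSE,
                          pixel_size_um = 0.32) {
  assert_image(dapi_img, "dapi_img")
  filt <- subtract_background(dapi_img, curvature)
  if (identical(threshold, "otsu")) {
    thr <- otsu_threshold(filt)
  } else if (is.numeric(threshold) && length(threshold) == 1 && threshold > 0) {
    thr <- threshold * median(filt)
  } else stop("threshold must be \"otsu\" or a positive number", call. = FALSE)
  mask <- filt > thr
  if (!any(mask)) return(new_nucleus_set(matrix(0L, nrow(dapi_img), ncol(dapi_img)),
                                         pixel_size_um))
  mask <- matrix(as.logical(EBImage::fillHull(mask)), nrow(mask), ncol(mask))
  if (split_touching) {
    dm <- EBImage::distmap(mask)
    lab <- EBImage::watershed(dm, tolerance = 1)
    lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  } else {
    lab <- label_components(mask, conn = 8)
  }
  st <- label_stats(lab)
  keep <- st$label[st$area_px >= min_area_px]
  lab[!(lab %in% keep)] <- 0L
  new_nucleus_set(relabel_consecutive(lab), pixel_size_um)
}

new_nucleus_set <- function(label_image, pixel_size_um) {
  st <- label_stats(label_image)
  st$area_um2 <- st$area_px * pixel_size_um^2
  st <- st[, c("label", "area_px", "area_um2", "centroid_row", "centroid_col")]
  structure(list(cells = st, label_image = label_image,
                 pixel_size_um = pixel_size_um),
            class = "nucleus_set")
}

#' @export
print.nucleus_set <- function(x, ...) {
  cat("<nucleus_set> ", nrow(x$cells), " nuclei, ",
      paste(dim(x$label_image), collapse = " x "), " px, ",
      x$pixel_size_um, " um/px\n", sep = "")
  print(x$cells, ...)
  invisible(x)
}

#' Rebuild a label image from nucleus regions
#'
#' Inverse of the region extraction in [detect_nuclei()]: paints each
#' nucleus pixel set into an integer label image. Overlapping regions are an
#' error (nuclei must be disjoint).
#'
#' @param nuclei A `nucleus_set` or a list of logical masks / linear-index
#'   vectors keyed by label.
#' @param shape Integer vector `c(nrow, ncol)`.
#' @return Integer matrix; 0 is background.
#' @export
nucleus_mask_image <- function(nuclei, shape) {
  out <- matrix(0L, shape[1], shape[2])
  px <- nucleus_pixels(nuclei)
  for (i in seq_along(px)) {
    idx <- px[[i]]
    if (any(out[idx] != 0L)) stop("overlapping nucleus regions", call. = FALSE)
    out[idx] <- as.integer(names(px)[i])
  }
  out
}

# linear pixel indices per nucleus, named by label
nucleus_pixels <- function(nuclei) {
  if (inherits(nuclei, "nucleus_set")) {
    lab <- nuclei$label_image
    idx <- which(lab > 0L)
    if (!length(idx)) return(list())
    return(split(idx, lab[idx]))
  }
  if (is.list(nuclei)) {
    out <- lapply(nuclei, function(p) if (is.logical(p)) which(p) else as.integer(p))
    if (is.null(names(out))) names(out) <- seq_along(out)
    return(out)
  }
  stop("cannot interpret nuclei", call. = FALSE)
}

# Otsu's threshold on a 256-bin histogram of the image range.
otsu_threshold <- function(img, n_bins = 256) {
  rng <- range(img)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- as.numeric(tabulate(findInterval(img, br, rightmost.closed = TRUE), n_bins))
  w <- cumsum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  mu <- cumsum(h * mids)
  tot <- w[n_bins]; mu_t <- mu[n_bins]
  between <- (mu_t * w - mu * tot)^2 / (w * (tot - w))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}
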