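# Low-level pixel-set helpers shared by the detection modules.
#
# Conventions: images are plain numeric matrices indexed [row, col], 1-based
# internally; all CSV writers emit 0-based (row, col) coordinates. Pixel sets
# are represented either as logical masks (same dim as the image) or as
# integer linear indices into the matrix.

#' @importFrom stats median quantile sd aov pt rnorm rpois runif
NULL

# Shift a matrix by (dr, dc), exposing `fill` at the vacated border.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1, 1 - dr):min(nr, nr - dr)
  sc <- max(1, 1 - dc):min(nc, nc - dc)
  if (length(sr) < 1 || length(sc) < 1 ||
      sr[1] > sr[length(sr)] || sc[1] > sc[length(sc)]) return(out)
  out[sr + dr, sc + dc] <- m[sr, sc, drop = FALSE]
  out
}

# One binary dilation step (8-connected chessboard unless conn = 4).
dilate_once <- function(mask, conn = 8, support = NULL) {
  dilate_k(mask, 1L, conn, support)
}

# k-step dilation: 8-connected gives Chebyshev distance <= k from the set.
# With `support`, growth is geodesic (constrained to support | mask).
dilate_k <- function(mask, k, conn = 8, support = NULL) {
  if (k <= 0) return(mask)
  if (typeof(mask) != "logical") storage.mode(mask) <- "logical"
  if (!is.null(support) && typeof(support) != "logical")
    storage.mode(support) <- "logical"
  .Call(binary_dilate_c, mask, as.integer(k), as.integer(conn), support)
}

# 8-connected labeling built on EBImage::bwlabel (4-connected) plus a
# union-find merge of diagonally touching labels.
label_components <- function(mask, conn = 8) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (conn == 4) return(relabel_consecutive(lab))
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  for (o in list(c(-1, -1), c(-1, 1))) {
    sh <- shift_mat(lab, o[1], o[2], 0L)
    touch <- which(lab > 0L & sh > 0L & lab != sh)
    if (length(touch)) {
      pr <- unique(cbind(lab[touch], sh[touch]))
      for (i in seq_len(nrow(pr))) unite(pr[i, 1], pr[i, 2])
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  lab[lab > 0L] <- root[lab[lab > 0L]]
  relabel_consecutive(lab)
}

relabel_consecutive <- function(lab) {
  u <- sort(unique(lab[lab > 0L]))
  if (!length(u)) return(lab)
  map <- integer(max(u)); map[u] <- seq_along(u)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  lab
}

# Areas / centroids of a label image, as a tibble ordered by label.
label_stats <- function(lab) {
  idx <- which(lab > 0L)
  if (!length(idx)) {
    return(tibble::tibble(label = integer(), area_px = integer(),
                          centroid_row = numeric(), centroid_col = numeric()))
  }
  l <- lab[idx]
  rc <- arrayInd(idx, dim(lab))
  tibble::tibble(
    label = as.integer(names(tapply(l, l, length))),
    area_px = as.integer(tapply(l, l, length)),
    centroid_row = as.numeric(tapply(rc[, 1], l, mean)),
    centroid_col = as.numeric(tapply(rc[, 2], l, mean))
  )
}

# Bounding box of a mask, optionally padded and clipped to the image.
mask_bbox <- function(mask, pad = 0) {
  idx <- which(mask, arr.ind = TRUE)
  c(r0 = max(1L, min(idx[, 1]) - pad), r1 = min(nrow(mask), max(idx[, 1]) + pad),
    c0 = max(1L, min(idx[, 2]) - pad), c1 = min(ncol(mask), max(idx[, 2]) + pad))
}

# round() half-away-from-zero, so pixel containment is deterministic
round_px <- function(x) floor(x + 0.5)

assert_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop(arg, " must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(img)))
    stop(arg, " contains non-finite pixels", call. = FALSE)
  invisible(img)
}
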