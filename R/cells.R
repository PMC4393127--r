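# Cytoplasm definition around nuclei and marker positivity calling
# (DARPP-32 / NeuN / GFP) against the local extracellular background.

#' Grow cytoplasm regions around detected nuclei
#'
#' Defines each cell's cytoplasmic compartment by geodesic dilation of its
#' nucleus within the marker-above-threshold support mask, up to
#' `max_radius_px` chessboard steps. Pixels reachable from more than one
#' nucleus are assigned to the nearest nucleus (Euclidean distance to the
#' nucleus pixel set; ties go to the lower label), so no pixel belongs to two
#' cells. The cell border is the outer boundary of nucleus plus cytoplasm.
#'
#' @param marker_img Numeric matrix of the marker channel used as cytoplasm
#'   support (e.g. DARPP-32 or NeuN).
#' @param nuclei A `nucleus_set` from [detect_nuclei()].
#' @param max_radius_px Maximum growth radius in pixels (default 15, a
#'   typical soma radius at 0.32 um/px).
#' @param marker_threshold Support threshold. `NULL` (default) removes the
#'   smooth background from the marker image with the sliding-parabola
#'   filter (`support_curvature`) and thresholds the result by Otsu's
#'   method, which separates cell-body marker signal from the
#'   extracellular level regardless of how much of the field is covered
#'   by tissue. A number is applied directly to the raw marker image.
#' @param support_curvature Parabola curvature used when deriving the
#'   default support (default 5).
#' @return Integer matrix of cytoplasm labels (0 = none); cytoplasm pixels
#'   never overlap any nucleus.
#' @export
detect_cytoplasm <- function(marker_img, nuclei, max_radius_px = 15,
                             marker_threshold = NULL, support_curvature = 5) {
  assert_image(marker_img, "marker_img")
  lab <- nuclei$label_image
  if (!all(dim(marker_img) == dim(lab)))
    stop("marker image and nucleus label image differ in shape", call. = FALSE)
  out <- matrix(0L, nrow(lab), ncol(lab))
  labs <- nuclei$cells$label
  if (!length(labs)) return(out)
  any_nuc <- lab > 0L
  if (is.null(marker_threshold)) {
    marker_img <- subtract_background(marker_img, support_curvature)
    thr_global <- otsu_threshold(marker_img)
  } else {
    thr_global <- marker_threshold
  }
  nr <- nrow(lab); dims <- dim(lab)
  nuc_px <- nucleus_pixels(nuclei)
  nuc_rc <- lapply(nuc_px, arrayInd, .dim = dims)
  claims <- list()
  for (li in labs) {
    rc0 <- nuc_rc[[as.character(li)]]
    bb <- c(r0 = max(1L, min(rc0[, 1]) - max_radius_px),
            r1 = min(dims[1], max(rc0[, 1]) + max_radius_px),
            c0 = max(1L, min(rc0[, 2]) - max_radius_px),
            c1 = min(dims[2], max(rc0[, 2]) + max_radius_px))
    rr <- bb["r0"]:bb["r1"]; cc <- bb["c0"]:bb["c1"]
    w_nuc <- matrix(FALSE, length(rr), length(cc))
    w_nuc[cbind(rc0[, 1] - bb["r0"] + 1L, rc0[, 2] - bb["c0"] + 1L)] <- TRUE
    support <- (marker_img[rr, cc, drop = FALSE] > thr_global) & !any_nuc[rr, cc, drop = FALSE]
    cur <- dilate_k(w_nuc, max_radius_px, conn = 8, support = support)
    grown <- cur & !w_nuc
    if (!any(grown)) next
    rc <- which(grown, arr.ind = TRUE)
    claims[[as.character(li)]] <- cbind(rc[, 1] + bb["r0"] - 1L,
                                        rc[, 2] + bb["c0"] - 1L)
  }
  if (!length(claims)) return(out)
  idx_all <- unlist(lapply(claims, function(rc) (rc[, 2] - 1L) * nr + rc[, 1]),
                    use.names = FALSE)
  owner_all <- rep(as.integer(names(claims)),
                   vapply(claims, nrow, integer(1)))
  contested <- unique(idx_all[duplicated(idx_all)])
  solo <- !(idx_all %in% contested)
  out[idx_all[solo]] <- owner_all[solo]
  if (length(contested)) {
    # nearest nucleus by Euclidean distance; for points outside a region
    # the nearest region pixel is a boundary pixel, so distances are taken
    # to the (much smaller) boundary sets, vectorised per owner group
    bnd_rc <- lapply(nuc_rc, boundary_rc)
    sub <- !solo
    by_px <- split(owner_all[sub], idx_all[sub])
    sets <- vapply(by_px, paste, collapse = ",", FUN.VALUE = "")
    px_ids <- as.integer(names(by_px))
    px_rc <- arrayInd(px_ids, dims)
    for (s in unique(sets)) {
      sel <- which(sets == s)
      owners <- sort(by_px[[sel[1]]])
      pr <- px_rc[sel, 1]; pc <- px_rc[sel, 2]
      best_d2 <- rep(Inf, length(sel)); best <- rep(NA_integer_, length(sel))
      for (li in owners) {
        rc <- bnd_rc[[as.character(li)]]
        d2 <- outer(pr, rc[, 1], `-`)^2 + outer(pc, rc[, 2], `-`)^2
        dmin <- do.call(pmin, c(asplit(d2, 2), list(rep(Inf, length(sel)))))
        upd <- dmin < best_d2  # strict: earlier (lower) label keeps ties
        best[upd] <- li; best_d2[upd] <- dmin[upd]
      }
      out[px_ids[sel]] <- best
    }
  }
  out
}

# boundary pixels of a region given its (row, col) matrix
boundary_rc <- function(rc) {
  r0 <- min(rc[, 1]); c0 <- min(rc[, 2])
  w <- matrix(FALSE, max(rc[, 1]) - r0 + 1L, max(rc[, 2]) - c0 + 1L)
  w[cbind(rc[, 1] - r0 + 1L, rc[, 2] - c0 + 1L)] <- TRUE
  interior <- shift_mat(w, 1, 0, FALSE) & shift_mat(w, -1, 0, FALSE) &
    shift_mat(w, 0, 1, FALSE) & shift_mat(w, 0, -1, FALSE)
  b <- which(w & !interior, arr.ind = TRUE)
  cbind(b[, 1] + r0 - 1L, b[, 2] + c0 - 1L)
}

#' Call marker positivity for one cell
#'
#' A cell is positive for a marker when its mean nuclear marker intensity
#' strictly exceeds `factor` times the mean local background, measured in an
#' extracellular rim (3 px wide, 2 px gap by default) around the cell border
#' with other cells excluded. At exact equality the call is negative. The
#' printed factors are 1.1 (DARPP-32), 2.0 (NeuN) and 1.5 (GFP).
#'
#' @param marker_img Numeric matrix.
#' @param nucleus_mask Logical matrix, the cell's nucleus pixels.
#' @param cell_mask Logical matrix, nucleus plus cytoplasm (the cell border
#'   is its outer boundary); defaults to the nucleus alone.
#' @param factor Positivity factor (> 0).
#' @param width_px,gap_px Rim geometry.
#' @param exclusion_mask Pixels of other cells, excluded from the rim.
#' @return One-row tibble: `nuclear_mean`, `local_bg_mean`, `factor_used`,
#'   `positive`, `qc` (`"rim_fallback"` when the rim was empty).
#' @export
call_positivity <- function(marker_img, nucleus_mask, cell_mask = nucleus_mask,
                            factor, width_px = 3, gap_px = 2,
                            exclusion_mask = NULL) {
  if (!is.numeric(factor) || factor <= 0) stop("factor must be > 0", call. = FALSE)
  nuclear_mean <- mean(marker_img[nucleus_mask])
  bg <- local_background_mean(marker_img, cell_mask, width_px, gap_px,
                              exclusion_mask)
  tibble::tibble(
    nuclear_mean = nuclear_mean,
    local_bg_mean = bg$mean,
    factor_used = factor,
    positive = nuclear_mean > factor * bg$mean,
    qc = if (bg$used_fallback) "rim_fallback" else NA_character_
  )
}

#' Classify all cells against a panel of markers
#'
#' Builds one cell record per nucleus: cytoplasm grown on a designated
#' support channel, then marker positivity called per [call_positivity()]
#' for every marker in `factors`, with all other cells excluded from each
#' cell's background rim. Deterministic given inputs.
#'
#' @param images Named list of co-registered marker matrices.
#' @param nuclei A `nucleus_set`.
#' @param factors Named numeric vector of positivity factors; names must
#'   exist in `images`. Default `c(DARPP32 = 1.1, NeuN = 2.0, GFP = 1.5)`
#'   restricted to the supplied channels.
#' @param cytoplasm_marker Channel used for cytoplasm support; the default
#'   `"max"` takes the pixelwise maximum over all marker channels, so a
#'   cell body outlined by any marker supports its cytoplasm.
#' @param max_radius_px,width_px,gap_px See [detect_cytoplasm()] and
#'   [call_positivity()].
#' @return A `cell_set`: list with `cells` (tibble per cell: geometry and
#'   area), `calls` (tibble per cell x marker), `cytoplasm_image`, `nuclei`.
#' @export
classify_cells <- function(images, nuclei,
                           factors = c(DARPP32 = 1.1, NeuN = 2.0, GFP = 1.5),
                           cytoplasm_marker = "max",
                           max_radius_px = 15, width_px = 3, gap_px = 2) {
  if (is.null(names(images)) || any(!nzchar(names(images))))
    stop("images must be a named list", call. = FALSE)
  shapes <- vapply(images, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(shapes)) > 1)
    stop("marker images are not co-registered: shapes ", paste(unique(shapes), collapse = ", "),
         call. = FALSE)
  if (!all(dim(images[[1]]) == dim(nuclei$label_image)))
    stop("marker images and nucleus label image differ in shape", call. = FALSE)
  factors <- factors[names(factors) %in% names(images)]
  if (!length(factors)) stop("no factor matches a supplied channel", call. = FALSE)
  support_img <- if (identical(cytoplasm_marker, "max")) {
    Reduce(pmax, images[names(factors)])
  } else images[[cytoplasm_marker]]
  cyto <- detect_cytoplasm(support_img, nuclei, max_radius_px = max_radius_px)
  lab <- nuclei$label_image
  all_cells <- lab > 0L | cyto > 0L
  px_size <- nuclei$pixel_size_um
  cells <- nuclei$cells
  n_lab <- max(cells$label, 0L)
  cyto_tab <- tabulate(cyto[cyto > 0L], nbins = n_lab)
  cells$cytoplasm_area_px <- as.integer(cyto_tab[cells$label])
  cells$cell_area_px <- cells$area_px + cells$cytoplasm_area_px
  cells$cell_area_um2 <- cells$cell_area_px * px_size^2
  dims <- dim(lab)
  pad <- width_px + gap_px
  own_px_list <- {
    idx <- which(lab > 0L | cyto > 0L)
    l <- pmax(lab[idx], cyto[idx])
    split(idx, l)
  }
  n_cells <- nrow(cells); n_mk <- length(factors)
  v_label <- integer(0); v_marker <- character(0)
  v_nm <- v_bg <- numeric(0); v_fb <- logical(0)
  img_medians <- vapply(images[names(factors)], median, numeric(1))
  for (li in cells$label) {
    own_px <- own_px_list[[as.character(li)]]
    rc <- arrayInd(own_px, dims)
    bb <- c(max(1L, min(rc[, 1]) - pad), min(dims[1], max(rc[, 1]) + pad),
            max(1L, min(rc[, 2]) - pad), min(dims[2], max(rc[, 2]) + pad))
    rr <- bb[1]:bb[2]; cc <- bb[3]:bb[4]
    own_w <- matrix(FALSE, length(rr), length(cc))
    own_w[cbind(rc[, 1] - bb[1] + 1L, rc[, 2] - bb[3] + 1L)] <- TRUE
    inner <- dilate_k(own_w, gap_px)
    ring <- dilate_k(inner, width_px) & !inner
    ring <- ring & !(all_cells[rr, cc, drop = FALSE] & !own_w)
    ring_idx <- which(ring)
    nuc_idx <- own_px[lab[own_px] == li]
    for (mk in names(factors)) {
      sub_img <- images[[mk]][rr, cc, drop = FALSE]
      fb <- length(ring_idx) == 0L
      bg <- if (fb) img_medians[[mk]] else mean(sub_img[ring_idx])
      v_label <- c(v_label, li); v_marker <- c(v_marker, mk)
      v_nm <- c(v_nm, mean(images[[mk]][nuc_idx])); v_bg <- c(v_bg, bg)
      v_fb <- c(v_fb, fb)
    }
  }
  calls <- tibble::tibble(
    label = v_label, marker = v_marker, nuclear_mean = v_nm,
    local_bg_mean = v_bg,
    factor_used = unname(factors[v_marker]),
    positive = v_nm > unname(factors[v_marker]) * v_bg,
    qc = ifelse(v_fb, "rim_fallback", NA_character_))
  structure(list(cells = cells, calls = calls, cytoplasm_image = cyto,
                 nuclei = nuclei),
            class = "cell_set")
}

#' @export
print.cell_set <- function(x, ...) {
  pos <- dplyr::summarise(dplyr::group_by(x$calls, .data$marker),
                          positive = sum(.data$positive), n = dplyr::n())
  cat("<cell_set> ", nrow(x$cells), " cells\n", sep = "")
  print(pos, ...)
  invisible(x)
}
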