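# EM48-ir inclusion detection: peak seeding, ring growth, size/shape/
# intensity filters, nuclear vs extranuclear compartment assignment.

#' Detect spot seeds as intensity peaks
#'
#' Finds candidate inclusion seeds on the background-filtered EM48 image:
#' 8-neighbourhood local maxima whose intensity strictly exceeds
#' `grow_factor` times the background level `bg` (the median of the whole
#' filtered image). Equal-valued plateau maxima yield a single representative,
#' the topmost-leftmost pixel. Seeds are returned sorted by descending
#' intensity, ties broken by (row, col).
#'
#' @param filtered_img EM48 channel after [subtract_background()] (curvature
#'   20 in the reference configuration).
#' @param bg Background level; by convention `median(filtered_img)`.
#' @param grow_factor Threshold multiple of `bg` (default 2).
#' @return Integer matrix with columns `row`, `col` (possibly zero rows).
#' @export
detect_seeds <- function(filtered_img, bg, grow_factor = 2) {
  assert_image(filtered_img, "filtered_img")
  nbr_max <- matrix(-Inf, nrow(filtered_img), ncol(filtered_img))
  for (o in list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1)))
    nbr_max <- pmax(nbr_max, shift_mat(filtered_img, o[1], o[2], -Inf))
  cand <- (filtered_img >= nbr_max) & (filtered_img > grow_factor * bg)
  if (!any(cand)) return(cbind(row = integer(), col = integer()))
  lab <- label_components(cand, conn = 8)
  idx <- which(lab > 0L)
  rc <- arrayInd(idx, dim(lab))
  ord <- order(lab[idx], rc[, 1], rc[, 2])
  first <- !duplicated(lab[idx][ord])
  reps <- idx[ord][first]
  rc <- arrayInd(reps, dim(lab))
  v <- filtered_img[reps]
  o <- order(-v, rc[, 1], rc[, 2])
  cbind(row = rc[o, 1], col = rc[o, 2])
}

#' Grow one spot from a seed
#'
#' Iterative frontier growth: starting from the seed, each step adds every
#' unclaimed pixel adjacent to the current object whose intensity strictly
#' exceeds `grow_factor * bg`, until no such pixel remains (or
#' `max_iterations`). Pixels already claimed by earlier spots are never
#' added, so spots grown in order are pairwise disjoint (first-seed-wins).
#' A seed at or below the threshold yields an empty set.
#'
#' @param filtered_img Background-filtered image.
#' @param seed Length-2 integer `(row, col)`.
#' @param bg Background level (median of the filtered image).
#' @param grow_factor Threshold multiple (default 2).
#' @param connectivity 4 or 8 (default 4: ring growth adds edge-adjacent
#'   pixels, keeping boundaries crisp).
#' @param claimed Logical matrix of pixels already owned by other spots.
#' @param max_iterations Safety cap on growth rounds.
#' @return Integer vector of linear pixel indices into the image.
#' @export
grow_spot <- function(filtered_img, seed, bg, grow_factor = 2,
                      connectivity = 4, claimed = NULL,
                      max_iterations = 10000L) {
  nr <- nrow(filtered_img); nc <- ncol(filtered_img)
  thr <- grow_factor * bg
  s <- (seed[2] - 1L) * nr + seed[1]
  if (!is.null(claimed) && claimed[s]) return(integer())
  if (filtered_img[s] <= thr) return(integer())
  # grow inside a local window (spots are small); if growth touches the
  # window border, restart with a doubled window, so the result is
  # identical to growing on the whole image
  half <- 12L
  repeat {
    r0 <- max(1L, seed[1] - half); r1 <- min(nr, seed[1] + half)
    c0 <- max(1L, seed[2] - half); c1 <- min(nc, seed[2] + half)
    wnr <- r1 - r0 + 1L; wnc <- c1 - c0 + 1L
    w <- filtered_img[r0:r1, c0:c1, drop = FALSE] > thr
    if (!is.null(claimed)) w <- w & !claimed[r0:r1, c0:c1, drop = FALSE]
    in_set <- matrix(FALSE, wnr, wnc)
    in_set[seed[1] - r0 + 1L, seed[2] - c0 + 1L] <- TRUE
    in_set <- dilate_k(in_set, max_iterations, connectivity, support = w)
    touches <- (r0 > 1L && any(in_set[1L, ])) || (r1 < nr && any(in_set[wnr, ])) ||
      (c0 > 1L && any(in_set[, 1L])) || (c1 < nc && any(in_set[, wnc]))
    if (!touches || (r0 == 1L && r1 == nr && c0 == 1L && c1 == nc)) {
      wi <- which(in_set, arr.ind = TRUE)
      return(unname((wi[, 2] + c0 - 2L) * nr + (wi[, 1] + r0 - 1L)))
    }
    half <- half * 2L
  }
}

#' Shape descriptors of a pixel set
#'
#' Computes the descriptors used by the inclusion filters:
#' * `area_px2` — pixel count;
#' * `roundness` — \eqn{4\pi A / P^2} with the perimeter \eqn{P} counted as
#'   pixel-edge segments on the region boundary (each pixel contributes
#'   4 minus its number of 4-neighbours in the set). With this convention a
#'   3x3 square has roundness \eqn{36\pi/144 \approx 0.785} and small
#'   discrete objects can exceed 1, which is why the upper gate is 1.2;
#' * `width_length_ratio` — minor/major axis of the second-moment best-fit
#'   ellipse (square root of the covariance eigenvalue ratio), 1 by
#'   convention for single pixels and degenerate moments;
#' * `centroid_row`, `centroid_col` — arithmetic mean of pixel coordinates
#'   (the "geometric center").
#'
#' @param pixels Integer linear indices (nonempty) into an image of
#'   dimensions `dims`, or a 2-column (row, col) matrix (then `dims` may be
#'   omitted).
#' @param dims Image dimensions when `pixels` is a linear index vector.
#' @return One-row tibble.
#' @export
shape_descriptors <- function(pixels, dims = NULL) {
  s <- shape_stats(pixels, dims)
  tibble::tibble(area_px2 = as.integer(s[["area_px2"]]),
                 roundness = s[["roundness"]],
                 width_length_ratio = s[["width_length_ratio"]],
                 centroid_row = s[["centroid_row"]],
                 centroid_col = s[["centroid_col"]])
}

# numeric-vector core of shape_descriptors (hot path)
shape_stats <- function(pixels, dims = NULL) {
  rc <- if (is.matrix(pixels)) pixels else {
    if (is.null(dims)) stop("dims required with linear indices", call. = FALSE)
    arrayInd(pixels, dims)
  }
  n <- nrow(rc)
  if (!n) stop("empty pixel set", call. = FALSE)
  # perimeter = pixel-edge segments: 4 edges per pixel minus shared edges,
  # counted on a small window mask
  r <- rc[, 1]; cl <- rc[, 2]
  r0 <- min(r); c0 <- min(cl)
  wr <- max(r) - r0 + 1L; wc <- max(cl) - c0 + 1L
  w <- matrix(FALSE, wr, wc)
  w[(cl - c0) * wr + (r - r0 + 1L)] <- TRUE
  nbr <- sum(w[-1L, , drop = FALSE] & w[-wr, , drop = FALSE]) * 2L +
    sum(w[, -1L, drop = FALSE] & w[, -wc, drop = FALSE]) * 2L
  per <- 4L * n - nbr
  roundness <- 4 * pi * n / per^2
  if (n == 1L) {
    ratio <- 1
  } else {
    mr <- mean(r); mc <- mean(cl)
    srr <- sum((r - mr)^2) / n; scc <- sum((cl - mc)^2) / n
    src <- sum((r - mr) * (cl - mc)) / n
    tr2 <- (srr + scc) / 2
    d <- sqrt(((srr - scc) / 2)^2 + src^2)
    l1 <- tr2 + d; l2 <- tr2 - d
    ratio <- if (l1 <= .Machine$double.eps) 1 else sqrt(max(l2, 0) / l1)
  }
  c(area_px2 = n, roundness = roundness, width_length_ratio = ratio,
    centroid_row = mean(r), centroid_col = mean(cl))
}

#' Filter candidate spots into inclusions
#'
#' Applies the inclusion definition: area strictly larger than 5 px²,
#' roundness in \[0.5, 1.2\], width/length ratio above 0.4, and mean raw
#' (unfiltered) intensity at least twice the mean spot intensity of the
#' candidate pool (see `spot_mean_reference`). All gates are
#' deterministic.
#'
#' @param candidates List of pixel-index vectors (grown spots).
#' @param unfiltered_img Raw EM48 matrix.
#' @param min_area_px2 Strict lower area bound (default 5: a 5-px² object is
#'   excluded, 6 px² kept).
#' @param roundness_range Inclusive roundness gate (default `c(0.5, 1.2)`).
#' @param min_ratio Strict lower width/length gate (default 0.4).
#' @param intensity_factor Multiple of the candidate-pool mean intensity a
#'   spot's mean raw intensity must reach (default 2).
#' @param spot_mean_reference Referent of the "mean spot intensity"
#'   comparator: `"spots"` (default) averages the per-candidate mean
#'   intensities, so the comparator tracks the dim diffuse-texture
#'   candidates that dominate by count and detection stays stable as the
#'   inclusion burden grows; `"pixels"` pools all candidate pixels, which
#'   weights large bright inclusions and can reject dim true inclusions
#'   in heavily burdened tissue.
#' @return Tibble of retained spots with shape descriptors and
#'   `mean_intensity_unfiltered`, plus a `pixels` list-column.
#' @export
filter_spots <- function(candidates, unfiltered_img, min_area_px2 = 5,
                         roundness_range = c(0.5, 1.2), min_ratio = 0.4,
                         intensity_factor = 2,
                         spot_mean_reference = c("spots", "pixels")) {
  spot_mean_reference <- match.arg(spot_mean_reference)
  keep0 <- lengths(candidates) > 0
  candidates <- candidates[keep0]
  if (!length(candidates)) return(empty_spot_tbl())
  cand_ids <- which(keep0)
  means <- vapply(candidates, function(px) mean(unfiltered_img[px]), numeric(1))
  ref <- if (spot_mean_reference == "pixels") {
    mean(unfiltered_img[unlist(candidates, use.names = FALSE)])
  } else mean(means)  # per-candidate means, equally weighted
  # the area gate is independent of the others, so shape descriptors are
  # only computed for candidates that can still pass
  big <- lengths(candidates) > min_area_px2
  if (!any(big)) return(empty_spot_tbl())
  st <- unname(vapply(candidates[big], shape_stats, numeric(5),
                      dims = dim(unfiltered_img)))
  desc <- tibble::tibble(
    area_px2 = as.integer(st[1, ]),
    roundness = st[2, ],
    width_length_ratio = st[3, ],
    centroid_row = st[4, ],
    centroid_col = st[5, ])
  desc$mean_intensity_unfiltered <- means[big]
  desc$pixels <- candidates[big]
  desc$candidate_id <- cand_ids[big]
  keep <- desc$roundness >= roundness_range[1] & desc$roundness <= roundness_range[2] &
    desc$width_length_ratio > min_ratio &
    desc$mean_intensity_unfiltered >= intensity_factor * ref
  desc[keep, , drop = FALSE]
}

empty_spot_tbl <- function() {
  tibble::tibble(area_px2 = integer(), roundness = numeric(),
                 width_length_ratio = numeric(), centroid_row = numeric(),
                 centroid_col = numeric(),
                 mean_intensity_unfiltered = numeric(), pixels = list(),
                 candidate_id = integer())
}

#' Assign a spot to the nuclear or extranuclear compartment
#'
#' The spot's geometric center, rounded to its containing pixel, decides the
#' compartment: inside a nucleus mask it is `nuclear`; inside the 9-px-wide
#' chessboard ring outside a nucleus border it is `extranuclear` (rings
#' contested between nuclei go to the Euclidean-nearest nucleus, ties to the
#' lower label); otherwise `unassigned` with no owner.
#'
#' @param centroid Numeric `(row, col)`.
#' @param nuclei A `nucleus_set`.
#' @param ring_width_px Ring width in chessboard pixels (default 9).
#' @param .cache Precomputed nucleus geometry (internal, for batch calls).
#' @return List with `compartment` and `owner_cell` (label or `NA`).
#' @export
assign_compartment <- function(centroid, nuclei, ring_width_px = 9,
                               .cache = NULL) {
  lab <- nuclei$label_image
  r <- round_px(centroid[1]); c <- round_px(centroid[2])
  r <- min(max(r, 1L), nrow(lab)); c <- min(max(c, 1L), ncol(lab))
  if (lab[r, c] > 0L)
    return(list(compartment = "nuclear", owner_cell = as.integer(lab[r, c])))
  if (is.null(.cache)) .cache <- nucleus_geometry_cache(nuclei)
  if (!length(.cache$labels))
    return(list(compartment = "unassigned", owner_cell = NA_integer_))
  # candidate nuclei whose bounding box (padded by the ring) contains the pixel
  bb <- .cache$bbox
  cand <- which(r >= bb[, 1] - ring_width_px & r <= bb[, 2] + ring_width_px &
                c >= bb[, 3] - ring_width_px & c <= bb[, 4] + ring_width_px)
  best <- NULL; best_d2 <- Inf
  for (i in cand) {
    rc <- .cache$rc[[i]]
    cheb <- min(pmax(abs(rc[, 1] - r), abs(rc[, 2] - c)))
    if (cheb > ring_width_px) next
    d2 <- min((rc[, 1] - r)^2 + (rc[, 2] - c)^2)
    li <- .cache$labels[i]
    if (d2 < best_d2 || (d2 == best_d2 && (is.null(best) || li < best))) {
      best <- li; best_d2 <- d2
    }
  }
  if (is.null(best)) return(list(compartment = "unassigned", owner_cell = NA_integer_))
  list(compartment = "extranuclear", owner_cell = best)
}

nucleus_geometry_cache <- function(nuclei) {
  nuc_px <- nucleus_pixels(nuclei)
  dims <- dim(nuclei$label_image)
  rc <- lapply(nuc_px, arrayInd, .dim = dims)
  bbox <- if (length(rc)) {
    t(vapply(rc, function(m) c(min(m[, 1]), max(m[, 1]), min(m[, 2]), max(m[, 2])),
             numeric(4)))
  } else matrix(numeric(), 0, 4)
  list(labels = as.integer(names(nuc_px)), rc = rc, bbox = bbox)
}

#' Detect EM48-ir inclusions in a raw image
#'
#' Full inclusion chain: sliding-parabola background removal (curvature 20),
#' peak seeding above twice the filtered-image median, first-seed-wins ring
#' growth, size/shape/intensity filtering, and compartment assignment
#' against the detected nuclei. All thresholds are relative (median-based),
#' so rescaling every intensity by a positive constant leaves the detected
#' pixel sets unchanged.
#'
#' @param raw_em48_img Raw EM48 channel matrix.
#' @param nuclei A `nucleus_set` (for compartments; may have zero nuclei).
#' @param curvature Parabola curvature (default 20).
#' @param grow_factor Seed/growth threshold multiple of the filtered-image
#'   median (default 2).
#' @param connectivity Growth connectivity, 4 or 8 (default 8).
#' @param ring_width_px Extranuclear ring width (default 9).
#' @param pixel_size_um Micrometres per pixel (default taken from `nuclei`).
#' @inheritParams filter_spots
#' @return A `spot_set`: list with `spots` tibble (one row per inclusion:
#'   id, areas in px² and um², shape, intensity, compartment, owner cell,
#'   seed, `pixels` list-column) and the `filtered` image.
#' @examples
#' sc <- render_scene(scene_spec(n_nuclei = 6, shape = c(160, 160),
#'                               nuclear_rate = 1), seed = 2)
#' nuc <- detect_nuclei(sc$channels$dapi)
#' detect_inclusions(sc$channels$em48, nuc)$spots
#' @export
detect_inclusions <- function(raw_em48_img, nuclei, curvature = 20,
                              grow_factor = 2, connectivity = 4,
                              ring_width_px = 9, min_area_px2 = 5,
                              roundness_range = c(0.5, 1.2), min_ratio = 0.4,
                              intensity_factor = 2,
                              spot_mean_reference = "spots",
                              pixel_size_um = NULL) {
  assert_image(raw_em48_img, "raw_em48_img")
  if (is.null(pixel_size_um))
    pixel_size_um <- if (!is.null(nuclei$pixel_size_um)) nuclei$pixel_size_um else 0.32
  filt <- subtract_background(raw_em48_img, curvature)
  bg <- median(filt)
  seeds <- detect_seeds(filt, bg, grow_factor)
  # Sequential first-seed-wins growth is equivalent to taking, for each
  # connected component of the above-threshold mask, the whole component
  # for the first (highest-priority) seed it contains: a later seed in the
  # same component finds its pixel claimed and grows nothing. Components
  # are computed once, which is much faster than per-seed flood fill and
  # bitwise identical (grow_spot remains the per-seed reference).
  grown <- list(); seed_list <- list()
  if (nrow(seeds)) {
    mask <- filt > grow_factor * bg
    complab <- label_components(mask, conn = connectivity)
    comp_px <- split(which(complab > 0L), complab[complab > 0L])
    seed_comp <- complab[cbind(seeds[, 1], seeds[, 2])]
    first <- !duplicated(seed_comp) & seed_comp > 0L
    grown <- comp_px[as.character(seed_comp[first])]
    seed_list <- lapply(which(first), function(i) seeds[i, ])
  }
  spots <- filter_spots(grown, raw_em48_img, min_area_px2, roundness_range,
                        min_ratio, intensity_factor,
                        spot_mean_reference = spot_mean_reference)
  seed_tbl <- do.call(rbind, seed_list)
  if (nrow(spots)) {
    kept_idx <- spots$candidate_id
    spots$seed_row <- seed_tbl[kept_idx, 1]
    spots$seed_col <- seed_tbl[kept_idx, 2]
    geom <- nucleus_geometry_cache(nuclei)
    comp <- purrr::map(seq_len(nrow(spots)), function(i)
      assign_compartment(c(spots$centroid_row[i], spots$centroid_col[i]),
                         nuclei, ring_width_px, .cache = geom))
    spots$compartment <- vapply(comp, `[[`, "", "compartment")
    spots$owner_cell <- vapply(comp, `[[`, integer(1), "owner_cell")
  } else {
    spots$seed_row <- integer(); spots$seed_col <- integer()
    spots$compartment <- character(); spots$owner_cell <- integer()
  }
  spots$area_um2 <- spots$area_px2 * pixel_size_um^2
  spots$candidate_id <- NULL
  spots <- tibble::add_column(spots, spot_id = seq_len(nrow(spots)), .before = 1)
  structure(list(spots = spots, filtered = filt, background = bg,
                 pixel_size_um = pixel_size_um),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat("<spot_set> ", nrow(x$spots), " inclusions (",
      sum(x$spots$compartment == "nuclear"), " nuclear, ",
      sum(x$spots$compartment == "extranuclear"), " extranuclear)\n", sep = "")
  print(dplyr::select(x$spots, -"pixels"), ...)
  invisible(x)
}
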