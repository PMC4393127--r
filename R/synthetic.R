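# Seeded synthetic tissue-section scenes with full ground truth, so every
# pipeline stage can be validated without real tissue.
#
# Intensities are on a 16-bit-like scale (nuclei ~3000 counts over a ~200
# base) so that the default parabola curvatures (5 for DAPI, 20 for EM48)
# relate to feature widths the way they do on real high-content images.

#' Specify a synthetic tissue-section scene
#'
#' Collects every knob of the scene generator with defaults that emulate a
#' striatal field at 0.32 um/px: hard-edged elliptical nuclei of 400–900 px²
#' with multiplicative DAPI texture, perinuclear marker-positive cytoplasm
#' for a configurable fraction of cells, compact bright EM48-ir inclusions
#' planted per cell at Poisson rates in nuclear and perinuclear
#' compartments, optional sub-resolution nuclear micropuncta (Gaussian,
#' sigma ~1 px), a smooth second-order polynomial background, and Gaussian
#' (optionally Poisson) noise. Nuclei and inclusions are rendered with sharp
#' boundaries so the planted pixel count is an exact ground-truth area;
#' micropuncta are Gaussians so sub-resolution structure is continuously
#' controllable.
#'
#' @param shape Image shape `c(nrow, ncol)` (default 384 x 384).
#' @param pixel_size_um Micrometres per pixel (default 0.32).
#' @param n_nuclei Number of nuclei to place (default 50).
#' @param nucleus_area_range Target nucleus areas, px² (default 400–900).
#' @param min_separation_px Minimum edge-to-edge nucleus separation.
#' @param dapi_base,dapi_intensity,dapi_texture_sd DAPI baseline, nuclear
#'   amplitude, and multiplicative within-nucleus texture.
#' @param markers Named list of `list(fraction, contrast)` per marker
#'   channel; default 90% DARPP-32 positive at 3x contrast.
#' @param marker_base Marker-channel background level (the "local
#'   background" a positive nucleus must exceed).
#' @param cytoplasm_width_px Width of the rendered perinuclear annulus.
#' @param nuclear_rate,extranuclear_rate Poisson mean inclusions per
#'   marker-positive cell in each compartment.
#' @param unassigned_rate Expected count of far-from-any-nucleus spots per
#'   scene (for compartment testing; default 0).
#' @param spot_area_range Inclusion areas, px² (default 8–40).
#' @param spot_amplitude_range Inclusion amplitudes above background.
#' @param spot_margin_px Minimum chessboard distance of planted spot
#'   centers from compartment borders (default 2).
#' @param spot_min_gap_px Minimum edge-to-edge gap between planted spots
#'   (center separation at least the sum of semi-major axes plus this).
#' @param em48_base,em48_diffuse_nuclear EM48 baseline and diffuse nuclear
#'   level (the substrate of the granularity index).
#' @param speckle_density,speckle_amplitude,speckle_sigma_px Dense dim
#'   EM48 tissue speckle: fraction of pixels hosting a sub-resolution
#'   punctum, its amplitude range, and Gaussian sigma. This diffuse
#'   punctate texture dominates the spot-candidate pool the way diffuse
#'   EM48-ir staining does in tissue, which is what makes the relative
#'   (2x candidate-mean) intensity filter select only bright inclusions.
#' @param micropuncta_per_nucleus,micropunctum_amplitude,micropunctum_sigma_px
#'   Sub-resolution punctum count, amplitude, and Gaussian sigma.
#' @param mab_base,mab_cyto_intensity Pan-HTT (MAB2174) baseline and
#'   cytoplasmic amplitude; scale `mab_cyto_intensity` to emulate knockdown.
#' @param background_amplitude Amplitude of the smooth polynomial shading.
#' @param noise_sd,poisson_noise Gaussian noise SD and optional Poisson
#'   shot noise. Gaussian noise is smoothed with a sigma
#'   `noise_correlation_px` kernel (then rescaled back to `noise_sd`) to
#'   mimic the spatial correlation the optical point-spread function
#'   imposes on real camera noise.
#' @param noise_correlation_px PSF-like correlation scale of the noise.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(shape = c(384, 384), pixel_size_um = 0.32,
                       n_nuclei = 50, nucleus_area_range = c(400, 900),
                       min_separation_px = 3,
                       dapi_base = 200, dapi_intensity = 3000,
                       dapi_texture_sd = 0.05,
                       markers = list(DARPP32 = list(fraction = 0.9, contrast = 3)),
                       marker_base = 400, cytoplasm_width_px = 5,
                       nuclear_rate = 0.5, extranuclear_rate = 0.2,
                       unassigned_rate = 0,
                       spot_area_range = c(8, 40),
                       spot_amplitude_range = c(4500, 6500),
                       spot_margin_px = 2, spot_min_gap_px = 2,
                       em48_base = 150, em48_diffuse_nuclear = 100,
                       speckle_density = 0.6,
                       speckle_amplitude = c(180, 260),
                       speckle_sigma_px = 0.6,
                       micropuncta_per_nucleus = 0,
                       micropunctum_amplitude = 800,
                       micropunctum_sigma_px = 1,
                       mab_base = 300, mab_cyto_intensity = 1000,
                       background_amplitude = 300,
                       noise_sd = 10, poisson_noise = FALSE,
                       noise_correlation_px = 0) {
  spec <- as.list(environment())
  stopifnot(all(c(spec$nuclear_rate, spec$extranuclear_rate,
                  spec$unassigned_rate) >= 0),
            spec$min_separation_px >= 0, spec$n_nuclei >= 0)
  structure(spec, class = "scene_spec")
}

#' Render a synthetic scene with ground truth
#'
#' Draws a full multichannel field from a [scene_spec()]: places nuclei by
#' rejection sampling at the requested separation (erroring after bounded
#' retries if the packing is infeasible), renders DAPI / marker / EM48 /
#' MAB2174 channels, and returns exact truth tables for every planted
#' object. Rendering is fully determined by `seed`; the same seed gives an
#' identical scene.
#'
#' @param spec A `scene_spec`.
#' @param seed Integer RNG seed, recorded in the truth output.
#' @param channels Channel names to render (default all). Dropping
#'   `mab2174` leaves every other channel identical for the same seed.
#' @return An `htt_scene`: list with `channels` (named list of matrices:
#'   `dapi`, one per marker, `em48`, `mab2174`), `truth` (list of tibbles:
#'   `nuclei`, `cells`, `spots`, `micropuncta`, plus the planted
#'   `nucleus_label_image`), `spec`, `seed`.
#' @export
render_scene <- function(spec, seed = 1L, channels = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(seed)
  nr <- spec$shape[1]; nc <- spec$shape[2]
  nuc <- place_nuclei(spec)
  lab <- nuc$label_image
  any_nuc <- lab > 0L
  bgpoly <- smooth_background(nr, nc, spec$background_amplitude)

  dapi <- matrix(spec$dapi_base, nr, nc) + bgpoly
  if (nrow(nuc$nuclei)) {
    idx <- which(any_nuc)
    dapi[idx] <- dapi[idx] +
      spec$dapi_intensity * (1 + rnorm(length(idx), 0, spec$dapi_texture_sd))
  }

  # marker positivity per cell, cytoplasm annuli
  cells <- tibble::tibble(label = nuc$nuclei$label)
  annulus <- if (nrow(nuc$nuclei)) dilate_k(any_nuc, spec$cytoplasm_width_px) & !any_nuc
             else any_nuc
  marker_imgs <- list()
  for (mk in names(spec$markers)) {
    frac <- spec$markers[[mk]]$fraction
    contrast <- spec$markers[[mk]]$contrast
    pos <- runif(nrow(cells)) < frac
    cells[[paste0(mk, "_pos")]] <- pos
    img <- matrix(spec$marker_base, nr, nc) + bgpoly
    if (any(pos)) {
      pos_nuc <- matrix(lab %in% cells$label[pos], nr, nc)
      cell <- dilate_k(pos_nuc, spec$cytoplasm_width_px) & (pos_nuc | !any_nuc)
      img[cell] <- img[cell] + spec$marker_base * (contrast - 1)
    }
    marker_imgs[[mk]] <- img
  }

  em48 <- matrix(spec$em48_base, nr, nc) + bgpoly
  if (nrow(nuc$nuclei) && spec$em48_diffuse_nuclear > 0)
    em48[any_nuc] <- em48[any_nuc] + spec$em48_diffuse_nuclear
  if (spec$speckle_density > 0) {
    n_sp <- round(spec$speckle_density * nr * nc)
    deposit <- matrix(0, nr, nc)
    at <- sample.int(nr * nc, n_sp)
    # peak of the discrete blur kernel, so deposited amplitudes land as peaks
    pk <- max(gaussian_blur(matrix(c(rep(0, 40), 1, rep(0, 40)), 9, 9),
                            spec$speckle_sigma_px))
    deposit[at] <- runif(n_sp, spec$speckle_amplitude[1],
                         spec$speckle_amplitude[2]) / pk
    em48 <- em48 + gaussian_blur(deposit, spec$speckle_sigma_px)
  }

  # inclusion carriers: cells positive for the first marker, else all
  carrier <- if (length(spec$markers)) cells[[paste0(names(spec$markers)[1], "_pos")]]
             else rep(TRUE, nrow(cells))
  planted <- plant_spots(spec, nuc, carrier)
  if (nrow(planted$spots)) {
    for (i in seq_len(nrow(planted$spots)))
      em48[planted$spots$pixels[[i]]] <- em48[planted$spots$pixels[[i]]] +
        planted$spots$amplitude[i]
  }

  # sub-resolution micropuncta
  mp <- tibble::tibble(label = cells$label,
                       n_puncta = rep(0L, nrow(cells)))
  if (spec$micropuncta_per_nucleus > 0 && nrow(nuc$nuclei)) {
    for (j in seq_len(nrow(nuc$nuclei))) {
      own <- lab == nuc$nuclei$label[j]
      interior <- which(!dilate_k(!own, 2L), arr.ind = TRUE)
      if (!nrow(interior)) next
      k <- spec$micropuncta_per_nucleus
      pick <- interior[sample.int(nrow(interior), k, replace = TRUE), , drop = FALSE]
      jit <- matrix(runif(2 * k, -0.5, 0.5), ncol = 2)
      em48 <- add_gaussians(em48, pick + jit, spec$micropunctum_amplitude,
                            spec$micropunctum_sigma_px)
      mp$n_puncta[j] <- k
    }
  }

  want_mab <- is.null(channels) || "mab2174" %in% channels
  mab <- NULL
  if (want_mab) {
    mab <- matrix(spec$mab_base, nr, nc) + bgpoly
    if (any(annulus)) mab[annulus] <- mab[annulus] + spec$mab_cyto_intensity
    if (any(any_nuc)) mab[any_nuc] <- mab[any_nuc] + spec$mab_cyto_intensity * 0.3
  }

  channels <- c(list(dapi = dapi), marker_imgs, list(em48 = em48),
                if (want_mab) list(mab2174 = mab))
  channels <- lapply(channels, function(img) {
    if (spec$poisson_noise) img <- matrix(rpois(length(img), pmax(img, 0)), nr, nc)
    if (spec$noise_sd > 0) {
      n <- matrix(rnorm(length(img)), nr, nc)
      if (spec$noise_correlation_px > 0) {
        n <- gaussian_blur(n, spec$noise_correlation_px)
        n <- n / sd(n)
      }
      img <- img + spec$noise_sd * n
    }
    pmax(img, 0)
  })
  structure(list(
    channels = channels,
    truth = list(nuclei = nuc$nuclei, cells = cells, spots = planted$spots,
                 micropuncta = mp, nucleus_label_image = lab, seed = seed),
    spec = spec, seed = seed), class = "htt_scene")
}

#' @export
print.htt_scene <- function(x, ...) {
  cat("<htt_scene> ", paste(x$spec$shape, collapse = " x "), " px, ",
      nrow(x$truth$nuclei), " nuclei, ", nrow(x$truth$spots),
      " planted inclusions, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# -- internals ---------------------------------------------------------------

place_nuclei <- function(spec) {
  nr <- spec$shape[1]; nc <- spec$shape[2]
  lab <- matrix(0L, nr, nc)
  n <- spec$n_nuclei
  v_r <- v_c <- v_a <- v_b <- v_t <- numeric(n); v_area <- integer(n)
  tries <- 0L; max_tries <- 300L * max(n, 1L)
  li <- 0L
  while (li < n) {
    if (tries > max_tries)
      stop("infeasible nucleus packing: placed ", li, " of ", n, call. = FALSE)
    tries <- tries + 1L
    area <- runif(1, spec$nucleus_area_range[1], spec$nucleus_area_range[2])
    ecc <- runif(1, 0.7, 1)
    a <- sqrt(area / (pi * ecc)); b <- a * ecc
    theta <- runif(1, 0, pi)
    r0 <- runif(1, a + 2, nr - a - 2); c0 <- runif(1, a + 2, nc - a - 2)
    if (li > 0L) {
      d <- sqrt((v_r[1:li] - r0)^2 + (v_c[1:li] - c0)^2)
      if (any(d < v_a[1:li] + a + spec$min_separation_px)) next
    }
    li <- li + 1L
    px <- ellipse_pixels(r0, c0, a, b, theta, nr, nc)
    lab[px] <- li
    v_r[li] <- r0; v_c[li] <- c0; v_a[li] <- a; v_b[li] <- b; v_t[li] <- theta
    v_area[li] <- length(px)
  }
  list(nuclei = tibble::tibble(label = seq_len(li), center_row = v_r,
                               center_col = v_c, a = v_a, b = v_b,
                               theta = v_t, area_px = v_area),
       label_image = lab)
}

# linear indices of an ellipse rasterized at pixel centers
ellipse_pixels <- function(r0, c0, a, b, theta, nr, nc) {
  rr <- max(1L, floor(r0 - a)):min(nr, ceiling(r0 + a))
  cc <- max(1L, floor(c0 - a)):min(nc, ceiling(c0 + a))
  dr <- outer(rr - r0, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - c0)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  (cc[idx[, 2]] - 1L) * nr + rr[idx[, 1]]
}

smooth_background <- function(nr, nc, amplitude) {
  if (amplitude <= 0) return(matrix(0, nr, nc))
  u <- matrix(seq(0, 1, length.out = nr), nr, nc)
  v <- matrix(seq(0, 1, length.out = nc), nr, nc, byrow = TRUE)
  co <- runif(5, -1, 1)
  f <- co[1] * u + co[2] * v + co[3] * u * v + co[4] * u^2 + co[5] * v^2
  f <- f - min(f)
  if (max(f) > 0) f <- f / max(f)
  amplitude * f
}

add_gaussians <- function(img, centers, amplitude, sigma) {
  nr <- nrow(img); nc <- ncol(img)
  r <- ceiling(4 * sigma)
  for (i in seq_len(nrow(centers))) {
    rr <- max(1L, floor(centers[i, 1] - r)):min(nr, ceiling(centers[i, 1] + r))
    cc <- max(1L, floor(centers[i, 2] - r)):min(nc, ceiling(centers[i, 2] + r))
    d2 <- outer((rr - centers[i, 1])^2, rep(1, length(cc))) +
      outer(rep(1, length(rr)), (cc - centers[i, 2])^2)
    img[rr, cc] <- img[rr, cc] + amplitude * exp(-d2 / (2 * sigma^2))
  }
  img
}

# Plant nuclear / extranuclear / unassigned inclusions with margins that
# keep planted compartment labels unambiguous.
plant_spots <- function(spec, nuc, carrier) {
  nr <- spec$shape[1]; nc <- spec$shape[2]
  lab <- nuc$label_image
  any_nuc <- lab > 0L
  claimed <- matrix(FALSE, nr, nc)
  out <- list()
  add_spot <- function(cand_fn, owner, compartment) {
    # cand_fn(a): linear indices of centers admissible for a spot of
    # semi-major axis a. Shapes are resampled until the rasterized object
    # passes the inclusion shape gates with margin: planted inclusions are
    # round by construction, so recovery measures detection fidelity
    # rather than rasterization artifacts of the discrete roundness
    # convention.
    for (try in 1:60) {
      # crowded neighbourhoods: later retries sample smaller areas so a
      # planted count is almost never dropped, at the cost of a mild
      # small-size bias in crowded nuclei
      hi <- if (try <= 30) spec$spot_area_range[2] else
        spec$spot_area_range[1] +
          0.3 * (spec$spot_area_range[2] - spec$spot_area_range[1])
      area <- runif(1, spec$spot_area_range[1], hi)
      ecc <- runif(1, 0.85, 1)
      a <- sqrt(area / (pi * ecc)); b <- a * ecc
      theta <- runif(1, 0, pi)
      center_cands <- cand_fn(a)
      if (!length(center_cands)) next
      ci <- center_cands[sample.int(length(center_cands), 1)]
      p <- arrayInd(ci, c(nr, nc))
      if (length(out)) {
        prev <- do.call(rbind, lapply(out, function(s)
          c(s$center_row, s$center_col, s$semi_major)))
        if (min(sqrt((prev[, 1] - p[1])^2 + (prev[, 2] - p[2])^2) -
                prev[, 3]) < a + spec$spot_min_gap_px) next
      }
      px <- ellipse_pixels(p[1], p[2], a, b, theta, nr, nc)
      if (length(px) < 7 || any(claimed[px])) next
      sh <- shape_stats(px, c(nr, nc))
      if (sh[["roundness"]] < 0.55 || sh[["roundness"]] > 1.15 ||
          sh[["width_length_ratio"]] <= 0.45) next
      claimed[px] <<- TRUE
      rc <- arrayInd(px, c(nr, nc))
      s <- list(owner = owner, compartment = compartment,
                semi_major = a,
                center_row = p[1], center_col = p[2],
                centroid_row = mean(rc[, 1]), centroid_col = mean(rc[, 2]),
                area_px2 = length(px),
                amplitude = runif(1, spec$spot_amplitude_range[1],
                                  spec$spot_amplitude_range[2]),
                pixels = px)
      out[[length(out) + 1L]] <<- s
      return(s)
    }
    NULL
  }
  max_rad <- ceiling(sqrt(spec$spot_area_range[2] / pi)) + 1L
  if (nrow(nuc$nuclei)) {
    for (j in seq_len(nrow(nuc$nuclei))) {
      if (!carrier[j]) next
      li <- nuc$nuclei$label[j]
      own <- lab == li
      n_in <- rpois(1, spec$nuclear_rate)
      if (n_in > 0) {
        bb <- mask_bbox(own, pad = 1L)
        w <- own[bb["r0"]:bb["r1"], bb["c0"]:bb["c1"], drop = FALSE]
        core_cache <- list()
        cand_fn <- function(a) {
          k <- as.character(ceiling(a) + spec$spot_margin_px)
          if (is.null(core_cache[[k]])) {
            core <- !dilate_k(!w, as.integer(k))
            wi <- which(core, arr.ind = TRUE)
            core_cache[[k]] <<- if (nrow(wi))
              (wi[, 2] + bb["c0"] - 2L) * nr + (wi[, 1] + bb["r0"] - 1L)
            else integer()
          }
          core_cache[[k]]
        }
        for (k in seq_len(n_in)) add_spot(cand_fn, li, "nuclear")
      }
      n_out <- rpois(1, spec$extranuclear_rate)
      if (n_out > 0) {
        bb <- mask_bbox(own, pad = 20L)
        w <- own[bb["r0"]:bb["r1"], bb["c0"]:bb["c1"], drop = FALSE]
        others <- (any_nuc & lab != li)[bb["r0"]:bb["r1"], bb["c0"]:bb["c1"], drop = FALSE]
        ring <- dilate_k(w, 7L) & !dilate_k(w, 2L) & !dilate_k(others, 11L)
        wi <- which(ring, arr.ind = TRUE)
        if (!nrow(wi)) next
        cands <- (wi[, 2] + bb["c0"] - 2L) * nr + (wi[, 1] + bb["r0"] - 1L)
        for (k in seq_len(n_out)) add_spot(function(a) cands, li, "extranuclear")
      }
    }
  }
  n_un <- if (spec$unassigned_rate > 0) rpois(1, spec$unassigned_rate) else 0L
  if (n_un > 0) {
    far <- !dilate_k(any_nuc, 9L + spec$spot_margin_px + max_rad)
    far[c(1:(max_rad + 1), (nr - max_rad):nr), ] <- FALSE
    far[, c(1:(max_rad + 1), (nc - max_rad):nc)] <- FALSE
    cands <- which(far)
    for (k in seq_len(n_un)) add_spot(function(a) cands, NA_integer_, "unassigned")
  }
  spots <- if (length(out)) {
    tibble::tibble(
      spot_id = seq_along(out),
      owner = vapply(out, function(s) as.integer(s$owner), integer(1)),
      compartment = vapply(out, `[[`, "", "compartment"),
      center_row = vapply(out, `[[`, numeric(1), "center_row"),
      center_col = vapply(out, `[[`, numeric(1), "center_col"),
      centroid_row = vapply(out, `[[`, numeric(1), "centroid_row"),
      centroid_col = vapply(out, `[[`, numeric(1), "centroid_col"),
      area_px2 = vapply(out, `[[`, integer(1), "area_px2"),
      amplitude = vapply(out, `[[`, numeric(1), "amplitude"),
      pixels = lapply(out, `[[`, "pixels"))
  } else {
    tibble::tibble(spot_id = integer(), owner = integer(),
                   compartment = character(), center_row = numeric(),
                   center_col = numeric(), centroid_row = numeric(),
                   centroid_col = numeric(), area_px2 = integer(),
                   amplitude = numeric(), pixels = list())
  }
  list(spots = spots)
}

#' The striatal inclusion time course used as the default age series
#'
#' Per-cell nuclear inclusion rates in striatal medium spiny neurons across
#' age (months), with between-animal standard deviations, and plausible mean
#' inclusion areas used when planting an age series. The rate trajectory is
#' strictly increasing and plateaus at the oldest age.
#'
#' @return Tibble with `age_months`, `rate`, `rate_sd`, `mean_area_px2`.
#' @export
striatal_trajectory <- function() {
  tibble::tibble(
    age_months = c(3, 4, 6, 8, 12),
    rate = c(0.059, 0.24, 0.55, 0.96, 1.084),
    rate_sd = c(0.026, 0.094, 0.078, 0.058, 0.072),
    mean_area_px2 = c(8, 12, 18, 26, 32))
}

#' Render an age series of scenes
#'
#' One scene per "age", each planting the requested per-cell nuclear
#' inclusion rate and mean inclusion size; defaults follow
#' [striatal_trajectory()]. Lists must have equal length.
#'
#' @param base A `scene_spec` used for everything except rates/sizes.
#' @param rates Per-cell nuclear inclusion rates, one per age.
#' @param sizes Mean inclusion areas (px²), one per age (or `NULL` to keep
#'   the base range).
#' @param seeds Integer seeds, one per age.
#' @param ages Optional age labels.
#' @return List of `htt_scene` objects with `age` and nominal `rate` fields.
#' @export
age_series <- function(base = scene_spec(),
                       rates = striatal_trajectory()$rate,
                       sizes = striatal_trajectory()$mean_area_px2,
                       seeds = seq_along(rates),
                       ages = NULL) {
  if (!is.null(sizes) && length(sizes) != length(rates))
    stop("rates and sizes differ in length", call. = FALSE)
  if (length(seeds) != length(rates))
    stop("rates and seeds differ in length", call. = FALSE)
  if (is.null(ages)) ages <- paste0("age", seq_along(rates))
  purrr::map(seq_along(rates), function(i) {
    sp <- base
    sp$nuclear_rate <- rates[i]
    if (!is.null(sizes))
      sp$spot_area_range <- c(max(4, 0.6 * sizes[i]), 1.4 * sizes[i])
    sc <- render_scene(sp, seed = seeds[i])
    sc$age <- ages[i]
    sc$nominal_rate <- rates[i]
    sc
  })
}
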