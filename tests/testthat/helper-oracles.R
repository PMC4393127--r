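# Brute-force oracles, independent of the implementation paths they check.

# Grayscale opening with the paraboloid structuring function, by explicit
# double loops over every pixel pair (erosion then dilation).
oracle_parabola_opening <- function(img, curvature) {
  n <- nrow(img); m <- ncol(img)
  ero <- matrix(0, n, m); dil <- matrix(0, n, m)
  for (r in 1:n) for (c in 1:m) {
    best <- Inf
    for (q in 1:n) for (p in 1:m)
      best <- min(best, img[q, p] + curvature * ((q - r)^2 + (p - c)^2))
    ero[r, c] <- best
  }
  for (r in 1:n) for (c in 1:m) {
    best <- -Inf
    for (q in 1:n) for (p in 1:m)
      best <- max(best, ero[q, p] - curvature * ((q - r)^2 + (p - c)^2))
    dil[r, c] <- best
  }
  dil
}

# Constrained flood fill from a seed over pixels with value > thr and not
# claimed, by an explicit queue.
oracle_flood_fill <- function(img, seed, thr, connectivity = 4,
                              claimed = NULL) {
  n <- nrow(img); m <- ncol(img)
  if (is.null(claimed)) claimed <- matrix(FALSE, n, m)
  s <- (seed[2] - 1L) * n + seed[1]
  if (claimed[s] || img[s] <= thr) return(integer())
  offs <- if (connectivity == 8) {
    list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  } else list(c(-1,0), c(1,0), c(0,-1), c(0,1))
  seen <- matrix(FALSE, n, m)
  seen[seed[1], seed[2]] <- TRUE
  queue <- list(seed)
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (o in offs) {
      q <- p + o
      if (q[1] < 1 || q[1] > n || q[2] < 1 || q[2] > m) next
      if (seen[q[1], q[2]] || claimed[q[1], q[2]]) next
      if (img[q[1], q[2]] > thr) { seen[q[1], q[2]] <- TRUE; queue <- c(queue, list(q)) }
    }
  }
  which(seen)
}

# Chessboard ring pixels at gap/width around a region, by enumeration over
# all pixels using Chebyshev distance to the region.
oracle_ring_pixels <- function(region_mask, width, gap) {
  rc <- which(region_mask, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(region_mask), ncol(region_mask))
  for (r in seq_len(nrow(region_mask))) for (c in seq_len(ncol(region_mask))) {
    d <- min(pmax(abs(rc[, 1] - r), abs(rc[, 2] - c)))
    if (d > gap && d <= gap + width) out[r, c] <- TRUE
  }
  out
}

# Greedy one-to-one matching of detected to planted spots by centroid
# distance; returns per-truth matches.
match_spots <- function(detected, truth, tol = 3) {
  used <- rep(FALSE, nrow(detected))
  idx <- rep(NA_integer_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    if (!nrow(detected)) break
    d <- sqrt((detected$centroid_row - truth$centroid_row[i])^2 +
              (detected$centroid_col - truth$centroid_col[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= tol) { used[j] <- TRUE; idx[i] <- j }
  }
  list(match = idx, tp = sum(!is.na(idx)), fp = sum(!used),
       fn = sum(is.na(idx)))
}

# Small scene used by several suites: a handful of cells with inclusions.
demo_scene <- function(seed = 42, ...) {
  render_scene(scene_spec(n_nuclei = 12, shape = c(224, 224),
                          nuclear_rate = 1, extranuclear_rate = 0.3, ...),
               seed = seed)
}
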