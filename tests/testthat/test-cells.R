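# Cytoplasm growth and marker positivity calling.

# small nucleus_set built directly from masks, bypassing detection
mini_nuclei <- function(masks, shape) {
  lab <- matrix(0L, shape[1], shape[2])
  for (i in seq_along(masks)) lab[masks[[i]]] <- i
  httquant:::new_nucleus_set(lab, 0.32)
}

disk_mask <- function(shape, center, r) {
  d2 <- outer((seq_len(shape[1]) - center[1])^2,
              (seq_len(shape[2]) - center[2])^2, `+`)
  d2 <= r^2
}

test_that("zero marker image yields empty cytoplasm everywhere", {
  nuc <- mini_nuclei(list(disk_mask(c(40, 40), c(20, 20), 6)), c(40, 40))
  cyto <- detect_cytoplasm(matrix(0, 40, 40), nuc)
  expect_true(all(cyto == 0))
})

test_that("a bright annulus becomes that cell's cytoplasm", {
  shape <- c(48, 48)
  nucmask <- disk_mask(shape, c(24, 24), 6)
  annulus <- disk_mask(shape, c(24, 24), 12) & !disk_mask(shape, c(24, 24), 6)
  img <- matrix(10, 48, 48); img[annulus] <- 100
  nuc <- mini_nuclei(list(nucmask), shape)
  cyto <- detect_cytoplasm(img, nuc, max_radius_px = 10, marker_threshold = 50)
  expect_equal(which(cyto == 1L), which(annulus))
})

test_that("a shared band splits by the nearest-nucleus rule, no double claims", {
  shape <- c(40, 80)
  n1 <- disk_mask(shape, c(20, 22), 5)
  n2 <- disk_mask(shape, c(20, 58), 5)
  band <- matrix(FALSE, 40, 80); band[17:23, 10:70] <- TRUE
  img <- matrix(0, 40, 80); img[band] <- 100
  nuc <- mini_nuclei(list(n1, n2), shape)
  cyto <- detect_cytoplasm(img, nuc, max_radius_px = 15, marker_threshold = 50)
  expect_true(all(cyto[n1 | n2] == 0))
  claimed <- which(cyto > 0, arr.ind = TRUE)
  rc1 <- which(n1, arr.ind = TRUE); rc2 <- which(n2, arr.ind = TRUE)
  for (k in seq_len(nrow(claimed))) {
    d1 <- min((rc1[, 1] - claimed[k, 1])^2 + (rc1[, 2] - claimed[k, 2])^2)
    d2 <- min((rc2[, 1] - claimed[k, 1])^2 + (rc2[, 2] - claimed[k, 2])^2)
    lab <- cyto[claimed[k, 1], claimed[k, 2]]
    expected <- if (d1 < d2) 1L else if (d2 < d1) 2L else 1L
    expect_equal(lab, expected)
  }
})

test_that("positivity is a strict inequality against factor x local background", {
  shape <- c(30, 30)
  nucmask <- disk_mask(shape, c(15, 15), 5)
  # exact control of the two means: nucleus value u, elsewhere value v
  make_img <- function(u, v) { img <- matrix(v, 30, 30); img[nucmask] <- u; img }
  r1 <- call_positivity(make_img(110, 100), nucmask, factor = 1.1)
  expect_false(r1$positive)                        # 110 is not > 110
  r2 <- call_positivity(make_img(110.1, 100), nucmask, factor = 1.1)
  expect_true(r2$positive)
  r3 <- call_positivity(make_img(201, 100), nucmask, factor = 2.0)
  expect_true(r3$positive)
  expect_equal(r1$nuclear_mean, 110)
  expect_equal(r1$local_bg_mean, 100)
  # multiplying the image by k > 0 never changes the call
  for (k in c(0.1, 3, 100)) {
    rk <- call_positivity(make_img(110.1, 100) * k, nucmask, factor = 1.1)
    expect_true(rk$positive)
  }
  expect_error(call_positivity(make_img(1, 1), nucmask, factor = 0), "factor")
})

test_that("planted positive fractions are recovered within binomial bounds", {
  pos_truth <- 0; pos_call <- 0; n <- 0
  for (s in 1:4) {
    sc <- render_scene(scene_spec(
      n_nuclei = 30, shape = c(288, 288), nuclear_rate = 0,
      markers = list(DARPP32 = list(fraction = 0.5, contrast = 3))), seed = s)
    nuc <- detect_nuclei(sc$channels$dapi)
    cl <- classify_cells(sc$channels["DARPP32"], nuc, factors = c(DARPP32 = 1.1))
    pos_call <- pos_call + sum(cl$calls$positive)
    pos_truth <- pos_truth + sum(sc$truth$cells$DARPP32_pos)
    n <- n + nrow(sc$truth$cells)
  }
  ci <- qbinom(c(0.025, 0.975), n, 0.5)
  expect_gte(pos_call, ci[1]); expect_lte(pos_call, ci[2])
  expect_lte(abs(pos_call - pos_truth), ceiling(0.02 * n))
})

test_that("classify_cells is deterministic, gated and shape-checked", {
  sc <- demo_scene(3)
  nuc <- detect_nuclei(sc$channels$dapi)
  imgs <- sc$channels["DARPP32"]
  a <- classify_cells(imgs, nuc, factors = c(DARPP32 = 1.1))
  b <- classify_cells(imgs, nuc, factors = c(DARPP32 = 1.1))
  expect_identical(a$calls, b$calls)
  # zero marker images give all-negative calls
  z <- classify_cells(list(DARPP32 = matrix(0, 224, 224)), nuc,
                      factors = c(DARPP32 = 1.1))
  expect_false(any(z$calls$positive))
  # factor sweep: positives never increase with the factor
  counts <- vapply(c(1.1, 1.5, 2, 3, 5), function(f)
    sum(classify_cells(imgs, nuc, factors = c(DARPP32 = f))$calls$positive),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(classify_cells(list(DARPP32 = matrix(0, 10, 10)), nuc), "shape")
  # no pixel belongs to two cells (cytoplasm labels are single-valued by
  # construction; nucleus/cytoplasm disjoint)
  expect_true(all(nuc$label_image[a$cytoplasm_image > 0] == 0))
})

test_that("disjoint marker populations give a diagonal confusion matrix", {
  sc <- render_scene(scene_spec(
    n_nuclei = 24, shape = c(288, 288), nuclear_rate = 0,
    markers = list(DARPP32 = list(fraction = 0.5, contrast = 3),
                   NeuN = list(fraction = 0.5, contrast = 3))), seed = 12)
  nuc <- detect_nuclei(sc$channels$dapi)
  cl <- classify_cells(sc$channels[c("DARPP32", "NeuN")], nuc,
                       factors = c(DARPP32 = 1.1, NeuN = 2.0))
  tr <- sc$truth
  # match detected to planted nuclei
  map <- vapply(seq_len(nrow(nuc$cells)), function(i) {
    d <- (tr$nuclei$center_row - nuc$cells$centroid_row[i])^2 +
      (tr$nuclei$center_col - nuc$cells$centroid_col[i])^2
    tr$nuclei$label[which.min(d)]
  }, integer(1))
  for (mk in c("DARPP32", "NeuN")) {
    calls <- cl$calls[cl$calls$marker == mk, ]
    truth <- tr$cells[[paste0(mk, "_pos")]][match(map, tr$cells$label)]
    expect_gte(mean(calls$positive == truth), 0.95)
  }
})
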