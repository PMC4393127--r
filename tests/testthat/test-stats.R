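# Region assignment, endpoint tables, ANOVA + Sidak pairwise comparisons.

fake_cells <- function(n, region_rows, region_cols, label0 = 0) {
  tibble::tibble(label = label0 + seq_len(n),
                 area_px = 500L, area_um2 = 500 * 0.32^2,
                 cell_area_um2 = 800 * 0.32^2,
                 centroid_row = region_rows, centroid_col = region_cols)
}

test_that("quadrant masks partition the field", {
  q <- quadrant_masks(c(40, 60))
  cover <- Reduce(`+`, lapply(q, function(m) m * 1L))
  expect_true(all(cover == 1L))
  expect_true(q$md[1, 1]); expect_true(q$lv[40, 60])
})

test_that("records are assigned to regions by centroid and owner", {
  masks <- quadrant_masks(c(100, 100))
  cells <- fake_cells(4, c(10, 90, 10, 90), c(10, 10, 90, 90))
  spots <- tibble::tibble(spot_id = 1:3, owner_cell = c(1L, 4L, NA),
                          centroid_row = c(50, 50, 95),
                          centroid_col = c(50, 50, 95),
                          compartment = c("nuclear", "nuclear", "unassigned"),
                          area_um2 = 1)
  ann <- assign_regions(cells, spots, masks)
  expect_equal(ann$cells$region, c("md", "mv", "ld", "lv"))
  # owned spots inherit the owner cell's region; unowned use their centroid
  expect_equal(ann$spots$region, c("md", "lv", "lv"))
  # one mask covering everything labels everything
  all_mask <- list(striatum = matrix(TRUE, 100, 100))
  expect_true(all(assign_regions(cells, NULL, all_mask)$cells$region == "striatum"))
  # cells outside every mask are unassigned
  part <- list(md = masks$md)
  expect_equal(assign_regions(cells, NULL, part)$cells$region,
               c("md", "unassigned", "unassigned", "unassigned"))
  overlapping <- list(a = masks$md, b = masks$md)
  expect_error(assign_regions(cells, NULL, overlapping), "overlap")
})

test_that("endpoint table computes the documented rates and densities", {
  cells <- fake_cells(10, rep(50, 10), seq(5, 95, 10))
  cells$marker_pos <- rep(c(TRUE, FALSE), 5)
  spots <- tibble::tibble(spot_id = 1:3, owner_cell = c(1L, 1L, 3L),
                          centroid_row = 50, centroid_col = c(5, 5, 25),
                          compartment = c("nuclear", "nuclear", "extranuclear"),
                          area_um2 = c(2, 4, 1))
  ep <- endpoint_table(cells, spots)
  expect_equal(ep$n_cells, 10L)
  expect_equal(ep$n_marker_pos, 5L)
  expect_equal(ep$nuclear_inclusions_per_cell, 2 / 5)
  expect_equal(ep$mean_inclusion_size_um2, 3)
  expect_equal(ep$size_area_ratio, 6 / (10 * 500 * 0.32^2))
  expect_equal(ep$count_per_nuclear_area, 2 / (10 * 500 * 0.32^2))
  expect_equal(ep$extranuclear_density_per_um2, 1 / (10 * 800 * 0.32^2))
  # no spots: zero counts, not NA
  ep0 <- endpoint_table(cells, NULL)
  expect_equal(ep0$nuclear_inclusions_per_cell, 0)
  expect_equal(ep0$extranuclear_density_per_um2, 0)
  # no positive cells: NA rate plus a QC flag
  cells2 <- cells; cells2$marker_pos <- FALSE
  ep2 <- endpoint_table(cells2, spots)
  expect_true(is.na(ep2$nuclear_inclusions_per_cell))
  expect_equal(ep2$qc, "no_positive_cells")
})

test_that("doubling the pixel size scales per-um2 densities by a quarter", {
  sc <- demo_scene(31)
  nuc1 <- detect_nuclei(sc$channels$dapi, pixel_size_um = 0.32)
  nuc2 <- detect_nuclei(sc$channels$dapi, pixel_size_um = 0.64)
  inc1 <- detect_inclusions(sc$channels$em48, nuc1)
  inc2 <- detect_inclusions(sc$channels$em48, nuc2)
  c1 <- dplyr::mutate(nuc1$cells, cell_area_um2 = area_um2, marker_pos = TRUE)
  c2 <- dplyr::mutate(nuc2$cells, cell_area_um2 = area_um2, marker_pos = TRUE)
  e1 <- endpoint_table(c1, inc1$spots)
  e2 <- endpoint_table(c2, inc2$spots)
  expect_equal(e2$extranuclear_density_per_um2,
               e1$extranuclear_density_per_um2 / 4, tolerance = 1e-12)
  expect_equal(e2$mean_inclusion_size_um2, e1$mean_inclusion_size_um2 * 4)
})

test_that("conservation: regional spot counts sum to total detections", {
  sc <- demo_scene(37)
  nuc <- detect_nuclei(sc$channels$dapi)
  inc <- detect_inclusions(sc$channels$em48, nuc)
  cells <- dplyr::mutate(nuc$cells, cell_area_um2 = area_um2, marker_pos = TRUE)
  masks <- quadrant_masks(dim(sc$channels$dapi))
  ann <- assign_regions(cells, inc$spots, masks)
  ep <- endpoint_table(ann$cells, ann$spots)
  expect_equal(sum(ep$n_nuclear) + sum(ep$n_extranuclear),
               sum(inc$spots$compartment != "unassigned"))
})

test_that("Sidak adjustment follows its closed form and m = 1 is raw", {
  set.seed(8)
  tab <- tibble::tibble(animal = rep(1:12, 2),
                        group = rep(c("a", "b"), each = 12),
                        y = rnorm(24))
  fit <- group_stats(tab, endpoints = "y")
  pw <- tidy(fit)
  expect_equal(pw$p.adjusted, pw$p.value)      # m = 1
  tab3 <- tibble::tibble(animal = rep(1:6, 3),
                         group = rep(c("a", "b", "c"), each = 6),
                         y = rnorm(18))
  pw3 <- tidy(group_stats(tab3, endpoints = "y"))
  expect_equal(pw3$p.adjusted, 1 - (1 - pw3$p.value)^3, tolerance = 1e-12)
  expect_error(group_stats(tab3[tab3$group == "a", ], endpoints = "y"),
               "two groups")
})

test_that("identical groups give F near 0 significance and flat p", {
  tab <- tibble::tibble(animal = rep(1:8, 3),
                        group = rep(c("a", "b", "c"), each = 8),
                        y = rep(rnorm(8), 3))
  fit <- group_stats(tab, endpoints = "y")
  expect_gt(min(tidy(fit)$p.adjusted), 0.99)
  expect_lt(glance(fit)$statistic, 1e-20)
})

test_that("sections are averaged per animal before the ANOVA", {
  set.seed(13)
  base <- tibble::tibble(animal = rep(1:6, each = 4),
                         section = rep(1:4, 6),
                         group = rep(c("a", "b"), each = 12),
                         y = rnorm(24))
  fit_sec <- group_stats(base, endpoints = "y")
  avg <- dplyr::summarise(dplyr::group_by(base, animal, group),
                          y = mean(y), .groups = "drop")
  fit_avg <- group_stats(avg, endpoints = "y")
  expect_equal(glance(fit_sec)$p.value, glance(fit_avg)$p.value)
  expect_equal(tidy(fit_sec)$p.adjusted, tidy(fit_avg)$p.adjusted)
})

test_that("a planted 3-SD shift is flagged significant with 8 animals", {
  # exact noncentral-t power at these settings: 0.935 for p < 0.001 and
  # 0.994 for p < 0.01, so the strong-significance check uses p < 0.01
  hits <- 0; reps <- 60
  set.seed(17)
  for (i in 1:reps) {
    tab <- tibble::tibble(animal = rep(1:16, 1),
                          group = rep(c("a", "b"), each = 8),
                          y = c(rnorm(8), rnorm(8, 3)))
    if (tidy(group_stats(tab, endpoints = "y"))$p.adjusted < 0.01)
      hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})

test_that("pairwise Sidak comparisons agree with emmeans", {
  skip_if_not_installed("emmeans")
  set.seed(23)
  tab <- tibble::tibble(animal = 1:18,
                        group = rep(c("a", "b", "c"), each = 6),
                        y = rnorm(18, rep(c(0, 1, 2), each = 6)))
  pw <- tidy(group_stats(tab, endpoints = "y"))
  fit <- stats::aov(y ~ group, data = tab)
  em <- summary(emmeans::emmeans(fit, pairwise ~ group, adjust = "sidak")$contrasts)
  expect_equal(pw$p.adjusted, em$p.value, tolerance = 1e-8)
  expect_equal(abs(pw$estimate), abs(em$estimate), tolerance = 1e-8)
})

test_that("two-way layouts report crossed-factor ANOVA terms", {
  set.seed(29)
  tab <- tidyr::expand_grid(animal = 1:4, region = c("md", "lv"),
                            age = c("m8", "m12"))
  tab$animal <- paste(tab$animal, tab$age)   # animals nested in age
  tab$y <- rnorm(nrow(tab)) + ifelse(tab$region == "lv", 2, 0)
  fit <- group_stats(tab, grouping = c("region", "age"), endpoints = "y")
  terms <- glance(fit)$term
  expect_setequal(terms, c("region", "age", "region:age"))
  expect_lt(glance(fit)$p.value[1], 0.01)
})

test_that("family-wise error under the null is controlled near nominal", {
  set.seed(31)
  reps <- 400; fw <- 0
  for (i in 1:reps) {
    tab <- tibble::tibble(animal = 1:24,
                          group = rep(c("a", "b", "c", "d"), each = 6),
                          y = rnorm(24))
    if (any(tidy(group_stats(tab, endpoints = "y"))$p.adjusted < 0.05))
      fw <- fw + 1
  }
  expect_lte(fw / reps, 0.07)
})
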