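# Subregional aggregation of per-cell / per-spot records and group
# statistics (one-way ANOVA + Sidak pairwise comparisons).

#' Build quadrant region masks
#'
#' Emulates the manual subdivision of the striatum into medial dorsal (md),
#' medial ventral (mv), lateral dorsal (ld) and lateral ventral (lv)
#' quadrants: splits a bounding box at a midline row and column. Rows above
#' the midline are dorsal; columns left of the midline are medial.
#'
#' @param shape `c(nrow, ncol)` of the field.
#' @param mid_row,mid_col Split lines (defaults: image centre).
#' @return Named list of disjoint logical masks `md`, `mv`, `ld`, `lv`.
#' @export
quadrant_masks <- function(shape, mid_row = shape[1] / 2, mid_col = shape[2] / 2) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  list(md = r <= mid_row & c <= mid_col, mv = r > mid_row & c <= mid_col,
       ld = r <= mid_row & c > mid_col, lv = r > mid_row & c > mid_col)
}

#' Assign cells and spots to anatomical subregions
#'
#' Labels every cell by the region mask containing its nucleus centroid and
#' every spot by its owner cell's region (falling back to the spot's own
#' centroid when it has no owner). Records outside all masks get
#' `"unassigned"`. Overlapping masks are an error.
#'
#' @param cells A `cell_set` (or its `cells` tibble with centroid columns).
#' @param spots A `spot_set` (or its `spots` tibble), or `NULL`.
#' @param masks Named list of logical matrices, disjoint within a section.
#' @return List with `cells` and `spots` tibbles, each gaining a `region`
#'   column.
#' @export
assign_regions <- function(cells, spots, masks) {
  if (is.null(names(masks)) || any(!nzchar(names(masks))))
    stop("masks must be named", call. = FALSE)
  cover <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  if (any(cover > 1L)) stop("region masks overlap", call. = FALSE)
  ctab <- if (inherits(cells, "cell_set")) cells$cells else cells
  stab <- if (inherits(spots, "spot_set")) spots$spots else spots
  region_at <- function(r, c) {
    r <- min(max(round_px(r), 1L), nrow(masks[[1]]))
    c <- min(max(round_px(c), 1L), ncol(masks[[1]]))
    for (nm in names(masks)) if (masks[[nm]][r, c]) return(nm)
    "unassigned"
  }
  ctab$region <- purrr::map2_chr(ctab$centroid_row, ctab$centroid_col, region_at)
  if (!is.null(stab)) {
    stab$region <- vapply(seq_len(nrow(stab)), function(i) {
      ow <- stab$owner_cell[i]
      if (!is.na(ow) && ow %in% ctab$label) ctab$region[match(ow, ctab$label)]
      else region_at(stab$centroid_row[i], stab$centroid_col[i])
    }, character(1))
  }
  list(cells = ctab, spots = stab)
}

#' Per-region endpoint table
#'
#' Aggregates per-cell and per-spot records into the endpoint metrics used
#' for group comparisons, one row per (animal, group, section, region):
#' * `n_cells`, `n_marker_pos` — cells and `restrict_to`-positive cells;
#' * `nuclear_inclusions_per_cell` — nuclear spot count per positive cell;
#' * `mean_inclusion_size_um2` — mean nuclear inclusion area;
#' * `size_area_ratio` — total inclusion area / total nuclear area;
#' * `count_per_nuclear_area` — inclusion count / total nuclear area (um^-2),
#'   the literal "ratio of inclusion number to nuclear area" reading, kept
#'   alongside the area-based ratio rather than silently choosing one;
#' * `extranuclear_density_per_um2` — extranuclear spot count per um² of
#'   total measured cell area;
#' * `granularity_mean` — mean nuclear granularity index.
#'
#' Regions with zero positive cells yield `NA` rate endpoints and a QC flag.
#'
#' @param cells Cell tibble with `region` (from [assign_regions()]), areas,
#'   and marker call columns `marker`/`positive` joined in, or a `cell_set`
#'   plus `calls`.
#' @param spots Spot tibble with `region`, `compartment`, `area_um2`.
#' @param granularity Optional tibble from [granularity_index()].
#' @param restrict_to Marker gating the per-cell denominators (default
#'   `"DARPP32"`).
#' @param animal,group,section Identifiers recycled onto every row.
#' @return Tibble of class `endpoint_table`.
#' @export
endpoint_table <- function(cells, spots, granularity = NULL, calls = NULL,
                           restrict_to = "DARPP32", animal = "a1",
                           group = "g1", section = "s1") {
  if (inherits(cells, "cell_set")) {
    if (is.null(calls)) calls <- cells$calls
    cells <- cells$cells
  }
  if (inherits(spots, "spot_set")) spots <- spots$spots
  if (!"region" %in% names(cells)) cells$region <- "all"
  if (!is.null(spots) && nrow(spots) && !"region" %in% names(spots)) spots$region <- "all"
  if (!is.null(calls)) {
    pos <- dplyr::filter(calls, .data$marker == restrict_to)
    cells$marker_pos <- cells$label %in% pos$label[pos$positive]
  } else if (!"marker_pos" %in% names(cells)) {
    cells$marker_pos <- TRUE
  }
  if (!is.null(granularity)) {
    cells$granularity_index <-
      granularity$granularity_index[match(cells$label, granularity$label)]
  }
  if (!"cell_area_um2" %in% names(cells)) cells$cell_area_um2 <- cells$area_um2
  per_region <- cells |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_marker_pos = sum(.data$marker_pos),
      total_nuclear_area_um2 = sum(.data$area_um2),
      total_cell_area_um2 = sum(.data$cell_area_um2),
      granularity_mean = if ("granularity_index" %in% names(cells))
        mean(.data$granularity_index, na.rm = TRUE) else NA_real_,
      .groups = "drop")
  sp <- if (is.null(spots) || !nrow(spots)) {
    tibble::tibble(region = character(), n_nuclear = integer(),
                   n_extranuclear = integer(), mean_size = numeric(),
                   total_size = numeric())
  } else {
    spots |>
      dplyr::group_by(.data$region) |>
      dplyr::summarise(
        n_nuclear = sum(.data$compartment == "nuclear"),
        n_extranuclear = sum(.data$compartment == "extranuclear"),
        mean_size = mean(.data$area_um2[.data$compartment == "nuclear"]),
        total_size = sum(.data$area_um2[.data$compartment == "nuclear"]),
        .groups = "drop")
  }
  out <- dplyr::full_join(per_region, sp, by = "region") |>
    dplyr::mutate(
      n_cells = dplyr::coalesce(.data$n_cells, 0L),
      n_marker_pos = dplyr::coalesce(.data$n_marker_pos, 0L),
      total_nuclear_area_um2 = dplyr::coalesce(.data$total_nuclear_area_um2, 0),
      total_cell_area_um2 = dplyr::coalesce(.data$total_cell_area_um2, 0),
      n_nuclear = dplyr::coalesce(.data$n_nuclear, 0L),
      n_extranuclear = dplyr::coalesce(.data$n_extranuclear, 0L),
      total_size = dplyr::coalesce(.data$total_size, 0),
      nuclear_inclusions_per_cell = ifelse(.data$n_marker_pos > 0,
        .data$n_nuclear / .data$n_marker_pos, NA_real_),
      mean_inclusion_size_um2 = .data$mean_size,
      size_area_ratio = .data$total_size / .data$total_nuclear_area_um2,
      count_per_nuclear_area = .data$n_nuclear / .data$total_nuclear_area_um2,
      extranuclear_density_per_um2 = .data$n_extranuclear / .data$total_cell_area_um2,
      qc = ifelse(.data$n_marker_pos == 0, "no_positive_cells", NA_character_)
    ) |>
    dplyr::select(-"mean_size", -"total_size")
  out <- tibble::add_column(out, animal = animal, group = group,
                            section = section, .before = 1)
  class(out) <- c("endpoint_table", class(out))
  out
}

#' One-way ANOVA with Sidak pairwise comparisons
#'
#' Runs the group analysis with the animal as the experimental unit:
#' section-level rows are first averaged per animal, then each endpoint gets
#' a one-way ANOVA across groups and pairwise comparisons on the pooled
#' residual variance, Sidak-adjusted as \eqn{p_{adj} = 1 - (1 - p)^m} for
#' the \eqn{m} comparisons performed. With `m = 1` the adjusted p equals
#' the raw p. Significance tiers are marked at 0.05 / 0.01 / 0.001. With
#' two grouping columns a two-way (crossed) ANOVA is reported and pairwise
#' comparisons are done on the first factor.
#'
#' @param table Data frame with `animal`, grouping column(s), optionally
#'   `section`, and numeric endpoint columns.
#' @param grouping Name(s) of the grouping column(s); default `"group"`.
#' @param endpoints Endpoint column names (default: all numeric columns not
#'   used as identifiers).
#' @param contrasts `"all"` pairwise, `"consecutive"` (adjacent levels in
#'   factor order), or a list of length-2 character vectors.
#' @return Object of class `htt_group_stats`; see [tidy.htt_group_stats()]
#'   and [glance.htt_group_stats()].
#' @examples
#' tab <- data.frame(animal = rep(1:6, 2), group = rep(c("a", "b"), each = 6),
#'                   y = c(rnorm(6), rnorm(6, 2)))
#' fit <- group_stats(tab, endpoints = "y")
#' tidy(fit)
#' @export
group_stats <- function(table, grouping = "group", endpoints = NULL,
                        contrasts = "all") {
  stopifnot(is.data.frame(table))
  if (!all(grouping %in% names(table)))
    stop("grouping column(s) not found", call. = FALSE)
  id_cols <- c("animal", "section", "region", "qc", grouping)
  if (is.null(endpoints)) {
    endpoints <- setdiff(names(table)[vapply(table, is.numeric, TRUE)], id_cols)
  }
  if (!length(endpoints)) stop("no endpoint columns", call. = FALSE)
  # average sections within animal x grouping first: the animal is the unit
  per_animal <- table |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("animal", grouping)))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(endpoints),
                                   ~ mean(.x, na.rm = TRUE)), .groups = "drop")
  g1 <- factor(per_animal[[grouping[1]]])
  if (nlevels(g1) < 2) stop("need at least two groups", call. = FALSE)
  anova_rows <- list(); pair_rows <- list()
  for (ep in endpoints) {
    y <- per_animal[[ep]]
    ok <- is.finite(y)
    if (length(grouping) == 2) {
      df2 <- data.frame(y = y, g1 = g1,
                        g2 = factor(per_animal[[grouping[2]]]))[ok, ]
      names(df2)[2:3] <- c("A", "B")
      fit <- aov(y ~ A * B, data = df2)
      sm <- summary(fit)[[1]]
      terms <- trimws(rownames(sm))
      labels <- c(A = grouping[1], B = grouping[2],
                  `A:B` = paste(grouping, collapse = ":"))
      for (i in seq_len(nrow(sm) - 1)) {
        anova_rows[[length(anova_rows) + 1]] <- tibble::tibble(
          endpoint = ep, term = unname(labels[terms[i]]),
          df = sm$Df[i], statistic = sm$`F value`[i], p.value = sm$`Pr(>F)`[i])
      }
      mse <- sm$`Mean Sq`[nrow(sm)]; df_err <- sm$Df[nrow(sm)]
    } else {
      fit <- aov(y[ok] ~ g1[ok])
      sm <- summary(fit)[[1]]
      anova_rows[[length(anova_rows) + 1]] <- tibble::tibble(
        endpoint = ep, term = grouping[1],
        df = sm$Df[1], statistic = sm$`F value`[1], p.value = sm$`Pr(>F)`[1])
      mse <- sm$`Mean Sq`[2]; df_err <- sm$Df[2]
    }
    pr <- sidak_pairwise(y[ok], g1[ok], mse, df_err, contrasts)
    if (nrow(pr)) { pr$endpoint <- ep; pair_rows[[length(pair_rows) + 1]] <- pr }
  }
  structure(list(anova = dplyr::bind_rows(anova_rows),
                 pairwise = dplyr::bind_rows(pair_rows),
                 per_animal = per_animal, grouping = grouping),
            class = "htt_group_stats")
}

# Pairwise t comparisons on the pooled ANOVA variance with Sidak adjustment.
sidak_pairwise <- function(y, g, mse, df_err, contrasts = "all") {
  lev <- levels(g)
  pairs <- if (identical(contrasts, "all")) {
    utils::combn(lev, 2, simplify = FALSE)
  } else if (identical(contrasts, "consecutive")) {
    purrr::map(seq_len(length(lev) - 1), ~ lev[c(.x, .x + 1)])
  } else contrasts
  m <- length(pairs)
  if (!m) return(tibble::tibble())
  purrr::map_dfr(pairs, function(pr) {
    n1 <- sum(g == pr[1]); n2 <- sum(g == pr[2])
    m1 <- mean(y[g == pr[1]]); m2 <- mean(y[g == pr[2]])
    se <- sqrt(mse * (1 / n1 + 1 / n2))
    t <- (m2 - m1) / se
    p <- 2 * pt(-abs(t), df_err)
    p_adj <- 1 - (1 - p)^m
    tibble::tibble(group1 = pr[1], group2 = pr[2], estimate = m2 - m1,
                   se = se, df = df_err, statistic = t, p.value = p,
                   p.adjusted = p_adj, n_comparisons = m,
                   signif = signif_tier(p_adj))
  })
}

signif_tier <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "ns")
}

#' @export
print.htt_group_stats <- function(x, ...) {
  cat("<htt_group_stats> one-way ANOVA + Sidak pairwise,",
      nrow(x$per_animal), "animal-level rows\n")
  print(x$anova, ...)
  if (nrow(x$pairwise)) print(x$pairwise, ...)
  invisible(x)
}

#' Tidy the pairwise comparisons of a group-stats fit
#'
#' @param x An `htt_group_stats` object.
#' @param ... Unused.
#' @return Tibble of pairwise comparisons with Sidak-adjusted p-values.
#' @export
tidy.htt_group_stats <- function(x, ...) x$pairwise

#' One-row-per-endpoint ANOVA summary of a group-stats fit
#'
#' @param x An `htt_group_stats` object.
#' @param ... Unused.
#' @return Tibble of ANOVA F statistics and p-values per endpoint.
#' @export
glance.htt_group_stats <- function(x, ...) x$anova

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
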