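# Core-grid tessellation, overlap filtering and core scoring.

side <- sqrt(2) * 1000  # square tile side for 2 mm^2, in um

test_that("an aligned 2x2-tile square ROI yields exactly 4 fully covered cores", {
  roi <- cbind(x = c(0, 2 * side, 2 * side, 0),
               y = c(0, 0, 2 * side, 2 * side))
  g <- generate_core_grid(list(roi_polygons = list(roi)))
  expect_equal(nrow(g), 4L)
  expect_equal(g$overlap_mm2, rep(2, 4), tolerance = 1e-9)
  expect_equal(g$tumor_fraction, rep(1, 4), tolerance = 1e-9)
})

test_that("a tile overlapping the ROI by only 0.6 mm^2 is excluded", {
  roi <- cbind(x = c(0, 1000, 1000, 0), y = c(0, 0, 600, 600))  # 0.6 mm^2
  g <- generate_core_grid(list(roi_polygons = list(roi)))
  expect_equal(nrow(g), 0L)
  all_tiles <- generate_core_grid(list(roi_polygons = list(roi)),
                                  keep_all = TRUE)
  expect_equal(all_tiles$overlap_mm2[1L], 0.6, tolerance = 1e-9)
  expect_false(any(all_tiles$retained))
  # 0.7 mm^2 exactly meets the floor
  roi2 <- cbind(x = c(0, 1000, 1000, 0), y = c(0, 0, 700, 700))
  g2 <- generate_core_grid(list(roi_polygons = list(roi2)))
  expect_equal(nrow(g2), 1L)
})

test_that("empty ROI list gives an empty core table", {
  g <- generate_core_grid(list(roi_polygons = list()))
  expect_equal(nrow(g), 0L)
})

test_that("tiles partition the bounding box and their overlaps sum to the ROI area", {
  roi <- cbind(x = c(200, 5200, 3000), y = c(100, 900, 4100))  # triangle
  g <- generate_core_grid(list(roi_polygons = list(roi)), keep_all = TRUE)
  grid <- attr(g, "grid")
  # tiles are disjoint and jointly cover the bounding box
  expect_equal(nrow(g), grid$n_col * grid$n_row)
  expect_true(!anyDuplicated(paste(g$row, g$col)))
  bb <- polygon_bbox(roi)
  expect_lte(grid$x0, bb["xmin"])
  expect_gte(max(g$x1_um), bb["xmax"])
  expect_gte(max(g$y1_um), bb["ymax"])
  expect_equal(sum(g$overlap_mm2) * 1e6, polygon_area(roi),
               tolerance = 1e-6)
})

test_that("per-tile cell counts with the shared-edge tie rule conserve the total", {
  roi <- cbind(x = c(0, 3000, 3000, 0), y = c(0, 0, 2500, 2500))
  geom <- list(roi_polygons = list(roi))
  set.seed(60)
  cells <- data.frame(x_um = runif(500, 0, 3000), y_um = runif(500, 0, 2500),
                      positive = runif(500) < 0.2)
  # add cells exactly on internal tile edges (x = side and y = side lines)
  cells <- rbind(cells,
                 data.frame(x_um = c(side, side, 1000),
                            y_um = c(500, side, side),
                            positive = TRUE))
  g <- generate_core_grid(geom, keep_all = TRUE)
  sc <- score_cores(g, cells, geom, drop_empty = FALSE)
  expect_equal(sum(sc$n_cells), nrow(cells))
  expect_equal(sum(sc$n_positive), sum(cells$positive))
})

test_that("shrinking min_overlap never loses retained cores; default filters are consistent", {
  roi <- cbind(x = c(100, 4800, 4000, 300), y = c(200, 500, 4200, 3600))
  geom <- list(roi_polygons = list(roi))
  counts <- vapply(c(0.2, 0.7, 1.2, 1.9), function(mo)
    nrow(generate_core_grid(geom, core_grid_config(min_overlap = mo))),
    integer(1L))
  expect_true(all(diff(counts) <= 0))
  # with defaults the 0.7 mm^2 floor implies tumor_fraction >= 0.35 > 0.33,
  # so the overlap filter is the operative one
  g_both <- generate_core_grid(geom, core_grid_config())
  g_overlap_only <- generate_core_grid(geom,
                                       core_grid_config(min_tumor_fraction = 0))
  expect_equal(g_both, g_overlap_only, ignore_attr = TRUE)
  expect_true(all(g_both$tumor_fraction >= 0.35 - 1e-12))
})

test_that("core scoring counts only cells inside rect-and-ROI (brute-force oracle)", {
  roi <- cbind(x = c(0, 2800, 1400), y = c(0, 0, 2600))  # triangle
  geom <- list(roi_polygons = list(roi))
  set.seed(61)
  cells <- data.frame(x_um = runif(800, 0, 2800), y_um = runif(800, 0, 2600),
                      positive = runif(800) < 0.3)
  g <- generate_core_grid(geom, keep_all = TRUE)
  sc <- score_cores(g, cells, geom, drop_empty = FALSE)
  in_roi <- vapply(seq_len(nrow(cells)), function(i)
    oracle_point_in_polygon(cells$x_um[i], cells$y_um[i], roi), logical(1L))
  expect_equal(sum(sc$n_cells), sum(in_roi))
  # per-core check against the double filter (strict interior cells, so the
  # tie rule cannot differ from plain rectangle membership)
  for (r in seq_len(nrow(sc))) {
    in_rect <- cells$x_um > sc$x0_um[r] & cells$x_um < sc$x1_um[r] &
      cells$y_um > sc$y0_um[r] & cells$y_um < sc$y1_um[r]
    expect_equal(sc$n_cells[r], sum(in_rect & in_roi))
  }
})

test_that("retained cores without cells are dropped with a warning", {
  roi <- cbind(x = c(0, 2 * side, 2 * side, 0),
               y = c(0, 0, 2 * side, 2 * side))
  geom <- list(roi_polygons = list(roi))
  # all cells in the first tile; the other three retained tiles are empty
  cells <- data.frame(x_um = runif(20, 1, side - 1),
                      y_um = runif(20, 1, side - 1),
                      positive = FALSE)
  g <- generate_core_grid(geom)
  expect_warning(sc <- score_cores(g, cells, geom), "zero cells")
  expect_equal(nrow(sc), 1L)
  expect_equal(sc$n_cells, 20L)
  expect_equal(sc$percent_cd8, 0)
})

test_that("grid config validation", {
  expect_error(core_grid_config(min_overlap = 3, core_area = 2), "min_overlap")
  expect_error(core_grid_config(min_tumor_fraction = 1.5), "min_tumor_fraction")
  expect_error(core_grid_config(core_area = 0), "core_area")
})
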