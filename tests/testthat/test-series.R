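# Dataset construction: tile cover, least-cloudy selection, patch windows,
# channel stacking and series IO.

test_that("greedy tile cover retains the expected tiles", {
  g <- toy_grid()
  # all records inside T1 only
  occ <- data.frame(occurrence_id = c("a", "b"), lon = c(0.1, 0.5),
                    lat = c(0.5, 0.5))
  expect_equal(compute_tile_cover(occ, g), "T1")
  # one record per disjoint tile
  occ2 <- data.frame(occurrence_id = c("a", "b"), lon = c(0.1, 2.5),
                     lat = c(0.5, 0.5))
  expect_equal(compute_tile_cover(occ2, g), c("T1", "T3"))
  # record outside everything
  occ3 <- data.frame(occurrence_id = "x", lon = 5, lat = 5)
  expect_error(compute_tile_cover(occ3, g), "x")
})

test_that("cover tie-break picks the smallest tile id and stays minimal", {
  g <- toy_grid()
  # A in the T1/T2 overlap (tie -> T1), B in T1 only => {T1}
  occ <- data.frame(occurrence_id = c("A", "B"), lon = c(0.9, 0.1),
                    lat = c(0.5, 0.5))
  cover <- compute_tile_cover(occ, g)
  expect_equal(cover, "T1")

  # oracle: point-in-polygon coverage of the union, and no proper subset of
  # the greedy trace covers all records
  contains <- function(tiles, lon, lat) {
    any(lon >= g$lon_min[g$tile_id %in% tiles] &
        lon <= g$lon_max[g$tile_id %in% tiles] &
        lat >= g$lat_min[g$tile_id %in% tiles] &
        lat <= g$lat_max[g$tile_id %in% tiles])
  }
  covers_all <- function(tiles) {
    all(vapply(seq_len(nrow(occ)),
               function(i) contains(tiles, occ$lon[i], occ$lat[i]), NA))
  }
  expect_true(covers_all(cover))
  if (length(cover) > 1) {
    for (drop in seq_along(cover)) {
      expect_false(covers_all(cover[-drop]))
    }
  } else {
    expect_false(covers_all(character(0)))
  }
})

test_that("cover of real occurrences contains every record (oracle check)", {
  sc <- tiny_scene()
  occ <- sample_occurrences(sc$world, tiny_pool(), 200, seed = 31)
  cover <- compute_tile_cover(occ, sc$grid)
  g <- sc$grid
  idx <- g$tile_id %in% cover
  for (i in seq_len(nrow(occ))) {
    expect_true(any(occ$lon[i] >= g$lon_min[idx] & occ$lon[i] <= g$lon_max[idx] &
                    occ$lat[i] >= g$lat_min[idx] & occ$lat[i] <= g$lat_max[idx]))
  }
})

test_that("least-cloudy selection is optimal with deterministic ties", {
  mk <- function(tile, month, cloud, time) {
    structure(list(tile_id = tile, month_index = month, product_index = 1L,
                   sensing_time = time, bands = array(0, c(2, 2, 4)),
                   cloud_percent = cloud, cloud_mask = NULL),
              class = "raster_product")
  }
  prods <- list(mk("T1", 0, 10, 1), mk("T1", 0, 5, 2), mk("T1", 0, 80, 3),
                mk("T1", 1, 5, 20), mk("T1", 1, 5, 10))
  sel <- select_monthly_products(prods, n_months = 3)
  tab <- sel$table
  expect_equal(tab$cloud_percent[tab$month_index == 0], 5)
  expect_equal(tab$sensing_time[tab$month_index == 1], 10) # earlier tie win
  expect_true(tab$missing[tab$month_index == 2])
  expect_false(any(tab$missing[tab$month_index < 2]))

  # exhaustive optimality on a rendered scene
  sc <- tiny_scene()
  meta <- data.frame(
    tile = vapply(sc$products, `[[`, "", "tile_id"),
    month = vapply(sc$products, function(p) p$month_index, 0L),
    cloud = vapply(sc$products, `[[`, 0, "cloud_percent"))
  tab2 <- sc$selected$table
  for (j in sample(nrow(tab2), 20)) {
    competing <- meta$cloud[meta$tile == tab2$tile_id[j] &
                            meta$month == tab2$month_index[j]]
    expect_true(all(tab2$cloud_percent[j] <= competing))
  }
})

test_that("patch windows follow the half-open centred convention", {
  sc <- tiny_scene()
  g <- sc$grid
  # centre at global zero-based pixel (20, 20): rows 12..27 for size 16,
  # i.e. the half-open window [centre - 8, centre + 8)
  lon <- attr(g, "lon0") + (20 + 0.5) * attr(g, "deg_per_px")
  lat <- attr(g, "lat_top") - (20 + 0.5) * attr(g, "deg_per_px")
  patch <- extract_patch(sc$selected, g, lon, lat, 0, 16)
  # oracle: slice the (single) tile directly
  tile <- sc$selected$products[["T01-01#00"]]$bands
  expect_equal(patch, tile[13:28, 13:28, , drop = FALSE],
               ignore_attr = TRUE)
  expect_error(extract_patch(sc$selected, g, lon, lat, 0, 15), "even")
  # window beyond the world bounds errors without a fill value
  expect_error(
    extract_patch(sc$selected, g,
                  attr(g, "lon0") + 0.5 * attr(g, "deg_per_px"),
                  lat, 0, 16),
    "beyond the world bounds")
})

test_that("windows crossing a tile edge equal a pre-assembled mosaic slice", {
  sc <- tiny_scene()
  g <- sc$grid
  tp <- attr(g, "tile_px")
  # centre 10 px right of the boundary between tile columns 1 and 2: part of
  # the window must be read from the western neighbour
  c0 <- tp + 10
  r0 <- 16
  lon <- attr(g, "lon0") + (c0 + 0.5) * attr(g, "deg_per_px")
  lat <- attr(g, "lat_top") - (r0 + 0.5) * attr(g, "deg_per_px")
  size <- 32
  patch <- extract_patch(sc$selected, g, lon, lat, 0, size)

  # oracle: concatenate the two tiles then slice
  west <- sc$selected$products[["T01-01#00"]]$bands
  east <- sc$selected$products[["T02-01#00"]]$bands
  mosaic <- array(0, c(tp, 2 * tp, 4))
  mosaic[, 1:tp, ] <- west
  mosaic[, tp + 1:tp, ] <- east
  expected <- mosaic[(r0 - size / 2 + 1):(r0 + size / 2),
                     (c0 - size / 2 + 1):(c0 + size / 2), , drop = FALSE]
  expect_equal(patch, expected, ignore_attr = TRUE)
})

test_that("patch footprint matches its ground size", {
  size_px <- 64
  resolution_m <- 10
  edge_m <- size_px * resolution_m
  expect_equal(edge_m, 640)
  expect_equal(edge_m^2 / 1e4, 40.96) # hectares
})

test_that("series stacking: shape, channel layout and missing-month fallback", {
  sc <- tiny_scene()
  occ <- sample_occurrences(sc$world, tiny_pool(), 5, seed = 41)
  s <- build_series(occ[1, ], sc$selected, sc$grid, 16, fill = 0)
  expect_equal(dim(s$data), c(16, 16, 48))
  expect_length(s$month_available, 12)

  # channel of (month m, band b), zero-based, is m*4 + b
  patch_m2 <- extract_patch(sc$selected, sc$grid, occ$lon[1], occ$lat[1],
                            2, 16, fill = 0)
  expect_equal(s$data[, , 2 * 4 + 3 + 1], patch_m2[, , 4]) # month 2, IR

  # drop every product of month 5: channels fall back to month 4
  sel2 <- sc$selected
  drop <- grepl("#05$", names(sel2$products))
  sel2$products <- sel2$products[!drop]
  sel2$table$missing[sel2$table$month_index == 5] <- TRUE
  s2 <- build_series(occ[1, ], sel2, sc$grid, 16, fill = 0)
  expect_false(s2$month_available[6])
  expect_equal(s2$data[, , 5 * 4 + 1:4], s2$data[, , 4 * 4 + 1:4])

  # all months missing errors
  sel3 <- sc$selected
  sel3$products <- list()
  expect_error(build_series(occ[1, ], sel3, sc$grid, 16), "missing")
})

test_that("series round-trip through disk is bit-exact", {
  sc <- tiny_scene()
  occ <- sample_occurrences(sc$world, tiny_pool(), 3, seed = 43)
  built <- build_series_set(occ, sc$selected, sc$grid, 12, fill = 0)
  f <- withr::local_tempfile(fileext = ".rds")
  write_series(built$series[[2]], f)
  back <- read_series(f)
  expect_identical(back$data, built$series[[2]]$data)

  d <- withr::local_tempdir()
  write_series_set(built, d)
  man <- utils::read.csv(file.path(d, "manifest.csv"))
  expect_equal(nrow(man), 3)
  expect_true(all(file.exists(man$path)))
  expect_identical(read_series(man$path[1])$data, built$series[[1]]$data)

  # stacked array preserves order and values
  x <- series_array(built$series)
  expect_equal(dim(x), c(12, 12, 48, 3))
  expect_identical(x[, , , 2], built$series[[2]]$data, ignore_attr = TRUE)
})
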