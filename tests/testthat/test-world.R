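# Synthetic world generator: determinism, seasonal structure, occurrence
# sampling, clouds, and the plain-text / raster IO round trips.

test_that("world generation is deterministic and validates its config", {
  cfg <- world_config(n_tiles_x = 2, n_tiles_y = 2, tile_px = 16,
                      n_habitats = 3, seed = 5)
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1$habitat, w2$habitat)
  expect_identical(w1$base, w2$base)
  expect_identical(w1$schedule, w2$schedule)
  expect_true(all(w1$habitat %in% 1:3))

  expect_error(world_config(n_tiles_x = 0), "count")
  expect_error(world_config(cloud_prob = 1.5), "probability")
  expect_error(world_config(seasonal_amplitude = -1), ">= 0")
})

test_that("zero amplitude and zero noise make all months of a pixel equal", {
  w <- generate_world(world_config(n_tiles_x = 1, n_tiles_y = 1,
                                   tile_px = 16, n_habitats = 4,
                                   n_regions_x = 1, n_regions_y = 1,
                                   seasonal_amplitude = 0, noise_sd = 0,
                                   cloud_prob = 0, seed = 2))
  p0 <- render_product(w, "T01-01", 0)
  for (m in 1:5) {
    pm <- render_product(w, "T01-01", m)
    expect_equal(pm$bands, p0$bands)
  }
})

test_that("noise-free cloudless raster equals the signature lookup exactly", {
  w <- generate_world(world_config(n_tiles_x = 1, n_tiles_y = 1,
                                   tile_px = 16, n_habitats = 4,
                                   n_regions_x = 1, n_regions_y = 1,
                                   noise_sd = 0, cloud_prob = 0, seed = 9))
  p <- render_product(w, "T01-01", 3)
  for (b in 1:4) {
    expect_equal(as.vector(p$bands[, , b]),
                 seasonal_signature(w, w$habitat, 3, b))
  }
  # same (tile, month, product) renders identically
  expect_equal(render_product(w, "T01-01", 3)$bands, p$bands)
  expect_error(render_product(w, "T99-01", 0), "unknown product")
})

test_that("cloud percentage equals the realised mask fraction", {
  w <- tiny_world(seed = 21, cloud = 1.0)
  sched <- w$schedule
  cloudy <- sched[sched$cloudy & sched$cloud_frac > 0.05, ][1:5, ]
  for (i in seq_len(nrow(cloudy))) {
    p <- render_product(w, cloudy$tile_id[i], cloudy$month_index[i],
                        cloudy$product_index[i])
    expect_equal(p$cloud_percent, 100 * mean(p$cloud_mask))
    expect_gt(p$cloud_percent, 0)
  }
})

test_that("occurrence sampling respects counts, niches and regions", {
  w <- tiny_world()
  pool <- tiny_pool()
  occ <- sample_occurrences(w, pool, 1000, seed = 4)
  expect_equal(nrow(occ), 1000)
  expect_equal(sum(table(occ$species_id)), 1000)
  expect_true(all(occ$species_id %in% seq_len(pool$n_species)))
  expect_true(all(occ$lon >= -180 & occ$lon < 180))
  expect_true(all(occ$lat >= -90 & occ$lat <= 90))

  # a species with affinity for exactly one habitat lands only on it
  pool1 <- tiny_pool()
  pool1$affinity[3, ] <- 0
  pool1$affinity[3, 2] <- 1
  occ1 <- sample_occurrences(w, pool1, 600, seed = 8)
  recs <- occ1[occ1$species_id == 3, ]
  col <- floor((recs$lon - w$lon_min) / w$deg_per_px) + 1
  row <- floor((w$lat_max - recs$lat) / w$deg_per_px) + 1
  expect_true(nrow(recs) > 0)
  expect_true(all(w$habitat[cbind(row, col)] == 2))
})

test_that("species frequencies follow the Zipf law (multinomial oracle)", {
  w <- tiny_world()
  pool <- species_pool(200, w$config$n_habitats, zipf_exponent = 1.4,
                       phase_dependence = 0, seed = 13)
  n <- 20000
  occ <- suppressWarnings(sample_occurrences(w, pool, n, seed = 17))
  counts <- tabulate(occ$species_id, 200)

  # oracle: direct multinomial draw from the same abundance law
  set.seed(99)
  rare <- 21:200 # rarest 90% of species
  oracle_shares <- replicate(200, {
    sum(stats::rmultinom(1, n, pool$abundance)[rare]) / n
  })
  share <- sum(counts[rare]) / n
  # occurrence sampling adds region truncation for low-rank species only in
  # some regions; allow a generous band around the oracle spread
  expect_lt(abs(share - mean(oracle_shares)),
            6 * stats::sd(oracle_shares) + 0.02)
})

test_that("Lorenz curve of species counts is convex and Gini grows with the exponent", {
  w <- tiny_world()
  gini <- function(counts) {
    x <- sort(counts)
    n <- length(x)
    sum((2 * seq_len(n) - n - 1) * x) / (n * sum(x))
  }
  g <- vapply(c(0.8, 1.8), function(a) {
    pool <- species_pool(60, w$config$n_habitats, zipf_exponent = a, seed = 1)
    occ <- suppressWarnings(sample_occurrences(w, pool, 6000, seed = 2))
    counts <- tabulate(occ$species_id, 60)
    lorenz <- cumsum(sort(counts)) / sum(counts)
    expect_true(all(diff(lorenz) >= 0))
    expect_true(all(diff(diff(lorenz)) >= -1e-12)) # convex
    gini(counts)
  }, 0)
  expect_gt(g[2], g[1])
})

test_that("with no phase dependence the pair members are interchangeable", {
  # the conditional species distribution given (group, side) then equals the
  # one given group alone: no information is carried by the temporal phase
  pool <- tiny_pool(pdep = 0)
  aff <- pool$affinity
  # affinity of side-1 and side-2 member of each pair must be identical
  for (g in 1:3) {
    expect_equal(aff[, 2 * g - 1], aff[, 2 * g], tolerance = 1e-12)
  }
})

test_that("occurrence and config files round-trip", {
  w <- tiny_world()
  occ <- sample_occurrences(w, tiny_pool(), 50, seed = 6)
  f <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(occ, f)
  back <- read_occurrences(f)
  expect_equal(back$species_id, occ$species_id)
  expect_equal(back$lon, occ$lon, tolerance = 1e-12)
  expect_identical(is.na(back$date), is.na(occ$date))

  cfgf <- withr::local_tempfile(fileext = ".cfg")
  write_world_config(w$config, cfgf)
  cfg2 <- read_world_config(cfgf)
  expect_equal(unclass(cfg2), unclass(w$config), tolerance = 1e-12)
})

test_that("raster products round-trip through TIFF at DN quantisation", {
  skip_if_not_installed("tiff")
  w <- tiny_world()
  p <- render_product(w, "T01-01", 2)
  f <- withr::local_tempfile(fileext = ".tif")
  write_product(p, f, world = w)
  q <- read_product(f)
  expect_equal(q$bands, p$bands, tolerance = 1e-4)
  expect_equal(q$cloud_percent, p$cloud_percent)
  expect_equal(q$tile_id, p$tile_id)
  expect_true(q$footprint$lon_min < q$footprint$lon_max)
})
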