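# Shared miniature fixtures, built in code and memoised per test run.

.fix <- new.env(parent = emptyenv())

tiny_world <- function(seed = 11, amp = 1.0, noise = 0.2, cloud = 0.3) {
  key <- paste("w", seed, amp, noise, cloud, sep = "_")
  if (is.null(.fix[[key]])) {
    .fix[[key]] <- generate_world(world_config(
      n_tiles_x = 3, n_tiles_y = 3, tile_px = 32, n_habitats = 6,
      seasonal_amplitude = amp, noise_sd = noise, cloud_prob = cloud,
      n_regions_x = 2, n_regions_y = 1, products_per_month = 2, seed = seed))
  }
  .fix[[key]]
}

tiny_pool <- function(n_species = 12, n_habitats = 6, pdep = 0.8, seed = 3) {
  species_pool(n_species, n_habitats, phase_dependence = pdep, seed = seed)
}

# world + selected products + grid, memoised (rendering is the slow part)
tiny_scene <- function(seed = 11) {
  key <- paste("scene", seed, sep = "_")
  if (is.null(.fix[[key]])) {
    world <- tiny_world(seed)
    products <- render_products(world)
    .fix[[key]] <- list(
      world = world,
      grid = tile_grid(world),
      selected = select_monthly_products(products, world$config$n_months),
      products = products)
  }
  .fix[[key]]
}

# hand-made overlapping tile grid for cover tests
toy_grid <- function() {
  g <- data.frame(
    tile_id = c("T1", "T2", "T3"),
    lon_min = c(0.0, 0.8, 2.0), lon_max = c(1.0, 1.8, 3.0),
    lat_min = c(0.0, 0.0, 0.0), lat_max = c(1.0, 1.0, 1.0),
    stringsAsFactors = FALSE
  )
  g
}
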