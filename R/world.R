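# Synthetic world generator: a miniature planet with tiled monthly rasters,
# habitats carrying seasonal spectral signatures, clouds, a long-tailed species
# pool and spatially biased occurrence sampling. Every downstream stage of the
# pipeline (series construction, splitting, model training, temporal ablation)
# can therefore be exercised fully offline.
#
# The key design property is that month ORDER is informative: habitats come in
# pairs sharing the same base reflectance in every band but with seasonal
# sinusoids offset by a quarter cycle (an integer number of months). The two
# members of a pair are then indistinguishable from the multiset of monthly
# values (permutation), from the temporal mean (averaging), or from a single
# unidentified month (sampling) -- only the chronologically ordered series
# separates them.

N_BANDS <- 4L # R, G, B, IR

#' World configuration
#'
#' Parameters of the synthetic world: the tiling grid, raster geometry,
#' habitat and seasonal structure, observation noise, cloudiness and the
#' region partition. A fixed seed makes the generated world bit-identical
#' across calls.
#'
#' @param n_tiles_x,n_tiles_y Number of tiles along each axis.
#' @param tile_px Pixels per tile edge.
#' @param resolution_m Ground size of one pixel in metres.
#' @param n_habitats Number of habitat classes. Habitats are paired: members
#'   of a pair share base reflectances and differ only in seasonal phase.
#' @param n_months Number of monthly time steps (default 12).
#' @param seasonal_amplitude Amplitude of the seasonal sinusoid added to each
#'   habitat's base reflectance (unitless reflectance, >= 0).
#' @param noise_sd Standard deviation of per-pixel Gaussian observation noise.
#' @param cloud_prob Probability that any given product is partly cloudy.
#' @param n_regions_x,n_regions_y Region partition: rectangular super-blocks
#'   of tiles playing the role of biogeographic regions.
#' @param products_per_month Number of alternative products (acquisitions)
#'   rendered per tile and month, so least-cloudy selection has real work.
#' @param seed Integer master seed.
#' @return An object of class `world_config`.
#' @export
world_config <- function(n_tiles_x = 6, n_tiles_y = 6, tile_px = 64,
                         resolution_m = 10, n_habitats = 8, n_months = 12,
                         seasonal_amplitude = 1.0, noise_sd = 0.25,
                         cloud_prob = 0.3, n_regions_x = 2, n_regions_y = 2,
                         products_per_month = 2, seed = 1) {
  cfg <- list(
    n_tiles_x = as.integer(n_tiles_x), n_tiles_y = as.integer(n_tiles_y),
    tile_px = as.integer(tile_px), resolution_m = resolution_m,
    n_habitats = as.integer(n_habitats), n_months = as.integer(n_months),
    seasonal_amplitude = seasonal_amplitude, noise_sd = noise_sd,
    cloud_prob = cloud_prob,
    n_regions_x = as.integer(n_regions_x),
    n_regions_y = as.integer(n_regions_y),
    products_per_month = as.integer(products_per_month),
    seed = as.integer(seed)
  )
  counts <- c("n_tiles_x", "n_tiles_y", "tile_px", "n_habitats", "n_months",
              "n_regions_x", "n_regions_y", "products_per_month")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      stop(sprintf("'%s' must be a count >= 1", f), call. = FALSE)
    }
  }
  if (cfg$resolution_m <= 0) stop("'resolution_m' must be positive", call. = FALSE)
  if (cfg$seasonal_amplitude < 0) stop("'seasonal_amplitude' must be >= 0", call. = FALSE)
  if (cfg$noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  if (cfg$cloud_prob < 0 || cfg$cloud_prob > 1) {
    stop("'cloud_prob' must be a probability in [0, 1]", call. = FALSE)
  }
  if (cfg$n_regions_x > cfg$n_tiles_x || cfg$n_regions_y > cfg$n_tiles_y) {
    stop("region grid cannot be finer than the tile grid", call. = FALSE)
  }
  structure(cfg, class = "world_config")
}

tile_id_of <- function(tx, ty) sprintf("T%02d-%02d", tx, ty)

#' Generate a synthetic world
#'
#' Builds the habitat map (spatially contiguous classes from smoothed random
#' fields), the per-habitat seasonal signature table, the cloud/acquisition
#' schedule, the region partition, and a smooth east--west observation-bias
#' surface. The result is a pure function of the configuration (including its
#' seed).
#'
#' The signature of habitat `h` in month `m` (zero-based) and band `b` is
#' `base(h, b) + seasonal_amplitude * sin(2 * pi * (m + phase_h) / n_months)`.
#' Habitat pair groups are encoded in the bands as a binary code with 0.5
#' reflectance separation, so groups are well separated while pair members are
#' identical except for an integer phase offset of a quarter cycle.
#'
#' @param config A [world_config()].
#' @return An object of class `sdm_world`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  cfg <- config
  H <- cfg$n_tiles_y * cfg$tile_px
  W <- cfg$n_tiles_x * cfg$tile_px

  withr::with_seed(child_seed(cfg$seed, "world"), {
    # Habitat map: argmax over smoothed white-noise fields, one per habitat.
    radius <- max(3L, cfg$tile_px %/% 4L)
    fields <- vapply(seq_len(cfg$n_habitats), function(h) {
      box_blur(matrix(stats::rnorm(H * W), H, W), radius, passes = 2)
    }, matrix(0, H, W))
    habitat <- matrix(max.col(matrix(fields, H * W, cfg$n_habitats),
                              ties.method = "first"), H, W)
    storage.mode(habitat) <- "integer"

    # Seasonal signature table. Pair group of habitat h (1-based) and side.
    group <- (seq_len(cfg$n_habitats) + 1L) %/% 2L
    side <- 2L - (seq_len(cfg$n_habitats) %% 2L) # 1, 2, 1, 2, ...
    n_groups <- max(group)
    base_g <- matrix(0, n_groups, N_BANDS)
    for (g in seq_len(n_groups)) {
      bits <- bitwAnd(bitwShiftR(g - 1L, 0:(N_BANDS - 1L)), 1L)
      base_g[g, ] <- 0.4 + 0.5 * bits + stats::rnorm(N_BANDS, 0, 0.02)
    }
    base <- base_g[group, , drop = FALSE] # pair members share base exactly
    phase <- ifelse(side == 2L, round(cfg$n_months / 4), 0L)

    # Acquisition/cloud schedule: per tile, month and product.
    sched <- expand.grid(
      ty = seq_len(cfg$n_tiles_y), tx = seq_len(cfg$n_tiles_x),
      month_index = 0:(cfg$n_months - 1L),
      product_index = seq_len(cfg$products_per_month),
      KEEP.OUT.ATTRS = FALSE
    )
    sched <- sched[order(sched$tx, sched$ty, sched$month_index,
                         sched$product_index), , drop = FALSE]
    sched$tile_id <- tile_id_of(sched$tx, sched$ty)
    # distinct sensing days within a tile-month
    days <- unlist(lapply(seq_len(nrow(sched) %/% cfg$products_per_month),
                          function(i) sort(sample.int(28, cfg$products_per_month))))
    sched$sensing_time <- sched$month_index * 100 + days
    sched$cloudy <- stats::runif(nrow(sched)) < cfg$cloud_prob
    sched$cloud_frac <- ifelse(sched$cloudy, stats::rbeta(nrow(sched), 2, 5), 0)
    rownames(sched) <- NULL

    # Observation bias: smooth east-west exponential gradient.
    xnorm <- (seq_len(W) - 0.5) / W
    obs_bias <- matrix(rep(exp(1.5 * xnorm), each = H), H, W)
  })

  # Region of each tile: rectangular super-blocks.
  tx_all <- seq_len(cfg$n_tiles_x)
  ty_all <- seq_len(cfg$n_tiles_y)
  rx <- pmin(cfg$n_regions_x, 1L + ((tx_all - 1L) * cfg$n_regions_x) %/% cfg$n_tiles_x)
  ry <- pmin(cfg$n_regions_y, 1L + ((ty_all - 1L) * cfg$n_regions_y) %/% cfg$n_tiles_y)
  region_tile <- outer(ry, rx, function(a, b) (a - 1L) * cfg$n_regions_x + b)

  dpp <- cfg$resolution_m / METERS_PER_DEGREE # degrees per pixel
  structure(list(
    config = cfg,
    habitat = habitat,
    base = base, phase = phase, group = group, side = side,
    schedule = sched,
    region_tile = region_tile,
    n_regions = cfg$n_regions_x * cfg$n_regions_y,
    obs_bias = obs_bias,
    # georeferencing: equirectangular, west edge at lon 0, centred on equator
    lon_min = 0, lat_max = (H / 2) * dpp, deg_per_px = dpp,
    width_px = W, height_px = H
  ), class = "sdm_world")
}

#' Seasonal signature lookup
#'
#' Expected (noise-free) reflectance of a habitat in a given month and band.
#' Vectorised over `habitat`.
#'
#' @param world An `sdm_world`.
#' @param habitat Habitat class indices (1-based).
#' @param month_index Zero-based month.
#' @param band Band index, 1 = R, 2 = G, 3 = B, 4 = IR.
#' @return Numeric vector of reflectances.
#' @export
seasonal_signature <- function(world, habitat, month_index, band) {
  cfg <- world$config
  h <- as.vector(habitat)
  world$base[cbind(h, band)] +
    cfg$seasonal_amplitude *
      sin(2 * pi * (month_index + world$phase[h]) / cfg$n_months)
}

# Region label of pixels given (row, col) matrices/vectors.
pixel_region <- function(world, row, col) {
  tp <- world$config$tile_px
  ty <- (row - 1L) %/% tp + 1L
  tx <- (col - 1L) %/% tp + 1L
  world$region_tile[cbind(ty, tx)]
}

#' Species pool with a long-tailed abundance law and seasonal niches
#'
#' Species relative abundances follow a Zipf law (rank-frequency exponent
#' `zipf_exponent`). Each species spreads its habitat affinity over the pair
#' groups (Dirichlet weights) and, within each group, prefers one seasonal
#' phase side with weight `(1 + p) / 2` where `p` is its `phase_dependence`.
#' With `phase_dependence = 0` the two members of each habitat pair are
#' equally likely for every species, so the occurrence process carries no
#' temporal-order signal at all.
#'
#' @param n_species Number of species.
#' @param n_habitats Number of habitat classes of the target world.
#' @param zipf_exponent Zipf rank-frequency exponent (larger = longer tail).
#' @param phase_dependence Scalar or per-species weight in \[0, 1\] giving how
#'   strongly the niche depends on the seasonal phase side.
#' @param group_concentration Dirichlet concentration of habitat-group
#'   weights; smaller values give more specialised species.
#' @param seed Integer seed.
#' @return An object of class `species_pool`.
#' @export
species_pool <- function(n_species = 40, n_habitats = 8, zipf_exponent = 1.4,
                         phase_dependence = 0.8, group_concentration = 0.7,
                         seed = 1) {
  stopifnot(n_species >= 1, n_habitats >= 1)
  if (any(phase_dependence < 0 | phase_dependence > 1)) {
    stop("'phase_dependence' must be in [0, 1]", call. = FALSE)
  }
  S <- as.integer(n_species)
  abundance <- seq_len(S)^(-zipf_exponent)
  abundance <- abundance / sum(abundance)
  group <- (seq_len(n_habitats) + 1L) %/% 2L
  side <- 2L - (seq_len(n_habitats) %% 2L)
  n_groups <- max(group)
  pdep <- rep_len(phase_dependence, S)

  withr::with_seed(child_seed(seed, "pool"), {
    gw <- matrix(stats::rgamma(S * n_groups, shape = group_concentration),
                 S, n_groups)
    gw <- gw / rowSums(gw)
    side_pref <- sample(1:2, S, replace = TRUE)
  })

  affinity <- matrix(0, S, n_habitats)
  for (h in seq_len(n_habitats)) {
    mult <- ifelse(side[h] == side_pref, (1 + pdep) / 2, (1 - pdep) / 2)
    # a habitat alone in its group takes the full group weight
    if (sum(group == group[h]) == 1L) mult <- 1
    affinity[, h] <- gw[, group[h]] * mult
  }
  affinity <- affinity / rowSums(affinity)
  if (any(rowSums(affinity > 0) < 1)) {
    stop("every species must have at least one positive habitat affinity",
         call. = FALSE)
  }

  structure(list(
    n_species = S, abundance = abundance, zipf_exponent = zipf_exponent,
    affinity = affinity, phase_dependence = pdep, side_pref = side_pref,
    group_weights = gw, seed = as.integer(seed)
  ), class = "species_pool")
}

# Nested region availability creating a richness gradient: region 1 hosts the
# full pool, the last region ~30% of it (most abundant species first).
region_species_mask <- function(world, pool) {
  R <- world$n_regions
  S <- pool$n_species
  frac <- if (R == 1) 1 else 1 - 0.7 * (seq_len(R) - 1) / (R - 1)
  mask <- matrix(FALSE, R, S)
  for (r in seq_len(R)) mask[r, seq_len(ceiling(S * frac[r]))] <- TRUE
  mask
}

#' Sample geolocated occurrences from the synthetic world
#'
#' Species are drawn from the pool's abundance law; each record's location is
#' drawn from pixels whose habitat matches the species niche, weighted by the
#' observation-bias surface, and restricted to the regions that host the
#' species (regions carry a nested richness gradient). Records receive a
#' (partly missing) observation month and coordinate uncertainty, mimicking
#' heterogeneous occurrence metadata.
#'
#' @param world An `sdm_world`.
#' @param pool A [species_pool()].
#' @param n Number of records to draw (>= 1).
#' @param bias Optional observation-bias surface (matrix of the world's pixel
#'   dimensions); defaults to the world's built-in east-west gradient.
#' @param seed Integer seed.
#' @return A data.frame with columns `occurrence_id`, `species_id`, `lon`,
#'   `lat`, `date`, `coord_uncertainty_m`, `region_id`.
#' @export
sample_occurrences <- function(world, pool, n, bias = NULL, seed = 1) {
  stopifnot(inherits(world, "sdm_world"), inherits(pool, "species_pool"))
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be >= 1", call. = FALSE)
  bias <- bias %||% world$obs_bias
  stopifnot(all(dim(bias) == dim(world$habitat)))

  H <- world$height_px; W <- world$width_px
  px <- seq_len(H * W)
  rowv <- ((px - 1L) %% H) + 1L
  colv <- ((px - 1L) %/% H) + 1L
  regv <- pixel_region(world, rowv, colv)
  habv <- as.vector(world$habitat)
  nH <- world$config$n_habitats
  R <- world$n_regions
  cat_of <- (regv - 1L) * nH + habv
  px_by_cat <- split(px, factor(cat_of, levels = seq_len(R * nH)))
  bias_by_cat <- lapply(px_by_cat, function(ix) bias[ix])
  bias_sum <- vapply(bias_by_cat, function(b) if (length(b)) sum(b) else 0, 0)
  allowed <- region_species_mask(world, pool)

  # category weights per species: affinity x regional availability x bias mass
  cat_reg <- rep(seq_len(R), each = nH)
  cat_hab <- rep(seq_len(nH), times = R)
  sp_cat_w <- function(s) {
    pool$affinity[s, cat_hab] * allowed[cbind(cat_reg, s)] * bias_sum
  }

  withr::with_seed(child_seed(seed, "occurrences"), {
    species <- resample(seq_len(pool$n_species), n, prob = pool$abundance)
    # species with an empty realised niche are warned about and resampled
    valid <- vapply(seq_len(pool$n_species), function(s) sum(sp_cat_w(s)) > 0,
                    NA)
    if (any(!valid[unique(species)])) {
      bad <- sort(unique(species[!valid[species]]))
      warning(sprintf("species with empty niche skipped and resampled: %s",
                      paste(bad, collapse = ", ")), call. = FALSE)
      while (any(!valid[species])) {
        k <- which(!valid[species])
        species[k] <- resample(seq_len(pool$n_species), length(k),
                               prob = pool$abundance)
      }
    }

    pixel <- integer(n)
    for (s in unique(species)) {
      ids <- which(species == s)
      w <- sp_cat_w(s)
      cats <- resample(which(w > 0), length(ids), prob = w[w > 0])
      for (cc in unique(cats)) {
        sub <- ids[cats == cc]
        pixel[sub] <- resample(px_by_cat[[cc]], length(sub),
                               prob = bias_by_cat[[cc]])
      }
    }

    r <- ((pixel - 1L) %% H) + 1L
    cl <- ((pixel - 1L) %/% H) + 1L
    lon <- world$lon_min + (cl - 0.5) * world$deg_per_px
    lat <- world$lat_max - (r - 0.5) * world$deg_per_px
    month <- sample.int(world$config$n_months, n, replace = TRUE) - 1L
    date <- sprintf("2020-%02d", month + 1L)
    date[stats::runif(n) < 0.15] <- NA
    unc <- round(stats::rlnorm(n, log(30), 0.8))
    unc[stats::runif(n) < 0.2] <- NA
  })

  data.frame(
    occurrence_id = sprintf("occ%06d", seq_len(n)),
    species_id = species,
    lon = lon, lat = lat,
    date = date,
    coord_uncertainty_m = unc,
    region_id = pixel_region(world, r, cl),
    stringsAsFactors = FALSE
  )
}

#' Render one raster product (a single acquisition of a tile)
#'
#' The noise-free value of each pixel is the seasonal signature of its
#' habitat; Gaussian observation noise is added, and -- for acquisitions the
#' world's schedule marks as cloudy -- a smooth thresholded-noise cloud field
#' overwrites part of the scene with high white reflectance. The reported
#' `cloud_percent` is computed from the realised mask.
#'
#' @param world An `sdm_world`.
#' @param tile_id Tile identifier, e.g. `"T01-02"`.
#' @param month_index Zero-based month.
#' @param product_index Which acquisition of that tile-month (1-based).
#' @return An object of class `raster_product` with fields `tile_id`,
#'   `month_index`, `sensing_time`, `bands` (tile_px x tile_px x 4 array),
#'   `cloud_percent` and `cloud_mask`.
#' @export
render_product <- function(world, tile_id, month_index, product_index = 1) {
  stopifnot(inherits(world, "sdm_world"))
  cfg <- world$config
  row <- world$schedule[world$schedule$tile_id == tile_id &
                        world$schedule$month_index == month_index &
                        world$schedule$product_index == product_index, ]
  if (nrow(row) != 1L) {
    stop(sprintf("unknown product: tile '%s', month %s, product %s",
                 tile_id, month_index, product_index), call. = FALSE)
  }
  tp <- cfg$tile_px
  hab <- world$habitat[(row$ty - 1L) * tp + seq_len(tp),
                       (row$tx - 1L) * tp + seq_len(tp), drop = FALSE]

  withr::with_seed(child_seed(cfg$seed, "product", tile_id, month_index,
                              product_index), {
    bands <- array(0, c(tp, tp, N_BANDS))
    for (b in seq_len(N_BANDS)) {
      bands[, , b] <- seasonal_signature(world, hab, month_index, b) +
        stats::rnorm(tp * tp, 0, cfg$noise_sd)
    }
    mask <- matrix(FALSE, tp, tp)
    if (row$cloudy && row$cloud_frac > 0) {
      field <- box_blur(matrix(stats::rnorm(tp * tp), tp, tp),
                        max(2L, tp %/% 8L), passes = 2)
      thr <- stats::quantile(field, 1 - row$cloud_frac)
      mask <- field >= thr
      n_cl <- sum(mask)
      if (n_cl > 0) {
        for (b in seq_len(N_BANDS)) {
          bb <- bands[, , b]
          bb[mask] <- stats::rnorm(n_cl, 1.8, 0.05)
          bands[, , b] <- bb
        }
      }
    }
  })
  bands[bands < 0] <- 0

  structure(list(
    tile_id = tile_id, month_index = as.integer(month_index),
    product_index = as.integer(product_index),
    sensing_time = row$sensing_time,
    bands = bands,
    cloud_percent = 100 * mean(mask),
    cloud_mask = mask
  ), class = "raster_product")
}

#' Render all products of a world (optionally a subset of tiles/months)
#'
#' @param world An `sdm_world`.
#' @param tiles Character vector of tile ids (default: all).
#' @param months Zero-based months (default: all).
#' @return A list of `raster_product` objects.
#' @export
render_products <- function(world, tiles = NULL, months = NULL) {
  sched <- world$schedule
  if (!is.null(tiles)) sched <- sched[sched$tile_id %in% tiles, ]
  if (!is.null(months)) sched <- sched[sched$month_index %in% months, ]
  lapply(seq_len(nrow(sched)), function(i) {
    render_product(world, sched$tile_id[i], sched$month_index[i],
                   sched$product_index[i])
  })
}

#' Write / read an occurrence table as CSV
#'
#' Plain CSV with the canonical header (`occurrence_id`, `species_id`, `lon`,
#' `lat`, `date`, `coord_uncertainty_m`, `region_id`).
#'
#' @param occurrences Occurrence data.frame.
#' @param path File path.
#' @return `read_occurrences` returns the data.frame.
#' @export
write_occurrences <- function(occurrences, path) {
  utils::write.csv(occurrences, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_occurrences
#' @export
read_occurrences <- function(path) {
  occ <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(date = "character"))
  occ$date[!is.na(occ$date) & occ$date == ""] <- NA
  occ
}

#' Write / read a world configuration as plain `key = value` text
#'
#' @param config A [world_config()].
#' @param path File path.
#' @return `read_world_config` returns a `world_config`.
#' @export
write_world_config <- function(config, path) {
  stopifnot(inherits(config, "world_config"))
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, format, "", digits = 17)), path)
  invisible(path)
}

#' @rdname write_world_config
#' @export
read_world_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- lapply(kv, function(x) as.numeric(x[2]))
  names(vals) <- vapply(kv, `[[`, "", 1)
  do.call(world_config, vals)
}

#' Write / read a raster product as a 16-bit TIFF plus JSON sidecar
#'
#' Reflectances are stored as digital numbers (reflectance x 10000) in a
#' 16-bit TIFF, following the Sentinel-2 L1C convention; georeferencing and
#' acquisition metadata (tile footprint, sensing time, cloud percentage,
#' scale factor) go to a JSON sidecar next to the image. Values survive the
#' round trip up to the 1e-4 quantisation step.
#'
#' @param product A `raster_product`.
#' @param path Output TIFF path (`<path>.json` holds the metadata).
#' @param world The originating `sdm_world` (for the footprint metadata).
#' @return `read_product` returns a `raster_product` (without cloud mask).
#' @export
write_product <- function(product, path, world = NULL) {
  scale <- 10000
  dn <- pmin(pmax(product$bands, 0), 65535 / scale)
  tiff::writeTIFF(dn * scale / 65535, path, bits.per.sample = 16,
                  reduce = FALSE)
  meta <- list(
    tile_id = product$tile_id, month_index = product$month_index,
    product_index = product$product_index,
    sensing_time = product$sensing_time,
    cloud_percent = product$cloud_percent,
    scale_factor = scale, n_bands = dim(product$bands)[3]
  )
  if (!is.null(world)) {
    sched <- world$schedule
    i <- match(product$tile_id, sched$tile_id)
    tp <- world$config$tile_px
    meta$footprint <- list(
      lon_min = world$lon_min + (sched$tx[i] - 1) * tp * world$deg_per_px,
      lon_max = world$lon_min + sched$tx[i] * tp * world$deg_per_px,
      lat_max = world$lat_max - (sched$ty[i] - 1) * tp * world$deg_per_px,
      lat_min = world$lat_max - sched$ty[i] * tp * world$deg_per_px,
      resolution_m = world$config$resolution_m
    )
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_product
#' @export
read_product <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  # the 4th (IR) sample triggers a benign "ExtraSamples" note in libtiff
  img <- suppressWarnings(tiff::readTIFF(path))
  bands <- round(img * 65535) / meta$scale_factor
  structure(list(
    tile_id = meta$tile_id, month_index = meta$month_index,
    product_index = meta$product_index, sensing_time = meta$sensing_time,
    bands = bands, cloud_percent = meta$cloud_percent, cloud_mask = NULL,
    footprint = meta$footprint
  ), class = "raster_product")
}
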