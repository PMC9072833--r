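# Dataset-construction workflow: from occurrences and monthly raster products
# to model-ready image time-series. Mirrors the real-data pipeline: greedy
# minimal tile cover, per-month least-cloudy product selection, windowed patch
# extraction (merging adjacent tiles where a window crosses an edge), and
# chronological channel stacking.

#' Tile grid of a synthetic world
#'
#' One row per tile with its lon/lat footprint. Footprints of a synthetic
#' world partition the plane, but [compute_tile_cover()] accepts any grid,
#' including overlapping footprints as real satellite tiling grids have.
#'
#' @param world An `sdm_world`.
#' @return A data.frame of class `tile_grid` with columns `tile_id`, `tx`,
#'   `ty`, `lon_min`, `lon_max`, `lat_min`, `lat_max`, plus attributes
#'   `tile_px`, `resolution_m` and the world georeferencing.
#' @export
tile_grid <- function(world) {
  stopifnot(inherits(world, "sdm_world"))
  cfg <- world$config
  tp <- cfg$tile_px
  g <- expand.grid(ty = seq_len(cfg$n_tiles_y), tx = seq_len(cfg$n_tiles_x),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$tx, g$ty), , drop = FALSE]
  dpp <- world$deg_per_px
  out <- data.frame(
    tile_id = tile_id_of(g$tx, g$ty), tx = g$tx, ty = g$ty,
    lon_min = world$lon_min + (g$tx - 1) * tp * dpp,
    lon_max = world$lon_min + g$tx * tp * dpp,
    lat_min = world$lat_max - g$ty * tp * dpp,
    lat_max = world$lat_max - (g$ty - 1) * tp * dpp,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, class = c("tile_grid", "data.frame"),
            tile_px = tp, resolution_m = cfg$resolution_m,
            lon0 = world$lon_min, lat_top = world$lat_max,
            deg_per_px = dpp,
            width_px = world$width_px, height_px = world$height_px)
}

# closed-interval point-in-footprint test; returns indices of containing tiles
tiles_containing <- function(grid, lon, lat) {
  which(lon >= grid$lon_min & lon <= grid$lon_max &
        lat >= grid$lat_min & lat <= grid$lat_max)
}

#' Greedy minimal tile cover of an occurrence set
#'
#' Iterates over the occurrences in input order; whenever a record is not yet
#' inside the union of retained tile footprints, one tile containing it is
#' added (the lexicographically smallest `tile_id` among candidates, for
#' determinism). The returned union contains every occurrence.
#'
#' @param occurrences Data.frame with `lon`, `lat` (and `occurrence_id` used
#'   in error messages).
#' @param grid A tile grid data.frame (footprints may overlap).
#' @return Sorted character vector of retained tile ids.
#' @export
compute_tile_cover <- function(occurrences, grid) {
  retained <- character(0)
  ret_idx <- integer(0)
  for (i in seq_len(nrow(occurrences))) {
    lon <- occurrences$lon[i]; lat <- occurrences$lat[i]
    if (length(ret_idx) &&
        any(lon >= grid$lon_min[ret_idx] & lon <= grid$lon_max[ret_idx] &
            lat >= grid$lat_min[ret_idx] & lat <= grid$lat_max[ret_idx])) {
      next
    }
    cand <- tiles_containing(grid, lon, lat)
    if (!length(cand)) {
      id <- if ("occurrence_id" %in% names(occurrences)) {
        occurrences$occurrence_id[i]
      } else {
        as.character(i)
      }
      stop(sprintf("occurrence '%s' (%g, %g) lies outside all tiles",
                   id, lon, lat), call. = FALSE)
    }
    pick <- cand[order(grid$tile_id[cand])][1]
    ret_idx <- c(ret_idx, pick)
    retained <- c(retained, grid$tile_id[pick])
  }
  sort(unique(retained))
}

#' Least-cloudy monthly product selection
#'
#' For every tile and month, retains the product with minimal cloud
#' percentage (ties broken by earliest sensing time). Months with no product
#' at all are flagged missing so the series builder can engage its fallback.
#'
#' @param products List of `raster_product` objects.
#' @param n_months Number of months of the target series (default: inferred
#'   as `max(month_index) + 1`).
#' @return An object of class `selected_products`: a list with `table` (one
#'   row per tile-month: `tile_id`, `month_index`, `cloud_percent`,
#'   `sensing_time`, `missing`) and `products` (chosen products keyed by
#'   `"<tile_id>#<month>"`).
#' @export
select_monthly_products <- function(products, n_months = NULL) {
  if (!length(products)) {
    return(structure(list(
      table = data.frame(tile_id = character(0), month_index = integer(0),
                         cloud_percent = numeric(0), sensing_time = numeric(0),
                         missing = logical(0)),
      products = list(), n_months = n_months %||% 0L
    ), class = "selected_products"))
  }
  meta <- data.frame(
    i = seq_along(products),
    tile_id = vapply(products, `[[`, "", "tile_id"),
    month_index = vapply(products, function(p) as.integer(p$month_index), 0L),
    cloud_percent = vapply(products, `[[`, 0, "cloud_percent"),
    sensing_time = vapply(products, `[[`, 0, "sensing_time"),
    stringsAsFactors = FALSE
  )
  n_months <- as.integer(n_months %||% (max(meta$month_index) + 1L))
  tiles <- sort(unique(meta$tile_id))
  tab <- expand.grid(month_index = 0:(n_months - 1L), tile_id = tiles,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- tab[, c("tile_id", "month_index")]
  tab$cloud_percent <- NA_real_
  tab$sensing_time <- NA_real_
  tab$missing <- TRUE
  chosen <- list()
  for (j in seq_len(nrow(tab))) {
    sub <- meta[meta$tile_id == tab$tile_id[j] &
                meta$month_index == tab$month_index[j], ]
    if (!nrow(sub)) next
    best <- sub[order(sub$cloud_percent, sub$sensing_time), ][1, ]
    tab$cloud_percent[j] <- best$cloud_percent
    tab$sensing_time[j] <- best$sensing_time
    tab$missing[j] <- FALSE
    chosen[[sprintf("%s#%02d", tab$tile_id[j], tab$month_index[j])]] <-
      products[[best$i]]
  }
  rownames(tab) <- NULL
  structure(list(table = tab, products = chosen, n_months = n_months),
            class = "selected_products")
}

# which tiles of a regular grid intersect global pixel window
# rows r0..r1, cols c0..c1 (zero-based, inclusive)
window_tiles <- function(grid, r0, r1, c0, c1) {
  tp <- attr(grid, "tile_px")
  tx0 <- c0 %/% tp + 1L; tx1 <- c1 %/% tp + 1L
  ty0 <- r0 %/% tp + 1L; ty1 <- r1 %/% tp + 1L
  expand.grid(tx = tx0:tx1, ty = ty0:ty1, KEEP.OUT.ATTRS = FALSE)
}

#' Extract a multispectral patch around a location
#'
#' The location is mapped to the pixel containing it; an even-sized window of
#' `size_px` pixels is taken with the centre pixel at (zero-based) index
#' `size_px / 2`, i.e. rows `[r - size_px/2, r + size_px/2)` in the half-open,
#' north-up, row-major convention. Windows crossing a tile edge are read from
#' the mosaic of the adjacent selected products. Windows leaving the world
#' bounds raise an error unless `fill` is given, in which case out-of-world
#' pixels take the fill value and the result is flagged.
#'
#' @param selected A [select_monthly_products()] result.
#' @param grid A [tile_grid()] of the originating world.
#' @param lon,lat Location in decimal degrees.
#' @param month_index Zero-based month to read.
#' @param size_px Even patch edge length in pixels.
#' @param fill Optional fill value for out-of-world pixels.
#' @return `size_px x size_px x 4` array with attributes `complete` (FALSE if
#'   any needed tile-month was missing) and `filled` (TRUE if out-of-world
#'   pixels were filled).
#' @export
extract_patch <- function(selected, grid, lon, lat, month_index, size_px,
                          fill = NULL) {
  if (size_px %% 2L != 0L) stop("'size_px' must be even", call. = FALSE)
  dpp <- attr(grid, "deg_per_px")
  lon0 <- attr(grid, "lon0"); lat_top <- attr(grid, "lat_top")
  Wpx <- attr(grid, "width_px"); Hpx <- attr(grid, "height_px")
  tp <- attr(grid, "tile_px")
  c_ctr <- floor((lon - lon0) / dpp)
  r_ctr <- floor((lat_top - lat) / dpp)
  half <- size_px %/% 2L
  r0 <- r_ctr - half; r1 <- r_ctr + half - 1L
  c0 <- c_ctr - half; c1 <- c_ctr + half - 1L

  filled <- r0 < 0 || c0 < 0 || r1 >= Hpx || c1 >= Wpx
  if (filled && is.null(fill)) {
    stop(sprintf(
      "window around (%g, %g) extends beyond the world bounds", lon, lat),
      call. = FALSE)
  }
  out <- array(if (filled) fill else 0, c(size_px, size_px, N_BANDS))
  complete <- TRUE
  wt <- window_tiles(grid, max(r0, 0L), min(r1, Hpx - 1L),
                     max(c0, 0L), min(c1, Wpx - 1L))
  for (i in seq_len(nrow(wt))) {
    tx <- wt$tx[i]; ty <- wt$ty[i]
    key <- sprintf("%s#%02d", tile_id_of(tx, ty), month_index)
    prod <- selected$products[[key]]
    if (is.null(prod)) {
      complete <- FALSE
      next
    }
    # overlap of the window with this tile, in global zero-based pixels
    gr0 <- max(r0, (ty - 1L) * tp); gr1 <- min(r1, ty * tp - 1L)
    gc0 <- max(c0, (tx - 1L) * tp); gc1 <- min(c1, tx * tp - 1L)
    out[(gr0 - r0 + 1L):(gr1 - r0 + 1L),
        (gc0 - c0 + 1L):(gc1 - c0 + 1L), ] <-
      prod$bands[(gr0 - (ty - 1L) * tp + 1L):(gr1 - (ty - 1L) * tp + 1L),
                 (gc0 - (tx - 1L) * tp + 1L):(gc1 - (tx - 1L) * tp + 1L), ,
                 drop = FALSE]
  }
  attr(out, "complete") <- complete
  attr(out, "filled") <- filled
  out
}

# months (zero-based) whose needed tiles are all present for this window
available_months <- function(selected, grid, lon, lat, size_px) {
  n_months <- selected$n_months
  ok <- logical(n_months)
  tab <- selected$table
  dpp <- attr(grid, "deg_per_px")
  tp <- attr(grid, "tile_px")
  half <- size_px %/% 2L
  c_ctr <- floor((lon - attr(grid, "lon0")) / dpp)
  r_ctr <- floor((attr(grid, "lat_top") - lat) / dpp)
  wt <- window_tiles(grid,
                     max(r_ctr - half, 0L),
                     min(r_ctr + half - 1L, attr(grid, "height_px") - 1L),
                     max(c_ctr - half, 0L),
                     min(c_ctr + half - 1L, attr(grid, "width_px") - 1L))
  ids <- tile_id_of(wt$tx, wt$ty)
  for (m in 0:(n_months - 1L)) {
    keys <- sprintf("%s#%02d", ids, m)
    ok[m + 1L] <- all(keys %in% names(selected$products))
  }
  ok
}

#' Build the image time-series of one occurrence
#'
#' Stacks monthly patches chronologically as the outer channel index with the
#' four bands (R, G, B, IR) inner, giving `n_months * 4` channels: channel
#' `m * 4 + b` (zero-based) is month `m`, band `b`. Months whose products are
#' missing are filled from the nearest available month (earlier preferred on
#' ties) and flagged in `month_available`.
#'
#' @param occurrence One-row data.frame (or list) with `occurrence_id`,
#'   `lon`, `lat`.
#' @param selected A [select_monthly_products()] result.
#' @param grid A [tile_grid()].
#' @param size_px Even patch edge length.
#' @param fill Optional fill value for out-of-world pixels.
#' @return An object of class `image_series`: list with `occurrence_id`,
#'   `data` (`size_px x size_px x n_months*4` array), `month_available`
#'   (logical), and `layout`.
#' @export
build_series <- function(occurrence, selected, grid, size_px, fill = NULL) {
  n_months <- selected$n_months
  avail <- available_months(selected, grid, occurrence$lon, occurrence$lat,
                            size_px)
  if (!any(avail)) {
    stop(sprintf("all %d months are missing for occurrence '%s'", n_months,
                 occurrence$occurrence_id), call. = FALSE)
  }
  data <- array(0, c(size_px, size_px, n_months * N_BANDS))
  cache <- vector("list", n_months)
  for (m in 0:(n_months - 1L)) {
    src <- m
    if (!avail[m + 1L]) {
      cand <- which(avail) - 1L
      # nearest available month, earlier preferred on distance ties
      src <- cand[order(abs(cand - m), cand)][1]
    }
    if (is.null(cache[[src + 1L]])) {
      cache[[src + 1L]] <- extract_patch(selected, grid, occurrence$lon,
                                         occurrence$lat, src, size_px,
                                         fill = fill)
    }
    data[, , m * N_BANDS + seq_len(N_BANDS)] <- cache[[src + 1L]]
  }
  structure(list(
    occurrence_id = occurrence$occurrence_id,
    data = data,
    month_available = avail,
    layout = "channel = month * 4 + band (zero-based); bands R,G,B,IR"
  ), class = "image_series")
}

#' Build series for a whole occurrence table
#'
#' @param occurrences Occurrence data.frame.
#' @param selected,grid,size_px,fill As in [build_series()].
#' @return List with `series` (list of `image_series`, in occurrence order)
#'   and `manifest` (data.frame: `occurrence_id`, `month_available` bitmask
#'   string, and the per-month cloud percentage of the occurrence's tile).
#' @export
build_series_set <- function(occurrences, selected, grid, size_px,
                             fill = NULL) {
  n_months <- selected$n_months
  series <- vector("list", nrow(occurrences))
  bitmask <- character(nrow(occurrences))
  cloud <- matrix(NA_real_, nrow(occurrences), n_months)
  tab <- selected$table
  for (i in seq_len(nrow(occurrences))) {
    s <- build_series(occurrences[i, ], selected, grid, size_px, fill = fill)
    series[[i]] <- s
    bitmask[i] <- paste(as.integer(s$month_available), collapse = "")
    ti <- tiles_containing(grid, occurrences$lon[i], occurrences$lat[i])[1]
    sub <- tab[tab$tile_id == grid$tile_id[ti], ]
    cloud[i, sub$month_index + 1L] <- sub$cloud_percent
  }
  manifest <- data.frame(occurrence_id = occurrences$occurrence_id,
                         month_available = bitmask,
                         stringsAsFactors = FALSE)
  manifest[sprintf("cloud_m%02d", 0:(n_months - 1L))] <- as.data.frame(cloud)
  list(series = series, manifest = manifest)
}

#' Stack a list of image series into one 4-d array
#'
#' Returns an `(size, size, channels, n)` array suitable for batched model
#' input, with occurrence ids as the names of the last dimension.
#'
#' @param series List of `image_series`.
#' @return 4-d numeric array.
#' @export
series_array <- function(series) {
  d <- dim(series[[1]]$data)
  x <- array(0, c(d, length(series)))
  for (i in seq_along(series)) x[, , , i] <- series[[i]]$data
  dimnames(x) <- list(NULL, NULL, NULL,
                      vapply(series, `[[`, "", "occurrence_id"))
  x
}

#' Write / read one image series, and write a series set with its manifest
#'
#' Each series is stored as one compressed RDS file (values survive the round
#' trip bit-exactly); a set is a directory of such files plus `manifest.csv`
#' adding the per-occurrence file path.
#'
#' @param series An `image_series` (or for the set variant, the result of
#'   [build_series_set()]).
#' @param path File path (directory for the set variant).
#' @return `read_series` returns the `image_series`.
#' @export
write_series <- function(series, path) {
  saveRDS(series, path)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) readRDS(path)

#' @rdname write_series
#' @export
write_series_set <- function(series, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  man <- series$manifest
  man$path <- file.path(path, paste0(man$occurrence_id, ".rds"))
  for (i in seq_along(series$series)) {
    saveRDS(series$series[[i]], man$path[i])
  }
  utils::write.csv(man, file.path(path, "manifest.csv"), row.names = FALSE)
  invisible(path)
}
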