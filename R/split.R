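# Spatial-block, region-stratified train/validation/test partition.
# Whole blocks -- not individual records -- are assigned to a set, so that
# validation/test locations are never a few pixels away from training ones
# (spatial autocorrelation would otherwise inflate test scores).

#' Spatial block of a coordinate
#'
#' Blocks are square cells of `block_deg` degrees in the spherical coordinate
#' system; the block id is the integer pair
#' `(floor(lon / block_deg), floor(lat / block_deg))`. At the default 0.025
#' degrees this is a 2.775 km block at the equator.
#'
#' @param lon,lat Coordinates in decimal degrees (vectorised).
#' @param block_deg Block edge in degrees.
#' @return data.frame with integer columns `block_x`, `block_y`.
#' @export
assign_block <- function(lon, lat, block_deg = 0.025) {
  data.frame(block_x = as.integer(floor(lon / block_deg)),
             block_y = as.integer(floor(lat / block_deg)))
}

#' Region-stratified spatial-block split
#'
#' Within each region, 90% of the spatial blocks (round-half-up) are drawn at
#' random into the training set; each remaining block goes to validation or
#' test by an independent fair coin (more generally, with probability
#' proportional to the second and third entries of `fractions`). All
#' occurrences of one block share one label. A region with a single block
#' sends it to training with a warning.
#'
#' @param occurrences Data.frame with `occurrence_id`, `lon`, `lat`,
#'   `region_id`.
#' @param fractions Length-3 target fractions (train, val, test).
#' @param block_deg Block edge in degrees.
#' @param seed Integer seed; the assignment is deterministic given it.
#' @return The input data.frame with added columns `block_x`, `block_y`,
#'   `block_id` and `split` (factor: train/val/test).
#' @export
stratified_block_split <- function(occurrences, fractions = c(0.9, 0.05, 0.05),
                                   block_deg = 0.025, seed = 1) {
  stopifnot(length(fractions) == 3, all(fractions >= 0),
            abs(sum(fractions) - 1) < 1e-8)
  if (!all(c("lon", "lat", "region_id") %in% names(occurrences))) {
    stop("occurrences need 'lon', 'lat' and 'region_id' columns",
         call. = FALSE)
  }
  occ <- occurrences
  bl <- assign_block(occ$lon, occ$lat, block_deg)
  occ$block_x <- bl$block_x
  occ$block_y <- bl$block_y
  occ$block_id <- paste(bl$block_x, bl$block_y, sep = ":")
  occ$split <- NA_character_
  p_val <- if (fractions[2] + fractions[3] > 0) {
    fractions[2] / (fractions[2] + fractions[3])
  } else {
    0.5
  }

  withr::with_seed(child_seed(seed, "split"), {
    for (r in sort(unique(occ$region_id))) {
      in_r <- occ$region_id == r
      blocks <- sort(unique(occ$block_id[in_r]))
      B <- length(blocks)
      if (B == 1L) {
        warning(sprintf(
          "region %s has a single spatial block; assigned to train", r),
          call. = FALSE)
        occ$split[in_r] <- "train"
        next
      }
      n_train <- as.integer(floor(fractions[1] * B + 0.5)) # round half up
      train_blocks <- sample(blocks, n_train)
      rest <- setdiff(blocks, train_blocks)
      to_val <- stats::runif(length(rest)) < p_val
      lab <- stats::setNames(rep("train", B), blocks)
      lab[rest] <- ifelse(to_val, "val", "test")
      occ$split[in_r] <- lab[occ$block_id[in_r]]
    }
  })
  occ$split <- factor(occ$split, levels = c("train", "val", "test"))
  occ
}

#' Drop validation/test occurrences of species unseen in training
#'
#' Validation and test occurrences whose species never occurs in the training
#' split are removed (their accuracy would be identically zero without the
#' model being at fault); the training set is untouched.
#'
#' @param split_occurrences Result of [stratified_block_split()].
#' @return The reduced data.frame.
#' @export
filter_unseen_species <- function(split_occurrences) {
  occ <- split_occurrences
  if (!nrow(occ)) return(occ)
  trained <- unique(occ$species_id[occ$split == "train"])
  keep <- occ$split == "train" | occ$species_id %in% trained
  occ[keep, , drop = FALSE]
}
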