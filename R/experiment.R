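# Orchestration of the four-model temporal-ablation experiment on a
# synthetic world: world -> products -> least-cloudy selection -> occurrences
# -> spatial-block split -> per-mode transformed datasets -> independently
# trained models -> evaluation statistics and relative-change analyses.

#' Experiment configuration
#'
#' Bundles the world, species pool, dataset, schedule and metric settings of
#' a full temporal-ablation experiment. The defaults are a desk-scale study:
#' a 6x6-tile world of 64 px tiles, 40 species, 2,000 occurrences and 16 px
#' patches, sized so that one full four-model replicate trains in minutes on
#' a single CPU.
#'
#' @param world A [world_config()].
#' @param n_species,zipf_exponent,phase_dependence,group_concentration
#'   Species-pool settings (see [species_pool()]).
#' @param n_occurrences Number of occurrence records to sample.
#' @param patch_px Patch edge in pixels (even).
#' @param block_deg Spatial-block edge in degrees; scaled to the world so a
#'   region holds tens of blocks.
#' @param fractions Train/val/test block fractions.
#' @param schedule A [train_schedule()].
#' @param backbone Backbone passed to [model_config()].
#' @param k Top-k of the reported metrics.
#' @param bins Occurrence-count interval edges for grouped tables.
#' @param q Hill diversity order.
#' @param min_region_support Minimal test occurrences for a region to enter
#'   the regional tables.
#' @param modes Subset of `c("original", "permute", "average", "sample")`.
#' @param seeds Replicate seeds: one independent model per mode and seed.
#' @param split_seed,occurrence_seed,pool_seed,transform_seed Seeds of the
#'   shared (mode-independent) pipeline stages.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(world = world_config(),
                              n_species = 40, zipf_exponent = 1.4,
                              phase_dependence = 0.8,
                              group_concentration = 0.7,
                              n_occurrences = 2000, patch_px = 16,
                              block_deg = 0.0025,
                              fractions = c(0.9, 0.05, 0.05),
                              schedule = train_schedule(
                                epochs = 10, batch_size = 64,
                                lr_decay_epochs = c(7, 9), drw_epoch = 9,
                                eval_every = 2, eval_k = 5),
                              backbone = "plain-cnn",
                              k = 5, bins = default_occurrence_bins, q = 1,
                              min_region_support = 10,
                              modes = TRANSFORM_MODES, seeds = 1,
                              split_seed = 1, occurrence_seed = 1,
                              pool_seed = 1, transform_seed = 1) {
  stopifnot(inherits(world, "world_config"),
            inherits(schedule, "train_schedule"))
  modes <- match.arg(modes, TRANSFORM_MODES, several.ok = TRUE)
  if (length(seeds) < 1) stop("need at least one replicate seed", call. = FALSE)
  structure(list(
    world = world, n_species = n_species, zipf_exponent = zipf_exponent,
    phase_dependence = phase_dependence,
    group_concentration = group_concentration,
    n_occurrences = n_occurrences, patch_px = as.integer(patch_px),
    block_deg = block_deg, fractions = fractions, schedule = schedule,
    backbone = backbone, k = as.integer(k), bins = bins, q = q,
    min_region_support = min_region_support, modes = modes, seeds = seeds,
    split_seed = split_seed, occurrence_seed = occurrence_seed,
    pool_seed = pool_seed, transform_seed = transform_seed
  ), class = "experiment_config")
}

#' All evaluation statistics of one model on one test set
#'
#' @param pred Probability matrix over species for the test occurrences.
#' @param test Test occurrence data.frame (`species_id`, `region_id`).
#' @param train_counts Per-species training occurrence counts.
#' @param k Top-k.
#' @param bins Occurrence-count interval edges.
#' @param q Hill diversity order.
#' @param min_region_support Region support cutoff.
#' @return List of class `metrics_report`: `hits`, `micro`, `species`
#'   (per-species scores), `macro`, `regions` (per-region scores), `by_bin`
#'   (macro accuracy per occurrence-count bin), `diversity`.
#' @export
metrics_report <- function(pred, test, train_counts, k = 30,
                           bins = default_occurrence_bins, q = 1,
                           min_region_support = 50) {
  hits <- top_k_hits(pred, test$species_id, k, region_id = test$region_id)
  species <- per_group_accuracy(hits)
  regions <- per_group_accuracy(hits, test$region_id,
                                min_support = min_region_support)
  ns <- train_counts[as.integer(species$group)]
  by_bin <- interval_grouped_mean(species, ns, bins)
  structure(list(
    hits = hits, micro = micro_accuracy(hits), species = species,
    macro = macro_mean(species), regions = regions,
    macro_region = if (nrow(regions)) macro_mean(regions) else NA_real_,
    by_bin = by_bin, diversity = diversity_table(test, q), k = k
  ), class = "metrics_report")
}

#' Run the temporal-ablation experiment end-to-end
#'
#' Generates the world and its products, selects the least-cloudy monthly
#' product per tile, samples occurrences, applies the region-stratified
#' spatial-block split (shared by all models), materialises the image
#' time-series once, and then -- for every transform mode and replicate seed
#' -- ablates a copy of the dataset, trains an independent model and
#' evaluates it on the common test occurrences. Relative-change tables and
#' the paired species test compare every ablated mode with the original
#' model of the same seed.
#'
#' @param config An [experiment_config()].
#' @param out_dir Optional directory to write the report CSVs to.
#' @param verbose Print stage progress.
#' @return List of class `experiment_report`.
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  say("generating world ...")
  world <- generate_world(config$world)
  pool <- species_pool(config$n_species, config$world$n_habitats,
                       config$zipf_exponent, config$phase_dependence,
                       config$group_concentration, seed = config$pool_seed)
  grid <- tile_grid(world)
  say("rendering %d products ...", nrow(world$schedule))
  products <- render_products(world)
  selected <- select_monthly_products(products, config$world$n_months)

  say("sampling %d occurrences ...", config$n_occurrences)
  occ <- sample_occurrences(world, pool, config$n_occurrences,
                            seed = config$occurrence_seed)
  occ <- stratified_block_split(occ, config$fractions, config$block_deg,
                                seed = config$split_seed)
  occ <- filter_unseen_species(occ)

  say("building series for %d occurrences ...", nrow(occ))
  built <- build_series_set(occ, selected, grid, config$patch_px, fill = 0)
  x_all <- series_array(built$series)

  is_train <- occ$split == "train"
  is_val <- occ$split == "val"
  is_test <- occ$split == "test"
  train_counts <- tabulate(occ$species_id[is_train], config$n_species)
  test <- occ[is_test, , drop = FALSE]

  runs <- list()
  for (mode in config$modes) {
    say("transform '%s' ...", mode)
    xm <- transform_series_array(x_all, mode, seed = config$transform_seed)
    for (seed in config$seeds) {
      sched <- config$schedule
      sched$seed <- child_seed(seed, mode, "schedule")
      mcfg <- model_config(
        n_species = config$n_species,
        input_channels = dim(xm)[3], input_px = config$patch_px,
        backbone = config$backbone,
        seed = child_seed(seed, mode, "model"))
      model <- build_model(mcfg)
      say("training mode '%s', seed %s ...", mode, seed)
      fit <- train_sdm(model,
                       xm[, , , is_train, drop = FALSE],
                       occ$species_id[is_train],
                       xm[, , , is_val, drop = FALSE],
                       occ$species_id[is_val],
                       sched, class_counts = train_counts)
      pred <- predict_sdm(fit$model, xm[, , , is_test, drop = FALSE])
      met <- metrics_report(pred, test, train_counts, k = config$k,
                            bins = config$bins, q = config$q,
                            min_region_support = config$min_region_support)
      runs[[sprintf("%s.%s", mode, seed)]] <- list(
        mode = mode, seed = seed, history = fit$history,
        best_epoch = fit$best_epoch, metrics = met)
    }
    rm(xm)
  }

  # summary: per-mode mean micro/macro over replicate seeds
  modes <- vapply(runs, `[[`, "", "mode")
  micro <- vapply(runs, function(r) r$metrics$micro, 0)
  macro <- vapply(runs, function(r) r$metrics$macro, 0)
  summary <- data.frame(
    mode = config$modes,
    micro_mean = as.numeric(tapply(micro, modes, mean)[config$modes]),
    macro_mean = as.numeric(tapply(macro, modes, mean)[config$modes]),
    macro_sd = as.numeric(tapply(macro, modes, stats::sd)[config$modes]),
    n_seeds = as.integer(table(modes)[config$modes])
  )

  # relative changes vs the original model of the same seed
  deltas <- list()
  if ("original" %in% config$modes) {
    for (seed in config$seeds) {
      ref <- runs[[sprintf("original.%s", seed)]]$metrics
      for (mode in setdiff(config$modes, "original")) {
        alt <- runs[[sprintf("%s.%s", mode, seed)]]$metrics
        sp_delta <- relative_change(ref$species, alt$species)
        ns <- stats::setNames(train_counts[as.integer(sp_delta$key)],
                              sp_delta$key)
        reg_delta <- if (nrow(ref$regions) && nrow(alt$regions)) {
          relative_change(ref$regions, alt$regions)
        } else {
          NULL
        }
        deltas[[sprintf("%s.%s", mode, seed)]] <- list(
          mode = mode, seed = seed,
          species = sp_delta,
          species_by_bin = grouped_relative_change(sp_delta, ns, config$bins),
          regions = reg_delta,
          paired_test = paired_species_test(ref$species, alt$species))
      }
    }
  }

  report <- structure(list(
    config = config, occurrences = occ, runs = runs, summary = summary,
    deltas = deltas, train_counts = train_counts,
    diversity = diversity_table(test, config$q)
  ), class = "experiment_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write an experiment report as a directory of CSV tables
#'
#' One CSV per table (summary, per-run history and per-species/region
#' scores, change tables with their `excluded` column, diversity) plus a
#' plain-text `summary.txt`.
#'
#' @param report An `experiment_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$diversity, file.path(dir, "diversity.csv"),
                   row.names = FALSE)
  for (nm in names(report$runs)) {
    r <- report$runs[[nm]]
    utils::write.csv(r$history, file.path(dir, sprintf("history_%s.csv", nm)),
                     row.names = FALSE)
    utils::write.csv(r$metrics$species,
                     file.path(dir, sprintf("species_%s.csv", nm)),
                     row.names = FALSE)
    utils::write.csv(r$metrics$regions,
                     file.path(dir, sprintf("regions_%s.csv", nm)),
                     row.names = FALSE)
    utils::write.csv(r$metrics$by_bin,
                     file.path(dir, sprintf("bins_%s.csv", nm)),
                     row.names = FALSE)
  }
  for (nm in names(report$deltas)) {
    d <- report$deltas[[nm]]
    utils::write.csv(d$species,
                     file.path(dir, sprintf("delta_species_%s.csv", nm)),
                     row.names = FALSE)
    utils::write.csv(d$species_by_bin,
                     file.path(dir, sprintf("delta_bins_%s.csv", nm)),
                     row.names = FALSE)
  }
  lines <- c("Temporal-ablation experiment summary",
             utils::capture.output(print(report$summary)))
  for (nm in names(report$deltas)) {
    pt <- report$deltas[[nm]]$paired_test
    lines <- c(lines, sprintf(
      "paired t-test original vs %s: t = %.3f, p = %.3g (n = %d species)",
      nm, pt$t, pt$p_value, pt$n))
  }
  writeLines(lines, file.path(dir, "summary.txt"))
  invisible(dir)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Temporal-ablation experiment\n")
  cat(sprintf("  occurrences: %d (train/val/test %d/%d/%d)\n",
              nrow(x$occurrences), sum(x$occurrences$split == "train"),
              sum(x$occurrences$split == "val"),
              sum(x$occurrences$split == "test")))
  cat(sprintf("  top-%d metrics over %d seed(s):\n", x$config$k,
              length(x$config$seeds)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
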