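# Temporal ablation: input transformations that selectively destroy temporal
# information (month permutation, temporal averaging, single-month sampling),
# relative performance-change statistics between a reference and an ablated
# model, and the species-level paired test.

TRANSFORM_MODES <- c("original", "permute", "average", "sample")

# per-occurrence month reindexing for one mode; n_months source indices
transform_months <- function(mode, n_months, occurrence_id, seed) {
  switch(mode,
    original = seq_len(n_months),
    permute = withr::with_seed(child_seed(seed, "transform", occurrence_id),
                               sample.int(n_months)),
    sample = rep(withr::with_seed(
      child_seed(seed, "transform", occurrence_id),
      sample.int(n_months, 1)), n_months),
    average = NULL, # handled separately
    stop(sprintf("unknown transform mode '%s'", mode), call. = FALSE)
  )
}

#' Ablate the temporal dimension of an image time-series
#'
#' Modes: `original` is the identity; `permute` reorders the months by a
#' per-occurrence uniform random permutation (all four bands of a month move
#' together), destroying the chronological sequencing but preserving the
#' multiset of monthly frames; `average` replaces every month by the
#' per-pixel, per-band mean over the months, keeping only the first temporal
#' moment; `sample` replicates one uniformly chosen month, removing temporal
#' information altogether. The output shape is unchanged. Random draws are
#' keyed by `(occurrence_id, seed)`, so the transform of a given occurrence
#' does not depend on dataset order and is fixed once for
#' training/validation/test alike.
#'
#' @param series An `image_series` or a list of them.
#' @param mode One of `"original"`, `"permute"`, `"average"`, `"sample"`.
#' @param seed Integer seed of the dataset-level transform.
#' @return The transformed series (same class/shape as the input).
#' @export
transform_series <- function(series, mode, seed = 1) {
  if (is.list(series) && !inherits(series, "image_series")) {
    return(lapply(series, transform_series, mode = mode, seed = seed))
  }
  stopifnot(inherits(series, "image_series"))
  mode <- match.arg(mode, TRANSFORM_MODES)
  d <- dim(series$data)
  n_months <- d[3] %/% N_BANDS
  out <- series
  if (mode == "original") return(out)
  if (mode == "average") {
    mean_frame <- array(0, c(d[1], d[2], N_BANDS))
    for (b in seq_len(N_BANDS)) {
      ch <- (seq_len(n_months) - 1L) * N_BANDS + b
      mean_frame[, , b] <- apply(series$data[, , ch, drop = FALSE], c(1, 2),
                                 mean)
    }
    for (m in seq_len(n_months)) {
      out$data[, , (m - 1L) * N_BANDS + seq_len(N_BANDS)] <- mean_frame
    }
    return(out)
  }
  src <- transform_months(mode, n_months, series$occurrence_id, seed)
  for (m in seq_len(n_months)) {
    out$data[, , (m - 1L) * N_BANDS + seq_len(N_BANDS)] <-
      series$data[, , (src[m] - 1L) * N_BANDS + seq_len(N_BANDS)]
  }
  out
}

#' Ablate a stacked series array
#'
#' Array variant of [transform_series()] operating on the
#' `(px, px, channels, n)` stack produced by [series_array()]; occurrence ids
#' are taken from the array's last dimnames so the per-occurrence draws match
#' the per-series variant exactly.
#'
#' @param x 4-d series array with occurrence ids as the 4th dimnames.
#' @param mode,seed As in [transform_series()].
#' @return Transformed array of identical shape.
#' @export
transform_series_array <- function(x, mode, seed = 1) {
  mode <- match.arg(mode, TRANSFORM_MODES)
  if (mode == "original") return(x)
  d <- dim(x)
  n_months <- d[3] %/% N_BANDS
  ids <- dimnames(x)[[4]] %||% as.character(seq_len(d[4]))
  out <- x
  if (mode == "average") {
    # mean over months per band, replicated
    xm <- array(x, c(d[1], d[2], N_BANDS, n_months, d[4]))
    mean_frame <- xm[, , , 1, , drop = FALSE]
    for (m in 2:n_months) mean_frame <- mean_frame + xm[, , , m, , drop = FALSE]
    mean_frame <- mean_frame / n_months
    for (m in seq_len(n_months)) xm[, , , m, ] <- mean_frame
    out <- array(xm, d)
    dimnames(out) <- dimnames(x)
    return(out)
  }
  for (i in seq_len(d[4])) {
    src <- transform_months(mode, n_months, ids[i], seed)
    for (m in seq_len(n_months)) {
      out[, , (m - 1L) * N_BANDS + seq_len(N_BANDS), i] <-
        x[, , (src[m] - 1L) * N_BANDS + seq_len(N_BANDS), i]
    }
  }
  out
}

#' Relative performance change between a reference and an ablated model
#'
#' `(ref - alt) / ref` per key (species or region). Keys whose reference
#' score is zero already have the lowest possible score, so no change can be
#' measured: they are marked excluded and must be dropped from grouped means.
#'
#' @param score_ref,score_alt Named numeric score vectors (same keys), or
#'   `grouped_scores` data.frames.
#' @return data.frame of class `change_table` with columns `key`, `ref`,
#'   `alt`, `change` (NA where excluded), `excluded`, `reason`.
#' @export
relative_change <- function(score_ref, score_alt) {
  as_named <- function(s) {
    if (is.data.frame(s)) stats::setNames(s$score, s$group) else s
  }
  ref <- as_named(score_ref)
  alt <- as_named(score_alt)
  keys <- intersect(names(ref), names(alt))
  ref <- ref[keys]
  alt <- alt[keys]
  excluded <- ref == 0
  change <- ifelse(excluded, NA_real_, (ref - alt) / ref)
  structure(data.frame(
    key = keys, ref = as.numeric(ref), alt = as.numeric(alt),
    change = change, excluded = excluded,
    reason = ifelse(excluded, "reference score is zero", ""),
    stringsAsFactors = FALSE
  ), class = c("change_table", "data.frame"))
}

#' Interval-grouped mean relative performance change
#'
#' Averages the per-key relative changes within covariate intervals (e.g.
#' per-species change grouped by training occurrences, or per-region change
#' grouped by diversity). Excluded keys (reference score zero) do not
#' contribute, and the reported supports count only contributing keys --
#' hence the support drop relative to the corresponding accuracy table.
#'
#' @param changes A [relative_change()] result.
#' @param covariate Named numeric covariate (or vector aligned with the
#'   non-excluded keys' order in `changes`).
#' @param breaks Interval edges as in [interval_grouped_mean()].
#' @return data.frame with `interval`, `lower`, `upper`, `mean`, `support`.
#' @export
grouped_relative_change <- function(changes, covariate, breaks) {
  keep <- !changes$excluded
  vals <- stats::setNames(changes$change[keep], changes$key[keep])
  cov <- if (!is.null(names(covariate))) {
    covariate[changes$key[keep]]
  } else {
    covariate[keep]
  }
  if (!sum(keep)) {
    out <- interval_grouped_mean(stats::setNames(numeric(0), character(0)),
                                 numeric(0), breaks)
    return(out)
  }
  interval_grouped_mean(vals, as.numeric(cov), breaks)
}

#' Paired t-test on per-species accuracies of two models
#'
#' Two-sided Student's paired t-test on the per-species top-k accuracy pairs
#' of a reference and an ablated model. If every pair has an identical
#' difference (zero variance) the statistic is degenerate: the p-value is
#' defined as 1 when the common difference is zero and 0 otherwise, with a
#' warning.
#'
#' @param sa_ref,sa_alt Named per-species accuracy vectors over the same
#'   species set (>= 2 species), or `grouped_scores` data.frames.
#' @return List with `t`, `p_value`, `df`, `mean_diff`, `n`.
#' @export
paired_species_test <- function(sa_ref, sa_alt) {
  as_named <- function(s) {
    if (is.data.frame(s)) stats::setNames(s$score, s$group) else s
  }
  ref <- as_named(sa_ref)
  alt <- as_named(sa_alt)
  if (!setequal(names(ref), names(alt))) {
    stop("species sets of the two models differ", call. = FALSE)
  }
  alt <- alt[names(ref)]
  n <- length(ref)
  if (n < 2) stop("need at least 2 species", call. = FALSE)
  d <- ref - alt
  if (stats::sd(d) < 1e-12) {
    warning("zero-variance paired differences; degenerate t-test",
            call. = FALSE)
    md <- mean(d)
    return(list(t = if (md == 0) 0 else sign(md) * Inf,
                p_value = if (md == 0) 1 else 0,
                df = n - 1, mean_diff = md, n = n))
  }
  tt <- stats::t.test(ref, alt, paired = TRUE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_diff = unname(tt$estimate), n = n)
}
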