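# Imbalance-aware evaluation statistics for set-valued (top-k) prediction on
# presence-only data: micro top-k accuracy, per-species / per-region
# accuracies and their macro means, interval-grouped means, and Hill
# diversity numbers.

#' Top-k hit indicator per occurrence
#'
#' An occurrence is a hit if its true species is among the k species with the
#' highest predicted probability. Ties are resolved by a stable descending
#' sort on probability with ascending species (column) index among equals, so
#' exactly k species are "returned" and the result is fully deterministic.
#'
#' @param pred Probability matrix, one row per occurrence, one column per
#'   species.
#' @param true_labels Integer vector of true species column indices.
#' @param k Size of the returned species set (1 <= k <= ncol(pred)).
#' @param species_id,region_id Optional per-occurrence labels carried along
#'   for grouped statistics (species defaults to `true_labels`).
#' @return data.frame of class `hit_vector` with columns `hit` (0/1),
#'   `species_id`, `region_id`; attribute `k`.
#' @export
top_k_hits <- function(pred, true_labels, k, species_id = NULL,
                       region_id = NULL) {
  pred <- as.matrix(pred)
  n <- nrow(pred)
  S <- ncol(pred)
  if (k < 1 || k > S) {
    stop(sprintf("k = %s outside 1..%d (number of species)", k, S),
         call. = FALSE)
  }
  if (length(true_labels) != n || any(true_labels < 1 | true_labels > S)) {
    stop("'true_labels' must be column indices, one per row of 'pred'",
         call. = FALSE)
  }
  p_true <- pred[cbind(seq_len(n), true_labels)]
  col_idx <- matrix(seq_len(S), n, S, byrow = TRUE)
  rank <- rowSums(pred > p_true) +
    rowSums(pred == p_true & col_idx < true_labels) + 1
  out <- data.frame(
    hit = as.integer(rank <= k),
    species_id = species_id %||% true_labels,
    region_id = if (is.null(region_id)) NA else region_id
  )
  structure(out, class = c("hit_vector", "data.frame"), k = k)
}

#' Micro-average top-k accuracy
#'
#' Mean of the per-occurrence hit indicators: every occurrence weighs the
#' same, so frequent species dominate.
#'
#' @param hits A [top_k_hits()] result (or 0/1 vector).
#' @return Scalar in \[0, 1\].
#' @export
micro_accuracy <- function(hits) {
  h <- if (is.data.frame(hits)) hits$hit else hits
  if (!length(h)) stop("empty hit vector", call. = FALSE)
  mean(h)
}

#' Per-group (species or region) top-k accuracy
#'
#' Mean hit rate within each group; groups supported by fewer than
#' `min_support` occurrences are omitted (the regional analyses use 50 as the
#' statistical-significance cutoff, per-species tables use 1).
#'
#' @param hits A [top_k_hits()] result (or 0/1 vector).
#' @param group_labels Group label per occurrence; defaults to the hit
#'   vector's `species_id`.
#' @param min_support Minimal group size retained.
#' @return data.frame of class `grouped_scores` with columns `group`,
#'   `score`, `support`.
#' @export
per_group_accuracy <- function(hits, group_labels = NULL, min_support = 1) {
  h <- if (is.data.frame(hits)) hits$hit else hits
  g <- group_labels %||% (if (is.data.frame(hits)) hits$species_id else NULL)
  if (is.null(g) || length(g) != length(h)) {
    stop("every occurrence needs a group label", call. = FALSE)
  }
  score <- tapply(h, g, mean)
  support <- tapply(h, g, length)
  out <- data.frame(group = names(score), score = as.numeric(score),
                    support = as.integer(support), stringsAsFactors = FALSE)
  out <- out[out$support >= min_support, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("grouped_scores", "data.frame"))
}

#' Macro mean of grouped scores
#'
#' Unweighted mean over groups: every species (or region) weighs the same
#' regardless of how many occurrences it has, which counteracts the long tail
#' of the occurrence distribution.
#'
#' @param scores A [per_group_accuracy()] result (or numeric vector).
#' @return Scalar mean.
#' @export
macro_mean <- function(scores) {
  s <- if (is.data.frame(scores)) scores$score else scores
  if (!length(s)) stop("empty grouped scores", call. = FALSE)
  mean(s)
}

#' Interval-grouped means of per-key values
#'
#' Groups keys (species or regions) by which interval their covariate falls
#' into (e.g. per-species accuracy grouped by the species' number of training
#' occurrences) and averages the values per interval. Intervals are defined
#' by a strictly increasing `breaks` vector as left-closed cells
#' `[b_i, b_{i+1})`, the last one closed on both ends; a value on an edge
#' therefore belongs to the interval whose left end it is.
#'
#' @param values Named numeric vector (or `grouped_scores` whose `group` and
#'   `score` are used) of per-key values.
#' @param covariate Numeric covariate per key, aligned with `values`.
#' @param breaks Strictly increasing interval edges covering the covariate
#'   range.
#' @return data.frame with `interval`, `lower`, `upper`, `mean` (NA for empty
#'   intervals) and `support`.
#' @export
interval_grouped_mean <- function(values, covariate, breaks) {
  if (is.data.frame(values)) {
    v <- values$score
    names(v) <- values$group
    values <- v
  }
  if (length(covariate) != length(values)) {
    stop("'covariate' must align with 'values'", call. = FALSE)
  }
  if (is.unsorted(breaks, strictly = TRUE)) {
    stop("'breaks' must be strictly increasing (intervals may not overlap)",
         call. = FALSE)
  }
  if (any(covariate < breaks[1] | covariate > breaks[length(breaks)])) {
    stop("covariate values outside the intervals", call. = FALSE)
  }
  n_int <- length(breaks) - 1L
  idx <- findInterval(covariate, breaks, rightmost.closed = TRUE)
  out <- data.frame(
    interval = sprintf("[%g,%g%s", breaks[-length(breaks)], breaks[-1],
                       c(rep(")", n_int - 1L), "]")),
    lower = breaks[-length(breaks)], upper = breaks[-1],
    mean = NA_real_, support = 0L
  )
  for (j in seq_len(n_int)) {
    sel <- idx == j
    out$support[j] <- sum(sel)
    if (any(sel)) out$mean[j] <- mean(values[sel])
  }
  out
}

#' Default occurrence-count interval edges
#'
#' Breaks used for tables of accuracy against training-set frequency:
#' species with 1-2, 3-10, 11-100, 101-1000, and more than 1000 training
#' occurrences. Edges are a package default and fully configurable.
#'
#' @format Numeric vector of interval edges for [interval_grouped_mean()].
#' @export
default_occurrence_bins <- c(1, 3, 11, 101, 1001, Inf)

#' Hill diversity number
#'
#' Effective number of species of order `q` for a prevalence vector `p`:
#' `(sum(p^q))^(1/(1-q))` for `q != 1`, and the exponential of the Shannon
#' entropy in the `q -> 1` limit (used when `|q - 1| < 1e-9`). `q = 0` gives
#' species richness; increasing `q` discounts rare species more strongly.
#'
#' @param prevalences Non-negative prevalences summing to 1 (renormalised if
#'   within 1e-6 of 1).
#' @param q Diversity order (vectorised).
#' @return Numeric vector of effective species numbers, one per `q`.
#' @export
hill_diversity <- function(prevalences, q) {
  p <- prevalences
  if (any(p < 0)) stop("prevalences must be non-negative", call. = FALSE)
  tot <- sum(p)
  if (abs(tot - 1) > 1e-6) {
    stop("prevalences must sum to 1", call. = FALSE)
  }
  p <- p[p > 0] / tot
  vapply(q, function(qi) {
    if (abs(qi - 1) < 1e-9) {
      exp(-sum(p * log(p)))
    } else {
      sum(p^qi)^(1 / (1 - qi))
    }
  }, 0)
}

#' Per-region diversity table
#'
#' Species richness and Hill diversity per region, computed from occurrence
#' counts (prevalence = share of the region's occurrences).
#'
#' @param occurrences Data.frame with `species_id` and `region_id`.
#' @param q Diversity order (default 1, the exponential Shannon entropy).
#' @return data.frame with `region_id`, `n`, `richness`, `qD`.
#' @export
diversity_table <- function(occurrences, q = 1) {
  regions <- sort(unique(occurrences$region_id))
  out <- data.frame(region_id = regions, n = NA_integer_,
                    richness = NA_integer_, qD = NA_real_)
  for (i in seq_along(regions)) {
    sp <- occurrences$species_id[occurrences$region_id == regions[i]]
    tab <- table(sp)
    out$n[i] <- length(sp)
    out$richness[i] <- length(tab)
    out$qD[i] <- hill_diversity(as.numeric(tab) / length(sp), q)
  }
  out
}
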