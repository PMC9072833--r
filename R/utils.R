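# Internal helpers shared across modules.

# Deterministic child seed derived from a master seed and arbitrary tags.
# Keeps every stochastic component a pure function of (config, seed) while
# decoupling the random streams of unrelated stages. Result is in
# [0, 2^31 - 2] so it is always a valid R integer seed.
child_seed <- function(...) {
  parts <- unlist(lapply(list(...), function(p) {
    if (is.character(p)) {
      utf8ToInt(paste(p, collapse = "|"))
    } else {
      as.numeric(p)
    }
  }), use.names = FALSE)
  h <- 0
  for (v in parts) {
    h <- (h * 69069 + abs(v) %% 2147483647 + 1) %% 2147483647
  }
  as.integer(h)
}

# sample() without the length-1 surprise: draws `size` elements of x with
# replacement, with optional per-element weights.
resample <- function(x, size, prob = NULL) {
  x[sample.int(length(x), size, replace = TRUE, prob = prob)]
}

# Separable box blur of a matrix, edge-clipped (windows are renormalised at
# the borders). Used for habitat fields and cloud masks.
box_blur <- function(m, radius, passes = 2) {
  blur1 <- function(x, r) {
    n <- nrow(x)
    cs <- rbind(0, apply(x, 2, cumsum))
    hi <- pmin(n, seq_len(n) + r)
    lo <- pmax(1, seq_len(n) - r)
    (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
  }
  for (i in seq_len(passes)) {
    m <- blur1(m, radius)
    m <- t(blur1(t(m), radius))
  }
  m
}

# Truncated-normal draws: values beyond 2 standard deviations are redrawn.
rtrunc_normal <- function(n, sd) {
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Metres of one degree of longitude/latitude on the synthetic equirectangular
# world (equator-scale arithmetic).
METERS_PER_DEGREE <- 111000
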