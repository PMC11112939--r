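# Independent brute-force oracles. These deliberately avoid the package's
# compiled code paths: plain R loops over mean() calls.

# scaled mean-difference statistic between x[a] and x[-a]
.oracle_stat <- function(x, arc_idx) {
  k <- length(arc_idx)
  n <- length(x)
  abs(mean(x[arc_idx]) - mean(x[-arc_idx])) / sqrt(1 / k + 1 / (n - k))
}

# residual sum of squares of a piecewise-constant fit with the given
# breakpoints (maximum-likelihood change-point criterion; for a single
# breakpoint, and for arc-shaped double changes, the SSE minimizer equals
# the maximizer of the two-sample arc statistic)
.oracle_sse <- function(x, bps) {
  bounds <- c(0, bps, length(x))
  total <- 0
  for (k in seq_len(length(bounds) - 1)) {
    seg <- x[(bounds[k] + 1):bounds[k + 1]]
    total <- total + sum((seg - mean(seg))^2)
  }
  total
}

# best single change-point by exhaustive least squares
oracle_one_breakpoint <- function(x, min_seg = 3) {
  n <- length(x)
  best <- Inf
  bp <- NA_integer_
  for (i in min_seg:(n - min_seg)) {
    s <- .oracle_sse(x, i)
    if (s < best) {
      best <- s
      bp <- i
    }
  }
  list(breakpoints = bp, sse = best)
}

# best pair of change-points by exhaustive least squares over all
# 2-breakpoint partitions
oracle_two_breakpoints <- function(x, min_seg = 3) {
  n <- length(x)
  best <- Inf
  bp <- c(NA_integer_, NA_integer_)
  for (i in min_seg:(n - 2 * min_seg)) {
    for (j in (i + min_seg):(n - min_seg)) {
      s <- .oracle_sse(x, c(i, j))
      if (s < best) {
        best <- s
        bp <- c(i, j)
      }
    }
  }
  list(breakpoints = bp, sse = best)
}

oracle_breakpoints <- function(x, k, min_seg = 3) {
  if (k == 1) oracle_one_breakpoint(x, min_seg)$breakpoints
  else oracle_two_breakpoints(x, min_seg)$breakpoints
}

# piecewise-constant profile with planted change-points and gaussian noise
planted_profile <- function(n, breakpoints, shifts, noise_sd = 0.05,
                            base = 2) {
  stopifnot(length(shifts) == length(breakpoints))
  mu <- rep(base, n)
  lev <- base
  bounds <- c(breakpoints, n)
  for (k in seq_along(breakpoints)) {
    lev <- base + shifts[k]
    mu[(breakpoints[k] + 1):bounds[k + 1]] <- lev
  }
  mu + rnorm(n, 0, noise_sd)
}

# segments of a raw numeric vector treated as one chromosome, via the
# package segmentation (helper to call CBS without building counts)
segment_vector <- function(x, genome1, ...) {
  prof <- structure(list(sample_id = "vec", cn = x,
                         weight = rep(1, length(x))),
                    class = "nics_profile")
  segment_cbs(prof, genome1, ...)
}
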