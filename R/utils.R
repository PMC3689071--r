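# Internal helpers shared across modules.

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Map times to half-open bin indices (1-based); NA outside [start, end).
# The ratio is rounded at 1e-9 so boundary spikes land in the upper bin
# regardless of floating-point representation of the bin width.
bin_index <- function(t, start, width, n_bins) {
  idx <- floor(round((t - start) / width, 9L)) + 1L
  idx[idx < 1L | idx > n_bins] <- NA_integer_
  idx
}

# Number of bins of `width` tiling (start, end); errors unless the window
# is an integer multiple of the width (within 1e-9).
n_bins_for <- function(window, width) {
  span <- window[2L] - window[1L]
  n <- span / width
  if (abs(n - round(n)) > 1e-9) {
    stop("window (", window[1L], ", ", window[2L],
         ") is not an integer multiple of bin width ", width)
  }
  as.integer(round(n))
}

# Indices of bins whose [lo, hi) interval lies inside `sub` on the grid
# defined by (window, width).
bins_in_window <- function(window, width, sub) {
  n <- n_bins_for(window, width)
  lo <- window[1L] + (seq_len(n) - 1L) * width
  hi <- lo + width
  which(lo >= sub[1L] - 1e-9 & hi <= sub[2L] + 1e-9)
}

# Enforce strictly increasing timestamps by perturbing ties upward by one
# timestamp-resolution unit (1e-4 s).
enforce_increasing <- function(ts, resolution = 1e-4) {
  ts <- sort(ts)
  while (any(diff(ts) <= 0)) {
    k <- which(diff(ts) <= 0) + 1L
    ts[k] <- ts[k - 1L] + resolution
    ts <- sort(ts)
  }
  ts
}

`%||%` <- function(a, b) if (is.null(a)) b else a
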