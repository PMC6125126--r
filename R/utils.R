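# Internal numerical helpers shared across modules.

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Gaussian noise band-limited to [band[1], band[2]] Hz via FFT masking,
# scaled to unit standard deviation. Components at DC and above the upper
# edge are removed exactly; the mask has hard edges (the generator does not
# need spectral smoothness, only band confinement). Shaping is done at the
# next power-of-2 length (then truncated) so the transforms stay fast at
# arbitrary session lengths.
bandlimited_noise <- function(n, rate, band) {
  m <- stats::nextn(n, 2)
  x <- stats::rnorm(m)
  X <- stats::fft(x)
  f <- fft_bin_freqs(m, rate)
  keep <- abs(f) >= band[1] & abs(f) <= band[2]
  X[!keep] <- 0+0i
  y <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)] / m
  s <- stats::sd(y)
  if (s == 0) stop("band too narrow for the requested length")
  y / s
}

# 1/f^alpha ("pink" for alpha = 1) background noise confined to `band` Hz,
# unit standard deviation.
pink_noise <- function(n, rate, alpha = 1, band = c(1, rate / 2)) {
  m <- stats::nextn(n, 2)
  x <- stats::rnorm(m)
  X <- stats::fft(x)
  f <- fft_bin_freqs(m, rate)
  amp <- rep(0, m)
  nz <- abs(f) >= band[1] & abs(f) <= band[2]
  amp[nz] <- 1 / (abs(f[nz])^(alpha / 2))
  X <- X * amp
  y <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)] / m
  y / stats::sd(y)
}

# Signed frequency of every FFT bin for a length-n transform at `rate` Hz.
fft_bin_freqs <- function(n, rate) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k * rate / n
}

# Delay a band-limited signal by `lag` seconds (positive = content moves
# later in time) using the FFT phase ramp; exact for any real lag, circular
# at the edges.
delay_signal <- function(x, rate, lag) {
  if (lag == 0) return(x)
  n <- length(x)
  f <- fft_bin_freqs(n, rate)
  X <- stats::fft(x) * exp(-2i * pi * f * lag)
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Analytic signal via the frequency-domain Hilbert construction. The
# signal is reflection-extended to the next power-of-2 length before the
# transforms (fast for arbitrary lengths, and the extension also softens
# the circular wrap discontinuity); the original span is returned.
analytic_signal <- function(x) {
  n <- length(x)
  m <- stats::nextn(n, 2)
  p <- m - n
  ext <- if (p > 0) extend_reflect(x, p)[(p + 1):(p + m)] else x
  X <- stats::fft(ext)
  h <- rep(0, m)
  h[1] <- 1
  h[m / 2 + 1] <- 1
  h[2:(m / 2)] <- 2
  (stats::fft(X * h, inverse = TRUE) / m)[seq_len(n)]
}

# Symmetric (reflection) extension of x by `pad` samples on each side.
# Mirrors about the end samples with period 2(n-1), so any pad length is
# supported even when pad > length(x).
extend_reflect <- function(x, pad) {
  n <- length(x)
  if (n < 2) stop("cannot reflect a signal shorter than 2 samples")
  idx <- seq.int(1 - pad, n + pad)
  period <- 2L * (n - 1L)
  m <- (idx - 1L) %% period
  m[m >= n - 1L] <- period - m[m >= n - 1L]
  x[m + 1L]
}

# Merge possibly overlapping [start, end) intervals; returns a two-column
# matrix of disjoint intervals in increasing order.
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  if (any(end < start)) stop("interval with end < start")
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out <- list()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out[[length(out) + 1L]] <- c(ms, me)
      ms <- start[i]; me <- end[i]
    }
  }
  out[[length(out) + 1L]] <- c(ms, me)
  m <- do.call(rbind, out)
  dimnames(m) <- list(NULL, c("start", "end"))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
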