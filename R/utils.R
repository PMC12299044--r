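# Internal helpers shared across modules.

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Analytic signal via the FFT
#'
#' Computes the analytic signal (the signal plus i times its Hilbert
#' transform) of a real vector or of each column of a real matrix, using the
#' standard frequency-domain construction: negative frequencies are zeroed
#' and positive frequencies doubled, so that a real tone \code{cos(w t)} maps
#' to \code{exp(i w t)}.
#'
#' @param x numeric vector or matrix (columns transformed independently).
#' @return complex vector/matrix of the same shape.
#' @export
analytic_signal <- function(x) {
  if (is.matrix(x)) {
    out <- matrix(0i, nrow(x), ncol(x))
    for (j in seq_len(ncol(x))) out[, j] <- analytic_signal(x[, j])
    return(out)
  }
  n <- length(x)
  if (n == 0L) return(complex(0))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    if (n > 1) h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

# Centered finite-difference time derivative at sampling rate fs
# (one-sided at the endpoints).  Works on vectors or column-wise matrices.
time_derivative <- function(x, fs) {
  if (is.matrix(x)) {
    n <- nrow(x)
    if (n < 2) return(x * 0)
    d <- x
    d[2:(n - 1), ] <- (x[3:n, , drop = FALSE] - x[1:(n - 2), , drop = FALSE]) * (fs / 2)
    d[1, ] <- (x[2, ] - x[1, ]) * fs
    d[n, ] <- (x[n, ] - x[n - 1, ]) * fs
    return(d)
  }
  n <- length(x)
  if (n < 2) return(x * 0)
  d <- x
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * (fs / 2)
  d[1] <- (x[2] - x[1]) * fs
  d[n] <- (x[n] - x[n - 1]) * fs
  d
}

# Linear interpolation of vector v (samples at t0 + (0:(n-1))/fs) at times tt,
# zero outside the grid.  Supports complex v.
sample_linear <- function(v, fs, t0, tt) {
  n <- length(v)
  pos <- (tt - t0) * fs
  i0 <- floor(pos)
  frac <- pos - i0
  ok <- i0 >= 0 & i0 <= n - 2
  out <- if (is.complex(v)) rep(0i, length(tt)) else numeric(length(tt))
  if (any(ok)) {
    i <- i0[ok] + 1
    out[ok] <- v[i] * (1 - frac[ok]) + v[i + 1] * frac[ok]
  }
  out
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
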