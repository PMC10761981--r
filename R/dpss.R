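#' Discrete prolate spheroidal sequences (Slepian tapers)
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth product
#' `nw`, via the eigenvectors of the classical symmetric tridiagonal matrix
#' whose eigenvectors coincide with the Slepian sequences. For long windows
#' (`n > 2049`) the tapers are computed on a 2049-point grid, spline
#' interpolated to length `n` and re-orthonormalized - the usual long-window
#' approximation, accurate for the low-order tapers used here.
#'
#' @param n window length in samples.
#' @param nw time-bandwidth product (default 2).
#' @param k number of tapers (default `2 * nw - 1`).
#' @return `n x k` matrix; columns are unit-energy tapers, polarity fixed so
#'   each taper has non-negative mean (odd tapers: non-negative initial slope).
#' @export
dpss_tapers <- function(n, nw = 2, k = 2 * nw - 1) {
  stopifnot(n >= 2, nw > 0, k >= 1, k <= n)
  key <- sprintf("%d_%g_%d", n, nw, k)
  cached <- .dpss_cache[[key]]
  if (!is.null(cached)) return(cached)
  n_direct <- 2049L
  if (n <= n_direct) {
    v <- dpss_direct(n, nw, k)
  } else {
    v0 <- dpss_direct(n_direct, nw, k)
    x0 <- seq(0, 1, length.out = n_direct)
    x1 <- seq(0, 1, length.out = n)
    v <- vapply(seq_len(k), function(j)
      spline(x0, v0[, j], xout = x1)$y, numeric(n))
    # re-orthonormalize (Gram-Schmidt) after interpolation
    for (j in seq_len(k)) {
      if (j > 1)
        v[, j] <- v[, j] - v[, 1:(j - 1), drop = FALSE] %*%
          crossprod(v[, 1:(j - 1), drop = FALSE], v[, j])
      v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
    }
  }
  # polarity convention
  for (j in seq_len(k)) {
    m <- sum(v[, j])
    if ((abs(m) > 1e-8 && m < 0) ||
        (abs(m) <= 1e-8 && v[2, j] - v[1, j] < 0)) v[, j] <- -v[, j]
  }
  .dpss_cache[[key]] <- v
  v
}

# tapers depend only on (n, nw, k); cache them per session
.dpss_cache <- new.env(parent = emptyenv())

dpss_direct <- function(n, nw, k) {
  w <- nw / n
  i <- seq_len(n) - 1
  d <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  e <- seq_len(n - 1) * (n - seq_len(n - 1)) / 2
  m <- matrix(0, n, n)
  diag(m) <- d
  m[cbind(seq_len(n - 1), 2:n)] <- e
  m[cbind(2:n, seq_len(n - 1))] <- e
  eg <- eigen(m, symmetric = TRUE)
  v <- eg$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
  v
}

#' Spectral concentration of a taper
#'
#' Fraction of a taper's energy inside the design band `[-w, w]` cycles/sample,
#' computed from a zero-padded FFT. Used as an independent quality check of the
#' taper construction.
#'
#' @param taper numeric vector.
#' @param w half-bandwidth in cycles/sample (`nw / n` for the matching design).
#' @param pad FFT zero-padding factor.
#' @return concentration ratio in (0, 1].
#' @export
dpss_concentration <- function(taper, w, pad = 8) {
  n <- length(taper)
  nfft <- 2^ceiling(log2(n * pad))
  spec <- abs(fft(c(taper, rep(0, nfft - n))))^2
  f <- (seq_len(nfft) - 1) / nfft
  f <- ifelse(f > 0.5, f - 1, f)
  sum(spec[abs(f) <= w]) / sum(spec)
}
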