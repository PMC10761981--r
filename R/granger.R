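# --- Spectral pairwise-conditional Granger causality -------------------------

#' Downsample a preprocessed trace to the GC analysis rate
#'
#' Decimates a 300 Hz low-passed trace from `fs_in` (5 kHz) to `fs_out`
#' (500 Hz) with a steep zero-phase FIR anti-alias filter below the output
#' Nyquist (cutoff 0.98 x Nyquist, 2048 taps, applied via FFT convolution with
#' group-delay compensation).
#'
#' @param x trace at `fs_in`.
#' @param fs_in input rate; must be an integer multiple of `fs_out`.
#' @param fs_out output rate, Hz.
#' @return trace of length `ceiling(length(x) / r)` at `fs_out`.
#' @export
downsample_for_gc <- function(x, fs_in = 5000, fs_out = 500) {
  r <- fs_in / fs_out
  if (abs(r - round(r)) > 1e-9 || r < 1)
    stop("fs_in (", fs_in, ") must be an integer multiple of fs_out (", fs_out, ")")
  r <- round(r)
  if (r == 1) return(x)
  ntaps <- 2048
  h <- as.numeric(signal::fir1(ntaps, 0.98 / r, type = "low"))
  y <- fft_convolve_centered(x, h)
  y[seq(1, length(y), by = r)]
}

# Linear-phase FIR filtering via FFT convolution, compensating the group
# delay of the (odd-length, symmetric) kernel so output aligns with input.
fft_convolve_centered <- function(x, h) {
  n <- length(x); m <- length(h)
  nfft <- 2^ceiling(log2(n + m - 1))
  y <- Re(fft(fft(c(x, rep(0, nfft - n))) * fft(c(h, rep(0, nfft - m))),
              inverse = TRUE)) / nfft
  d <- (m - 1) %/% 2
  y[(d + 1):(d + n)]
}

#' Spectral pairwise-conditional Granger causality
#'
#' For every directed pair (source j -> target i), Geweke's conditional
#' spectral GC of j on i given all remaining channels, computed from a model
#' autocovariance sequence: the full VAR is recovered by the Whittle recursion,
#' and for each source channel a reduced VAR (source omitted) is re-derived
#' from the autocovariance submatrix; the partitioned transfer-function formula
#' then yields the conditional spectral GC, non-negative by construction.
#'
#' @param G autocovariance array from [var_to_autocov()] (or a compatible
#'   `n x n x (q+1)` array).
#' @param n_freqs number of frequency bins on `[0, Nyquist]` (default 128).
#' @param fs sampling rate used to label the frequency grid, Hz.
#' @param reduced_order order of the re-derived reduced models (default: all
#'   available autocovariance lags, the VAR(inf) truncation).
#' @return object of class `gc_spectra`: list with `f` (array
#'   `n x n x n_freqs`; entry `[i, j, ]` is the GC spectrum j -> i, diagonal
#'   NA), `freqs` (Hz), `fs`.
#' @export
spectral_pairwise_conditional_gc <- function(G, n_freqs = 128, fs = 500,
                                             reduced_order = NULL) {
  n <- dim(G)[1]
  q <- dim(G)[3] - 1
  pr <- reduced_order %||% q
  pr <- min(pr, q)
  full <- whittle_var(G, pr)
  H <- var_transfer(full$A, n_freqs)
  Sig <- full$Sigma
  f <- array(NA_real_, dim = c(n, n, n_freqs))
  for (j in seq_len(n)) {
    r <- setdiff(seq_len(n), j)
    red <- whittle_var(G[r, r, , drop = FALSE], pr)
    GR <- var_transfer(red$A, n_freqs)
    # residual partialization of the source channel
    crow <- solve(Sig[r, r], Sig[r, j])           # (n-1) vector
    s_part <- as.numeric(Sig[j, j] - Sig[j, r] %*% crow)
    Srr <- Sig[r, r]
    nr_ <- length(r)
    for (k in seq_len(n_freqs)) {
      GRk <- matrix(GR[, , k], nr_, nr_)
      Hrk <- matrix(H[r, , k], nr_, n)
      Qr <- solve(GRk, Hrk)                            # (n-1) x n
      if (nr_ == 1) Qr <- matrix(Qr, nrow = 1)
      for (ii in seq_along(r)) {
        i <- r[ii]
        qprime <- Qr[ii, r] + Qr[ii, j] * crow         # corrected own-rows
        den <- Re(crossprod(Conj(qprime), Srr %*% qprime))
        num <- den + Mod(Qr[ii, j])^2 * s_part
        f[i, j, k] <- max(0, log(num / den))
      }
    }
  }
  structure(list(f = f, freqs = (seq_len(n_freqs) - 1) / (n_freqs - 1) * fs / 2,
                 fs = fs),
            class = "gc_spectra")
}

#' Band-limited Granger causality
#'
#' Bandwidth-normalized mean of the spectral GC over the band's frequency bins
#' (so values are comparable across bands of different widths). With the full
#' `[0, Nyquist]` range this approximates the time-domain GC (Geweke's
#' equality).
#'
#' @param spectra a [spectral_pairwise_conditional_gc()] result.
#' @param band `"theta"`, `"gamma"`, numeric `c(lo, hi)` in Hz, or `"all"` for
#'   the full range (trapezoidal average).
#' @return `n x n` matrix; entry `[i, j]` is GC j -> i over the band.
#' @export
band_gc <- function(spectra, band) {
  if (identical(band, "all")) {
    h <- length(spectra$freqs)
    w <- rep(1, h); w[c(1, h)] <- 0.5
    return(apply(spectra$f, c(1, 2), function(v) sum(v * w) / (h - 1)))
  }
  b <- band_limits(band)
  sel <- spectra$freqs >= b[1] & spectra$freqs <= b[2]
  if (!any(sel)) stop("band outside the spectral GC frequency grid")
  apply(spectra$f[, , sel, drop = FALSE], c(1, 2), mean)
}

#' Time-domain Granger causality from an autocovariance sequence
#'
#' `ln(Sigma^R_ii / Sigma_ii)`: the log-ratio of the target's residual variance
#' in the reduced model (source omitted, all other channels kept) to its
#' residual variance in the full model. Used to verify Geweke's equality
#' against the frequency-averaged spectral GC.
#'
#' @inheritParams spectral_pairwise_conditional_gc
#' @param i target channel index.
#' @param j source channel index.
#' @return scalar GC value (>= 0 up to numerical error).
#' @export
time_domain_gc <- function(G, i, j, reduced_order = NULL) {
  q <- dim(G)[3] - 1
  pr <- min(reduced_order %||% q, q)
  full <- whittle_var(G, pr)
  r <- setdiff(seq_len(dim(G)[1]), j)
  red <- whittle_var(G[r, r, , drop = FALSE], pr)
  ii <- match(i, r)
  log(red$Sigma[ii, ii] / full$Sigma[i, i])
}

# --- Dataset-level GC change analysis ----------------------------------------

# Fit a VAR on one period of a session (region subset, GC rate) and return
# the band GC matrix. Splits the period around exclusion windows and fits on
# the contiguous pieces as multiple trials.
period_band_gc <- function(session, regions, band, period, order = NULL,
                           p_max = 30, gc_fs = 500, n_freqs = 128,
                           half_window_s = 30, max_lags = 1500) {
  idx <- match(regions, session$region_labels)
  if (anyNA(idx)) stop("regions not all recorded in ", session_id(session))
  fs <- session$sampling_rate
  x <- session$signals[idx, , drop = FALSE]
  if (fs > gc_fs) {
    x <- do.call(rbind, lapply(seq_len(nrow(x)), function(r)
      downsample_for_gc(x[r, ], fs, gc_fs)))
    fs <- gc_fs
  }
  excl <- exclusion_intervals(session, half_window_s)
  pieces <- subtract_intervals(period, excl)
  trials <- lapply(seq_len(nrow(pieces)), function(r) {
    s0 <- floor(pieces[r, 1] * fs) + 1L
    s1 <- min(ncol(x), floor(pieces[r, 2] * fs))
    x[, s0:s1, drop = FALSE]
  })
  trials <- trials[vapply(trials, ncol, integer(1)) > 10 * p_max]
  if (!length(trials)) stop("period too short for VAR fitting")
  # LFP is not a finite-order VAR; the BIC boundary order is an accepted
  # outcome here, so the boundary warning is not propagated.
  p <- order %||% suppressWarnings(select_model_order(trials, p_max)$order)
  model <- fit_var(trials, p)
  G <- var_to_autocov(model, max_lags = max_lags)
  sp <- spectral_pairwise_conditional_gc(G, n_freqs = n_freqs, fs = fs)
  band_gc(sp, band)
}

#' Per-session encounter-versus-baseline GC changes
#'
#' For every session of a dataset, fits separate VAR models on the baseline and
#' encounter periods over a region subset (each period with its own BIC order,
#' or a shared fixed `order`), computes band-limited pairwise-conditional GC,
#' and returns the per-directed-pair change (encounter minus baseline).
#' Sessions whose fit is unstable are dropped with a warning.
#'
#' @param dataset an [lfp_dataset()].
#' @param regions region subset (all must be recorded in a session for it to
#'   contribute).
#' @param band band name or limits.
#' @param ... forwarded to the per-period fitter (`order`, `p_max`, `gc_fs`,
#'   `n_freqs`, `max_lags`).
#' @return data frame `session_id, subject, task, from, to, baseline,
#'   encounter, change`.
#' @export
gc_session_changes <- function(dataset, regions, band, ...) {
  rows <- list()
  for (id in names(dataset$sessions)) {
    s <- dataset$sessions[[id]]
    if (!all(regions %in% s$region_labels)) next
    res <- tryCatch({
      gb <- period_band_gc(s, regions, band, s$baseline_interval, ...)
      ge <- period_band_gc(s, regions, band, s$encounter_interval, ...)
      list(gb = gb, ge = ge)
    }, error = function(e) {
      warning("session ", id, " dropped from GC analysis: ",
              conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    n <- length(regions)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      rows[[length(rows) + 1]] <- data.frame(
        session_id = id, subject = s$subject_id, task = s$task,
        from = regions[j], to = regions[i],
        baseline = res$gb[i, j], encounter = res$ge[i, j],
        change = res$ge[i, j] - res$gb[i, j], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Test GC changes across sessions
#'
#' Per directed pair, a two-sided paired Wilcoxon signed-rank test of the
#' per-session change (encounter minus baseline) against zero, with
#' Benjamini-Hochberg correction across directed pairs.
#'
#' @param changes a [gc_session_changes()] table (one task/band).
#' @param min_sessions minimum sessions per directed pair.
#' @return data frame `from, to, n, median_change, p, p_adj`.
#' @export
gc_change_analysis <- function(changes, min_sessions = 5) {
  keys <- unique(changes[, c("from", "to")])
  res <- do.call(rbind, lapply(seq_len(nrow(keys)), function(k) {
    d <- changes$change[changes$from == keys$from[k] & changes$to == keys$to[k]]
    d <- d[is.finite(d)]
    if (length(d) < min_sessions) return(NULL)
    p <- wilcox.test(d, mu = 0, exact = FALSE)$p.value
    data.frame(from = keys$from[k], to = keys$to[k], n = length(d),
               median_change = median(d), p = p, stringsAsFactors = FALSE)
  }))
  if (is.null(res)) return(NULL)
  res$p_adj <- p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}

#' Directional asymmetry of GC changes
#'
#' For each unordered region pair, per session
#' `d = change(1 -> 2) - change(2 -> 1)`; a two-sided Wilcoxon signed-rank
#' test of `d` against zero across sessions, BH-corrected across pairs.
#' Swapping the channel order of a pair flips the sign of `d` exactly.
#'
#' @inheritParams gc_change_analysis
#' @return data frame `region1, region2, n, median_d, p, p_adj` (direction of
#'   `d` is region1 -> region2 minus region2 -> region1, with region1 < region2).
#' @export
directional_asymmetry <- function(changes, min_sessions = 5) {
  changes$key <- pair_key(changes$from, changes$to)
  res <- do.call(rbind, lapply(unique(changes$key), function(k) {
    sub <- changes[changes$key == k, ]
    r1 <- pair_split(k)[1]; r2 <- pair_split(k)[2]
    fw <- sub[sub$from == r1, c("session_id", "change")]
    bw <- sub[sub$from == r2, c("session_id", "change")]
    m <- merge(fw, bw, by = "session_id", suffixes = c("_fw", "_bw"))
    d <- m$change_fw - m$change_bw
    d <- d[is.finite(d)]
    if (length(d) < min_sessions) return(NULL)
    data.frame(region1 = r1, region2 = r2, n = length(d), median_d = median(d),
               p = wilcox.test(d, mu = 0, exact = FALSE)$p.value,
               stringsAsFactors = FALSE)
  }))
  if (is.null(res)) return(NULL)
  res$p_adj <- p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}
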