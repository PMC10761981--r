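#' Frequency band definitions
#'
#' Theta is 4-12 Hz and gamma 30-80 Hz throughout.
#'
#' @param name `"theta"` or `"gamma"`, or a numeric length-2 `c(lo, hi)` passed
#'   through unchanged.
#' @return numeric `c(lo, hi)` in Hz.
#' @export
band_limits <- function(name) {
  if (is.numeric(name)) {
    stopifnot(length(name) == 2, name[1] < name[2])
    return(as.numeric(name))
  }
  switch(match.arg(name, c("theta", "gamma")),
         theta = c(4, 12), gamma = c(30, 80))
}

# Zero-phase Butterworth filtering (forward-backward).
butter_filtfilt <- function(x, order, w, type) {
  bf <- signal::butter(order, w, type = type)
  as.numeric(signal::filtfilt(bf, x))
}

#' Preprocess a raw LFP trace
#'
#' Decimates to `fs_out` (default 5 kHz) with Butterworth anti-alias filtering,
#' then applies a zero-phase low-pass Butterworth at `lp_hz` (default 300 Hz,
#' order 4 applied forward-backward).
#'
#' @param x raw trace.
#' @param fs_in input sampling rate, must be at least `fs_out`.
#' @param fs_out output rate, Hz; `fs_in / fs_out` must be an integer.
#' @param lp_hz low-pass corner, Hz.
#' @param order Butterworth order (applied twice via filtfilt).
#' @return list with `x` (processed trace) and `fs` (= `fs_out`).
#' @export
preprocess <- function(x, fs_in, fs_out = 5000, lp_hz = 300, order = 4) {
  if (fs_in < fs_out)
    stop("input sampling rate ", fs_in, " Hz is below the target ", fs_out, " Hz")
  if (fs_in > fs_out) {
    r <- fs_in / fs_out
    if (abs(r - round(r)) > 1e-9)
      stop("fs_in must be an integer multiple of fs_out")
    r <- round(r)
    x <- butter_filtfilt(x, 8, 0.8 / r, "low")
    x <- x[seq(1, length(x), by = r)]
  }
  x <- butter_filtfilt(x, order, lp_hz / (fs_out / 2), "low")
  list(x = x, fs = fs_out)
}

#' Multitaper spectrogram
#'
#' Short-time power spectral density with DPSS tapers: 2 s windows on a 0.5 s
#' stride (75% overlap), giving 0.5 Hz frequency increments and 0.5 s time
#' bins. The first `k` Slepian tapers at time-bandwidth `nw = 2` are averaged.
#'
#' @param x trace (microvolts).
#' @param fs sampling rate, Hz.
#' @param window_s taper window length, seconds.
#' @param step_s output bin stride, seconds.
#' @param nw time-bandwidth product.
#' @param k number of tapers.
#' @param fmax highest frequency retained, Hz (trims storage; default 100).
#' @return object of class `tf_power`: list with `power`
#'   (`n_freqs x n_timebins`, uV^2/Hz, one-sided), `freqs` (Hz), `time_bins`
#'   (window-center times, s), `fs`, `window_s`, `step_s`.
#' @export
spectrogram <- function(x, fs, window_s = 2, step_s = 0.5, nw = 2, k = 3,
                        fmax = 100) {
  nwin <- round(window_s * fs)
  step <- round(step_s * fs)
  if (length(x) < nwin)
    stop("trace shorter than one ", window_s, " s window")
  tapers <- dpss_tapers(nwin, nw = nw, k = k)
  starts <- seq(1, length(x) - nwin + 1, by = step)
  freqs_all <- (seq_len(nwin %/% 2 + 1) - 1) * fs / nwin
  keep <- freqs_all <= min(fmax, fs / 2)
  nf <- sum(keep)
  pow <- matrix(0, nf, length(starts))
  # one-sided PSD scaling: 2|X|^2 / fs for interior bins (unit-energy tapers)
  scale <- rep(2 / fs, nwin %/% 2 + 1)
  scale[1] <- 1 / fs
  if (nwin %% 2 == 0) scale[length(scale)] <- 1 / fs
  scale <- scale[keep]
  for (w in seq_along(starts)) {
    seg <- x[starts[w]:(starts[w] + nwin - 1)]
    seg <- seg - mean(seg)
    acc <- numeric(nf)
    for (j in seq_len(k)) {
      sp <- fft(seg * tapers[, j])[seq_len(nwin %/% 2 + 1)][keep]
      acc <- acc + Re(sp * Conj(sp))
    }
    pow[, w] <- acc / k * scale
  }
  structure(list(power = pow, freqs = freqs_all[keep],
                 time_bins = (starts - 1) / fs + window_s / 2,
                 fs = fs, window_s = window_s, step_s = step_s),
            class = "tf_power")
}

#' Band power series and period means
#'
#' Averages a spectrogram over the frequency bins of a band, giving one band
#' power value per time bin; `period_band_mean` averages those over the time
#' bins of a period, skipping bins whose centers fall inside exclusion
#' intervals.
#'
#' @param tf a [spectrogram()] result.
#' @param band band name or `c(lo, hi)` (see [band_limits()]).
#' @return `band_power_series`: list with `values` (per-time-bin band power),
#'   `time_bins`, `band`.
#' @export
band_power_series <- function(tf, band) {
  b <- band_limits(band)
  sel <- tf$freqs >= b[1] & tf$freqs <= b[2]
  if (!any(sel)) stop("band outside the spectrogram frequency grid")
  list(values = colMeans(tf$power[sel, , drop = FALSE]),
       time_bins = tf$time_bins, band = b)
}

#' @rdname band_power_series
#' @param bp a `band_power_series` result.
#' @param interval `[t0, t1)` period in seconds.
#' @param exclude optional matrix of `[start, end)` intervals to mask out.
#' @export
period_band_mean <- function(bp, interval, exclude = NULL) {
  sel <- bp$time_bins >= interval[1] & bp$time_bins < interval[2]
  if (!is.null(exclude) && nrow(exclude)) {
    for (r in seq_len(nrow(exclude)))
      sel <- sel & !(bp$time_bins >= exclude[r, 1] & bp$time_bins < exclude[r, 2])
  }
  if (!any(sel)) return(NA_real_)
  mean(bp$values[sel])
}

#' Encounter-versus-baseline band power change
#'
#' The session-wide band power change for one region: mean band power over the
#' encounter period minus mean band power over the baseline period, both
#' honoring the insertion/removal exclusion windows.
#'
#' @param session a [recording_session()].
#' @param region region code recorded in the session.
#' @param band `"theta"`, `"gamma"` or `c(lo, hi)`.
#' @param half_window_s exclusion half-window around insertion/removal, s.
#' @param tf optional precomputed [spectrogram()] of the region's trace.
#' @return list with `region`, `band`, `mean_baseline_power`,
#'   `mean_encounter_power`, `delta`, and the per-time-bin `series`.
#' @export
delta_band_power <- function(session, region, band, half_window_s = 30,
                             tf = NULL) {
  if (is.null(tf)) tf <- session_spectrogram(session, region)
  bp <- band_power_series(tf, band)
  excl <- exclusion_intervals(session, half_window_s)
  base <- period_band_mean(bp, session$baseline_interval, excl)
  enc <- period_band_mean(bp, session$encounter_interval, excl)
  list(region = region, band = band_limits(band),
       mean_baseline_power = base, mean_encounter_power = enc,
       delta = enc - base, series = bp)
}

session_spectrogram <- function(session, region, ...) {
  i <- match(region, session$region_labels)
  if (is.na(i)) stop("region ", region, " not recorded in ", session_id(session))
  spectrogram(session$signals[i, ], session$sampling_rate, ...)
}

# Duration-weighted mean of a band-power series over a set of bouts:
# total power-seconds / total seconds, over time bins whose centers fall
# inside a bout. `per_bout = TRUE` averages per-bout means instead.
bout_series_mean <- function(bp, bouts, per_bout = FALSE) {
  if (nrow(bouts) == 0) return(NA_real_)
  per <- lapply(seq_len(nrow(bouts)), function(i) {
    sel <- bp$time_bins >= bouts$start_s[i] & bp$time_bins < bouts$end_s[i]
    bp$values[sel]
  })
  n <- vapply(per, length, integer(1))
  if (sum(n) == 0) return(NA_real_)
  if (per_bout) mean(vapply(per[n > 0], mean, numeric(1)))
  else sum(unlist(per)) / sum(n)
}

#' Bout-locked band power change
#'
#' For each encounter stimulus: the average band power per second during that
#' stimulus's valid investigation bouts (strictly longer than the duration
#' threshold) minus the average band power per second during investigation of
#' both empty chambers in the baseline period. "Power per second" is the
#' duration-weighted mean over concatenated bout time bins; set
#' `per_bout = TRUE` for the average-of-per-bout-means variant.
#'
#' @inheritParams delta_band_power
#' @param bouts the session's [bout_table()] (full table; the duration filter
#'   is applied here).
#' @param min_duration_s bout duration threshold, seconds (strict `>`).
#' @param per_bout averaging variant, see above.
#' @return data frame with one row per stimulus: `region`, `band`, `stimulus`,
#'   `value` (NA when a stimulus has no valid bouts, which callers log/omit),
#'   `n_bouts`.
#' @export
bout_band_power <- function(session, bouts, region, band, min_duration_s = 2,
                            per_bout = FALSE, tf = NULL) {
  if (is.null(tf)) tf <- session_spectrogram(session, region)
  bp <- band_power_series(tf, band)
  vb <- valid_bouts(bouts, min_duration_s)
  base_ref <- bout_series_mean(
    bp, vb[vb$stimulus == EMPTY_STIMULUS, , drop = FALSE], per_bout)
  stim <- task_stimuli(session$task)
  do.call(rbind, lapply(stim, function(st) {
    sb <- vb[vb$stimulus == st, , drop = FALSE]
    data.frame(region = region, band = paste(band_limits(band), collapse = "-"),
               stimulus = st,
               value = bout_series_mean(bp, sb, per_bout) - base_ref,
               n_bouts = nrow(sb), stringsAsFactors = FALSE)
  }))
}

#' Event-aligned band power Z-scores
#'
#' For each behavioral event, band power in 0.5 s bins over [-5, +5] s around
#' the event is Z-scored against the mean and SD of the 5 s pre-event window,
#' then averaged across same-category events. Events without a full 5 s
#' pre-event window, or with zero pre-event SD, are dropped.
#'
#' @param tf a [spectrogram()] result (or a precomputed `band_power_series`).
#' @param events data frame from [extract_events()], already filtered to the
#'   desired kind/stimulus by the caller.
#' @param band band name or limits (ignored when `tf` is already a series).
#' @param pre_s,post_s window half-lengths, seconds.
#' @return list with `z` (mean Z trace over relative bins), `rel_time`
#'   (nominal bin centers, s), `n_events` (events contributing), `per_event`
#'   (matrix events x bins).
#' @export
event_zscore <- function(tf, events, band, pre_s = 5, post_s = 5) {
  bp <- if (inherits(tf, "tf_power")) band_power_series(tf, band) else tf
  nb <- round(pre_s / 0.5)
  na_ <- round(post_s / 0.5)
  step <- bp$time_bins[2] - bp$time_bins[1]
  rows <- list()
  for (t0 in events$time_s) {
    k <- findInterval(t0 - 1e-9, bp$time_bins)  # last bin center < t0
    if (k < nb || k + na_ > length(bp$values)) next
    pre <- bp$values[(k - nb + 1):k]
    s <- sd(pre)
    if (!is.finite(s) || s == 0) next
    seg <- bp$values[(k - nb + 1):(k + na_)]
    rows[[length(rows) + 1]] <- (seg - mean(pre)) / s
  }
  rel <- (seq_len(nb + na_) - nb - 0.5) * step
  if (!length(rows)) {
    return(list(z = rep(NA_real_, nb + na_), rel_time = rel, n_events = 0L,
                per_event = matrix(numeric(0), 0, nb + na_)))
  }
  pe <- do.call(rbind, rows)
  list(z = colMeans(pe), rel_time = rel, n_events = nrow(pe), per_event = pe)
}

#' Compare event-aligned Z-scores between two categories
#'
#' Each session contributes one scalar per category: its mean Z over the
#' `window` (default the 5 s starting at the event). The two sets of
#' session scalars are compared with the normality-dispatched two-sample test
#' from [group_compare()].
#'
#' @param zA,zB lists of per-session [event_zscore()] results (one element per
#'   session) for categories A and B.
#' @param window `[t0, t1)` in seconds relative to the event.
#' @param paired are the sessions matched across categories?
#' @return the [group_compare()] result, plus `means` for the two categories.
#' @export
compare_event_categories <- function(zA, zB, window = c(0, 5), paired = TRUE) {
  summarize <- function(zl) vapply(zl, function(z) {
    sel <- z$rel_time >= window[1] & z$rel_time < window[2]
    mean(z$z[sel])
  }, numeric(1))
  a <- summarize(zA); b <- summarize(zB)
  if (length(a) < 2 || length(b) < 2)
    stop("need at least two sessions per category")
  res <- group_compare(list(a, b),
                       design = if (paired) "paired_2" else "unpaired_2")
  res$means <- c(A = mean(a), B = mean(b))
  res
}
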