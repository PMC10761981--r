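# --- Welch segmentation helpers ---------------------------------------------

# Window start indices (1-based samples) for Welch segmentation of a set of
# [start, end) intervals (seconds). Windows never span interval boundaries.
welch_window_starts <- function(intervals, fs, window_s, overlap) {
  nwin <- round(window_s * fs)
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- integer(0)
  for (r in seq_len(nrow(intervals))) {
    s0 <- floor(intervals[r, 1] * fs) + 1L
    s1 <- floor(intervals[r, 2] * fs)
    if (s1 - s0 + 1 < nwin) next
    starts <- c(starts, seq(s0, s1 - nwin + 1L, by = step))
  }
  starts
}

# Hann-tapered FFTs of all windows for the selected signal rows.
# Returns list(F = array [n_bins x n_windows x n_channels], freqs, enbw_scale).
welch_ffts <- function(signals, fs, starts, window_s, fmax = Inf) {
  nwin <- round(window_s * fs)
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nwin) - 1) / nwin)
  u <- sum(win^2)  # window power for PSD normalization
  nb_all <- nwin %/% 2 + 1
  freqs <- (seq_len(nb_all) - 1) * fs / nwin
  keep <- which(freqs <= fmax)
  f <- array(complex(real = 0), dim = c(length(keep), length(starts), nrow(signals)))
  for (ch in seq_len(nrow(signals))) {
    x <- signals[ch, ]
    for (w in seq_along(starts)) {
      seg <- x[starts[w]:(starts[w] + nwin - 1)]
      seg <- (seg - mean(seg)) * win
      f[, w, ch] <- fft(seg)[keep]
    }
  }
  list(F = f, freqs = freqs[keep], scale = 1 / (fs * u))
}

msc_from_ffts <- function(fobj, a, b) {
  fa <- fobj$F[, , a]; fb <- fobj$F[, , b]
  sxy <- rowMeans(fa * Conj(fb))
  sxx <- rowMeans(Re(fa * Conj(fa)))
  syy <- rowMeans(Re(fb * Conj(fb)))
  Mod(sxy)^2 / (sxx * syy)
}

#' Welch magnitude-squared coherence
#'
#' MSC(f) = |S_xy(f)|^2 / (S_xx(f) S_yy(f)) with Welch-averaged cross- and
#' auto-spectra over Hann-tapered, `overlap`-overlapped segments of
#' `window_s` seconds. MSC lies in [0, 1]; with `n` independent segments and
#' truly incoherent signals its expectation is approximately `1/n` (the
#' estimator bias floor).
#'
#' @param x,y equal-length traces.
#' @param fs sampling rate, Hz.
#' @param window_s segment length, s.
#' @param overlap fractional segment overlap.
#' @param fmax highest frequency retained, Hz.
#' @return object of class `coherence_spectrum`: list with `freqs`, `msc`,
#'   `n_segments`, and the Welch spectra `sxx`, `syy`, `sxy` (PSD scale).
#' @export
welch_msc <- function(x, y, fs, window_s = 2, overlap = 0.5, fmax = Inf) {
  stopifnot(length(x) == length(y))
  iv <- matrix(c(0, length(x) / fs), 1)
  starts <- welch_window_starts(iv, fs, window_s, overlap)
  if (length(starts) < 2)
    stop("fewer than 2 Welch segments; MSC would be degenerate")
  fobj <- welch_ffts(rbind(x, y), fs, starts, window_s, fmax)
  fa <- fobj$F[, , 1]; fb <- fobj$F[, , 2]
  sxy <- rowMeans(fa * Conj(fb)) * fobj$scale
  sxx <- rowMeans(Re(fa * Conj(fa))) * fobj$scale
  syy <- rowMeans(Re(fb * Conj(fb))) * fobj$scale
  structure(list(freqs = fobj$freqs, msc = Mod(sxy)^2 / (sxx * syy),
                 n_segments = length(starts),
                 sxx = sxx, syy = syy, sxy = sxy),
            class = "coherence_spectrum")
}

# MSC over a set of [start, end) intervals of a session, for one region pair.
msc_over_intervals <- function(session, pair, intervals, window_s, overlap = 0.5,
                               fmax = 100) {
  ia <- match(pair[1], session$region_labels)
  ib <- match(pair[2], session$region_labels)
  if (is.na(ia) || is.na(ib)) return(NULL)
  starts <- welch_window_starts(intervals, session$sampling_rate, window_s, overlap)
  if (length(starts) < 2) return(NULL)
  fobj <- welch_ffts(session$signals[c(ia, ib), , drop = FALSE],
                     session$sampling_rate, starts, window_s, fmax)
  list(freqs = fobj$freqs, msc = msc_from_ffts(fobj, 1, 2),
       n_segments = length(starts))
}

# Remove exclusion intervals from a period, returning the remaining
# [start, end) pieces.
subtract_intervals <- function(period, exclude) {
  pieces <- matrix(period, ncol = 2)
  if (is.null(exclude) || !nrow(exclude)) return(pieces)
  for (r in seq_len(nrow(exclude))) {
    out <- matrix(numeric(0), ncol = 2)
    for (p in seq_len(nrow(pieces))) {
      a <- pieces[p, 1]; b <- pieces[p, 2]
      e0 <- exclude[r, 1]; e1 <- exclude[r, 2]
      if (e1 <= a || e0 >= b) { out <- rbind(out, c(a, b)); next }
      if (e0 > a) out <- rbind(out, c(a, e0))
      if (e1 < b) out <- rbind(out, c(e1, b))
    }
    pieces <- out
  }
  pieces
}

#' Normalized encounter-versus-baseline coherence change
#'
#' MSC spectra are estimated separately for the baseline and encounter periods
#' (exclusion windows honored); over the band's frequency bins the change is
#' `delta = mean(d) / sd(d)` where `d(f) = MSC_encounter(f) - MSC_baseline(f)`
#' (sample SD across band bins). The band-mean baseline MSC is also returned.
#'
#' @param session a [recording_session()].
#' @param pair character vector of two region codes (unordered).
#' @param band `"theta"`, `"gamma"` or `c(lo, hi)`.
#' @param window_s,overlap Welch parameters for the period spectra.
#' @param half_window_s insertion/removal exclusion half-window, s.
#' @return list with `pair`, `band`, `baseline_mean`, `delta`, `n_bins`;
#'   `delta` is 0 (flagged via `degenerate = TRUE`) when `sd(d) == 0`; NULL
#'   when either region is not recorded.
#' @export
coherence_change <- function(session, pair, band, window_s = 2, overlap = 0.5,
                             half_window_s = 30) {
  b <- band_limits(band)
  excl <- exclusion_intervals(session, half_window_s)
  base_iv <- subtract_intervals(session$baseline_interval, excl)
  enc_iv <- subtract_intervals(session$encounter_interval, excl)
  mb <- msc_over_intervals(session, pair, base_iv, window_s, overlap,
                           fmax = b[2] + 5)
  me <- msc_over_intervals(session, pair, enc_iv, window_s, overlap,
                           fmax = b[2] + 5)
  if (is.null(mb) || is.null(me)) return(NULL)
  sel <- mb$freqs >= b[1] & mb$freqs <= b[2]
  d <- me$msc[sel] - mb$msc[sel]
  s <- sd(d)
  degen <- !is.finite(s) || s == 0
  if (degen) warning("degenerate coherence change (zero SD across band bins)")
  list(pair = pair_key(pair[1], pair[2]), band = b,
       baseline_mean = mean(mb$msc[sel]),
       delta = if (degen) 0 else mean(d) / s,
       n_bins = sum(sel), degenerate = degen)
}

#' Bout-locked coherence change
#'
#' For each encounter stimulus: band-mean MSC estimated over the concatenation
#' of that stimulus's valid bouts (1 s sub-windows with 50% overlap, never
#' spanning bout boundaries) minus the band-mean MSC over the baseline
#' empty-chamber bouts. Duration weighting is implicit in pooling all
#' sub-windows before averaging.
#'
#' @inheritParams coherence_change
#' @param bouts the session's [bout_table()].
#' @param window_s sub-window length within bouts, s.
#' @param min_duration_s bout duration threshold (strict `>`).
#' @return data frame with one row per stimulus: `pair`, `band`, `stimulus`,
#'   `value` (NA when too little bout time), `n_segments`; NULL when either
#'   region is missing from the session.
#' @export
bout_coherence_change <- function(session, bouts, pair, band, window_s = 1,
                                  min_duration_s = 2) {
  b <- band_limits(band)
  ia <- match(pair[1], session$region_labels)
  ib <- match(pair[2], session$region_labels)
  if (is.na(ia) || is.na(ib)) return(NULL)
  vb <- valid_bouts(bouts, min_duration_s)
  grp_msc <- function(rows) {
    if (!nrow(rows)) return(NULL)
    msc_over_intervals(session, pair, cbind(rows$start_s, rows$end_s),
                       window_s, 0.5, fmax = b[2] + 5)
  }
  ref <- grp_msc(vb[vb$stimulus == EMPTY_STIMULUS, , drop = FALSE])
  ref_val <- if (is.null(ref)) NA_real_ else {
    sel <- ref$freqs >= b[1] & ref$freqs <= b[2]
    mean(ref$msc[sel])
  }
  do.call(rbind, lapply(task_stimuli(session$task), function(st) {
    m <- grp_msc(vb[vb$stimulus == st, , drop = FALSE])
    val <- if (is.null(m) || !is.finite(ref_val)) NA_real_ else {
      sel <- m$freqs >= b[1] & m$freqs <= b[2]
      mean(m$msc[sel]) - ref_val
    }
    data.frame(pair = pair_key(pair[1], pair[2]),
               band = paste(b, collapse = "-"), stimulus = st, value = val,
               n_segments = if (is.null(m)) 0L else m$n_segments,
               stringsAsFactors = FALSE)
  }))
}

#' Dataset-level coherence table
#'
#' Long-format table of coherence statistics over all eligible region pairs and
#' sessions. In `session_wide` mode each session-pair contributes the band-mean
#' baseline MSC and the normalized change `delta`; in `bout` mode each
#' session-pair-stimulus contributes the bout-locked change. Pairs not recorded
#' in a subject are emitted as explicit missing entries (NA values), which the
#' decoder's imputation consumes.
#'
#' @param dataset an [lfp_dataset()].
#' @param band band name or limits.
#' @param mode `"session_wide"` or `"bout"`.
#' @param pairs optional pair keys (default [eligible_pairs()]).
#' @param ... forwarded to [coherence_change()] / [bout_coherence_change()].
#' @return data frame `subject, task, session_id, session_index, pair,
#'   stimulus, metric, value`.
#' @export
dataset_coherence_table <- function(dataset, band,
                                    mode = c("session_wide", "bout"),
                                    pairs = NULL, ...) {
  mode <- match.arg(mode)
  if (is.null(pairs)) pairs <- eligible_pairs(dataset)
  pm <- pair_split(pairs)
  rows <- list()
  for (id in names(dataset$sessions)) {
    s <- dataset$sessions[[id]]
    bts <- dataset$bout_tables[[id]]
    if (mode == "session_wide") {
      for (k in seq_along(pairs)) {
        cc <- coherence_change(s, pm[k, ], band, ...)
        base <- data.frame(subject = s$subject_id, task = s$task,
                           session_id = id, session_index = s$session_index,
                           pair = pairs[k], stimulus = NA_character_,
                           stringsAsFactors = FALSE)
        rows[[length(rows) + 1]] <- rbind(
          cbind(base, metric = "baseline_co",
                value = if (is.null(cc)) NA_real_ else cc$baseline_mean),
          cbind(base, metric = "delta_co",
                value = if (is.null(cc)) NA_real_ else cc$delta))
      }
    } else {
      # share window FFTs across pairs within each segment group
      rows[[length(rows) + 1]] <- session_bout_coherence(s, bts, pairs, band, ...)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Bout-mode table for one session over many pairs, computing each region's
# window FFTs once per segment group (per stimulus and baseline reference).
session_bout_coherence <- function(session, bouts, pairs, band, window_s = 1,
                                   min_duration_s = 2) {
  if (!length(pairs))
    return(data.frame(subject = character(0), task = character(0),
                      session_id = character(0), session_index = integer(0),
                      pair = character(0), stimulus = character(0),
                      metric = character(0), value = numeric(0)))
  b <- band_limits(band)
  vb <- valid_bouts(bouts, min_duration_s)
  pm <- pair_split(pairs)
  fs <- session$sampling_rate
  groups <- c(list(empty = vb[vb$stimulus == EMPTY_STIMULUS, , drop = FALSE]),
              setNames(lapply(task_stimuli(session$task), function(st)
                vb[vb$stimulus == st, , drop = FALSE]),
                task_stimuli(session$task)))
  gvals <- lapply(groups, function(rows) {
    if (!nrow(rows)) return(NULL)
    starts <- welch_window_starts(cbind(rows$start_s, rows$end_s), fs,
                                  window_s, 0.5)
    if (length(starts) < 2) return(NULL)
    fobj <- welch_ffts(session$signals, fs, starts, window_s, fmax = b[2] + 5)
    sel <- fobj$freqs >= b[1] & fobj$freqs <= b[2]
    vals <- rep(NA_real_, length(pairs))
    for (k in seq_along(pairs)) {
      ia <- match(pm[k, 1], session$region_labels)
      ib <- match(pm[k, 2], session$region_labels)
      if (is.na(ia) || is.na(ib)) next
      vals[k] <- mean(msc_from_ffts(fobj, ia, ib)[sel])
    }
    vals
  })
  out <- list()
  for (st in task_stimuli(session$task)) {
    val <- if (is.null(gvals[[st]]) || is.null(gvals$empty)) {
      rep(NA_real_, length(pairs))
    } else gvals[[st]] - gvals$empty
    out[[st]] <- data.frame(
      subject = session$subject_id, task = session$task,
      session_id = session_id(session), session_index = session$session_index,
      pair = pairs, stimulus = st, metric = "bout_delta_co", value = val,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
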