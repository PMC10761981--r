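# --- Synthetic multi-region LFP generator ------------------------------------

#' Simulation configuration
#'
#' Parameters of the synthetic multi-region LFP + behavior generator. Band
#' oscillators are band-pass-filtered Gaussian noise (not pure tones), so
#' spectra resemble LFP and pairwise coherence is tunable by linear mixing:
#' each region's band component mixes a globally shared source (weight
#' `shared_weight`), optional pair-private sources (the coherence/context
#' signatures), and an independent source, normalized to keep unit band
#' variance. A pink (1/f) background sits underneath. The encounter period
#' applies per-band amplitude gains (the encounter-induced global state);
#' investigation bouts apply per-stimulus amplitude gains and, when a context
#' signature is configured, task-specific pair-coherence offsets. Bouts follow
#' an alternating renewal process: exponential gaps, lognormal durations,
#' stimulus chosen by preference weights.
#'
#' @param n_subjects number of subjects.
#' @param regions region codes per subject before dropout.
#' @param region_dropout per-region probability that a subject lacks the
#'   region (mistargeted electrode); at least two regions are always kept.
#' @param sampling_rate Hz.
#' @param baseline_s,encounter_s period lengths, seconds.
#' @param theta_band,gamma_band oscillator pass-bands, Hz.
#' @param theta_amp,gamma_amp oscillator amplitudes (microvolt scale units).
#' @param pink_amp pink background amplitude.
#' @param scale_uv overall microvolt scale factor.
#' @param shared_weight global shared-source mixing weight in [0, 1) per band
#'   (squared product of two regions' weights sets the baseline pair MSC).
#' @param encounter_gain named list per band of encounter amplitude gains
#'   (scalar or per-region vector).
#' @param bout_gain named list per band: amplitude gain applied during bouts,
#'   as a named vector by stimulus (default none).
#' @param context_signature named list task -> named numeric vector
#'   (pair key -> pair-source mixing weight) applied during that task's
#'   encounter bouts; raises those pairs' bout coherence at constant power.
#' @param bout_gap_mean_s,bout_min_gap_s,bout_dur_meanlog,bout_dur_sdlog bout
#'   process parameters.
#' @param preference_weight odds of choosing the task-preferred stimulus.
#' @param bands which band oscillators to synthesize (analyses needing only
#'   theta features can skip generating gamma content).
#' @param gc_couplings list of directed couplings, each
#'   `list(from =, to =, coef =, lag_s =, band =, period = "encounter")`;
#'   adds a scaled, lagged copy of the source region's band component to the
#'   target during the period (a true directed influence for GC scenarios).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subjects = 12,
                       regions = c("AcbC", "BLA", "CeA", "EA", "IL",
                                   "LS", "MeAD", "Pir", "PrL", "vDG"),
                       region_dropout = 0,
                       sampling_rate = 5000,
                       baseline_s = 300, encounter_s = 300,
                       theta_band = c(4, 12), gamma_band = c(30, 80),
                       theta_amp = 1, gamma_amp = 0.5, pink_amp = 0.6,
                       scale_uv = 30,
                       shared_weight = c(theta = 0.75, gamma = 0.6),
                       encounter_gain = list(theta = 1.3, gamma = 1.15),
                       bout_gain = list(),
                       context_signature = list(),
                       bout_gap_mean_s = 10, bout_min_gap_s = 0.5,
                       bout_dur_meanlog = log(4), bout_dur_sdlog = 0.5,
                       preference_weight = 2,
                       bands = c("theta", "gamma"),
                       gc_couplings = list()) {
  cfg <- as.list(environment())
  stopifnot(all(unlist(encounter_gain) >= 0),
            shared_weight >= 0, shared_weight <= 1,
            region_dropout >= 0, region_dropout < 1)
  for (sig in cfg$context_signature)
    stopifnot(all(sig >= 0), all(sig < 1))
  class(cfg) <- "sim_config"
  cfg
}

# Draw a Gaussian time series with the given one-sided magnitude profile over
# the positive-frequency bins, via a single inverse FFT (Hermitian spectrum).
shaped_noise <- function(n, mag) {
  nh <- n %/% 2
  z <- complex(real = rnorm(nh), imaginary = rnorm(nh)) * mag
  spec <- complex(real = numeric(n))
  spec[2:(nh + 1)] <- z
  spec[n:(n - nh + 2)] <- Conj(z[seq_len(nh - 1)])
  if (n %% 2 == 0) spec[nh + 1] <- complex(real = sqrt(2) * Re(z[nh]))
  x <- Re(fft(spec, inverse = TRUE)) / n
  (x - mean(x)) / sd(x)
}

# Pink (1/f amplitude) Gaussian noise, unit variance.
pink_noise <- function(n) {
  f <- seq_len(n %/% 2)
  shaped_noise(n, 1 / sqrt(f))
}

# Band-limited Gaussian noise, unit variance: 4th-order Butterworth band-pass
# magnitude profile synthesized spectrally.
band_noise <- function(n, fs, band) {
  f <- seq_len(n %/% 2) * fs / n
  w <- (f^2 - band[1] * band[2]) / (f * (band[2] - band[1]))
  shaped_noise(n, 1 / sqrt(1 + w^8))
}

#' Simulate an investigation bout table
#'
#' Alternating renewal process within each period: exponential inter-bout gaps
#' (plus a minimum gap), lognormal durations, stimulus drawn by preference
#' weights during the encounter; baseline bouts target the empty chambers.
#'
#' @param cfg a [sim_config()].
#' @param task task code.
#' @param session_id session identifier written into the table.
#' @param seed RNG seed.
#' @return a [bout_table()].
#' @export
simulate_bouts <- function(cfg, task, session_id, seed) {
  stim <- task_stimuli(task)
  pref <- task_preferred_stimulus(task)
  b1 <- cfg$baseline_s
  e0 <- b1; e1 <- b1 + cfg$encounter_s
  with_seed(seed, {
    gen_period <- function(t0, t1, stimuli, probs) {
      rows <- list()
      t <- t0 + rexp(1, 1 / cfg$bout_gap_mean_s)
      while (TRUE) {
        dur <- rlnorm(1, cfg$bout_dur_meanlog, cfg$bout_dur_sdlog)
        if (t + dur >= t1 - 0.5) break
        s <- sample(stimuli, 1, prob = probs)
        rows[[length(rows) + 1]] <- data.frame(
          session_id = session_id, stimulus = s,
          chamber = if (s == EMPTY_STIMULUS)
            sample(c("left", "right"), 1)
          else c("left", "right")[match(s, stim)],
          start_s = t, end_s = t + dur, stringsAsFactors = FALSE)
        t <- t + dur + cfg$bout_min_gap_s + rexp(1, 1 / cfg$bout_gap_mean_s)
      }
      do.call(rbind, rows)
    }
    w <- cfg$preference_weight
    probs <- ifelse(stim == pref, w, 1)
    df <- rbind(gen_period(2, b1 - 2, EMPTY_STIMULUS, 1),
                gen_period(e0 + 2, e1 - 2, stim, probs))
    if (is.null(df))
      df <- data.frame(session_id = character(0), stimulus = character(0),
                       chamber = character(0), start_s = numeric(0),
                       end_s = numeric(0), stringsAsFactors = FALSE)
    bout_table(df)
  })
}

# 0/1 indicator over samples of bout membership for a subset of bouts.
bout_indicator <- function(bouts, n, fs) {
  ind <- rep(FALSE, n)
  for (i in seq_len(nrow(bouts))) {
    a <- floor(bouts$start_s[i] * fs) + 1L
    b <- min(n, floor(bouts$end_s[i] * fs))
    if (a <= b) ind[a:b] <- TRUE
  }
  ind
}

#' Simulate one recording session with ground truth
#'
#' Generates the bout table, then the multi-region signal: per band, a shared
#' source, pair-signature sources (during this task's encounter bouts) and
#' independent sources are mixed at constant unit band variance; the encounter
#' gain and per-stimulus bout gains multiply the band amplitude; a pink
#' background and directed lagged couplings are added; insertion/removal times
#' are stamped at the encounter boundaries.
#'
#' @param cfg a [sim_config()].
#' @param subject_id,task,session_index session identity.
#' @param seed RNG seed.
#' @param regions region subset for this subject (default all of
#'   `cfg$regions`).
#' @return list with `session` ([recording_session()]), `bouts`
#'   ([bout_table()]), and `truth` (realized per-region/band/period in-band
#'   variances of the oscillator and pink components, plus the applied gains
#'   and signatures).
#' @export
simulate_session <- function(cfg, subject_id, task, session_index, seed,
                             regions = cfg$regions) {
  fs <- cfg$sampling_rate
  total_s <- cfg$baseline_s + cfg$encounter_s
  n <- round(total_s * fs)
  nr <- length(regions)
  sid <- sprintf("%s_%s_%02d", subject_id, task, session_index)
  bouts <- simulate_bouts(cfg, task, sid, child_seed(seed, "bouts"))
  enc_sel <- seq_len(n) > cfg$baseline_s * fs
  bands <- list(theta = cfg$theta_band, gamma = cfg$gamma_band)
  bands <- bands[intersect(names(bands), cfg$bands)]
  amps <- c(theta = cfg$theta_amp, gamma = cfg$gamma_amp)
  sig_spec <- cfg$context_signature[[task]]
  # per-stimulus bout sample indicators (encounter bouts only)
  eb <- bouts[bouts$stimulus != EMPTY_STIMULUS, , drop = FALSE]
  stim_ind <- lapply(setNames(task_stimuli(task), task_stimuli(task)),
                     function(st)
                       bout_indicator(eb[eb$stimulus == st, , drop = FALSE], n, fs))
  any_bout <- Reduce(`|`, stim_ind)
  osc <- matrix(0, nr, n)
  truth_power <- list()
  with_seed(child_seed(seed, "signals"), {
    for (bn in names(bands)) {
      band <- bands[[bn]]
      w <- cfg$shared_weight[[bn]]
      shared <- band_noise(n, fs, band)
      # pair-signature sources for pairs touching each region
      pair_src <- list()
      if (!is.null(sig_spec) && length(sig_spec)) {
        for (pk in names(sig_spec)) pair_src[[pk]] <- band_noise(n, fs, band)
      }
      gain_env_base <- rep(1, n)
      eg <- cfg$encounter_gain[[bn]] %||% 1
      bg <- cfg$bout_gain[[bn]]
      for (r in seq_len(nr)) {
        rg <- regions[r]
        v2 <- 0
        comp <- w * shared
        if (length(pair_src)) {
          for (pk in names(pair_src)) {
            rr <- pair_split(pk)
            if (rg %in% rr) {
              v <- sig_spec[[pk]]
              # signature active only during encounter bouts; independent
              # share shrinks there so band variance stays constant
              comp <- comp + (v * any_bout) * pair_src[[pk]]
              v2 <- v2 + v^2
            }
          }
        }
        ind_w_out <- sqrt(max(0, 1 - w^2))
        ind_w_in <- sqrt(max(0, 1 - w^2 - v2))
        iw <- ifelse(any_bout, ind_w_in, ind_w_out)
        comp <- comp + iw * band_noise(n, fs, band)
        env <- gain_env_base
        egr <- if (length(eg) == nr) eg[r] else eg[1]
        env[enc_sel] <- egr
        if (!is.null(bg)) {
          for (st in names(bg)) {
            gr <- bg[[st]]
            gr <- if (length(gr) == nr) gr[r] else gr[1]
            env[stim_ind[[st]]] <- env[stim_ind[[st]]] * gr
          }
        }
        comp <- amps[[bn]] * env * comp
        osc[r, ] <- osc[r, ] + comp
        truth_power[[paste(rg, bn, sep = ".")]] <- list(
          region = rg, band = bn,
          osc_var_baseline = var(comp[!enc_sel]),
          osc_var_encounter = var(comp[enc_sel]))
      }
    }
    pink <- matrix(0, nr, n)
    for (r in seq_len(nr)) pink[r, ] <- cfg$pink_amp * pink_noise(n)
    signals <- (osc + pink) * cfg$scale_uv
    # directed lagged couplings (GC scenarios)
    for (cp in cfg$gc_couplings) {
      fi <- match(cp$from, regions); ti <- match(cp$to, regions)
      if (is.na(fi) || is.na(ti)) next
      lag <- round(cp$lag_s * fs)
      src <- signals[fi, ]
      lagged <- c(rep(0, lag), src[seq_len(n - lag)])
      mask <- if (identical(cp$period, "encounter")) enc_sel
              else if (identical(cp$period, "baseline")) !enc_sel
              else rep(TRUE, n)
      signals[ti, mask] <- signals[ti, mask] + cp$coef * lagged[mask]
    }
    # pink in-band variances per band/period (for expected power ratios)
    pink_band <- lapply(list(theta = cfg$theta_band, gamma = cfg$gamma_band),
                        function(band) {
      if (band[2] >= fs / 2)
        return(c(baseline = NA_real_, encounter = NA_real_))
      pb <- butter_filtfilt(pink[1, ], 4, band / (fs / 2), "pass")
      c(baseline = var(pb[!enc_sel]), encounter = var(pb[enc_sel]))
    })
    session <- recording_session(
      subject_id = subject_id, task = task, session_index = session_index,
      sampling_rate = fs, signals = signals, region_labels = regions,
      baseline_interval = c(0, cfg$baseline_s),
      encounter_interval = c(cfg$baseline_s, total_s),
      stimulus_map = setNames(task_stimuli(task), c("left", "right")))
    list(session = session, bouts = bouts,
         truth = list(power = truth_power, pink_band_var = pink_band,
                      encounter_gain = cfg$encounter_gain,
                      context_signature = sig_spec,
                      shared_weight = cfg$shared_weight,
                      amps = amps, pink_amp = cfg$pink_amp))
  })
}

#' Simulate a full multi-subject, three-task dataset
#'
#' Three sessions per subject and task, with per-subject region dropout
#' (emulating mistargeted electrodes) recorded in the ground truth's
#' missingness map.
#'
#' @param cfg a [sim_config()].
#' @param seed master RNG seed; all sessions derive child seeds from it.
#' @param n_sessions sessions per subject-task.
#' @return an [lfp_dataset()]; `$ground_truth` holds the missingness map,
#'   context signatures and generator parameters.
#' @export
simulate_dataset <- function(cfg, seed, n_sessions = 3) {
  subjects <- sprintf("m%02d", seq_len(cfg$n_subjects))
  region_map <- lapply(setNames(subjects, subjects), function(sj) {
    with_seed(child_seed(seed, paste0("dropout_", sj)), {
      keep <- runif(length(cfg$regions)) >= cfg$region_dropout
      if (sum(keep) < 2) keep[sample(length(keep), 2)] <- TRUE
      cfg$regions[keep]
    })
  })
  sessions <- list(); bouts <- list()
  for (sj in subjects) {
    for (task in task_vocabulary()) {
      for (k in seq_len(n_sessions)) {
        res <- simulate_session(
          cfg, sj, task, k,
          child_seed(seed, sprintf("%s_%s_%d", sj, task, k)),
          regions = region_map[[sj]])
        id <- session_id(res$session)
        sessions[[id]] <- res$session
        bouts[[id]] <- res$bouts
      }
    }
  }
  lfp_dataset(sessions, bouts,
              ground_truth = list(region_map = region_map,
                                  context_signature = cfg$context_signature,
                                  shared_weight = as.list(cfg$shared_weight),
                                  encounter_gain = cfg$encounter_gain,
                                  seed = seed))
}

#' Calibration map from mixing weight to realized theta MSC
#'
#' Simulates two regions sharing a band source at a grid of mixing weights and
#' estimates the realized band-mean MSC, giving the map used to choose weights
#' for a target coherence (exact analytic inversion is not attempted because
#' the pink background dilutes the mixed-oscillator coherence).
#'
#' @param weights mixing-weight grid.
#' @param cfg a [sim_config()] (sampling rate, amplitudes, bands used).
#' @param duration_s simulated length per grid point.
#' @param seed RNG seed.
#' @param band band name.
#' @return data frame `weight, msc`.
#' @export
calibrate_coherence <- function(weights = seq(0, 0.95, by = 0.05), cfg = sim_config(),
                                duration_s = 120, seed = 1, band = "theta") {
  fs <- cfg$sampling_rate
  n <- round(duration_s * fs)
  bl <- band_limits(band)
  amp <- if (identical(band, "theta")) cfg$theta_amp else cfg$gamma_amp
  msc <- vapply(seq_along(weights), function(k) {
    w <- weights[k]
    with_seed(child_seed(seed, paste0("cal", k)), {
      s <- band_noise(n, fs, bl)
      x <- amp * (w * s + sqrt(1 - w^2) * band_noise(n, fs, bl)) +
        cfg$pink_amp * pink_noise(n)
      y <- amp * (w * s + sqrt(1 - w^2) * band_noise(n, fs, bl)) +
        cfg$pink_amp * pink_noise(n)
      cs <- welch_msc(x, y, fs, window_s = 2, overlap = 0.5, fmax = bl[2] + 5)
      sel <- cs$freqs >= bl[1] & cs$freqs <= bl[2]
      mean(cs$msc[sel])
    })
  }, numeric(1))
  data.frame(weight = weights, msc = msc)
}

#' @rdname calibrate_coherence
#' @param target_msc desired band-mean MSC.
#' @param calibration a `calibrate_coherence()` table.
#' @return interpolated mixing weight.
#' @export
weight_for_msc <- function(target_msc, calibration) {
  stopifnot(target_msc >= min(calibration$msc), target_msc <= max(calibration$msc))
  approx(calibration$msc, calibration$weight, xout = target_msc)$y
}


# Per-subject recorded regions under dropout, derived from the master seed.
dataset_region_map <- function(cfg, seed) {
  subjects <- sprintf("m%02d", seq_len(cfg$n_subjects))
  lapply(setNames(subjects, subjects), function(sj) {
    with_seed(child_seed(seed, paste0("dropout_", sj)), {
      keep <- runif(length(cfg$regions)) >= cfg$region_dropout
      if (sum(keep) < 2) keep[sample(length(keep), 2)] <- TRUE
      cfg$regions[keep]
    })
  })
}

# One independent RNG seed per session, drawn from a single master stream:
# label-derived seeds leave residual correlations between the streams of
# same-task sessions, strong enough to bias session-level statistics.
session_seed_table <- function(cfg, seed, n_sessions) {
  subjects <- sprintf("m%02d", seq_len(cfg$n_subjects))
  keys <- as.vector(outer(
    as.vector(outer(subjects, task_vocabulary(), paste, sep = "_")),
    seq_len(n_sessions), paste, sep = "_"))
  vals <- with_seed(child_seed(seed, "session_seeds"),
                    sample.int(2147483645L, length(keys)))
  setNames(as.list(vals), keys)
}


#' Simulate stationary multi-region signals with coherence ground truth
#'
#' The stationary core of the generator (no behavior, no gains): each region's
#' band components mix the shared and independent sources per the
#' configuration, on top of the pink background. Returned ground truth gives
#' the oscillator mixing weights and the implied oscillator-level MSC per pair
#' (the realized MSC is lower after pink dilution; see
#' [calibrate_coherence()]).
#'
#' @param cfg a [sim_config()].
#' @param duration_s signal length, seconds.
#' @param seed RNG seed.
#' @return list with `signals` (regions x samples), `regions`, `fs`, and
#'   `truth` (per band: shared weight and oscillator MSC per pair).
#' @export
simulate_region_signals <- function(cfg, duration_s = 60, seed = 1) {
  fs <- cfg$sampling_rate
  n <- round(duration_s * fs)
  nr <- length(cfg$regions)
  bands <- list(theta = cfg$theta_band, gamma = cfg$gamma_band)
  bands <- bands[intersect(names(bands), cfg$bands)]
  amps <- c(theta = cfg$theta_amp, gamma = cfg$gamma_amp)
  with_seed(seed, {
    x <- matrix(0, nr, n)
    for (bn in names(bands)) {
      w <- cfg$shared_weight[[bn]]
      shared <- band_noise(n, fs, bands[[bn]])
      for (r in seq_len(nr))
        x[r, ] <- x[r, ] + amps[[bn]] *
          (w * shared + sqrt(1 - w^2) * band_noise(n, fs, bands[[bn]]))
    }
    for (r in seq_len(nr)) x[r, ] <- x[r, ] + cfg$pink_amp * pink_noise(n)
    truth <- lapply(bands, function(b) {
      w <- cfg$shared_weight[[if (identical(b, cfg$theta_band)) "theta" else
        "gamma"]]
      list(shared_weight = w, oscillator_msc = (w * w)^2)
    })
    list(signals = x * cfg$scale_uv, regions = cfg$regions, fs = fs,
         truth = truth)
  })
}
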