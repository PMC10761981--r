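# Shared fixtures: tiny hand-built sessions and datasets, generated in code.

# A minimal valid session: `dur_s` seconds at `fs` Hz, white-noise signals,
# first half baseline / second half encounter.
toy_session <- function(subject = "m01", task = "SP", idx = 1L,
                        regions = c("AcbC", "BLA"), fs = 50, dur_s = 20,
                        seed = 1) {
  half <- dur_s / 2
  sig <- sblfp:::with_seed(seed,
    matrix(rnorm(length(regions) * fs * dur_s), length(regions)))
  recording_session(
    subject_id = subject, task = task, session_index = idx,
    sampling_rate = fs, signals = sig, region_labels = regions,
    baseline_interval = c(0, half), encounter_interval = c(half, dur_s),
    stimulus_map = setNames(task_stimuli(task), c("left", "right")))
}

toy_bouts <- function(session, starts, ends, stimuli,
                      chambers = rep("left", length(starts))) {
  bout_table(data.frame(session_id = sblfp:::session_id(session),
                        stimulus = stimuli, chamber = chambers,
                        start_s = starts, end_s = ends,
                        stringsAsFactors = FALSE),
             session = session)
}

# Dataset built from a design table (subject, task, idx, regions list-column).
toy_dataset <- function(design, fs = 50, dur_s = 20) {
  sessions <- list(); bouts <- list()
  for (i in seq_len(nrow(design))) {
    s <- toy_session(design$subject[i], design$task[i], design$idx[i],
                     regions = design$regions[[i]], fs = fs, dur_s = dur_s,
                     seed = i)
    id <- sblfp:::session_id(s)
    sessions[[id]] <- s
    bouts[[id]] <- toy_bouts(s, 11, 13, task_stimuli(design$task[i])[1])
  }
  lfp_dataset(sessions, bouts)
}

# Feature table built directly from a meta frame and matrix.
toy_feature_table <- function(meta, x) {
  structure(list(meta = meta, x = x), class = "feature_table")
}

# RMS amplitude of a sinusoid component at frequency f in a trace.
tone_amplitude <- function(x, fs, f) {
  t <- (seq_along(x) - 1) / fs
  2 * sqrt(mean(x * sin(2 * pi * f * t))^2 + mean(x * cos(2 * pi * f * t))^2)
}
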