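#' Recording session container
#'
#' One subject-task-session of multichannel LFP: a regions-by-samples signal
#' matrix (microvolts), region labels drawn from [region_vocabulary()], the
#' sampling rate, the baseline and encounter intervals (half-open, seconds from
#' session start), the chamber-to-stimulus map for the encounter, and the
#' stimulus insertion/removal times.
#'
#' @param subject_id character scalar.
#' @param task one of `"SP"`, `"EsP"`, `"SxP"`.
#' @param session_index positive integer.
#' @param sampling_rate sampling rate in Hz.
#' @param signals numeric matrix `n_regions x n_samples`, microvolts.
#' @param region_labels character vector of unique legal region codes, one per
#'   signal row.
#' @param baseline_interval,encounter_interval numeric length-2 vectors
#'   `[t0, t1)` in seconds; disjoint, nominally 300 s each.
#' @param stimulus_map named character vector mapping chamber (`"left"`,
#'   `"right"`) to the task's stimulus labels.
#' @param insertion_time,removal_time stimulus insertion/removal times in
#'   seconds (typically the encounter boundaries).
#' @return an object of class `recording_session`.
#' @export
recording_session <- function(subject_id, task, session_index, sampling_rate,
                              signals, region_labels,
                              baseline_interval, encounter_interval,
                              stimulus_map,
                              insertion_time = encounter_interval[1],
                              removal_time = encounter_interval[2]) {
  s <- structure(
    list(
      subject_id = as.character(subject_id),
      task = match.arg(task, task_vocabulary()),
      session_index = as.integer(session_index),
      sampling_rate = as.numeric(sampling_rate),
      signals = signals,
      region_labels = as.character(region_labels),
      baseline_interval = as.numeric(baseline_interval),
      encounter_interval = as.numeric(encounter_interval),
      stimulus_map = stimulus_map,
      insertion_time = as.numeric(insertion_time),
      removal_time = as.numeric(removal_time)
    ),
    class = "recording_session"
  )
  validate_recording_session(s)
  s
}

session_id <- function(session) {
  sprintf("%s_%s_%02d", session$subject_id, session$task, session$session_index)
}

session_duration <- function(session) {
  ncol(session$signals) / session$sampling_rate
}

validation_error <- function(record, field, msg) {
  stop(structure(
    class = c("sblfp_validation_error", "error", "condition"),
    list(message = sprintf("[%s] field '%s': %s", record, field, msg),
         call = NULL, record = record, field = field)
  ))
}

#' @rdname recording_session
#' @param session a `recording_session`.
#' @export
validate_recording_session <- function(session) {
  id <- session_id(session)
  if (!is.matrix(session$signals) || !is.numeric(session$signals))
    validation_error(id, "signals", "must be a numeric matrix")
  if (length(session$region_labels) != nrow(session$signals))
    validation_error(id, "region_labels",
                     "length must equal the number of signal rows")
  if (anyDuplicated(session$region_labels))
    validation_error(id, "region_labels", "region labels must be unique")
  bad <- setdiff(session$region_labels, region_vocabulary())
  if (length(bad))
    validation_error(id, "region_labels",
                     sprintf("unknown region code(s) %s; legal codes: %s",
                             paste(bad, collapse = ", "),
                             paste(region_vocabulary(), collapse = ", ")))
  if (!is.finite(session$sampling_rate) || session$sampling_rate <= 0)
    validation_error(id, "sampling_rate", "missing or non-positive")
  for (f in c("baseline_interval", "encounter_interval")) {
    iv <- session[[f]]
    if (length(iv) != 2 || !all(is.finite(iv)) || iv[1] >= iv[2])
      validation_error(id, f, "must be a finite [t0, t1) interval")
  }
  b <- session$baseline_interval; e <- session$encounter_interval
  if (max(b[1], e[1]) < min(b[2], e[2]))
    validation_error(id, "encounter_interval",
                     "baseline and encounter intervals must be disjoint")
  dur <- session_duration(session)
  if (max(b[2], e[2]) > dur + 1 / session$sampling_rate)
    validation_error(id, "signals",
                     sprintf("n_samples (%.1f s) shorter than the stated periods",
                             dur))
  stim <- task_stimuli(session$task)
  if (!all(sort(unname(session$stimulus_map)) == sort(stim)))
    validation_error(id, "stimulus_map",
                     sprintf("stimuli must be exactly {%s} for task %s",
                             paste(stim, collapse = ", "), session$task))
  invisible(session)
}

#' Bout table of timed investigation events
#'
#' Rows of `(session_id, stimulus, chamber, start_s, end_s)` describing
#' investigation bouts toward labeled stimuli; `duration_s` is derived. Bouts
#' must be non-overlapping and lie inside the session's time range. Baseline
#' bouts toward the still-empty chambers carry stimulus `"empty"`.
#'
#' @param df data frame with columns `session_id`, `stimulus`, `chamber`,
#'   `start_s`, `end_s`.
#' @param session optional `recording_session` to validate against (time range
#'   and legal stimulus labels).
#' @return a `bout_table` (a validated data frame with `duration_s` added).
#' @export
bout_table <- function(df, session = NULL) {
  need <- c("session_id", "stimulus", "chamber", "start_s", "end_s")
  miss <- setdiff(need, names(df))
  if (length(miss))
    validation_error("bout_table", miss[1], "missing required column")
  df <- df[order(df$start_s), need, drop = FALSE]
  rownames(df) <- NULL
  df$duration_s <- df$end_s - df$start_s
  bad <- which(df$end_s <= df$start_s)
  if (length(bad))
    validation_error(sprintf("%s row %d", df$session_id[bad[1]], bad[1]),
                     "end_s", "bout end must exceed bout start")
  if (nrow(df) > 1) {
    ov <- which(df$start_s[-1] < df$end_s[-nrow(df)])
    if (length(ov))
      validation_error(sprintf("%s row %d", df$session_id[ov[1] + 1], ov[1] + 1),
                       "start_s", "bouts overlap the preceding bout")
  }
  if (!is.null(session)) {
    dur <- session_duration(session)
    if (nrow(df) && (min(df$start_s) < 0 || max(df$end_s) > dur))
      validation_error(session_id(session), "bout_table",
                       "bouts extend outside the session time range")
    legal <- c(task_stimuli(session$task), EMPTY_STIMULUS)
    bad <- setdiff(unique(df$stimulus), legal)
    if (length(bad))
      validation_error(session_id(session), "stimulus",
                       sprintf("illegal stimulus label(s) %s for task %s",
                               paste(bad, collapse = ", "), session$task))
  }
  class(df) <- c("bout_table", "data.frame")
  df
}

#' Dataset of sessions with aligned bout tables
#'
#' @param sessions list of `recording_session` objects.
#' @param bout_tables list of `bout_table`s, aligned with `sessions`.
#' @param ground_truth optional generator ground truth (kept as-is).
#' @return an `lfp_dataset` with `subjects` and `region_validity`
#'   (subject -> recorded regions) derived.
#' @export
lfp_dataset <- function(sessions, bout_tables, ground_truth = NULL) {
  if (length(sessions) != length(bout_tables))
    validation_error("dataset", "bout_tables",
                     "every session needs exactly one bout table")
  ids <- vapply(sessions, session_id, character(1))
  names(sessions) <- ids
  names(bout_tables) <- ids
  subjects <- unique(vapply(sessions, `[[`, character(1), "subject_id"))
  region_validity <- lapply(setNames(subjects, subjects), function(sj) {
    labs <- lapply(sessions[vapply(sessions, function(s)
      s$subject_id == sj, logical(1))], `[[`, "region_labels")
    sort(unique(unlist(labs)))
  })
  structure(
    list(sessions = sessions, bout_tables = bout_tables,
         subjects = subjects, region_validity = region_validity,
         ground_truth = ground_truth),
    class = "lfp_dataset"
  )
}

#' @export
print.lfp_dataset <- function(x, ...) {
  cat(sprintf("<lfp_dataset> %d sessions, %d subjects, tasks: %s\n",
              length(x$sessions), length(x$subjects),
              paste(sort(unique(vapply(x$sessions, `[[`, character(1), "task"))),
                    collapse = ", ")))
  invisible(x)
}

# Long summary data frame of the dataset design (one row per session).
dataset_index <- function(dataset) {
  do.call(rbind, lapply(dataset$sessions, function(s) {
    data.frame(session_id = session_id(s), subject_id = s$subject_id,
               task = s$task, session_index = s$session_index,
               n_regions = length(s$region_labels),
               stringsAsFactors = FALSE)
  }))
}
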