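#' Region and pair eligibility filters
#'
#' `filter_regions` keeps a region iff it was recorded in more than
#' `min_sessions` sessions (strict) across at least `min_subjects` distinct
#' subjects. `eligible_pairs` keeps an unordered region pair iff the two
#' regions were recorded simultaneously in at least `min_sessions` sessions,
#' from at least `min_subjects` subjects, and in every one of the three tasks.
#'
#' @param dataset an [lfp_dataset()].
#' @param min_sessions,min_subjects eligibility thresholds. Defaults follow the
#'   study's rules: regions need `> 5` sessions across `>= 3` mice; pairs need
#'   `>= 5` sessions from `>= 2` subjects in all three tasks.
#' @return `filter_regions`: character vector of kept region codes.
#'   `eligible_pairs`: character vector of pair keys `"A|B"` (A < B).
#' @export
filter_regions <- function(dataset, min_sessions = 5, min_subjects = 3) {
  tab <- do.call(rbind, lapply(dataset$sessions, function(s)
    data.frame(region = s$region_labels, subject = s$subject_id,
               stringsAsFactors = FALSE)))
  if (is.null(tab)) return(character(0))
  keep <- vapply(unique(tab$region), function(r) {
    rows <- tab$region == r
    sum(rows) > min_sessions && length(unique(tab$subject[rows])) >= min_subjects
  }, logical(1))
  sort(unique(tab$region)[keep[unique(tab$region)]])
}

#' @rdname filter_regions
#' @export
eligible_pairs <- function(dataset, min_sessions = 5, min_subjects = 2) {
  regions <- filter_regions(dataset)
  recs <- lapply(dataset$sessions, function(s)
    list(subject = s$subject_id, task = s$task,
         regions = intersect(s$region_labels, regions)))
  counts <- new.env(parent = emptyenv())
  for (r in recs) {
    rg <- sort(r$regions)
    if (length(rg) < 2) next
    cmb <- combn(rg, 2)
    for (k in seq_len(ncol(cmb))) {
      key <- pair_key(cmb[1, k], cmb[2, k])
      e <- counts[[key]]
      if (is.null(e)) e <- list(n = 0L, subjects = character(0), tasks = character(0))
      e$n <- e$n + 1L
      e$subjects <- union(e$subjects, r$subject)
      e$tasks <- union(e$tasks, r$task)
      counts[[key]] <- e
    }
  }
  keys <- ls(counts)
  keep <- vapply(keys, function(k) {
    e <- counts[[k]]
    e$n >= min_sessions && length(e$subjects) >= min_subjects &&
      all(task_vocabulary() %in% e$tasks)
  }, logical(1))
  sort(keys[keep])
}

#' Filter bouts by minimum duration
#'
#' Keeps bouts strictly longer than `min_duration_s` (default 2 s): short bouts
#' neither discriminate between stimuli nor allow reliable theta-coherence
#' estimation.
#'
#' @param bouts a [bout_table()].
#' @param min_duration_s duration threshold in seconds (strict `>`).
#' @return the filtered `bout_table`.
#' @export
valid_bouts <- function(bouts, min_duration_s = 2) {
  out <- bouts[bouts$duration_s > min_duration_s, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(bouts)
  out
}

#' Derive behavioral events from a bout table
#'
#' Each bout emits a `bout_start` and a `bout_end` event; every bout after the
#' first additionally emits a `transition_start` (previous bout targeted the
#' other stimulus) or a `repeat_start` (same stimulus). The first bout of a
#' session emits neither.
#'
#' @param bouts a time-sorted [bout_table()].
#' @return data frame with columns `kind`, `time_s`, `stimulus`,
#'   `previous_stimulus` (NA for ends and for the first start).
#' @export
extract_events <- function(bouts) {
  n <- nrow(bouts)
  empty <- data.frame(kind = character(0), time_s = numeric(0),
                      stimulus = character(0), previous_stimulus = character(0),
                      stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  prev <- c(NA_character_, bouts$stimulus[-n])
  ev <- rbind(
    data.frame(kind = "bout_start", time_s = bouts$start_s,
               stimulus = bouts$stimulus, previous_stimulus = prev,
               stringsAsFactors = FALSE),
    data.frame(kind = "bout_end", time_s = bouts$end_s,
               stimulus = bouts$stimulus, previous_stimulus = NA_character_,
               stringsAsFactors = FALSE)
  )
  if (n > 1) {
    idx <- 2:n
    kind <- ifelse(bouts$stimulus[idx] == bouts$stimulus[idx - 1],
                   "repeat_start", "transition_start")
    ev <- rbind(ev, data.frame(
      kind = kind, time_s = bouts$start_s[idx], stimulus = bouts$stimulus[idx],
      previous_stimulus = bouts$stimulus[idx - 1], stringsAsFactors = FALSE))
  }
  ev <- ev[order(ev$time_s, match(ev$kind, c("bout_start", "transition_start",
                                             "repeat_start", "bout_end"))), ]
  rownames(ev) <- NULL
  ev
}

#' Relative discrimination index (RDI)
#'
#' RDI = (T_preferred - T_other) / (T_preferred + T_other) over total
#' investigation times in one encounter period, together with the total
#' investigation time and the number of transitions between stimuli.
#'
#' @param bouts a [bout_table()] restricted to one encounter period (bouts
#'   toward the two task stimuli).
#' @param preferred stimulus label treated as preferred.
#' @return list with `rdi`, `total_investigation_s`, `n_transitions`, and
#'   `defined` (FALSE with `rdi = NA` when total investigation time is zero).
#' @export
preference_index <- function(bouts, preferred) {
  stim <- unique(bouts$stimulus)
  t_pref <- sum(bouts$duration_s[bouts$stimulus == preferred])
  t_other <- sum(bouts$duration_s[bouts$stimulus != preferred])
  total <- t_pref + t_other
  n_trans <- if (nrow(bouts) > 1)
    sum(bouts$stimulus[-1] != bouts$stimulus[-nrow(bouts)]) else 0L
  if (total <= 0) {
    warning("zero total investigation time; RDI undefined")
    return(list(rdi = NA_real_, total_investigation_s = 0,
                n_transitions = n_trans, defined = FALSE))
  }
  list(rdi = (t_pref - t_other) / total, total_investigation_s = total,
       n_transitions = as.integer(n_trans), defined = TRUE)
}

#' Sample mask excluding stimulus insertion/removal artefacts
#'
#' Samples within `half_window_s` (default 30 s, i.e. a 60 s window) of each
#' stimulus insertion or removal event are masked out to avoid handling
#' artefacts.
#'
#' @param session a [recording_session()].
#' @param half_window_s half-width of the exclusion window, seconds.
#' @return logical vector over samples; `FALSE` inside the exclusion windows.
#' @export
exclusion_mask <- function(session, half_window_s = 30) {
  n <- ncol(session$signals)
  fs <- session$sampling_rate
  mask <- rep(TRUE, n)
  for (t0 in c(session$insertion_time, session$removal_time)) {
    if (!is.finite(t0)) next
    i0 <- max(1L, floor((t0 - half_window_s) * fs) + 1L)
    i1 <- min(n, ceiling((t0 + half_window_s) * fs))
    if (i0 <= i1) mask[i0:i1] <- FALSE
  }
  mask
}

# Masked-out time intervals [start, end) in seconds, for time-bin logic.
exclusion_intervals <- function(session, half_window_s = 30) {
  ts <- c(session$insertion_time, session$removal_time)
  ts <- ts[is.finite(ts)]
  if (!length(ts)) return(matrix(numeric(0), ncol = 2))
  iv <- cbind(pmax(0, ts - half_window_s),
              pmin(session_duration(session), ts + half_window_s))
  iv[order(iv[, 1]), , drop = FALSE]
}
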