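#' Read and write datasets on disk
#'
#' On-disk layout: one directory per session under `<root>/sessions/`, holding
#' `signals.feather` (Arrow IPC, one column per region, microvolts),
#' `session.json` (subject, task, intervals, stimulus map, insertion/removal
#' times, sampling rate, region order) and `bouts.csv`
#' (`session_id,stimulus,chamber,start_s,end_s`). An optional
#' `ground_truth.json` at the root is passed through.
#'
#' @param dataset an [lfp_dataset()].
#' @param root directory path.
#' @return `write_dataset` returns `root` invisibly; `read_dataset` returns a
#'   validated [lfp_dataset()]. Malformed sessions raise a validation error
#'   naming the file and field.
#' @export
write_dataset <- function(dataset, root) {
  dir.create(file.path(root, "sessions"), recursive = TRUE, showWarnings = FALSE)
  for (id in names(dataset$sessions)) {
    s <- dataset$sessions[[id]]
    dir <- file.path(root, "sessions", id)
    dir.create(dir, showWarnings = FALSE)
    sig <- as.data.frame(t(s$signals))
    names(sig) <- s$region_labels
    arrow::write_feather(sig, file.path(dir, "signals.feather"))
    meta <- list(
      subject_id = s$subject_id, task = s$task,
      session_index = s$session_index,
      sampling_rate_hz = s$sampling_rate,
      region_labels = s$region_labels,
      baseline_interval = s$baseline_interval,
      encounter_interval = s$encounter_interval,
      stimulus_map = as.list(s$stimulus_map),
      insertion_time = s$insertion_time,
      removal_time = s$removal_time
    )
    jsonlite::write_json(meta, file.path(dir, "session.json"),
                         auto_unbox = TRUE, digits = NA)
    b <- dataset$bout_tables[[id]]
    write.csv(b[, c("session_id", "stimulus", "chamber", "start_s", "end_s")],
              file.path(dir, "bouts.csv"), row.names = FALSE)
  }
  if (!is.null(dataset$ground_truth))
    jsonlite::write_json(dataset$ground_truth,
                         file.path(root, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(root)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(root) {
  sdirs <- list.dirs(file.path(root, "sessions"), recursive = FALSE)
  if (!length(sdirs)) stop("no sessions found under ", root)
  sessions <- list(); bouts <- list()
  for (dir in sort(sdirs)) {
    mfile <- file.path(dir, "session.json")
    if (!file.exists(mfile))
      validation_error(mfile, "session.json", "sidecar missing")
    meta <- jsonlite::read_json(mfile, simplifyVector = TRUE)
    if (is.null(meta$sampling_rate_hz))
      validation_error(mfile, "sampling_rate_hz", "missing sampling rate")
    sig <- as.data.frame(arrow::read_feather(file.path(dir, "signals.feather")))
    sig_m <- t(as.matrix(sig[, meta$region_labels, drop = FALSE]))
    dimnames(sig_m) <- NULL
    s <- recording_session(
      subject_id = meta$subject_id, task = meta$task,
      session_index = meta$session_index,
      sampling_rate = meta$sampling_rate_hz,
      signals = sig_m,
      region_labels = meta$region_labels,
      baseline_interval = meta$baseline_interval,
      encounter_interval = meta$encounter_interval,
      stimulus_map = unlist(meta$stimulus_map),
      insertion_time = meta$insertion_time,
      removal_time = meta$removal_time
    )
    b <- bout_table(read.csv(file.path(dir, "bouts.csv"),
                             stringsAsFactors = FALSE), session = s)
    sessions[[session_id(s)]] <- s
    bouts[[session_id(s)]] <- b
  }
  gt_file <- file.path(root, "ground_truth.json")
  gt <- if (file.exists(gt_file))
    jsonlite::read_json(gt_file, simplifyVector = TRUE) else NULL
  lfp_dataset(sessions, bouts, ground_truth = gt)
}
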