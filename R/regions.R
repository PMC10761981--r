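#' Region and task vocabularies
#'
#' The 18 recorded brain regions of the social-brain electrode array, the three
#' binary discrimination tasks, and the legal stimulus labels for each task.
#' During the baseline (pre-encounter) period both chambers are empty; bouts in
#' that period carry the reserved stimulus label `"empty"`.
#'
#' @return `region_vocabulary()` returns the character vector of legal region
#'   codes; `task_vocabulary()` the three task codes; `task_stimuli(task)` the
#'   two encounter stimulus labels of a task; `task_preferred_stimulus(task)`
#'   the stimulus the subject is expected to prefer in that task.
#' @export
region_vocabulary <- function() {
  c("AcbC", "AcbSh", "AhiAL", "BLA", "BMP", "DMD", "EA", "IL", "LS",
    "MeAD", "Pir", "PLH", "PrL", "PVN", "vCA1", "vDG", "VP", "CeA")
}

#' @rdname region_vocabulary
#' @export
task_vocabulary <- function() c("SP", "EsP", "SxP")

#' @rdname region_vocabulary
#' @param task one of `"SP"`, `"EsP"`, `"SxP"`.
#' @export
task_stimuli <- function(task) {
  switch(match.arg(task, task_vocabulary()),
    SP  = c("social", "object"),
    EsP = c("isolated", "grouped"),
    SxP = c("female", "male")
  )
}

#' @rdname region_vocabulary
#' @export
task_preferred_stimulus <- function(task) {
  switch(match.arg(task, task_vocabulary()),
    SP = "social", EsP = "isolated", SxP = "female")
}

# Stimulus label reserved for baseline-period empty-chamber investigation.
EMPTY_STIMULUS <- "empty"

# Canonical unordered pair key "A|B" with A < B lexicographically.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# Split pair keys back into a 2-column character matrix.
pair_split <- function(keys) {
  do.call(rbind, strsplit(keys, "|", fixed = TRUE))
}
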