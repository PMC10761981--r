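# --- End-to-end helpers -------------------------------------------------------

# Eligible pairs implied by a simulation design (region map + sessions per
# subject-task), without materializing signals: a pair is eligible iff the
# subjects recording both regions jointly provide >= min_sessions sessions,
# >= min_subjects subjects, and all three tasks.
design_eligible_pairs <- function(region_map, n_sessions = 3,
                                  min_sessions = 5, min_subjects = 2) {
  regions <- sort(unique(unlist(region_map)))
  if (length(regions) < 2) return(character(0))
  cmb <- combn(regions, 2)
  keys <- character(0)
  for (k in seq_len(ncol(cmb))) {
    subj <- names(region_map)[vapply(region_map, function(r)
      all(cmb[, k] %in% r), logical(1))]
    if (length(subj) >= min_subjects &&
        length(subj) * n_sessions * 3 >= min_sessions)
      keys <- c(keys, pair_key(cmb[1, k], cmb[2, k]))
  }
  sort(keys)
}

#' Simulate a dataset and extract bout-coherence features, streaming
#'
#' Generates each session of the full multi-subject, three-task design in turn,
#' computes its bout-locked coherence-change values over the design's eligible
#' pairs, and discards the signals - so feature extraction over long sessions
#' stays within memory. Ground truth (region map, signatures) is returned with
#' the long table.
#'
#' @param cfg a [sim_config()].
#' @param seed master seed (same derivation as [simulate_dataset()], so the
#'   features equal those of the materialized dataset).
#' @param band band name or limits.
#' @param n_sessions sessions per subject-task.
#' @return list with `table` (long bout-coherence table), `pairs`,
#'   `region_map`.
#' @export
simulate_bout_coherence_features <- function(cfg, seed, band = "theta",
                                             n_sessions = 3) {
  subjects <- sprintf("m%02d", seq_len(cfg$n_subjects))
  region_map <- dataset_region_map(cfg, seed)
  seed_tab <- session_seed_table(cfg, seed, n_sessions)
  pairs <- design_eligible_pairs(region_map, n_sessions)
  rows <- list()
  for (sj in subjects) {
    for (task in task_vocabulary()) {
      for (k in seq_len(n_sessions)) {
        res <- simulate_session(
          cfg, sj, task, k,
          seed_tab[[sprintf("%s_%s_%d", sj, task, k)]],
          regions = region_map[[sj]])
        rows[[length(rows) + 1]] <-
          session_bout_coherence(res$session, res$bouts, pairs, band)
        rm(res)
      }
    }
  }
  list(table = do.call(rbind, rows), pairs = pairs, region_map = region_map)
}

#' Full context-decoding pipeline
#'
#' Feature table from a bout-coherence table, sparse-mouse exclusion, per-mouse
#' normalization, iterative regression imputation, leave-one-mouse-out
#' random-forest confusion matrices, the random-classifier null, and per-cell
#' significance.
#'
#' @param coh_table long bout-coherence table (see
#'   [dataset_coherence_table()] / [simulate_bout_coherence_features()]).
#' @param label decoder labeling (see [crossval_confusion()]).
#' @param min_pairs sparse-mouse threshold.
#' @param n_repeats forest repeats per mouse.
#' @param n_null_matrices,inner_repeats null-classifier parameters.
#' @param n_trees trees per forest.
#' @param seed master seed for imputation, balancing, forests and the null.
#' @return list with `features` (imputed `feature_table`), `real`
#'   (confusion summary), `null`, `cells` (per-cell significance).
#' @export
decode_context <- function(coh_table, label = "context_3class",
                           min_pairs = 40, n_repeats = 100,
                           n_null_matrices = 83, inner_repeats = 100,
                           n_trees = 80, seed = 1) {
  ft <- build_feature_table(coh_table)
  ft <- exclude_sparse_mice(ft, min_pairs)
  ft <- normalize_per_mouse(ft)
  ft <- impute_features(ft, n_iterations = 20, seed = child_seed(seed, "impute"))
  real <- crossval_confusion(ft, label, n_trees = n_trees,
                             n_repeats = n_repeats,
                             seed = child_seed(seed, "rf"))
  null <- random_null_confusion(ft, label, n_matrices = n_null_matrices,
                                inner_repeats = inner_repeats,
                                seed = child_seed(seed, "null"))
  cells <- cell_significance(real, null)
  list(features = ft, real = real, null = null, cells = cells)
}
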