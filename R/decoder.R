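# --- Context decoder: features, imputation, random-forest cross-validation ---

#' Build the decoder feature table
#'
#' Pivots a bout-mode coherence (or power) table into one row per
#' session x stimulus ("average bout") with one column per region pair. Pairs
#' never recorded for a mouse are explicit missing entries; rows with no
#' finite value (a session with no valid bouts for a stimulus) are dropped.
#'
#' @param coh_table long table from [dataset_coherence_table()] (bout mode):
#'   columns `subject, task, session_id, stimulus, pair, value`.
#' @return object of class `feature_table`: list with `meta` (data frame
#'   `mouse, task, session_id, stimulus`) and `x` (numeric matrix rows x
#'   pairs, NA = missing).
#' @export
build_feature_table <- function(coh_table) {
  pairs <- sort(unique(coh_table$pair))
  key <- paste(coh_table$session_id, coh_table$stimulus, sep = "#")
  rows <- unique(data.frame(key = key, mouse = coh_table$subject,
                            task = coh_table$task,
                            session_id = coh_table$session_id,
                            stimulus = coh_table$stimulus,
                            stringsAsFactors = FALSE))
  x <- matrix(NA_real_, nrow(rows), length(pairs),
              dimnames = list(rows$key, pairs))
  x[cbind(match(key, rows$key), match(coh_table$pair, pairs))] <- coh_table$value
  keep <- rowSums(is.finite(x)) > 0
  if (any(!keep))
    message(sum(!keep), " session-stimulus rows dropped (no valid bouts)")
  structure(list(meta = rows[keep, c("mouse", "task", "session_id", "stimulus")],
                 x = x[keep, , drop = FALSE]),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d rows x %d pairs, %d mice, %.1f%% missing\n",
              nrow(x$x), ncol(x$x), length(unique(x$meta$mouse)),
              100 * mean(!is.finite(x$x))))
  invisible(x)
}

#' Exclude mice with too few recorded pairs
#'
#' Mice whose number of recorded (ever-finite) pair columns is strictly below
#' `min_pairs` are removed.
#'
#' @param ft a [build_feature_table()] result.
#' @param min_pairs threshold (strict `<` removal).
#' @return filtered `feature_table`; attribute `removed` lists dropped mice.
#' @export
exclude_sparse_mice <- function(ft, min_pairs = 40) {
  n_pairs <- vapply(unique(ft$meta$mouse), function(m) {
    sum(colSums(is.finite(ft$x[ft$meta$mouse == m, , drop = FALSE])) > 0)
  }, numeric(1))
  bad <- names(n_pairs)[n_pairs < min_pairs]
  keep <- !(ft$meta$mouse %in% bad)
  out <- structure(list(meta = ft$meta[keep, ], x = ft$x[keep, , drop = FALSE]),
                   class = "feature_table")
  attr(out, "removed") <- bad
  out
}

#' Per-mouse feature normalization
#'
#' For each mouse and pair: the mean value of each stimulus's rows is computed,
#' those per-stimulus means are averaged (unweighted, so no stimulus is
#' over-represented), and the result is subtracted from all of that
#' mouse-pair's entries. The unweighted stimulus-mean of the normalized values
#' is exactly zero.
#'
#' @param ft a `feature_table` (sparse mice excluded).
#' @return normalized `feature_table`.
#' @export
normalize_per_mouse <- function(ft) {
  x <- ft$x
  for (m in unique(ft$meta$mouse)) {
    rows <- which(ft$meta$mouse == m)
    stim <- ft$meta$stimulus[rows]
    for (j in seq_len(ncol(x))) {
      v <- x[rows, j]
      if (!any(is.finite(v))) next
      sm <- tapply(v, stim, function(z)
        if (any(is.finite(z))) mean(z, na.rm = TRUE) else NA_real_)
      grand <- mean(sm, na.rm = TRUE)
      x[rows, j] <- v - grand
    }
  }
  structure(list(meta = ft$meta, x = x), class = "feature_table")
}

#' Iterative regression imputation of missing pairs
#'
#' Missing entries are first initialized with the column mean over observed
#' rows. Then, for `n_iterations` rounds: pairs are visited in a freshly
#' randomized order; for each pair a random predictor set of other pairs
#' (size `min(floor(0.5 * n_rows) - 1, n_pairs - 1)`, keeping the coefficient
#' count strictly below half the number of rows) is drawn, least-squares
#' coefficients with intercept are fitted over all rows, and the
#' originally-missing entries are overwritten with the predictions.
#' Rank-deficient fits use the pivoted-QR solution with aliased coefficients
#' set to zero. Observed entries are never altered.
#'
#' @param ft a normalized `feature_table`.
#' @param n_iterations number of sweeps.
#' @param seed RNG seed (predictor draws and visiting order).
#' @param fit_observed_only fit the regressions on originally-observed rows of
#'   the target pair only, instead of all rows.
#' @return `feature_table` with a complete matrix.
#' @export
impute_features <- function(ft, n_iterations = 20, seed = 1,
                            fit_observed_only = FALSE) {
  x <- ft$x
  obs <- is.finite(x)
  if (any(colSums(obs) == 0))
    stop("pair(s) with no observed value cannot be imputed: ",
         paste(colnames(x)[colSums(obs) == 0], collapse = ", "))
  if (all(obs)) return(ft)
  np <- ncol(x); nr <- nrow(x)
  for (j in which(colSums(!obs) > 0))
    x[!obs[, j], j] <- mean(x[obs[, j], j])
  n_pred <- max(1L, min(floor(0.5 * nr) - 1L, np - 1L))
  with_seed(seed, {
    for (it in seq_len(n_iterations)) {
      for (i in sample.int(np)) {
        miss <- !obs[, i]
        if (!any(miss)) next
        preds <- sample(setdiff(seq_len(np), i), n_pred)
        rows <- if (fit_observed_only) which(obs[, i]) else seq_len(nr)
        X <- cbind(1, x[rows, preds, drop = FALSE])
        fit <- qr(X, LAPACK = FALSE)
        cf <- qr.coef(fit, x[rows, i])
        cf[!is.finite(cf)] <- 0
        x[miss, i] <- cbind(1, x[miss, preds, drop = FALSE]) %*% cf
      }
    }
  })
  out <- structure(list(meta = ft$meta, x = x), class = "feature_table")
  attr(out, "observed_mask") <- obs
  out
}

decoder_labels <- function(ft, label = c("stimulus_2class", "context_3class",
                                         "stimulus_6class")) {
  label <- match.arg(label)
  switch(label,
    stimulus_2class = list(rows = which(ft$meta$task == "SP"),
                           y = factor(ft$meta$stimulus[ft$meta$task == "SP"])),
    context_3class = list(rows = seq_len(nrow(ft$x)),
                          y = factor(ft$meta$task, levels = task_vocabulary())),
    stimulus_6class = list(rows = seq_len(nrow(ft$x)),
                           y = factor(ft$meta$stimulus)))
}

# Column-percentage matrix from a count matrix (columns = ground truth).
counts_to_percent <- function(cm) {
  cs <- colSums(cm)
  pm <- sweep(cm, 2, cs, "/") * 100
  pm[, cs == 0] <- NA_real_
  pm
}

#' Leave-one-mouse-out random-forest confusion matrices
#'
#' For each mouse and repeat: a random forest (`n_trees` trees, default
#' splitting) is trained on all rows of the other mice after balancing the
#' classes by random down-sampling, then predicts the held-out mouse's rows.
#' Counts accumulate over repeats into a per-mouse confusion matrix
#' (rows = prediction, columns = ground truth); percentages are per
#' ground-truth column.
#'
#' @param ft a complete (imputed) `feature_table`.
#' @param label `"stimulus_2class"`, `"context_3class"` or
#'   `"stimulus_6class"`.
#' @param n_trees trees per forest.
#' @param n_repeats repeats per mouse (balancing and the forest are random).
#' @param seed master seed; each (mouse, repeat) uses a derived child seed.
#' @return list of class `confusion_summary`: `per_mouse` (named list of
#'   percentage matrices), `per_mouse_counts`, `overall` (percentage matrix
#'   aggregated over all mouse-repeats), `classes`, `label`.
#' @export
crossval_confusion <- function(ft, label = "context_3class", n_trees = 80,
                               n_repeats = 100, seed = 1) {
  lab <- decoder_labels(ft, label)
  x <- ft$x[lab$rows, , drop = FALSE]
  y <- lab$y
  mice <- ft$meta$mouse[lab$rows]
  classes <- levels(y)
  K <- length(classes)
  per_mouse_counts <- list()
  for (m in unique(mice)) {
    tr <- mice != m
    if (any(table(y[tr]) == 0))
      stop("class absent from the training fold for mouse ", m)
    counts <- matrix(0, K, K, dimnames = list(pred = classes, truth = classes))
    for (rep_ in seq_len(n_repeats)) {
      counts <- counts + with_seed(
        child_seed(seed, sprintf("rf_%s_%d", m, rep_)), {
          idx <- balance_classes(y[tr])
          fit <- randomForest::randomForest(
            x = x[tr, , drop = FALSE][idx, , drop = FALSE],
            y = y[tr][idx], ntree = n_trees)
          pred <- predict(fit, x[!tr, , drop = FALSE])
          table(factor(pred, classes), factor(y[!tr], classes))
        })
    }
    per_mouse_counts[[m]] <- counts
  }
  total <- Reduce(`+`, per_mouse_counts)
  structure(list(per_mouse = lapply(per_mouse_counts, counts_to_percent),
                 per_mouse_counts = per_mouse_counts,
                 overall = counts_to_percent(total),
                 classes = classes, label = label),
            class = "confusion_summary")
}

# Indices balancing a factor by random down-sampling to the smallest class.
balance_classes <- function(y) {
  nmin <- min(table(y))
  unlist(lapply(levels(y), function(cl) {
    i <- which(y == cl)
    if (length(i) > nmin) sample(i, nmin) else i
  }), use.names = FALSE)
}

#' Random-classifier null confusion matrices
#'
#' Identical folds to [crossval_confusion()] but predictions are drawn
#' uniformly over the classes: each of `n_matrices` null matrices per mouse is
#' the average of `inner_repeats` confusion matrices. Every cell's expectation
#' is `100 / K` percent.
#'
#' @inheritParams crossval_confusion
#' @param n_matrices null matrices per mouse.
#' @param inner_repeats confusion matrices averaged per null matrix.
#' @return list: `per_mouse` (named list over mice, each a list of
#'   `n_matrices` percentage matrices), `classes`.
#' @export
random_null_confusion <- function(ft, label = "context_3class",
                                  n_matrices = 83, inner_repeats = 100,
                                  seed = 1) {
  lab <- decoder_labels(ft, label)
  y <- lab$y
  mice <- ft$meta$mouse[lab$rows]
  classes <- levels(y)
  K <- length(classes)
  per_mouse <- list()
  for (m in unique(mice)) {
    n_truth <- table(factor(y[mice == m], classes))
    per_mouse[[m]] <- with_seed(child_seed(seed, paste0("null_", m)), {
      lapply(seq_len(n_matrices), function(b) {
        counts <- matrix(0, K, K, dimnames = list(pred = classes,
                                                  truth = classes))
        for (j in seq_len(K)) {
          if (n_truth[j] == 0) next
          # uniform predictions for n_truth[j] test rows, inner_repeats times
          counts[, j] <- rowSums(rmultinom(inner_repeats, n_truth[j],
                                           rep(1 / K, K))) / inner_repeats
        }
        counts_to_percent(counts)
      })
    })
  }
  list(per_mouse = per_mouse, classes = classes, label = label)
}

#' Per-cell significance of the trained decoder against the null
#'
#' For each confusion cell (i, j): a two-sided Mann-Whitney U test comparing
#' the per-mouse percentages of the trained classifier to all per-mouse null
#' percentages; mice lacking any test bout of ground-truth class j are dropped
#' from column j's cells. Benjamini-Hochberg FDR across all testable cells.
#'
#' @param real a [crossval_confusion()] result.
#' @param null a [random_null_confusion()] result over the same mice.
#' @param q FDR level.
#' @return list with `p`, `p_adj`, `rejected` (K x K matrices; NA where fewer
#'   than 2 mice contribute), `n_mice` (contributing mice per column).
#' @export
cell_significance <- function(real, null, q = 0.05) {
  classes <- real$classes
  K <- length(classes)
  mice <- names(real$per_mouse)
  stopifnot(setequal(mice, names(null$per_mouse)))
  p <- matrix(NA_real_, K, K, dimnames = list(pred = classes, truth = classes))
  n_mice <- integer(K)
  for (j in seq_len(K)) {
    ok <- vapply(mice, function(m)
      all(is.finite(real$per_mouse[[m]][, j])), logical(1))
    n_mice[j] <- sum(ok)
    if (n_mice[j] < 2) next
    for (i in seq_len(K)) {
      rv <- vapply(mice[ok], function(m) real$per_mouse[[m]][i, j], numeric(1))
      nv <- unlist(lapply(mice[ok], function(m)
        vapply(null$per_mouse[[m]], function(nm) nm[i, j], numeric(1))))
      nv <- nv[is.finite(nv)]
      p[i, j] <- suppressWarnings(wilcox.test(rv, nv)$p.value)
    }
  }
  adj <- bh_fdr(as.vector(p), q)
  list(p = p,
       p_adj = matrix(adj$p_adj, K, K, dimnames = dimnames(p)),
       rejected = matrix(adj$rejected, K, K, dimnames = dimnames(p)),
       n_mice = setNames(n_mice, classes))
}
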