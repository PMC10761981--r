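make_long_table <- function(n_mice = 4, pairs = paste0("A|R", 1:6), seed = 1,
                            effect = NULL) {
  sblfp:::with_seed(seed, {
    rows <- list()
    for (m in sprintf("m%02d", seq_len(n_mice)))
      for (tk in task_vocabulary())
        for (k in 1:3)
          for (st in task_stimuli(tk))
            for (p in pairs) {
              v <- rnorm(1, sd = 0.3)
              if (!is.null(effect)) v <- v + effect(tk, p)
              rows[[length(rows) + 1]] <- data.frame(
                subject = m, task = tk,
                session_id = sprintf("%s_%s_%02d", m, tk, k),
                session_index = k, pair = p, stimulus = st,
                metric = "bout_delta_co", value = v,
                stringsAsFactors = FALSE)
            }
    do.call(rbind, rows)
  })
}

test_that("feature table pivots session-stimulus rows over pairs", {
  tab <- make_long_table(n_mice = 2)
  ft <- build_feature_table(tab)
  # 2 stimuli x 3 sessions x 3 tasks x 2 mice
  expect_equal(nrow(ft$x), 2 * 3 * 3 * 2)
  expect_equal(ncol(ft$x), 6)
  # row values equal a direct lookup
  i <- 5
  want <- tab$value[tab$session_id == ft$meta$session_id[i] &
                      tab$stimulus == ft$meta$stimulus[i]]
  expect_equal(unname(ft$x[i, sort(unique(tab$pair))]),
               want[order(tab$pair[tab$session_id == ft$meta$session_id[i] &
                                     tab$stimulus == ft$meta$stimulus[i]])])
  # a session-stimulus with all-NA values produces no row
  tab2 <- tab
  drop_id <- tab2$session_id[1]
  tab2$value[tab2$session_id == drop_id & tab2$stimulus == "social"] <- NA
  expect_message(ft2 <- build_feature_table(tab2), "dropped")
  expect_equal(nrow(ft2$x), nrow(ft$x) - 1)
})

test_that("sparse mice are excluded by the strict threshold", {
  tab <- make_long_table(n_mice = 3)
  tab$value[tab$subject == "m03" & tab$pair %in% paste0("A|R", 3:6)] <- NA
  ft <- build_feature_table(tab)   # m03 records 2 of 6 pairs
  kept3 <- exclude_sparse_mice(ft, min_pairs = 3)
  expect_false("m03" %in% kept3$meta$mouse)
  expect_identical(attr(kept3, "removed"), "m03")
  kept2 <- exclude_sparse_mice(ft, min_pairs = 2)  # exactly at threshold: kept
  expect_true("m03" %in% kept2$meta$mouse)
  expect_length(attr(exclude_sparse_mice(ft, 1), "removed"), 0)
})

test_that("per-mouse normalization uses unweighted stimulus means", {
  # worked example: one mouse, one pair; stimulus A rows {1, 3}, B rows {5}
  meta <- data.frame(mouse = "m01", task = "SP", session_id = c("s1", "s2", "s2"),
                     stimulus = c("a", "a", "b"), stringsAsFactors = FALSE)
  ft <- toy_feature_table(meta, matrix(c(1, 3, 5), 3, 1,
                                       dimnames = list(NULL, "X|Y")))
  norm <- normalize_per_mouse(ft)
  expect_equal(as.vector(norm$x), c(-2.5, -0.5, 1.5))
  # postcondition: unweighted stimulus-mean of normalized values is 0
  sm <- tapply(norm$x[, 1], meta$stimulus, mean)
  expect_equal(mean(sm), 0)
  # balanced stimuli reduce to plain mean subtraction
  ftb <- toy_feature_table(
    data.frame(mouse = "m01", task = "SP", session_id = "s",
               stimulus = rep(c("a", "b"), 3)),
    matrix(rnorm(6), 6, 1, dimnames = list(NULL, "X|Y")))
  nb <- normalize_per_mouse(ftb)
  expect_equal(as.vector(nb$x), ftb$x[, 1] - mean(ftb$x[, 1]))
})

test_that("iterative regression imputation recovers linear structure", {
  # no missing entries: identity
  ft_full <- toy_feature_table(
    data.frame(mouse = "m01", task = "SP", session_id = "s",
               stimulus = rep(c("a", "b"), 50)),
    matrix(rnorm(100 * 5), 100, 5, dimnames = list(NULL, paste0("P|", 1:5))))
  expect_identical(impute_features(ft_full, seed = 1)$x, ft_full$x)
  # exact dependence bp_1 = 2 bp_2: masked entries recovered ~ exactly
  X <- sblfp:::with_seed(2, matrix(rnorm(200 * 10), 200, 10,
                                   dimnames = list(NULL, paste0("P|", 1:10))))
  X[, 1] <- 2 * X[, 2]
  mask <- sblfp:::with_seed(3, sample(200, 40))
  truth <- X[mask, 1]
  X[mask, 1] <- NA
  ft <- toy_feature_table(
    data.frame(mouse = "m01", task = "SP", session_id = "s",
               stimulus = rep(c("a", "b"), 100)), X)
  imp <- impute_features(ft, seed = 4)
  expect_lt(sqrt(mean((imp$x[mask, 1] - truth)^2)), 1e-6)
  # observed entries untouched
  obs <- setdiff(seq_len(200), mask)
  expect_identical(imp$x[obs, ], ft$x[obs, ])
  # noisy linear rule: RMSE ~ noise SD, not below the floor
  sigma <- 0.4
  Xn <- sblfp:::with_seed(5, matrix(rnorm(300 * 8), 300, 8,
                                    dimnames = list(NULL, paste0("P|", 1:8))))
  Xn[, 1] <- Xn[, 2] - 0.5 * Xn[, 3] + rnorm(300, sd = sigma)
  maskn <- sblfp:::with_seed(6, sample(300, 60))
  truthn <- Xn[maskn, 1]
  Xn[maskn, 1] <- NA
  ftn <- toy_feature_table(
    data.frame(mouse = "m01", task = "SP", session_id = "s",
               stimulus = rep(c("a", "b"), 150)), Xn)
  impn <- impute_features(ftn, seed = 7)
  rmse <- sqrt(mean((impn$x[maskn, 1] - truthn)^2))
  expect_gt(rmse, 0.5 * sigma)
  expect_lt(rmse, 1.8 * sigma)
  # a pair observed nowhere cannot be imputed
  Xbad <- Xn; Xbad[, 4] <- NA
  expect_error(impute_features(toy_feature_table(ftn$meta, Xbad), seed = 1),
               "no observed value")
})

test_that("leave-one-mouse-out forests separate constructed classes", {
  eff <- function(tk, p) {
    if (tk == "SP" && p %in% paste0("A|R", 1:2)) 2
    else if (tk == "EsP" && p %in% paste0("A|R", 3:4)) 2
    else if (tk == "SxP" && p %in% paste0("A|R", 5:6)) 2
    else 0
  }
  tab <- make_long_table(n_mice = 4, seed = 8, effect = eff)
  ft <- build_feature_table(tab)
  real <- crossval_confusion(ft, "context_3class", n_repeats = 4, seed = 9)
  expect_gt(min(diag(real$overall)), 90)
  # columns sum to 100 at every aggregation level
  expect_equal(colSums(real$overall), rep(100, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  for (m in names(real$per_mouse))
    expect_equal(colSums(real$per_mouse[[m]]), rep(100, 3), tolerance = 1e-9,
                 ignore_attr = TRUE)
  # determinism under a fixed master seed
  real2 <- crossval_confusion(ft, "context_3class", n_repeats = 4, seed = 9)
  expect_identical(real$per_mouse_counts, real2$per_mouse_counts)
  # shuffled labels: diagonal near chance
  ft_sh <- ft
  ft_sh$meta$task <- sblfp:::with_seed(10, sample(ft$meta$task))
  sh <- crossval_confusion(ft_sh, "context_3class", n_repeats = 4, seed = 11)
  expect_lt(max(abs(diag(sh$overall) - 100 / 3)), 20)
  # two-class labeling restricted to the SP task
  r2 <- crossval_confusion(ft, "stimulus_2class", n_repeats = 2, seed = 12)
  expect_equal(sort(r2$classes), sort(task_stimuli("SP")))
})

test_that("random-classifier null is calibrated at chance", {
  tab <- make_long_table(n_mice = 4, seed = 13)
  ft <- build_feature_table(tab)
  null <- random_null_confusion(ft, n_matrices = 83, inner_repeats = 100,
                                seed = 14)
  cells <- unlist(lapply(null$per_mouse, function(l)
    lapply(l, function(m) diag(m))))
  expect_equal(mean(cells), 100 / 3, tolerance = 0.3)
  # per-cell SD tracks the binomial formula 100 sqrt(p(1-p)/(inner n_j))
  n_j <- 6  # rows per class per mouse here
  sd_theory <- 100 * sqrt((1 / 3) * (2 / 3) / (100 * n_j))
  one_cell <- vapply(null$per_mouse[[1]], function(m) m[1, 1], numeric(1))
  expect_equal(sd(one_cell), sd_theory, tolerance = 0.5)
})

test_that("per-cell significance separates a shifted diagonal", {
  eff <- function(tk, p) if (tk == "SP" && p == "A|R1") 3 else
    if (tk == "EsP" && p == "A|R2") 3 else if (tk == "SxP" && p == "A|R3") 3 else 0
  tab <- make_long_table(n_mice = 5, seed = 15, effect = eff)
  ft <- build_feature_table(tab)
  real <- crossval_confusion(ft, n_repeats = 4, seed = 16)
  null <- random_null_confusion(ft, n_matrices = 20, inner_repeats = 20,
                                seed = 17)
  cells <- cell_significance(real, null)
  expect_true(all(diag(cells$rejected)))
  expect_true(all(cells$n_mice == 5))
  # locality: removing one mouse's SP rows only affects the SP column count
  keep <- !(ft$meta$mouse == "m01" & ft$meta$task == "SP")
  ft2 <- toy_feature_table(ft$meta[keep, ], ft$x[keep, , drop = FALSE])
  real2 <- crossval_confusion(ft2, n_repeats = 2, seed = 18)
  null2 <- random_null_confusion(ft2, n_matrices = 10, inner_repeats = 10,
                                 seed = 19)
  cells2 <- cell_significance(real2, null2)
  expect_equal(unname(cells2$n_mice), c(4, 5, 5))
})
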