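test_that("dataset writing and reading round-trips signals and metadata", {
  s <- toy_session()
  b <- toy_bouts(s, c(2, 11, 15), c(4, 13.5, 18),
                 c("empty", "social", "object"))
  ds <- lfp_dataset(list(s), list(b))
  root <- withr::local_tempdir()
  write_dataset(ds, root)
  ds2 <- read_dataset(root)
  expect_length(ds2$sessions, 1)
  s2 <- ds2$sessions[[1]]
  expect_identical(s2$signals, s$signals)
  expect_identical(s2$region_labels, s$region_labels)
  expect_equal(s2$sampling_rate, s$sampling_rate)
  expect_equal(s2$baseline_interval, s$baseline_interval)
  expect_equal(s2$encounter_interval, s$encounter_interval)
  expect_equal(ds2$bout_tables[[1]]$start_s, b$start_s)
  expect_equal(ds2$bout_tables[[1]]$stimulus, b$stimulus)
})

test_that("validation errors name the offending record and field", {
  s <- toy_session()
  expect_error(
    toy_bouts(s, 5, 4, "social"),
    "end_s", class = "sblfp_validation_error")
  expect_error(
    toy_bouts(s, c(1, 2), c(3, 4), c("social", "object")),
    "overlap", class = "sblfp_validation_error")
  # unknown region code lists the legal vocabulary
  err <- tryCatch(
    recording_session("m01", "SP", 1, 50, matrix(0, 1, 1000), "XYZ",
                      c(0, 10), c(10, 20),
                      setNames(task_stimuli("SP"), c("left", "right"))),
    error = conditionMessage)
  expect_match(err, "XYZ")
  for (code in c("AcbC", "vDG", "CeA")) expect_match(err, code)
  # task/stimulus mismatch
  expect_error(toy_bouts(s, 2, 5, "female"), "illegal stimulus",
               class = "sblfp_validation_error")
  # missing sampling rate detected on read
  root <- withr::local_tempdir()
  write_dataset(lfp_dataset(list(s), list(toy_bouts(s, 2, 5, "social"))), root)
  sidecar <- list.files(root, "session.json", recursive = TRUE,
                        full.names = TRUE)
  meta <- jsonlite::read_json(sidecar)
  meta$sampling_rate_hz <- NULL
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE)
  expect_error(read_dataset(root), "sampling rate",
               class = "sblfp_validation_error")
})

test_that("region filter applies the strict >5 sessions and >=3 subjects rules", {
  # region A: 6 sessions across 3 mice -> kept
  # region B: 10 sessions of 1 mouse -> dropped
  # region C: exactly 5 sessions across 3 mice -> dropped (strict)
  design <- rbind(
    data.frame(subject = c("m01", "m01", "m02", "m02", "m03", "m03"),
               task = "SP", idx = 1:6),
    data.frame(subject = "m04", task = "SP", idx = 1:10),
    data.frame(subject = c("m01", "m02", "m03", "m01", "m02"),
               task = "SP", idx = 11:15))
  design$regions <- c(replicate(6, c("AcbC", "vDG"), simplify = FALSE),
                      replicate(10, c("BLA", "vDG"), simplify = FALSE),
                      replicate(5, c("CeA", "vDG"), simplify = FALSE))
  ds <- toy_dataset(design)
  kept <- filter_regions(ds)
  expect_true("AcbC" %in% kept)
  expect_false("BLA" %in% kept)   # one subject only
  expect_false("CeA" %in% kept)   # exactly 5 sessions
  expect_true("vDG" %in% kept)
})

test_that("pair eligibility requires sessions, subjects and all three tasks", {
  # m01-m03 record {AcbC, BLA, vDG} in all tasks (2 sessions each), so those
  # regions survive the >=3-subject filter; m04 records {AcbC, PrL} in SP
  # only, so PrL is filtered and AcbC|PrL never becomes eligible.
  rows <- list()
  for (sj in c("m01", "m02", "m03")) for (tk in task_vocabulary()) for (k in 1:2)
    rows[[length(rows) + 1]] <- data.frame(subject = sj, task = tk, idx = k,
                                           stringsAsFactors = FALSE)
  d1 <- do.call(rbind, rows)
  d1$regions <- replicate(nrow(d1), c("AcbC", "BLA", "vDG"), simplify = FALSE)
  d2 <- data.frame(subject = "m04", task = "SP", idx = 1:7)
  d2$regions <- replicate(7, c("AcbC", "PrL"), simplify = FALSE)
  ds <- toy_dataset(rbind(d1, d2))
  pairs <- eligible_pairs(ds)
  # brute-force oracle over the design
  expect_setequal(pairs, c("AcbC|BLA", "AcbC|vDG", "BLA|vDG"))
  expect_false("AcbC|PrL" %in% pairs)  # SP-only co-recording
  # subset property: all pair members pass the region filter
  expect_true(all(unique(as.vector(sblfp:::pair_split(pairs))) %in%
                    filter_regions(ds)))
})

test_that("bout duration filter is strict and idempotent", {
  s <- toy_session(dur_s = 40, fs = 50)
  b <- toy_bouts(s, c(1, 5, 9, 13), c(2.9, 7.0, 11.1, 18.0),
                 rep("social", 4))
  v <- valid_bouts(b, 2)
  expect_equal(v$duration_s, c(2.1, 5.0))
  expect_equal(valid_bouts(v, 2), v)
  expect_equal(nrow(valid_bouts(b[0, ], 2)), 0)
  # randomized filter count equals a direct oracle
  durs <- sblfp:::with_seed(7, rlnorm(100, log(2), 0.5))
  starts <- cumsum(c(1, durs[-100] + 1))
  b2 <- bout_table(data.frame(session_id = "x", stimulus = "social",
                              chamber = "left", start_s = starts,
                              end_s = starts + durs))
  expect_equal(nrow(valid_bouts(b2, 2)), sum(durs > 2))
})

test_that("behavioral events follow the transition/repeat rules", {
  s <- toy_session(dur_s = 40)
  b <- toy_bouts(s, c(1, 5, 9), c(3, 7, 11), c("social", "social", "object"))
  ev <- extract_events(b)
  expect_equal(sum(ev$kind == "bout_start"), 3)
  expect_equal(sum(ev$kind == "bout_end"), 3)
  expect_equal(ev$kind[ev$time_s == 5 & ev$kind != "bout_start"],
               "repeat_start")
  expect_equal(ev$kind[ev$time_s == 9 & ev$kind != "bout_start"],
               "transition_start")
  # single bout: start and end only
  expect_equal(nrow(extract_events(b[1, ])), 2)
  # n bouts emit 2n + (n-1) events; transition count matches a direct scan
  stim <- sblfp:::with_seed(3, sample(c("social", "object"), 50, TRUE))
  starts <- seq(1, by = 4, length.out = 50)
  b3 <- bout_table(data.frame(session_id = "x", stimulus = stim,
                              chamber = "left", start_s = starts,
                              end_s = starts + 2))
  ev3 <- extract_events(b3)
  expect_equal(nrow(ev3), 2 * 50 + 49)
  expect_equal(sum(ev3$kind == "transition_start"),
               sum(stim[-1] != stim[-50]))
})

test_that("preference index follows the RDI formula and is antisymmetric", {
  s <- toy_session(dur_s = 200)
  b <- toy_bouts(s, c(10, 80), c(70, 120), c("social", "object"))
  expect_equal(preference_index(b, "social")$rdi, 0.2)
  expect_equal(preference_index(b, "object")$rdi, -0.2)
  b2 <- toy_bouts(s, c(10, 30, 50), c(20, 40, 70),
                  c("social", "object", "social"))
  pi2 <- preference_index(b2, "social")
  expect_equal(pi2$rdi, 0.5)
  expect_equal(pi2$n_transitions, 2L)
  expect_warning(pi0 <- preference_index(b2[0, ], "social"), "undefined")
  expect_true(is.na(pi0$rdi))
})

test_that("exclusion mask removes +/-30 s around insertion and removal", {
  fs <- 100
  s <- recording_session("m01", "SP", 1, fs, matrix(0, 1, fs * 700), "AcbC",
                         c(0, 300), c(300, 600),
                         setNames(task_stimuli("SP"), c("left", "right")),
                         insertion_time = 300, removal_time = 600)
  m <- exclusion_mask(s)
  t <- (seq_along(m) - 1) / fs
  expect_false(any(m[t >= 270 & t < 330]))
  expect_false(any(m[t >= 570 & t < 630]))
  expect_true(all(m[t < 269.9]))
  expect_true(all(m[t > 330.1 & t < 569.9]))
  # no events -> all-true mask
  s2 <- recording_session("m01", "SP", 1, fs, matrix(0, 1, fs * 700), "AcbC",
                          c(0, 300), c(300, 600),
                          setNames(task_stimuli("SP"), c("left", "right")),
                          insertion_time = NA_real_, removal_time = NA_real_)
  expect_true(all(exclusion_mask(s2)))
  # overlapping windows: masked duration equals the interval union
  s3 <- recording_session("m01", "SP", 1, fs, matrix(0, 1, fs * 700), "AcbC",
                          c(0, 300), c(300, 600),
                          setNames(task_stimuli("SP"), c("left", "right")),
                          insertion_time = 300, removal_time = 330)
  masked_s <- sum(!exclusion_mask(s3)) / fs
  # union of [270,330] and [300,360] = [270,360]: 90 s
  expect_equal(masked_s, 90, tolerance = 0.01)
})
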