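test_that("the reference BST stores sorted keys and looks up exactly", {
  one <- bst_build(42L, "fetal_left_static")
  expect_equal(bst_lookup(one, 42L), "fetal_left_static")
  expect_true(is.na(bst_lookup(one, 41L)))
  set.seed(3)
  keys <- sample(0:63, 12)
  labels <- posture_labels()
  bst <- bst_build(keys, labels)
  expect_equal(bst_keys(bst), sort(keys))        # in-order = sorted
  for (i in seq_along(keys)) {
    expect_equal(bst_lookup(bst, keys[i]), labels[i])
  }
  expect_true(is.na(bst_lookup(bst, setdiff(0:63, keys)[1])))
  expect_error(bst_build(c(1L, 1L), c("a", "b")), "duplicate")
  # lookups stay logarithmic: a 12-key tree is at most 4 deep
  depth <- function(b, node) {
    if (is.na(node)) return(0L)
    1L + max(depth(b, b$nodes$left[node]), depth(b, b$nodes$right[node]))
  }
  expect_lte(depth(bst, bst$root), 4L)
})

test_that("posture matching prefers BST hits and falls back to the forest", {
  d <- tibble::tibble(f1 = c(0, 0, 1, 1), label = c("A", "A", "B", "B"))
  forest <- train_forest(d, trees = 3, mtry = 1, seed = 1)
  bst <- bst_build(3L, "bst_label")
  pattern <- c(0L, 0L, 0L, 0L, 1L, 1L)          # key 3
  expect_equal(match_posture(bst, pattern, forest, c(f1 = 0)), "bst_label")
  miss <- c(1L, 0L, 0L, 0L, 0L, 0L)             # key 32, absent
  expect_equal(match_posture(bst, miss, forest, c(f1 = 0)), "A")
  empty <- bst_build(integer(), character())
  expect_equal(match_posture(empty, pattern, forest, c(f1 = 1)), "B")
  expect_true(is.na(match_posture(empty, pattern, NULL, NULL)))
})

test_that("fusion measurement is the absolute difference of window means", {
  b <- empty_bed_profile_fixture()
  w1 <- constant_stream(b, seconds = 1)
  expect_equal(unname(fusion_measurement(w1, w1)), c(0, 0))
  w2 <- constant_stream(b - c(0, 0, 0, 0, 1500, 0), seconds = 1)
  fm <- fusion_measurement(w1, w2)
  expect_equal(unname(fm["LLL"]), 1500)
  expect_equal(unname(fm["LLR"]), 0)
  expect_error(fusion_measurement(w1[0, ], w2), "non-empty")
  # pure noise stays far below the default threshold
  set.seed(12)
  below <- replicate(200, {
    n1 <- make_frames(matrix(rnorm(24, 19000, 30), ncol = 6))
    n2 <- make_frames(matrix(rnorm(24, 19000, 30), ncol = 6))
    max(fusion_measurement(n1, n2))
  })
  expect_true(all(below < 1000))
})

test_that("limb flags reproduce logic-level left/right motion per second", {
  # static session: no flags
  static <- simulate_session(zero_noise_config(duration_s = 20))
  expect_true(all(limb_flags(static$frames)$flag_LLL == 0))
  # left-then-right scenario: at T1 LLL=1 & LLR=0, later LLR=1 & LLL=0
  cfg <- zero_noise_config(
    duration_s = 40,
    episodes = tibble::tibble(limb = c("left", "right"),
                              onset_s = c(5, 25), movement_count = 1,
                              movement_duration_s = 1,
                              inter_movement_interval_s = 2,
                              magnitude_mm = 150))
  fl <- limb_flags(simulate_session(cfg)$frames)
  expect_equal(fl$flag_LLL[fl$t_s == 5], 1L)
  expect_equal(fl$flag_LLR[fl$t_s == 5], 0L)
  expect_equal(fl$flag_LLL[fl$t_s == 25], 0L)
  expect_equal(fl$flag_LLR[fl$t_s == 25], 1L)
  # zero-noise episode flags equal simulator ground truth exactly
  sess <- simulate_session(zero_noise_config(
    duration_s = 60,
    episodes = tibble::tibble(limb = "left", onset_s = 10,
                              movement_count = 3, movement_duration_s = 2,
                              inter_movement_interval_s = 12,
                              magnitude_mm = 200)))
  fl2 <- limb_flags(sess$frames)
  expect_equal(fl2$flag_LLL, sess$truth$flags$flag_LLL)
  expect_equal(fl2$flag_LLR, sess$truth$flags$flag_LLR)
})

test_that("raising the movement threshold never adds flagged seconds", {
  sess <- simulate_session(sim_config(
    duration_s = 60, noise_sd_mm = 10, seed = 17,
    episodes = tibble::tibble(limb = "both", onset_s = 10,
                              movement_count = 3, movement_duration_s = 1,
                              inter_movement_interval_s = 10,
                              magnitude_mm = 150)))
  thresholds <- c(100, 500, 1000, 1400, 2000)
  totals <- vapply(thresholds, function(thr) {
    fl <- limb_flags(sess$frames,
                     detector_config(movement_threshold_tmm = thr))
    sum(fl$flag_LLL) + sum(fl$flag_LLR)
  }, numeric(1))
  expect_true(all(diff(totals) <= 0))
})

test_that("event extraction partitions flags into both/left/right runs with TLM", {
  empty <- extract_events(tibble::tibble(t_s = 0:9, flag_LLL = 0L,
                                         flag_LLR = 0L))
  expect_equal(nrow(empty$events), 0)
  expect_equal(empty$tlm, 0)
  # left runs of lengths 2, 1, 3 -> three events, TLM 6
  l <- c(0, 1, 1, 0, 1, 0, 0, 1, 1, 1, 0)
  flags <- tibble::tibble(t_s = seq_along(l) - 1L, flag_LLL = as.integer(l),
                          flag_LLR = 0L)
  ex <- extract_events(flags)
  expect_equal(ex$events$limb, rep("left", 3))
  expect_equal(ex$events$duration_units, c(2L, 1L, 3L))
  expect_equal(ex$events$start_s, c(1L, 4L, 7L))
  expect_equal(ex$tlm, 6)
  # partial overlap splits into both + residual single-limb events
  flags2 <- tibble::tibble(t_s = 0:5,
                           flag_LLL = c(0L, 1L, 1L, 1L, 0L, 0L),
                           flag_LLR = c(0L, 0L, 1L, 1L, 1L, 0L))
  ex2 <- extract_events(flags2)
  expect_equal(ex2$events$limb, c("left", "both", "right"))
  expect_equal(ex2$events$duration_units, c(1L, 2L, 1L))
  expect_equal(ex2$tlm, 4)   # both-limb seconds count one unit
})

test_that("TLM matches a brute-force flag counter on random series", {
  set.seed(23)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    l <- sample(0:1, n, replace = TRUE, prob = c(0.7, 0.3))
    r <- sample(0:1, n, replace = TRUE, prob = c(0.7, 0.3))
    flags <- tibble::tibble(t_s = seq_len(n) - 1L, flag_LLL = l,
                            flag_LLR = r)
    expect_equal(extract_events(flags)$tlm, brute_tlm(l, r))
  }
})

test_that("the duration FIFO is circular with oldest-first overwrite", {
  d <- duration_fifo(8)
  expect_equal(dfifo_values(d), numeric(0))
  d <- dfifo_push(d, 1:5)
  expect_equal(dfifo_values(d), 1:5)
  d <- dfifo_push(d, 6:12)
  expect_length(dfifo_values(d), 8)
  expect_equal(dfifo_values(d), 5:12)   # exactly the last `capacity`
  set.seed(5)
  for (cap in c(1, 3, 8)) {
    f <- duration_fifo(cap)
    vals <- sample(1:100, 30, replace = TRUE)
    for (v in vals) {
      f <- dfifo_push(f, v)
      expect_lte(length(dfifo_values(f)), cap)
    }
    expect_equal(dfifo_values(f), tail(vals, cap))
  }
})

test_that("decision fusion applies exclusions and confirms series", {
  cfg <- detector_config()
  # no events
  no_events <- tibble::tibble(limb = character(), start_s = numeric(),
                              duration_units = integer())
  none <- decision_fusion(no_events, cfg, session_s = 120)
  expect_equal(none$status, "none")
  expect_equal(none$stage, "not-applicable")
  expect_equal(none$tlm, 0)
  # single 1-unit both event at a posture transition: pose change, not PLMD
  ev <- tibble::tibble(limb = "both", start_s = 60, duration_units = 1L)
  pc <- decision_fusion(ev, cfg, session_s = 120, transitions = 60)
  expect_equal(pc$status, "none")
  expect_equal(pc$exclusions$reason, "pose_change")
  # the same event away from a transition is kept (but unconfirmed alone)
  kept <- decision_fusion(ev, cfg, session_s = 120, transitions = 30)
  expect_equal(nrow(kept$exclusions), 0)
  expect_equal(kept$status, "none")   # below min_series
  # one unbroken 120-unit run: constant movement, non-PLMD
  long_run <- tibble::tibble(limb = "left", start_s = 20,
                             duration_units = 120L)
  cm <- decision_fusion(long_run, cfg, session_s = 180)
  expect_equal(cm$status, "none")
  expect_equal(cm$exclusions$reason, "constant_movement")
  # eight 1-unit left events 10 s apart: confirmed left series, 8 units
  series <- tibble::tibble(limb = "left", start_s = 20 + 10 * (0:7),
                           duration_units = 1L)
  conf <- decision_fusion(series, cfg, session_s = 180)
  expect_equal(conf$status, "left")
  expect_equal(conf$tlm, 8)
  expect_equal(nrow(conf$episodes), 8)
  expect_equal(dfifo_values(conf$durations), rep(1, 8))
  # gaps beyond max_interval_s break the chain below min_series
  sparse <- tibble::tibble(limb = "left", start_s = c(0, 100, 200, 300),
                           duration_units = 1L)
  expect_equal(decision_fusion(sparse, cfg, session_s = 400)$status, "none")
})

test_that("stage assignment follows the events-per-hour bounds", {
  cfg <- detector_config()
  mk <- function(n, session_s) {
    ev <- tibble::tibble(limb = "left",
                         start_s = seq(0, by = 60, length.out = n),
                         duration_units = 1L)
    decision_fusion(ev, cfg, session_s = session_s)
  }
  expect_equal(mk(10, 3600)$stage, "early")    # 10 events/h < 25
  expect_equal(mk(30, 3600)$stage, "middle")   # 25 <= 30 < 50
  expect_equal(mk(55, 3600)$stage, "high")     # >= 50
})

test_that("zero-noise scenarios are recovered exactly against ground truth", {
  set.seed(31)
  for (i in 1:30) {
    cfg <- random_scenario()
    sess <- simulate_session(cfg)
    res <- analyze_stream(sess$frames, baseline = NULL)
    expected <- episodes_to_events(cfg$episodes)
    detected <- dplyr::arrange(res$all_events, start_s, limb)
    expect_equal(detected$limb, expected$limb)
    expect_equal(as.numeric(detected$start_s), as.numeric(expected$start_s))
    expect_equal(as.numeric(detected$duration_units),
                 as.numeric(expected$duration_units))
    # TLM of all extracted events equals the flagged-second count
    expect_equal(res$tlm_observed,
                 brute_tlm(sess$truth$flags$flag_LLL,
                           sess$truth$flags$flag_LLR))
  }
})

test_that("exp presets drive the full detector to the documented statuses", {
  lib <- scenario_library(seed = 2)
  run <- function(cfg, labels = NULL) {
    sess <- simulate_session(cfg)
    truth_labels <- plmwatch:::label_at_second(
      cfg$posture_schedule,
      (seq_len(cfg$duration_s)) - 1L)
    analyze_stream(sess$frames, posture_labels = truth_labels)
  }
  r1 <- run(lib$exp1)
  expect_equal(r1$status, "both")
  expect_equal(nrow(r1$episodes), 15)           # 6 both + 5 right + 4 left
  r2 <- run(lib$exp2)
  expect_equal(r2$status, "left")
  expect_equal(r2$tlm, 8)
  r3 <- run(lib$exp3)
  expect_equal(r3$status, "both")
  # constant movement and pose change are never PLMD, with or without noise
  for (seed in 1:5) {
    noisy <- scenario_library(seed = seed, noise_sd_mm = 3)
    expect_equal(run(noisy$exp4)$status, "none")
    expect_equal(run(noisy$pose_change)$status, "none")
  }
  rp <- run(lib$pose_change)
  expect_equal(rp$exclusions$reason, "pose_change")
  expect_equal(nrow(rp$episodes), 0)
})

test_that("stream analysis closes posture segments and reports event types", {
  # quiet static session: empty result
  quiet <- simulate_session(zero_noise_config(duration_s = 30))
  rq <- analyze_stream(quiet$frames)
  expect_equal(rq$status, "none")
  expect_equal(sum(rq$report$count_units[rq$report$event_type != "static"]), 0)
  expect_equal(rq$report$count_units[rq$report$event_type == "static"], 30)
  # exp1: event-type units equal simulator ground truth
  lib <- scenario_library(seed = 3)
  sess <- simulate_session(lib$exp1)
  res <- analyze_stream(sess$frames)
  rep_tbl <- res$report
  units <- function(type) rep_tbl$count_units[rep_tbl$event_type == type]
  expect_equal(units("both"), 6)
  expect_equal(units("left"), 4)
  expect_equal(units("right"), 5)
  expect_error(analyze_stream(quiet$frames[1:4, ]), "two analysis windows")
})
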