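test_that("identity and one-sided matchings produce the expected counts", {
  ev <- nest_events(1L, "entry", 100L)
  cc <- match_events(ev, nest_events(1L, "entry", 100L, "truth"))
  expect_equal(cc$tp, 1L)
  expect_equal(cc$fp, 0L)
  expect_equal(cc$fn, 0L)

  cc2 <- match_events(ev, nest_events(source = "truth"))
  expect_equal(cc2$fp, 1L)
  cc3 <- match_events(nest_events(), nest_events(2L, "exit", 5L, "truth"))
  expect_equal(cc3$fn, 1L)
  expect_error(match_events(ev, ev, tolerance_frames = -1), "tolerance")
})

test_that("matching respects kind, lineage and frame tolerance", {
  pred <- nest_events(c(1L, 2L), c("entry", "exit"), c(100L, 100L))
  truth <- nest_events(c(1L, 2L), c("exit", "exit"), c(100L, 500L), "truth")
  cc <- match_events(pred, truth, tolerance_frames = 240)
  # pred 1 has the wrong kind; pred 2 is 400 frames away
  expect_equal(cc$tp, 0L)
  expect_equal(cc$fp, 2L)
  expect_equal(cc$fn, 2L)
  # a lineage map reunites a switched ID with its parent's truth
  pred2 <- nest_events(7L, "entry", 100L)
  truth2 <- nest_events(1L, "entry", 120L, "truth")
  lin <- tibble::tibble(track_id = 7L, lineage_id = 1L)
  expect_equal(match_events(pred2, truth2, lineage = lin)$tp, 1L)
  expect_equal(match_events(pred2, truth2)$tp, 0L)
})

test_that("turn-back episodes count as negatives only when nothing fires", {
  vf <- virtual_frame()
  b_track <- state_track(c(FALSE, TRUE, TRUE, FALSE), frames = c(1, 2, 40, 41))
  units <- track_episodes(b_track, vf, 240)
  truth <- nest_events(source = "truth")
  # naive counter: two spurious events on the episode, so no negatives
  cc_y <- match_events(count_yolo_only(b_track, vf), truth, units = units)
  expect_equal(cc_y$fp, 2L)
  expect_equal(cc_y$tn, 0L)
  # parity counter: silent on the episode, which becomes a true negative
  cc_p <- match_events(count_parity(b_track, vf, 240), truth, units = units)
  expect_equal(cc_p$fp, 0L)
  expect_equal(cc_p$tn, 1L)
})

test_that("metric formulas match direct arithmetic", {
  cc <- confusion_counts(tp = 1, fp = 0, fn = 0, tn = 1)
  expect_equal(accuracy(cc), 1)
  expect_equal(precision(cc), 1)
  expect_equal(recall(cc), 1)
  expect_equal(f1_score(cc), 1)

  cc2 <- confusion_counts(tp = 0, fp = 1, fn = 0, tn = 0)
  expect_equal(accuracy(cc2), 0)
  expect_equal(precision(cc2), 0)
  expect_true(is.na(recall(cc2)))     # undefined, never silently 0

  cc3 <- confusion_counts(tp = 2, fp = 1, fn = 1, tn = 2)
  expect_equal(accuracy(cc3), 4 / 6)
  expect_equal(precision(cc3), 2 / 3)
  expect_equal(recall(cc3), 2 / 3)
  expect_equal(f1_score(cc3), 4 / 6)

  cc0 <- confusion_counts()
  expect_true(all(is.na(c(accuracy(cc0), precision(cc0), recall(cc0),
                          f1_score(cc0)))))
  expect_error(confusion_counts(tp = -1), "nonnegative")
})

test_that("metrics are bounded and F1 sits between precision and recall", {
  withr::local_seed(31)
  for (rep in 1:200) {
    cc <- confusion_counts(sample(0:20, 1), sample(0:20, 1),
                           sample(0:20, 1), sample(0:20, 1))
    m <- c(accuracy(cc), precision(cc), recall(cc), f1_score(cc))
    expect_true(all(is.na(m) | (m >= 0 & m <= 1)))
    p <- precision(cc); r <- recall(cc); f <- f1_score(cc)
    if (!is.na(p) && !is.na(r) && !is.na(f)) {
      expect_lte(f, max(p, r) + 1e-12)
      expect_gte(f, min(p, r) - 1e-12)
      if (p > 0 && r > 0) expect_equal(f, 2 * p * r / (p + r))
    }
  }
})

test_that("matching conserves event totals on random instances", {
  withr::local_seed(41)
  for (rep in 1:50) {
    np <- sample(0:8, 1); nt <- sample(0:8, 1)
    pred <- nest_events(sample(1:3, np, TRUE),
                        sample(c("entry", "exit"), np, TRUE),
                        sample(0:1000, np))
    truth <- nest_events(sample(1:3, nt, TRUE),
                         sample(c("entry", "exit"), nt, TRUE),
                         sample(0:1000, nt), "truth")
    cc <- match_events(pred, truth, tolerance_frames = 150)
    expect_equal(cc$tp + cc$fp, np)
    expect_equal(cc$tp + cc$fn, nt)
  }
})

test_that("greedy matching attains the optimal matching size", {
  # random instances with up to 6 events per side, checked against an
  # exhaustive maximum-cardinality matcher
  withr::local_seed(51)
  for (rep in 1:150) {
    np <- sample(0:6, 1); nt <- sample(0:6, 1)
    pred <- nest_events(sample(1:2, np, TRUE),
                        sample(c("entry", "exit"), np, TRUE),
                        sample(0:500, np))
    truth <- nest_events(sample(1:2, nt, TRUE),
                         sample(c("entry", "exit"), nt, TRUE),
                         sample(0:500, nt), "truth")
    tol <- sample(c(50, 150, 300), 1)
    cc <- match_events(pred, truth, tolerance_frames = tol)
    compat <- outer(seq_len(np), seq_len(nt), Vectorize(function(i, j) {
      pred$track_id[i] == truth$track_id[j] &&
        pred$kind[i] == truth$kind[j] &&
        abs(pred$frame_index[i] - truth$frame_index[j]) <= tol
    }))
    if (np == 0 || nt == 0) compat <- matrix(FALSE, np, nt)
    expect_equal(cc$tp, oracle_max_matching(compat))
  }
})

test_that("metric_table lays out one row per method in percent", {
  tab <- metric_table(list(
    parity = confusion_counts(9, 1, 1, 9),
    yolo_only = confusion_counts(9, 11, 0, 0)
  ))
  expect_equal(tab$method, c("parity", "yolo_only"))
  expect_equal(tab$accuracy, c(90, 45))
  expect_equal(tab$recall[2], 100)
  fmt <- format_metric_table(tab)
  expect_equal(fmt[["recall (%)"]], c("90.0", "100.0"))
})
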