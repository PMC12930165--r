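test_that("sim_config validates weights and probabilities", {
  expect_error(sim_config(pattern_weights = c(A = 0.5, B = 0.4)), "sum to 1")
  expect_error(sim_config(pattern_weights = c(A = 0.5, Z = 0.5)), "named")
  expect_error(sim_config(pattern_weights = c(A = 1.2, B = -0.2)),
               "nonnegative")
  expect_error(sim_config(dropout_prob = 1), "dropout_prob")
  expect_error(sim_config(multi_turn_k = 2), "odd")
  cfg <- sim_config(pattern_weights = c(A = 1))
  expect_equal(unname(cfg$pattern_weights["B"]), 0)
})

test_that("every pattern produces a track consistent with its label", {
  cfg <- sim_config(jitter_sd = 0)
  vf <- cfg$vf
  expected <- list(A = "entry", B = NULL, C = "exit", D = NULL,
                   pass_over = NULL, multi_turn = "entry")
  withr::with_seed(33, {
    for (rep in 1:10) {
      for (pat in names(expected)) {
        lt <- sample_track(pat, cfg, track_id = 1L, start_frame = 100L)
        expect_s3_class(lt$track, "tbl_df")
        expect_gt(nrow(lt$track), 1)
        want <- expected[[pat]]
        if (is.null(want)) {
          expect_equal(nrow(lt$true_events), 0L, label = pat)
        } else {
          expect_equal(lt$true_events$kind, want, label = pat)
          expect_equal(lt$true_events$source, "truth")
        }
        # noise-free tracks are classified exactly by the parity counter
        pred <- count_parity(lt$track, vf, vf$fps)
        expect_equal(pred$kind, lt$true_events$kind, label = pat)
        expect_equal(pred$frame_index, lt$true_events$frame_index,
                     label = pat)
      }
    }
  })
  expect_error(withr::with_seed(1, sample_track("Z", cfg)), "unknown pattern")
})

test_that("pattern geometry matches the crossing structure", {
  cfg <- sim_config(jitter_sd = 0)
  vf <- cfg$vf
  withr::with_seed(5, {
    a <- sample_track("A", cfg)
    cr <- detect_crossings(a$track, vf)
    expect_equal(cr$direction, "inward")           # ends in the nest
    b <- sample_track("B", cfg)
    expect_equal(detect_crossings(b$track, vf)$direction,
                 c("inward", "outward"))
    d <- sample_track("D", cfg)
    expect_equal(detect_crossings(d$track, vf)$direction,
                 c("outward", "inward"))
    p <- sample_track("pass_over", cfg)
    crp <- detect_crossings(p$track, vf)
    expect_equal(crp$direction, c("inward", "outward"))
    # a pass-over transits in well under the one-second threshold
    expect_lt(diff(crp$frame_index), vf$fps)
    m <- sample_track("multi_turn", cfg)
    expect_equal(nrow(detect_crossings(m$track, vf)), cfg$multi_turn_k)
  })
})

test_that("generate_dataset is reproducible from its seed", {
  cfg <- sim_config(n_tracks = 30, id_switch_prob = 0.2, id_merge_prob = 0.2,
                    seed = 77)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$tracks, d2$tracks)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$lineage, d2$lineage)
  d3 <- generate_dataset(sim_config(n_tracks = 30, id_switch_prob = 0.2,
                                    id_merge_prob = 0.2, seed = 78))
  expect_false(identical(d1$tracks, d3$tracks))
})

test_that("pure pattern mixes yield the constructed truth", {
  ds <- generate_dataset(sim_config(n_tracks = 10,
                                    pattern_weights = c(A = 1), seed = 3))
  expect_equal(nrow(ds$truth), 10L)
  expect_true(all(ds$truth$kind == "entry"))
  expect_equal(sort(unique(ds$tracks$track_id)), 1:10)
})

test_that("entry fraction of an A/C mixture is binomially consistent", {
  ds <- generate_dataset(sim_config(
    n_tracks = 1000, pattern_weights = c(A = 0.5, C = 0.5), seed = 19
  ))
  expect_equal(nrow(ds$truth), 1000L)
  frac <- mean(ds$truth$kind == "entry")
  ci99 <- 2.576 * sqrt(0.25 / 1000)
  expect_lt(abs(frac - 0.5), ci99)
})

test_that("ID switch splits a track and re-attributes its truth", {
  cfg <- sim_config(jitter_sd = 0)
  withr::with_seed(8, {
    lt <- sample_track("A", cfg, track_id = 4L, start_frame = 50L)
    halves <- corrupt_id_switch(lt, new_id = 99L)
    expect_length(halves, 2L)
    expect_equal(nrow(halves[[1]]$track) + nrow(halves[[2]]$track),
                 nrow(lt$track))
    expect_equal(unique(halves[[2]]$track$track_id), 99L)
    ev <- dplyr::bind_rows(halves[[1]]$true_events, halves[[2]]$true_events)
    expect_equal(nrow(ev), 1L)  # the entry survives, on one of the halves
    # determinism of the split point
    h2 <- withr::with_seed(123, corrupt_id_switch(lt, 99L))
    h3 <- withr::with_seed(123, corrupt_id_switch(lt, 99L))
    expect_identical(h2[[1]]$track, h3[[1]]$track)
  })
  short <- structure(
    list(track = state_track(c(FALSE, TRUE, TRUE)),
         true_events = nest_events(source = "truth"), pattern = "A"),
    class = "labelled_track"
  )
  out <- corrupt_id_switch(short, 99L)
  expect_length(out, 1L)
  expect_true(isTRUE(attr(out[[1]], "switch_skipped")))
})

test_that("a switch inside a turn-back creates spurious parity events", {
  # dip track whose only interior cut points sit around the two crossings
  vf <- virtual_frame()
  lt <- structure(
    list(track = state_track(c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE),
                             frames = 1:6),
         true_events = nest_events(source = "truth"), pattern = "B"),
    class = "labelled_track"
  )
  expect_equal(nrow(count_parity(lt$track, vf, 240)), 0L)
  withr::with_seed(2, {
    halves <- corrupt_id_switch(lt, 50L)
    det <- dplyr::bind_rows(halves[[1]]$track, halves[[2]]$track)
    expect_gte(nrow(count_parity(det, vf, 240)), 1L)  # false positives appear
  })
})

test_that("ID merge concatenates two bees under one ID", {
  cfg <- sim_config(jitter_sd = 0)
  withr::with_seed(14, {
    a <- sample_track("A", cfg, track_id = 1L, start_frame = 0L)
    c_ <- sample_track("C", cfg, track_id = 2L, start_frame = 0L)
    m <- corrupt_id_merge(a, c_, gap_frames = 100L)
    expect_equal(nrow(m$track), nrow(a$track) + nrow(c_$track))
    expect_equal(unique(m$track$track_id), 1L)
    expect_equal(nrow(m$true_events), 2L)
    expect_equal(sort(m$true_events$kind), c("entry", "exit"))
    expect_true(all(m$true_events$track_id == 1L))
    # frames strictly increasing across the junction
    expect_true(all(diff(m$track$frame) > 0))
    expect_error(corrupt_id_merge(a, c_, gap_frames = 0), "gap_frames")
  })
})

test_that("extreme dropout warns about vanished tracks but does not crash", {
  cfg <- sim_config(n_tracks = 30, pattern_weights = c(A = 1),
                    dropout_prob = 0.99, seed = 6)
  expect_warning(ds <- generate_dataset(cfg), "dropout")
  expect_s3_class(ds$tracks, "tbl_df")
})

test_that("clean datasets are recovered exactly by the parity counter", {
  # no noise, no corruption, dwells below the threshold: predictions equal
  # ground truth event for event
  cfg <- sim_config(n_tracks = 60, jitter_sd = 0, seed = 10)
  ds <- generate_dataset(cfg)
  pred <- count_parity(ds$tracks, cfg$vf, cfg$vf$fps)
  expect_equal(
    as.data.frame(pred[c("track_id", "kind", "frame_index")]),
    as.data.frame(ds$truth[c("track_id", "kind", "frame_index")])
  )
})
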