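#' Configure the trajectory simulator
#'
#' Builds the configuration for [generate_dataset()]: top-view bumblebee
#' trajectories around a nest-box entrance, rendered as per-frame bounding
#' boxes at the camera's frame rate, with ground-truth nest events. The
#' supported behaviour patterns are:
#'
#' * `A` — approach from the greenhouse, descend into the entrance (track
#'   ends inside the virtual frame): one true entry.
#' * `B` — dip into the frame and turn back out: no event.
#' * `C` — emerge from the entrance (track starts inside) and fly off: one
#'   true exit.
#' * `D` — poke out of the frame and return inside: no event.
#' * `pass_over` — fly straight across the frame without landing: no event.
#' * `multi_turn` — enter with `multi_turn_k` (odd) boundary transitions,
#'   hesitating at the edge, finally descending into the entrance: one true
#'   entry.
#'
#' Tracker failure modes are modelled by per-track corruption probabilities:
#' an ID switch splits one bee's trajectory across two IDs (the false-positive
#' mode of the parity counter), an ID merge stitches two bees onto one ID
#' with a short gap (the false-negative mode).
#'
#' @param n_tracks Number of tracks to draw.
#' @param pattern_weights Named nonnegative weights over the patterns above,
#'   summing to 1 (within 1e-9). Patterns omitted from the vector get
#'   weight 0.
#' @param vf The [virtual_frame()] geometry (also fixes fps).
#' @param speed_meanlog,speed_sdlog Log-normal flight-speed distribution in
#'   px/frame (median `exp(speed_meanlog)`, default ~3 px/frame); one speed
#'   is drawn per track.
#' @param speed_min Lower clip on speed, px/frame.
#' @param jitter_sd Gaussian noise sd on detected centres, pixels.
#' @param dropout_prob Per-detection omission probability in \[0, 1).
#' @param id_switch_prob,id_merge_prob Per-track corruption probabilities in
#'   \[0, 1).
#' @param dwell_range_frames Uniform range of frames a turn-back bee hovers
#'   at its turning point (patterns B, D).
#' @param long_dwell_prob Probability that a turn-back dwell is drawn from
#'   `long_dwell_range_frames` instead — dwells exceeding the one-second gap
#'   threshold exercise the counter's false-positive mode.
#' @param long_dwell_range_frames Uniform range of long dwells, frames.
#' @param merge_gap_range_frames Uniform range of the frame gap inserted
#'   between the two halves of an ID merge.
#' @param multi_turn_k Odd number of boundary transitions for `multi_turn`.
#' @param box_size Nominal bounding-box side, pixels (+/-10% jitter).
#' @param start_frame_max Track start frames are drawn uniformly from
#'   `[0, start_frame_max]` (default: a 10-minute clip at 240 fps).
#' @param seed Integer RNG seed; the whole dataset is reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_tracks = 200,
                       pattern_weights = c(A = 0.3, B = 0.2, C = 0.3,
                                           D = 0.1, pass_over = 0.1),
                       vf = virtual_frame(),
                       speed_meanlog = log(3), speed_sdlog = 0.4,
                       speed_min = 1.5,
                       jitter_sd = 1.0,
                       dropout_prob = 0,
                       id_switch_prob = 0, id_merge_prob = 0,
                       dwell_range_frames = c(12, 96),
                       long_dwell_prob = 0,
                       long_dwell_range_frames = c(288, 480),
                       merge_gap_range_frames = c(60, 180),
                       multi_turn_k = 3,
                       box_size = 20,
                       start_frame_max = 144000,
                       seed = 1) {
  patterns <- c("A", "B", "C", "D", "pass_over", "multi_turn")
  # YAML configs hand the weights over as a named list
  if (is.list(pattern_weights)) pattern_weights <- unlist(pattern_weights)
  if (is.null(names(pattern_weights)) ||
      !all(names(pattern_weights) %in% patterns)) {
    stop("pattern_weights must be named with patterns among: ",
         paste(patterns, collapse = ", "), call. = FALSE)
  }
  if (any(pattern_weights < 0)) {
    stop("pattern weights must be nonnegative", call. = FALSE)
  }
  if (abs(sum(pattern_weights) - 1) > 1e-9) {
    stop("pattern weights must sum to 1 (got ", sum(pattern_weights), ")",
         call. = FALSE)
  }
  w <- stats::setNames(rep(0, length(patterns)), patterns)
  w[names(pattern_weights)] <- pattern_weights
  for (p in c("dropout_prob", "id_switch_prob", "id_merge_prob",
              "long_dwell_prob")) {
    v <- get(p)
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v >= 1) {
      stop("`", p, "` must lie in [0, 1)", call. = FALSE)
    }
  }
  if (n_tracks < 1) stop("`n_tracks` must be >= 1", call. = FALSE)
  if (multi_turn_k %% 2L != 1L || multi_turn_k < 1) {
    stop("`multi_turn_k` must be a positive odd integer", call. = FALSE)
  }
  structure(
    list(
      n_tracks = as.integer(n_tracks), pattern_weights = w, vf = vf,
      speed_meanlog = speed_meanlog, speed_sdlog = speed_sdlog,
      speed_min = speed_min, jitter_sd = jitter_sd,
      dropout_prob = dropout_prob, id_switch_prob = id_switch_prob,
      id_merge_prob = id_merge_prob,
      dwell_range_frames = dwell_range_frames,
      long_dwell_prob = long_dwell_prob,
      long_dwell_range_frames = long_dwell_range_frames,
      merge_gap_range_frames = merge_gap_range_frames,
      multi_turn_k = as.integer(multi_turn_k),
      box_size = box_size,
      start_frame_max = as.integer(start_frame_max),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# --- waypoint helpers (all draw from the current RNG stream) ----------------

# a point in the greenhouse airspace above the frame
.pt_outside_above <- function(vf) {
  c(runif(1, vf$x_min + 30, vf$x_max - 30),
    runif(1, 10, vf$y_min - 40))
}

# a landing point deep inside the frame (the entrance hole region)
.pt_entrance <- function(vf) {
  cx <- (vf$x_min + vf$x_max) / 2
  c(runif(1, cx - 70, cx + 70),
    runif(1, vf$y_min + 60, vf$y_max - 30))
}

# a shallow point just inside the upper frame edge (turn-back target, B)
.pt_dip_inside <- function(vf) {
  c(runif(1, vf$x_min + 40, vf$x_max - 40),
    runif(1, vf$y_min + 20, vf$y_min + 50))
}

# a point just outside the upper frame edge (poke-out target, D / multi_turn)
.pt_poke_outside <- function(vf) {
  c(runif(1, vf$x_min + 40, vf$x_max - 40),
    runif(1, max(10, vf$y_min - 60), vf$y_min - 15))
}

.pt_outside_below <- function(vf) {
  c(runif(1, vf$x_min + 30, vf$x_max - 30),
    runif(1, vf$y_max + 40, vf$image_height - 10))
}

.draw_dwell <- function(cfg) {
  r <- if (runif(1) < cfg$long_dwell_prob) {
    cfg$long_dwell_range_frames
  } else {
    cfg$dwell_range_frames
  }
  as.integer(round(runif(1, r[1], r[2])))
}

# Render a piecewise-linear waypoint path at one position per frame.
# `dwell_after[i]` frames are spent hovering at waypoint i+1.
.render_path <- function(waypoints, speed, dwell_after = NULL) {
  n_seg <- nrow(waypoints) - 1L
  if (is.null(dwell_after)) dwell_after <- rep(0L, n_seg)
  xs <- waypoints[1, 1]
  ys <- waypoints[1, 2]
  for (i in seq_len(n_seg)) {
    a <- waypoints[i, ]
    b <- waypoints[i + 1L, ]
    d <- sqrt(sum((b - a)^2))
    steps <- max(1L, ceiling(d / speed))
    t <- seq_len(steps) / steps
    xs <- c(xs, a[1] + t * (b[1] - a[1]))
    ys <- c(ys, a[2] + t * (b[2] - a[2]))
    if (dwell_after[i] > 0L) {
      xs <- c(xs, rep(b[1], dwell_after[i]))
      ys <- c(ys, rep(b[2], dwell_after[i]))
    }
  }
  cbind(unname(xs), unname(ys))
}

#' Draw one labelled synthetic track
#'
#' Renders a single bee trajectory of the requested pattern (see
#' [sim_config()]) and stamps its ground-truth nest events from the clean
#' (noise-free) geometry: the truth frame of an entry or exit is the frame of
#' the decisive boundary transition of the clean path. Centre jitter,
#' box-size jitter and detection dropout are then applied to the observed
#' detections only — the truth is a property of the bee, not of the detector.
#'
#' @param pattern One of `"A"`, `"B"`, `"C"`, `"D"`, `"pass_over"`,
#'   `"multi_turn"`.
#' @param cfg A [sim_config()].
#' @param track_id Track ID to assign.
#' @param start_frame First frame index of the track.
#' @return A list of class `labelled_track` with elements `track` (a
#'   detections tibble), `true_events` (an event tibble, `source = "truth"`)
#'   and `pattern`. Draws from the current RNG stream; seed externally (e.g.
#'   [withr::with_seed()]) for reproducibility.
#' @export
sample_track <- function(pattern, cfg, track_id = 1L, start_frame = 0L) {
  patterns <- c("A", "B", "C", "D", "pass_over", "multi_turn")
  if (!pattern %in% patterns) {
    stop("unknown pattern: ", pattern, call. = FALSE)
  }
  vf <- cfg$vf
  speed <- max(cfg$speed_min, rlnorm(1, cfg$speed_meanlog, cfg$speed_sdlog))

  wp <- NULL
  dwell_after <- NULL
  if (pattern == "A") {
    wp <- rbind(.pt_outside_above(vf), .pt_entrance(vf))
  } else if (pattern == "B") {
    wp <- rbind(.pt_outside_above(vf), .pt_dip_inside(vf),
                .pt_outside_above(vf))
    dwell_after <- c(.draw_dwell(cfg), 0L)
  } else if (pattern == "C") {
    wp <- rbind(.pt_entrance(vf), .pt_outside_above(vf))
  } else if (pattern == "D") {
    wp <- rbind(.pt_entrance(vf), .pt_poke_outside(vf), .pt_entrance(vf))
    dwell_after <- c(.draw_dwell(cfg), 0L)
  } else if (pattern == "pass_over") {
    a <- .pt_outside_above(vf)
    b <- .pt_outside_below(vf)
    # keep the crossing near-vertical so the transit stays well under 1 s
    b[1] <- min(max(a[1] + runif(1, -60, 60), vf$x_min + 10), vf$x_max - 10)
    wp <- rbind(a, b)
  } else if (pattern == "multi_turn") {
    # k transitions, k odd: out, (in, out) x (k-1)/2 hesitations, final in
    k <- cfg$multi_turn_k
    wp <- .pt_outside_above(vf)
    dwell_after <- integer(0)
    for (i in seq_len((k - 1L) / 2L)) {
      wp <- rbind(wp, .pt_dip_inside(vf), .pt_poke_outside(vf))
      dwell_after <- c(dwell_after, .draw_dwell(cfg), .draw_dwell(cfg))
    }
    wp <- rbind(wp, .pt_entrance(vf))
    dwell_after <- c(dwell_after, 0L)
  }

  path <- .render_path(wp, speed, dwell_after)
  n <- nrow(path)
  frames <- start_frame + seq_len(n) - 1L

  # ground truth from the clean path geometry
  inside <- is_inside(path[, 1], path[, 2], vf)
  trans <- which(inside[-1] != inside[-n]) + 1L  # index of the new state
  truth <- nest_events(source = "truth")
  if (pattern == "A") {
    truth <- nest_events(track_id, "entry", frames[trans[1]], "truth")
  } else if (pattern == "C") {
    truth <- nest_events(track_id, "exit", frames[trans[1]], "truth")
  } else if (pattern == "multi_turn") {
    truth <- nest_events(track_id, "entry", frames[trans[length(trans)]],
                         "truth")
  }

  # observation noise
  cx <- path[, 1] + rnorm(n, 0, cfg$jitter_sd)
  cy <- path[, 2] + rnorm(n, 0, cfg$jitter_sd)
  w <- cfg$box_size * runif(n, 0.9, 1.1)
  h <- cfg$box_size * runif(n, 0.9, 1.1)
  conf <- runif(n, 0.85, 1)
  keep <- runif(n) >= cfg$dropout_prob
  det <- tibble::tibble(
    frame = frames, track_id = as.integer(track_id),
    cx = cx, cy = cy, width = w, height = h, conf = conf
  )[keep, ]

  structure(
    list(track = det, true_events = truth, pattern = pattern),
    class = "labelled_track"
  )
}

#' Corrupt a track by an ID switch
#'
#' Models the tracker losing a bee mid-flight and re-acquiring it under a
#' fresh ID: the track is split at a uniformly drawn interior detection and
#' the second half re-labelled `new_id`. Truth events are re-attributed to
#' whichever half contains their frame. A turn-back track split between its
#' two crossings becomes two one-crossing tracks, each of which the parity
#' counter classifies as a (spurious) nest event — the switch is a
#' false-positive generator.
#'
#' @param lt A `labelled_track` with at least 4 detections (shorter tracks
#'   are returned unchanged, with attribute `switch_skipped` set).
#' @param new_id Fresh unique track ID for the second half.
#' @return A list of one or two `labelled_track`s.
#' @export
corrupt_id_switch <- function(lt, new_id) {
  stopifnot(inherits(lt, "labelled_track"))
  n <- nrow(lt$track)
  if (n < 4L) {
    attr(lt, "switch_skipped") <- TRUE
    return(list(lt))
  }
  cut <- sample(2:(n - 1L), 1)  # first detection index of the second half
  cut_frame <- lt$track$frame[cut]
  first <- lt$track[seq_len(cut - 1L), ]
  second <- lt$track[cut:n, ]
  second$track_id <- as.integer(new_id)
  ev <- lt$true_events
  ev1 <- ev[ev$frame_index < cut_frame, ]
  ev2 <- ev[ev$frame_index >= cut_frame, ]
  if (nrow(ev2) > 0) ev2$track_id <- as.integer(new_id)
  list(
    structure(list(track = first, true_events = ev1, pattern = lt$pattern),
              class = "labelled_track"),
    structure(list(track = second, true_events = ev2, pattern = lt$pattern),
              class = "labelled_track")
  )
}

#' Corrupt two tracks by an ID merge
#'
#' Models the tracker assigning one ID to two different bees in succession:
#' the second track is re-stamped to begin `gap_frames` after the first ends
#' and both are concatenated under the first track's ID. Truth is the union
#' of both event lists (re-attributed to the shared ID). When the gap is
#' below the parity counter's threshold, an entering and an exiting bee merge
#' into one even-parity episode and both true events are missed — the merge
#' is the false-negative generator.
#'
#' @param lt1,lt2 `labelled_track`s.
#' @param gap_frames Positive frame gap inserted between them.
#' @return One merged `labelled_track` with `pattern = "merged"`. Total
#'   detection count is conserved.
#' @export
corrupt_id_merge <- function(lt1, lt2, gap_frames) {
  stopifnot(inherits(lt1, "labelled_track"), inherits(lt2, "labelled_track"))
  if (gap_frames < 1) stop("`gap_frames` must be >= 1", call. = FALSE)
  id <- lt1$track$track_id[1]
  end1 <- max(lt1$track$frame)
  shift <- end1 + as.integer(gap_frames) - min(lt2$track$frame)
  t2 <- lt2$track
  t2$frame <- t2$frame + shift
  t2$track_id <- id
  if (min(t2$frame) <= end1) {
    stop("merged tracks overlap in frame range", call. = FALSE)
  }
  ev2 <- lt2$true_events
  if (nrow(ev2) > 0) {
    ev2$frame_index <- ev2$frame_index + shift
    ev2$track_id <- id
  }
  truth <- nest_events(
    c(lt1$true_events$track_id, ev2$track_id),
    c(lt1$true_events$kind, ev2$kind),
    c(lt1$true_events$frame_index, ev2$frame_index),
    "truth"
  )
  structure(
    list(track = dplyr::bind_rows(lt1$track, t2), true_events = truth,
         pattern = "merged"),
    class = "labelled_track"
  )
}

#' Generate a labelled synthetic dataset
#'
#' Draws `cfg$n_tracks` tracks from the configured pattern mixture, applies
#' ID-merge and ID-switch corruptions at their configured probabilities, and
#' returns the observed detections together with the ground-truth event list
#' and the track lineage (mapping every final track ID to the pre-switch
#' parent it descends from, so evaluation can credit predictions made under
#' switched IDs). Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_dataset`: `tracks` (detections tibble),
#'   `truth` (event tibble, `source = "truth"`), `lineage` (tibble
#'   `track_id`, `lineage_id`), `patterns` (tibble `track_id`, `pattern`),
#'   and `config`.
#' @examples
#' ds <- generate_dataset(sim_config(n_tracks = 5, seed = 42))
#' nrow(ds$tracks); ds$truth
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, .generate_dataset_impl(cfg))
}

.generate_dataset_impl <- function(cfg) {
  patterns <- names(cfg$pattern_weights)
  drawn <- sample(patterns, cfg$n_tracks, replace = TRUE,
                  prob = cfg$pattern_weights)
  starts <- sample.int(cfg$start_frame_max + 1L, cfg$n_tracks,
                       replace = TRUE) - 1L
  lts <- purrr::map(seq_len(cfg$n_tracks), function(i) {
    sample_track(drawn[i], cfg, track_id = i, start_frame = starts[i])
  })
  empty <- purrr::map_int(lts, ~ nrow(.x$track)) == 0L
  if (any(empty)) {
    warning(sum(empty), " track(s) lost all detections to dropout and were ",
            "discarded", call. = FALSE)
    lts <- lts[!empty]
  }

  # ID merges: pair up marked tracks, gap drawn from merge_gap_range_frames
  if (cfg$id_merge_prob > 0 && length(lts) >= 2) {
    marked <- which(runif(length(lts)) < cfg$id_merge_prob)
    while (length(marked) >= 2) {
      i <- marked[1]; j <- marked[2]
      gap <- as.integer(round(runif(1, cfg$merge_gap_range_frames[1],
                                    cfg$merge_gap_range_frames[2])))
      lts[[i]] <- corrupt_id_merge(lts[[i]], lts[[j]], gap)
      marked <- marked[-(1:2)]
      lts[j] <- list(NULL)
    }
    lts <- purrr::compact(lts)
  }

  # ID switches: fresh IDs above every ID in use
  next_id <- max(purrr::map_int(lts, ~ max(.x$track$track_id))) + 1L
  out <- list()
  lineage <- list()
  for (lt in lts) {
    parent <- lt$track$track_id[1]
    if (cfg$id_switch_prob > 0 && runif(1) < cfg$id_switch_prob) {
      halves <- corrupt_id_switch(lt, next_id)
      if (length(halves) == 2L) next_id <- next_id + 1L
      for (h in halves) {
        out[[length(out) + 1L]] <- h
        lineage[[length(lineage) + 1L]] <-
          c(h$track$track_id[1], parent)
      }
    } else {
      out[[length(out) + 1L]] <- lt
      lineage[[length(lineage) + 1L]] <- c(parent, parent)
    }
  }

  tracks <- validate_detections(
    purrr::list_rbind(purrr::map(out, "track"))
  )
  truth_parts <- purrr::map(out, "true_events")
  truth <- purrr::list_rbind(truth_parts)
  truth <- nest_events(truth$track_id, truth$kind, truth$frame_index, "truth")
  lin <- purrr::list_rbind(
    purrr::map(lineage, ~ tibble::tibble(track_id = .x[1], lineage_id = .x[2]))
  )
  pats <- purrr::list_rbind(
    purrr::map(out, ~ tibble::tibble(track_id = .x$track$track_id[1],
                                     pattern = .x$pattern))
  )
  structure(
    list(tracks = tracks, truth = truth, lineage = lin, patterns = pats,
         config = cfg),
    class = "sim_dataset"
  )
}
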