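#' Naive virtual-frame counter
#'
#' The baseline method: every boundary crossing of the virtual frame is taken
#' at face value as a nest event — an inward crossing becomes an entry, an
#' outward crossing an exit, stamped with the crossing's frame. No time
#' threshold and no parity reasoning are applied, so a bee that dips into the
#' frame and turns back, or passes over it, generates spurious events. By
#' construction this counter can never miss a detected crossing, so on data
#' where every true nest event produces at least one crossing its recall
#' is 100%, at the cost of precision.
#'
#' @param detections A detections table.
#' @param vf A [virtual_frame()].
#' @return An event tibble (`track_id`, `kind`, `frame_index`,
#'   `source = "predicted"`), one row per crossing.
#' @export
count_yolo_only <- function(detections, vf) {
  cr <- detect_crossings(detections, vf)
  nest_events(
    track_id = cr$track_id,
    kind = ifelse(cr$direction == "inward", "entry", "exit"),
    frame_index = cr$frame_index,
    source = "predicted"
  )
}

#' Classify episodes by crossing-count parity
#'
#' The parity rule: an episode with an odd number of crossings means the bee
#' ended up on the other side of the boundary from where it started — it
#' entered or exited the nest box. An even count means it turned back (or
#' poked out and returned) and no nest event occurred. For odd episodes the
#' direction follows from the start/end states: outside to inside is an entry
#' (the bee came from the greenhouse and descended into the entrance), inside
#' to outside an exit (it emerged and flew off). The event is stamped with
#' the episode's last crossing frame.
#'
#' @param episodes An episode tibble from [split_episodes()] or
#'   [track_episodes()]; vectorised over rows.
#' @return An event tibble with one row per odd-parity episode (possibly
#'   zero rows).
#' @export
classify_episode <- function(episodes) {
  if (nrow(episodes) == 0) return(nest_events())
  odd <- episodes$n_crossings %% 2L == 1L
  bad <- odd & (episodes$start_state == episodes$end_state)
  if (any(bad)) {
    stop("inconsistent episode: odd crossing count but identical start and ",
         "end state", call. = FALSE)
  }
  ep <- episodes[odd, , drop = FALSE]
  nest_events(
    track_id = ep$track_id,
    kind = ifelse(ep$start_state == "outside" & ep$end_state == "inside",
                  "entry", "exit"),
    frame_index = ep$last_frame,
    source = "predicted"
  )
}

#' Parity counter with inter-crossing time threshold
#'
#' The full counting algorithm: detect boundary crossings per track, group
#' them into episodes wherever consecutive crossings are less than
#' `gap_threshold_frames` apart ([split_episodes()]), and classify each
#' episode by parity ([classify_episode()]). Per track, the number of emitted
#' events is at most the number of episodes, which is at most the number of
#' crossings — so this counter never emits more events than
#' [count_yolo_only()].
#'
#' Lowering the threshold splits genuine turn-backs into odd fragments and
#' inflates false positives; raising it merges genuinely separate visits
#' (e.g. two bees sharing one track ID) into even groups and inflates false
#' negatives.
#'
#' @inheritParams track_episodes
#' @return An event tibble (`track_id`, `kind`, `frame_index`,
#'   `source = "predicted"`).
#' @examples
#' vf <- virtual_frame()
#' # a bee approaching from above and descending into the entrance
#' det <- tibble::tibble(
#'   frame = 0:9 * 10L, track_id = 1L,
#'   cx = 320, cy = seq(60, 240, length.out = 10),
#'   width = 20, height = 20, conf = 1
#' )
#' count_parity(det, vf)      # one entry
#' count_yolo_only(det, vf)   # same here: a single inward crossing
#' @export
count_parity <- function(detections, vf, gap_threshold_frames = vf$fps) {
  episodes <- track_episodes(detections, vf, gap_threshold_frames)
  classify_episode(episodes)
}
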