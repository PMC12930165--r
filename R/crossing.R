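#' Test points against the virtual frame
#'
#' Half-open rectangle membership: inside iff `x_min <= x < x_max` and
#' `y_min <= y < y_max`. Vectorised over `x` and `y`.
#'
#' @param x,y Point coordinates in pixels.
#' @param vf A [virtual_frame()].
#' @return Logical vector.
#' @export
is_inside <- function(x, y, vf) {
  stopifnot(inherits(vf, "virtual_frame"))
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("point coordinates must be finite", call. = FALSE)
  }
  x >= vf$x_min & x < vf$x_max & y >= vf$y_min & y < vf$y_max
}

#' Detect boundary crossings along tracks
#'
#' A crossing is a change of the inside/outside state of a track's
#' bounding-box centre between two consecutive detections: `inward` for
#' outside to inside, `outward` for the reverse. The crossing is stamped with
#' the frame of the later detection — the first frame at which the new state
#' is observed. No interpolation is performed across detection gaps: however
#' many frames separate the pair, at most one crossing is recorded.
#'
#' The number of crossings of a track always has the parity of
#' `is_inside(first) != is_inside(last)`, and directions strictly alternate.
#'
#' @param detections A detections table (one or many tracks).
#' @param vf A [virtual_frame()].
#' @return A tibble with columns `track_id`, `frame_index`, `direction`
#'   (`"inward"` or `"outward"`), sorted by `(track_id, frame_index)`.
#'   Tracks with a single detection, or that never change state, contribute
#'   no rows.
#' @export
detect_crossings <- function(detections, vf) {
  detections <- validate_detections(detections)
  if (nrow(detections) == 0) {
    return(tibble::tibble(track_id = integer(), frame_index = integer(),
                          direction = character()))
  }
  detections |>
    dplyr::mutate(inside = is_inside(.data$cx, .data$cy, vf)) |>
    dplyr::group_by(.data$track_id) |>
    dplyr::mutate(prev_inside = dplyr::lag(.data$inside)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$prev_inside),
                  .data$inside != .data$prev_inside) |>
    dplyr::transmute(
      track_id = .data$track_id,
      frame_index = .data$frame,
      direction = ifelse(.data$inside, "inward", "outward")
    ) |>
    dplyr::arrange(.data$track_id, .data$frame_index)
}

#' Group one track's crossings into episodes
#'
#' An episode is a maximal run of a single track's crossings in which every
#' gap between consecutive crossings is below the threshold; a gap of
#' `gap_threshold_frames` or more starts a new episode. The threshold
#' separates a bee that briefly dipped into the frame and left again (both
#' crossings belong to one episode, even count, no nest event) from
#' unrelated visits far apart in time. Parity is later evaluated per episode
#' by [classify_episode()].
#'
#' @param crossings A crossing table for a single track, sorted by
#'   `frame_index` (as returned by [detect_crossings()]).
#' @param gap_threshold_frames Positive number of frames; `Inf` puts all
#'   crossings into one episode.
#' @param start_state `"inside"` or `"outside"`: the track's state before its
#'   first crossing.
#' @return A tibble of episodes with columns `track_id`, `episode`,
#'   `n_crossings`, `start_state`, `end_state`, `first_frame`, `last_frame`.
#'   `start_state` of episode k is the track's state just before that
#'   episode's first crossing; `end_state = start_state` XOR odd count.
#' @examples
#' cr <- tibble::tibble(track_id = 1L, frame_index = c(100L, 150L),
#'                      direction = c("inward", "outward"))
#' split_episodes(cr, 240, "outside")        # one episode, even
#' cr2 <- dplyr::mutate(cr, frame_index = c(100L, 400L))
#' split_episodes(cr2, 240, "outside")       # gap 300 >= 240: two episodes
#' @export
split_episodes <- function(crossings, gap_threshold_frames, start_state) {
  stopifnot(length(gap_threshold_frames) == 1L, gap_threshold_frames > 0)
  start_state <- match.arg(start_state, c("inside", "outside"))
  empty <- tibble::tibble(
    track_id = integer(), episode = integer(), n_crossings = integer(),
    start_state = character(), end_state = character(),
    first_frame = integer(), last_frame = integer()
  )
  if (nrow(crossings) == 0) return(empty)
  if (length(unique(crossings$track_id)) != 1L) {
    stop("split_episodes expects crossings of a single track", call. = FALSE)
  }
  f <- crossings$frame_index
  if (is.unsorted(f)) {
    stop("crossings must be sorted by frame_index", call. = FALSE)
  }
  gaps <- diff(f)
  episode <- cumsum(c(1L, as.integer(gaps >= gap_threshold_frames)))
  states <- c("outside", "inside")
  # state just before crossing j: start_state flipped (j - 1) times
  start_bit <- as.integer(start_state == "inside")
  n_before <- seq_along(f) - 1L
  first_of_ep <- !duplicated(episode)
  ep_start_bit <- (start_bit + n_before[first_of_ep]) %% 2L
  counts <- as.integer(table(episode))
  tibble::tibble(
    track_id = rep(crossings$track_id[1], length(counts)),
    episode = seq_along(counts),
    n_crossings = counts,
    start_state = states[ep_start_bit + 1L],
    end_state = states[(ep_start_bit + counts) %% 2L + 1L],
    first_frame = f[first_of_ep],
    last_frame = f[cumsum(counts)]
  )
}

#' Compute threshold-separated episodes for every track
#'
#' Convenience composition of [detect_crossings()] and [split_episodes()]
#' across a whole detections table. Tracks that never cross the virtual
#' frame's boundary contribute no episodes. These episodes are also the
#' candidate units over which true negatives are counted by
#' [match_events()].
#'
#' @inheritParams detect_crossings
#' @param gap_threshold_frames Positive number of frames (default: one second
#'   at the frame's fps).
#' @return An episode tibble as in [split_episodes()], covering all tracks.
#' @export
track_episodes <- function(detections, vf, gap_threshold_frames = vf$fps) {
  detections <- validate_detections(detections)
  crossings <- detect_crossings(detections, vf)
  first_det <- detections |>
    dplyr::group_by(.data$track_id) |>
    dplyr::slice_min(.data$frame, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  start_states <- stats::setNames(
    ifelse(is_inside(first_det$cx, first_det$cy, vf), "inside", "outside"),
    as.character(first_det$track_id)
  )
  crossings |>
    dplyr::group_by(.data$track_id) |>
    dplyr::group_split() |>
    purrr::map(function(cr) {
      split_episodes(cr, gap_threshold_frames,
                     start_states[[as.character(cr$track_id[1])]])
    }) |>
    purrr::list_rbind() |>
    (\(x) if (nrow(x) == 0) tibble::tibble(
      track_id = integer(), episode = integer(), n_crossings = integer(),
      start_state = character(), end_state = character(),
      first_frame = integer(), last_frame = integer()
    ) else x)()
}
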