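#' Define the virtual counting frame
#'
#' The virtual frame is the rectangular region placed over the nest-box
#' entrance in image coordinates. A tracked bee's bounding-box centre is
#' tested against this rectangle; transitions between outside and inside are
#' the primitive crossing events that all counting methods consume.
#'
#' Coordinates are 0-based pixels, origin top-left, x rightward, y downward.
#' Membership is half-open: a point is inside iff
#' `x_min <= x < x_max` and `y_min <= y < y_max`, so boundary points are never
#' double-counted. Fractional edges are allowed (the default rectangle,
#' a 495 x 150 region centred in a 640 x 480 image, has half-pixel x edges).
#'
#' @param x_min,y_min,x_max,y_max Rectangle edges in pixels.
#' @param image_width,image_height Image size in pixels.
#' @param fps Video frame rate in frames per second. Used to convert
#'   time thresholds expressed in seconds into frames.
#' @return An object of class `virtual_frame`.
#' @examples
#' vf <- virtual_frame()
#' vf
#' is_inside(320, 240, vf)
#' @export
virtual_frame <- function(x_min = 72.5, y_min = 165, x_max = 567.5, y_max = 315,
                          image_width = 640, image_height = 480, fps = 240) {
  for (nm in c("x_min", "y_min", "x_max", "y_max", "image_width",
               "image_height", "fps")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  if (fps <= 0) stop("`fps` must be > 0", call. = FALSE)
  if (!(0 <= x_min && x_min < x_max && x_max <= image_width)) {
    stop("invalid x extent: need 0 <= x_min < x_max <= image_width ",
         "(x_min = ", x_min, ", x_max = ", x_max, ")", call. = FALSE)
  }
  if (!(0 <= y_min && y_min < y_max && y_max <= image_height)) {
    stop("invalid y extent: need 0 <= y_min < y_max <= image_height ",
         "(y_min = ", y_min, ", y_max = ", y_max, ")", call. = FALSE)
  }
  structure(
    list(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
         image_width = image_width, image_height = image_height, fps = fps),
    class = "virtual_frame"
  )
}

#' @export
print.virtual_frame <- function(x, ...) {
  cat(sprintf(
    "<virtual_frame> [%g, %g) x [%g, %g) px (%g x %g) in %g x %g image, %g fps\n",
    x$x_min, x$x_max, x$y_min, x$y_max,
    x$x_max - x$x_min, x$y_max - x$y_min,
    x$image_width, x$image_height, x$fps
  ))
  invisible(x)
}

#' Validate a detections table
#'
#' Checks the tidy detection layout used throughout the package: one row per
#' tracked bounding box, columns `frame`, `track_id`, `cx`, `cy`, `width`,
#' `height`, `conf`. Enforces positive box sizes, confidences in \[0, 1\],
#' unique `(frame, track_id)` keys and, when a [virtual_frame()] is supplied,
#' warns (without rejecting) about centres outside the image bounds, since
#' detectors can emit boxes straddling the border.
#'
#' @param detections A data frame of detections.
#' @param vf Optional [virtual_frame()] giving image bounds for the warning.
#' @return The detections as a tibble, sorted by `(track_id, frame)`.
#' @export
validate_detections <- function(detections, vf = NULL) {
  detections <- tibble::as_tibble(detections)
  missing <- setdiff(.det_cols, names(detections))
  if (length(missing) > 0) {
    stop("detections table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(detections) == 0) return(detections[.det_cols])
  if (any(detections$width <= 0) || any(detections$height <= 0)) {
    stop("bounding-box width and height must be > 0", call. = FALSE)
  }
  if (any(detections$conf < 0 | detections$conf > 1)) {
    stop("confidence must lie in [0, 1]", call. = FALSE)
  }
  if (any(detections$frame < 0) || any(detections$track_id < 1)) {
    stop("frame must be >= 0 and track_id >= 1", call. = FALSE)
  }
  key <- paste(detections$frame, detections$track_id)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (frame, track_id) detection: ", dup, call. = FALSE)
  }
  if (!is.null(vf)) {
    out <- detections$cx < 0 | detections$cx >= vf$image_width |
      detections$cy < 0 | detections$cy >= vf$image_height
    if (any(out)) {
      warning(sum(out), " detection centre(s) fall outside the ",
              vf$image_width, " x ", vf$image_height, " image bounds",
              call. = FALSE)
    }
  }
  dplyr::arrange(detections[.det_cols], .data$track_id, .data$frame)
}

#' Read tracked detections from a MOT-challenge CSV
#'
#' Parses the de-facto standard multi-object-tracking interchange format:
#' headerless CSV rows
#' `frame,id,bb_left,bb_top,bb_width,bb_height,conf,x,y,z` (the last three
#' columns are ignored and may be -1). Bounding-box centres are computed as
#' corner plus half extent; rows are sorted by `(track_id, frame)` and
#' duplicate `(frame, id)` rows are rejected.
#'
#' @param path Path to the CSV file. An empty file yields an empty table.
#' @param vf Optional [virtual_frame()] used to warn about out-of-image
#'   centres.
#' @return A tibble of detections with columns `frame`, `track_id`, `cx`,
#'   `cy`, `width`, `height`, `conf`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines("10,3,100,200,20,20,0.9,-1,-1,-1", f)
#' read_tracks(f)
#' @export
read_tracks <- function(path, vf = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  info <- file.info(path)
  if (info$size == 0) {
    return(validate_detections(tibble::tibble(
      frame = integer(), track_id = integer(), cx = double(), cy = double(),
      width = double(), height = double(), conf = double()
    )))
  }
  raw <- suppressWarnings(readr::read_csv(
    path,
    col_names = .mot_cols,
    col_types = readr::cols(.default = readr::col_double()),
    progress = FALSE
  ))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    stop("malformed MOT CSV row at line ", probs$row[1], " of ", path, ": ",
         probs$expected[1], " expected, got ", probs$actual[1], call. = FALSE)
  }
  if (any(!is.finite(raw$frame)) || any(!is.finite(raw$id))) {
    stop("malformed MOT CSV: non-numeric frame or id in ", path, call. = FALSE)
  }
  det <- tibble::tibble(
    frame = as.integer(raw$frame),
    track_id = as.integer(raw$id),
    cx = raw$bb_left + raw$bb_width / 2,
    cy = raw$bb_top + raw$bb_height / 2,
    width = raw$bb_width,
    height = raw$bb_height,
    conf = ifelse(is.na(raw$conf) | raw$conf < 0, 1.0, raw$conf)
  )
  validate_detections(det, vf)
}

#' Write tracked detections to a MOT-challenge CSV
#'
#' Inverse of [read_tracks()]: emits headerless
#' `frame,id,bb_left,bb_top,bb_width,bb_height,conf,x,y,z` rows (corner
#' recovered as centre minus half extent; `x,y,z` written as -1), sorted by
#' `(frame, id)`. A read-back restores `(frame, track_id, cx, cy, width,
#' height, conf)` exactly up to float formatting.
#'
#' @param detections A detections table (see [validate_detections()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(detections, path) {
  detections <- validate_detections(detections)
  out <- tibble::tibble(
    frame = detections$frame,
    id = detections$track_id,
    bb_left = detections$cx - detections$width / 2,
    bb_top = detections$cy - detections$height / 2,
    bb_width = detections$width,
    bb_height = detections$height,
    conf = detections$conf,
    x = -1, y = -1, z = -1
  )
  out <- dplyr::arrange(out, .data$frame, .data$id)
  readr::write_csv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Construct a nest-event table
#'
#' A nest event is an entry into or an exit from the nest box attributed to a
#' track at a frame, either predicted by a counting method or asserted by
#' ground truth.
#'
#' @param track_id Integer track IDs.
#' @param kind `"entry"` or `"exit"`.
#' @param frame_index Frame of the decisive crossing.
#' @param source `"predicted"` or `"truth"`.
#' @return A tibble with columns `track_id`, `kind`, `frame_index`, `source`,
#'   sorted by `(frame_index, track_id)`.
#' @export
nest_events <- function(track_id = integer(), kind = character(),
                        frame_index = integer(), source = "predicted") {
  if (length(kind) > 0 && !all(kind %in% c("entry", "exit"))) {
    stop("event kind must be 'entry' or 'exit'", call. = FALSE)
  }
  if (length(source) > 0 && !all(source %in% c("predicted", "truth"))) {
    stop("event source must be 'predicted' or 'truth'", call. = FALSE)
  }
  ev <- tibble::tibble(
    track_id = as.integer(track_id),
    kind = as.character(kind),
    frame_index = as.integer(frame_index),
    source = rep_len(as.character(source), length(track_id))
  )
  dplyr::arrange(ev, .data$frame_index, .data$track_id)
}

#' Write nest events to CSV
#'
#' Writes a CSV with header `track_id,kind,frame_index,source`, rows stably
#' ordered by `(frame_index, track_id)`. [read_events()] round-trips
#' losslessly.
#'
#' @param events An event table as produced by [nest_events()],
#'   [count_parity()] or [count_yolo_only()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  events <- nest_events(events$track_id, events$kind, events$frame_index,
                        events$source)
  readr::write_csv(events, path, progress = FALSE)
  invisible(path)
}

#' Read nest events from CSV
#'
#' @param path Path to a CSV written by [write_events()].
#' @return An event tibble.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ev <- readr::read_csv(
    path,
    col_types = readr::cols(
      track_id = readr::col_integer(),
      kind = readr::col_character(),
      frame_index = readr::col_integer(),
      source = readr::col_character()
    ),
    progress = FALSE
  )
  nest_events(ev$track_id, ev$kind, ev$frame_index, ev$source)
}

#' Load a run configuration
#'
#' Reads a YAML (or JSON — YAML is a superset) key-value configuration and
#' fills missing keys with the package defaults: a 640 x 480 image, a
#' 495 x 150 virtual frame centred in it, 240 fps, a gap threshold of one
#' second, and the parity counting method. Recognised keys: `image_width`,
#' `image_height`, `frame_x_min`, `frame_y_min`, `frame_x_max`, `frame_y_max`,
#' `fps`, `gap_threshold_seconds`, `method`, and an optional `simulate`
#' mapping passed through to [sim_config()].
#'
#' @param path Path to the config file, or `NULL` for all defaults.
#' @return A list with elements `vf` (a [virtual_frame()]),
#'   `gap_threshold_seconds`, `gap_threshold_frames`, `method`, and `sim`
#'   (a list of simulator overrides, possibly empty).
#' @examples
#' cfg <- load_config(NULL)
#' cfg$gap_threshold_frames  # 240 frames = 1 s at 240 fps
#' @export
load_config <- function(path = NULL) {
  raw <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
    raw <- yaml::read_yaml(path)
    if (is.null(raw)) raw <- list()
    if (!is.list(raw)) stop("config must be a key-value mapping", call. = FALSE)
  }
  pick <- function(key, default) {
    v <- raw[[key]]
    if (is.null(v)) return(default)
    if (key != "method" && (!is.numeric(v) || length(v) != 1L)) {
      stop("config key `", key, "` must be a single number", call. = FALSE)
    }
    v
  }
  image_width <- pick("image_width", 640)
  image_height <- pick("image_height", 480)
  # default rectangle: 495 x 150 centred in the image
  x_min <- pick("frame_x_min", (image_width - 495) / 2)
  x_max <- pick("frame_x_max", x_min + 495)
  y_min <- pick("frame_y_min", (image_height - 150) / 2)
  y_max <- pick("frame_y_max", y_min + 150)
  fps <- pick("fps", 240)
  gap_s <- pick("gap_threshold_seconds", 1.0)
  if (gap_s <= 0) {
    stop("config key `gap_threshold_seconds` must be > 0", call. = FALSE)
  }
  method <- pick("method", "parity")
  if (!method %in% c("parity", "yolo-only")) {
    stop("config key `method` must be 'parity' or 'yolo-only'", call. = FALSE)
  }
  vf <- tryCatch(
    virtual_frame(x_min, y_min, x_max, y_max, image_width, image_height, fps),
    error = function(e) {
      stop("config geometry invalid (keys frame_x_min/frame_x_max/",
           "frame_y_min/frame_y_max/image_width/image_height/fps): ",
           conditionMessage(e), call. = FALSE)
    }
  )
  sim <- raw[["simulate"]]
  if (is.null(sim)) sim <- list()
  list(
    vf = vf,
    gap_threshold_seconds = gap_s,
    gap_threshold_frames = max(1L, as.integer(round(gap_s * fps))),
    method = method,
    sim = sim
  )
}
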