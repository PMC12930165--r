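#' Confusion counts
#'
#' Plain container for the TP/FP/FN/TN tallies that feed the four
#' performance metrics.
#'
#' @param tp,fp,fn,tn Nonnegative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp = 0L, fp = 0L, fn = 0L, tn = 0L) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(v < 0) || any(v != round(v))) {
    stop("confusion counts must be nonnegative integers", call. = FALSE)
  }
  structure(as.list(as.integer(v)) |> stats::setNames(names(v)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  FP %d  FN %d  TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Match predicted nest events to ground truth
#'
#' Greedy one-to-one matching: predictions are visited in frame order and
#' each is paired with the earliest unmatched truth event of the same track
#' lineage and same kind within `tolerance_frames`. Matched pairs are TP,
#' unmatched predictions FP, unmatched truths FN, so
#' `TP + FP = |predicted|` and `TP + FN = |truth|` always hold.
#'
#' True negatives need a unit of observation: here a candidate unit is one
#' threshold-separated episode of a track that touched the virtual frame
#' (see [track_episodes()]). A unit with neither a true nor a predicted
#' event attributed to it — no event of its lineage within its frame span,
#' widened by the tolerance — is a TN. A turn-back episode correctly
#' classified as "no event" thus scores one TN for the parity counter; the
#' naive counter predicts an event for every episode it forms, so it can
#' score no negatives at all. If `units` is omitted, TN = 0.
#'
#' @param predicted,truth Event tibbles (`track_id`, `kind`, `frame_index`).
#' @param tolerance_frames Nonnegative matching tolerance in frames
#'   (default 240, one second at 240 fps).
#' @param units Optional episode tibble ([track_episodes()]) defining the
#'   candidate units for TN counting.
#' @param lineage Optional tibble (`track_id`, `lineage_id`) mapping
#'   post-corruption track IDs to their parent, as returned by
#'   [generate_dataset()]; IDs absent from the map are their own lineage.
#' @return A [confusion_counts()].
#' @export
match_events <- function(predicted, truth, tolerance_frames = 240,
                         units = NULL, lineage = NULL) {
  if (tolerance_frames < 0) {
    stop("`tolerance_frames` must be >= 0", call. = FALSE)
  }
  to_lineage <- function(ids) {
    if (is.null(lineage)) return(as.integer(ids))
    m <- match(ids, lineage$track_id)
    out <- lineage$lineage_id[m]
    out[is.na(m)] <- ids[is.na(m)]
    as.integer(out)
  }
  p <- dplyr::arrange(tibble::as_tibble(predicted),
                      .data$frame_index, .data$track_id)
  t <- dplyr::arrange(tibble::as_tibble(truth),
                      .data$frame_index, .data$track_id)
  p_lin <- to_lineage(p$track_id)
  t_lin <- to_lineage(t$track_id)
  t_used <- rep(FALSE, nrow(t))
  tp <- 0L
  for (i in seq_len(nrow(p))) {
    ok <- !t_used & t_lin == p_lin[i] & t$kind == p$kind[i] &
      abs(t$frame_index - p$frame_index[i]) <= tolerance_frames
    j <- which(ok)
    if (length(j) > 0) {
      t_used[j[1]] <- TRUE  # first fit in frame order
      tp <- tp + 1L
    }
  }
  fp <- nrow(p) - tp
  fn <- nrow(t) - tp
  tn <- 0L
  if (!is.null(units) && nrow(units) > 0) {
    u_lin <- to_lineage(units$track_id)
    ev_lin <- c(p_lin, t_lin)
    ev_frame <- c(p$frame_index, t$frame_index)
    for (k in seq_len(nrow(units))) {
      hit <- ev_lin == u_lin[k] &
        ev_frame >= units$first_frame[k] - tolerance_frames &
        ev_frame <= units$last_frame[k] + tolerance_frames
      if (!any(hit)) tn <- tn + 1L
    }
  }
  confusion_counts(tp, fp, fn, tn)
}

#' Performance metrics from confusion counts
#'
#' The four standard detection metrics:
#' accuracy = (TP + TN) / (TP + FP + FN + TN),
#' precision = TP / (TP + FP), recall = TP / (TP + FN),
#' F1 = 2 TP / (2 TP + FP + FN). A metric whose denominator is zero is
#' undefined and returned as `NA` (never silently 0). Whenever precision and
#' recall are both defined and positive, F1 equals their harmonic mean.
#'
#' @param c A [confusion_counts()].
#' @return A fraction in \[0, 1\], or `NA_real_` when undefined.
#' @examples
#' cc <- confusion_counts(tp = 2, fp = 1, fn = 1, tn = 2)
#' accuracy(cc); precision(cc); recall(cc); f1_score(cc)
#' @name metrics
NULL

.ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' @rdname metrics
#' @export
accuracy <- function(c) .ratio(c$tp + c$tn, c$tp + c$fp + c$fn + c$tn)

#' @rdname metrics
#' @export
precision <- function(c) .ratio(c$tp, c$tp + c$fp)

#' @rdname metrics
#' @export
recall <- function(c) .ratio(c$tp, c$tp + c$fn)

#' @rdname metrics
#' @export
f1_score <- function(c) .ratio(2 * c$tp, 2 * c$tp + c$fp + c$fn)

#' Tabulate metrics for one or more methods
#'
#' @param counts A named list of [confusion_counts()], one per method.
#' @param percent Report metrics in percent (default) or as fractions.
#' @return A tibble with one row per method: `method`, `tp`, `fp`, `fn`,
#'   `tn`, `accuracy`, `precision`, `recall`, `f1`.
#' @export
metric_table <- function(counts, percent = TRUE) {
  scale <- if (percent) 100 else 1
  purrr::imap(counts, function(cc, nm) {
    tibble::tibble(
      method = nm, tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
      accuracy = scale * accuracy(cc),
      precision = scale * precision(cc),
      recall = scale * recall(cc),
      f1 = scale * f1_score(cc)
    )
  }) |> purrr::list_rbind()
}
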