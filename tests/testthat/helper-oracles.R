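# Independent oracles and fixture builders shared across test files.
# These re-derive expected behaviour by direct enumeration, deliberately
# avoiding the package's own crossing/episode code paths.

# A detections table realising a given inside/outside state sequence against
# the default virtual frame: inside -> frame centre, outside -> image corner.
state_track <- function(states, frames = seq_along(states), track_id = 1L,
                        vf = virtual_frame()) {
  cx <- ifelse(states, (vf$x_min + vf$x_max) / 2, 10)
  cy <- ifelse(states, (vf$y_min + vf$y_max) / 2, 10)
  tibble::tibble(
    frame = as.integer(frames), track_id = as.integer(track_id),
    cx = cx, cy = cy, width = 20, height = 20, conf = 1
  )
}

# Direct enumeration of the parity rule: walk the state sequence, split
# transitions wherever the frame gap reaches the threshold, emit one event
# per odd-count group, direction from the states flanking the group.
oracle_parity_events <- function(states, frames, threshold) {
  n <- length(states)
  trans <- which(states[-1] != states[-n]) + 1L
  out <- list()
  if (length(trans) > 0) {
    grp_start <- 1L
    tf <- frames[trans]
    flush <- function(a, b) {
      count <- b - a + 1L
      if (count %% 2L == 1L) {
        before <- states[trans[a] - 1L]
        after <- states[trans[b]]
        list(kind = if (!before && after) "entry" else "exit",
             frame_index = frames[trans[b]])
      }
    }
    for (k in seq_along(trans)[-1]) {
      if (tf[k] - tf[k - 1L] >= threshold) {
        ev <- flush(grp_start, k - 1L)
        if (!is.null(ev)) out[[length(out) + 1L]] <- ev
        grp_start <- k
      }
    }
    ev <- flush(grp_start, length(trans))
    if (!is.null(ev)) out[[length(out) + 1L]] <- ev
  }
  if (length(out) == 0) {
    return(tibble::tibble(kind = character(), frame_index = integer()))
  }
  tibble::tibble(
    kind = vapply(out, `[[`, "", "kind"),
    frame_index = vapply(out, function(e) as.integer(e$frame_index), 1L)
  )
}

# Maximum-cardinality bipartite matching by exhaustive recursion, for
# checking the greedy matcher on small instances.
oracle_max_matching <- function(compat) {
  np <- nrow(compat)
  nt <- ncol(compat)
  if (np == 0 || nt == 0) return(0L)
  rec <- function(i, used) {
    if (i > np) return(0L)
    best <- rec(i + 1L, used)
    for (j in which(compat[i, ] & !used)) {
      used2 <- used
      used2[j] <- TRUE
      best <- max(best, 1L + rec(i + 1L, used2))
    }
    best
  }
  rec(1L, rep(FALSE, nt))
}

# All inside/outside state sequences of length n as a logical matrix.
all_state_seqs <- function(n) {
  as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
}
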