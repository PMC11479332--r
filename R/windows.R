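#' Analysis window specification
#'
#' Sliding windows over a held pose: 45 s long (2250 samples at 50 Hz),
#' stepped by 15 s, so a three-minute hold yields exactly 10 windows.
#'
#' @param length Window length, seconds.
#' @param step Window step, seconds.
#' @return A `window_spec` object.
#' @export
window_spec <- function(length = 45, step = 15) {
  if (!(length > step && step > 0)) {
    stop("need window length > step > 0", call. = FALSE)
  }
  structure(list(length = length, step = step), class = "window_spec")
}

#' Segment a recording into per-pose sliding windows
#'
#' For every pose segment of a `simulated_recording` (positional-change
#' intervals are never part of a segment by construction), enumerates all
#' fully contained windows: `floor((N - L) / S) + 1` windows for a pose of
#' `N` samples with window length `L` and step `S` in samples. Poses shorter
#' than one window contribute no windows (with a warning).
#'
#' @param recording A `simulated_recording`.
#' @param spec A [window_spec()].
#' @param roles Which segment roles to window (default both primary and
#'   intermediate holds).
#' @return A data.frame with one row per window: `segment`, `target_tpa`,
#'   `role`, `start`, `end` (sample indices into the recording) and
#'   `window_index` (within the pose).
#' @export
segment_windows <- function(recording, spec = window_spec(),
                            roles = c("primary", "intermediate")) {
  stopifnot(inherits(spec, "window_spec"))
  rate <- recording$rate
  L <- round(spec$length * rate)
  S <- round(spec$step * rate)
  segs <- recording$segments
  rows <- list()
  for (i in seq_len(nrow(segs))) {
    if (!(segs$role[i] %in% roles)) next
    n <- segs$end[i] - segs$start[i] + 1L
    if (n < L) {
      warning(sprintf("pose %d shorter than one window; skipped", i),
              call. = FALSE)
      next
    }
    k <- floor((n - L) / S) + 1L
    starts <- segs$start[i] + (seq_len(k) - 1L) * S
    rows[[length(rows) + 1L]] <- data.frame(
      segment = i, target_tpa = segs$target_tpa[i], role = segs$role[i],
      start = starts, end = starts + L - 1L, window_index = seq_len(k))
  }
  if (!length(rows)) {
    return(data.frame(segment = integer(0), target_tpa = numeric(0),
                      role = character(0), start = integer(0),
                      end = integer(0), window_index = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
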