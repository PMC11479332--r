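#' Pose protocol
#'
#' An ordered sequence of held postures. Each segment has a target transverse
#' pelvic angle (TPA), a hold duration and a within-hold jitter level; during
#' simulation the realized angle is a slow bounded drift around the target,
#' clipped so it never deviates more than 5 degrees (the experimenter
#' correction rule).
#'
#' @param target_tpa Numeric vector of target TPAs, degrees, each in
#'   (-180, 180].
#' @param duration Hold durations, seconds (recycled).
#' @param jitter_sd Drift scale, degrees (recycled).
#' @param role Segment role, `"primary"` or `"intermediate"` (recycled).
#'
#' @return A `pose_protocol`: data.frame with columns `target_tpa`,
#'   `duration`, `jitter_sd`, `role`.
#' @export
pose_protocol <- function(target_tpa, duration = 180, jitter_sd = 1,
                          role = "primary") {
  if (any(duration <= 0)) stop("durations must be positive", call. = FALSE)
  if (any(abs(target_tpa) > 180)) {
    stop("|target_tpa| must be <= 180 degrees", call. = FALSE)
  }
  out <- data.frame(target_tpa = target_tpa,
                    duration = rep_len(duration, length(target_tpa)),
                    jitter_sd = rep_len(jitter_sd, length(target_tpa)),
                    role = rep_len(role, length(target_tpa)),
                    stringsAsFactors = FALSE)
  class(out) <- c("pose_protocol", "data.frame")
  out
}

#' Phase One pose protocol
#'
#' The structured protocol: 11 unique primary TPA targets (0, +/-15, +/-30,
#' +/-45, +/-60, +/-90 degrees) each held for three minutes, interleaved with
#' one-minute intermediate holds. Intermediates are supine, except a
#' right-side 90-degree hold before the +90 primary and a left-side 90-degree
#' hold before the -90 primary, so all three intermediate postures occur.
#'
#' @param seed Integer seed (kept for interface symmetry; the protocol itself
#'   is deterministic, only within-hold jitter uses the recording seed).
#' @param jitter_sd Within-hold drift scale, degrees.
#' @return A [pose_protocol()].
#' @examples
#' p <- phase_one_protocol()
#' sum(p$role == "primary") # 11
#' @export
phase_one_protocol <- function(seed = 1L, jitter_sd = 1) {
  primaries <- c(0, 15, -15, 30, -30, 45, -45, 60, -60, 90, -90)
  tpa <- numeric(0); dur <- numeric(0); role <- character(0)
  for (i in seq_along(primaries)) {
    if (i > 1L) {
      inter <- if (primaries[i] == 90) 90 else if (primaries[i] == -90) -90 else 0
      tpa <- c(tpa, inter); dur <- c(dur, 60); role <- c(role, "intermediate")
    }
    tpa <- c(tpa, primaries[i]); dur <- c(dur, 180); role <- c(role, "primary")
  }
  pose_protocol(tpa, duration = dur, jitter_sd = jitter_sd, role = role)
}

#' Phase Two pose protocol
#'
#' Free-choice postures: `n_poses` targets drawn uniformly from
#' (-180, 180] degrees, each held for three minutes.
#'
#' @param seed Integer seed controlling the drawn angles.
#' @param n_poses Number of poses (default 10).
#' @param jitter_sd Within-hold drift scale, degrees.
#' @return A [pose_protocol()].
#' @examples
#' p <- phase_two_protocol(seed = 7)
#' nrow(p) # 10
#' @export
phase_two_protocol <- function(seed = 1L, n_poses = 10, jitter_sd = 1) {
  if (n_poses < 1) stop("n_poses must be >= 1", call. = FALSE)
  angles <- with_local_seed(as.integer(seed), {
    180 - stats::runif(n_poses) * 360  # uniform on (-180, 180]
  })
  pose_protocol(angles, duration = 180, jitter_sd = jitter_sd,
                role = "primary")
}
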