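#' Simulate one held pose on the instrumented bed
#'
#' Forward physical model of the four-channel load-cell signal for a person
#' holding a fixed transverse pelvic angle (TPA). The combined bed+occupant
#' centre of mass (CoM) is placed from the participant's mass, longitudinal
#' position and TPA-dependent lateral shift; static corner forces are the
#' unique weight distribution that reproduces that CoM under the moment
#' balance about both bed axes with zero diagonal imbalance. Respiration
#' moves the CoM sinusoidally along the direction given by the participant's
#' `resp_angle_map(TPA)`; the cardiac cycle modulates the total vertical
#' force; white sensor noise is added per channel.
#'
#' The realized TPA drifts slowly around the target (bounded random walk)
#' but never deviates more than 5 degrees, mimicking experimenter
#' correction.
#'
#' @param participant A [virtual_participant()].
#' @param bed A [bed_model()].
#' @param tpa Target TPA, degrees, in (-180, 180].
#' @param duration Hold duration, seconds; must cover at least one breath.
#' @param rate Sampling rate, Hz (default 50).
#' @param jitter_sd Drift scale of the realized TPA, degrees (0 = hold the
#'   target exactly).
#' @param seed Seed for jitter and noise; defaults to the participant seed.
#' @param participant_id Identifier stored in the recording.
#' @param phase Protocol phase label, `"one"` or `"two"`.
#'
#' @return A `simulated_recording`: list with `force` (data.frame `time`,
#'   `LH`, `RH`, `LF`, `RF` in newtons, 1/rate spacing), `truth_tpa`
#'   (degrees per sample), `segments` (per-pose index table), `rate`, `bed`,
#'   `participant_id`, `phase`.
#' @examples
#' rec <- simulate_pose(virtual_participant(seed = 1), bed_model(),
#'                      tpa = 30, duration = 10)
#' @export
simulate_pose <- function(participant, bed, tpa, duration, rate = 50,
                          jitter_sd = 0, seed = NULL,
                          participant_id = "p1", phase = "one") {
  proto <- pose_protocol(tpa, duration = duration, jitter_sd = jitter_sd)
  simulate_protocol(participant, bed, proto, rate = rate, seed = seed,
                    participant_id = participant_id, phase = phase)
}

#' Simulate a full pose protocol
#'
#' Concatenates [simulate_pose()]-style segments for every row of a
#' [pose_protocol()], with a shared time axis and a per-sample ground-truth
#' TPA stream.
#'
#' @inheritParams simulate_pose
#' @param protocol A [pose_protocol()].
#' @return A `simulated_recording` (see [simulate_pose()]).
#' @export
simulate_protocol <- function(participant, bed, protocol, rate = 50,
                              seed = NULL, participant_id = "p1",
                              phase = "one") {
  stopifnot(inherits(participant, "virtual_participant"),
            inherits(bed, "bed_model"), inherits(protocol, "pose_protocol"))
  if (rate <= 0) stop("sampling rate must be positive", call. = FALSE)
  if (any(protocol$duration <= 0)) {
    stop("segment durations must be positive", call. = FALSE)
  }
  if (any(protocol$duration < 1 / participant$resp_rate)) {
    stop("each segment must cover at least one breath period", call. = FALSE)
  }
  seed <- seed %||% participant$seed

  chunks <- vector("list", nrow(protocol))
  seg_tab <- protocol
  seg_tab$start <- NA_integer_
  seg_tab$end <- NA_integer_
  offset <- 0L
  t_offset <- 0
  for (i in seq_len(nrow(protocol))) {
    seg <- simulate_segment(participant, bed,
                            target = protocol$target_tpa[i],
                            duration = protocol$duration[i], rate = rate,
                            jitter_sd = protocol$jitter_sd[i],
                            seed = derive_seed(seed, i),
                            t0 = t_offset)
    chunks[[i]] <- seg
    seg_tab$start[i] <- offset + 1L
    seg_tab$end[i] <- offset + nrow(seg$force)
    offset <- seg_tab$end[i]
    t_offset <- t_offset + protocol$duration[i]
  }
  force <- do.call(rbind, lapply(chunks, `[[`, "force"))
  rownames(force) <- NULL
  rec <- list(force = force,
              truth_tpa = unlist(lapply(chunks, `[[`, "truth_tpa"),
                                 use.names = FALSE),
              segments = seg_tab, rate = rate, bed = bed,
              participant_id = participant_id, phase = phase)
  class(rec) <- "simulated_recording"
  rec
}

# One protocol segment: realized TPA path, CoM path, corner-force inversion.
simulate_segment <- function(participant, bed, target, duration, rate,
                             jitter_sd, seed, t0 = 0) {
  n <- round(duration * rate)
  t <- t0 + (seq_len(n) - 1L) / rate
  p <- participant

  with_local_seed(seed, {
    tpa <- target + tpa_jitter_path(n, rate, jitter_sd)

    # body CoM in bed coordinates, then combined with the frame (at origin)
    m <- p$mass; M <- bed$frame_mass
    x_body <- p$lateral_shift_coeff * tpa * pi / 180
    y_body <- p$com_longitudinal_frac * bed$length_l
    x_c <- x_body * m / (m + M)
    y_c <- rep(y_body * m / (m + M), n)

    # respiration: CoM oscillation along the TPA-dependent orientation
    theta <- p$resp_angle_map(tpa) * pi / 180
    s <- p$resp_amplitude * sin(2 * pi * p$resp_rate * t)
    x <- x_c + s * cos(theta)
    y <- y_c + s * sin(theta)

    a <- 2 * x / bed$width_w
    b <- 2 * y / bed$length_l
    if (any(abs(x) > bed$width_w / 2) || any(abs(y) > bed$length_l / 2) ||
        any(abs(a) + abs(b) > 1)) {
      stop("configured CoM path leaves the supported bed footprint",
           call. = FALSE)
    }

    W <- (m + M) * bed$gravity
    total <- W + p$cardiac_amplitude * sin(2 * pi * p$cardiac_rate * t)
    LH <- total * (1 + a + b) / 4
    RH <- total * (1 - a + b) / 4
    LF <- total * (1 + a - b) / 4
    RF <- total * (1 - a - b) / 4
    if (p$noise_sd > 0) {
      LH <- LH + stats::rnorm(n, 0, p$noise_sd)
      RH <- RH + stats::rnorm(n, 0, p$noise_sd)
      LF <- LF + stats::rnorm(n, 0, p$noise_sd)
      RF <- RF + stats::rnorm(n, 0, p$noise_sd)
    }
    list(force = data.frame(time = t, LH = LH, RH = RH, LF = LF, RF = RF),
         truth_tpa = tpa)
  })
}

# Bounded slow drift: random walk at 1 Hz knots, clamped into +/-4.5 deg,
# linearly interpolated to the sampling rate. Zero jitter_sd -> flat path.
tpa_jitter_path <- function(n, rate, jitter_sd) {
  if (jitter_sd <= 0 || n < 2) return(rep(0, n))
  n_knots <- max(2L, ceiling(n / rate) + 1L)
  lim <- 4.5
  steps <- stats::rnorm(n_knots, 0, jitter_sd)
  path <- numeric(n_knots)
  for (k in 2:n_knots) {
    path[k] <- min(max(path[k - 1] + steps[k], -lim), lim)
  }
  stats::approx(seq(0, by = rate, length.out = n_knots), path,
                xout = seq_len(n) - 1L, rule = 2)$y
}

#' Generate a synthetic cohort
#'
#' Draws `n` virtual participants with anthropometrics in the range of the
#' reference cohort (height 174.4 +/- 10.6 cm, mass 77.9 +/- 19.2 kg) and
#' simulates a Phase One (structured 11-pose protocol) and a Phase Two
#' (10 free poses) recording for each. Per-participant seeds are derived
#' deterministically from `master_seed`.
#'
#' @param n Number of participants (>= 2; leave-one-participant-out needs at
#'   least two).
#' @param bed A [bed_model()].
#' @param master_seed Integer master seed.
#' @param rate Sampling rate, Hz.
#' @param noise_sd Per-channel sensor noise, newtons.
#' @param jitter_sd Within-hold TPA drift scale, degrees.
#' @param pose_duration Primary hold duration, seconds.
#' @param n_phase_two Number of Phase Two free poses.
#' @return A `cohort`: list with `participants` (list of
#'   [virtual_participant()]) and `recordings` (per participant, list with
#'   elements `one` and `two`, each a `simulated_recording`).
#' @export
generate_cohort <- function(n, bed = bed_model(), master_seed = 1L,
                            rate = 50, noise_sd = 0.2, jitter_sd = 1,
                            pose_duration = 180, n_phase_two = 10) {
  if (n < 2) stop("a cohort needs at least 2 participants", call. = FALSE)
  participants <- vector("list", n)
  recordings <- vector("list", n)
  ids <- sprintf("p%02d", seq_len(n))
  for (i in seq_len(n)) {
    sd_i <- derive_seed(master_seed, i)
    participants[[i]] <- with_local_seed(sd_i, {
      height <- min(max(stats::rnorm(1, 1.744, 0.106), 1.50), 2.00)
      mass <- min(max(stats::rnorm(1, 77.9, 19.2), 45), 125)
      virtual_participant(
        mass = mass, height = height,
        com_longitudinal_frac = stats::runif(1, 0.05, 0.15),
        lateral_shift_coeff = stats::runif(1, 0.04, 0.06),
        resp_rate = stats::runif(1, 0.15, 0.35),
        resp_amplitude = stats::runif(1, 0.003, 0.006),
        cardiac_rate = stats::runif(1, 0.9, 1.4),
        cardiac_amplitude = stats::runif(1, 0.3, 0.8),
        noise_sd = noise_sd, seed = sd_i)
    })
    p1 <- phase_one_protocol(jitter_sd = jitter_sd)
    p1$duration[p1$role == "primary"] <- pose_duration
    p1$duration[p1$role == "intermediate"] <- max(pose_duration / 3, 10)
    p2 <- phase_two_protocol(seed = derive_seed(sd_i, 1001L),
                             n_poses = n_phase_two, jitter_sd = jitter_sd)
    p2$duration <- pose_duration
    recordings[[i]] <- list(
      one = simulate_protocol(participants[[i]], bed, p1, rate = rate,
                              seed = derive_seed(sd_i, 1L),
                              participant_id = ids[i], phase = "one"),
      two = simulate_protocol(participants[[i]], bed, p2, rate = rate,
                              seed = derive_seed(sd_i, 2L),
                              participant_id = ids[i], phase = "two"))
  }
  structure(list(participants = stats::setNames(participants, ids),
                 recordings = stats::setNames(recordings, ids),
                 bed = bed, master_seed = as.integer(master_seed)),
            class = "cohort")
}
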