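#' @keywords internal
feature_names <- function() {
  c("meanCoM_x", "meanCoM_y", "ratio_meanCoM",
    "stdCoM_x", "stdCoM_y", "ratio_stdCoM",
    "CoM_resp_ANG", "stdCoM_resp_ANG",
    "rmsCoM_resp_x", "rmsCoM_resp_y", "ratio_rmsCoM_resp",
    "rmsPulse")
}

# wrap an angle into (-180, 180]
wrap_angle <- function(a) {
  w <- (a + 180) %% 360 - 180
  ifelse(w == -180, 180, w)
}

rms <- function(x) sqrt(mean(x^2))

#' Extract the 12-feature vector for one window
#'
#' Computes, for one 45-s force window: mean and standard deviation of
#' `CoM_x` and `CoM_y` with their y/x quotients; the mean and standard
#' deviation of the per-breath respiration CoM angle (each breath taken
#' from an end-exhalation maximum to the following end-inhalation minimum);
#' the root-mean-square of the mean-centred respiration-band CoM components
#' normalised to the recording's 97th-percentile amplitude, with their
#' quotient; and the root-mean-square of the cardiac-band corner-force
#' signals (`rmsPulse`).
#'
#' Undefined values (no detected breath, zero denominator) are returned as
#' `NA` and can be filled by [impute_missing()].
#'
#' @param force Force window data.frame (`LH`, `RH`, `LF`, `RF`).
#' @param bed A [bed_model()].
#' @param spec Respiration [filter_spec()].
#' @param pulse_band Cardiac pass band, Hz.
#' @param rate Sampling rate, Hz.
#' @param resp_norm Optional length-2 numeric, per-axis 97th-percentile
#'   normalisation scale for the respiration rms (computed from the window
#'   itself when omitted).
#' @param precomputed Optional list with elements `com`, `resp`, `pulse`
#'   already restricted to the window (used by the recording-level driver to
#'   avoid re-filtering per window).
#' @return One-row data.frame with the 12 feature columns.
#' @export
extract_features <- function(force, bed, spec = filter_spec(),
                             pulse_band = c(0.8, 2.5), rate = 50,
                             resp_norm = NULL, precomputed = NULL) {
  if (is.null(precomputed)) {
    com <- compute_com(force, bed)
    resp <- isolate_respiration(com, spec, rate)
    pulse <- pulse_band_filter(force, pulse_band, rate)
  } else {
    com <- precomputed$com; resp <- precomputed$resp
    pulse <- precomputed$pulse
  }

  mx <- mean(com$CoM_x); my <- mean(com$CoM_y)
  sx <- stats::sd(com$CoM_x); sy <- stats::sd(com$CoM_y)
  ratio_mean <- if (mx != 0) my / mx else NA_real_
  ratio_std <- if (sx > 0) sy / sx else NA_real_

  rx <- resp$CoM_resp_x - mean(resp$CoM_resp_x)
  ry <- resp$CoM_resp_y - mean(resp$CoM_resp_y)
  if (is.null(resp_norm)) {
    resp_norm <- c(stats::quantile(abs(rx), 0.97, names = FALSE),
                   stats::quantile(abs(ry), 0.97, names = FALSE))
  }
  rms_x <- if (resp_norm[1] > 0) rms(rx) / resp_norm[1] else NA_real_
  rms_y <- if (resp_norm[2] > 0) rms(ry) / resp_norm[2] else NA_real_
  ratio_rms <- if (!is.na(rms_x) && !is.na(rms_y) && rms_x > 0) {
    rms_y / rms_x
  } else NA_real_

  ang <- breath_angles(data.frame(CoM_resp_x = rx, CoM_resp_y = ry))
  ang_mean <- if (length(ang)) mean(ang) else NA_real_
  ang_sd <- if (length(ang) >= 2) stats::sd(ang) else NA_real_

  pv <- unlist(pulse[c("LH", "RH", "LF", "RF")], use.names = FALSE)

  data.frame(meanCoM_x = mx, meanCoM_y = my, ratio_meanCoM = ratio_mean,
             stdCoM_x = sx, stdCoM_y = sy, ratio_stdCoM = ratio_std,
             CoM_resp_ANG = ang_mean, stdCoM_resp_ANG = ang_sd,
             rmsCoM_resp_x = rms_x, rmsCoM_resp_y = rms_y,
             ratio_rmsCoM_resp = ratio_rms, rmsPulse = rms(pv))
}

#' Extract the feature table for a whole recording
#'
#' Windows the recording per pose ([segment_windows()]), filters each pose
#' segment once (respiration low-pass, optionally personalised from the
#' recording's own spectrum, and cardiac band-pass), computes the
#' 12-feature vector for every window, attaches the window-mean ground-truth
#' TPA, and imputes undefined values within each pose.
#'
#' @param recording A `simulated_recording`.
#' @param wspec A [window_spec()].
#' @param spec A [filter_spec()], or `"auto"` for the personalised design
#'   (see [personalize_filter()]).
#' @param pulse_band Cardiac pass band, Hz.
#' @param impute Impute missing values per pose (default TRUE).
#' @param roles Segment roles to include.
#' @return Data.frame: 12 feature columns plus `truth_tpa`,
#'   `participant_id`, `phase`, `segment`, `window_index`.
#' @export
extract_recording_features <- function(recording, wspec = window_spec(),
                                       spec = "auto",
                                       pulse_band = c(0.8, 2.5),
                                       impute = TRUE,
                                       roles = c("primary", "intermediate")) {
  bed <- recording$bed
  rate <- recording$rate
  com <- compute_com(recording$force, bed)
  if (identical(spec, "auto")) spec <- personalize_filter(com, rate)
  wins <- segment_windows(recording, wspec, roles = roles)
  if (!nrow(wins)) {
    stop("recording contains no windowable pose", call. = FALSE)
  }

  # filter per pose segment; collect per-segment-centred respiration values
  # for the recording-level 97th-percentile normalisation
  segs <- sort(unique(wins$segment))
  resp_by_seg <- list(); pulse_by_seg <- list()
  abs_rx <- list(); abs_ry <- list()
  for (s in segs) {
    i0 <- recording$segments$start[s]; i1 <- recording$segments$end[s]
    idx <- i0:i1
    r <- isolate_respiration(com[idx, , drop = FALSE], spec, rate)
    resp_by_seg[[as.character(s)]] <- r
    pulse_by_seg[[as.character(s)]] <-
      pulse_band_filter(recording$force[idx, , drop = FALSE], pulse_band,
                        rate)
    abs_rx[[as.character(s)]] <- abs(r$CoM_resp_x - mean(r$CoM_resp_x))
    abs_ry[[as.character(s)]] <- abs(r$CoM_resp_y - mean(r$CoM_resp_y))
  }
  resp_norm <- c(stats::quantile(unlist(abs_rx), 0.97, names = FALSE),
                 stats::quantile(unlist(abs_ry), 0.97, names = FALSE))

  rows <- vector("list", nrow(wins))
  for (k in seq_len(nrow(wins))) {
    s <- wins$segment[k]
    i0 <- recording$segments$start[s]
    a <- wins$start[k] - i0 + 1L
    b <- wins$end[k] - i0 + 1L
    idx <- wins$start[k]:wins$end[k]
    pre <- list(com = com[idx, , drop = FALSE],
                resp = resp_by_seg[[as.character(s)]][a:b, , drop = FALSE],
                pulse = pulse_by_seg[[as.character(s)]][a:b, , drop = FALSE])
    fv <- extract_features(recording$force[idx, , drop = FALSE], bed,
                           spec, pulse_band, rate, resp_norm = resp_norm,
                           precomputed = pre)
    fv$truth_tpa <- wrap_angle(mean(recording$truth_tpa[idx]))
    rows[[k]] <- fv
  }
  out <- cbind(do.call(rbind, rows),
               participant_id = recording$participant_id,
               phase = recording$phase,
               segment = wins$segment, window_index = wins$window_index,
               role = wins$role)
  rownames(out) <- NULL
  if (impute) out <- impute_by_pose(out)
  out
}

#' Impute undefined feature values within a pose
#'
#' Replaces `NA` feature fields by linear interpolation over the pose's
#' window sequence; at the edges the nearest defined value is carried. A
#' pose in which a field is undefined for every window is dropped with a
#' warning.
#'
#' @param features Feature data.frame for one pose (windows in order).
#' @return The completed data.frame.
#' @export
impute_missing <- function(features) {
  fn <- intersect(feature_names(), names(features))
  keep <- TRUE
  for (f in fn) {
    v <- features[[f]]
    if (!anyNA(v)) next
    if (all(is.na(v))) {
      warning(sprintf("feature %s undefined for an entire pose; pose dropped",
                      f), call. = FALSE)
      keep <- FALSE
      break
    }
    if (sum(!is.na(v)) == 1L) {
      features[[f]][is.na(v)] <- v[!is.na(v)]
    } else {
      features[[f]] <- stats::approx(which(!is.na(v)), v[!is.na(v)],
                                     xout = seq_along(v), rule = 2)$y
    }
  }
  if (!keep) features[0, , drop = FALSE] else features
}

# apply impute_missing per (participant, phase, segment) group
impute_by_pose <- function(features) {
  key <- interaction(features$participant_id, features$phase,
                     features$segment, drop = TRUE)
  parts <- lapply(split(features, key), impute_missing)
  out <- do.call(rbind, parts)
  out <- out[order(out$participant_id, out$phase, out$segment,
                   out$window_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract features for every recording of a cohort
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param ... Passed to [extract_recording_features()].
#' @return Combined feature data.frame over all participants and phases.
#' @export
extract_cohort_features <- function(cohort, ...) {
  rows <- list()
  for (id in names(cohort$recordings)) {
    for (ph in c("one", "two")) {
      rows[[paste(id, ph)]] <-
        extract_recording_features(cohort$recordings[[id]][[ph]], ...)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank feature importance with gradient-boosted trees
#'
#' Fits a multiclass gradient-boosted tree model to the feature table and
#' returns the impurity (gain) importance of each feature, normalised to
#' sum to one, in descending order.
#'
#' @param features Data.frame containing the 12 feature columns.
#' @param labels Class labels (factor or character), one per row.
#' @param nrounds Boosting rounds.
#' @param seed RNG seed for the fit.
#' @return Data.frame with columns `feature`, `importance`, sorted
#'   descending; importances sum to 1.
#' @export
rank_feature_importance <- function(features, labels, nrounds = 50,
                                    seed = 1L) {
  y <- factor(labels)
  if (nlevels(y) < 2) {
    stop("feature importance needs at least 2 classes", call. = FALSE)
  }
  fn <- intersect(feature_names(), names(features))
  x <- as.matrix(features[fn])
  fit <- with_local_seed(seed, {
    dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L)
    xgboost::xgb.train(params = list(objective = "multi:softprob",
                                     num_class = nlevels(y), max_depth = 3,
                                     eta = 0.3, nthread = 1,
                                     seed = as.integer(seed)),
                       data = dtrain, nrounds = nrounds)
  })
  imp <- xgboost::xgb.importance(model = fit)
  score <- stats::setNames(rep(0, length(fn)), fn)
  score[imp$Feature] <- imp$Gain
  score <- score / sum(score)
  out <- data.frame(feature = names(score), importance = as.numeric(score))
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  out
}
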