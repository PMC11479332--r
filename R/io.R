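#' Write and read load-cell recordings as CSV
#'
#' Force traces use the header `time_s,LH_N,RH_N,LF_N,RF_N` with one row per
#' 50 Hz sample; ground-truth files use `time_s,tpa_deg`. Values are written
#' with fixed formatting so identical simulations produce byte-identical
#' files.
#'
#' @param recording A `simulated_recording` (see [simulate_pose()]).
#' @param force_path Output path for the force CSV.
#' @param truth_path Output path for the ground-truth CSV (optional).
#' @return Invisibly, the force path.
#' @export
write_force_csv <- function(recording, force_path, truth_path = NULL) {
  f <- recording$force
  lines <- c("time_s,LH_N,RH_N,LF_N,RF_N",
             sprintf("%.4f,%.6f,%.6f,%.6f,%.6f",
                     f$time, f$LH, f$RH, f$LF, f$RF))
  writeLines(lines, force_path)
  if (!is.null(truth_path)) {
    tl <- c("time_s,tpa_deg",
            sprintf("%.4f,%.6f", f$time, recording$truth_tpa))
    writeLines(tl, truth_path)
  }
  invisible(force_path)
}

#' @rdname write_force_csv
#' @param path Path of a force CSV written by [write_force_csv()].
#' @param rate Sampling rate, Hz.
#' @return `read_force_csv()`: a force data.frame with columns `time`, `LH`,
#'   `RH`, `LF`, `RF`.
#' @export
read_force_csv <- function(path, rate = 50) {
  d <- utils::read.csv(path)
  stopifnot(identical(names(d), c("time_s", "LH_N", "RH_N", "LF_N", "RF_N")))
  data.frame(time = d$time_s, LH = d$LH_N, RH = d$RH_N,
             LF = d$LF_N, RF = d$RF_N)
}

#' Write a cohort to disk
#'
#' One force and one truth CSV per participant-phase, plus a JSON manifest
#' holding the bed geometry and every participant's parameters and seed.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(master_seed = cohort$master_seed,
                   bed = cohort$bed[c("length_l", "width_w", "frame_mass",
                                      "gravity")],
                   participants = list())
  for (id in names(cohort$recordings)) {
    for (ph in c("one", "two")) {
      rec <- cohort$recordings[[id]][[ph]]
      write_force_csv(rec,
                      file.path(dir, sprintf("%s_phase_%s_force.csv", id, ph)),
                      file.path(dir, sprintf("%s_phase_%s_truth.csv", id, ph)))
    }
    p <- cohort$participants[[id]]
    manifest$participants[[id]] <-
      p[c("mass", "height", "com_longitudinal_frac", "lateral_shift_coeff",
          "resp_rate", "resp_amplitude", "cardiac_rate", "cardiac_amplitude",
          "noise_sd", "seed")]
  }
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Write a feature table as CSV
#'
#' One row per analysis window: the 12 features plus `truth_tpa`,
#' `participant_id`, `phase` and `window_index`, with 9-significant-digit
#' numeric formatting.
#'
#' @param features Feature data.frame from [extract_recording_features()] or
#'   [extract_cohort_features()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_feature_csv <- function(features, path) {
  num <- vapply(features, is.numeric, logical(1))
  out <- features
  out[num] <- lapply(out[num], function(x) signif(x, 9))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
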