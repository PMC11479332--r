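#' Centre of mass from four corner forces
#'
#' Converts the four vertical corner forces into the combined bed+occupant
#' centre-of-mass (CoM) coordinates by moment balance:
#' \deqn{CoM_x = \frac{w}{2}\,\frac{LH + LF - RH - RF}{LH + LF + RH + RF},
#'       \qquad
#'       CoM_y = \frac{l}{2}\,\frac{LH + RH - LF - RF}{LH + LF + RH + RF}}
#' where `w` and `l` are the load-cell spacings along the bed width and
#' length. `CoM_x` runs parallel to the bed width (positive towards the left
#' sensors) and `CoM_y` parallel to the bed length (positive towards the
#' head).
#'
#' @param force Force data.frame with columns `LH`, `RH`, `LF`, `RF`
#'   (newtons), e.g. the `force` element of a `simulated_recording`.
#' @param bed A [bed_model()].
#' @return A data.frame with columns `CoM_x`, `CoM_y` (metres), one row per
#'   sample.
#' @examples
#' f <- data.frame(LH = 100, RH = 100, LF = 100, RF = 100)
#' compute_com(f, bed_model()) # (0, 0)
#' @export
compute_com <- function(force, bed) {
  stopifnot(all(c("LH", "RH", "LF", "RF") %in% names(force)),
            inherits(bed, "bed_model"))
  total <- force$LH + force$LF + force$RH + force$RF
  bad <- which(total <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive total force at sample %d", bad[1]),
         call. = FALSE)
  }
  data.frame(
    CoM_x = (bed$width_w / 2) * (force$LH + force$LF - force$RH - force$RF) /
      total,
    CoM_y = (bed$length_l / 2) * (force$LH + force$RH - force$LF - force$RF) /
      total)
}
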