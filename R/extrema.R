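#' Detect breath extrema in a respiration-band signal
#'
#' Finds the zero crossings of the first-order forward difference. Maxima
#' (sign change + to -) mark end of exhalation, minima (- to +) end of
#' inhalation. Exact zero differences carry the previous sign so plateaus do
#' not spawn spurious extrema. Alternation is enforced: of any two adjacent
#' same-type extrema the less prominent one (lower maximum / higher minimum)
#' is dropped.
#'
#' @param x Numeric respiration-band signal (length >= 3).
#' @return A list with integer vectors `tmax` and `tmin` (sample indices,
#'   strictly increasing, alternating). Monotone signals yield empty
#'   vectors.
#' @examples
#' t <- seq(0, 45, by = 0.02)
#' ex <- detect_breath_extrema(sin(2 * pi * 0.25 * t))
#' @export
detect_breath_extrema <- function(x) {
  if (length(x) < 3) stop("signal must have at least 3 samples", call. = FALSE)
  d <- diff(x)
  s <- sign(d)
  # carry previous sign through exact zeros
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  idx <- which(s[-1] != s[-length(s)] & s[-1] != 0 & s[-length(s)] != 0) + 1L
  if (!length(idx)) return(list(tmax = integer(0), tmin = integer(0)))
  type <- ifelse(s[idx - 1L] > 0, "max", "min")

  # enforce alternation: drop the less prominent of same-type neighbours
  keep <- rep(TRUE, length(idx))
  last <- 1L
  for (i in seq_along(idx)[-1]) {
    if (type[i] == type[last]) {
      better_i <- if (type[i] == "max") x[idx[i]] >= x[idx[last]] else
        x[idx[i]] <= x[idx[last]]
      if (better_i) { keep[last] <- FALSE; last <- i } else keep[i] <- FALSE
    } else last <- i
  }
  idx <- idx[keep]; type <- type[keep]
  list(tmax = idx[type == "max"], tmin = idx[type == "min"])
}

#' Respiration CoM angle for one breath
#'
#' Angle of the principal axis of the ellipse traced by the respiration-band
#' CoM over one breath, taken from the end-exhalation maximum `tmax` to the
#' subsequent end-inhalation minimum `tmin`:
#' \deqn{\arctan\frac{CoM_{resp,y}(t_{max}) - CoM_{resp,y}(t_{min})}
#'                   {CoM_{resp,x}(t_{max}) - CoM_{resp,x}(t_{min})}}
#' in degrees, range (-90, 90]. A zero x-difference returns the vertical
#' limit 90 degrees.
#'
#' @param resp Data.frame with columns `CoM_resp_x`, `CoM_resp_y` (from
#'   [isolate_respiration()]).
#' @param tmax,tmin Sample indices of the breath maximum and the following
#'   minimum.
#' @return Angle in degrees.
#' @examples
#' resp <- data.frame(CoM_resp_x = c(1, 0), CoM_resp_y = c(1, 0))
#' com_resp_angle(resp, 1, 2) # 45
#' @export
com_resp_angle <- function(resp, tmax, tmin) {
  stopifnot(tmax >= 1, tmin >= 1, tmax <= nrow(resp), tmin <= nrow(resp))
  dx <- resp$CoM_resp_x[tmax] - resp$CoM_resp_x[tmin]
  dy <- resp$CoM_resp_y[tmax] - resp$CoM_resp_y[tmin]
  if (dx == 0) return(90)
  atan(dy / dx) * 180 / pi
}

# Per-breath angles for a respiration segment: extrema on the
# dominant-variance axis define the breath timing, both axes are read at
# those times; each maximum is paired with the next minimum.
breath_angles <- function(resp) {
  vx <- stats::var(resp$CoM_resp_x)
  vy <- stats::var(resp$CoM_resp_y)
  axis <- if (isTRUE(vy > vx)) resp$CoM_resp_y else resp$CoM_resp_x
  ex <- detect_breath_extrema(axis)
  if (!length(ex$tmax) || !length(ex$tmin)) return(numeric(0))
  angles <- numeric(0)
  for (tm in ex$tmax) {
    nxt <- ex$tmin[ex$tmin > tm]
    if (length(nxt)) angles <- c(angles, com_resp_angle(resp, tm, nxt[1]))
  }
  angles
}
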