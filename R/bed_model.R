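#' Bed geometry and frame model
#'
#' Describes a hospital bed instrumented with one single-axis load cell under
#' each of the four legs. `length_l` and `width_w` are the load-cell spacings
#' along the bed length (head-foot) and width (left-right); together with the
#' frame mass they fix the static force distribution for any occupant
#' centre of mass (CoM).
#'
#' @param length_l Load-cell spacing along the bed length, metres.
#' @param width_w Load-cell spacing along the bed width, metres.
#' @param frame_mass Mass of the bed frame, kg; assumed centred on the
#'   footprint.
#' @param gravity Gravitational acceleration, m/s^2.
#'
#' @return An object of class `bed_model`.
#' @examples
#' bed <- bed_model()
#' bed$length_l
#' @export
bed_model <- function(length_l = 2.0, width_w = 0.9, frame_mass = 60,
                      gravity = 9.81) {
  stopifnot(is.numeric(length_l), length(length_l) == 1L,
            is.numeric(width_w), length(width_w) == 1L)
  if (length_l <= 0 || width_w <= 0) {
    stop("bed load-cell spacings must be positive", call. = FALSE)
  }
  if (frame_mass < 0) stop("frame_mass must be >= 0", call. = FALSE)
  structure(list(length_l = length_l, width_w = width_w,
                 frame_mass = frame_mass, gravity = gravity),
            class = "bed_model")
}

#' Default mapping from TPA to respiration-ellipse orientation
#'
#' Orientation (degrees, relative to the bed-width axis) of the line along
#' which the centre of mass oscillates with each breath, as a function of the
#' transverse pelvic angle (TPA). The map is strictly monotone over
#' (-180, 180], passes through 0 deg at supine, and stays inside (-90, 90) so
#' the principal-axis angle of the traced ellipse identifies it uniquely.
#' Human data give no quantitative TPA-to-orientation relation; this map is a
#' construction that makes the three coarse postures (and the finer side bins)
#' separable through the respiration-angle feature.
#'
#' @param tpa TPA in degrees.
#' @return Orientation in degrees, in (-90, 90).
#' @export
default_resp_angle_map <- function(tpa) {
  72 * sin(tpa * pi / 360)
}

#' Virtual participant for load-cell simulation
#'
#' Parameters of a simulated person lying on the instrumented bed. The
#' physical signal model is: a static CoM set by body mass, longitudinal
#' position and a TPA-dependent lateral shift; a respiration-driven CoM
#' oscillation of amplitude `resp_amplitude` along the direction
#' `resp_angle_map(TPA)`; a ballistocardiographic force sinusoid at
#' `cardiac_rate`; and additive white sensor noise per channel.
#'
#' @param mass Body mass, kg (40-130).
#' @param height Body height, metres.
#' @param com_longitudinal_frac Body CoM position along the bed length as a
#'   fraction of `length_l` measured from the bed centre towards the head
#'   (0 = centre).
#' @param lateral_shift_coeff Lateral CoM displacement per radian of TPA,
#'   metres/radian (rolling shifts weight towards the side rolled onto).
#' @param resp_rate Respiration rate, Hz (0.1-0.5).
#' @param resp_amplitude Peak CoM excursion per breath, metres.
#' @param resp_angle_map Function mapping TPA (degrees) to the orientation
#'   (degrees) of the respiratory CoM oscillation.
#' @param cardiac_rate Cardiac rate, Hz; must exceed `resp_rate`.
#' @param cardiac_amplitude Amplitude of the cardiac force sinusoid, newtons.
#' @param noise_sd Per-channel white noise standard deviation, newtons.
#' @param seed Integer seed for this participant's random components.
#'
#' @return An object of class `virtual_participant`.
#' @examples
#' p <- virtual_participant(mass = 70, height = 1.75, seed = 1)
#' @export
virtual_participant <- function(mass = 78, height = 1.74,
                                com_longitudinal_frac = 0.1,
                                lateral_shift_coeff = 0.05,
                                resp_rate = 0.25,
                                resp_amplitude = 0.004,
                                resp_angle_map = default_resp_angle_map,
                                cardiac_rate = 1.1,
                                cardiac_amplitude = 0.5,
                                noise_sd = 0.2,
                                seed = 1L) {
  if (mass < 40 || mass > 130) stop("mass must be in [40, 130] kg", call. = FALSE)
  if (resp_rate < 0.1 || resp_rate > 0.5) {
    stop("resp_rate must be in [0.1, 0.5] Hz", call. = FALSE)
  }
  if (resp_amplitude <= 0) stop("resp_amplitude must be > 0", call. = FALSE)
  if (cardiac_rate <= resp_rate) {
    stop("cardiac_rate must exceed resp_rate", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  stopifnot(is.function(resp_angle_map))
  structure(list(mass = mass, height = height,
                 com_longitudinal_frac = com_longitudinal_frac,
                 lateral_shift_coeff = lateral_shift_coeff,
                 resp_rate = resp_rate, resp_amplitude = resp_amplitude,
                 resp_angle_map = resp_angle_map,
                 cardiac_rate = cardiac_rate,
                 cardiac_amplitude = cardiac_amplitude,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "virtual_participant")
}
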