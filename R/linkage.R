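# Degree-based trig used throughout: every angle in the model (trunk, contact,
# release, seat angle) is handled in degrees end-to-end.
sind <- function(x) sinpi(x / 180)
cosd <- function(x) cospi(x / 180)
atand <- function(x) atan(x) * 180 / pi

#' Athlete segment lengths
#'
#' Bundles the three planar segment lengths of the propulsion model: trunk
#' (hip to acromion), upper arm, and forearm, all in millimetres. Lengths must
#' be positive; a trunk length outside 300--700 mm is accepted with a warning
#' since it is outside the plausible adult range.
#'
#' @param trunk_length Trunk (hip--acromion) length, mm.
#' @param upper_arm_length Upper-arm length, mm.
#' @param forearm_length Forearm length, mm.
#' @return An object of class `anthropometrics`.
#' @examples
#' anthropometrics(480, 310, 270)
#' @export
anthropometrics <- function(trunk_length, upper_arm_length, forearm_length) {
  lens <- c(trunk_length = trunk_length, upper_arm_length = upper_arm_length,
            forearm_length = forearm_length)
  if (!all(is.finite(lens))) {
    stop("anthropometric lengths must be finite numbers", call. = FALSE)
  }
  if (any(lens <= 0)) {
    stop("anthropometric lengths must be positive (mm)", call. = FALSE)
  }
  if (trunk_length < 300 || trunk_length > 700) {
    warning(sprintf("trunk_length = %.0f mm is outside the plausible 300-700 mm range",
                    trunk_length))
  }
  structure(as.list(lens), class = "anthropometrics")
}

#' Wheelchair set-up configuration
#'
#' One tested configuration of the four adjustable set-up parameters. Seat
#' height and depth are the vertical and horizontal distances from the rear of
#' the seat to the rear-wheel axle (mm); seat angle is the sagittal
#' inclination of the seat above horizontal (deg); tire pressure is in psi.
#'
#' @param seat_height Vertical rear-seat-to-axle distance, mm (> 0).
#' @param seat_depth Horizontal rear-seat-to-axle distance, mm (>= 0).
#' @param seat_angle Seat inclination above horizontal, deg.
#' @param tire_pressure Tire pressure, psi (> 0).
#' @return An object of class `setup_config`.
#' @examples
#' setup_config(400, 100, 10, 100)
#' @export
setup_config <- function(seat_height, seat_depth, seat_angle, tire_pressure) {
  vals <- c(seat_height = seat_height, seat_depth = seat_depth,
            seat_angle = seat_angle, tire_pressure = tire_pressure)
  if (!all(is.finite(vals))) {
    stop("set-up parameters must be finite numbers", call. = FALSE)
  }
  if (seat_height <= 0) stop("seat_height must be > 0 mm", call. = FALSE)
  if (seat_depth < 0) stop("seat_depth must be >= 0 mm", call. = FALSE)
  if (tire_pressure <= 0) stop("tire_pressure must be > 0 psi", call. = FALSE)
  structure(as.list(vals), class = "setup_config")
}

as_setup_config <- function(x) {
  if (inherits(x, "setup_config")) return(x)
  setup_config(x[["seat_height"]], x[["seat_depth"]],
               x[["seat_angle"]], x[["tire_pressure"]])
}

#' Shoulder position for a given trunk angle
#'
#' The hip is assumed coincident with the rear corner of the seat, so in the
#' axle-origin frame (x forward, y up) it sits at (-seat_depth, +seat_height)
#' and moves with seat depth and height. The trunk segment rotates about the
#' hip; trunk flexion (leaning forward) is positive, so the shoulder
#' (acromion) is at hip + trunk_length * (sin(theta), cos(theta)).
#'
#' @param anthro An [anthropometrics()] object (trunk length is used).
#' @param setup A [setup_config()] object.
#' @param trunk_angle Trunk angle from vertical, deg; flexion positive.
#'   Must lie in \[-30, 90\].
#' @return A list with `x_hs` (mm forward of the axle) and `y_hs` (mm above
#'   the axle).
#' @examples
#' shoulder_position(anthropometrics(500, 300, 260),
#'                   setup_config(400, 100, 10, 100), trunk_angle = 0)
#' @export
shoulder_position <- function(anthro, setup, trunk_angle) {
  setup <- as_setup_config(setup)
  if (!all(is.finite(trunk_angle))) {
    stop("trunk_angle must be finite", call. = FALSE)
  }
  if (any(trunk_angle < -30 | trunk_angle > 90)) {
    stop("trunk_angle must be within [-30, 90] degrees", call. = FALSE)
  }
  list(x_hs = -setup$seat_depth + anthro$trunk_length * sind(trunk_angle),
       y_hs = setup$seat_height + anthro$trunk_length * cosd(trunk_angle))
}

# Hand position relative to the axle for a trunk angle theta and a forearm
# orientation phi (both deg from vertical, forward positive). The upper arm
# hangs from the shoulder along the trunk direction; the forearm points from
# the elbow with orientation phi.
hand_position <- function(anthro, setup, theta, phi) {
  sh <- shoulder_position(anthro, setup, theta)
  list(hand_x = sh$x_hs - anthro$upper_arm_length * sind(theta) +
         anthro$forearm_length * sind(phi),
       hand_y = sh$y_hs - anthro$upper_arm_length * cosd(theta) +
         anthro$forearm_length * cosd(phi))
}

# Geometric hand angle from top dead center (deg, in-front positive) for the
# beta = 1 assumption; the principal-value arctangent of hand_x / hand_y.
base_hand_angle <- function(anthro, setup, theta, phi, context = "geometry") {
  h <- hand_position(anthro, setup, theta, phi)
  if (any(h$hand_y <= 0)) {
    stop(sprintf(paste0("degenerate geometry in %s: hand at or below axle ",
                        "height (hand_y = %.1f mm) for set-up ",
                        "(height %.0f, depth %.0f, angle %.1f, pressure %.0f)"),
                 context, min(h$hand_y), setup$seat_height, setup$seat_depth,
                 setup$seat_angle, setup$tire_pressure), call. = FALSE)
  }
  atand(h$hand_x / h$hand_y)
}

#' Predicted hand contact angle
#'
#' Contact angle on the wheel, measured about the axle from top dead center
#' (TDC; in-front positive, behind negative), predicted from the planar
#' trunk--upper-arm--forearm linkage and scaled by a dimensionless contact
#' coefficient `beta`. Two contact-geometry assumptions are supported:
#' `"original"`, where the forearm is perpendicular to the wheel tangent at
#' contact (forearm orientation -theta_TI from vertical), and `"altered"`,
#' where athletes with trunk flexion contact with the forearm approximately
#' parallel to the tangent (a 90-degree shift: orientation 90 - theta_TI).
#' `beta = 1` means the chosen assumption holds exactly.
#'
#' @param anthro An [anthropometrics()] object.
#' @param setup A [setup_config()] object.
#' @param theta_ti Initial (contact) trunk angle, deg, flexion positive.
#' @param beta Contact coefficient, dimensionless, in \[-0.5, 1.5\].
#' @param method `"original"` or `"altered"` contact assumption.
#' @return Contact angle in degrees, TDC convention.
#' @examples
#' a <- anthropometrics(500, 300, 280)
#' s <- setup_config(400, 100, 10, 100)
#' contact_angle(a, s, theta_ti = 20, beta = 1, method = "altered")
#' @export
contact_angle <- function(anthro, setup, theta_ti, beta = 1,
                          method = c("original", "altered")) {
  method <- match.arg(method)
  if (any(!is.finite(beta)) || any(beta < -0.5 | beta > 1.5)) {
    stop("beta must lie in [-0.5, 1.5]", call. = FALSE)
  }
  phi <- if (method == "altered") 90 - theta_ti else -theta_ti
  beta * base_hand_angle(anthro, setup, theta_ti, phi, context = "contact_angle")
}

#' Predicted hand release angle
#'
#' Release is assumed to occur when the forearm is parallel to the wheel
#' tangent with the trunk at its most flexed position, so the shoulder is at
#' its most forward point. The functional form matches the parallel-forearm
#' (altered) contact geometry evaluated at the release trunk angle
#' `theta_tr`, scaled by a release coefficient `beta_r`.
#'
#' @inheritParams contact_angle
#' @param theta_tr Release (most-flexed) trunk angle, deg.
#' @param beta_r Release coefficient, dimensionless, in \[-0.5, 1.5\].
#' @return Release angle in degrees, TDC convention.
#' @export
release_angle <- function(anthro, setup, theta_tr, beta_r = 1) {
  if (any(!is.finite(beta_r)) || any(beta_r < -0.5 | beta_r > 1.5)) {
    stop("beta_r must lie in [-0.5, 1.5]", call. = FALSE)
  }
  beta_r * base_hand_angle(anthro, setup, theta_tr, 90 - theta_tr,
                           context = "release_angle")
}

#' Construct an athlete
#'
#' An athlete couples segment lengths, the contact-geometry assumption, a
#' trunk-angle profile (contact and release trunk angles per stroke measured
#' at the three tested seat-angle levels), and -- once calibrated -- the
#' per-stroke contact and release coefficients.
#'
#' The trunk profile is a data frame with columns `level` (one of `"low"`,
#' `"current"`, `"high"`), `seat_angle` (the seat angle in degrees at which
#' that level was measured), `stroke` (1--3), `theta_ti` and `theta_tr`
#' (contact and release trunk angles, deg, flexion positive). For each row
#' `theta_tr >= theta_ti`: release happens at the most-flexed position.
#'
#' @param id Athlete identifier (character).
#' @param anthro An [anthropometrics()] object.
#' @param method `"original"` or `"altered"` contact assumption.
#' @param trunk_profile Trunk-angle profile data frame (see Details).
#' @param coefficients Optional calibrated coefficient set: data frame with
#'   columns `stroke`, `beta_contact`, `beta_release` (see
#'   [calibrate_athlete()]).
#' @return An object of class `athlete`.
#' @export
athlete <- function(id, anthro, method = c("original", "altered"),
                    trunk_profile, coefficients = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(anthro, "anthropometrics"))
  req <- c("level", "seat_angle", "stroke", "theta_ti", "theta_tr")
  if (!is.data.frame(trunk_profile) || !all(req %in% names(trunk_profile))) {
    stop("trunk_profile must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (!all(trunk_profile$level %in% c("low", "current", "high"))) {
    stop("trunk_profile$level must be one of 'low', 'current', 'high'",
         call. = FALSE)
  }
  if (any(trunk_profile$theta_tr < trunk_profile$theta_ti)) {
    stop("release trunk angle theta_tr must be >= contact trunk angle theta_ti",
         call. = FALSE)
  }
  structure(list(id = as.character(id), anthro = anthro, method = method,
                 trunk_profile = trunk_profile, coefficients = coefficients),
            class = "athlete")
}

#' @export
print.athlete <- function(x, ...) {
  cat(sprintf("<athlete %s> %s contact method; trunk %.0f / upper arm %.0f / forearm %.0f mm\n",
              x$id, x$method, x$anthro$trunk_length,
              x$anthro$upper_arm_length, x$anthro$forearm_length))
  if (is.null(x$coefficients)) {
    cat("  not calibrated\n")
  } else {
    cat(sprintf("  beta_contact: %s | beta_release: %s\n",
                paste(sprintf("%.2f", x$coefficients$beta_contact), collapse = " "),
                paste(sprintf("%.2f", x$coefficients$beta_release), collapse = " ")))
  }
  invisible(x)
}

#' Attach calibrated coefficients to an athlete
#'
#' @param ath An [athlete()] object.
#' @param coefficients A coefficient set from [calibrate_athlete()].
#' @return The athlete with coefficients set.
#' @export
set_coefficients <- function(ath, coefficients) {
  stopifnot(inherits(ath, "athlete"))
  ath$coefficients <- coefficients
  ath
}

# Interpolated (theta_ti, theta_tr) for one stroke at an arbitrary seat angle.
# Linear between the three profiled seat-angle levels, constant beyond them
# (rule = 2): seat angle acts on the model only through this lookup.
trunk_angles_at <- function(ath, seat_angle, stroke) {
  prof <- ath$trunk_profile[ath$trunk_profile$stroke == stroke, , drop = FALSE]
  if (nrow(prof) == 0) {
    stop(sprintf("athlete %s has no trunk profile for stroke %d", ath$id, stroke),
         call. = FALSE)
  }
  prof <- prof[order(prof$seat_angle), , drop = FALSE]
  if (nrow(prof) == 1) {
    return(list(theta_ti = prof$theta_ti, theta_tr = prof$theta_tr))
  }
  list(theta_ti = stats::approx(prof$seat_angle, prof$theta_ti,
                                xout = seat_angle, rule = 2)$y,
       theta_tr = stats::approx(prof$seat_angle, prof$theta_tr,
                                xout = seat_angle, rule = 2)$y)
}

#' Predict per-stroke contact, release and push angles for a set-up
#'
#' Looks up the athlete's contact/release trunk angles for the set-up's seat
#' angle (interpolating linearly between profiled seat-angle levels), then
#' applies the calibrated per-stroke contact and release coefficients through
#' the linkage geometry. Push angle is release minus contact.
#'
#' @param ath A calibrated [athlete()].
#' @param setup A [setup_config()] object.
#' @param strokes Which strokes to predict (subset of 1:3).
#' @return A data frame with columns `stroke`, `contact`, `release`, `push`
#'   (deg, TDC convention).
#' @export
predict_stroke_kinematics <- function(ath, setup, strokes = 1:3) {
  stopifnot(inherits(ath, "athlete"))
  setup <- as_setup_config(setup)
  if (is.null(ath$coefficients)) {
    stop(sprintf("athlete %s is not calibrated: no coefficient set", ath$id),
         call. = FALSE)
  }
  out <- lapply(strokes, function(k) {
    cf <- ath$coefficients[ath$coefficients$stroke == k, , drop = FALSE]
    if (nrow(cf) != 1 || anyNA(cf[c("beta_contact", "beta_release")])) {
      stop(sprintf("athlete %s is not calibrated for stroke %d", ath$id, k),
           call. = FALSE)
    }
    ta <- trunk_angles_at(ath, setup$seat_angle, k)
    ct <- contact_angle(ath$anthro, setup, ta$theta_ti, cf$beta_contact,
                        method = ath$method)
    rl <- release_angle(ath$anthro, setup, ta$theta_tr, cf$beta_release)
    data.frame(stroke = k, contact = ct, release = rl, push = rl - ct)
  })
  do.call(rbind, out)
}
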