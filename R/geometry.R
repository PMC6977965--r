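#' Two-link arm geometry
#'
#' Planar two-link arm (upper arm and forearm-plus-hand, shoulder fixed at
#' `shoulder_origin`). The simulation lives in the x-y plane at z = 0 with x
#' to the animal's right (ipsilateral for a right arm), y forward and z up;
#' all exported kinematic signals carry a z component (identically zero) so
#' that downstream design matrices keep their full 3-D dimensionality.
#'
#' @param upper_arm_length Shoulder-to-elbow link length in metres.
#' @param forearm_length Elbow-to-hand (handle) link length in metres.
#' @param shoulder_origin 3-vector shoulder position in metres.
#' @param elbow_bend_sign +1 or -1, selecting which of the two
#'   inverse-kinematics branches is the anatomical one. +1 places the elbow
#'   to the right of the shoulder-to-hand chord (natural for a right arm
#'   reaching forward).
#' @return An object of class `arm_geometry`.
#' @export
#' @examples
#' geom <- arm_geometry(0.16, 0.22)
#' elbow_from_hand(c(0, 0.3), geom)
arm_geometry <- function(upper_arm_length = 0.16,
                         forearm_length = 0.22,
                         shoulder_origin = c(0, 0, 0),
                         elbow_bend_sign = 1) {
  check_scalar_pos(upper_arm_length, "upper_arm_length")
  check_scalar_pos(forearm_length, "forearm_length")
  stopifnot(length(shoulder_origin) == 3, elbow_bend_sign %in% c(-1, 1))
  structure(
    list(upper_arm_length = upper_arm_length,
         forearm_length = forearm_length,
         shoulder_origin = as.numeric(shoulder_origin),
         elbow_bend_sign = elbow_bend_sign),
    class = "arm_geometry"
  )
}

#' @export
print.arm_geometry <- function(x, ...) {
  cat(sprintf(
    "Two-link arm: upper %.3f m, forearm %.3f m, shoulder (%.2f, %.2f, %.2f), bend %+d\n",
    x$upper_arm_length, x$forearm_length,
    x$shoulder_origin[1], x$shoulder_origin[2], x$shoulder_origin[3],
    x$elbow_bend_sign))
  invisible(x)
}

#' Minimum-jerk point-to-point trajectory
#'
#' Samples the quintic minimum-jerk polynomial between two planar points:
#' s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5 along the straight line, which has
#' zero velocity and acceleration at both endpoints and a single interior
#' speed peak of 1.875 * distance / duration.
#'
#' @param start,end 2-vectors (m).
#' @param duration Movement time (s); must be at least `2 * dt`.
#' @param dt Sample step (s).
#' @return List with `t`, and `position`, `velocity`, `acceleration`
#'   matrices (samples x 2). The final sample lands exactly on `duration`.
#' @export
minimum_jerk_segment <- function(start, end, duration, dt) {
  check_scalar_pos(duration, "duration")
  check_scalar_pos(dt, "dt")
  stopifnot(length(start) == 2, length(end) == 2)
  if (duration < 2 * dt) stop_invalid("duration must be >= 2 * dt")
  t <- seq(0, duration, by = dt)
  if (t[length(t)] < duration) t <- c(t, duration)
  tau <- t / duration
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  ds <- (30 * tau^2 - 60 * tau^3 + 30 * tau^4) / duration
  dds <- (60 * tau - 180 * tau^2 + 120 * tau^3) / duration^2
  d <- rbind(end - start)
  list(t = t,
       position = cbind(start[1] + s * d[1], start[2] + s * d[2]),
       velocity = cbind(ds * d[1], ds * d[2]),
       acceleration = cbind(dds * d[1], dds * d[2]))
}

#' Elbow position from hand position (planar inverse kinematics)
#'
#' Closed-form circle-circle intersection for the two-link arm; the branch
#' is selected deterministically by `geometry$elbow_bend_sign`. At full
#' extension (or full fold) the two branches coincide and the elbow lies on
#' the shoulder-hand line; this singular configuration triggers a warning.
#'
#' @param hand_position 2-vector (m), or an n x 2 matrix of positions.
#' @param geometry An [arm_geometry()] object.
#' @return Elbow position(s), same shape as the input.
#' @export
elbow_from_hand <- function(hand_position, geometry) {
  stopifnot(inherits(geometry, "arm_geometry"))
  one <- is.null(dim(hand_position))
  h <- if (one) rbind(as.numeric(hand_position)) else as.matrix(hand_position)
  stopifnot(ncol(h) == 2)
  s <- geometry$shoulder_origin[1:2]
  l1 <- geometry$upper_arm_length
  l2 <- geometry$forearm_length
  dx <- h[, 1] - s[1]
  dy <- h[, 2] - s[2]
  d <- sqrt(dx^2 + dy^2)
  eps <- 1e-12
  if (any(d > l1 + l2 + eps) || any(d < abs(l1 - l2) - eps) || any(d < eps)) {
    stop_invalid("hand position outside the reachable workspace of the arm")
  }
  a <- (l1^2 - l2^2 + d^2) / (2 * d)
  h2sq <- pmax(l1^2 - a^2, 0)
  if (any(l1^2 - a^2 < -1e-9)) {
    stop_invalid("inconsistent inverse-kinematics geometry")
  }
  if (any(h2sq < 1e-16)) {
    warning("arm at a singular (fully extended/folded) configuration; ",
            "elbow placed on the shoulder-hand line")
  }
  hh <- sqrt(h2sq)
  ux <- dx / d
  uy <- dy / d
  # perpendicular (uy, -ux): bend sign +1 puts the elbow right of the chord
  ex <- s[1] + a * ux + geometry$elbow_bend_sign * hh * uy
  ey <- s[2] + a * uy - geometry$elbow_bend_sign * hh * ux
  out <- cbind(ex, ey, deparse.level = 0)
  if (one) out[1, ] else out
}

#' Joint angles of the two-link arm
#'
#' Shoulder angle q1 = direction of the upper arm (counterclockwise from
#' +x); elbow angle q2 = direction of the forearm relative to the upper arm.
#' Both wrapped to (-pi, pi].
#'
#' @param hand,elbow n x 2 matrices (m).
#' @param geometry An [arm_geometry()] object.
#' @return n x 2 matrix with columns `q1`, `q2` (rad).
#' @export
joint_angles <- function(hand, elbow, geometry) {
  s <- geometry$shoulder_origin[1:2]
  hand <- as.matrix(hand); elbow <- as.matrix(elbow)
  q1 <- atan2(elbow[, 2] - s[2], elbow[, 1] - s[1])
  q2 <- wrap_angle(atan2(hand[, 2] - elbow[, 2], hand[, 1] - elbow[, 1]) - q1)
  cbind(q1 = wrap_angle(q1), q2 = q2)
}

#' Forward kinematics of the two-link arm
#'
#' @param q n x 2 matrix of joint angles (rad): shoulder q1, elbow q2
#'   (forearm direction relative to the upper arm).
#' @param geometry An [arm_geometry()] object.
#' @return List of n x 2 matrices `elbow`, `hand` (m).
#' @export
forward_kinematics <- function(q, geometry) {
  q <- if (is.null(dim(q))) rbind(as.numeric(q)) else as.matrix(q)
  s <- geometry$shoulder_origin[1:2]
  ex <- s[1] + geometry$upper_arm_length * cos(q[, 1])
  ey <- s[2] + geometry$upper_arm_length * sin(q[, 1])
  hx <- ex + geometry$forearm_length * cos(q[, 1] + q[, 2])
  hy <- ey + geometry$forearm_length * sin(q[, 1] + q[, 2])
  list(elbow = cbind(ex, ey, deparse.level = 0),
       hand = cbind(hx, hy, deparse.level = 0))
}

#' Default surrogate muscle set
#'
#' Six straight-line surrogate muscles spanning the planar arm: a flexor and
#' an extensor at the shoulder, a flexor and an extensor at the elbow, and
#' two biarticular muscles. Each muscle is an origin/insertion point pair;
#' points are expressed in the frame of the body segment carrying them
#' (`trunk` = lab frame at the shoulder, `upper` = upper-arm frame with +x
#' along the link, `fore` = forearm frame likewise).
#'
#' @return List of muscle descriptors (name, origin frame/point, insertion
#'   frame/point; coordinates in metres).
#' @export
default_muscle_set <- function() {
  m <- function(name, of, op, insf, insp) {
    list(name = name, origin_frame = of, origin = op,
         insertion_frame = insf, insertion = insp)
  }
  list(
    m("sh_flex", "trunk", c(0.02, 0.04), "upper", c(0.06, 0.015)),
    m("sh_ext",  "trunk", c(-0.02, -0.04), "upper", c(0.06, -0.015)),
    # elbow muscles attach on the link axes at different radii, so their
    # lengths are strictly monotonic in elbow angle over (0, pi)
    m("el_flex", "upper", c(0.05, 0), "fore", c(0.045, 0)),
    m("el_ext",  "upper", c(0.10, 0), "fore", c(0.02, 0)),
    m("bi_flex", "trunk", c(0.015, 0.03), "fore", c(0.05, 0.01)),
    m("bi_ext",  "trunk", c(-0.015, -0.03), "fore", c(0.05, -0.01))
  )
}

muscle_point_world <- function(frame, p, q1, q2, geometry) {
  s <- geometry$shoulder_origin[1:2]
  rot <- function(theta, p) {
    cbind(cos(theta) * p[1] - sin(theta) * p[2],
          sin(theta) * p[1] + cos(theta) * p[2])
  }
  if (frame == "trunk") {
    cbind(s[1] + rep(p[1], length(q1)), s[2] + rep(p[2], length(q1)))
  } else if (frame == "upper") {
    s0 <- rot(q1, p)
    cbind(s[1] + s0[, 1], s[2] + s0[, 2])
  } else if (frame == "fore") {
    el <- forward_kinematics(cbind(q1, q2), geometry)$elbow
    s0 <- rot(q1 + q2, p)
    cbind(el[, 1] + s0[, 1], el[, 2] + s0[, 2])
  } else {
    stop_invalid("unknown muscle attachment frame '%s'", frame)
  }
}

#' Surrogate muscle lengths and derivatives
#'
#' Lengths are Euclidean origin-insertion distances for the current arm
#' pose; derivatives are central differences in time (one-sided at the
#' ends). A geometric surrogate for musculotendon path length, adequate for
#' building low-dimensional muscle-kinematic covariates.
#'
#' @param q n x 2 matrix of joint angles (rad) sampled at a uniform step.
#' @param dt Sample step (s) used for the time derivatives.
#' @param geometry An [arm_geometry()] object.
#' @param muscles Muscle descriptors as from [default_muscle_set()]; at
#'   least 6 muscles spanning both joints.
#' @return List with `lengths` and `dlengths`, n x n_muscles matrices.
#' @export
surrogate_muscle_lengths <- function(q, dt, geometry,
                                     muscles = default_muscle_set()) {
  stopifnot(length(muscles) >= 6)
  q <- as.matrix(q)
  len <- matrix(NA_real_, nrow(q), length(muscles))
  for (j in seq_along(muscles)) {
    mu <- muscles[[j]]
    o <- muscle_point_world(mu$origin_frame, mu$origin, q[, 1], q[, 2], geometry)
    i <- muscle_point_world(mu$insertion_frame, mu$insertion, q[, 1], q[, 2],
                            geometry)
    l <- sqrt((o[, 1] - i[, 1])^2 + (o[, 2] - i[, 2])^2)
    if (any(l <= 0)) {
      stop_invalid("muscle '%s' has coincident origin and insertion", mu$name)
    }
    len[, j] <- l
  }
  colnames(len) <- vapply(muscles, `[[`, "", "name")
  list(lengths = len, dlengths = central_diff(len, dt))
}

# central differences along rows, one-sided at both ends
central_diff <- function(x, dt) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 1) return(x * 0)
  d <- x * NA_real_
  if (n > 2) d[2:(n - 1), ] <- (x[3:n, , drop = FALSE] -
                                  x[1:(n - 2), , drop = FALSE]) / (2 * dt)
  d[1, ] <- (x[2, ] - x[1, ]) / dt
  d[n, ] <- (x[n, ] - x[n - 1, ]) / dt
  d
}
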