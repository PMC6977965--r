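test_that("minimum-jerk segments honor their boundary conditions", {
  seg <- minimum_jerk_segment(c(0, 0), c(0.1, 0), duration = 0.5, dt = 0.01)
  n <- length(seg$t)
  expect_equal(seg$position[1, ], c(0, 0))
  expect_equal(seg$position[n, ], c(0.1, 0))
  expect_equal(seg$velocity[1, ], c(0, 0))
  expect_equal(seg$velocity[n, ], c(0, 0), tolerance = 1e-12)
  expect_equal(seg$acceleration[1, ], c(0, 0))
  # symmetry: midpoint of the path at half time
  mid <- which.min(abs(seg$t - 0.25))
  expect_equal(seg$position[mid, ], c(0.05, 0), tolerance = 1e-12)
  # unimodal speed profile
  speed <- sqrt(rowSums(seg$velocity^2))
  peak <- which.max(speed)
  expect_true(all(diff(speed[1:peak]) >= -1e-12))
  expect_true(all(diff(speed[peak:n]) <= 1e-12))
})

test_that("degenerate reach stays put with zero velocity", {
  seg <- minimum_jerk_segment(c(0, 0), c(0, 0), duration = 0.5, dt = 0.01)
  expect_true(all(seg$position == 0))
  expect_true(all(seg$velocity == 0))
})

test_that("peak speed matches the dense numeric maximum of the quintic", {
  # oracle: evaluate the closed-form speed profile on a very fine grid
  d <- 0.23; dur <- 0.7
  tau <- seq(0, 1, length.out = 200001)
  oracle_peak <- max(abs(30 * tau^2 - 60 * tau^3 + 30 * tau^4)) * d / dur
  seg <- minimum_jerk_segment(c(0, 0), c(d, 0), dur, dt = 0.001)
  expect_equal(max(sqrt(rowSums(seg$velocity^2))), oracle_peak,
               tolerance = 1e-6)
  expect_equal(oracle_peak, 1.875 * d / dur, tolerance = 1e-9)
})

test_that("minimum-jerk rejects invalid durations", {
  expect_error(minimum_jerk_segment(c(0, 0), c(1, 0), -1, 0.01), "positive")
  expect_error(minimum_jerk_segment(c(0, 0), c(1, 0), 0.01, 0.01), ">= 2")
})

test_that("elbow inverse kinematics solves textbook configurations", {
  geom <- arm_geometry(1, 1, c(0, 0, 0), elbow_bend_sign = 1)
  # right angle: elbow below the shoulder-hand chord
  expect_equal(elbow_from_hand(c(1, 1), geom), c(1, 0), tolerance = 1e-12)
  # full extension: singular, elbow on the line
  expect_warning(e <- elbow_from_hand(c(2, 0), geom), "singular")
  expect_equal(e, c(1, 0), tolerance = 1e-12)
  # opposite branch
  geom2 <- arm_geometry(1, 1, c(0, 0, 0), elbow_bend_sign = -1)
  expect_equal(elbow_from_hand(c(1, 1), geom2), c(0, 1), tolerance = 1e-12)
})

test_that("elbow position matches an independent circle-intersection solver", {
  geom <- arm_geometry(1, 1, c(0, 0, 0), elbow_bend_sign = 1)
  hand <- c(0.5, 0.9)
  # oracle: root-find the elbow angle phi on the shoulder circle such that
  # the elbow-hand distance equals the forearm length
  f <- function(phi) {
    e <- c(cos(phi), sin(phi))
    sqrt(sum((e - hand)^2)) - 1
  }
  # the +1 bend branch is the root clockwise from the hand direction
  hand_ang <- atan2(hand[2], hand[1])
  root <- stats::uniroot(f, c(hand_ang - pi + 1e-6, hand_ang),
                         tol = 1e-14)$root
  oracle <- c(cos(root), sin(root))
  expect_equal(elbow_from_hand(hand, geom), oracle, tolerance = 1e-9)
})

test_that("unreachable hands are rejected", {
  geom <- arm_geometry(1, 1)
  expect_error(elbow_from_hand(c(3, 0), geom), "workspace")
  geom2 <- arm_geometry(1, 0.4)
  expect_error(elbow_from_hand(c(0.1, 0), geom2), "workspace")
})

test_that("forward kinematics inverts elbow_from_hand everywhere", {
  geom <- arm_geometry()
  set.seed(7)
  for (i in 1:50) {
    r <- runif(1, abs(geom$upper_arm_length - geom$forearm_length) + 0.01,
               geom$upper_arm_length + geom$forearm_length - 0.01)
    ang <- runif(1, -pi, pi)
    hand <- r * c(cos(ang), sin(ang))
    elbow <- elbow_from_hand(hand, geom)
    q <- joint_angles(rbind(hand), rbind(elbow), geom)
    fk <- forward_kinematics(q, geom)
    expect_equal(drop(fk$hand), hand, tolerance = 1e-9)
    expect_equal(drop(fk$elbow), elbow, tolerance = 1e-9)
    # link-length constraints
    expect_equal(sqrt(sum(elbow^2)), geom$upper_arm_length,
                 tolerance = 1e-12)
    expect_equal(sqrt(sum((hand - elbow)^2)), geom$forearm_length,
                 tolerance = 1e-12)
  }
})

test_that("surrogate muscle lengths behave geometrically", {
  geom <- arm_geometry()
  # static posture: zero derivatives
  q <- matrix(rep(c(1.2, 0.8), each = 20), 20, 2)
  ml <- surrogate_muscle_lengths(q, 0.01, geom)
  expect_true(all(abs(ml$dlengths) < 1e-12))
  expect_true(all(ml$lengths > 0))
  # single-joint elbow muscle is monotonic in elbow angle over (0, pi)
  q2 <- cbind(1.2, seq(0.05, pi - 0.05, length.out = 50))
  ml2 <- surrogate_muscle_lengths(q2, 0.01, geom)
  dl <- diff(ml2$lengths[, "el_flex"])
  expect_true(all(dl > 0) || all(dl < 0))
  # tabulated pose vs hand-computed distance for a trunk-to-upper muscle
  qa <- c(pi / 3, 0.5)
  ml3 <- surrogate_muscle_lengths(rbind(qa), 0.01, geom)
  mu <- default_muscle_set()[[1]]  # sh_flex: trunk -> upper
  rot <- function(th, p) c(cos(th) * p[1] - sin(th) * p[2],
                           sin(th) * p[1] + cos(th) * p[2])
  oracle <- sqrt(sum((mu$origin - rot(qa[1], mu$insertion))^2))
  expect_equal(unname(ml3$lengths[1, "sh_flex"]), oracle, tolerance = 1e-12)
})

test_that("coincident muscle attachment points are a configuration error", {
  geom <- arm_geometry()
  bad <- default_muscle_set()
  bad[[1]]$origin <- c(0, 0)
  bad[[1]]$insertion <- c(0, 0)
  bad[[1]]$insertion_frame <- "trunk"
  expect_error(surrogate_muscle_lengths(rbind(c(1, 1)), 0.01, geom, bad),
               "coincident")
})

test_that("angle helpers wrap and average on the circle", {
  expect_equal(wrap_angle(pi), pi)
  expect_equal(wrap_angle(-pi), pi)
  expect_equal(wrap_angle(3 * pi / 2), -pi / 2)
  expect_equal(circ_mean(c(0.3, 0.5)), 0.4, tolerance = 1e-12)
  expect_equal(abs(circ_mean(c(3, -3))), pi, tolerance = 1e-9)
  expect_warning(m <- circ_mean(c(0, pi)), "undefined")
  expect_true(is.na(m))
})
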