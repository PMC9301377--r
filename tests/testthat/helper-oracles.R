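# Independent oracles used across the suite. These deliberately avoid the
# package's closed-form code paths: the geometry oracle places segments with
# explicit 2-D homogeneous transforms and measures the hand direction with
# atan2; the fitting and Welch oracles are direct textbook evaluations.

# counter-clockwise rotation + translation as a 3x3 homogeneous transform
hom_rotate <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}
hom_translate <- function(x, y) {
  matrix(c(1, 0, 0, 0, 1, 0, x, y, 1), 3, 3)
}

# Shoulder position by transform composition: hip frame at (-depth, height),
# trunk segment (0, trunk_length) rotated clockwise by theta (flexion -> +x).
oracle_shoulder <- function(trunk_length, depth, height, theta) {
  p <- hom_translate(-depth, height) %*% hom_rotate(-theta) %*% c(0, trunk_length, 1)
  c(x = p[1], y = p[2])
}

# Hand angle from top dead center (deg, forward positive): chain trunk, upper
# arm (anti-parallel to trunk), forearm at orientation phi from vertical.
oracle_hand_angle <- function(trunk_length, upper_arm, forearm,
                              depth, height, theta, phi) {
  sh <- oracle_shoulder(trunk_length, depth, height, theta)
  el <- sh + (hom_rotate(-theta) %*% c(0, -upper_arm, 0))[1:2]
  hand <- el + (hom_rotate(-phi) %*% c(0, forearm, 0))[1:2]
  if (hand[2] <= 0) return(NA_real_)
  unname(atan2(hand[1], hand[2]) * 180 / pi)
}

oracle_contact <- function(anthro, setup, theta_ti, beta, method) {
  phi <- if (method == "altered") 90 - theta_ti else -theta_ti
  beta * oracle_hand_angle(anthro$trunk_length, anthro$upper_arm_length,
                           anthro$forearm_length, setup$seat_depth,
                           setup$seat_height, theta_ti, phi)
}

# exhaustive grid search, written as a plain loop
oracle_fit_coefficient <- function(measured, base, lo = -0.5, hi = 1.5,
                                   step = 0.01) {
  best_beta <- NA_real_
  best_err <- Inf
  for (beta in seq(lo, hi, by = step)) {
    err <- abs(measured - beta * base)
    if (err < best_err) {
      best_err <- err
      best_beta <- beta
    }
  }
  best_beta
}

# Welch statistic, Satterthwaite df and two-sided p from the formulas
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

random_geometry <- function() {
  list(anthro = suppressWarnings(
         anthropometrics(runif(1, 400, 550), runif(1, 280, 340),
                         runif(1, 240, 300))),
       setup = setup_config(runif(1, 300, 500), runif(1, 0, 200),
                            runif(1, 0, 20), runif(1, 80, 130)),
       theta = runif(1, 0, 45),
       method = sample(c("original", "altered"), 1))
}

# small fixed athlete used by several suites: flat trunk profile with a
# seat-angle response, calibrated with unit coefficients unless overridden
make_test_athlete <- function(method = "original",
                              coefficients = data.frame(stroke = 1:3,
                                                        beta_contact = 1,
                                                        beta_release = 1)) {
  prof <- expand.grid(level = c("low", "current", "high"), stroke = 1:3,
                      stringsAsFactors = FALSE)
  prof$seat_angle <- c(5, 10, 15)[match(prof$level, c("low", "current", "high"))]
  prof$theta_ti <- 10 + 2 * (prof$seat_angle - 10) / 5 + prof$stroke
  prof$theta_tr <- prof$theta_ti + 30
  athlete("T1", anthropometrics(480, 310, 270), method, prof, coefficients)
}
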