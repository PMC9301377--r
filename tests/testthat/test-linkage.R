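test_that("shoulder position follows the hip-centred trunk geometry", {
  a <- anthropometrics(500, 300, 260)
  # vertical trunk: pure seat offsets
  sh <- shoulder_position(a, setup_config(400, 100, 10, 100), trunk_angle = 0)
  expect_equal(sh$x_hs, -100)
  expect_equal(sh$y_hs, 900)
  # fully flexed trunk is horizontal
  sh <- shoulder_position(a, setup_config(1e-9, 0, 0, 100), trunk_angle = 90)
  expect_equal(sh$x_hs, 500)
  expect_equal(sh$y_hs, 1e-9)  # cospi(1/2) is exactly zero
  # general pose agrees with the homogeneous-transform oracle
  a2 <- anthropometrics(480, 300, 260)
  sh <- shoulder_position(a2, setup_config(410, 120, 10, 100), trunk_angle = 30)
  orc <- oracle_shoulder(480, 120, 410, 30)
  expect_equal(sh$x_hs, unname(orc["x"]), tolerance = 1e-12)
  expect_equal(sh$y_hs, unname(orc["y"]), tolerance = 1e-12)
  expect_error(shoulder_position(a, setup_config(400, 100, 10, 100), 91),
               "-30, 90")
  expect_error(shoulder_position(a, setup_config(400, 100, 10, 100), NaN),
               "finite")
})

test_that("contact angle matches the segment-placement oracle and its limits", {
  a <- anthropometrics(500, 300, 280)
  s <- setup_config(400, 100, 10, 100)
  # zero coefficient annihilates the angle
  expect_identical(contact_angle(a, s, 20, beta = 0, method = "altered"), 0)
  # hand contrived onto top dead center: theta 0, altered, forearm_length = depth
  a0 <- anthropometrics(500, 300, 100)
  expect_equal(contact_angle(a0, s, 0, beta = 1.3, method = "altered"), 0)
  # closed form vs geometric oracle at the worked geometry
  got <- contact_angle(a, s, 20, beta = 1, method = "altered")
  expect_equal(got, oracle_contact(a, s, 20, 1, "altered"), tolerance = 1e-9)
  expect_gt(got, 0)
  # original method differs by the 90-degree forearm shift
  expect_equal(contact_angle(a, s, 20, 1, "original"),
               oracle_contact(a, s, 20, 1, "original"), tolerance = 1e-9)
  expect_error(contact_angle(a, s, 20, beta = 2), "-0.5, 1.5")
})

test_that("closed form equals the brute-force oracle over random geometries", {
  set.seed(101)
  for (i in 1:300) {
    g <- random_geometry()
    orc <- oracle_contact(g$anthro, g$setup, g$theta, 1, g$method)
    if (is.na(orc)) next
    expect_equal(contact_angle(g$anthro, g$setup, g$theta, 1, g$method),
                 orc, tolerance = 1e-9)
    orc_r <- oracle_contact(g$anthro, g$setup, g$theta, 1, "altered")
    expect_equal(release_angle(g$anthro, g$setup, g$theta, 1),
                 orc_r, tolerance = 1e-9)
  }
})

test_that("contact angle is linear in the coefficient", {
  set.seed(7)
  for (i in 1:25) {
    g <- random_geometry()
    one <- contact_angle(g$anthro, g$setup, g$theta, 0.6, g$method)
    two <- contact_angle(g$anthro, g$setup, g$theta, 1.2, g$method)
    expect_equal(two, 2 * one, tolerance = 1e-12)
  }
})

test_that("deeper seats pull the hand behind TDC and the angle down", {
  a <- anthropometrics(480, 310, 270)
  depths <- seq(0, 200, by = 25)
  angs <- vapply(depths, function(d) {
    contact_angle(a, setup_config(400, d, 10, 100), 15, 1, "altered")
  }, numeric(1))
  expect_true(all(diff(angs) < 0))
  # a hand behind TDC reports a negative angle
  behind <- contact_angle(a, setup_config(400, 150, 10, 100), 10, 1, "original")
  expect_lt(behind, 0)
})

test_that("degenerate geometry below the axle is rejected with set-up context", {
  a <- suppressWarnings(anthropometrics(400, 460, 250))
  expect_error(contact_angle(a, setup_config(1, 50, 10, 100), 0, 1, "altered"),
               "hand at or below axle")
  expect_error(release_angle(a, setup_config(1, 50, 10, 100), 0, 1),
               "release_angle")
})

test_that("release angle uses the parallel-forearm geometry at the flexed trunk", {
  a <- anthropometrics(500, 300, 280)
  s <- setup_config(400, 100, 10, 100)
  expect_identical(release_angle(a, s, 45, beta_r = 0), 0)
  # theta chosen so the release hand sits on TDC: solve not needed, use the
  # altered-contact equivalence at the same trunk angle instead
  expect_equal(release_angle(a, s, 45, 1),
               contact_angle(a, s, 45, 1, "altered"), tolerance = 1e-12)
  expect_equal(release_angle(a, s, 45, 1),
               oracle_contact(a, s, 45, 1, "altered"), tolerance = 1e-9)
})

test_that("stroke kinematics look up trunk angles by seat-angle level", {
  ath <- make_test_athlete()
  plan <- build_setups(setup_config(400, 100, 10, 100))
  # at a profiled level the interpolation is the identity
  su <- setup_config(400, 100, 15, 100)
  kin <- predict_stroke_kinematics(ath, su)
  prof <- ath$trunk_profile[ath$trunk_profile$level == "high", ]
  for (k in 1:3) {
    expect_equal(kin$contact[k],
                 contact_angle(ath$anthro, su, prof$theta_ti[prof$stroke == k],
                               1, ath$method))
    expect_equal(kin$release[k],
                 release_angle(ath$anthro, su, prof$theta_tr[prof$stroke == k], 1))
  }
  expect_equal(kin$push, kin$release - kin$contact)
  # midway between levels: trunk angles are the midpoint of the lookup table
  su_mid <- setup_config(400, 100, 12.5, 100)
  kin_mid <- predict_stroke_kinematics(ath, su_mid, strokes = 1)
  ti_mid <- mean(ath$trunk_profile$theta_ti[ath$trunk_profile$stroke == 1 &
                   ath$trunk_profile$level %in% c("current", "high")])
  expect_equal(kin_mid$contact,
               contact_angle(ath$anthro, su_mid, ti_mid, 1, ath$method))
  # beyond the profiled range the lookup saturates
  lo <- predict_stroke_kinematics(ath, setup_config(400, 100, 0, 100), 1)
  at_lo <- predict_stroke_kinematics(ath, setup_config(400, 100, 5, 100), 1)
  expect_equal(lo$contact, at_lo$contact)
})

test_that("identical contact and release geometry gives zero push angle", {
  prof <- expand.grid(level = c("low", "current", "high"), stroke = 1:3,
                      stringsAsFactors = FALSE)
  prof$seat_angle <- c(5, 10, 15)[match(prof$level, c("low", "current", "high"))]
  prof$theta_ti <- 20
  prof$theta_tr <- 20
  ath <- athlete("Z", anthropometrics(480, 310, 270), "altered", prof,
                 data.frame(stroke = 1:3, beta_contact = 0.9, beta_release = 0.9))
  kin <- predict_stroke_kinematics(ath, setup_config(400, 100, 10, 100))
  expect_equal(kin$push, rep(0, 3))
})

test_that("an uncalibrated athlete cannot predict kinematics", {
  ath <- make_test_athlete(coefficients = NULL)
  expect_error(predict_stroke_kinematics(ath, setup_config(400, 100, 10, 100)),
               "not calibrated")
  half <- make_test_athlete(coefficients = data.frame(stroke = 1:2,
                                                      beta_contact = 1,
                                                      beta_release = 1))
  expect_error(predict_stroke_kinematics(half, setup_config(400, 100, 10, 100)),
               "stroke 3")
})

test_that("anthropometric and set-up validation catch bad inputs", {
  expect_warning(anthropometrics(250, 300, 260), "300-700")
  expect_error(anthropometrics(500, -1, 260), "positive")
  expect_error(setup_config(0, 100, 10, 100), "seat_height")
  expect_error(setup_config(400, -5, 10, 100), "seat_depth")
  expect_error(setup_config(400, 100, 10, 0), "tire_pressure")
})
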