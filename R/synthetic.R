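#' Generate a synthetic wheelchair-rugby cohort
#'
#' Simulates a cohort of athletes with the statistical structure the
#' prediction pipeline assumes, so calibration, regression and evaluation can
#' be exercised end-to-end without study data. For each athlete the generator
#' samples segment lengths, a contact method (3 altered : 5 original mix in
#' an 8-athlete cohort), a baseline set-up, a trunk-angle profile that varies
#' with seat-angle level, and true per-stroke contact/release coefficients on
#' the two-decimal grid in \[0.8, 1.2\]. It then realizes the L9 design,
#' computes noiseless stroke kinematics through the linkage model with the
#' true coefficients, adds independent Gaussian angle noise per trial and
#' side, and generates sprint times from a linear model in the 13 z-scored
#' predictors plus Gaussian noise.
#'
#' @param n_athletes Number of athletes (default 8, mirroring an elite squad).
#' @param seed Optional integer seed; the same seed reproduces the cohort
#'   bit-identically.
#' @param angle_sd Angle measurement noise SD, deg (per stroke, trial, side).
#' @param time_sd Sprint-time noise SD, s (per trial).
#' @param n_trials Sprints per set-up.
#' @param deltas [level_deltas()] for the design.
#' @return An object of class `sprint_cohort`: a list with `athletes` (list
#'   of [athlete()] objects, uncalibrated), `plans` (per-athlete realized L9
#'   design), `truth` (true coefficients and time-model parameters),
#'   `trials` (long data frame: `athlete_id`, `setup_id`, `trial`, `stroke`,
#'   `side`, `contact_deg`, `release_deg`, plus the noiseless
#'   `contact_true`/`release_true`), `times` (per-trial sprint times with
#'   `time_true`), and the generator settings.
#' @export
generate_cohort <- function(n_athletes = 8, seed = NULL, angle_sd = 2,
                            time_sd = 0.05, n_trials = 2,
                            deltas = level_deltas()) {
  if (n_athletes < 1) stop("n_athletes must be >= 1", call. = FALSE)
  if (angle_sd < 0 || time_sd < 0) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  n_altered <- round(3 * n_athletes / 8)
  altered_idx <- if (n_altered > 0) sample.int(n_athletes, n_altered) else integer(0)
  sides <- c("left", "right")

  athletes <- list(); plans <- list(); truth <- list()
  trial_rows <- list(); time_rows <- list()

  for (i in seq_len(n_athletes)) {
    id <- sprintf("P%d", i)
    anthro <- anthropometrics(stats::runif(1, 400, 550),
                              stats::runif(1, 280, 340),
                              stats::runif(1, 240, 300))
    method <- if (i %in% altered_idx) "altered" else "original"
    baseline <- setup_config(stats::runif(1, 350, 450),
                             stats::runif(1, 100, 150),
                             stats::runif(1, 5, 20),
                             stats::runif(1, 90, 120))
    plan <- build_setups(baseline, deltas)

    # trunk profile: per-stroke base angle plus an athlete-specific response
    # of trunk posture to seat angle, clamped to the plausible 5-30 deg band
    slope <- stats::runif(1, 0.2, 0.8)
    prof <- do.call(rbind, lapply(1:3, function(k) {
      base_ti <- stats::runif(1, 8, 25)
      gap <- stats::runif(1, 20, 45)
      lev <- c(-1, 0, 1)
      ti <- pmin(30, pmax(5, base_ti + slope * deltas$seat_angle * lev))
      data.frame(level = c("low", "current", "high"),
                 seat_angle = baseline$seat_angle + lev * deltas$seat_angle,
                 stroke = k, theta_ti = ti, theta_tr = ti + gap)
    }))
    ath <- athlete(id, anthro, method, prof)

    true_coef <- data.frame(
      stroke = 1:3,
      beta_contact = round(stats::runif(3, 0.8, 1.2), 2),
      beta_release = round(stats::runif(3, 0.8, 1.2), 2))
    ath_true <- set_coefficients(ath, true_coef)

    # noiseless kinematics and features per set-up
    kin_true <- lapply(1:9, function(s) {
      predict_stroke_kinematics(ath_true, plan[plan$setup_id == s, ])
    })
    feats <- t(vapply(1:9, function(s) {
      assemble_features(plan[plan$setup_id == s, ], kin_true[[s]])
    }, numeric(13)))

    f_center <- colMeans(feats)
    f_scale <- apply(feats, 2, stats::sd)
    f_scale[f_scale < 1e-9] <- 1
    weights <- stats::runif(13, -0.05, 0.05)
    intercept <- stats::runif(1, 2.0, 2.8)
    time_model <- list(intercept = intercept, weights = weights,
                       center = f_center, scale = f_scale)
    time_true <- intercept +
      drop(sweep(sweep(feats, 2, f_center), 2, f_scale, "/") %*% weights)

    grid <- expand.grid(side = sides, stroke = 1:3, trial = seq_len(n_trials),
                        setup_id = 1:9, stringsAsFactors = FALSE)
    ct <- vapply(seq_len(nrow(grid)), function(r) {
      kin_true[[grid$setup_id[r]]]$contact[grid$stroke[r]]
    }, numeric(1))
    rt <- vapply(seq_len(nrow(grid)), function(r) {
      kin_true[[grid$setup_id[r]]]$release[grid$stroke[r]]
    }, numeric(1))
    trial_rows[[i]] <- data.frame(
      athlete_id = id, setup_id = grid$setup_id, trial = grid$trial,
      stroke = grid$stroke, side = grid$side,
      contact_deg = ct + stats::rnorm(nrow(grid), 0, angle_sd),
      release_deg = rt + stats::rnorm(nrow(grid), 0, angle_sd),
      contact_true = ct, release_true = rt)

    tg <- expand.grid(trial = seq_len(n_trials), setup_id = 1:9)
    time_rows[[i]] <- data.frame(
      athlete_id = id, setup_id = tg$setup_id, trial = tg$trial,
      time_s = time_true[tg$setup_id] + stats::rnorm(nrow(tg), 0, time_sd),
      time_true = time_true[tg$setup_id])

    athletes[[id]] <- ath
    plans[[id]] <- plan
    truth[[id]] <- list(coefficients = true_coef, time_model = time_model)
  }

  trials <- do.call(rbind, trial_rows)
  # loose physical-plausibility bands, checked on the noiseless angles; the
  # planar model keeps release directions well short of the on-court 70-105
  # deg range, so only sign/degeneracy problems are worth flagging here
  if (any(trials$contact_true < -60 | trials$contact_true > 30)) {
    warning("some generated contact angles fall outside the loose -60..30 deg band")
  }
  if (any(trials$release_true < 0 | trials$release_true > 120)) {
    warning("some generated release angles fall outside the 0..120 deg band")
  }

  structure(list(athletes = athletes, plans = plans, truth = truth,
                 trials = trials, times = do.call(rbind, time_rows),
                 angle_sd = angle_sd, time_sd = time_sd,
                 n_trials = n_trials, seed = seed),
            class = "sprint_cohort")
}

#' @export
print.sprint_cohort <- function(x, ...) {
  cat(sprintf("<sprint_cohort> %d athletes, %d set-ups x %d trials; angle SD %.2f deg, time SD %.3f s\n",
              length(x$athletes), 9, x$n_trials, x$angle_sd, x$time_sd))
  invisible(x)
}

#' Inject a set-up-dependent technique change into the held-out set-ups
#'
#' Real athletes may adapt their propulsion to a specific set-up, breaking
#' the assumption of fixed per-stroke coefficients. This stress generator
#' perturbs the true contact and release coefficients of the final two
#' set-ups by `0.1 * drift * (setup_id - 7)` and regenerates the affected
#' angles and sprint times, reusing the original noise draws so that the
#' comparison against the unperturbed cohort is exactly paired. With
#' `drift = 0` the cohort is returned unchanged.
#'
#' @param cohort A `sprint_cohort` from [generate_cohort()].
#' @param drift Non-negative perturbation scale.
#' @return The perturbed `sprint_cohort`.
#' @export
corrupt_relationship <- function(cohort, drift) {
  stopifnot(inherits(cohort, "sprint_cohort"))
  if (drift < 0) stop("drift must be >= 0", call. = FALSE)
  if (drift == 0) return(cohort)

  for (id in names(cohort$athletes)) {
    ath <- cohort$athletes[[id]]
    plan <- cohort$plans[[id]]
    tm <- cohort$truth[[id]]$time_model
    coef <- cohort$truth[[id]]$coefficients
    setup_ids <- sort(unique(plan$setup_id))
    affected <- utils::tail(setup_ids, 2)

    # noiseless features for all set-ups under the (possibly drifted) truth
    feats <- matrix(0, length(setup_ids), 13)
    kin_by_setup <- list()
    for (s in setup_ids) {
      su <- as_setup_config(plan[plan$setup_id == s, ])
      pert <- if (s %in% affected) 0.1 * drift * (s - affected[1] + 1) else 0
      kin <- do.call(rbind, lapply(1:3, function(k) {
        ta <- trunk_angles_at(ath, su$seat_angle, k)
        phi_c <- if (ath$method == "altered") 90 - ta$theta_ti else -ta$theta_ti
        bc <- coef$beta_contact[k] + pert
        br <- coef$beta_release[k] + pert
        ct <- bc * base_hand_angle(ath$anthro, su, ta$theta_ti, phi_c)
        rl <- br * base_hand_angle(ath$anthro, su, ta$theta_tr, 90 - ta$theta_tr)
        data.frame(stroke = k, contact = ct, release = rl, push = rl - ct)
      }))
      kin_by_setup[[as.character(s)]] <- kin
      feats[match(s, setup_ids), ] <- assemble_features(su, kin)
    }
    time_true <- tm$intercept +
      drop(sweep(sweep(feats, 2, tm$center), 2, tm$scale, "/") %*% tm$weights)

    rows <- cohort$trials$athlete_id == id & cohort$trials$setup_id %in% affected
    tr <- cohort$trials[rows, ]
    new_ct <- vapply(seq_len(nrow(tr)), function(r) {
      kin_by_setup[[as.character(tr$setup_id[r])]]$contact[tr$stroke[r]]
    }, numeric(1))
    new_rt <- vapply(seq_len(nrow(tr)), function(r) {
      kin_by_setup[[as.character(tr$setup_id[r])]]$release[tr$stroke[r]]
    }, numeric(1))
    cohort$trials$contact_deg[rows] <- new_ct + (tr$contact_deg - tr$contact_true)
    cohort$trials$release_deg[rows] <- new_rt + (tr$release_deg - tr$release_true)
    cohort$trials$contact_true[rows] <- new_ct
    cohort$trials$release_true[rows] <- new_rt

    trow <- cohort$times$athlete_id == id & cohort$times$setup_id %in% affected
    tt <- cohort$times[trow, ]
    new_time <- time_true[match(tt$setup_id, setup_ids)]
    cohort$times$time_s[trow] <- new_time + (tt$time_s - tt$time_true)
    cohort$times$time_true[trow] <- new_time
  }
  cohort
}
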