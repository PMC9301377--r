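require_columns <- function(df, cols, context) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("missing column(s) %s in %s",
                 paste(missing, collapse = ", "), context), call. = FALSE)
  }
  invisible(df)
}

# Per-trial 13-predictor rows from measured kinematics: sides are pooled per
# stroke (per-side mean, then mean of side means), one row per (set-up, trial).
measured_features <- function(trials, times, plan) {
  require_columns(trials, c("setup_id", "trial", "stroke", "contact_deg",
                            "release_deg"), "measured trials")
  if (!"side" %in% names(trials)) trials$side <- "pooled"
  keys <- unique(trials[c("setup_id", "trial")])
  rows <- lapply(seq_len(nrow(keys)), function(r) {
    o <- trials[trials$setup_id == keys$setup_id[r] &
                  trials$trial == keys$trial[r], , drop = FALSE]
    kin <- do.call(rbind, lapply(sort(unique(o$stroke)), function(k) {
      ok <- o[o$stroke == k, , drop = FALSE]
      data.frame(stroke = k,
                 contact = mean(tapply(ok$contact_deg, ok$side, mean)),
                 release = mean(tapply(ok$release_deg, ok$side, mean)))
    }))
    su <- plan[plan$setup_id == keys$setup_id[r], , drop = FALSE]
    f <- assemble_features(su, kin)
    cbind(keys[r, , drop = FALSE], as.data.frame(as.list(f)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  merge(out, times[c("setup_id", "trial", "time_s")],
        by = c("setup_id", "trial"), sort = TRUE)
}

#' Compare predicted and measured propulsion kinematics for a cohort
#'
#' For every athlete and stroke, measured contact and release angles are
#' averaged per set-up (over trials and sides) and compared against the
#' linkage-model predictions across all tested set-ups, giving one
#' mean/SD/min/max difference summary per athlete, stroke and measure. The
#' per-stroke error distributions (one mean difference per athlete) are then
#' compared pairwise between strokes with Welch's t-test under a Bonferroni
#' correction over the six comparisons (three stroke pairs for contact,
#' three for release).
#'
#' @param athletes Named list of calibrated [athlete()]s.
#' @param plans Named list of realized design plans ([build_setups()]).
#' @param trials Measured-kinematics data frame (`athlete_id`, `setup_id`,
#'   `trial`, `stroke`, `side`, `contact_deg`, `release_deg`).
#' @return List with `summary` (one row per athlete x stroke x measure),
#'   `tests` (the six Welch comparisons with `t`, `df`, `p`, significance at
#'   the adjusted alpha), and `alpha` (the [bonferroni_alpha()] result).
#' @export
evaluate_kinematics <- function(athletes, plans, trials) {
  require_columns(trials, c("athlete_id", "setup_id", "stroke",
                            "contact_deg", "release_deg"), "measured trials")
  if (!"side" %in% names(trials)) trials$side <- "pooled"
  summaries <- list()
  for (id in names(athletes)) {
    ath <- athletes[[id]]
    plan <- plans[[id]]
    tr <- trials[trials$athlete_id == id, , drop = FALSE]
    for (k in 1:3) {
      ok <- tr[tr$stroke == k, , drop = FALSE]
      setup_ids <- sort(unique(ok$setup_id))
      meas_c <- vapply(setup_ids, function(s) {
        o <- ok[ok$setup_id == s, ]; mean(tapply(o$contact_deg, o$side, mean))
      }, numeric(1))
      meas_r <- vapply(setup_ids, function(s) {
        o <- ok[ok$setup_id == s, ]; mean(tapply(o$release_deg, o$side, mean))
      }, numeric(1))
      pred <- do.call(rbind, lapply(setup_ids, function(s) {
        predict_stroke_kinematics(ath, plan[plan$setup_id == s, ], strokes = k)
      }))
      for (measure in c("contact", "release")) {
        meas <- if (measure == "contact") meas_c else meas_r
        sm <- summarize_differences(pred[[measure]], meas)
        summaries[[length(summaries) + 1]] <-
          cbind(data.frame(athlete_id = id, stroke = k, measure = measure), sm)
      }
    }
  }
  summary <- do.call(rbind, summaries)

  alpha <- bonferroni_alpha(0.05, 6)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  tests <- list()
  for (measure in c("contact", "release")) {
    for (pr in pairs) {
      g1 <- summary$mean[summary$measure == measure & summary$stroke == pr[1]]
      g2 <- summary$mean[summary$measure == measure & summary$stroke == pr[2]]
      wt <- if (length(g1) >= 2 && length(g2) >= 2 &&
                stats::var(g1) + stats::var(g2) > 0) {
        welch_test(g1, g2)
      } else {
        list(t = NA_real_, df = NA_real_, p = NA_real_)
      }
      tests[[length(tests) + 1]] <- data.frame(
        measure = measure, stroke_a = pr[1], stroke_b = pr[2],
        t = wt$t, df = wt$df, p = wt$p,
        significant = !is.na(wt$p) && wt$p < alpha$alpha_adjusted)
    }
  }
  list(summary = summary, tests = do.call(rbind, tests), alpha = alpha)
}

#' Run the full set-up-to-performance prediction pipeline
#'
#' Executes the two-step method for every athlete in a dataset: (1) calibrate
#' per-stroke contact and release coefficients against the measured
#' kinematics across all tested set-ups; (2) train a per-athlete PLS
#' regression of sprint time on the 13 predictors using per-trial rows from
#' the first seven set-ups, select the component count at the
#' explained-variance plateau (capped at five), and predict sprint times for
#' the held-out final two set-ups using the linkage-model *predicted*
#' kinematics (never the measured ones), so the held-out evaluation is a
#' true set-up-to-performance prediction. Kinematic accuracy is evaluated
#' with per-stroke difference summaries and the six Welch/Bonferroni stroke
#' comparisons; a level-average analysis of mean sprint time over the design
#' is included per athlete.
#'
#' @param data A `sprint_cohort` from [generate_cohort()], or any list with
#'   fields `athletes`, `plans`, `trials`, `times` in the same schemas.
#' @param plateau Explained-variance plateau threshold, percentage points.
#' @param max_components Component cap for [select_components()].
#' @param scale Scale predictors to unit variance in the PLS fit.
#' @param n_train_setups Leading set-ups used for training (default 7 of 9).
#' @param grid Coefficient grid for calibration.
#' @return An object of class `sprint_pipeline`: calibrated athletes and
#'   coefficient sets, per-athlete PLS models and selected component counts,
#'   per-trial test-set time predictions (`time_predictions`), the kinematic
#'   evaluation tables (`kinematics_eval`), a test-set time-difference
#'   summary (`time_summary`), and per-athlete level-average effects of the
#'   set-up parameters on measured sprint time (`setup_effects`).
#' @export
run_pipeline <- function(data, plateau = 2, max_components = 5, scale = FALSE,
                         n_train_setups = 7, grid = c(-0.5, 1.5, 0.01)) {
  stopifnot(is.list(data),
            all(c("athletes", "plans", "trials", "times") %in% names(data)))
  require_columns(data$trials, c("athlete_id", "setup_id", "trial", "stroke",
                                 "contact_deg", "release_deg"), "trials table")
  require_columns(data$times, c("athlete_id", "setup_id", "trial", "time_s"),
                  "times table")

  calibrated <- list(); coefficients <- list(); models <- list()
  ncomp <- integer(0); pred_rows <- list(); effects <- list()

  for (id in names(data$athletes)) {
    ath <- data$athletes[[id]]
    plan <- data$plans[[id]]
    tr <- data$trials[data$trials$athlete_id == id, , drop = FALSE]
    tm <- data$times[data$times$athlete_id == id, , drop = FALSE]

    coefs <- calibrate_athlete(tr, ath, plan, grid)
    ath_cal <- set_coefficients(ath, coefs)
    calibrated[[id]] <- ath_cal
    coefficients[[id]] <- coefs

    feat <- measured_features(tr, tm, plan)
    split <- split_train_test(feat, n_train_setups)
    Xtr <- as.matrix(split$train[feature_names()])
    ytr <- split$train$time_s
    kmax <- min(nrow(Xtr) - 1L, 13L, max_components + 3L)
    model <- train_pls(Xtr, ytr, n_components = kmax, scale = scale)
    k <- select_components(model$explvar_y, plateau, cap = max_components)
    models[[id]] <- model
    ncomp[id] <- k

    test_setups <- sort(unique(split$test$setup_id))
    for (s in test_setups) {
      su <- plan[plan$setup_id == s, , drop = FALSE]
      kin_pred <- predict_stroke_kinematics(ath_cal, su)
      f_pred <- assemble_features(su, kin_pred)
      t_pred <- predict_time(model, f_pred, ncomp = k)
      meas <- tm[tm$setup_id == s, , drop = FALSE]
      pred_rows[[length(pred_rows) + 1]] <- data.frame(
        athlete_id = id, setup_id = s, trial = meas$trial,
        predicted_s = t_pred, measured_s = meas$time_s,
        diff_s = t_pred - meas$time_s)
    }

    mean_time <- vapply(sort(unique(tm$setup_id)), function(s) {
      mean(tm$time_s[tm$setup_id == s])
    }, numeric(1))
    effects[[id]] <- level_average_analysis(plan, mean_time)
  }

  time_predictions <- do.call(rbind, pred_rows)
  kinematics_eval <- evaluate_kinematics(calibrated, data$plans, data$trials)

  structure(list(
    athletes = calibrated, coefficients = coefficients, models = models,
    n_components = ncomp, time_predictions = time_predictions,
    time_summary = summarize_differences(time_predictions$predicted_s,
                                         time_predictions$measured_s),
    kinematics_eval = kinematics_eval, setup_effects = effects,
    config = list(plateau = plateau, max_components = max_components,
                  scale = scale, n_train_setups = n_train_setups,
                  grid = grid)),
    class = "sprint_pipeline")
}

#' @export
print.sprint_pipeline <- function(x, ...) {
  ts <- x$time_summary
  cat(sprintf("<sprint_pipeline> %d athletes; held-out sprint-time error %.3f +/- %.3f s (n = %d)\n",
              length(x$athletes), ts$mean, ts$sd, ts$n))
  invisible(x)
}
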