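TRIALS_COLUMNS <- c("athlete_id", "setup_id", "trial", "stroke", "side",
                    "contact_deg", "release_deg")
TIMES_COLUMNS <- c("athlete_id", "setup_id", "trial", "time_s")

#' Read and write measured-kinematics trial tables
#'
#' Plain CSV with columns `athlete_id`, `setup_id`, `trial`, `stroke`,
#' `side`, `contact_deg`, `release_deg`; angles in degrees (TDC convention).
#' Extra columns are preserved.
#'
#' @param path CSV file path.
#' @param trials Trials data frame.
#' @return `read_trials_csv` returns the validated data frame;
#'   `write_trials_csv` returns `path` invisibly.
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, TRIALS_COLUMNS, paste0("trials file '", path, "'"))
  df
}

#' @rdname read_trials_csv
#' @export
write_trials_csv <- function(trials, path) {
  require_columns(trials, TRIALS_COLUMNS, "trials table")
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Read and write per-trial sprint-time tables
#'
#' Plain CSV with columns `athlete_id`, `setup_id`, `trial`, `time_s`
#' (seconds).
#'
#' @param path CSV file path.
#' @param times Times data frame.
#' @return `read_times_csv` returns the validated data frame;
#'   `write_times_csv` returns `path` invisibly.
#' @export
read_times_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, TIMES_COLUMNS, paste0("times file '", path, "'"))
  df
}

#' @rdname read_times_csv
#' @export
write_times_csv <- function(times, path) {
  require_columns(times, TIMES_COLUMNS, "times table")
  utils::write.csv(times, path, row.names = FALSE)
  invisible(path)
}

#' Read and write athlete definition files
#'
#' YAML holding, per athlete: id, anthropometrics (mm), contact method,
#' the 9-row trunk-angle profile (3 seat-angle levels x 3 strokes) and, when
#' calibrated, the per-stroke coefficient set.
#'
#' @param path YAML file path.
#' @param athletes Named list of [athlete()] objects.
#' @return `read_athletes_yaml` returns a named list of athletes;
#'   `write_athletes_yaml` returns `path` invisibly.
#' @export
write_athletes_yaml <- function(athletes, path) {
  ser <- lapply(athletes, function(a) {
    out <- list(
      id = a$id,
      anthropometrics = list(trunk_length = a$anthro$trunk_length,
                             upper_arm_length = a$anthro$upper_arm_length,
                             forearm_length = a$anthro$forearm_length),
      method = a$method,
      trunk_profile = lapply(seq_len(nrow(a$trunk_profile)), function(r) {
        as.list(a$trunk_profile[r, c("level", "seat_angle", "stroke",
                                     "theta_ti", "theta_tr")])
      }))
    if (!is.null(a$coefficients)) {
      cf <- as.data.frame(a$coefficients)
      out$coefficients <- lapply(seq_len(nrow(cf)), function(r) {
        as.list(cf[r, c("stroke", "beta_contact", "beta_release")])
      })
    }
    out
  })
  yaml::write_yaml(list(schema = "wheelsprint/athletes/v1",
                        athletes = unname(ser)), path)
  invisible(path)
}

#' @rdname write_athletes_yaml
#' @export
read_athletes_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$athletes)) {
    stop(sprintf("athletes file '%s' has no 'athletes' entry", path),
         call. = FALSE)
  }
  out <- lapply(doc$athletes, function(a) {
    prof <- do.call(rbind, lapply(a$trunk_profile, as.data.frame))
    coefs <- if (!is.null(a$coefficients)) {
      do.call(rbind, lapply(a$coefficients, as.data.frame))
    }
    athlete(a$id,
            anthropometrics(a$anthropometrics$trunk_length,
                            a$anthropometrics$upper_arm_length,
                            a$anthropometrics$forearm_length),
            a$method, prof, coefs)
  })
  stats::setNames(out, vapply(out, function(a) a$id, character(1)))
}

#' Read and write realized design plans
#'
#' Plain CSV of a [build_setups()] plan: `setup_id`, the four `level_*`
#' columns and the realized parameter values.
#'
#' @param path CSV file path.
#' @param plan A `design_plan` data frame.
#' @return `read_plan_csv` returns the plan; `write_plan_csv` returns
#'   `path` invisibly.
#' @export
write_plan_csv <- function(plan, path) {
  utils::write.csv(plan, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plan_csv
#' @export
read_plan_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("setup_id", "seat_height", "seat_depth", "seat_angle",
                        "tire_pressure"), paste0("plan file '", path, "'"))
  class(df) <- c("design_plan", class(df))
  df
}

#' Serialize a fitted PLS model to plain JSON
#'
#' Versioned plain-array serialization (no binary formats) so models can be
#' stored alongside the CSV artifacts and re-read for prediction.
#'
#' @param model A `pls_model`.
#' @param path JSON file path.
#' @return `write_pls_model_json` returns `path` invisibly;
#'   `read_pls_model_json` returns the `pls_model`.
#' @export
write_pls_model_json <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  payload <- list(schema = "wheelsprint/pls_model/v1",
                  n_components = model$n_components,
                  x_center = model$x_center, x_scale = model$x_scale,
                  y_center = model$y_center, scale = model$scale,
                  weights = model$weights, loadings = model$loadings,
                  q = model$q, coefficients = model$coefficients,
                  explvar_x = model$explvar_x, explvar_y = model$explvar_y,
                  feature_names = model$feature_names)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_pls_model_json
#' @export
read_pls_model_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(doc$x_center)
  model <- list(n_components = as.integer(doc$n_components),
                x_center = stats::setNames(as.numeric(doc$x_center),
                                           doc$feature_names),
                x_scale = as.numeric(doc$x_scale),
                y_center = as.numeric(doc$y_center),
                scale = isTRUE(doc$scale),
                weights = matrix(unlist(doc$weights), nrow = p),
                loadings = matrix(unlist(doc$loadings), nrow = p),
                q = as.numeric(doc$q),
                coefficients = matrix(unlist(doc$coefficients), nrow = p,
                                      dimnames = list(doc$feature_names, NULL)),
                explvar_x = as.numeric(doc$explvar_x),
                explvar_y = as.numeric(doc$explvar_y),
                feature_names = doc$feature_names)
  structure(model, class = "pls_model")
}
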