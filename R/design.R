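#' The L9 orthogonal array for four three-level factors
#'
#' Returns the canonical Taguchi L9(3^4) array over levels -1 (decrease),
#' 0 (athlete's current value) and +1 (increase), built from the GF(3)
#' Latin-square construction with the all-current row first, so the first
#' realized set-up always replicates the athlete's typical set-up. Each
#' column contains each level exactly three times and every ordered level
#' pair appears exactly once in every column pair, so main effects of the
#' four factors are estimable from nine runs.
#'
#' @return A 9 x 4 integer matrix with columns `seat_height`, `seat_depth`,
#'   `seat_angle`, `tire_pressure` and entries in \{-1, 0, 1\}.
#' @examples
#' l9_array()
#' @export
l9_array <- function() {
  a <- rep(0:2, each = 3)
  b <- rep(0:2, times = 3)
  codes <- cbind(a, b, (a + b) %% 3, (a + 2 * b) %% 3)
  lv <- c(0L, -1L, 1L)  # code 0 = current so row 1 is the baseline run
  m <- matrix(lv[codes + 1], nrow = 9, ncol = 4)
  colnames(m) <- c("seat_height", "seat_depth", "seat_angle", "tire_pressure")
  m
}

#' Per-parameter level offsets for the test design
#'
#' The increments applied to the athlete's current set-up for the high/low
#' design levels: seat height and depth by 15 mm, seat angle by 5 degrees and
#' tire pressure by 15 psi unless overridden.
#'
#' @param seat_height,seat_depth Offsets in mm (> 0).
#' @param seat_angle Offset in deg (> 0).
#' @param tire_pressure Offset in psi (> 0).
#' @return A named list of class `level_deltas`.
#' @export
level_deltas <- function(seat_height = 15, seat_depth = 15,
                         seat_angle = 5, tire_pressure = 15) {
  d <- list(seat_height = seat_height, seat_depth = seat_depth,
            seat_angle = seat_angle, tire_pressure = tire_pressure)
  if (any(unlist(d) <= 0)) stop("level deltas must be positive", call. = FALSE)
  structure(d, class = "level_deltas")
}

#' Realize the L9 design around a baseline set-up
#'
#' Builds the nine tested configurations: each array row adds
#' `level * delta` to the corresponding baseline parameter. Row 1 is the
#' baseline itself.
#'
#' @param baseline A [setup_config()]: the athlete's current set-up.
#' @param deltas A [level_deltas()] object.
#' @return A data frame of class `design_plan` with columns `setup_id`,
#'   the four level columns (`level_seat_height`, ...), and the realized
#'   parameter values.
#' @examples
#' build_setups(setup_config(400, 100, 10, 100))
#' @export
build_setups <- function(baseline, deltas = level_deltas()) {
  baseline <- as_setup_config(baseline)
  arr <- l9_array()
  pars <- colnames(arr)
  realized <- sapply(pars, function(p) baseline[[p]] + arr[, p] * deltas[[p]])
  realized <- as.data.frame(realized)
  if (any(realized$seat_height <= 0)) {
    stop("invalid design: a realized seat_height is <= 0 mm", call. = FALSE)
  }
  if (any(realized$tire_pressure <= 0)) {
    stop("invalid design: a realized tire_pressure is <= 0 psi", call. = FALSE)
  }
  if (any(realized$seat_depth < 0)) {
    stop("invalid design: a realized seat_depth is negative", call. = FALSE)
  }
  levels <- as.data.frame(arr)
  names(levels) <- paste0("level_", pars)
  out <- cbind(data.frame(setup_id = 1:9), levels, realized)
  class(out) <- c("design_plan", class(out))
  out
}

#' Randomize the execution order of a design plan
#'
#' Testing order is a seeded shuffle of run execution; the array itself (and
#' hence `setup_id`) is never permuted, so set-up 1 remains the baseline run
#' and the train/test split by set-up order is unaffected.
#'
#' @param plan A `design_plan` from [build_setups()].
#' @return The plan with an added `run_order` column.
#' @export
randomize_run_order <- function(plan) {
  plan$run_order <- sample.int(nrow(plan))
  plan
}

#' Level-average (main-effect) analysis of a design response
#'
#' For each parameter and level, the mean response over the three runs at
#' that level is compared against the grand mean; in the balanced L9 the
#' three effects of every parameter sum to zero and main effects of a purely
#' additive response are recovered exactly.
#'
#' @param plan A `design_plan` from [build_setups()].
#' @param responses Numeric vector of one response per plan row (e.g. mean
#'   sprint time per set-up, s).
#' @return A data frame with columns `parameter`, `level`, `level_mean`,
#'   `effect` (level mean minus grand mean).
#' @export
level_average_analysis <- function(plan, responses) {
  if (length(responses) != nrow(plan) || anyNA(responses)) {
    stop("incomplete design: need one non-missing response per plan row",
         call. = FALSE)
  }
  grand <- mean(responses)
  pars <- c("seat_height", "seat_depth", "seat_angle", "tire_pressure")
  rows <- lapply(pars, function(p) {
    lev <- plan[[paste0("level_", p)]]
    means <- tapply(responses, factor(lev, levels = c(-1, 0, 1)), mean)
    data.frame(parameter = p, level = c(-1, 0, 1),
               level_mean = as.numeric(means),
               effect = as.numeric(means) - grand)
  })
  out <- do.call(rbind, rows)
  attr(out, "grand_mean") <- grand
  out
}
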