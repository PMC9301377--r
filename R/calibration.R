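#' Grid-search fit of a single propulsion coefficient
#'
#' The predicted angle is linear in the coefficient (`beta * base`), so the
#' geometry is evaluated once at `beta = 1` and the coefficient grid is then
#' searched exhaustively for the value minimizing the absolute error against
#' the measured angle. Ties break toward the smaller coefficient; the result
#' is confined to the grid bounds.
#'
#' @param measured_angle Measured contact or release angle, deg.
#' @param base_angle Model angle at `beta = 1` for the same geometry, deg.
#' @param grid Numeric `c(lo, hi, step)`; defaults to the standard coefficient
#'   grid `c(-0.5, 1.5, 0.01)` (201 candidate values at two decimal places).
#' @return The fitted coefficient (a grid value).
#' @examples
#' fit_coefficient(30, 30)    # assumption exactly true -> 1
#' fit_coefficient(100, 50)   # clipped at the upper bound -> 1.5
#' @export
fit_coefficient <- function(measured_angle, base_angle,
                            grid = c(-0.5, 1.5, 0.01)) {
  stopifnot(length(grid) == 3, grid[3] > 0, grid[2] > grid[1])
  if (!is.finite(measured_angle) || !is.finite(base_angle)) {
    stop("measured and base angles must be finite", call. = FALSE)
  }
  if (base_angle == 0 && measured_angle != 0) {
    stop("coefficient is unidentifiable: model base angle is 0 but measured angle is not",
         call. = FALSE)
  }
  betas <- seq(grid[1], grid[2], by = grid[3])
  err <- abs(measured_angle - betas * base_angle)
  # which.min returns the first minimum; betas ascend, so ties go to smaller beta
  betas[which.min(err)]
}

#' Calibrate an athlete's per-stroke coefficients from measured kinematics
#'
#' For each stroke and each tested set-up, measured contact and release
#' angles are pooled (per-side means, then the mean across sides, which also
#' averages repeat trials) and a coefficient is fitted on the grid against
#' the linkage-model base angle for that set-up. The per-set-up coefficients
#' are then averaged across set-ups and rounded to two decimal places; the
#' frozen set assumes the athlete keeps one propulsion technique across
#' set-ups. Contact and release are calibrated independently.
#'
#' @param measured Data frame of measured strokes with columns `setup_id`,
#'   `stroke`, `contact_deg`, `release_deg` and optionally `side` and `trial`.
#' @param ath An [athlete()] (trunk profile and method are used).
#' @param plan Realized design: data frame with `setup_id`, `seat_height`,
#'   `seat_depth`, `seat_angle`, `tire_pressure` (see [build_setups()]).
#' @param grid Coefficient grid `c(lo, hi, step)` as in [fit_coefficient()].
#' @return A data frame of class `coefficient_set` with columns `stroke`,
#'   `beta_contact`, `beta_release`; the per-set-up fits are attached as
#'   attribute `"per_setup"`.
#' @export
calibrate_athlete <- function(measured, ath, plan, grid = c(-0.5, 1.5, 0.01)) {
  stopifnot(inherits(ath, "athlete"))
  req <- c("setup_id", "stroke", "contact_deg", "release_deg")
  if (!all(req %in% names(measured))) {
    stop("measured kinematics need columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!"side" %in% names(measured)) measured$side <- "pooled"
  strokes <- sort(unique(measured$stroke))
  per_setup <- list()
  final <- list()
  for (k in 1:3) {
    obs <- measured[measured$stroke == k, , drop = FALSE]
    if (nrow(obs) == 0) {
      stop(sprintf("athlete %s cannot be calibrated: no observations for stroke %d",
                   ath$id, k), call. = FALSE)
    }
    fits <- lapply(unique(obs$setup_id), function(sid) {
      su_row <- plan[plan$setup_id == sid, , drop = FALSE]
      if (nrow(su_row) != 1) {
        stop(sprintf("set-up %s missing from the design plan", sid), call. = FALSE)
      }
      su <- as_setup_config(su_row)
      o <- obs[obs$setup_id == sid, , drop = FALSE]
      # per-side means first, then average side means (left/right combined to
      # reduce the impact of outliers; a missing side just drops out)
      m_contact <- mean(tapply(o$contact_deg, o$side, mean))
      m_release <- mean(tapply(o$release_deg, o$side, mean))
      ta <- trunk_angles_at(ath, su$seat_angle, k)
      base_c <- contact_angle(ath$anthro, su, ta$theta_ti, beta = 1,
                              method = ath$method)
      base_r <- release_angle(ath$anthro, su, ta$theta_tr, beta_r = 1)
      data.frame(setup_id = sid, stroke = k,
                 beta_contact = fit_coefficient(m_contact, base_c, grid),
                 beta_release = fit_coefficient(m_release, base_r, grid))
    })
    fits <- do.call(rbind, fits)
    per_setup[[k]] <- fits
    final[[k]] <- data.frame(
      stroke = k,
      beta_contact = round(mean(fits$beta_contact), 2),
      beta_release = round(mean(fits$beta_release), 2))
  }
  out <- do.call(rbind, final)
  attr(out, "per_setup") <- do.call(rbind, per_setup)
  class(out) <- c("coefficient_set", class(out))
  out
}
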