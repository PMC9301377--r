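#' Names of the 13 sprint-time predictors, in canonical order
#'
#' Set-up parameters first (seat height mm, seat depth mm, seat angle deg,
#' tire pressure psi), then contact, release and push angles (deg) for the
#' first three strokes.
#'
#' @return Character vector of length 13.
#' @export
feature_names <- function() {
  c("seat_height", "seat_depth", "seat_angle", "tire_pressure",
    paste0("contact_", 1:3), paste0("release_", 1:3), paste0("push_", 1:3))
}

#' Assemble the 13-predictor feature vector for one trial
#'
#' @param setup A [setup_config()] (or a row with the four parameters).
#' @param kin Data frame with columns `stroke`, `contact`, `release` for
#'   strokes 1--3 (as from [predict_stroke_kinematics()]); push angles are
#'   recomputed as release minus contact.
#' @return Named numeric vector of length 13 in [feature_names()] order.
#' @export
assemble_features <- function(setup, kin) {
  setup <- as_setup_config(setup)
  if (!all(1:3 %in% kin$stroke)) {
    stop("incomplete features: kinematics must cover strokes 1, 2 and 3",
         call. = FALSE)
  }
  kin <- kin[match(1:3, kin$stroke), , drop = FALSE]
  v <- c(setup$seat_height, setup$seat_depth, setup$seat_angle,
         setup$tire_pressure, kin$contact, kin$release,
         kin$release - kin$contact)
  stats::setNames(v, feature_names())
}

#' Fit a PLS1 regression by NIPALS
#'
#' Partial-least-squares regression of a single response on a predictor
#' matrix: components are extracted iteratively, each maximizing covariance
#' between the (deflated) predictors and the response. Predictors and
#' response are mean-centered; unit-variance scaling of the predictors is
#' optional and off by default. Per-component explained variance in both the
#' predictors and the response is recorded for component selection.
#'
#' @param X Numeric matrix or data frame, n rows by p predictors.
#' @param y Numeric response of length n (sprint time, s).
#' @param n_components Number of latent components to extract; capped at the
#'   rank limit `min(n - 1, p)`.
#' @param scale Logical; scale predictors to unit variance before fitting.
#' @return An object of class `pls_model` with the fitted weights, loadings,
#'   per-component regression coefficients and explained variances
#'   (`explvar_x`, `explvar_y`, in percent per component).
#' @export
train_pls <- function(X, y, n_components, scale = FALSE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X and y sizes differ", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("X and y must be complete", call. = FALSE)
  if (stats::var(y) == 0) stop("response is constant; nothing to fit", call. = FALSE)
  kmax <- min(n - 1L, p)
  if (n_components < 1) stop("n_components must be >= 1", call. = FALSE)
  if (n < n_components + 1) {
    stop("need at least n_components + 1 training rows", call. = FALSE)
  }
  n_components <- min(n_components, kmax)

  x_center <- colMeans(X)
  Xc <- sweep(X, 2, x_center)
  x_scale <- rep(1, p)
  if (scale) {
    x_scale <- apply(Xc, 2, stats::sd)
    x_scale[x_scale == 0] <- 1
    Xc <- sweep(Xc, 2, x_scale, "/")
  }
  if (all(abs(Xc) < 1e-12)) {
    stop("degenerate predictors: all training rows are identical", call. = FALSE)
  }
  y_center <- mean(y)
  yc <- y - y_center

  ss_x <- sum(Xc^2)
  ss_y <- sum(yc^2)
  W <- P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  Xr <- Xc; yr <- yc
  k_used <- 0L
  for (h in seq_len(n_components)) {
    w <- drop(crossprod(Xr, yr))          # covariance direction
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break                 # residual predictors uninformative
    w <- w / wn
    t_h <- drop(Xr %*% w)
    tt <- sum(t_h^2)
    if (tt < 1e-12) break
    p_h <- drop(crossprod(Xr, t_h)) / tt
    q_h <- sum(yr * t_h) / tt
    Xr <- Xr - tcrossprod(t_h, p_h)
    yr <- yr - t_h * q_h
    k_used <- h
    W[, h] <- w; P[, h] <- p_h; Tm[, h] <- t_h; q[h] <- q_h
  }
  if (k_used == 0L) stop("PLS training failed: no informative component",
                         call. = FALSE)
  W <- W[, seq_len(k_used), drop = FALSE]
  P <- P[, seq_len(k_used), drop = FALSE]
  Tm <- Tm[, seq_len(k_used), drop = FALSE]
  q <- q[seq_len(k_used)]

  tss <- colSums(Tm^2)
  explvar_x <- 100 * colSums(P^2) * tss / ss_x
  explvar_y <- 100 * q^2 * tss / ss_y

  # cumulative regression coefficients (centered/scaled space) for each k
  coefs <- matrix(0, p, k_used)
  for (k in seq_len(k_used)) {
    Wk <- W[, 1:k, drop = FALSE]
    Pk <- P[, 1:k, drop = FALSE]
    coefs[, k] <- Wk %*% solve(crossprod(Pk, Wk), q[1:k])
  }
  rownames(coefs) <- colnames(X)

  structure(list(n_components = k_used, x_center = x_center,
                 x_scale = x_scale, y_center = y_center, scale = scale,
                 weights = W, loadings = P, q = q, coefficients = coefs,
                 explvar_x = explvar_x, explvar_y = explvar_y,
                 feature_names = colnames(X)),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d component(s), %d predictors%s\n",
              x$n_components, nrow(x$coefficients),
              if (x$scale) ", scaled" else ""))
  cat("  explained variance in y (%):",
      paste(sprintf("%.1f", x$explvar_y), collapse = " "), "\n")
  invisible(x)
}

#' Choose the number of PLS components at the explained-variance plateau
#'
#' The component count is the largest number of leading components whose
#' per-component explained variance in the response all meet the plateau
#' threshold: selection stops just before the first component contributing
#' less than `plateau` percentage points, and is capped (five by default).
#'
#' @param explvar_y Per-component explained variance in the response, in
#'   percentage points (as from a [train_pls()] fit).
#' @param plateau Plateau threshold in percentage points.
#' @param cap Maximum number of components.
#' @return Selected component count (>= 1).
#' @examples
#' select_components(c(60, 20, 10, 1, 0.5))  # 3
#' @export
select_components <- function(explvar_y, plateau = 2, cap = 5) {
  stopifnot(length(explvar_y) >= 1)
  below <- which(explvar_y < plateau)
  k <- if (length(below) == 0) length(explvar_y) else below[1] - 1L
  max(1L, min(k, cap, length(explvar_y)))
}

#' Split trial rows into training and test sets by set-up order
#'
#' The first seven of the nine tested set-ups train the prediction models and
#' the final two assess them; all trials of a set-up stay on one side of the
#' split. With a different number of set-ups the split falls back to holding
#' out the final two set-ups, with a warning.
#'
#' @param trials Data frame with a `setup_id` column (plus any trial data).
#' @param n_train_setups Number of leading set-ups used for training.
#' @return List with elements `train` and `test` (row subsets of `trials`).
#' @export
split_train_test <- function(trials, n_train_setups = 7) {
  ids <- unique(trials$setup_id)
  n <- length(ids)
  if (n != 9) {
    n_train_setups <- max(1L, n - 2L)
    warning(sprintf("expected 9 set-ups, found %d; training on the first %d",
                    n, n_train_setups))
  }
  if (n_train_setups >= n) stop("no set-ups left for testing", call. = FALSE)
  train_ids <- ids[seq_len(n_train_setups)]
  list(train = trials[trials$setup_id %in% train_ids, , drop = FALSE],
       test = trials[!trials$setup_id %in% train_ids, , drop = FALSE])
}

#' Predict sprint time from a fitted PLS model
#'
#' @param model A `pls_model` from [train_pls()].
#' @param features A 13-value feature vector ([assemble_features()]), or a
#'   matrix/data frame of such rows.
#' @param ncomp Number of components to use (defaults to all fitted).
#' @return Predicted sprint time(s), s.
#' @export
predict_time <- function(model, features, ncomp = model$n_components) {
  stopifnot(inherits(model, "pls_model"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1,
                                                 dimnames = list(NULL, names(features)))
  X <- as.matrix(features)
  p <- nrow(model$coefficients)
  if (ncol(X) != p) {
    stop(sprintf("feature dimension %d does not match the model's %d predictors",
                 ncol(X), p), call. = FALSE)
  }
  if (!is.null(model$feature_names) && !is.null(colnames(X))) {
    X <- X[, model$feature_names, drop = FALSE]
  }
  ncomp <- max(1L, min(ncomp, model$n_components))
  Xc <- sweep(sweep(X, 2, model$x_center), 2, model$x_scale, "/")
  drop(model$y_center + Xc %*% model$coefficients[, ncomp])
}
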