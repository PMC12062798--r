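# State-difference least-squares identification of airway resistance and
# lung elastance from a matched assisted/natural session pair. Subtracting
# the plant balance of the natural session (group B) from the assisted one
# (group A) at matched phase points cancels the unmeasurable muscle
# pressure, leaving R*(Q_A - Q_B) + E*(V_A - V_B) = delta*Fa.

#' Build the identification design matrix
#'
#' Breath boundaries are detected once on the natural trace (metronome
#' pacing makes them common to the pair) and both traces are resampled onto
#' the same per-breath grid of `phase_points` uniformly spaced time points
#' by linear interpolation. The regressor matrix H has columns
#' (Q_A - Q_B, V_A - V_B); the response is y = delta * Fa from the assisted
#' trace, with delta reconciled to cmH2O/N. Rows where both differences
#' fall below `noise_floor` times their respective maxima are dropped (they
#' only inflate the conditioning) and counted.
#'
#' @param assisted assisted-session `session_trace` (group A).
#' @param natural natural-session `session_trace` (group B).
#' @param tm a [transmission_model()] supplying delta.
#' @param phase_points resampled points per breath (default 200).
#' @param noise_floor relative threshold for dropping inactive rows.
#' @return list with `H` (n x 2), `y`, `n_dropped`, `degenerate` (all-zero
#'   design, e.g. identical traces with no assistance).
#' @export
build_design <- function(assisted, natural, tm, phase_points = 200,
                         noise_floor = 0.01) {
  stopifnot(is.data.frame(assisted), is.data.frame(natural))
  if (nrow(assisted) != nrow(natural))
    stop("trace length mismatch: sessions must share the sampling grid",
         call. = FALSE)
  br <- segment_breaths(natural)
  if (nrow(br) < 1L) stop("no complete breath in the natural trace",
                          call. = FALSE)
  tA <- assisted$t; tB <- natural$t
  dQ <- c(); dV <- c(); fa <- c()
  for (k in seq_len(nrow(br))) {
    idx <- br$cycle_start[k]:br$cycle_end[k]
    tg <- seq(tB[idx[1L]], tB[idx[length(idx)]], length.out = phase_points)
    qa <- stats::approx(tA, assisted$Q, tg)$y
    va <- stats::approx(tA, assisted$V, tg)$y
    qb <- stats::approx(tB, natural$Q, tg)$y
    vb <- stats::approx(tB, natural$V, tg)$y
    dQ <- c(dQ, qa - qb); dV <- c(dV, va - vb)
    fa <- c(fa, stats::approx(tA, assisted$Fa, tg)$y)
  }
  H <- cbind(dQ = dQ, dV = dV)
  y <- delta_cmh2o(tm) * fa
  mq <- max(abs(dQ)); mv <- max(abs(dV))
  degenerate <- mq == 0 && mv == 0
  keep <- if (degenerate) rep(TRUE, nrow(H)) else
    abs(dQ) >= noise_floor * mq | abs(dV) >= noise_floor * mv
  list(H = H[keep, , drop = FALSE], y = y[keep],
       n_dropped = sum(!keep), degenerate = degenerate)
}

#' Least-squares identification of R and E
#'
#' Solves the normal equations of y = H (R, E)' for the airway resistance
#' and lung elastance. On noiseless synthetic data the generating values
#' are recovered to numerical precision. The condition number of H is
#' always reported; an ill-conditioned or singular design is an explicit
#' error (no silent pseudo-inverse fallback).
#'
#' @param H n x 2 design matrix of flow and volume state differences.
#' @param y response vector delta * Fa, cmH2O.
#' @param cond_cap maximum admissible condition number of H.
#' @return an object of class `lung_id` with fields `R_hat` (cmH2O.s/L),
#'   `E_hat` (cmH2O/L), `residual_norm`, `condition_number`, `n_samples`.
#' @export
identify_RE <- function(H, y, cond_cap = 1e8) {
  H <- as.matrix(H)
  if (ncol(H) != 2L || nrow(H) < 2L)
    stop("H must be an n x 2 matrix with n >= 2", call. = FALSE)
  if (length(y) != nrow(H)) stop("length(y) must match nrow(H)",
                                 call. = FALSE)
  d <- svd(H, nu = 0, nv = 0)$d
  cond <- if (d[2L] == 0) Inf else d[1L] / d[2L]
  if (!is.finite(cond) || cond > cond_cap)
    stop(sprintf("ill-conditioned design: condition number %.3g exceeds cap %.3g",
                 cond, cond_cap), call. = FALSE)
  est <- unname(drop(solve(crossprod(H), crossprod(H, y))))
  fitted <- drop(H %*% est)
  res <- y - fitted
  structure(list(R_hat = est[1L], E_hat = est[2L],
                 residual_norm = sqrt(sum(res^2)),
                 condition_number = cond, n_samples = nrow(H),
                 coefficients = c(R = unname(est[1L]), E = unname(est[2L])),
                 fitted.values = fitted, residuals = res),
            class = "lung_id")
}

#' Identify lung mechanics from a matched session pair
#'
#' High-level fitting interface: builds the state-difference design from an
#' assisted/natural trace pair and solves for (R, E).
#'
#' @inheritParams build_design
#' @param ... passed to [build_design()] and [identify_RE()].
#' @return a `lung_id` fit; see [identify_RE()].
#' @examples
#' \donttest{
#' s <- quiet_subject(subject_from_table("S1"))
#' spec_n <- session_spec("natural", 20, 30, seed = 7)
#' spec_a <- session_spec("assisted", 20, 30, seed = 7)
#' fit <- identify_lung(run_session(s, spec = spec_a, noise = FALSE),
#'                      run_session(s, spec = spec_n, noise = FALSE), s$tm)
#' coef(fit)  # recovers the subject's (R, E)
#' }
#' @export
identify_lung <- function(assisted, natural, tm, phase_points = 200,
                          noise_floor = 0.01, ...) {
  des <- build_design(assisted, natural, tm, phase_points, noise_floor)
  if (des$degenerate)
    stop("degenerate design: traces are identical (no assistance signal)",
         call. = FALSE)
  fit <- identify_RE(des$H, des$y, ...)
  fit$n_dropped <- des$n_dropped
  fit$call <- match.call()
  fit
}

#' @export
coef.lung_id <- function(object, ...) object$coefficients

#' @export
residuals.lung_id <- function(object, ...) object$residuals

#' @export
fitted.lung_id <- function(object, ...) object$fitted.values

#' @export
predict.lung_id <- function(object, newH, ...) {
  if (missing(newH)) return(object$fitted.values)
  drop(as.matrix(newH) %*% c(object$R_hat, object$E_hat))
}

#' @export
print.lung_id <- function(x, ...) {
  cat("State-difference least-squares lung identification\n")
  cat(sprintf("  R = %.4g cmH2O.s/L, E = %.4g cmH2O/L\n", x$R_hat, x$E_hat))
  cat(sprintf("  n = %d, ||residual|| = %.3g, condition number = %.3g\n",
              x$n_samples, x$residual_norm, x$condition_number))
  invisible(x)
}

#' @export
summary.lung_id <- function(object, ...) {
  rmse <- object$residual_norm / sqrt(object$n_samples)
  cat("State-difference least-squares lung identification\n")
  cat(sprintf("  airway resistance R = %.4g cmH2O.s/L\n", object$R_hat))
  cat(sprintf("  lung elastance   E = %.4g cmH2O/L\n", object$E_hat))
  cat(sprintf("  samples %d (%s dropped below noise floor), RMSE %.3g cmH2O, cond(H) %.3g\n",
              object$n_samples,
              if (is.null(object$n_dropped)) "0" else object$n_dropped,
              rmse, object$condition_number))
  invisible(object)
}
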