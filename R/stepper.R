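# One integration step: explicit prediction, assembly and factorization of
# the Newton iteration matrix, and the simplified Newton solve of the
# implicit corrector relation.

#' Explicit predictor for the next state
#'
#' Initial guess for the implicit corrector.  With step history available it
#' is the value at `t + h` of the degree-4 extrapolant matching `x`, `xdot`,
#' `xddot` at `t` and `xdot`, `xddot` at `t - h_prev` (order-matched to the
#' corrector and built entirely from stored derivative history).  On the very
#' first step it degenerates to the second-order Taylor polynomial
#' `x + h xdot + h^2/2 xddot`.
#'
#' @param history step history list with fields `x`, `xdot`, `xddot`,
#'   `has_prev` and, when `has_prev`, `h_prev`, `xdot_prev`, `xddot_prev`.
#' @param h step size (> 0).
#' @return Predicted state vector.
#' @export
predict_step <- function(history, h) {
  .check_pos_scalar(h, "h")
  if (!isTRUE(history$has_prev))
    return(history$x + h * history$xdot + 0.5 * h^2 * history$xddot)
  w <- .predictor_weights(h, history$h_prev)$weights
  w[["x"]] * history$x + w[["xdot"]] * history$xdot +
    w[["xddot"]] * history$xddot + w[["xdot_prev"]] * history$xdot_prev +
    w[["xddot_prev"]] * history$xddot_prev
}

#' Assemble and factorize the Newton iteration matrix
#'
#' `M = (h/2) J_f - (h^2/12) J_Jf - I`, with both Jacobians evaluated at the
#' predictor (simplified Newton: they stay frozen for the whole step) and
#' factorized exactly once.  Previously computed Jacobians (e.g. re-used from
#' the sensitivity stage of the last accepted step) can be injected through
#' `J` / `JJ`, in which case no new Jacobian evaluations are performed.
#'
#' @param model an `sd_model` (needs `second_rhs_jacobian`).
#' @param x_pred predictor state at which to evaluate the Jacobians.
#' @param p parameter vector.
#' @param h step size.
#' @param counters optional counter environment (internal bookkeeping).
#' @param J,JJ optional pre-evaluated Jacobians to re-use.
#' @return A Newton workspace: list with `M`, its `qr` factorization, the
#'   Jacobians `J`, `JJ`, `h` and `reused` flag.
#' @export
build_newton_matrix <- function(model, x_pred, p, h, counters = NULL,
                                J = NULL, JJ = NULL) {
  if (any(!is.finite(x_pred)))
    sd_error("sd_eval_error", "non-finite predictor state")
  reused <- !is.null(J) && !is.null(JJ)
  if (is.null(J)) {
    J <- model$jacobian(x_pred, p)
    if (!is.null(counters)) counters$n_jac <- counters$n_jac + 1L
  }
  if (is.null(JJ)) {
    if (is.null(model$second_rhs_jacobian))
      sd_error("sd_invalid_argument", "model lacks a 'second_rhs_jacobian' evaluator")
    JJ <- model$second_rhs_jacobian(x_pred, p)
    if (!is.null(counters)) counters$n_jjac <- counters$n_jjac + 1L
  }
  n <- model$n_states
  M <- (h / 2) * J - (h^2 / 12) * JJ - diag(n)
  if (any(!is.finite(M)))
    sd_error("sd_eval_error", "non-finite Newton matrix")
  qrM <- qr(M)
  if (!is.null(counters)) counters$n_fact <- counters$n_fact + 1L
  if (qrM$rank < n)
    sd_error("sd_singular_matrix",
             sprintf("Newton iteration matrix is singular (rank %d < %d)",
                     qrM$rank, n))
  list(M = M, qr = qrM, J = J, JJ = JJ, h = h, reused = reused)
}

#' Simplified Newton solve of the implicit corrector relation
#'
#' Iterates `x <- x - M^{-1} (g4(t+h) - x)` with the frozen, factorized
#' Newton matrix until the estimated remaining error (correction norm times
#' `theta/(1-theta)`, with `theta` the observed contraction rate) drops below
#' `newton_tol` in the weighted error norm.  Divergence is declared when the
#' contraction rate exceeds 0.9 twice or the correction grows.
#'
#' @param ws workspace from [build_newton_matrix()].
#' @param model an `sd_model`.
#' @param p parameter vector.
#' @param history step history (state and derivatives at `t`).
#' @param h step size.
#' @param x_pred predictor used as the starting iterate.
#' @param weights weight vector `atol + rtol |x|` defining the norm.
#' @param newton_tol convergence threshold in weighted-norm units.
#' @param max_iter iteration cap (default 7).
#' @param counters optional counter environment.
#' @return List with `converged`, the converged `x`, the consistent `xdot`
#'   (`f` at `x`) and `xddot` (`J_f f` at `x`), `iters` and the last
#'   correction norm.
#' @export
newton_solve <- function(ws, model, p, history, h, x_pred, weights,
                         newton_tol = 1e-7, max_iter = 7L, counters = NULL) {
  const <- history$x + (h / 2) * history$xdot + (h^2 / 12) * history$xddot
  x <- x_pred
  norm_old <- NA_real_; nbad <- 0L; converged <- FALSE; nd <- NA_real_
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    if (!is.null(counters)) { counters$n_newton <- counters$n_newton + 1L
                              counters$n_f <- counters$n_f + 1L
                              counters$n_xddot <- counters$n_xddot + 1L }
    f_new <- model$rhs(x, p)
    if (any(!is.finite(f_new))) break
    xdd_new <- second_derivative(model, x, p)
    resid <- const + (h / 2) * f_new - (h^2 / 12) * xdd_new - x
    delta <- -solve(ws$qr, resid)
    x <- x + delta
    if (any(!is.finite(x))) break
    nd <- .wrms(delta, weights)
    if (it > 1L) {
      theta <- nd / norm_old
      if (!is.finite(theta) || theta >= 1) break
      if (theta > 0.9) {
        nbad <- nbad + 1L
        if (nbad >= 2L) break
      }
      if (nd * theta / (1 - theta) <= newton_tol || nd == 0) {
        converged <- TRUE; break
      }
    } else if (nd <= 0.01 * newton_tol) {
      converged <- TRUE; break
    }
    norm_old <- nd
  }
  if (!converged)
    return(list(converged = FALSE, iters = it, correction_norm = nd,
                x_last = if (all(is.finite(x))) x else NULL))
  if (!is.null(counters)) { counters$n_f <- counters$n_f + 1L
                            counters$n_xddot <- counters$n_xddot + 1L }
  xdot <- model$rhs(x, p)
  xddot <- second_derivative(model, x, p)
  list(converged = TRUE, x = x, xdot = xdot, xddot = xddot,
       iters = it, correction_norm = nd)
}
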