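# Staggered computation of local parameter sensitivities s_k = dx/dp_k.
#
# The state step is converged first; the sensitivities then satisfy a
# *linear* version of the same implicit rule, so all n_p columns are obtained
# from a single matrix factorization (the left-hand side is k-independent).
# The Jacobians are re-evaluated at the converged state, as the staggered
# formulation requires, and can be fed back into the next step's Newton
# matrix.

#' Time derivatives of the sensitivity matrix
#'
#' `Sdot = J_f(x) S + df/dp(x)` (the linear sensitivity ODE) and
#' `Sddot = J_Jf(x) S + d(xddot)/dp(x)` (its second-derivative analogue).
#'
#' @param model an `sd_model` providing the parameter-derivative evaluators
#'   (otherwise an error of class `sd_unsupported_model` is raised; the
#'   module never finite-differences silently).
#' @param x state at which to evaluate.
#' @param p parameter vector.
#' @param S current `n_x x n_p` sensitivity matrix.
#' @param J,JJ optional pre-evaluated Jacobians at `x`.
#' @param counters optional counter environment.
#' @return List with `Sdot`, `Sddot` and the Jacobians `J`, `JJ` used.
#' @export
sensitivity_derivatives <- function(model, x, p, S, J = NULL, JJ = NULL,
                                    counters = NULL) {
  if (!supports_sensitivities(model))
    sd_error("sd_unsupported_model",
             "model lacks parameter-derivative evaluators (rhs_param_jac / second_rhs_param_jac)")
  S <- matrix(S, model$n_states, model$n_params)
  if (is.null(J)) {
    J <- model$jacobian(x, p)
    if (!is.null(counters)) counters$n_jac <- counters$n_jac + 1L
  }
  if (is.null(JJ)) {
    JJ <- model$second_rhs_jacobian(x, p)
    if (!is.null(counters)) counters$n_jjac <- counters$n_jjac + 1L
  }
  list(Sdot = J %*% S + model$rhs_param_jac(x, p),
       Sddot = JJ %*% S + model$second_rhs_param_jac(x, p),
       J = J, JJ = JJ)
}

# Right-hand side of the direct sensitivity solve, shared by both modes.
.sens_rhs <- function(prev, h, dfdp_new, dxddp_new) {
  prev$S + (h / 2) * (prev$Sdot + dfdp_new) +
    (h^2 / 12) * (prev$Sddot - dxddp_new)
}

#' Direct staggered sensitivity step
#'
#' After the state step has converged to `x_new` at `t + h`, the implicit
#' corrector applied to the sensitivity ODE is linear in the unknown
#' `S(t+h)`.  Isolating it gives
#' `(I - h/2 J_f + h^2/12 J_Jf) S(t+h) = S + h/2 (Sdot + df/dp) + h^2/12 (Sddot - d(xddot)/dp)`,
#' with all Jacobians and parameter derivatives freshly evaluated at the
#' converged state.  The left-hand side is the same for every parameter, so
#' one factorization serves all `n_p` columns.
#'
#' @param model an `sd_model` with parameter-derivative evaluators.
#' @param x_new converged state at `t + h`.
#' @param p parameter vector.
#' @param h step size of the accepted step.
#' @param prev sensitivity block at `t`: list with `S`, `Sdot`, `Sddot`.
#' @param counters optional counter environment (`n_fact_sens` increases by
#'   exactly 1 per call, independent of `n_p`).
#' @return Sensitivity block at `t + h` (`S`, `Sdot`, `Sddot`) plus the fresh
#'   `J`, `JJ` for re-use in the next step's Newton matrix.
#' @export
sensitivity_step_direct <- function(model, x_new, p, h, prev, counters = NULL) {
  if (!supports_sensitivities(model))
    sd_error("sd_unsupported_model",
             "model lacks parameter-derivative evaluators (rhs_param_jac / second_rhs_param_jac)")
  n <- model$n_states
  J <- model$jacobian(x_new, p)
  JJ <- model$second_rhs_jacobian(x_new, p)
  if (!is.null(counters)) { counters$n_jac <- counters$n_jac + 1L
                            counters$n_jjac <- counters$n_jjac + 1L }
  dfdp_new <- model$rhs_param_jac(x_new, p)
  dxddp_new <- model$second_rhs_param_jac(x_new, p)
  A <- diag(n) - (h / 2) * J + (h^2 / 12) * JJ
  qrA <- qr(A)
  if (!is.null(counters)) counters$n_fact_sens <- counters$n_fact_sens + 1L
  if (qrA$rank < n)
    sd_error("sd_singular_matrix", "singular sensitivity system matrix")
  S_new <- matrix(solve(qrA, .sens_rhs(prev, h, dfdp_new, dxddp_new)),
                  n, model$n_params)
  list(S = S_new,
       Sdot = J %*% S_new + dfdp_new,
       Sddot = JJ %*% S_new + dxddp_new,
       J = J, JJ = JJ, iters = NA_integer_)
}

#' Iterative staggered sensitivity step
#'
#' Solves the same linear relation as [sensitivity_step_direct()] by Newton
#' iteration that re-uses the *state* step's factorized Newton matrix (whose
#' Jacobians were evaluated at the predictor, not the converged state).
#' Because the residual is linear, the iteration contracts at a rate set by
#' the predictor-vs-converged Jacobian mismatch; it is provided as a
#' cross-validation mode and falls back to the direct solve if it does not
#' converge.
#'
#' @inheritParams sensitivity_step_direct
#' @param ws the state step's Newton workspace.
#' @param tol convergence threshold on the weighted correction norm.
#' @param weights weight vector for the norm (defaults to all-ones).
#' @param max_iter iteration cap.
#' @return Sensitivity block as in [sensitivity_step_direct()], with `iters`
#'   set to the number of iterations used (`NA` if it fell back).
#' @export
sensitivity_step_iterative <- function(model, x_new, p, h, prev, ws,
                                       tol = 1e-9, weights = NULL,
                                       max_iter = 12L, counters = NULL) {
  if (!supports_sensitivities(model))
    sd_error("sd_unsupported_model",
             "model lacks parameter-derivative evaluators (rhs_param_jac / second_rhs_param_jac)")
  n <- model$n_states; np <- model$n_params
  if (is.null(weights)) weights <- rep(1, n)
  J <- model$jacobian(x_new, p)
  JJ <- model$second_rhs_jacobian(x_new, p)
  if (!is.null(counters)) { counters$n_jac <- counters$n_jac + 1L
                            counters$n_jjac <- counters$n_jjac + 1L }
  dfdp_new <- model$rhs_param_jac(x_new, p)
  dxddp_new <- model$second_rhs_param_jac(x_new, p)
  B <- (h / 2) * J - (h^2 / 12) * JJ    # residual G(S) = const + B S - S
  const <- .sens_rhs(prev, h, dfdp_new, dxddp_new)
  S <- matrix(prev$S, n, np)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    resid <- const + B %*% S - S
    delta <- -matrix(solve(ws$qr, resid), n, np)
    S <- S + delta
    nd <- .wrms(delta, weights)
    if (!is.finite(nd)) break
    if (nd <= tol) { converged <- TRUE; break }
  }
  if (!converged) {
    out <- sensitivity_step_direct(model, x_new, p, h, prev, counters)
    out$iters <- NA_integer_
    return(out)
  }
  list(S = S,
       Sdot = J %*% S + dfdp_new,
       Sddot = JJ %*% S + dxddp_new,
       J = J, JJ = JJ, iters = it)
}
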