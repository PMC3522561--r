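# Local error estimation and step-size control.
#
# The error estimate is one Newton step from the converged corrector solution
# toward the degree-5 reference solution, computed with the step's
# already-factorized Newton matrix: a single extra back-substitution, no new
# factorization, no new model evaluations.

#' Local error estimate from the degree-5 reference rule
#'
#' Computes `eps = M^{-1} (g5(t+h) - x_new)`, where `g5` is assembled from
#' [g5_weights()] with the converged `xdot(t+h)`, `xddot(t+h)` and the stored
#' history (including the second-to-last value `x(t - h_prev)`).  The
#' back-substitution re-uses the factorization held in the workspace; the
#' factorization counter does not increase.
#'
#' Before any history exists (first step), or when the step ratio makes the
#' degree-5 system ill-conditioned, a lower-quality fallback based on the
#' corrector-predictor difference is returned (`quality = "fallback"`, with
#' controller order 3 matching the Taylor predictor).
#'
#' @param ws Newton workspace of the current step ([build_newton_matrix()]).
#' @param history step history at `t`.
#' @param h step size taken.
#' @param x_new,xdot_new,xddot_new converged state and derivatives at `t + h`.
#' @param x_pred predictor state (used by the fallback estimate).
#' @param atol,rtol tolerances defining the weighted norm (threshold 1).
#' @return List of class `sd_error_estimate`: `eps_vector`, `eps_norm`,
#'   `accepted` (`eps_norm <= 1`), `quality` (`"g5"` or `"fallback"`) and the
#'   controller `order`.
#' @export
estimate_error <- function(ws, history, h, x_new, xdot_new, xddot_new,
                           x_pred, atol, rtol) {
  est <- NULL
  if (isTRUE(history$has_prev)) {
    rw <- tryCatch(g5_weights(h, history$h_prev),
                   sd_step_ratio_error = function(e) NULL)
    if (!is.null(rw)) {
      w <- rw$weights
      g5 <- w[["x_prev"]] * history$x_prev + w[["x"]] * history$x +
        w[["xdot"]] * history$xdot + w[["xddot"]] * history$xddot +
        w[["xdot_new"]] * xdot_new + w[["xddot_new"]] * xddot_new
      eps <- drop(solve(ws$qr, g5 - x_new))
      est <- list(eps_vector = eps, quality = "g5", order = 5L)
    }
  }
  if (is.null(est)) {
    est <- list(eps_vector = x_new - x_pred, quality = "fallback", order = 3L)
  }
  est$eps_norm <- error_norm(est$eps_vector, x_new, atol, rtol)
  est$accepted <- est$eps_norm <= 1
  class(est) <- "sd_error_estimate"
  est
}

#' Step-size proposal from the local error estimate
#'
#' Assuming the leading error term varies slowly, the step scaling that makes
#' the *next* estimate equal to half the tolerance is
#' `sigma = (tau / (2 eps_norm))^(1/order)` (targeting `tau/2` rather than
#' `tau` so that roughly half the steps are not rejected).  `sigma` is
#' clipped to `[sigma_min, sigma_max]`.
#'
#' @param eps_norm weighted error-estimate norm of the last step (>= 0).
#' @param tau acceptance threshold in the same units (1 when the tolerance is
#'   absorbed into the norm weights).
#' @param h current step size.
#' @param sigma_min,sigma_max per-step scaling bounds (defaults 0.1 and 5).
#' @param order controller order (5 for the degree-5 estimate).
#' @return The proposed next step size `sigma * h`.
#' @examples
#' next_step_size(0.5, 1, h = 1)   # controller fixed point: h unchanged
#' next_step_size(16,  1, h = 1)   # (1/32)^(1/5) = 1/2
#' @export
next_step_size <- function(eps_norm, tau = 1, h, sigma_min = 0.1,
                           sigma_max = 5, order = 5L) {
  sigma <- if (eps_norm <= 0) sigma_max
           else (tau / (2 * eps_norm))^(1 / order)
  min(max(sigma, sigma_min), sigma_max) * h
}

# First-step size from the scales of f and xddot at the initial point,
# in the tolerance-weighted norm; always vetted by the first error estimate.
.initial_step_size <- function(x0, f0, xdd0, tspan, atol, rtol) {
  span <- tspan[2] - tspan[1]
  w <- .sd_weights(x0, atol, rtol)
  nf <- .wrms(f0, w)
  if (nf < .Machine$double.xmin^0.5) return(span / 10)
  h1 <- 0.01 * max(.wrms(x0, w), 1) / nf
  nxdd <- .wrms(xdd0, w)
  h2 <- if (nxdd > 0) (720 / nxdd)^(1 / 5) else Inf
  max(min(h1, h2, span / 10), span * 1e-12)
}
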