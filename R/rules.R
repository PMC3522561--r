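# Hermite-Birkhoff interpolation rules underlying the integrator:
# the degree-4 two-point corrector (g4), the degree-5 error-reference rule
# (g5, which adds the second-to-last value node), the explicit predictor,
# and the truncation-error constants.
#
# All weights are derived generically by solving the interpolation conditions
# in the scaled variable s = (t' - t)/h (for conditioning), not from
# hand-derived variable-step formulas; exactness on monomials up to the rule
# degree pins them down uniquely.

.rule_node_scales <- function(h, labels) {
  # derivative nodes carry their h / h^2 scaling inside the weight
  sc <- c(x_prev = 1, x = 1, xdot = h, xddot = h^2, xdot_new = h, xddot_new = h^2)
  sc[labels]
}

#' Weights of the degree-4 two-point corrector rule
#'
#' The implicit rule advances the state through
#' `x(t+h) = x(t) + h/2 (xdot(t) + xdot(t+h)) + h^2/12 (xddot(t) - xddot(t+h))`,
#' i.e. the degree-4 polynomial interpolating the state value at `t` and the
#' first and second time derivatives at both endpoints, evaluated at `t + h`.
#'
#' @param h step size (> 0).
#' @return An object of class `sd_rule_weights` with elements
#'   `weights` (applied to the raw node values, `h` scalings folded in),
#'   `unit_weights` (applied to the scaled nodes `x`, `h*xdot`, `h^2*xddot`,
#'   ...), `degree` and `h`.
#' @examples
#' g4_weights(1)$unit_weights  # 1, 1/2, 1/12, 1/2, -1/12
#' @seealso [g5_weights()], [truncation_constants()]
#' @export
g4_weights <- function(h) {
  .check_pos_scalar(h, "h")
  labels <- c("x", "xdot", "xddot", "xdot_new", "xddot_new")
  wu <- c(x = 1, xdot = 1 / 2, xddot = 1 / 12, xdot_new = 1 / 2, xddot_new = -1 / 12)
  structure(list(weights = wu * .rule_node_scales(h, labels),
                 unit_weights = wu, degree = 4L, h = h),
            class = "sd_rule_weights")
}

#' Weights of the degree-5 error-reference rule
#'
#' The degree-5 polynomial interpolating the same nodes as the corrector plus
#' the second-to-last accepted value `x(t - h_prev)`, evaluated at `t + h`.
#' The weights are obtained by solving the 6x6 Hermite-Birkhoff condition
#' system in the scaled variable `s = (t' - t)/h`.  For equal steps the
#' scaled weights on `h*xdot(t+h)` and `h^2*xddot(t+h)` have magnitudes
#' 14/31 and 2/31 - close to the corrector's 1/2 and 1/12, which is what
#' justifies re-using the corrector's Newton matrix for the error estimate.
#'
#' @param h current step size (> 0).
#' @param h_prev previous accepted step size (> 0).
#' @return An `sd_rule_weights` object; `unit_weights` are named
#'   `x_prev, x, xdot, xddot, xdot_new, xddot_new`.
#' @section Step-ratio guard: ratios `h/h_prev` outside `[1e-3, 1e3]` make the
#'   condition system ill-conditioned and raise an error of class
#'   `sd_step_ratio_error`; the driver then falls back to the
#'   predictor-difference error estimate.
#' @export
g5_weights <- function(h, h_prev) {
  .check_pos_scalar(h, "h")
  .check_pos_scalar(h_prev, "h_prev")
  ratio <- h / h_prev
  if (ratio < 1e-3 || ratio > 1e3)
    sd_error("sd_step_ratio_error",
             sprintf("step ratio h/h_prev = %.3g outside [1e-3, 1e3]", ratio),
             ratio = ratio)
  r <- h_prev / h
  m <- 0:5
  A <- rbind((-r)^m,                                   # p(-r)   = x(t - h_prev)
             c(1, rep(0, 5)),                          # p(0)    = x(t)
             c(0, 1, rep(0, 4)),                       # p'(0)   = h xdot(t)
             c(0, 0, 2, rep(0, 3)),                    # p''(0)  = h^2 xddot(t)
             c(0, m[-1] * 1^(m[-1] - 1)),              # p'(1)   = h xdot(t+h)
             c(0, 0, m[-(1:2)] * (m[-(1:2)] - 1)))     # p''(1)  = h^2 xddot(t+h)
  wu <- solve(t(A), rep(1, 6))                         # p(1) = sum(coef)
  labels <- c("x_prev", "x", "xdot", "xddot", "xdot_new", "xddot_new")
  names(wu) <- labels
  structure(list(weights = wu * .rule_node_scales(h, labels),
                 unit_weights = wu, degree = 5L,
                 h = h, h_prev = h_prev, step_ratio = ratio),
            class = "sd_rule_weights")
}

# Weights of the explicit degree-4 predictor: the polynomial matching
# x, xdot, xddot at t and xdot, xddot at t - h_prev, evaluated at t + h.
.predictor_weights <- function(h, h_prev) {
  r <- h_prev / h
  m <- 0:4
  A <- rbind(c(1, rep(0, 4)),                          # p(0)    = x(t)
             c(0, 1, rep(0, 3)),                       # p'(0)   = h xdot(t)
             c(0, 0, 2, rep(0, 2)),                    # p''(0)  = h^2 xddot(t)
             c(0, m[-1] * (-r)^(m[-1] - 1)),           # p'(-r)  = h xdot(t-h_prev)
             c(0, 0, m[-(1:2)] * (m[-(1:2)] - 1) * (-r)^(m[-(1:2)] - 2)))
  wu <- solve(t(A), rep(1, 5))
  labels <- c("x", "xdot", "xddot", "xdot_prev", "xddot_prev")
  names(wu) <- labels
  sc <- c(x = 1, xdot = h, xddot = h^2, xdot_prev = h, xddot_prev = h^2)
  list(weights = wu * sc, unit_weights = wu)
}

# Constant 5x5 condition matrix of the dense-output polynomial
# (conditions p(0), p'(0), p''(0), p'(1), p''(1) on scaled data).
.dense_A5 <- rbind(c(1, 0, 0, 0, 0),
                   c(0, 1, 0, 0, 0),
                   c(0, 0, 2, 0, 0),
                   c(0, 1, 2, 3, 4),
                   c(0, 0, 2, 6, 12))
.dense_A5_inv <- solve(.dense_A5)

# Evaluate the per-step degree-4 interpolant at scaled position s in [0, 1].
# b: 5 x n matrix of scaled node data (x0, h*xd0, h^2*xdd0, h*xd1, h^2*xdd1).
.dense_eval <- function(b, s) {
  co <- .dense_A5_inv %*% b
  drop(c(1, s, s^2, s^3, s^4) %*% co)
}

#' Leading truncation-error constants
#'
#' Computes, by measuring the one-step defect on the monomial `t^5` with unit
#' step, the leading local truncation-error constant (coefficient of
#' `h^5 x^(5)`) of the two-point second-derivative corrector and of the
#' constant-step implicit Adams-Moulton rule of the same degree.  The
#' Adams-Moulton constant is 19/720 versus 1/720 for the second-derivative
#' rule: a 19-fold advantage from the narrower interpolation stencil.
#'
#' Nothing is hard-coded: the corrector defect comes from [g4_weights()] and
#' the Adams-Moulton weights from the generic interpolatory-quadrature solve
#' on nodes `t+h, t, t-h, t-2h`.
#'
#' @return A list with `second_derivative` (1/720), `adams_moulton4` (19/720)
#'   and `ratio` (19).
#' @export
truncation_constants <- function() {
  val <- function(t) t^5
  d1 <- function(t) 5 * t^4
  d2 <- function(t) 20 * t^3
  # corrector defect on t^5, unit step from t = 0
  g4 <- g4_weights(1)
  nodes <- c(val(0), d1(0), d2(0), d1(1), d2(1))
  c_sd <- abs(sum(g4$weights * nodes) - val(1)) / factorial(5)
  # degree-4 Adams-Moulton: interpolatory quadrature on s = 1, 0, -1, -2
  s <- c(1, 0, -1, -2)
  V <- vapply(0:3, function(m) s^m, numeric(4))
  w_am <- solve(t(V), 1 / (1:4))          # int_0^1 s^m ds moments
  c_am <- abs(val(0) + sum(w_am * d1(s)) - val(1)) / factorial(5)
  list(second_derivative = c_sd, adams_moulton4 = c_am, ratio = c_am / c_sd)
}

#' @export
print.sd_rule_weights <- function(x, ...) {
  cat(sprintf("Interpolation rule of degree %d (h = %g%s)\n", x$degree, x$h,
              if (!is.null(x$h_prev)) sprintf(", h_prev = %g", x$h_prev) else ""))
  cat("scaled-node weights:\n")
  print(x$unit_weights)
  invisible(x)
}
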