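# Internal helpers shared across the solver modules.

# Classed conditions so callers can distinguish failure modes
# (model evaluation, singular matrices, extreme step ratios, validation).
sd_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "sd_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Weighted root-mean-square error norm
#'
#' The norm in which the Newton iteration and the step-acceptance test are
#' performed.  Each component is scaled by `atol + rtol * |x_ref|`, so the
#' acceptance threshold is 1 in these units: the tolerance is absorbed into
#' the weights.
#'
#' @param eps_vector error vector (per component).
#' @param x_ref reference state used to build the relative part of the weight.
#' @param atol absolute tolerance, scalar or per component.
#' @param rtol relative tolerance (scalar).
#' @return Non-negative scalar; 0 iff `eps_vector` is 0.
#' @examples
#' error_norm(c(2e-8, 0), c(0, 0), atol = 1e-8, rtol = 0)  # sqrt(2)
#' @export
error_norm <- function(eps_vector, x_ref, atol, rtol) {
  w <- atol + rtol * abs(x_ref)
  sqrt(mean((eps_vector / w)^2))
}

# Scaled weights vector used repeatedly inside the driver.
.sd_weights <- function(x_ref, atol, rtol) atol + rtol * abs(x_ref)

.wrms <- function(v, w) sqrt(mean((v / w)^2))

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == round(x)

.check_pos_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    sd_error("sd_invalid_argument",
             sprintf("'%s' must be a positive finite scalar", name))
  invisible(x)
}

# Fresh counter environment for solver statistics.
.new_counters <- function() {
  ct <- new.env(parent = emptyenv())
  ct$n_f <- 0L; ct$n_jac <- 0L; ct$n_jjac <- 0L; ct$n_xddot <- 0L
  ct$n_newton <- 0L; ct$n_fact <- 0L; ct$n_fact_sens <- 0L
  ct$steps_accepted <- 0L; ct$steps_rejected <- 0L; ct$rej_after_rej <- 0L
  ct$rej_newton <- 0L; ct$rej_error <- 0L
  ct
}

.counters_list <- function(ct) {
  list(steps_accepted = ct$steps_accepted,
       steps_rejected = ct$steps_rejected,
       n_f = ct$n_f, n_jac = ct$n_jac, n_jjac = ct$n_jjac,
       n_xddot = ct$n_xddot, n_newton = ct$n_newton,
       n_fact = ct$n_fact, n_fact_sens = ct$n_fact_sens,
       rejections_newton = ct$rej_newton, rejections_error = ct$rej_error,
       rejections_after_rejection = ct$rej_after_rej)
}
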