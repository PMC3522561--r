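# The model contract: what any integrable system must provide.
# Evaluators may come from the symbolic compiler (compile_model) or be
# supplied directly as R functions.

#' Construct an ODE model from evaluator functions
#'
#' Bundles the right-hand side `f(x, p)` of an autonomous ODE system with the
#' derivative evaluators the second-derivative integrator needs: the Jacobian
#' `J_f = df/dx`, the Jacobian `J_Jf = d(J_f f)/dx = dJ_f/dx . f + J_f^2` of
#' the second time derivative, and (for sensitivity analysis) the parameter
#' derivatives `df/dp` and `d(xddot)/dp`.
#'
#' @param n_states number of state variables (`n_x`, positive integer).
#' @param n_params number of parameters (`n_p`, non-negative integer).
#' @param rhs `function(x, p)` returning the length-`n_x` rate vector `f`.
#' @param jacobian `function(x, p)` returning the `n_x x n_x` matrix `J_f`.
#' @param second_rhs_jacobian `function(x, p)` returning `J_Jf`
#'   (required for integration).
#' @param xddot optional fused evaluator `function(x, p)` for the second time
#'   derivative `J_f f`.  When absent, [second_derivative()] falls back to the
#'   explicit matrix-vector product; a fused closed-form evaluator (the
#'   symbolic compiler emits one) is typically not much more expensive than
#'   `f` itself.
#' @param rhs_param_jac optional `function(x, p)` returning the
#'   `n_x x n_p` matrix `df/dp`.
#' @param second_rhs_param_jac optional `function(x, p)` returning
#'   `d(xddot)/dp`.  Both parameter evaluators must be present for the
#'   sensitivity module to run; it refuses to finite-difference silently.
#' @param jac_sparsity optional logical `n_x x n_x` structural pattern, a
#'   superset of the true non-zero pattern of `J_f`.
#' @param state_names,param_names optional labels.
#' @return An object of class `sd_model`.
#' @seealso [compile_model()] which generates all evaluators symbolically,
#'   [validate_model()], [second_derivative()].
#' @export
ode_model <- function(n_states, n_params, rhs, jacobian,
                      second_rhs_jacobian = NULL, xddot = NULL,
                      rhs_param_jac = NULL, second_rhs_param_jac = NULL,
                      jac_sparsity = NULL,
                      state_names = NULL, param_names = NULL) {
  if (!.is_count(n_states) || n_states < 1)
    sd_error("sd_invalid_argument", "'n_states' must be a positive integer")
  if (!.is_count(n_params))
    sd_error("sd_invalid_argument", "'n_params' must be a non-negative integer")
  stopifnot(is.function(rhs), is.function(jacobian))
  if (!is.null(jac_sparsity)) {
    jac_sparsity <- as.matrix(jac_sparsity)
    storage.mode(jac_sparsity) <- "logical"
    stopifnot(identical(dim(jac_sparsity), c(as.integer(n_states), as.integer(n_states))))
  }
  if (is.null(state_names)) state_names <- paste0("x", seq_len(n_states))
  if (is.null(param_names) && n_params > 0) param_names <- paste0("p", seq_len(n_params))
  structure(list(n_states = as.integer(n_states), n_params = as.integer(n_params),
                 rhs = rhs, jacobian = jacobian,
                 second_rhs_jacobian = second_rhs_jacobian, xddot = xddot,
                 rhs_param_jac = rhs_param_jac,
                 second_rhs_param_jac = second_rhs_param_jac,
                 jac_sparsity = jac_sparsity,
                 state_names = state_names, param_names = param_names),
            class = "sd_model")
}

#' @export
print.sd_model <- function(x, ...) {
  cat(sprintf("ODE model: %d states, %d parameters\n", x$n_states, x$n_params))
  cat(sprintf("  fused xddot: %s; parameter derivatives: %s\n",
              if (is.null(x$xddot)) "no (J_f f fallback)" else "yes",
              if (supports_sensitivities(x)) "yes" else "no"))
  if (!is.null(x$jac_sparsity))
    cat(sprintf("  Jacobian non-zero fraction: %.4g\n",
                mean(x$jac_sparsity)))
  invisible(x)
}

#' Does a model provide the evaluators needed for sensitivity analysis?
#' @param model an `sd_model`.
#' @return `TRUE` if both `rhs_param_jac` and `second_rhs_param_jac` are set.
#' @export
supports_sensitivities <- function(model) {
  !is.null(model$rhs_param_jac) && !is.null(model$second_rhs_param_jac)
}

#' Second time derivative of the state
#'
#' Evaluates `xddot = J_f(x) f(x)`, the quantity the two-point corrector rule
#' interpolates alongside `f`.  If the model supplies a fused evaluator
#' (the symbolic compiler emits one that re-uses the already computed `f`
#' components), that is used; otherwise the explicit matrix-vector product.
#'
#' @param model an `sd_model`.
#' @param x state vector (length `n_x`, finite).
#' @param p parameter vector.
#' @return The length-`n_x` vector of second time derivatives.
#' @examples
#' # enzyme / substrate / complex / product scheme: component 4 is k3 * f3
#' fx <- make_fixture("michaelis_menten")
#' m <- compile_model(fx$model)
#' x <- c(0.4, 0.7, 0.6, 0.1)
#' f <- m$rhs(x, fx$p)
#' all.equal(second_derivative(m, x, fx$p)[4], fx$p[3] * f[3])
#' @export
second_derivative <- function(model, x, p) {
  if (any(!is.finite(x)))
    sd_error("sd_eval_error",
             sprintf("non-finite state in component %d", which(!is.finite(x))[1]),
             index = which(!is.finite(x))[1])
  v <- if (!is.null(model$xddot)) model$xddot(x, p)
       else drop(model$jacobian(x, p) %*% model$rhs(x, p))
  bad <- which(!is.finite(v))
  if (length(bad))
    sd_error("sd_eval_error",
             sprintf("model evaluation failed: non-finite second derivative in component %d",
                     bad[1]),
             index = bad[1])
  v
}

# Central finite difference of a vector-valued map along coordinate j.
.fd_col <- function(fun, v, j, step) {
  d <- step * max(1, abs(v[j]))
  vp <- v; vp[j] <- v[j] + d
  vm <- v; vm[j] <- v[j] - d
  (fun(vp) - fun(vm)) / (2 * d)
}

#' Validate a model's analytic derivatives against finite differences
#'
#' Compares `jacobian`, `second_rhs_jacobian` and (when present) the
#' parameter-derivative evaluators against central finite differences of
#' `rhs` / [second_derivative()] at a generic point, and flags analytic
#' Jacobian entries outside the declared sparsity pattern.  This guards in
#' particular the identity `J_Jf = dJ_f/dx . f + J_f^2`.
#'
#' @param model an `sd_model`.
#' @param x0 state at which to validate; should be a generic (e.g. strictly
#'   positive) point so that structural zeros are distinguishable from
#'   accidental ones.
#' @param p parameter vector.
#' @param fd_step relative finite-difference step (default `1e-6`).
#' @param threshold if non-`NULL`, a maximum admissible relative discrepancy;
#'   exceeding it raises an error of class `sd_validation_error` naming the
#'   worst entry.
#' @return Invisibly for errors, otherwise a list with one report per
#'   evaluator: `max_rel` (worst relative discrepancy, scaled by the larger
#'   of 1 and the matrix magnitude), `worst` (its `(row, col)` index), plus
#'   `sparsity_violations` and `ok`.
#' @export
validate_model <- function(model, x0, p = numeric(0), fd_step = 1e-6,
                           threshold = NULL) {
  n <- model$n_states
  np <- model$n_params
  check <- function(analytic, fd) {
    scale <- max(1, max(abs(analytic)), max(abs(fd)))
    d <- abs(analytic - fd) / scale
    i <- which(d == max(d), arr.ind = TRUE)[1, , drop = TRUE]
    list(max_rel = max(d), worst = unname(i))
  }
  J <- model$jacobian(x0, p)
  J_fd <- vapply(seq_len(n), function(j) .fd_col(function(v) model$rhs(v, p),
                                                 x0, j, fd_step), numeric(n))
  rep_out <- list(jacobian = check(J, J_fd))
  if (!is.null(model$second_rhs_jacobian)) {
    JJ <- model$second_rhs_jacobian(x0, p)
    JJ_fd <- vapply(seq_len(n),
                    function(j) .fd_col(function(v) second_derivative(model, v, p),
                                        x0, j, fd_step), numeric(n))
    rep_out$second_rhs_jacobian <- check(JJ, JJ_fd)
  }
  if (supports_sensitivities(model)) {
    dfdp <- model$rhs_param_jac(x0, p)
    dfdp_fd <- vapply(seq_len(np), function(k) .fd_col(function(q) model$rhs(x0, q),
                                                       p, k, fd_step), numeric(n))
    rep_out$rhs_param_jac <- check(matrix(dfdp, n, np), matrix(dfdp_fd, n, np))
    dxdp <- model$second_rhs_param_jac(x0, p)
    dxdp_fd <- vapply(seq_len(np),
                      function(k) .fd_col(function(q) second_derivative(model, x0, q),
                                          p, k, fd_step), numeric(n))
    rep_out$second_rhs_param_jac <- check(matrix(dxdp, n, np), matrix(dxdp_fd, n, np))
  }
  viol <- if (!is.null(model$jac_sparsity)) {
    which(J != 0 & !model$jac_sparsity, arr.ind = TRUE)
  } else matrix(integer(0), 0, 2)
  rep_out$sparsity_violations <- viol
  worst_name <- names(rep_out)[which.max(vapply(
    rep_out[setdiff(names(rep_out), "sparsity_violations")],
    function(r) r$max_rel, 0))]
  worst <- rep_out[[worst_name]]
  rep_out$ok <- is.null(threshold) ||
    (worst$max_rel <= threshold && nrow(viol) == 0)
  if (!is.null(threshold) && !rep_out$ok)
    sd_error("sd_validation_error",
             sprintf("%s mismatch at entry (%d, %d): relative discrepancy %.3g exceeds %.3g",
                     worst_name, worst$worst[1], worst$worst[2],
                     worst$max_rel, threshold),
             report = rep_out)
  rep_out
}
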