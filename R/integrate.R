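# The integration driver: predict -> simplified Newton -> error estimate ->
# accept/reject -> sensitivity stage, with dense output and statistics.

#' Integrate a stiff ODE system with the second-derivative method
#'
#' Advances the system from `tspan[1]` to `tspan[2]` with the implicit
#' two-point second-derivative rule, adaptive steps from the reused-
#' factorization degree-5 error estimate, and (optionally) staggered direct
#' parameter sensitivities.
#'
#' @param model an `sd_model` (see [ode_model()], [compile_model()]).
#'   An `sd_symbolic` model is compiled on the fly.
#' @param x0 initial state (finite, length `n_x`).
#' @param p parameter vector.
#' @param tspan numeric length-2 increasing time interval.
#' @param rtol relative tolerance (scalar, default `1e-6`).
#' @param atol absolute tolerance (scalar or per component, default `1e-8`).
#' @param output_times optional times (within `tspan`) at which to report the
#'   solution via dense output; never constrain step selection.
#' @param sensitivities compute `S = dx/dp` alongside the states
#'   (default `FALSE`).  Sensitivities are excluded from the step-acceptance
#'   error norm: the step sequence is identical with and without them.
#' @param s0 initial sensitivity matrix `dx0/dp` (`n_x x n_p`, default zero;
#'   supply it when the initial conditions depend on the parameters).
#' @param sens_method `"direct"` (one factorization for all parameters,
#'   the default) or `"iterative"` (re-uses the state step's factorization;
#'   cross-validation mode).
#' @param jacobian_reuse re-use the Jacobians evaluated at the converged
#'   state during the sensitivity stage in the next step's Newton matrix
#'   (saves Jacobian evaluations at the predictor; requires
#'   `sensitivities = TRUE`).
#' @param newton_kappa Newton tolerance as a fraction of the acceptance
#'   threshold (default 0.1).
#' @param max_newton_iter simplified-Newton iteration cap (default 7).
#' @param sigma_min,sigma_max per-step step-scaling bounds (0.1, 5).
#' @param h_init optional first step size (otherwise chosen from the scales
#'   of `f` and `xddot` at `x0`).
#' @param h_min,h_max absolute step bounds; repeated failures at `h_min`
#'   abort the integration and return the partial solution with
#'   `success = FALSE`.
#' @param fixed_h if non-`NULL`, integrate with this constant step and the
#'   controller disabled (debug mode for order measurements).
#' @param max_steps cap on accepted steps (default `1e5`).
#' @return An object of class `sd_sol`: `times`, `states` (rows = times),
#'   `sens` (`n_x x n_p x n_t` array or `NULL`), `stats` (evaluation and
#'   factorization counters), `diagnostics` (per accepted step: `h`,
#'   `eps_norm`, Newton iterations, estimator quality), `success`, and the
#'   dense-output mesh used by [predict.sd_sol()].
#' @examples
#' fx <- make_fixture("linear_decay")
#' sol <- sd_integrate(compile_model(fx$model), fx$x0, fx$p, c(0, 10),
#'                     rtol = 1e-8, atol = 1e-10)
#' abs(sol$states[nrow(sol$states), 1] - exp(-10)) / exp(-10)
#' @export
sd_integrate <- function(model, x0, p = numeric(0), tspan,
                         rtol = 1e-6, atol = 1e-8,
                         output_times = NULL,
                         sensitivities = FALSE, s0 = NULL,
                         sens_method = c("direct", "iterative"),
                         jacobian_reuse = FALSE,
                         newton_kappa = 0.1, max_newton_iter = 7L,
                         sigma_min = 0.1, sigma_max = 5,
                         h_init = NULL, h_min = NULL, h_max = Inf,
                         fixed_h = NULL, max_steps = 100000L) {
  if (inherits(model, "sd_symbolic")) model <- compile_model(model)
  if (!inherits(model, "sd_model"))
    sd_error("sd_invalid_argument", "'model' must be an 'sd_model' or 'sd_symbolic'")
  sens_method <- match.arg(sens_method)
  if (!is.numeric(tspan) || length(tspan) != 2L || !all(is.finite(tspan)) ||
      tspan[2] <= tspan[1])
    sd_error("sd_invalid_argument", "'tspan' must be a finite increasing interval")
  if (any(rtol <= 0) || any(atol <= 0))
    sd_error("sd_invalid_argument", "tolerances must be positive")
  if (any(!is.finite(x0)) || length(x0) != model$n_states)
    sd_error("sd_invalid_argument", "'x0' must be finite with length n_states")
  if (sensitivities && !supports_sensitivities(model))
    sd_error("sd_unsupported_model",
             "sensitivities requested but the model lacks parameter-derivative evaluators")
  if (jacobian_reuse && !sensitivities)
    sd_error("sd_invalid_argument",
             "'jacobian_reuse' needs the sensitivity stage (sensitivities = TRUE)")
  t0 <- tspan[1]; tend <- tspan[2]; span <- tend - t0
  if (is.null(h_min)) h_min <- max(span * 1e-13, 16 * .Machine$double.eps * max(abs(tspan)))
  ct <- .new_counters()
  fixed <- !is.null(fixed_h)
  newton_tol <- newton_kappa  # acceptance threshold is 1 in weighted units

  x0 <- as.numeric(x0)
  f0 <- model$rhs(x0, p); ct$n_f <- ct$n_f + 1L
  xdd0 <- second_derivative(model, x0, p); ct$n_xddot <- ct$n_xddot + 1L
  if (any(!is.finite(f0)))
    sd_error("sd_eval_error", "right-hand side not finite at the initial state")

  np <- model$n_params
  sens_block <- NULL
  if (sensitivities) {
    S0 <- if (is.null(s0)) matrix(0, model$n_states, np) else
      matrix(s0, model$n_states, np)
    sd0 <- sensitivity_derivatives(model, x0, p, S0, counters = ct)
    sens_block <- list(S = S0, Sdot = sd0$Sdot, Sddot = sd0$Sddot)
  }

  h <- if (fixed) fixed_h else if (!is.null(h_init)) h_init else
    .initial_step_size(x0, f0, xdd0, tspan, atol, rtol)
  h <- min(h, h_max, span)

  hist <- list(t = t0, x = x0, xdot = f0, xddot = xdd0, has_prev = FALSE)

  cap <- 256L
  times <- numeric(cap); Xs <- matrix(NA_real_, cap, model$n_states)
  Xd <- Xs; Xdd <- Xs
  times[1] <- t0; Xs[1, ] <- x0; Xd[1, ] <- f0; Xdd[1, ] <- xdd0
  if (sensitivities) {
    Sarr <- array(NA_real_, c(model$n_states, np, cap))
    Sdarr <- Sarr; Sddarr <- Sarr
    Sarr[, , 1] <- sens_block$S; Sdarr[, , 1] <- sens_block$Sdot
    Sddarr[, , 1] <- sens_block$Sddot
  }
  nrec <- 1L
  diag_h <- numeric(0); diag_eps <- numeric(0); diag_iter <- integer(0)
  diag_quality <- character(0); diag_clamped <- logical(0)

  grow <- function() {
    cap2 <- cap * 2L
    times <<- c(times, numeric(cap))
    Xs <<- rbind(Xs, matrix(NA_real_, cap, model$n_states))
    Xd <<- rbind(Xd, matrix(NA_real_, cap, model$n_states))
    Xdd <<- rbind(Xdd, matrix(NA_real_, cap, model$n_states))
    if (sensitivities) {
      pad <- array(NA_real_, c(model$n_states, np, cap))
      abind2 <- function(a, b) {
        out <- array(NA_real_, c(dim(a)[1:2], dim(a)[3] + dim(b)[3]))
        out[, , seq_len(dim(a)[3])] <- a
        out
      }
      Sarr <<- abind2(Sarr, pad); Sdarr <<- abind2(Sdarr, pad)
      Sddarr <<- abind2(Sddarr, pad)
    }
    cap <<- cap2
  }

  t <- t0
  reuse_J <- NULL; reuse_JJ <- NULL
  last_rejected <- FALSE
  success <- TRUE; message_out <- NULL
  tiny <- 4 * .Machine$double.eps * max(abs(t0), abs(tend))

  while (t < tend - tiny) {
    if (ct$steps_accepted >= max_steps) {
      success <- FALSE
      message_out <- sprintf("maximum number of steps (%d) reached at t = %g",
                             max_steps, t)
      break
    }
    clamped <- FALSE
    if (fixed) {
      h <- min(fixed_h, tend - t)
    } else {
      h <- min(h, h_max)
      if (t + 1.05 * h >= tend) { h <- tend - t; clamped <- TRUE }
    }
    if (h < h_min) {
      success <- FALSE
      message_out <- sprintf("step size %.3g below h_min at t = %g", h, t)
      break
    }

    # Newton attempt cascade at this h: the degree-4 extrapolant predictor
    # first; if the frozen-Jacobian iteration fails (stiff components make
    # high-order extrapolation unreliable), retry with the robust first-order
    # Taylor predictor, then once more continuing from the last Newton
    # iterate with a fresh matrix.  Every sub-attempt evaluates the Jacobians
    # once at its own predictor and counts as one attempted (rejected) step.
    x_pred0 <- predict_step(hist, h)
    preds <- list(x_pred0)
    if (isTRUE(hist$has_prev)) preds <- c(preds, list(hist$x + h * hist$xdot))
    res <- NULL
    for (k in seq_len(length(preds) + 1L)) {
      x_pred <- if (k <= length(preds)) preds[[k]] else res_last
      if (is.null(x_pred)) break
      attempt <- tryCatch({
        w <- .sd_weights(pmax(abs(hist$x), abs(x_pred)), atol, rtol)
        ws <- build_newton_matrix(model, x_pred, p, h, ct,
                                  J = if (k == 1L) reuse_J else NULL,
                                  JJ = if (k == 1L) reuse_JJ else NULL)
        ns <- newton_solve(ws, model, p, hist, h, x_pred, w,
                           newton_tol = newton_tol,
                           max_iter = max_newton_iter, counters = ct)
        list(ws = ws, ns = ns, x_pred = x_pred)
      }, sd_eval_error = function(e) NULL, sd_singular_matrix = function(e) NULL)
      if (!is.null(attempt) && attempt$ns$converged) { res <- attempt; break }
      res_last <- if (!is.null(attempt)) attempt$ns$x_last else NULL
      if (k < length(preds) + 1L) {      # failed sub-attempt: count and go on
        ct$steps_rejected <- ct$steps_rejected + 1L
        ct$rej_newton <- ct$rej_newton + 1L
        reuse_J <- NULL; reuse_JJ <- NULL
      }
    }

    if (is.null(res)) {                  # all sub-attempts failed: reduce h
      ct$steps_rejected <- ct$steps_rejected + 1L
      ct$rej_newton <- ct$rej_newton + 1L
      if (last_rejected) ct$rej_after_rej <- ct$rej_after_rej + 1L
      last_rejected <- TRUE
      reuse_J <- NULL; reuse_JJ <- NULL
      h <- h / 2
      next
    }

    ns <- res$ns; ws <- res$ws
    est <- estimate_error(ws, hist, h, ns$x, ns$xdot, ns$xddot,
                          res$x_pred, atol, rtol)

    if (!fixed && !est$accepted) {
      ct$steps_rejected <- ct$steps_rejected + 1L
      ct$rej_error <- ct$rej_error + 1L
      if (last_rejected) ct$rej_after_rej <- ct$rej_after_rej + 1L
      last_rejected <- TRUE
      reuse_J <- NULL; reuse_JJ <- NULL
      h <- next_step_size(est$eps_norm, 1, h, sigma_min, sigma_max, est$order)
      next
    }

    # ---- accepted ----
    last_rejected <- FALSE
    if (sensitivities) {
      blk <- if (sens_method == "direct")
        sensitivity_step_direct(model, ns$x, p, h, sens_block, ct)
      else
        sensitivity_step_iterative(model, ns$x, p, h, sens_block, ws,
                                   tol = newton_tol,
                                   weights = .sd_weights(ns$x, atol, rtol),
                                   counters = ct)
      sens_block <- blk
      if (jacobian_reuse) { reuse_J <- blk$J; reuse_JJ <- blk$JJ }
    }
    hist <- list(t = t + h, x = ns$x, xdot = ns$xdot, xddot = ns$xddot,
                 x_prev = hist$x, xdot_prev = hist$xdot,
                 xddot_prev = hist$xddot, h_prev = h, has_prev = TRUE)
    t <- t + h
    ct$steps_accepted <- ct$steps_accepted + 1L
    nrec <- nrec + 1L
    if (nrec > cap) grow()
    times[nrec] <- t; Xs[nrec, ] <- ns$x; Xd[nrec, ] <- ns$xdot
    Xdd[nrec, ] <- ns$xddot
    if (sensitivities) {
      Sarr[, , nrec] <- sens_block$S
      Sdarr[, , nrec] <- sens_block$Sdot
      Sddarr[, , nrec] <- sens_block$Sddot
    }
    diag_h <- c(diag_h, h); diag_eps <- c(diag_eps, est$eps_norm)
    diag_iter <- c(diag_iter, ns$iters)
    diag_quality <- c(diag_quality, est$quality)
    diag_clamped <- c(diag_clamped, clamped)
    if (!fixed)
      h <- next_step_size(est$eps_norm, 1, h, sigma_min, sigma_max, est$order)
  }

  idx <- seq_len(nrec)
  mesh <- list(times = times[idx],
               states = Xs[idx, , drop = FALSE],
               xdots = Xd[idx, , drop = FALSE],
               xddots = Xdd[idx, , drop = FALSE],
               sens = if (sensitivities) Sarr[, , idx, drop = FALSE] else NULL,
               sens_dot = if (sensitivities) Sdarr[, , idx, drop = FALSE] else NULL,
               sens_ddot = if (sensitivities) Sddarr[, , idx, drop = FALSE] else NULL)
  colnames(mesh$states) <- model$state_names
  stats <- .counters_list(ct)
  diagnostics <- data.frame(t = times[idx][-1][seq_along(diag_h)],
                            h = diag_h, eps_norm = diag_eps,
                            newton_iters = diag_iter,
                            estimator = diag_quality,
                            clamped = diag_clamped,
                            stringsAsFactors = FALSE)
  sol <- structure(list(times = mesh$times, states = mesh$states,
                        sens = mesh$sens,
                        stats = stats, diagnostics = diagnostics,
                        success = success, message = message_out,
                        mesh = mesh, tspan = c(t0, tend),
                        atol = atol, rtol = rtol,
                        state_names = model$state_names,
                        param_names = model$param_names,
                        n_params = np, sensitivities = sensitivities),
                   class = "sd_sol")
  if (!is.null(output_times)) {
    interp <- predict(sol, output_times, sens = sensitivities)
    sol$times <- output_times
    sol$states <- interp$states
    sol$sens <- interp$sens
  }
  sol
}
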