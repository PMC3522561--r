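# Methods on the solution object: dense output, printing, plotting,
# precision measurement.

# Locate the accepted step bracketing each query time.
.mesh_interval <- function(mesh_times, t) {
  i <- findInterval(t, mesh_times, rightmost.closed = TRUE)
  pmin(pmax(i, 1L), length(mesh_times) - 1L)
}

#' Dense output: evaluate the solution between accepted steps
#'
#' Interpolates with each accepted step's own degree-4 polynomial (the one
#' the corrector rule is built on, matching `x`, `xdot`, `xddot` at the left
#' node and `xdot`, `xddot` at the right node).  Queries at stored nodes
#' return the stored values bit-exactly.
#'
#' @param object an `sd_sol` from [sd_integrate()].
#' @param times query times inside the integration range.
#' @param sens also interpolate the sensitivity blocks (only if they were
#'   computed).
#' @param ... unused.
#' @return List with `times`, `states` (matrix, rows = query times) and
#'   `sens` (`n_x x n_p x length(times)` array or `NULL`).
#' @export
predict.sd_sol <- function(object, times, sens = FALSE, ...) {
  mesh <- object$mesh
  tt <- mesh$times
  rng <- range(tt)
  if (any(times < rng[1] - 4 * .Machine$double.eps * max(abs(rng)) |
          times > rng[2] + 4 * .Machine$double.eps * max(abs(rng))))
    sd_error("sd_range_error",
             sprintf("query time outside the integration range [%g, %g]",
                     rng[1], rng[2]))
  nx <- ncol(mesh$states)
  out <- matrix(NA_real_, length(times), nx)
  colnames(out) <- colnames(mesh$states)
  want_sens <- sens && !is.null(mesh$sens)
  np <- if (want_sens) dim(mesh$sens)[2] else 0L
  sarr <- if (want_sens) array(NA_real_, c(nx, np, length(times))) else NULL
  iv <- .mesh_interval(tt, times)
  for (q in seq_along(times)) {
    tq <- times[q]
    hit <- which(tt == tq)
    if (length(hit)) {          # endpoint queries are bit-exact
      out[q, ] <- mesh$states[hit[1], ]
      if (want_sens) sarr[, , q] <- mesh$sens[, , hit[1]]
      next
    }
    i <- iv[q]
    h <- tt[i + 1] - tt[i]
    s <- (tq - tt[i]) / h
    b <- rbind(mesh$states[i, ],
               h * mesh$xdots[i, ],
               h^2 * mesh$xddots[i, ],
               h * mesh$xdots[i + 1, ],
               h^2 * mesh$xddots[i + 1, ])
    out[q, ] <- .dense_eval(b, s)
    if (want_sens) {
      bs <- rbind(as.numeric(mesh$sens[, , i]),
                  h * as.numeric(mesh$sens_dot[, , i]),
                  h^2 * as.numeric(mesh$sens_ddot[, , i]),
                  h * as.numeric(mesh$sens_dot[, , i + 1]),
                  h^2 * as.numeric(mesh$sens_ddot[, , i + 1]))
      sarr[, , q] <- matrix(.dense_eval(bs, s), nx, np)
    }
  }
  list(times = times, states = out, sens = sarr)
}

#' Interpolated state at arbitrary times (functional form)
#'
#' Convenience wrapper around [predict.sd_sol()] returning just the state
#' matrix.
#' @inheritParams predict.sd_sol
#' @export
dense_output <- function(object, times, ...) {
  predict(object, times, ...)$states
}

#' Maximum relative final-state error against a reference solution
#'
#' The precision measure used in work-precision assessments: the maximum over
#' states (restricted to reference components larger in magnitude than
#' machine precision) of `|x - x_ref| / |x_ref|` at the shared final time.
#'
#' @param solution an `sd_sol` or a numeric final-state vector.
#' @param reference an `sd_sol` (computed at much tighter tolerance) or a
#'   numeric final-state vector.
#' @return Non-negative scalar (0 for identical states; `NA` if no reference
#'   component exceeds machine precision).
#' @examples
#' precision_of(c(1.0, 1e-20), c(1.001, 0))  # ~1e-3; zero component excluded
#' @export
precision_of <- function(solution, reference) {
  final_state <- function(s) {
    if (inherits(s, "sd_sol")) s$states[nrow(s$states), ] else as.numeric(s)
  }
  x <- final_state(solution); xr <- final_state(reference)
  keep <- abs(xr) > .Machine$double.eps
  if (!any(keep)) return(NA_real_)
  max(abs(x[keep] - xr[keep]) / abs(xr[keep]))
}

#' @export
print.sd_sol <- function(x, ...) {
  st <- x$stats
  cat(sprintf("Second-derivative ODE solution over [%g, %g]%s\n",
              x$tspan[1], x$tspan[2],
              if (x$success) "" else "  (FAILED, partial)"))
  cat(sprintf("  %d accepted / %d rejected steps; %d f, %d Jacobian, %d second-Jacobian evaluations\n",
              st$steps_accepted, st$steps_rejected, st$n_f, st$n_jac, st$n_jjac))
  cat(sprintf("  %d Newton iterations, %d matrix factorizations (states) + %d (sensitivities)\n",
              st$n_newton, st$n_fact, st$n_fact_sens))
  if (!is.null(x$message)) cat("  note:", x$message, "\n")
  n_show <- min(nrow(x$states), 4L)
  cat("final state:\n")
  print(x$states[nrow(x$states), ])
  invisible(x)
}

#' @export
summary.sd_sol <- function(object, ...) {
  d <- object$diagnostics
  cat(sprintf("Integration over [%g, %g]: %s\n", object$tspan[1],
              object$tspan[2], if (object$success) "success" else "FAILED"))
  print(as.data.frame(object$stats))
  if (nrow(d)) {
    cat(sprintf("step sizes: min %.3g / median %.3g / max %.3g\n",
                min(d$h), stats::median(d$h), max(d$h)))
    g5 <- d$eps_norm[d$estimator == "g5" & !d$clamped]
    if (length(g5))
      cat(sprintf("accepted error estimates (weighted, tau = 1): geometric mean %.3g\n",
                  exp(mean(log(pmax(g5, 1e-300))))))
  }
  invisible(object)
}

#' @export
as.data.frame.sd_sol <- function(x, ...) {
  df <- data.frame(t = x$times, x$states, check.names = FALSE)
  if (!is.null(x$sens)) {
    nx <- dim(x$sens)[1]; np <- dim(x$sens)[2]
    for (k in seq_len(np)) {
      for (i in seq_len(nx)) {
        df[[sprintf("s[%s/%s]", x$state_names[i], x$param_names[k])]] <-
          x$sens[i, k, ]
      }
    }
  }
  df
}

#' Plot a computed trajectory
#'
#' @param x an `sd_sol`.
#' @param which state indices or names to draw (default all).
#' @param log passed to [graphics::matplot()] (e.g. `"y"`).
#' @param ... further arguments to `matplot`.
#' @export
plot.sd_sol <- function(x, which = NULL, log = "", ...) {
  S <- x$states
  if (!is.null(which)) S <- S[, which, drop = FALSE]
  graphics::matplot(x$times, S, type = "l", lty = 1, xlab = "t",
                    ylab = "state", log = log, ...)
  graphics::legend("topright", legend = colnames(S), lty = 1,
                   col = seq_len(ncol(S)), bty = "n")
  invisible(x)
}
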