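# Shared fixtures and oracle helpers, all built in code.

# compiled fixtures, cached per test run (keyed by name and generator args)
compiled_fixture <- local({
  cache <- list()
  function(fixture, seed = 1L, n = 6L) {
    key <- paste(fixture, seed, n, sep = "#")
    if (is.null(cache[[key]])) {
      fx <- make_fixture(fixture, seed = seed, n = n)
      fx$compiled <- compile_model(fx$model)
      cache[[key]] <<- fx
    }
    cache[[key]]
  }
})

# hand-built linear model dx/dt = A x with fused second derivative A(Ax)
linear_model <- function(A) {
  n <- nrow(A)
  ode_model(n_states = n, n_params = 0L,
            rhs = function(x, p) drop(A %*% x),
            jacobian = function(x, p) A,
            second_rhs_jacobian = function(x, p) A %*% A,
            xddot = function(x, p) drop(A %*% (A %*% x)))
}

# nilpotent shift system: solutions are polynomials of degree <= n-1,
# x1(t) = sum_{k<n} x0[n-k] t^k / k!; handy as an exact-polynomial oracle
nilpotent_model <- function(n) {
  A <- matrix(0, n, n)
  A[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- 1
  linear_model(A)
}

# one-step amplification factor of the corrector on xdot = z x
stability_R <- function(z) {
  wu <- g4_weights(1)$unit_weights
  (1 + wu[["xdot"]] * z + wu[["xddot"]] * z^2) /
    (1 - (wu[["xdot_new"]] * z + wu[["xddot_new"]] * z^2))
}

# exact step history for x(t) = exp(-t) at time t = 0 with previous step hp
decay_history <- function(hp) {
  list(t = 0, x = 1, xdot = -1, xddot = 1,
       x_prev = exp(hp), xdot_prev = -exp(hp), xddot_prev = exp(hp),
       h_prev = hp, has_prev = TRUE)
}

# exact step history for a polynomial trajectory given by value/derivative funs
poly_history <- function(val, d1, d2, t, hp) {
  list(t = t, x = val(t), xdot = d1(t), xddot = d2(t),
       x_prev = val(t - hp), xdot_prev = d1(t - hp), xddot_prev = d2(t - hp),
       h_prev = hp, has_prev = TRUE)
}

# wrap a model so Jacobian-evaluator calls are counted externally
counting_model <- function(model) {
  ct <- new.env(); ct$jac <- 0L; ct$jjac <- 0L
  m <- model
  m$jacobian <- function(x, p) { ct$jac <- ct$jac + 1L; model$jacobian(x, p) }
  m$second_rhs_jacobian <- function(x, p) {
    ct$jjac <- ct$jjac + 1L; model$second_rhs_jacobian(x, p)
  }
  list(model = m, counts = ct)
}

# reference trajectory from an independent stiff solver at tight tolerance
desolve_reference <- function(model, x0, p, tspan, rtol = 1e-13, atol = 1e-18) {
  skip_if_not_installed("deSolve")
  out <- deSolve::lsoda(
    y = x0, times = tspan,
    func = function(t, y, parms) list(model$rhs(y, p)),
    parms = NULL,
    jacfunc = function(t, y, parms) model$jacobian(y, p),
    jactype = "fullusr", rtol = rtol, atol = atol)
  as.numeric(out[nrow(out), -1])
}

# fit a log-log slope of err against h
loglog_slope <- function(h, err) {
  stats::coef(stats::lm(log(err) ~ log(h)))[[2]]
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(abs(y), .Machine$double.xmin), tol)
}
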