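# The driver: accuracy against closed forms and a tight-tolerance reference
# solver, global order, dense output, work-precision behaviour, statistics
# and failure handling.

test_that("decay is integrated to the requested accuracy", {
  fx <- compiled_fixture("linear_decay")
  sol <- sd_integrate(fx$compiled, 1, 1, c(0, 10), rtol = 1e-8, atol = 1e-14)
  expect_true(sol$success)
  expect_lt(abs(sol$states[nrow(sol$states), 1] - exp(-10)) / exp(-10), 1e-6)
})

test_that("a zero right-hand side yields a constant solution in few steps", {
  m <- compile_model(symbolic_model(c("x1", "x2"), character(0), c("0", "0")))
  sol <- sd_integrate(m, c(1, 2), numeric(0), c(0, 100))
  expect_true(sol$success)
  expect_identical(sol$stats$steps_rejected, 0L)
  expect_lte(sol$stats$steps_accepted, 12L)
  expect_equal(sol$states[nrow(sol$states), ], c(x1 = 1, x2 = 2))
})

test_that("enzyme scheme matches a tight-tolerance reference and conserves totals", {
  fx <- compiled_fixture("michaelis_menten")
  sol <- sd_integrate(fx$compiled, fx$x0, fx$p, c(0, 100),
                      rtol = 1e-6, atol = 1e-8)
  expect_true(sol$success)
  ref <- desolve_reference(fx$compiled, fx$x0, fx$p, c(0, 100))
  expect_lt(precision_of(sol, ref), 1e-5)
  cv <- conservation_laws(fx$model)
  drift <- t(cv) %*% sol$states[nrow(sol$states), ] - t(cv) %*% fx$x0
  expect_lt(max(abs(drift)), 1e-9)
})

test_that("global error in fixed-step mode scales as h^4", {
  fx <- compiled_fixture("linear_decay")
  Ns <- c(8, 16, 32, 64)
  errs <- vapply(Ns, function(N) {
    sol <- sd_integrate(fx$compiled, 1, 1, c(0, 1), fixed_h = 1 / N,
                        newton_kappa = 1e-6, max_newton_iter = 20)
    abs(sol$states[nrow(sol$states), 1] - exp(-1))
  }, 0)
  expect_lt(abs(loglog_slope(1 / Ns, errs) - 4), 0.1)
})

test_that("dense output is exact at nodes, on quartic solutions, and accurate inside steps", {
  # stored endpoints reproduced bit-exactly
  fx <- compiled_fixture("linear_decay")
  sol <- sd_integrate(fx$compiled, 1, 1, c(0, 5), rtol = 1e-8, atol = 1e-10)
  mid_nodes <- sol$times[c(2, 4)]
  got <- dense_output(sol, mid_nodes)
  expect_identical(got[1, 1], sol$states[2, 1])
  expect_identical(got[2, 1], sol$states[4, 1])
  # quartic polynomial solution: interior values to round-off
  m <- nilpotent_model(5)
  x0 <- c(0, 0, 0, 0, 24)   # x1(t) = t^4
  psol <- sd_integrate(m, x0, numeric(0), c(0, 2), rtol = 1e-8, atol = 1e-10)
  tq <- seq(0.1, 1.9, by = 0.2)
  vals <- dense_output(psol, tq)
  expect_lt(max(abs(vals[, 1] - tq^4)) / max(tq^4), 1e-9)
  # decay midpoints stay within a local error bound
  tm <- (sol$times[-1] + sol$times[-length(sol$times)]) / 2
  dm <- dense_output(sol, tm)
  expect_lt(max(abs(dm[, 1] - exp(-tm))), 1e-6)
  # out-of-range queries are errors
  expect_error(predict(sol, 5.5), class = "sd_range_error")
})

test_that("precision measure follows its definition", {
  expect_identical(precision_of(c(1, 2), c(1, 2)), 0)
  # hand pair: tiny reference components are excluded
  expect_equal(precision_of(c(1.0, 1e-20), c(1.001, 0)), 0.001 / 1.001)
})

test_that("work-precision improves monotonically as the tolerance tightens", {
  fx <- compiled_fixture("michaelis_menten")
  ref <- desolve_reference(fx$compiled, fx$x0, fx$p, c(0, 20))
  rtols <- 10^c(-4, -6, -8, -10)
  prec <- vapply(rtols, function(rt) {
    sol <- sd_integrate(fx$compiled, fx$x0, fx$p, c(0, 20),
                        rtol = rt, atol = rt * 1e-2)
    precision_of(sol, ref)
  }, 0)
  for (i in seq_len(length(prec) - 1))
    expect_lt(prec[i + 1], 2 * prec[i])    # monotone within a factor 2
  expect_lt(prec[4], prec[1] / 10)
})

test_that("statistics counters are mutually consistent", {
  fx <- compiled_fixture("michaelis_menten")
  sol <- sd_integrate(fx$compiled, fx$x0, fx$p, c(0, 50),
                      rtol = 1e-6, atol = 1e-8)
  st <- sol$stats
  attempted <- st$steps_accepted + st$steps_rejected
  expect_gte(st$n_f, st$n_newton)
  expect_identical(st$n_jac, attempted)
  expect_identical(st$n_jjac, attempted)
  expect_identical(st$n_fact, attempted)
  expect_identical(st$steps_accepted, length(sol$times) - 1L)
  expect_true(all(sol$diagnostics$h > 0))
  expect_true(all(diff(sol$times) > 0))
})

test_that("finite-time blow-up returns a flagged partial solution", {
  # xdot = x^2 from x(0) = 1 blows up at t = 1
  m <- compile_model(symbolic_model("x1", character(0), "x1^2"))
  sol <- suppressWarnings(
    sd_integrate(m, 1, numeric(0), c(0, 2), rtol = 1e-6, atol = 1e-8))
  expect_false(sol$success)
  expect_true(is.character(sol$message))
  expect_lt(max(sol$times), 1.01)
  expect_true(all(is.finite(sol$states)))
})

test_that("output times are served by dense output without constraining steps", {
  fx <- compiled_fixture("linear_decay")
  ot <- seq(0, 10, by = 0.5)
  sol <- sd_integrate(fx$compiled, 1, 1, c(0, 10), rtol = 1e-8, atol = 1e-10,
                      output_times = ot)
  expect_identical(sol$times, ot)
  expect_lt(max(abs(sol$states[, 1] - exp(-ot))), 1e-7)
  # sensitivities are interpolated too
  m <- compile_model(symbolic_model("x1", "p1", "-p1*x1"))
  ss <- sd_integrate(m, 1, 1, c(0, 2), rtol = 1e-8, atol = 1e-12,
                     sensitivities = TRUE, output_times = c(0.5, 1, 1.7))
  exact <- -c(0.5, 1, 1.7) * exp(-c(0.5, 1, 1.7))
  expect_lt(max(abs(ss$sens[1, 1, ] - exact) / abs(exact)), 1e-6)
})

test_that("invalid driver inputs are rejected", {
  fx <- compiled_fixture("linear_decay")
  expect_error(sd_integrate(fx$compiled, 1, 1, c(1, 0)),
               class = "sd_invalid_argument")
  expect_error(sd_integrate(fx$compiled, 1, 1, c(0, 1), rtol = 0),
               class = "sd_invalid_argument")
  expect_error(sd_integrate(fx$compiled, c(1, 2), 1, c(0, 1)),
               class = "sd_invalid_argument")
  expect_error(sd_integrate(fx$compiled, 1, 1, c(0, 1), jacobian_reuse = TRUE),
               class = "sd_invalid_argument")
})
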