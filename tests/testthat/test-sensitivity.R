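# Staggered parameter sensitivities: derivative assembly, direct and
# iterative steps, closed-form and finite-difference oracles.

test_that("sensitivity derivative assembly matches hand differentiation of scalar decay", {
  # xdot = -p x: Sdot = -p S - x, Sddot = p^2 S + 2 p x
  m <- compile_model(symbolic_model("x1", "p1", "-p1*x1"))
  x <- 0.8; p <- 1.7; S <- matrix(0.3, 1, 1)
  sd <- sensitivity_derivatives(m, x, p, S)
  expect_equal(sd$Sdot[1, 1], -p * S[1, 1] - x, tolerance = 1e-13)
  expect_equal(sd$Sddot[1, 1], p^2 * S[1, 1] + 2 * p * x, tolerance = 1e-13)
})

test_that("parameter-independent models with zero initial sensitivity stay at zero", {
  # f independent of p: df/dp = 0, S stays identically zero
  m <- compile_model(symbolic_model(c("x1", "x2"), "p1",
                                    c("-x1 + x2", "-x2")))
  sd <- sensitivity_derivatives(m, c(1, 2), 3, matrix(0, 2, 1))
  expect_identical(sd$Sdot, matrix(0, 2, 1))
  expect_identical(sd$Sddot, matrix(0, 2, 1))
  sol <- sd_integrate(m, c(1, 2), 3, c(0, 2), rtol = 1e-8, atol = 1e-10,
                      sensitivities = TRUE)
  expect_lt(max(abs(sol$sens)), 1e-12)
})

test_that("models without parameter evaluators are refused", {
  m <- linear_model(matrix(-1, 1, 1))
  expect_error(sensitivity_derivatives(m, 1, numeric(0), matrix(0, 1, 0)),
               class = "sd_unsupported_model")
  expect_error(sd_integrate(m, 1, numeric(0), c(0, 1), sensitivities = TRUE),
               class = "sd_unsupported_model")
})

test_that("first-derivative sensitivity ODE matches finite differences of f over p", {
  fx <- compiled_fixture("michaelis_menten")
  m <- fx$compiled
  set.seed(4)
  x <- runif(4, 0.2, 1.5); p <- fx$p
  S <- matrix(rnorm(12), 4, 3)
  sd <- sensitivity_derivatives(m, x, p, S)
  J <- m$jacobian(x, p)
  for (k in 1:3) {
    d <- 1e-6 * p[k]
    pp <- p; pp[k] <- p[k] + d; pm <- p; pm[k] <- p[k] - d
    dfdp_fd <- (m$rhs(x, pp) - m$rhs(x, pm)) / (2 * d)
    expect_lt(max(abs(sd$Sdot[, k] - (J %*% S[, k] + dfdp_fd))), 1e-6)
  }
})

test_that("scalar decay recovers the closed-form sensitivity -t exp(-p t)", {
  m <- compile_model(symbolic_model("x1", "p1", "-p1*x1"))
  sol <- sd_integrate(m, 1, 1, c(0, 1), rtol = 1e-8, atol = 1e-12,
                      sensitivities = TRUE)
  S_end <- sol$sens[1, 1, dim(sol$sens)[3]]
  exact <- -1 * exp(-1)
  expect_lt(abs(S_end - exact) / abs(exact), 1e-6)
})

test_that("enzyme-scheme sensitivities match central finite differences of trajectories", {
  fx <- compiled_fixture("michaelis_menten")
  m <- fx$compiled
  sol <- sd_integrate(m, fx$x0, fx$p, c(0, 10), rtol = 1e-8, atol = 1e-10,
                      sensitivities = TRUE)
  S_end <- sol$sens[, , dim(sol$sens)[3]]
  for (k in 1:3) {
    d <- 1e-6 * fx$p[k]
    pp <- fx$p; pp[k] <- pp[k] + d
    pm <- fx$p; pm[k] <- pm[k] - d
    xp <- sd_integrate(m, fx$x0, pp, c(0, 10), rtol = 1e-10, atol = 1e-12)
    xm <- sd_integrate(m, fx$x0, pm, c(0, 10), rtol = 1e-10, atol = 1e-12)
    fd <- (xp$states[nrow(xp$states), ] - xm$states[nrow(xm$states), ]) / (2 * d)
    expect_lt(max(abs(S_end[, k] - fd)) / max(abs(fd)), 1e-4)
  }
})

test_that("direct and iterative sensitivity modes agree within Newton tolerance", {
  fx <- compiled_fixture("michaelis_menten")
  m <- fx$compiled
  sd <- sd_integrate(m, fx$x0, fx$p, c(0, 10), rtol = 1e-8, atol = 1e-10,
                     sensitivities = TRUE)
  si <- sd_integrate(m, fx$x0, fx$p, c(0, 10), rtol = 1e-8, atol = 1e-10,
                     sensitivities = TRUE, sens_method = "iterative")
  n_t <- dim(sd$sens)[3]
  dmax <- error_norm(as.numeric(sd$sens[, , n_t] - si$sens[, , n_t]),
                     as.numeric(sd$sens[, , n_t]), 1e-10, 1e-8)
  expect_lt(dmax, 10 * 0.1)   # 10x the kappa = 0.1 Newton tolerance
})

test_that("the iterative mode converges in at most two sweeps for a linear model", {
  # xdot = -p x is linear in x; the sensitivity relation is solved exactly
  # by the first correction
  m <- compile_model(symbolic_model("x1", "p1", "-p1*x1"))
  x_new <- 0.9; p <- 1.2; h <- 0.05
  prev <- list(S = matrix(0.2, 1, 1), Sdot = matrix(-0.2 * p - 1, 1, 1),
               Sddot = matrix(p^2 * 0.2 + 2 * p, 1, 1))
  ws <- build_newton_matrix(m, x_new, p, h)
  it <- sensitivity_step_iterative(m, x_new, p, h, prev, ws, tol = 1e-12)
  dir <- sensitivity_step_direct(m, x_new, p, h, prev)
  expect_lte(it$iters, 2L)
  expect_lt(abs(it$S - dir$S), 1e-12)
})

test_that("one factorization serves all parameter columns per accepted step", {
  fx <- compiled_fixture("michaelis_menten")
  sol <- sd_integrate(fx$compiled, fx$x0, fx$p, c(0, 10), rtol = 1e-6,
                      atol = 1e-8, sensitivities = TRUE)
  expect_identical(sol$stats$n_fact_sens, sol$stats$steps_accepted)
})

test_that("enabling sensitivities leaves the accepted step sequence bitwise unchanged", {
  fx <- compiled_fixture("michaelis_menten")
  m <- fx$compiled
  on <- sd_integrate(m, fx$x0, fx$p, c(0, 20), rtol = 1e-6, atol = 1e-8,
                     sensitivities = TRUE)
  off <- sd_integrate(m, fx$x0, fx$p, c(0, 20), rtol = 1e-6, atol = 1e-8)
  expect_identical(on$times, off$times)
  expect_identical(on$states, off$states)
  expect_identical(on$stats$steps_accepted, off$stats$steps_accepted)
  expect_identical(on$stats$steps_rejected, off$stats$steps_rejected)
})

test_that("linear-model sensitivities match the matrix-exponential derivative", {
  skip_if_not_installed("Matrix")
  # xdot = A(p) x with A = [[-p1, 1], [0, -p2]]; dx/dp_k at t from the
  # block-triangular exponential exp(t [[A, dA/dp_k], [0, A]])
  m <- compile_model(symbolic_model(
    c("x1", "x2"), c("p1", "p2"),
    c("-p1*x1 + x2", "-p2*x2")))
  p <- c(0.6, 1.4); x0 <- c(1, 2); tend <- 1.5
  sol <- sd_integrate(m, x0, p, c(0, tend), rtol = 1e-10, atol = 1e-12,
                      sensitivities = TRUE)
  A <- rbind(c(-p[1], 1), c(0, -p[2]))
  dA <- list(rbind(c(-1, 0), c(0, 0)), rbind(c(0, 0), c(0, -1)))
  S_end <- sol$sens[, , dim(sol$sens)[3]]
  for (k in 1:2) {
    blk <- rbind(cbind(A, dA[[k]]), cbind(matrix(0, 2, 2), A))
    E <- as.matrix(Matrix::expm(tend * blk))
    exact <- E[1:2, 3:4] %*% x0
    expect_lt(max(abs(S_end[, k] - exact)) / max(abs(exact)), 1e-7)
  }
})

test_that("Jacobian re-use preserves results within tolerance while saving evaluations", {
  fx <- compiled_fixture("michaelis_menten")
  m <- fx$compiled
  base <- sd_integrate(m, fx$x0, fx$p, c(0, 20), rtol = 1e-8, atol = 1e-10,
                       sensitivities = TRUE)
  reuse <- sd_integrate(m, fx$x0, fx$p, c(0, 20), rtol = 1e-8, atol = 1e-10,
                        sensitivities = TRUE, jacobian_reuse = TRUE)
  expect_lt(reuse$stats$n_jac, base$stats$n_jac)
  x_b <- base$states[nrow(base$states), ]
  x_r <- reuse$states[nrow(reuse$states), ]
  expect_lt(max(abs(x_b - x_r)) / max(abs(x_b)), 1e-6)
})
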