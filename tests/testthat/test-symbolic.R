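# Symbolic compiler: generated rates, Jacobians, sparsity, conservation laws.

test_that("compiled enzyme scheme reproduces the printed rate and second-derivative structure", {
  fx <- compiled_fixture("michaelis_menten")
  m <- fx$compiled
  set.seed(2)
  for (rep in 1:5) {
    x <- runif(4, 0.1, 2); p <- runif(3, 0.2, 3)
    f <- m$rhs(x, p)
    # f1 = -k1 x1 x2 + (k2 + k3) x3
    expect_equal(f[1], -p[1] * x[1] * x[2] + (p[2] + p[3]) * x[3],
                 tolerance = 1e-12)
    # xddot1 = -k1 x2 f1 - k1 x1 f2 + (k2 + k3) f3
    xdd <- m$xddot(x, p)
    expect_equal(xdd[1], -p[1] * x[2] * f[1] - p[1] * x[1] * f[2] +
                   (p[2] + p[3]) * f[3], tolerance = 1e-12)
  }
})

test_that("single-species decay compiles to the closed-form derivatives", {
  m <- compile_model(symbolic_model("x1", "k1", "-k1*x1"))
  x <- 0.7; k <- 1.3
  expect_equal(m$jacobian(x, k)[1, 1], -k)
  expect_equal(m$second_rhs_jacobian(x, k)[1, 1], k^2)
  expect_equal(m$xddot(x, k), k^2 * x)
})

test_that("compiled evaluators equal direct substitution into the rate expressions", {
  fx <- compiled_fixture("random_massaction", seed = 9, n = 5)
  m <- fx$compiled
  sm <- fx$model
  set.seed(31)
  for (rep in 1:20) {
    x <- runif(5, 0.1, 3)
    e <- as.environment(c(as.list(setNames(x, sm$species)),
                          as.list(setNames(fx$p, sm$params))))
    parent.env(e) <- baseenv()
    direct <- vapply(sm$rate_exprs, function(ex) eval(ex, e), numeric(1))
    got <- m$rhs(x, fx$p)
    expect_lt(max(abs(got - direct)) / max(abs(direct), 1), 1e-12)
  }
})

test_that("undeclared symbols are reported by name", {
  err <- tryCatch(symbolic_model("x1", "k1", "-k9*x1"),
                  sd_compile_error = function(e) e)
  expect_s3_class(err, "sd_compile_error")
  expect_match(conditionMessage(err), "k9")
})

test_that("sparsity pattern is honest: outside entries are exactly zero", {
  set.seed(13)
  for (fx in list(compiled_fixture("michaelis_menten"),
                  compiled_fixture("random_massaction", seed = 4, n = 5))) {
    m <- fx$compiled
    outside <- which(!m$jac_sparsity, arr.ind = TRUE)
    if (!nrow(outside)) next
    for (rep in 1:25) {
      x <- runif(m$n_states, 0.05, 5)
      J <- m$jacobian(x, fx$p)
      expect_identical(unname(J[outside]), rep(0, nrow(outside)))
      # cross-check by finite differences of the compiled rhs
      J_fd <- vapply(seq_len(m$n_states), function(j) {
        d <- 1e-7 * max(1, abs(x[j]))
        xp <- x; xp[j] <- x[j] + d; xm <- x; xm[j] <- x[j] - d
        (m$rhs(xp, fx$p) - m$rhs(xm, fx$p)) / (2 * d)
      }, numeric(m$n_states))
      expect_lt(max(abs(J_fd[outside])), 1e-6)
    }
  }
})

test_that("Jacobian non-zero fractions: 5/8 for the enzyme scheme, 1/n for diagonal decay, 1 for dense coupling", {
  expect_equal(jacobian_nnz_fraction(make_fixture("michaelis_menten")$model), 5 / 8)
  n <- 4
  diagm <- symbolic_model(paste0("x", 1:n), paste0("k", 1:n),
                          sprintf("-k%d*x%d", 1:n, 1:n))
  expect_equal(jacobian_nnz_fraction(diagm), 1 / n)
  dense <- symbolic_model(c("x1", "x2"), character(0),
                          c("x1 + x2", "x1 - x2"))
  expect_equal(jacobian_nnz_fraction(dense), 1)
  # compiled models report the same fraction through their sparsity pattern
  expect_equal(jacobian_nnz_fraction(compiled_fixture("michaelis_menten")$compiled),
               5 / 8)
})

test_that("conservation laws span the expected invariants", {
  in_span <- function(basis, v) {
    qr_b <- qr(basis)
    resid <- v - basis %*% qr.coef(qr_b, v)
    max(abs(resid)) < 1e-9
  }
  # enzyme scheme: total enzyme (1,0,1,0) and total substrate mass (0,1,1,1)
  mm <- make_fixture("michaelis_menten")$model
  cv <- conservation_laws(mm)
  expect_identical(ncol(cv), 2L)
  expect_true(all(t(cv) %*% mm$stoich == 0))
  expect_true(in_span(cv, c(1, 0, 1, 0)))
  expect_true(in_span(cv, c(0, 1, 1, 1)))
  # irreversible decay chain x1 -> x2 -> x3: total mass
  chain <- mass_action_model(cbind(c(-1, 1, 0), c(0, -1, 1)),
                             cbind(c(1, 0, 0), c(0, 1, 0)))
  cvc <- conservation_laws(chain)
  expect_identical(ncol(cvc), 1L)
  expect_true(in_span(cvc, c(1, 1, 1)))
  # full-row-rank stoichiometry: empty basis
  prod2 <- mass_action_model(diag(2), matrix(0L, 2, 2))
  expect_identical(ncol(conservation_laws(prod2)), 0L)
  # models without reaction structure refuse
  expect_error(conservation_laws(make_fixture("repressilator_like")$model),
               class = "sd_invalid_argument")
})

test_that("random mass-action conservation vectors annihilate the stoichiometry exactly", {
  for (seed in c(1, 2, 3)) {
    fx <- make_fixture("random_massaction", seed = seed, n = 6)
    cv <- conservation_laws(fx$model)
    expect_identical(nrow(cv), 6L)     # one entry per species, possibly 0 cols
    expect_true(all(cv == round(cv)))  # integer basis
    if (ncol(cv) > 0)
      expect_true(all(t(cv) %*% fx$model$stoich == 0))
  }
})

test_that("mass-action expansion and compiled rhs agree with stoichiometry times rates", {
  fx <- make_fixture("random_massaction", seed = 8, n = 5)
  m <- compile_model(fx$model)
  set.seed(77)
  x <- runif(5, 0.2, 2)
  rates <- vapply(seq_len(ncol(fx$model$stoich)), function(r)
    fx$p[r] * prod(x^fx$model$orders[, r]), numeric(1))
  expect_lt(max(abs(m$rhs(x, fx$p) - drop(fx$model$stoich %*% rates))), 1e-12)
})

test_that("audit source emission lists the generated expressions", {
  m <- compile_model(make_fixture("linear_decay")$model, emit_source = TRUE)
  src <- attr(m, "source")
  expect_true(any(grepl("^Jf\\[1,1\\]", src)))
  expect_true(any(grepl("^JJf\\[1,1\\]", src)))
})
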