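# Built-in test models.  All fixtures are symbolic, so every derivative
# evaluator comes out of the compiler; random networks are seed-deterministic.

#' Built-in model fixtures
#'
#' Reproducible symbolic models with initial conditions, parameters and a
#' default integration interval:
#' \describe{
#'   \item{`michaelis_menten`}{the four-species enzyme kinetics scheme
#'     (enzyme + substrate <-> complex -> enzyme + product) with mass-action
#'     rates, `k = (1, 1, 1)`, `x0 = (1, 1, 0, 0)`, `t in [0, 100]`.  Its
#'     Jacobian has non-zero fraction 5/8 and it conserves total enzyme
#'     `x1 + x3` and total substrate mass `x2 + x3 + x4`.}
#'   \item{`linear_decay`}{scalar `dx/dt = -k x`; closed-form solution
#'     available for oracle tests.}
#'   \item{`robertson`}{the classic three-species stiff kinetics benchmark
#'     (rate constants 0.04, 1e4, 3e7) over `[0, 1e4]`.}
#'   \item{`repressilator_like`}{a three-gene ring oscillator (mRNA +
#'     protein per gene, Hill repression), a stiff oscillatory fixture with
#'     non-polynomial rate laws.}
#'   \item{`random_massaction`}{a random mass-action network with `n`
#'     species and `2n` reactions drawn from conversion, association and
#'     dissociation motifs (which keep concentrations non-negative);
#'     deterministic for a given `seed`.}
#' }
#'
#' @param name fixture name (see above).
#' @param seed integer seed (used by `random_massaction` only).
#' @param n number of species for `random_massaction` (default 6).
#' @return List with `name`, `model` (an `sd_symbolic`), `x0`, `p`, `tspan`.
#' @export
make_fixture <- function(name, seed = 1L, n = 6L) {
  switch(name,
    michaelis_menten = {
      S <- cbind(c(-1, -1, 1, 0), c(1, 1, -1, 0), c(1, 0, -1, 1))
      O <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 1, 0))
      list(name = name, model = mass_action_model(S, O),
           x0 = c(1, 1, 0, 0), p = c(1, 1, 1), tspan = c(0, 100))
    },
    linear_decay = {
      list(name = name,
           model = symbolic_model("x1", "k1", "-k1*x1"),
           x0 = 1, p = 1, tspan = c(0, 10))
    },
    robertson = {
      # y1 -> y2 (slow); y2 + y3 -> y1 + y3; 2 y2 -> y2 + y3
      S <- cbind(c(-1, 1, 0), c(1, -1, 0), c(0, -1, 1))
      O <- cbind(c(1, 0, 0), c(0, 1, 1), c(0, 2, 0))
      list(name = name, model = mass_action_model(S, O),
           x0 = c(1, 0, 0), p = c(0.04, 1e4, 3e7), tspan = c(0, 1e4))
    },
    repressilator_like = {
      species <- c("m1", "m2", "m3", "q1", "q2", "q3")
      params <- c("alpha", "alpha0", "beta")
      rates <- c("alpha/(1 + q3^2) + alpha0 - m1",
                 "alpha/(1 + q1^2) + alpha0 - m2",
                 "alpha/(1 + q2^2) + alpha0 - m3",
                 "beta*(m1 - q1)", "beta*(m2 - q2)", "beta*(m3 - q3)")
      list(name = name, model = symbolic_model(species, params, rates),
           x0 = c(5, 1, 1, 2, 1, 1), p = c(100, 0.2, 5), tspan = c(0, 50))
    },
    random_massaction = .random_massaction(n, seed),
    sd_error("sd_invalid_argument", sprintf("unknown fixture '%s'", name))
  )
}

#' Names of the available fixtures
#' @return Character vector.
#' @export
fixture_names <- function() {
  c("michaelis_menten", "linear_decay", "robertson",
    "repressilator_like", "random_massaction")
}

.random_massaction <- function(n, seed) {
  n <- as.integer(n)
  if (n < 3L) sd_error("sd_invalid_argument", "random network needs >= 3 species")
  # isolate the fixture's RNG from the caller's stream
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  nr <- 2L * n
  S <- matrix(0L, n, nr); O <- matrix(0L, n, nr)
  for (r in seq_len(nr)) {
    type <- sample(3L, 1L)
    if (type == 1L) {              # conversion A -> B
      ab <- sample(n, 2L)
      S[ab[1], r] <- -1L; S[ab[2], r] <- 1L; O[ab[1], r] <- 1L
    } else if (type == 2L) {       # association A + B -> C
      abc <- sample(n, 3L)
      S[abc[1], r] <- -1L; S[abc[2], r] <- -1L; S[abc[3], r] <- 1L
      O[abc[1], r] <- 1L; O[abc[2], r] <- 1L
    } else {                       # dissociation C -> A + B
      abc <- sample(n, 3L)
      S[abc[1], r] <- -1L; S[abc[2], r] <- 1L; S[abc[3], r] <- 1L
      O[abc[1], r] <- 1L
    }
  }
  p <- round(10^stats::runif(nr, -1, 1), 6)
  x0 <- round(stats::runif(n, 0.5, 2), 6)
  list(name = "random_massaction", model = mass_action_model(S, O),
       x0 = x0, p = p, tspan = c(0, 10), seed = seed)
}
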