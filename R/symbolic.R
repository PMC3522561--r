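# Symbolic model layer: rate expressions (or mass-action stoichiometry) in,
# compiled derivative evaluators out.  Differentiation uses base R's D() on
# parsed expressions; only structurally non-zero entries are emitted, and the
# fused second-derivative evaluator re-uses the already computed f components
# instead of re-expanding them.

#' Define a model symbolically by per-species rate expressions
#'
#' @param species character vector of state-variable names (ordered).
#' @param params character vector of parameter names (ordered; may be empty).
#' @param rates character vector (length = number of species) of R rate
#'   expressions `f_i(x, p)`, e.g. `"-k1*x1*x2 + (k2+k3)*x3"`.  Every free
#'   symbol must be a declared species or parameter.
#' @param stoich optional integer stoichiometry matrix
#'   (species x reactions) when the model has reaction structure; enables
#'   [conservation_laws()].
#' @param orders optional non-negative integer reactant-order matrix
#'   (species x reactions) for mass-action models.
#' @return An object of class `sd_symbolic`.
#' @seealso [mass_action_model()], [compile_model()]
#' @export
symbolic_model <- function(species, params = character(0), rates,
                           stoich = NULL, orders = NULL) {
  species <- as.character(species); params <- as.character(params)
  if (anyDuplicated(c(species, params)))
    sd_error("sd_invalid_argument", "species and parameter names must be distinct")
  if (length(rates) != length(species))
    sd_error("sd_invalid_argument", "need one rate expression per species")
  exprs <- lapply(rates, function(r) {
    if (is.character(r)) str2lang(r) else r
  })
  declared <- c(species, params)
  for (i in seq_along(exprs)) {
    und <- setdiff(all.vars(exprs[[i]]), declared)
    if (length(und))
      sd_error("sd_compile_error",
               sprintf("undeclared symbol '%s' in rate expression %d", und[1], i),
               symbol = und[1])
  }
  if (!is.null(stoich)) stoich <- as.matrix(stoich)
  if (!is.null(orders)) orders <- as.matrix(orders)
  structure(list(species = species, params = params,
                 rates = vapply(exprs, function(e) paste(deparse(e), collapse = " "), ""),
                 rate_exprs = exprs, stoich = stoich, orders = orders),
            class = "sd_symbolic")
}

#' Define a mass-action reaction network
#'
#' Rate laws are `k_r * prod_i x_i^order[i, r]`, combined through the
#' stoichiometry: `f = stoich %*% rates`.  The symbolic rate expressions are
#' expanded automatically.
#'
#' @param stoich integer stoichiometry matrix, species (rows) x reactions
#'   (columns): net change of each species per firing.
#' @param orders non-negative integer matrix of the same shape: kinetic order
#'   of each species in each reaction's rate law.
#' @param rate_constants parameter names, one per reaction
#'   (default `k1, k2, ...`).
#' @param species species names (default `x1, x2, ...`).
#' @return An `sd_symbolic` model carrying the reaction structure.
#' @examples
#' # enzyme + substrate <-> complex -> enzyme + product
#' S <- cbind(c(-1, -1, 1, 0), c(1, 1, -1, 0), c(1, 0, -1, 1))
#' O <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 1, 0))
#' mm <- mass_action_model(S, O)
#' mm$rates[1]  # -(k1*x1*x2) + k2*x3 + k3*x3
#' @export
mass_action_model <- function(stoich, orders,
                              rate_constants = paste0("k", seq_len(ncol(stoich))),
                              species = paste0("x", seq_len(nrow(stoich)))) {
  stoich <- as.matrix(stoich); orders <- as.matrix(orders)
  if (!identical(dim(stoich), dim(orders)))
    sd_error("sd_invalid_argument", "'stoich' and 'orders' must have equal dimensions")
  if (any(orders < 0) || any(orders != round(orders)))
    sd_error("sd_invalid_argument", "'orders' must contain non-negative integers")
  n <- nrow(stoich); nr <- ncol(stoich)
  rate_str <- vapply(seq_len(nr), function(r) {
    terms <- c(rate_constants[r],
               unlist(lapply(which(orders[, r] > 0), function(i) {
                 if (orders[i, r] == 1) species[i]
                 else sprintf("%s^%d", species[i], orders[i, r])
               })))
    paste(terms, collapse = "*")
  }, "")
  f_str <- vapply(seq_len(n), function(i) {
    idx <- which(stoich[i, ] != 0)
    if (!length(idx)) return("0")
    paste(vapply(idx, function(r) {
      s <- stoich[i, r]
      coef <- if (abs(s) == 1) "" else paste0(abs(s), "*")
      paste0(if (s < 0) "-" else "+", coef, "(", rate_str[r], ")")
    }, ""), collapse = " ")
  }, "")
  sm <- symbolic_model(species, rate_constants, f_str,
                       stoich = stoich, orders = orders)
  sm
}

#' @export
print.sd_symbolic <- function(x, ...) {
  cat(sprintf("Symbolic ODE model: %d species, %d parameters%s\n",
              length(x$species), length(x$params),
              if (!is.null(x$stoich)) sprintf(", %d reactions", ncol(x$stoich)) else ""))
  for (i in seq_along(x$species))
    cat(sprintf("  d%s/dt = %s\n", x$species[i], x$rates[i]))
  invisible(x)
}

.is_zero_expr <- function(e) is.numeric(e) && length(e) == 1L && e == 0

# Differentiate expr by each name; keep only structurally non-zero entries
# as a triplet list (i fixed by caller).
.d_row <- function(expr, names) {
  lapply(seq_along(names), function(j) {
    d <- stats::D(expr, names[j])
    if (.is_zero_expr(d)) NULL else list(j = j, expr = d)
  })
}

.sum_calls <- function(terms) {
  if (!length(terms)) return(0)
  Reduce(function(a, b) call("+", a, b), terms)
}

# Build an environment binding species and parameter values.
.sym_env <- function(species, params) {
  force(species); force(params)
  function(x, p) {
    e <- new.env(parent = baseenv(), size = length(species) + length(params) + 1L)
    for (i in seq_along(species)) assign(species[i], x[[i]], envir = e)
    for (i in seq_along(params)) assign(params[i], p[[i]], envir = e)
    e
  }
}

#' Compile a symbolic model into evaluator functions
#'
#' Generates, by symbolic differentiation, every evaluator the integrator and
#' the sensitivity module need: `f`, `J_f = df/dx`, a fused second derivative
#' `xddot = J_f f` (computed from the non-zero `J_f` entries and the already
#' evaluated `f` components), `J_Jf = d(J_f f)/dx`, `df/dp` and `d(xddot)/dp`.
#' Only structurally non-zero entries are stored and evaluated; the Jacobian
#' sparsity pattern is filled in from the structure.
#'
#' @param model an `sd_symbolic` model.
#' @param emit_source if `TRUE`, attach human-readable source of all generated
#'   expressions as attribute `"source"` of the returned model (for audit).
#' @return An [ode_model()] with all evaluators populated.
#' @export
compile_model <- function(model, emit_source = FALSE) {
  if (!inherits(model, "sd_symbolic"))
    sd_error("sd_invalid_argument", "'model' must be an 'sd_symbolic' object")
  sp <- model$species; pa <- model$params
  n <- length(sp); np <- length(pa)
  f_exprs <- model$rate_exprs

  J_trip <- list()
  for (i in seq_len(n)) {
    for (ent in .d_row(f_exprs[[i]], sp)) {
      if (!is.null(ent)) J_trip[[length(J_trip) + 1L]] <-
          list(i = i, j = ent$j, expr = ent$expr)
    }
  }
  # expanded xddot_i = sum_j J_ij * f_j, used only for further differentiation;
  # the runtime evaluator re-uses the f components instead
  xdd_exprs <- lapply(seq_len(n), function(i) {
    terms <- lapply(Filter(function(t) t$i == i, J_trip), function(t)
      call("*", call("(", t$expr), call("(", f_exprs[[t$j]])))
    .sum_calls(terms)
  })
  JJ_trip <- list()
  for (i in seq_len(n)) {
    if (.is_zero_expr(xdd_exprs[[i]])) next
    for (ent in .d_row(xdd_exprs[[i]], sp)) {
      if (!is.null(ent)) JJ_trip[[length(JJ_trip) + 1L]] <-
          list(i = i, j = ent$j, expr = ent$expr)
    }
  }
  dfdp_trip <- list(); dxddp_trip <- list()
  if (np > 0) {
    for (i in seq_len(n)) {
      for (ent in .d_row(f_exprs[[i]], pa)) {
        if (!is.null(ent)) dfdp_trip[[length(dfdp_trip) + 1L]] <-
            list(i = i, j = ent$j, expr = ent$expr)
      }
      if (!.is_zero_expr(xdd_exprs[[i]])) {
        for (ent in .d_row(xdd_exprs[[i]], pa)) {
          if (!is.null(ent)) dxddp_trip[[length(dxddp_trip) + 1L]] <-
              list(i = i, j = ent$j, expr = ent$expr)
        }
      }
    }
  }

  env_of <- .sym_env(sp, pa)
  eval_vec <- function(exprs, len) {
    force(exprs); force(len)
    function(x, p) {
      e <- env_of(x, p)
      vapply(exprs, function(ex) as.numeric(eval(ex, e)), numeric(1))
    }
  }
  trip_parts <- function(trip) list(
    ii = vapply(trip, `[[`, 0L, "i"),
    jj = vapply(trip, `[[`, 0L, "j"),
    ex = lapply(trip, `[[`, "expr"))
  eval_mat <- function(trip, nr, nc) {
    tp <- trip_parts(trip)
    function(x, p) {
      M <- matrix(0, nr, nc)
      if (length(tp$ii)) {
        e <- env_of(x, p)
        M[cbind(tp$ii, tp$jj)] <-
          vapply(tp$ex, function(ex) as.numeric(eval(ex, e)), numeric(1))
      }
      M
    }
  }
  Jp <- trip_parts(J_trip)
  fused_xddot <- function(x, p) {
    e <- env_of(x, p)
    f <- vapply(f_exprs, function(ex) as.numeric(eval(ex, e)), numeric(1))
    v <- numeric(n)
    if (length(Jp$ii)) {
      jv <- vapply(Jp$ex, function(ex) as.numeric(eval(ex, e)), numeric(1))
      contrib <- jv * f[Jp$jj]
      for (t in seq_along(Jp$ii)) v[Jp$ii[t]] <- v[Jp$ii[t]] + contrib[t]
    }
    v
  }
  sparsity <- matrix(FALSE, n, n)
  if (length(J_trip)) sparsity[cbind(Jp$ii, Jp$jj)] <- TRUE

  out <- ode_model(
    n_states = n, n_params = np,
    rhs = eval_vec(f_exprs, n),
    jacobian = eval_mat(J_trip, n, n),
    second_rhs_jacobian = eval_mat(JJ_trip, n, n),
    xddot = fused_xddot,
    rhs_param_jac = if (np > 0) eval_mat(dfdp_trip, n, np) else NULL,
    second_rhs_param_jac = if (np > 0) eval_mat(dxddp_trip, n, np) else NULL,
    jac_sparsity = sparsity,
    state_names = sp, param_names = pa)
  out$symbolic <- model
  if (emit_source) {
    dep <- function(trip, what) vapply(trip, function(t)
      sprintf("%s[%d,%d] = %s", what, t$i, t$j,
              paste(deparse(t$expr), collapse = " ")), "")
    attr(out, "source") <- c(
      sprintf("f[%d] = %s", seq_len(n), model$rates),
      dep(J_trip, "Jf"), dep(JJ_trip, "JJf"),
      dep(dfdp_trip, "dfdp"), dep(dxddp_trip, "dxddotdp"))
  }
  out
}

#' Structural non-zero fraction of the Jacobian
#'
#' Count of structurally non-zero `df_i/dx_j` entries divided by `n_x^2`.
#' For the four-species enzyme kinetics scheme this is 10/16 = 5/8.
#'
#' @param model an `sd_symbolic` or compiled `sd_model`.
#' @return A number in `(0, 1]` (0 for a constant right-hand side).
#' @export
jacobian_nnz_fraction <- function(model) {
  if (inherits(model, "sd_model")) {
    if (is.null(model$jac_sparsity))
      sd_error("sd_invalid_argument", "compiled model lacks a sparsity pattern")
    return(mean(model$jac_sparsity))
  }
  if (!inherits(model, "sd_symbolic"))
    sd_error("sd_invalid_argument", "'model' must be symbolic or compiled")
  sp <- model$species
  nnz <- 0L
  for (i in seq_along(sp)) {
    for (j in seq_along(sp)) {
      if (!.is_zero_expr(stats::D(model$rate_exprs[[i]], sp[j]))) nnz <- nnz + 1L
    }
  }
  nnz / length(sp)^2
}

# Integer basis of the null space of an integer matrix A (columns v, A v = 0),
# by fraction-free Gauss-Jordan elimination; entries stay exact in doubles.
.nullspace_int <- function(A) {
  A <- matrix(as.numeric(round(A)), nrow(A))
  m <- nrow(A); n <- ncol(A)
  gcd2 <- function(a, b) { a <- abs(a); b <- abs(b)
    while (b > 0) { t <- b; b <- a %% b; a <- t }; a }
  row_gcd <- function(r) { g <- 0; for (v in r[r != 0]) g <- gcd2(g, v)
    if (g == 0) 1 else g }
  r <- 0L; pivcols <- integer(0)
  for (cc in seq_len(n)) {
    if (r >= m) break
    sub <- which(A[(r + 1L):m, cc] != 0)
    if (!length(sub)) next
    pr <- r + sub[1]
    if (pr != r + 1L) A[c(r + 1L, pr), ] <- A[c(pr, r + 1L), ]
    r <- r + 1L
    A[r, ] <- A[r, ] / row_gcd(A[r, ])
    if (A[r, cc] < 0) A[r, ] <- -A[r, ]
    for (i in seq_len(m)[-r]) {
      if (A[i, cc] != 0) {
        A[i, ] <- A[i, ] * A[r, cc] - A[r, ] * A[i, cc]
        A[i, ] <- A[i, ] / row_gcd(A[i, ])
      }
    }
    pivcols <- c(pivcols, cc)
  }
  free <- setdiff(seq_len(n), pivcols)
  if (!length(free)) return(matrix(0, n, 0))
  scale_int <- function(v) {
    for (k in 1:5040) {
      if (all(abs(v * k - round(v * k)) < 1e-9)) {
        w <- round(v * k)
        return(w / row_gcd(w))
      }
    }
    v  # give up: return rational vector unscaled (not expected for fixtures)
  }
  basis <- vapply(free, function(fc) {
    v <- numeric(n); v[fc] <- 1
    for (j in seq_along(pivcols)) v[pivcols[j]] <- -A[j, fc] / A[j, pivcols[j]]
    scale_int(v)
  }, numeric(n))
  matrix(basis, nrow = n)
}

#' Conservation laws of a reaction network
#'
#' Integer basis of the left null space of the stoichiometry matrix: vectors
#' `v` with `t(v) %*% stoich == 0`, so `t(v) %*% f(x, p)` vanishes identically
#' and the linear combination `t(v) %*% x` is constant along exact
#' trajectories.  For the enzyme kinetics scheme the basis spans the total
#' enzyme `x1 + x3` and total substrate mass `x2 + x3 + x4`.
#'
#' @param model an `sd_symbolic` model with reaction structure (`stoich`).
#' @return Integer matrix with one conservation vector per column (possibly
#'   zero columns for full-row-rank stoichiometry).
#' @export
conservation_laws <- function(model) {
  if (!inherits(model, "sd_symbolic") || is.null(model$stoich))
    sd_error("sd_invalid_argument",
             "conservation laws require a model with a stoichiometry matrix")
  .nullspace_int(t(model$stoich))
}
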