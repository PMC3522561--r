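# Model/trajectory input-output and the command-line interface.
#
# JSON model schema (version 1):
#   {
#     "format": "sdsolve-model", "version": 1,
#     "species":    [{"name": "x1", "initial": 1.0}, ...],
#     "parameters": [{"name": "k1", "value": 1.0}, ...],
#     "reactions":  [{"reactants": {"x1": 1, "x2": 1},
#                     "products":  {"x3": 1},
#                     "rate": "k1*x1*x2"}, ...]
#   }
# Reactant/product entries map species name -> stoichiometric coefficient;
# "rate" is an R expression over declared species and parameters.  The
# per-species right-hand side is assembled as sum_r (products - reactants) * rate_r.

#' Read a model from the JSON schema
#'
#' @param path path to a JSON model file (schema above).
#' @return List with `model` (an `sd_symbolic` carrying the reaction
#'   stoichiometry), `x0` and `p` in declaration order.
#' @seealso [write_model_json()]
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$format, "sdsolve-model"))
    sd_error("sd_io_error", "not an sdsolve model file (missing format tag)")
  species <- vapply(doc$species, `[[`, "", "name")
  x0 <- vapply(doc$species, function(s) as.numeric(s$initial), 0)
  params <- vapply(doc$parameters, `[[`, "", "name")
  p <- vapply(doc$parameters, function(s) as.numeric(s$value), 0)
  nr <- length(doc$reactions)
  n <- length(species)
  stoich <- matrix(0, n, nr)
  rate_str <- character(nr)
  for (r in seq_len(nr)) {
    rx <- doc$reactions[[r]]
    for (nm in names(rx$reactants))
      stoich[match(nm, species), r] <- stoich[match(nm, species), r] - as.numeric(rx$reactants[[nm]])
    for (nm in names(rx$products))
      stoich[match(nm, species), r] <- stoich[match(nm, species), r] + as.numeric(rx$products[[nm]])
    rate_str[r] <- rx$rate
  }
  f_str <- vapply(seq_len(n), function(i) {
    idx <- which(stoich[i, ] != 0)
    if (!length(idx)) return("0")
    paste(vapply(idx, function(r) {
      s <- stoich[i, r]
      coef <- if (abs(s) == 1) "" else paste0(abs(s), "*")
      paste0(if (s < 0) "-" else "+", coef, "(", rate_str[r], ")")
    }, ""), collapse = " ")
  }, "")
  model <- symbolic_model(species, params, f_str, stoich = stoich)
  model$reaction_rates <- rate_str
  list(model = model, x0 = stats::setNames(x0, species),
       p = stats::setNames(p, params))
}

#' Write a reaction-structured model to the JSON schema
#'
#' @param model an `sd_symbolic` with a stoichiometry matrix and per-reaction
#'   rates (as produced by [mass_action_model()] or [read_model_json()]).
#' @param x0,p initial state and parameter values.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, x0, p, path) {
  if (!inherits(model, "sd_symbolic") || is.null(model$stoich))
    sd_error("sd_io_error", "JSON export needs a reaction-structured symbolic model")
  rate_str <- model$reaction_rates
  if (is.null(rate_str)) {
    # reconstruct mass-action rate strings from orders
    if (is.null(model$orders))
      sd_error("sd_io_error", "model has no per-reaction rate expressions")
    rate_str <- vapply(seq_len(ncol(model$stoich)), function(r) {
      terms <- c(model$params[r],
                 unlist(lapply(which(model$orders[, r] > 0), function(i) {
                   if (model$orders[i, r] == 1) model$species[i]
                   else sprintf("%s^%d", model$species[i], model$orders[i, r])
                 })))
      paste(terms, collapse = "*")
    }, "")
  }
  reactions <- lapply(seq_len(ncol(model$stoich)), function(r) {
    sc <- model$stoich[, r]
    consumed <- if (!is.null(model$orders)) model$orders[, r] else pmax(-sc, 0)
    produced <- sc + consumed
    list(reactants = as.list(stats::setNames(consumed[consumed > 0],
                                             model$species[consumed > 0])),
         products = as.list(stats::setNames(produced[produced > 0],
                                            model$species[produced > 0])),
         rate = rate_str[r])
  })
  doc <- list(format = "sdsolve-model", version = 1,
              species = lapply(seq_along(model$species), function(i)
                list(name = model$species[i], initial = unname(x0[i]))),
              parameters = lapply(seq_along(model$params), function(i)
                list(name = model$params[i], value = unname(p[i]))),
              reactions = reactions)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a trajectory to CSV at full precision
#'
#' Comma-separated, header row, `.` decimal separator, every value rendered
#' with 17 significant digits so that re-reading reproduces the doubles
#' exactly.  Sensitivity columns are named `s[x_i/p_k]`.
#'
#' @param sol an `sd_sol`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(sol, path) {
  df <- as.data.frame(sol)
  chr <- vapply(df, function(col) sprintf("%.17g", col), character(nrow(df)))
  chr <- matrix(chr, nrow = nrow(df), dimnames = list(NULL, names(df)))
  utils::write.table(chr, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Solver statistics as JSON
#' @param sol an `sd_sol`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(sol, path) {
  jsonlite::write_json(c(list(schema = "sdsolve-stats", version = 1,
                              success = sol$success),
                         sol$stats),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.cli_usage <- function() {
  paste(
    "usage: sdsolve <command> [options]",
    "",
    "commands:",
    "  run             integrate a model and write the trajectory",
    "  validate        check a model's analytic derivatives by finite differences",
    "  fixtures        list the built-in model fixtures",
    "  work-precision  sweep tolerances and report precision vs. work",
    "",
    "run options:",
    "  --fixture NAME | --model FILE.json   (exactly one model source)",
    "  --t0 T --t-end T    integration interval (t-end required for --model)",
    "  --rtol R --atol A   tolerances (default 1e-6 / 1e-8)",
    "  --sensitivities     also integrate parameter sensitivities",
    "  --out FILE.csv      trajectory output (default trajectory.csv)",
    "  --stats FILE.json   statistics output (default <out>_stats.json)",
    "  --seed N            seed for random fixtures",
    "  --n N               species count for random fixtures",
    sep = "\n")
}

.cli_parse <- function(args) {
  opts <- list(flags = character(0), vals = list())
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      sd_error("sd_cli_error", sprintf("unexpected argument '%s'", a))
    key <- substring(a, 3)
    if (key %in% c("sensitivities", "help")) {
      opts$flags <- c(opts$flags, key); i <- i + 1L
    } else {
      if (i == length(args))
        sd_error("sd_cli_error", sprintf("option --%s needs a value", key))
      opts$vals[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  opts
}

.cli_num <- function(opts, key, default) {
  v <- opts$vals[[key]]
  if (is.null(v)) return(default)
  out <- suppressWarnings(as.numeric(v))
  if (is.na(out)) sd_error("sd_cli_error", sprintf("--%s must be numeric", key))
  out
}

.cli_load_model <- function(opts) {
  has_fix <- !is.null(opts$vals$fixture); has_file <- !is.null(opts$vals$model)
  if (has_fix == has_file)
    sd_error("sd_cli_error", "give exactly one of --fixture or --model")
  if (has_fix) {
    fx <- make_fixture(opts$vals$fixture,
                       seed = as.integer(.cli_num(opts, "seed", 1)),
                       n = as.integer(.cli_num(opts, "n", 6)))
  } else {
    m <- read_model_json(opts$vals$model)
    fx <- list(name = opts$vals$model, model = m$model, x0 = m$x0, p = m$p,
               tspan = c(0, NA))
  }
  fx$tspan[1] <- .cli_num(opts, "t0", fx$tspan[1])
  fx$tspan[2] <- .cli_num(opts, "t-end", fx$tspan[2])
  if (is.na(fx$tspan[2]))
    sd_error("sd_cli_error", "--t-end is required for this model source")
  fx
}

#' Command-line entry point
#'
#' Thin shell over the package functions (see `inst/cli/sdode` for the
#' executable wrapper).  Subcommands: `run`, `validate`, `fixtures`,
#' `work-precision`.
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit code: 0 on success, 2 for configuration/model
#'   errors, 3 for integration failure.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("--help", "help")) {
    cat(.cli_usage(), "\n"); return(0L)
  }
  cmd <- args[1]
  res <- tryCatch({
    opts <- .cli_parse(args[-1])
    switch(cmd,
      fixtures = {
        cat(paste(fixture_names(), collapse = "\n"), "\n")
        0L
      },
      validate = {
        fx <- .cli_load_model(opts)
        model <- compile_model(fx$model)
        x0 <- fx$x0
        if (all(x0 >= 0)) x0 <- x0 + 0.1  # generic positive point
        rep_out <- validate_model(model, x0, fx$p,
                                  fd_step = .cli_num(opts, "fd-step", 1e-6))
        for (nm in setdiff(names(rep_out), c("sparsity_violations", "ok")))
          cat(sprintf("%-24s max relative discrepancy %.3g at (%d, %d)\n", nm,
                      rep_out[[nm]]$max_rel, rep_out[[nm]]$worst[1],
                      rep_out[[nm]]$worst[2]))
        cat(sprintf("sparsity violations: %d\n",
                    nrow(rep_out$sparsity_violations)))
        0L
      },
      run = {
        fx <- .cli_load_model(opts)
        rtol <- .cli_num(opts, "rtol", 1e-6)
        atol <- .cli_num(opts, "atol", 1e-8)
        if (rtol <= 0 || atol <= 0)
          sd_error("sd_cli_error", "tolerances must be positive")
        sol <- sd_integrate(compile_model(fx$model), fx$x0, fx$p, fx$tspan,
                            rtol = rtol, atol = atol,
                            sensitivities = "sensitivities" %in% opts$flags)
        out <- if (!is.null(opts$vals$out)) opts$vals$out else "trajectory.csv"
        write_trajectory_csv(sol, out)
        stats_path <- if (!is.null(opts$vals$stats)) opts$vals$stats else
          paste0(sub("\\.csv$", "", out), "_stats.json")
        write_stats_json(sol, stats_path)
        if (!sol$success) {
          message("integration failed: ", sol$message)
          3L
        } else {
          cat(sprintf("wrote %s (%d rows) and %s\n", out, length(sol$times),
                      stats_path))
          0L
        }
      },
      `work-precision` = {
        fx <- .cli_load_model(opts)
        model <- compile_model(fx$model)
        rtols <- as.numeric(strsplit(
          if (!is.null(opts$vals$rtols)) opts$vals$rtols
          else "1e-4,1e-6,1e-8", ",")[[1]])
        ref <- sd_integrate(model, fx$x0, fx$p, fx$tspan,
                            rtol = min(rtols) * 1e-3,
                            atol = .cli_num(opts, "atol", 1e-10))
        rows <- lapply(rtols, function(rt) {
          s <- sd_integrate(model, fx$x0, fx$p, fx$tspan, rtol = rt,
                            atol = .cli_num(opts, "atol", 1e-10))
          data.frame(rtol = rt, precision = precision_of(s, ref),
                     steps = s$stats$steps_accepted, n_f = s$stats$n_f)
        })
        tab <- do.call(rbind, rows)
        out <- if (!is.null(opts$vals$out)) opts$vals$out else ""
        if (nzchar(out)) utils::write.csv(tab, out, row.names = FALSE)
        else print(tab)
        0L
      },
      sd_error("sd_cli_error", sprintf("unknown command '%s'", cmd))
    )
  },
  sd_cli_error = function(e) { message(conditionMessage(e));
                               message(.cli_usage()); 2L },
  sd_invalid_argument = function(e) { message(conditionMessage(e)); 2L },
  sd_io_error = function(e) { message(conditionMessage(e)); 2L },
  sd_compile_error = function(e) { message(conditionMessage(e)); 2L },
  error = function(e) { message(conditionMessage(e)); 3L })
  res
}
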