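# Runtime adapters between a reaction_network and the compiled solver.

# Pack the model + parameter values into plain arrays for the C routines.
model_runtime <- function(model, params) {
  params <- check_params(model, params)
  sp <- model$species$name
  ns <- length(sp)
  N <- stoichiometry(model)
  storage.mode(N) <- "double"
  r1 <- r2 <- integer(length(model$reactions))
  for (j in seq_along(model$reactions)) {
    re <- match(model$reactions[[j]]$reactants, sp)
    r1[j] <- if (length(re) >= 1) re[1] - 1L else -1L
    r2[j] <- if (length(re) >= 2) re[2] - 1L else -1L
  }
  rates <- rate_values(model, as.list(params))
  L <- model$conservation$matrix
  storage.mode(L) <- "double"
  stim_law <- match(model$stimulus, model$conservation$totals)
  law_base <- vapply(model$conservation$totals, function(sym) {
    if (sym == "1") 1
    else if (sym == model$stimulus) NA_real_
    else unname(params[[sym]])
  }, numeric(1))
  adjust_name <- vapply(seq_len(nrow(L)), function(l) {
    members <- sp[L[l, ] != 0]
    pick <- intersect(c("Ec", "Sc", "F", "Fc"), members)
    pick[1]
  }, character(1))
  # drained (and their released partners) when the kinase total is lowered:
  # free cytosolic kinase, free nuclear kinase, then complexes (which give
  # their substrate back to the matching compartment).
  drain_def <- list(c("Ec", NA), c("E", NA), c("Xc", "Sc"), c("X", "S"))
  drain_def <- Filter(function(d) d[1] %in% sp, drain_def)
  list(
    stoich = N, r1 = r1, r2 = r2, rates = as.numeric(rates),
    law = L, law_base = as.numeric(law_base), stim_law = as.integer(stim_law),
    adjust = as.integer(match(adjust_name, sp) - 1L),
    enz_drain = as.integer(vapply(drain_def, function(d) match(d[1], sp), 1L) - 1L),
    enz_release = as.integer(vapply(drain_def, function(d) {
      if (is.na(d[2])) 0L else match(d[2], sp)
    }, 1L) - 1L),
    resp = as.integer(match(model$response, sp)),
    params = params)
}

solver_options <- function(rtol = 1e-4, atol = 1e-9, ss_tol = 1e-6,
                           t_min = 10, t_max = 1e6, h0 = 1e-4,
                           max_steps = 50000L, newton_gate = TRUE) {
  c(rtol, atol, ss_tol, t_min, t_max, h0, max_steps, as.numeric(newton_gate))
}

#' Relax a model to steady state
#'
#' Integrates the mass-action ODE system from `initial_state` until the
#' relative rate of change of every species falls below `tolerance` (per unit
#' dimensionless time), or the time cap is hit. Two backends are available:
#' the package's compiled L-stable Rosenbrock integrator (`"ros2"`, default,
#' used by the mass sweeps) and [deSolve::lsoda()] (`"lsoda"`), kept as an
#' independent route for cross-checks. Integrator failure is reported through
#' the convergence flag, never as an error, so that parameter-space sweeps
#' are not aborted by a single pathological point.
#'
#' @param model a `reaction_network`.
#' @param params named parameter values.
#' @param stimulus kinase total (fixes the kinase conservation law).
#' @param initial_state non-negative state consistent with the conservation
#'   laws; default [initial_state()] (all enzymes cytosolic and inactive).
#' @param tolerance steady-state threshold on `max |dx_i/dt| / max(x_i, 1e-6)`.
#' @param method `"ros2"` or `"lsoda"`.
#' @param t_max time cap (dimensionless time units).
#' @return list with `state` (named), `converged` (logical).
#' @export
steady_state <- function(model, params, stimulus, initial_state = NULL,
                         tolerance = 1e-6, method = c("ros2", "lsoda"),
                         t_max = 1e6) {
  method <- match.arg(method)
  rt <- model_runtime(model, params)
  if (is.null(initial_state)) {
    initial_state <- compswitch::initial_state(model, as.list(rt$params), stimulus)
  }
  x0 <- as.numeric(initial_state[model$species$name])
  if (any(x0 < 0) || any(!is.finite(x0))) {
    stop("initial state must be finite and non-negative")
  }
  targets <- rt$law_base
  targets[rt$stim_law] <- stimulus
  lv <- drop(rt$law %*% x0)
  if (any(abs(lv - targets) > 1e-6 * pmax(abs(targets), 1))) {
    stop("initial state is inconsistent with the conservation laws")
  }
  if (method == "ros2") {
    res <- .Call(C_relax, rt$stoich, rt$r1, rt$r2, rt$rates, x0,
                 solver_options(ss_tol = tolerance, t_max = t_max),
                 rt$law, targets, rt$adjust)
    state <- setNames(res[[1]], model$species$name)
    return(list(state = state, converged = res[[2]] == 1L))
  }
  ## lsoda route: geometric output times to the cap, convergence judged on
  ## the trailing interval.
  f <- function(t, y, p) {
    y <- pmax(y, 0)
    flux <- rt$rates
    has1 <- rt$r1 >= 0L
    flux[has1] <- flux[has1] * y[rt$r1[has1] + 1L]
    has2 <- rt$r2 >= 0L
    flux[has2] <- flux[has2] * y[rt$r2[has2] + 1L]
    list(drop(rt$stoich %*% flux))
  }
  times <- unique(c(0, 10 * 4^(0:ceiling(log(t_max / 10, 4))), t_max))
  times <- times[times <= t_max]
  sol <- try(suppressWarnings(
    deSolve::lsoda(y = x0, times = times, func = f, parms = NULL,
                   rtol = 1e-6, atol = 1e-9)), silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < 2) {
    return(list(state = setNames(x0, model$species$name), converged = FALSE))
  }
  converged <- FALSE
  kfin <- nrow(sol)
  for (k in 2:nrow(sol)) {
    dt <- sol[k, 1] - sol[k - 1, 1]
    xk <- sol[k, -1]; xp <- sol[k - 1, -1]
    rate <- max(abs(xk - xp) / pmax(abs(xk), 1e-6)) / dt
    if (sol[k, 1] >= 10 && rate < tolerance) { converged <- TRUE; kfin <- k; break }
  }
  state <- setNames(pmax(as.numeric(sol[kfin, -1]), 0), model$species$name)
  list(state = state, converged = converged)
}
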