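# Going-up and coming-down analysis: sweep the stimulus ascending then
# descending, warm-starting every steady-state relaxation from a slightly
# perturbed copy of the previous one, and classify the branch pair.

#' Logarithmic stimulus grid
#'
#' @param from,to positive range limits.
#' @param points_per_decade grid density (default 10).
#' @return strictly increasing stimulus vector.
#' @export
stimulus_grid <- function(from, to, points_per_decade = 10) {
  stopifnot(from > 0, to > from)
  n <- max(3, ceiling(log10(to / from) * points_per_decade) + 1)
  10^seq(log10(from), log10(to), length.out = n)
}

default_stimulus_range <- function(model) {
  if (model$name == "MINIMAL") c(1e-6, 1e1) else c(1e-3, 1e3)
}

#' Going-up/coming-down stimulus sweep
#'
#' Computes the steady-state response curve while the stimulus (total kinase)
#' ascends through `stimulus_vector` and then descends back. The first
#' relaxation starts from the all-cytosolic inactive state; every subsequent
#' one is warm-started from the previous steady state, multiplied by
#' `1 + perturbation` on its nonzero entries and re-projected onto the
#' conservation laws of the new stimulus. The descending branch starts from
#' the final ascending state.
#'
#' @param model a `reaction_network`.
#' @param params named parameter values.
#' @param stimulus_vector strictly increasing positive stimuli; default a
#'   log grid over the model's standard range (`1e-6`-`1e1` for the minimal
#'   model, `1e-3`-`1e3` otherwise).
#' @param points_per_decade density of the default grid.
#' @param perturbation relative warm-start perturbation (default `1e-4`).
#' @param tolerance steady-state tolerance (see [steady_state()]).
#' @param t_max relaxation time cap per stimulus.
#' @return a `branch_pair`: list with `stimulus`, `up`, `down` (responses at
#'   each grid stimulus; `down` is indexed ascending but was computed
#'   descending), `converged_up`, `converged_down`.
#' @export
sweep_up_down <- function(model, params, stimulus_vector = NULL,
                          points_per_decade = 10, perturbation = 1e-4,
                          tolerance = 1e-6, t_max = 1e6, newton_gate = TRUE) {
  if (is.null(stimulus_vector)) {
    rg <- default_stimulus_range(model)
    stimulus_vector <- stimulus_grid(rg[1], rg[2], points_per_decade)
  }
  if (any(diff(stimulus_vector) <= 0) || any(stimulus_vector <= 0)) {
    stop("stimulus_vector must be strictly increasing and positive")
  }
  rt <- model_runtime(model, params)
  x0 <- as.numeric(initial_state(model, as.list(rt$params), stimulus_vector[1])[model$species$name])
  res <- .Call(C_sweep, rt$stoich, rt$r1, rt$r2, rt$rates, x0,
               as.numeric(stimulus_vector),
               solver_options(ss_tol = tolerance, t_max = t_max,
                              newton_gate = newton_gate),
               rt$law, rt$law_base, rt$stim_law, rt$adjust,
               rt$enz_drain, rt$enz_release, rt$resp, perturbation)
  structure(list(stimulus = as.numeric(stimulus_vector),
                 up = res[[1]], down = res[[2]],
                 converged_up = res[[3]] == 1L,
                 converged_down = res[[4]] == 1L,
                 model = model$name),
            class = "branch_pair")
}

#' Construct a branch pair from precomputed curves
#'
#' Used for synthetic fixtures and external data.
#'
#' @param stimulus ascending stimulus vector.
#' @param up,down responses at each stimulus (down computed descending but
#'   stored in ascending stimulus order).
#' @param converged_up,converged_down optional per-point convergence flags.
#' @return a `branch_pair`.
#' @export
branch_pair <- function(stimulus, up, down,
                        converged_up = rep(TRUE, length(stimulus)),
                        converged_down = rep(TRUE, length(stimulus))) {
  stopifnot(length(up) == length(stimulus), length(down) == length(stimulus))
  structure(list(stimulus = as.numeric(stimulus), up = as.numeric(up),
                 down = as.numeric(down),
                 converged_up = converged_up, converged_down = converged_down,
                 model = NA_character_),
            class = "branch_pair")
}

#' @export
print.branch_pair <- function(x, ...) {
  cat("<branch_pair> ", length(x$stimulus), " stimuli in [",
      format(min(x$stimulus)), ", ", format(max(x$stimulus)), "]\n", sep = "")
  cat("  response range up: [", format(min(x$up)), ", ", format(max(x$up)),
      "]  down: [", format(min(x$down)), ", ", format(max(x$down)), "]\n", sep = "")
  cat("  non-converged points: ",
      sum(!x$converged_up) + sum(!x$converged_down), "\n", sep = "")
  invisible(x)
}

#' Detect discontinuities along a response branch
#'
#' A discontinuity exists at position `i` (in traversal order) if the response
#' step `|r_i - r_(i-1)|` is at least `ratio` times the previous step
#' `|r_(i-1) - r_(i-2)|` and larger than `floor` in absolute value.
#'
#' @param branch responses in traversal order (ascending stimulus for the
#'   going-up branch; pass the coming-down branch reversed).
#' @param ratio trend multiplier (default 5).
#' @param floor absolute jump floor (default `1e-3`).
#' @return integer vector of traversal indices (`>= 3`) at which a
#'   discontinuity occurs.
#' @export
detect_discontinuities <- function(branch, ratio = 5, floor = 1e-3) {
  n <- length(branch)
  if (n < 3) stop("branch must contain at least 3 points")
  d <- abs(diff(branch))            # d[i] = |r_(i+1) - r_i|
  i <- 3:n
  hit <- d[i - 1] >= ratio * d[i - 2] & d[i - 1] > floor
  i[hit]
}

#' Classify a branch pair as monostable, bistable, or flagged
#'
#' One discontinuity on each branch labels the pair bistable, with
#' `stim_on` the stimulus at the going-up jump and `stim_off` the stimulus at
#' the coming-down jump; no discontinuity on either branch labels it
#' monostable; anything else (a single one-sided jump, multiple jumps on one
#' branch, an inverted threshold pair, or too many non-converged relaxations)
#' is flagged for further analysis. Pairs whose response never reaches
#' `response_floor` are recorded as monostable with
#' `passed_response_floor = FALSE` and are excluded from downstream scoring.
#'
#' @param pair a `branch_pair`.
#' @param response_floor minimal response the analysis requires (default
#'   `1e-2`).
#' @param max_nonconverged flag the pair when more than this fraction of
#'   relaxations did not converge (default 0.1).
#' @return a `bistability_result`: list with `label`, `stim_on`, `stim_off`,
#'   `idx_on`, `idx_off` (ascending grid indices), `passed_response_floor`,
#'   `converged_fraction`, `n_jumps_up`, `n_jumps_down`.
#' @export
classify <- function(pair, response_floor = 1e-2, max_nonconverged = 0.1) {
  stopifnot(inherits(pair, "branch_pair"))
  n <- length(pair$stimulus)
  conv_frac <- mean(c(pair$converged_up, pair$converged_down))
  floor_ok <- max(pair$up, pair$down) >= response_floor
  res <- list(label = "monostable", stim_on = NA_real_, stim_off = NA_real_,
              idx_on = NA_integer_, idx_off = NA_integer_,
              passed_response_floor = floor_ok,
              converged_fraction = conv_frac,
              n_jumps_up = 0L, n_jumps_down = 0L)
  class(res) <- "bistability_result"
  if (!floor_ok) return(res)

  ju <- detect_discontinuities(pair$up)
  jd_trav <- detect_discontinuities(rev(pair$down))
  jd <- n + 1L - jd_trav                 # ascending grid index of the jump
  res$n_jumps_up <- length(ju)
  res$n_jumps_down <- length(jd)

  if ((1 - conv_frac) > max_nonconverged) {
    res$label <- "flagged"
    return(res)
  }
  if (length(ju) == 0 && length(jd) == 0) return(res)
  if (length(ju) == 1 && length(jd) == 1) {
    stim_on <- pair$stimulus[ju]
    stim_off <- pair$stimulus[jd]
    if (stim_off < stim_on) {
      res$label <- "bistable"
      res$stim_on <- stim_on; res$stim_off <- stim_off
      res$idx_on <- ju; res$idx_off <- jd
      return(res)
    }
  }
  res$label <- "flagged"
  res
}

#' @export
print.bistability_result <- function(x, ...) {
  cat("<bistability_result> ", x$label, sep = "")
  if (x$label == "bistable") {
    cat("  stim_off = ", format(x$stim_off), ", stim_on = ", format(x$stim_on),
        sep = "")
  }
  if (!x$passed_response_floor) cat("  (below response floor)")
  cat("\n")
  invisible(x)
}

#' Scan one parameter set end to end
#'
#' Convenience wrapper: sweep, classify, and (for bistable results) score the
#' hysteresis loop. Flagged results can optionally be re-scanned once with
#' the stimulus range widened by one decade on each side; if the re-scan
#' still finds a single one-sided jump the case is reported as a one-way
#' switch via the `one_way` field.
#'
#' @param model a `reaction_network`.
#' @param params named parameter values.
#' @param rescan_flagged logical; widen the range and retry flagged cases.
#' @param ... passed to [sweep_up_down()].
#' @return list with `pair`, `result`, `metrics` (NULL unless bistable),
#'   `one_way` (logical).
#' @export
scan_parameter_set <- function(model, params, rescan_flagged = FALSE, ...) {
  pair <- sweep_up_down(model, params, ...)
  result <- classify(pair)
  one_way <- FALSE
  if (result$label == "flagged" && rescan_flagged) {
    rg <- range(pair$stimulus)
    wide <- stimulus_grid(rg[1] / 10, rg[2] * 10)
    pair2 <- sweep_up_down(model, params, stimulus_vector = wide)
    result2 <- classify(pair2)
    if (result2$label != "flagged") {
      pair <- pair2; result <- result2
    } else if (xor(result2$n_jumps_up == 1, result2$n_jumps_down == 1)) {
      one_way <- TRUE
    }
  }
  metrics <- if (result$label == "bistable") score_hysteresis(pair, result) else NULL
  list(pair = pair, result = result, metrics = metrics, one_way = one_way)
}
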