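# Seeded log-uniform Latin hypercube sampling of parameter space.

#' Define a sampling plan
#'
#' @param ranges named list (or 2-row matrix with named columns) of positive
#'   `[low, high]` bounds per parameter, sampled log-uniformly.
#' @param n_samples number of points.
#' @param seed integer RNG seed.
#' @return a `sampling_plan`.
#' @export
sampling_plan <- function(ranges, n_samples, seed) {
  if (is.matrix(ranges)) {
    ranges <- setNames(lapply(seq_len(ncol(ranges)), function(j) ranges[, j]),
                       colnames(ranges))
  }
  stopifnot(length(ranges) >= 1, n_samples >= 1)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || any(!is.finite(r)) || any(r <= 0) || r[1] >= r[2]) {
      stop("invalid range for parameter '", nm,
           "': need positive low < high")
    }
  }
  structure(list(ranges = ranges, n_samples = as.integer(n_samples),
                 seed = as.integer(seed), scale = "log10"),
            class = "sampling_plan")
}

#' Default sampling plan for a model
#'
#' All free non-concentration parameters over `[1e-3, 1e3]`. For the minimal
#' model this is the standard study design (all 8 parameters); the full
#' models additionally sample their concentration ratios over the same range
#' unless a restricted plan is supplied.
#'
#' @param model a `reaction_network`.
#' @param n_samples number of points (default 5000, a desk-scale version of
#'   the reference 30000-point design).
#' @param seed RNG seed.
#' @param range common `[low, high]` range (default `c(1e-3, 1e3)`).
#' @return a `sampling_plan`.
#' @export
default_sampling_plan <- function(model, n_samples = 5000, seed = 1,
                                  range = c(1e-3, 1e3)) {
  syms <- model$parameters$symbol
  sampling_plan(setNames(rep(list(range), length(syms)), syms),
                n_samples, seed)
}

#' Draw a Latin hypercube sample
#'
#' Each parameter's `n_samples` values occupy distinct equal-width strata in
#' log10 space (the Latin property); the draw is reproducible from the plan's
#' seed.
#'
#' @param plan a [sampling_plan()].
#' @return data.frame, one row per sampled point, one column per parameter,
#'   with attributes `seed` and `plan`.
#' @export
lhs_sample <- function(plan) {
  stopifnot(inherits(plan, "sampling_plan"))
  k <- length(plan$ranges)
  set.seed(plan$seed)
  u <- lhs::randomLHS(plan$n_samples, k)
  vals <- vapply(seq_len(k), function(j) {
    r <- log10(plan$ranges[[j]])
    10^(r[1] + u[, j] * (r[2] - r[1]))
  }, numeric(plan$n_samples))
  vals <- matrix(vals, nrow = plan$n_samples, ncol = k)
  out <- as.data.frame(vals)
  names(out) <- names(plan$ranges)
  attr(out, "seed") <- plan$seed
  attr(out, "plan") <- plan
  out
}
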