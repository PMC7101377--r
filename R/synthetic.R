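# Synthetic fixtures: hysteresis curves with known geometry, discovery and
# caching of verifiably bistable parameter points, and substitute restricted
# sampling ranges (standing in for externally derived seed parameter sets).

#' Synthetic hysteresis loop with known geometry
#'
#' Builds a going-up/coming-down branch pair on a log-spaced stimulus grid
#' from smooth baseline branches plus a single jump per branch: the up branch
#' jumps from the low to the high level at `stim_on`, the down branch drops
#' back at `stim_off`. With `noise_sd = 0` the curves realize the requested
#' geometry exactly; the true metrics are computed from the generating
#' functions on a fine quadrature grid, independently of the scoring code.
#'
#' @param stim_on,stim_off jump positions (`stim_off < stim_on`).
#' @param low_level,high_level branch plateaus in `[0, 1]`.
#' @param stim_range stimulus range (default one decade margin around the
#'   jumps).
#' @param points_per_decade grid density.
#' @param slope log10-stimulus scale of the smooth baseline rise (larger =
#'   flatter branches).
#' @param baseline_rise fraction of the branch gap carried by the smooth
#'   baseline sigmoids (0 gives an ideal rectangular loop).
#' @param noise_sd additive Gaussian response noise.
#' @param seed RNG seed for the noise.
#' @return a `synthetic_loop`: the `branch_pair` in `$pair` plus
#'   `true_stim_on`, `true_stim_off`, `true_width`, `true_area`,
#'   `true_distance_1`, `true_distance_2`.
#' @export
make_synthetic_loop <- function(stim_on, stim_off, low_level = 0,
                                high_level = 1, stim_range = NULL,
                                points_per_decade = 30, slope = 4,
                                baseline_rise = 0.15, noise_sd = 0, seed = 1) {
  if (stim_off >= stim_on) stop("stim_off must be strictly below stim_on")
  stopifnot(low_level >= 0, high_level <= 1, low_level < high_level)
  if (is.null(stim_range)) stim_range <- c(stim_off / 10, stim_on * 10)
  s <- stimulus_grid(stim_range[1], stim_range[2], points_per_decade)
  # realize the jumps exactly on the grid: the reported true geometry is the
  # snapped one, so the generated curves match it exactly at noise_sd = 0
  stim_on <- s[which.min(abs(log10(s) - log10(stim_on)))]
  stim_off <- s[which.min(abs(log10(s) - log10(stim_off)))]
  if (stim_off >= stim_on) stop("jump positions collapse onto one grid point")
  mid <- log10(sqrt(stim_on * stim_off))
  gap <- high_level - low_level
  # gentle sigmoids in log-stimulus; the branch gap carries the jump
  lower <- function(x) low_level + baseline_rise * gap / (1 + exp(-(log10(x) - mid) / slope))
  upper <- function(x) high_level - baseline_rise * gap / (1 + exp(-(mid - log10(x)) / slope))
  up <- ifelse(s < stim_on, lower(s), upper(s))
  down <- ifelse(s > stim_off, upper(s), lower(s))
  if (noise_sd > 0) {
    set.seed(seed)
    up <- pmin(1, pmax(0, up + stats::rnorm(length(s), 0, noise_sd)))
    down <- pmin(1, pmax(0, down + stats::rnorm(length(s), 0, noise_sd)))
  }
  fine <- seq(stim_off, stim_on, length.out = 20000)
  structure(list(
    pair = branch_pair(s, up, down),
    true_stim_on = stim_on, true_stim_off = stim_off,
    true_width = stim_on - stim_off,
    true_area = sum(diff(fine) * (head(upper(fine) - lower(fine), -1) +
                                    tail(upper(fine) - lower(fine), -1)) / 2),
    true_distance_1 = upper(stim_on) - lower(stim_on),
    true_distance_2 = upper(stim_off) - lower(stim_on),
    noise_sd = noise_sd), class = "synthetic_loop")
}

#' Discover verified bistable parameter points
#'
#' Draws `n` Latin-hypercube points from `plan` (default: the model's
#' standard log-uniform plan), classifies each with the going-up/coming-down
#' sweep, and keeps the bistable ones that an independent check confirms:
#' relaxing to steady state at the geometric mid-loop stimulus from two
#' distinct initial conditions (all species cytosolic and inactive vs all
#' substrate nuclear and phosphorylated) must yield two steady states whose
#' nuclear phosphorylated substrate differs by more than `gap`.
#'
#' @param model a `reaction_network`.
#' @param n number of candidate points.
#' @param seed sampling seed.
#' @param plan optional [sampling_plan()] overriding the default ranges.
#' @param gap minimal response separation for confirmation (default `1e-2`).
#' @param ... passed to [sweep_up_down()].
#' @return a `bistable_cache`: data.frame of confirmed points (parameters
#'   plus `stim_on`, `stim_off`) with attributes `model`, `seed`,
#'   `n_searched`, `n_detected` (sweep-bistable before confirmation).
#' @export
discover_bistable_points <- function(model, n = 5000, seed = 1, plan = NULL,
                                     gap = 1e-2, ...) {
  if (is.null(plan)) plan <- default_sampling_plan(model, n_samples = n, seed = seed)
  X <- lhs_sample(plan)
  sp <- model$species$name
  rows <- list()
  n_detected <- 0L
  for (i in seq_len(nrow(X))) {
    p <- unlist(X[i, ])
    res <- classify(sweep_up_down(model, p, ...))
    if (res$label != "bistable") next
    n_detected <- n_detected + 1L
    smid <- sqrt(res$stim_on * res$stim_off)
    ic2 <- setNames(numeric(length(sp)), sp)
    ic2["Sp"] <- if (model$name == "FULL_DIM") p[["S_tot"]] else 1
    ic2["E"] <- smid
    if ("F" %in% sp) ic2["F"] <- law_targets(model, as.list(p), smid)[3]
    if ("Fc" %in% sp) ic2["Fc"] <- law_targets(model, as.list(p), smid)[4]
    s1 <- steady_state(model, p, smid)
    s2 <- steady_state(model, p, smid, initial_state = ic2)
    if (s1$converged && s2$converged &&
        abs(s1$state[["Sp"]] - s2$state[["Sp"]]) > gap) {
      rows[[length(rows) + 1L]] <-
        data.frame(as.list(p), stim_on = res$stim_on, stim_off = res$stim_off)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    warning("no verified bistable points found in ", n, " draws")
    X[0, , drop = FALSE]
  }
  attr(out, "model") <- model$name
  attr(out, "seed") <- seed
  attr(out, "n_searched") <- nrow(X)
  attr(out, "n_detected") <- n_detected
  class(out) <- c("bistable_cache", "data.frame")
  out
}

#' Restricted sampling ranges from a bistable-point cache
#'
#' Per parameter, `[min/10, max*10]` over the cached bistable points, clipped
#' to `bounds`. This reproduces the restrict-then-sample strategy: seed
#' points of known bistability define the region worth sampling densely.
#'
#' @param cache a [discover_bistable_points()] result (nonempty).
#' @param bounds global clipping bounds (default `c(1e-3, 1e3)`).
#' @return named list of ranges usable in [sampling_plan()].
#' @export
derive_restricted_ranges <- function(cache, bounds = c(1e-3, 1e3)) {
  stopifnot(inherits(cache, "bistable_cache"))
  if (nrow(cache) == 0) stop("cannot derive ranges from an empty cache")
  pars <- setdiff(names(cache), c("stim_on", "stim_off"))
  out <- lapply(pars, function(p) {
    lo <- max(min(cache[[p]]) / 10, bounds[1])
    hi <- min(max(cache[[p]]) * 10, bounds[2])
    if (lo >= hi) { lo <- bounds[1]; hi <- bounds[2] }
    c(lo, hi)
  })
  names(out) <- pars
  out
}

#' A full-model parameter point realizing the minimal-model dynamics
#'
#' Lifts a bistable minimal-model parameter point into the 21-parameter
#' dimensionless full model by choosing limits that realize each reduction
#' step approximately: a low-affinity/fast-catalysis nuclear kinase emulates
#' the single-step phosphorylation, an unsaturated nuclear phosphatase
#' emulates the pseudo-first-order dephosphorylation (with overall rate
#' `rho`, the time-unit ratio), the cytosolic phosphatase is made negligible,
#' and the substrate shuttling back-rates are made small to emulate the
#' irreversible transport. Used to seed the full-model bistable-point search
#' when no external seed sets are available.
#'
#' @param minimal_params named vector with `b1..b4`, `s1..s4` (minimal model).
#' @param rho time-scale ratio between the minimal model's dephosphorylation
#'   unit and the full model's phosphatase catalytic unit (default 0.05;
#'   smaller = better separation, slower dynamics).
#' @return named numeric vector of 21 `FULL_NONDIM` parameters.
#' @export
lift_minimal_to_full <- function(minimal_params, rho = 0.05) {
  p <- unlist(minimal_params)
  need <- c(paste0("b", 1:4), paste0("s", 1:4))
  stopifnot(all(need %in% names(p)))
  eps <- 1e-4   # "negligible" rates emulating removed/irreversible reactions
  c(
    # nuclear kinase: E+S -> X fast-through (rate-limiting b1), X negligible
    b1 = unname(p["b1"] * rho), b2 = 0.01, b3 = 100,
    # nuclear phosphatase: pseudo-first-order with overall rate rho:
    # konF * f1 * kcat/(koff+kcat) = rho, kept far from saturation by f1 >> 1
    b4 = unname(rho * 1.1 / 30), b5 = 0.1,
    # cytosolic kinase: direct map, rescaled to full-model time units
    b6 = unname(p["b2"] * rho), b7 = unname(p["b3"] * rho),
    b8 = unname(p["b4"] * rho),
    # cytosolic phosphatase: negligible
    b9 = eps * rho, b10 = 1, b11 = 1,
    # shuttling: substrate out / phospho-substrate in as in the minimal
    # model; reverse substrate directions negligible (irreversible limit)
    s1 = unname(p["s3"] * rho), s2 = eps * rho,
    s3 = eps * rho, s4 = unname(p["s4"] * rho),
    s5 = unname(p["s1"] * rho), s6 = unname(p["s2"] * rho),
    s7 = eps * rho, s8 = eps * rho,
    f1 = 30, f2 = 0.01)
}
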