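# Steady-state relaxation, the going-up/coming-down sweep, discontinuity
# detection, and classification.

test_that("discontinuity rule is applied literally", {
  expect_equal(detect_discontinuities(c(0.100, 0.101, 0.600)), 3L)
  expect_length(detect_discontinuities(rep(0.3, 10)), 0)
  # absolute floor binds even when the trend ratio fires
  expect_length(detect_discontinuities(c(0.1, 0.1005, 0.1011)), 0)
  expect_error(detect_discontinuities(c(1, 2)), "at least 3")
  # every qualifying index is reported
  br <- c(0, 0.001, 0.4, 0.4, 0.4005, 0.9)
  expect_equal(detect_discontinuities(br), c(3L, 6L))
})

test_that("steady states are genuine equilibria and fixed points of the solver", {
  m <- build_model("MINIMAL")
  p <- c(b1 = 1, b2 = 50, b3 = 1, b4 = 5, s1 = 1, s2 = 1, s3 = 0.5, s4 = 2)
  st <- steady_state(m, p, stimulus = 0.5)
  expect_true(st$converged)
  expect_lt(max(abs(rhs(m, p, 0.5, st$state))), 1e-8)
  # re-fed as initial condition: returns itself
  st2 <- steady_state(m, p, stimulus = 0.5, initial_state = st$state)
  expect_true(st2$converged)
  expect_equal(st2$state, st$state, tolerance = 1e-9)
  # negative initial states are rejected
  bad <- st$state; bad[1] <- -1
  expect_error(steady_state(m, p, 0.5, initial_state = bad), "non-negative")
})

test_that("with no shuttling flux into the nucleus the nuclear response is zero", {
  # all shuttling rates effectively zero and zero stimulus: the nucleus only
  # dephosphorylates, so the steady state has no nuclear phosphosubstrate
  m <- build_model("MINIMAL")
  p <- c(b1 = 1, b2 = 1, b3 = 1, b4 = 1,
         s1 = 1e-12, s2 = 1e-12, s3 = 1e-12, s4 = 1e-12)
  x0 <- initial_state(m, as.list(p), 0)
  x0["Sp"] <- 0.3; x0["Sc"] <- 0.7     # some phosphorylated substrate present
  st <- steady_state(m, p, 0, initial_state = x0, t_max = 1e7)
  expect_lt(st$state[["Sp"]], 1e-6)
})

test_that("ros2 and lsoda backends find the same steady states", {
  m <- build_model("MINIMAL")
  for (seed in 1:10) {
    p <- random_params(m, seed = seed, lo = 1e-2, hi = 1e2)
    s1 <- steady_state(m, p, stimulus = 0.3)
    s2 <- steady_state(m, p, stimulus = 0.3, method = "lsoda")
    if (s1$converged && s2$converged) {
      expect_equal(s1$state, s2$state, tolerance = 1e-5,
                   info = paste("seed", seed))
    }
  }
})

test_that("steady states agree with an independent algebraic root-finder", {
  skip_if_not_installed("pracma")
  m <- build_model("MINIMAL")
  sp <- m$species$name
  found <- 0
  for (seed in 1:20) {
    p <- random_params(m, seed = 1000 + seed, lo = 1e-2, hi = 1e2)
    st <- steady_state(m, p, stimulus = 0.5)
    if (!st$converged) next
    # solve the steady-state system (2 conservation laws + 5 rate equations)
    g <- function(x) {
      x <- setNames(pmax(x, 0), sp)
      d <- rhs(m, p, 0.5, x)
      c(sum(x[c("E", "Ec", "Xc")]) - 0.5,
        sum(x[c("S", "Sp", "Sc", "Spc", "Xc")]) - 1,
        d[c("Sp", "E", "Sc", "Spc", "Xc")])
    }
    sol <- tryCatch(pracma::fsolve(g, as.numeric(st$state) + 1e-3),
                    error = function(e) NULL)
    if (is.null(sol)) next
    found <- found + 1
    expect_lt(max(abs(pmax(sol$x, 0) - as.numeric(st$state))), 1e-5)
  }
  expect_gte(found, 10)
})

test_that("monostable sweeps have coincident, path-independent branches", {
  m <- build_model("MINIMAL")
  p <- c(b1 = 1, b2 = 50, b3 = 1, b4 = 5, s1 = 1, s2 = 1, s3 = 0.5, s4 = 2)
  pair <- sweep_up_down(m, p)
  expect_s3_class(pair, "branch_pair")
  expect_length(pair$up, length(pair$stimulus))
  expect_true(all(pair$up >= 0 & pair$up <= 1 + 1e-9))
  expect_lt(max(abs(pair$up - pair$down)), 1e-4)
  expect_equal(classify(pair)$label, "monostable")
})

test_that("a cached bistable parameter set shows hysteresis with correct thresholds", {
  m <- build_model("MINIMAL")
  p <- bistable_minimal_params()
  pair <- sweep_up_down(m, p)
  res <- classify(pair)
  expect_equal(res$label, "bistable")
  expect_lt(res$stim_off, res$stim_on)
  # branches genuinely separate between the thresholds
  mid <- which(pair$stimulus > res$stim_off & pair$stimulus < res$stim_on)
  expect_gt(max(pair$down[mid] - pair$up[mid]), 1e-2)
  # two-initial-condition verification: two distinct equilibria at mid-loop
  smid <- sqrt(res$stim_on * res$stim_off)
  lo <- steady_state(m, p, smid)
  ic2 <- setNames(numeric(7), m$species$name)
  ic2["Sp"] <- 1; ic2["E"] <- smid
  hi <- steady_state(m, p, smid, initial_state = ic2)
  expect_true(lo$converged && hi$converged)
  expect_gt(abs(hi$state[["Sp"]] - lo$state[["Sp"]]), 1e-2)
})

test_that("doubling the grid density preserves the label and the thresholds", {
  m <- build_model("MINIMAL")
  p <- bistable_minimal_params()
  r1 <- classify(sweep_up_down(m, p, points_per_decade = 10))
  r2 <- classify(sweep_up_down(m, p, points_per_decade = 20))
  expect_equal(r2$label, r1$label)
  # thresholds move by less than one coarse grid step (in log10 units)
  step <- 1 / 10
  expect_lt(abs(log10(r2$stim_on) - log10(r1$stim_on)), step + 1e-9)
  expect_lt(abs(log10(r2$stim_off) - log10(r1$stim_off)), step + 1e-9)
})

test_that("classification follows the branch-count rules", {
  s <- 10^seq(-2, 2, length.out = 41)
  flat <- rep(0.2, 41)
  jumpy <- flat; jumpy[30:41] <- 0.9
  # one jump on each branch at different stimuli: bistable
  down <- flat; down[20:41] <- 0.9
  res <- classify(branch_pair(s, jumpy, down))
  expect_equal(res$label, "bistable")
  expect_equal(res$stim_on, s[30])
  # descending, the drop is observed at the first lower-branch point
  expect_equal(res$stim_off, s[19])
  # identical smooth branches: monostable
  expect_equal(classify(branch_pair(s, flat, flat))$label, "monostable")
  # up-branch jump only: flagged
  expect_equal(classify(branch_pair(s, jumpy, jumpy * 0 + 0.9))$label, "flagged")
  # below the response floor: monostable, recorded distinctly
  tiny <- classify(branch_pair(s, flat / 100, flat / 100))
  expect_equal(tiny$label, "monostable")
  expect_false(tiny$passed_response_floor)
  # non-convergence flags the pair
  nc <- branch_pair(s, jumpy, down, converged_up = c(rep(FALSE, 10), rep(TRUE, 31)))
  expect_equal(classify(nc)$label, "flagged")
})

test_that("sweeps are deterministic", {
  m <- build_model("MINIMAL")
  p <- bistable_minimal_params()
  p1 <- sweep_up_down(m, p)
  p2 <- sweep_up_down(m, p)
  expect_identical(p1$up, p2$up)
  expect_identical(p1$down, p2$down)
})
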