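# Synthetic fixtures: loop generator, bistable-point discovery, and
# restricted sampling ranges.

test_that("the square-loop fixture is classified and scored exactly", {
  syn <- make_synthetic_loop(2, 1, low_level = 0, high_level = 1,
                             baseline_rise = 0)
  res <- classify(syn$pair)
  expect_equal(res$label, "bistable")
  mt <- score_hysteresis(syn$pair, res)
  expect_equal(mt$width, syn$true_width, tolerance = 1e-9)
  expect_equal(mt$area, syn$true_area, tolerance = 1e-3)
  expect_equal(mt$distance_1, 1, tolerance = 1e-3)
  expect_equal(mt$distance_2, 1, tolerance = 1e-3)
  expect_error(make_synthetic_loop(1, 2), "stim_off")
})

test_that("smooth sigmoid branches with no jump classify as monostable", {
  s <- stimulus_grid(1e-3, 1e3, 20)
  resp <- 1 / (1 + exp(-(log10(s)) / 0.8))
  expect_equal(classify(branch_pair(s, resp, resp))$label, "monostable")
})

test_that("jump detection survives small response noise across many seeds", {
  hits <- 0L
  for (seed in 1:100) {
    syn <- make_synthetic_loop(2, 1, low_level = 0.2, high_level = 0.7,
                               noise_sd = 1e-4, seed = seed)
    res <- classify(syn$pair)
    if (res$label == "bistable" &&
        abs(log10(res$stim_on) - log10(syn$true_stim_on)) < 1e-9 &&
        abs(log10(res$stim_off) - log10(syn$true_stim_off)) < 1e-9) {
      hits <- hits + 1L
    }
  }
  expect_equal(hits, 100L)
})

test_that("discovery finds, verifies and caches bistable minimal points", {
  m <- build_model("MINIMAL")
  # search a neighbourhood of a known bistable island so the unit test stays
  # small; the acceptance script runs the default full-range search
  seedpt <- bistable_minimal_params()
  plan <- sampling_plan(lapply(as.list(seedpt), function(v) c(v / 3, v * 3)),
                        n_samples = 150, seed = 424242)
  cache <- discover_bistable_points(m, seed = 424242, plan = plan)
  expect_s3_class(cache, "bistable_cache")
  expect_gt(nrow(cache), 0)
  expect_true(all(cache$stim_off < cache$stim_on))
  # cached points re-verify as bistable at the discovery density; at doubled
  # density the label survives for the large majority (borderline narrow
  # loops can acquire extra flagged detections on a finer grid)
  k <- min(20, nrow(cache))
  relab <- relab2 <- character(k)
  for (i in seq_len(k)) {
    p <- unlist(cache[i, !(names(cache) %in% c("stim_on", "stim_off"))])
    relab[i] <- classify(sweep_up_down(m, p))$label
    relab2[i] <- classify(sweep_up_down(m, p, points_per_decade = 20))$label
  }
  expect_true(all(relab == "bistable"))
  expect_gte(mean(relab2 == "bistable"), 0.8)
})

test_that("cached bistable points are locally robust to small perturbations", {
  m <- build_model("MINIMAL")
  pts <- list(bistable_minimal_params(), bistable_minimal_params_2())
  ok <- vapply(pts, function(p) {
    classify(sweep_up_down(m, p * 1.01))$label == "bistable"
  }, logical(1))
  expect_gte(sum(ok), 1)
})

test_that("restricted ranges cover the cache and honor the x10 margin", {
  m <- build_model("MINIMAL")
  fake <- data.frame(b1 = c(1, 10), b2 = c(0.5, 2), b3 = c(1, 1), b4 = c(2, 3),
                     s1 = c(1, 1), s2 = c(1, 1), s3 = c(1, 1), s4 = c(1, 1),
                     stim_on = c(1, 1), stim_off = c(0.5, 0.5))
  class(fake) <- c("bistable_cache", "data.frame")
  rr <- derive_restricted_ranges(fake)
  expect_equal(rr$b1, c(0.1, 100))
  expect_equal(rr$b2, c(0.05, 20))
  expect_equal(rr$b3, c(0.1, 10))   # single value: one decade each way
  for (p in setdiff(names(fake), c("stim_on", "stim_off"))) {
    expect_true(all(fake[[p]] >= rr[[p]][1] & fake[[p]] <= rr[[p]][2]))
  }
  # clipping to the global bounds
  fake$b1 <- c(1e-3, 1e3)
  rr2 <- derive_restricted_ranges(fake)
  expect_equal(rr2$b1, c(1e-3, 1e3))
  empty <- fake[0, ]
  class(empty) <- c("bistable_cache", "data.frame")
  expect_error(derive_restricted_ranges(empty), "empty")
})

test_that("a lifted minimal bistable point stays bistable in the full model", {
  mfull <- build_model("FULL_NONDIM")
  pf <- lift_minimal_to_full(bistable_minimal_params_2())
  expect_length(pf, 21)
  res <- classify(sweep_up_down(mfull, pf,
                                stimulus_vector = stimulus_grid(1e-3, 1e2, 10)))
  expect_equal(res$label, "bistable")
  # the loop position survives the lift approximately (same time-free
  # thresholds as the minimal model's sweep)
  rmin <- classify(sweep_up_down(build_model("MINIMAL"),
                                 bistable_minimal_params_2()))
  expect_lt(abs(log10(res$stim_on) - log10(rmin$stim_on)), 0.5)
})
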