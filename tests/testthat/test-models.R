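# Model construction, structural counts, mass-action right-hand sides, and
# the dimensional/nondimensional correspondence.

test_that("structural counts match the compartmentalized model family", {
  full <- build_model("FULL_DIM")
  sc <- structural_counts(full)
  expect_equal(sc$species, 12)
  expect_equal(unname(sc$parameters["biochemical"]), 12)
  expect_equal(unname(sc$parameters["shuttling"]), 8)
  expect_equal(unname(sc$parameters["concentration"]), 3)
  expect_equal(sc$parameters_total, 23)
  expect_equal(sc$independent_variables, 12 - qr(full$conservation$matrix)$rank)

  nd <- structural_counts(build_model("FULL_NONDIM"))
  expect_equal(nd$parameters_total, 21)
  expect_equal(nd$independent_variables, 8)

  mn <- structural_counts(build_model("MINIMAL"))
  expect_equal(mn$independent_variables, 5)
  expect_equal(mn$parameters_total, 8)

  # MODEL_B is the full network minus the cytosolic phosphatase
  b <- build_model("MODEL_B")
  expect_setequal(setdiff(build_model("FULL_NONDIM")$species$name,
                          b$species$name), c("Fc", "Yc"))
  full_rates <- vapply(build_model("FULL_NONDIM")$reactions, `[[`, "", "rate")
  b_rates <- vapply(b$reactions, `[[`, "", "rate")
  expect_true(all(b_rates %in% full_rates))
  expect_setequal(setdiff(full_rates, b_rates), c("b9", "b10", "b11"))

  expect_error(build_model("NOPE"), "valid names")
})

test_that("every rate symbol appears in exactly one reaction", {
  for (nm in model_names()) {
    m <- build_model(nm)
    rates <- vapply(m$reactions, `[[`, "", "rate")
    free <- rates[rates != "one"]
    expect_equal(anyDuplicated(free), 0L, info = nm)
    # free reaction rates are declared parameters
    expect_true(all(free %in% m$parameters$symbol), info = nm)
  }
})

test_that("rhs vanishes at the origin and respects conservation laws", {
  for (nm in c("FULL_DIM", "MINIMAL", "MODEL_C")) {
    m <- build_model(nm)
    p <- random_params(m, seed = 11)
    zero <- setNames(numeric(nrow(m$species)), m$species$name)
    expect_equal(unname(rhs(m, p, 0, zero)), numeric(nrow(m$species)), info = nm)
    set.seed(2)
    st <- setNames(runif(nrow(m$species)), m$species$name)
    d <- rhs(m, p, 1, st)
    expect_equal(unname(m$conservation$matrix %*% d),
                 matrix(0, nrow(m$conservation$matrix)),
                 tolerance = 1e-12, info = nm)
  }
  m <- build_model("MINIMAL")
  p <- random_params(m, seed = 3)
  st <- setNames(runif(7), m$species$name); st[2] <- -1e-3
  expect_error(rhs(m, p, 1, st), "negative")
})

test_that("full-model rhs agrees with the printed equations written out independently", {
  # independent oracle: the twelve dimensional rate equations coded verbatim,
  # term by term
  oracle <- function(k, x) {
    with(as.list(c(k, x)), c(
      E = (koffE + kcatE) * X - konE * E * S - koutE * E + kinE * Ec,
      X = -(koffE + kcatE) * X + konE * E * S - koutX * X + kinX * Xc,
      S = koffE * X - konE * E * S + kcatF * Y - koutS * S + kinS * Sc,
      Sp = kcatE * X - konF * Sp * F + koffF * Y - koutSp * Sp + kinSp * Spc,
      F = -konF * Sp * F + koffF * Y + kcatF * Y,
      Y = konF * Sp * F - koffF * Y - kcatF * Y,
      Ec = (koffEc + kcatEc) * Xc - konEc * Ec * Sc + koutE * E - kinE * Ec,
      Xc = -(koffEc + kcatEc) * Xc + konEc * Ec * Sc + koutX * X - kinX * Xc,
      Sc = koffEc * Xc - konEc * Ec * Sc + kcatFc * Yc + koutS * S - kinS * Sc,
      Spc = kcatEc * Xc - konFc * Spc * Fc + koffFc * Yc + koutSp * Sp - kinSp * Spc,
      Fc = -konFc * Spc * Fc + koffFc * Yc + kcatFc * Yc,
      Yc = konFc * Spc * Fc - koffFc * Yc - kcatFc * Yc))
  }
  m <- build_model("FULL_DIM")
  for (seed in 1:5) {
    p <- random_params(m, seed = seed)
    set.seed(seed + 100)
    x <- setNames(runif(12, 0, 2), m$species$name)
    expect_equal(rhs(m, p, 1, x), oracle(p, x), tolerance = 1e-12)
  }
})

test_that("nondimensionalization yields 21 parameters and preserves dynamics", {
  m <- build_model("FULL_DIM")
  p <- random_params(m, seed = 21, lo = 0.1, hi = 10)
  p <- c(p, E_tot = 0.7)
  nd <- nondimensionalize(p)
  expect_length(nd$params, 21)
  expect_equal(nd$c1, unname(p["E_tot"] / p["S_tot"]))

  # self-scaling: all rates equal to kcatF and all totals equal to S_tot
  ps <- p; ps[1:20] <- 1; ps[c("S_tot", "F_tot", "Fc_tot", "E_tot")] <- 2
  nds <- nondimensionalize(ps)
  bi <- c("b1", "b4", "b6", "b9")        # bimolecular: k * S_tot / kcatF = 2
  expect_equal(unname(nds$params[bi]), rep(2, 4))
  expect_equal(unname(nds$params[setdiff(paste0("b", 1:11), bi)]), rep(1, 7))
  expect_equal(unname(nds$params[c("f1", "f2")]), c(1, 1))
  expect_equal(nds$c1, 1)

  # scaling invariance: doubling S_tot and halving all bimolecular on-rates
  p2 <- p
  p2["S_tot"] <- 2 * p["S_tot"]
  for (k in c("konE", "konF", "konEc", "konFc")) p2[k] <- p[k] / 2
  for (k in c("F_tot", "Fc_tot", "E_tot")) p2[k] <- 2 * p[k]
  expect_equal(nondimensionalize(p2)$params, nd$params, tolerance = 1e-12)

  expect_error(nondimensionalize(p[-1]), "missing")
  pneg <- p; pneg["konE"] <- -1
  expect_error(nondimensionalize(pneg), "positive")
})

test_that("dimensional and nondimensional trajectories match after rescaling", {
  m_dim <- build_model("FULL_DIM")
  m_nd <- build_model("FULL_NONDIM")
  p <- random_params(m_dim, seed = 5, lo = 0.2, hi = 5)
  p <- c(p, E_tot = 0.4 * p[["S_tot"]])
  nd <- nondimensionalize(p)

  pd <- p[setdiff(names(p), "E_tot")]
  f_dim <- function(t, y, parms) list(unname(rhs(m_dim, pd, p[["E_tot"]], pmax(y, 0))))
  f_nd <- function(t, y, parms) list(unname(rhs(m_nd, nd$params, nd$c1, pmax(y, 0))))
  x0_dim <- initial_state(m_dim, as.list(p), p[["E_tot"]])
  x0_nd <- initial_state(m_nd, as.list(nd$params), nd$c1)
  taus <- seq(0, 5, by = 1)
  kcatF <- p[["kcatF"]]; S_tot <- p[["S_tot"]]
  sol_dim <- deSolve::lsoda(unname(x0_dim), taus / kcatF, f_dim, NULL,
                            rtol = 1e-10, atol = 1e-12)
  sol_nd <- deSolve::lsoda(unname(x0_nd), taus, f_nd, NULL,
                           rtol = 1e-10, atol = 1e-12)
  rescaled <- sol_dim[, -1] / S_tot
  expect_lt(max(abs(rescaled - sol_nd[, -1])) / max(abs(sol_nd[, -1])), 1e-6)
})

test_that("trajectories conserve the laws and stay non-negative", {
  for (nm in c("MINIMAL", "FULL_NONDIM")) {
    m <- build_model(nm)
    p <- random_params(m, seed = 8)
    st <- steady_state(m, p, stimulus = 0.5, t_max = 1e4, tolerance = 0)
    tg <- c(0.5, 1, if (nm == "FULL_NONDIM") unname(p[c("f1", "f2")]))
    expect_equal(unname(conservation_values(m, st$state)), tg,
                 tolerance = 1e-6, info = nm)
    expect_true(all(st$state >= 0), info = nm)
  }
})

test_that("reaction list export is one reaction per line", {
  m <- build_model("MINIMAL")
  lines <- export_reaction_list(m)
  expect_length(lines, length(m$reactions))
  expect_true(all(grepl("->.*;", lines)))
  expect_true(any(grepl("S \\+ E -> Sp \\+ E ; b1", lines)))
})

test_that("SBML export is well-formed and complete", {
  m <- build_model("MODEL_B")
  path <- tempfile(fileext = ".xml")
  export_sbml(m, path, params = random_params(m, 1))
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)
  expect_equal(length(xml2::xml_find_all(doc, "//d1:species", ns)),
               nrow(m$species))
  expect_equal(length(xml2::xml_find_all(doc, "//d1:reaction", ns)),
               length(m$reactions))
  expect_equal(length(xml2::xml_find_all(doc, "//d1:compartment", ns)), 2)
  unlink(path)
})
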