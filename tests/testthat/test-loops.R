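# Jacobian injectivity criterion and feedback-loop identification.

test_that("determinant expansion matches numeric determinants at random points", {
  for (nm in c("MINIMAL", "MODEL_C")) {
    m <- build_model(nm)
    J <- compswitch:::substituted_jacobian(m)
    ex <- compswitch:::det_expand(J)
    sp <- m$species$name
    rates <- setdiff(vapply(m$reactions, `[[`, "", "rate"), "one")
    set.seed(17)
    for (rep in 1:5) {
      vals <- setNames(10^runif(length(sp) + length(rates), -1, 1),
                       c(sp, rates))
      # numeric Jacobian of the substituted map, entry by entry
      n <- length(sp)
      Jn <- matrix(0, n, n)
      for (i in 1:n) for (j in 1:n) {
        terms <- compswitch:::collapse_entry(J[[i]][[j]])
        if (is.null(terms)) next
        Jn[i, j] <- sum(vapply(terms, function(t) t$coef * prod(vals[t$vars]),
                               numeric(1)))
      }
      expect_equal(compswitch:::eval_monomials(ex$monomials, vals), det(Jn),
                   tolerance = 1e-8, info = nm)
    }
  }
})

test_that("linear production/decay and the single well-mixed cycle are injective", {
  # one-species production/decay
  sp <- data.frame(name = "Z", compartment = "nucleus")
  net <- reaction_network(
    "DECAY", sp,
    list(list(reactants = character(0), products = "Z", rate = "kprod"),
         list(reactants = "Z", products = character(0), rate = "kdec")),
    list(matrix = matrix(0L, 0, 1, dimnames = list(NULL, "Z")),
         totals = character(0)),
    data.frame(symbol = c("kprod", "kdec"), class = "biochemical"),
    stimulus = "kprod", response = "Z")
  rep1 <- injectivity_analysis(net)
  expect_true(rep1$determinant_sign_uniform)
  expect_equal(rep1$monomials$key, "kdec")

  # the classical single-compartment phosphorylation cycle is monostable
  rep2 <- injectivity_analysis(single_cycle_network())
  expect_true(rep2$determinant_sign_uniform)
  expect_equal(find_feedback_loops(single_cycle_network(), rep2)$n_relevant, 0)
})

test_that("the minimal model has exactly one relevant loop, with translocation", {
  m <- build_model("MINIMAL")
  rep <- injectivity_analysis(m)
  expect_false(rep$determinant_sign_uniform)
  expect_equal(nrow(rep$offending), 1)
  lr <- find_feedback_loops(m, rep)
  expect_equal(lr$n_relevant, 1)
  expect_equal(lr$n_relevant_translocating, 1)
  expect_true(lr$removal_restores_uniformity)
  # the loop couples both compartments through the cytosolic kinase complex
  expect_true("Xc" %in% lr$relevant_loops[[1]]$species)
})

test_that("breaking the cytosolic binding precludes multistationarity", {
  rep <- injectivity_analysis(minimal_without_binding())
  expect_true(rep$determinant_sign_uniform)
  # b2 is among the rates required by every offending term of the intact model
  expect_true("b2" %in% injectivity_analysis(build_model("MINIMAL"))$offending_rates)
})

test_that("deleting any edge of the minimal model's relevant loop restores sign-uniformity", {
  m <- build_model("MINIMAL")
  lr <- find_feedback_loops(m)
  loop <- lr$relevant_loops[[1]]
  spv <- loop$species
  edges <- data.frame(from = spv, to = c(spv[-1], spv[1]), sign = loop$signs,
                      stringsAsFactors = FALSE)
  for (r in seq_len(nrow(edges))) {
    res <- injectivity_after_edge_removal(m, edges[r, , drop = FALSE])
    expect_true(res$determinant_sign_uniform,
                info = paste(edges$from[r], "->", edges$to[r]))
  }
})

test_that("relevant loop counts across the reduction chain", {
  lr_b <- find_feedback_loops(build_model("MODEL_B"))
  expect_equal(lr_b$n_relevant, 5)
  expect_true(lr_b$removal_restores_uniformity)
  lr_c <- find_feedback_loops(build_model("MODEL_C"))
  expect_equal(lr_c$n_relevant, 4)
  lr_m <- find_feedback_loops(build_model("MINIMAL"))
  expect_equal(lr_m$n_relevant, 1)
  # every relevant loop is positive by construction
  for (l in c(lr_b$relevant_loops, lr_c$relevant_loops, lr_m$relevant_loops)) {
    expect_true(prod(ifelse(l$signs == "+", 1, -1)) > 0)
  }
})

test_that("cycle enumeration agrees with a brute-force search on small graphs", {
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(4:6, 1)
    adj <- lapply(1:n, function(i) sort(sample(setdiff(1:n, i),
                                               sample(0:(n - 1), 1))))
    fast <- compswitch:::enumerate_simple_cycles(adj, n)
    slow <- brute_force_cycles(adj, n)
    canon <- function(cyc) {
      k <- which.min(cyc)
      paste(c(cyc[k:length(cyc)], cyc[seq_len(k - 1)]), collapse = ">")
    }
    expect_setequal(vapply(fast, canon, ""), vapply(slow, canon, ""))
  }
})

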