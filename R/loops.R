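# Jacobian injectivity criterion and identification of the positive feedback
# loops relevant for multistationarity.
#
# The positive steady states of a mass-action network solve f(x) = 0 where,
# for each conservation class, one rate equation is replaced by the
# conservation relation. If every monomial of det(J_x(f)) carries the same
# sign, the determinant cannot vanish on the positive orthant, f is injective
# there, and multistationarity is precluded. Monomials of the minority sign
# ("offending terms") encode the structural positive feedback loops through
# which multiple steady states can arise: every determinant monomial comes
# from permutations of the Jacobian, and each permutation factors into cycles
# of the species influence graph.

#' Jacobian injectivity analysis of a mass-action network
#'
#' Builds the steady-state map of the network (conservation laws substituted
#' for the rate equation of the first species of each conservation class),
#' expands the determinant of its Jacobian exactly as a polynomial in the
#' rate constants and species concentrations, and classifies the sign of
#' every surviving monomial. A sign-uniform determinant proves injectivity on
#' the positive orthant, hence monostationarity for every choice of rate
#' constants; otherwise the rate constants occurring in every offending
#' monomial give necessary conditions for multistationarity (setting any of
#' them to zero restores a sign-uniform determinant).
#'
#' @param model a `reaction_network`.
#' @param term_cap cap on the number of expansion terms; exceeding it yields
#'   a truncated (partial) report with `truncated = TRUE`.
#' @return an `injectivity_report`: `determinant_sign_uniform`,
#'   `dominant_sign`, `monomials` (surviving monomials with net
#'   coefficients), `offending` (minority-sign monomials), `offending_rates`
#'   (rate constants present in every offending monomial),
#'   `necessary_conditions` (human-readable), `truncated`, plus internal
#'   expansion data used by [find_feedback_loops()].
#' @export
injectivity_analysis <- function(model, term_cap = 5e6) {
  stopifnot(inherits(model, "reaction_network"))
  J <- substituted_jacobian(model)
  ex <- det_expand(J, term_cap)
  mono <- ex$monomials
  if (nrow(mono) == 0) stop("determinant is identically zero; check the conservation laws")
  pos <- sum(mono$coef > 0); neg <- sum(mono$coef < 0)
  dominant <- if (pos >= neg) 1 else -1
  offending <- mono[sign(mono$coef) != dominant, , drop = FALSE]
  rate_syms <- setdiff(vapply(model$reactions, function(r) r$rate, character(1)), "one")
  off_rates <- if (nrow(offending) > 0) {
    Reduce(intersect, lapply(offending$key, function(k) {
      intersect(unique(strsplit(k, "*", fixed = TRUE)[[1]]), rate_syms)
    }))
  } else character(0)
  conditions <- if (nrow(offending) == 0) {
    "determinant sign-uniform: multistationarity precluded for all positive rate constants"
  } else {
    sprintf("multistationarity requires %s > 0 (setting it to 0 removes every offending determinant term)",
            off_rates)
  }
  structure(list(
    model = model$name,
    determinant_sign_uniform = nrow(offending) == 0,
    dominant_sign = dominant,
    monomials = mono,
    offending = offending,
    offending_rates = off_rates,
    necessary_conditions = conditions,
    truncated = ex$truncated,
    .expansion = ex, .jacobian = J,
    .species = model$species), class = "injectivity_report")
}

#' @export
print.injectivity_report <- function(x, ...) {
  cat("<injectivity_report> ", x$model, "\n", sep = "")
  cat("  surviving monomials: ", nrow(x$monomials),
      "  offending: ", nrow(x$offending), "\n", sep = "")
  cat("  sign-uniform: ", x$determinant_sign_uniform,
      if (x$truncated) "  [TRUNCATED]" else "", "\n", sep = "")
  for (s in x$necessary_conditions) cat("  - ", s, "\n", sep = "")
  invisible(x)
}

# influence loop in influence direction from one cycle of a determinant
# permutation; sign_string holds the sign of the chosen Jacobian term per row
loop_from_sigma_cycle <- function(cyc, sign_chars) {
  nodes <- rev(cyc)
  k <- length(nodes)
  nxt <- c(nodes[-1], nodes[1])
  signs <- sign_chars[nxt]           # edge nodes[p] -> nodes[p+1] sits in row nodes[p+1]
  cc <- canonical_cycle(nodes, signs)
  cc
}

enumerate_simple_cycles <- function(adj, n) {
  cycles <- list()
  for (root in seq_len(n)) {
    path <- integer(0)
    onpath <- logical(n)
    dfs <- function(v) {
      path[length(path) + 1L] <<- v
      onpath[v] <<- TRUE
      for (w in adj[[v]]) {
        if (w < root) next
        if (w == root && length(path) >= 2) {
          cycles[[length(cycles) + 1L]] <<- path
        } else if (!onpath[w]) {
          dfs(w)
        }
      }
      onpath[v] <<- FALSE
      path <<- path[-length(path)]
    }
    dfs(root)
  }
  cycles
}

#' Positive feedback loops and their relevance for bistability
#'
#' Enumerates the simple cycles of the species influence graph of the
#' substituted steady-state map (an edge `j -> i` with the sign of
#' `d f_i / d x_j`; entries of mixed sign contribute one edge per sign) and
#' reports the positive loops (edge-sign product +). The loops *relevant* for
#' bistability are the positive cycles occurring in the permutation
#' decomposition of at least one offending determinant monomial; removing all
#' of them jointly (deleting their signed edges from the Jacobian) must
#' restore a sign-uniform determinant, which is verified and reported.
#'
#' @param model a `reaction_network`.
#' @param report optional precomputed [injectivity_analysis()] result.
#' @return a `loop_report`: `positive_loops` and `relevant_loops` (lists with
#'   `species`, `signs`, `translocation`), `n_relevant`,
#'   `n_relevant_translocating`, `removal_restores_uniformity`.
#' @export
find_feedback_loops <- function(model, report = NULL) {
  if (is.null(report)) report <- injectivity_analysis(model)
  sp <- model$species$name
  comp <- model$species$compartment
  J <- report$.jacobian
  n <- length(sp)

  # signed influence edges of the substituted system
  edges <- list()
  adj <- lapply(seq_len(n), function(i) integer(0))
  esigns <- new.env(parent = emptyenv())
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    terms <- collapse_entry(J[[i]][[j]])
    if (is.null(terms)) next
    sgns <- unique(ifelse(vapply(terms, function(t) t$coef, numeric(1)) > 0, "+", "-"))
    adj[[j]] <- c(adj[[j]], i)
    assign(paste0(j, ">", i), sgns, envir = esigns)
  }

  cyc_nodes <- enumerate_simple_cycles(adj, n)
  positive <- list()
  for (nodes in cyc_nodes) {
    k <- length(nodes)
    nxt <- c(nodes[-1], nodes[1])
    opts <- lapply(seq_len(k), function(p) {
      get(paste0(nodes[p], ">", nxt[p]), envir = esigns)
    })
    combos <- expand.grid(opts, stringsAsFactors = FALSE)
    for (r in seq_len(nrow(combos))) {
      sgn <- unlist(combos[r, ], use.names = FALSE)
      if (prod(ifelse(sgn == "+", 1, -1)) > 0) {
        cc <- canonical_cycle(nodes, sgn)
        positive[[cycle_id(cc$nodes, cc$signs)]] <- cc
      }
    }
  }

  # Relevant loops: a positive cycle is implicated when it is the sole
  # positive cycle of a permutation contributing (with the surviving sign) to
  # an offending determinant monomial — the cycle the sign flip of that term
  # is attributable to. Positive cycles that only ever co-occur with other
  # positive cycles are passengers and are not reported.
  relevant <- list()
  if (nrow(report$offending) > 0) {
    leaves <- report$.expansion$leaves
    net <- setNames(report$offending$coef, report$offending$key)
    sel <- leaves$key %in% names(net) &
      sign(leaves$coef) == sign(net[leaves$key])
    sub <- leaves[sel, , drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      sigma <- report$.expansion$sigmas[[sub$sigma_id[r]]]
      sign_chars <- strsplit(sub$signs[r], "")[[1]]
      ccs <- lapply(permutation_cycles(sigma), loop_from_sigma_cycle,
                    sign_chars = sign_chars)
      pos_cc <- Filter(function(cc) prod(ifelse(cc$signs == "+", 1, -1)) > 0, ccs)
      if (length(pos_cc) != 1) next
      cc <- pos_cc[[1]]
      relevant[[cycle_id(cc$nodes, cc$signs)]] <- cc
    }
  }

  describe <- function(cc) {
    list(species = sp[cc$nodes], signs = cc$signs,
         translocation = any(comp[cc$nodes] != comp[c(cc$nodes[-1], cc$nodes[1])]))
  }
  pos_out <- lapply(positive, describe)
  rel_out <- lapply(relevant, describe)

  # joint-removal check: breaking every relevant loop (removing the reactions
  # behind its mass-action edges; conservation-law edges are removed
  # entry-wise) must leave a sign-uniform determinant
  removal_ok <- NA
  if (length(relevant) > 0) {
    edges <- do.call(rbind, lapply(relevant, function(cc) {
      nodes <- cc$nodes
      data.frame(from = sp[nodes], to = sp[c(nodes[-1], nodes[1])],
                 sign = cc$signs, stringsAsFactors = FALSE)
    }))
    res <- injectivity_after_edge_removal(model, edges)
    removal_ok <- res$determinant_sign_uniform
  }

  structure(list(model = model$name,
                 positive_loops = pos_out,
                 relevant_loops = rel_out,
                 n_positive = length(pos_out),
                 n_relevant = length(rel_out),
                 n_relevant_translocating =
                   sum(vapply(rel_out, function(l) l$translocation, logical(1))),
                 removal_restores_uniformity = removal_ok),
            class = "loop_report")
}

#' @export
print.loop_report <- function(x, ...) {
  cat("<loop_report> ", x$model, "\n", sep = "")
  cat("  positive loops: ", x$n_positive,
      "   relevant for bistability: ", x$n_relevant,
      " (", x$n_relevant_translocating, " with translocation)\n", sep = "")
  for (l in x$relevant_loops) {
    cat("  [", paste(l$species, collapse = " -> "), " -> ",
        l$species[1], "]  signs ", paste(l$signs, collapse = ""),
        if (l$translocation) "  (translocation)" else "", "\n", sep = "")
  }
  if (!is.na(x$removal_restores_uniformity)) {
    cat("  removing all relevant loops restores sign-uniformity: ",
        x$removal_restores_uniformity, "\n", sep = "")
  }
  invisible(x)
}

#' Injectivity analysis after breaking influence edges
#'
#' Breaks the given edges of the species influence graph and re-runs the
#' determinant sign classification. A mass-action edge is generated by one or
#' more reactions; breaking it removes those reactions' rate constants from
#' the system everywhere (the structural analogue of setting the rate to
#' zero). An edge contributed by a substituted conservation law carries no
#' rate constant and is removed entry-wise instead.
#'
#' @param model a `reaction_network`.
#' @param edges data.frame with columns `from`, `to` (species names) and
#'   `sign` (`"+"` or `"-"`).
#' @return list with `determinant_sign_uniform`, `n_offending`, `monomials`,
#'   `removed_rates`.
#' @export
injectivity_after_edge_removal <- function(model, edges) {
  J <- substituted_jacobian(model)
  sp <- model$species$name
  rate_syms <- setdiff(vapply(model$reactions, function(r) r$rate, character(1)), "one")
  drop_rates <- character(0)
  for (r in seq_len(nrow(edges))) {
    i <- match(edges$to[r], sp); j <- match(edges$from[r], sp)
    terms <- collapse_entry(J[[i]][[j]])
    if (is.null(terms)) next
    hit <- vapply(terms, function(t) (t$coef > 0) == (edges$sign[r] == "+"),
                  logical(1))
    rates_here <- intersect(unique(unlist(lapply(terms[hit], `[[`, "vars"))),
                            rate_syms)
    if (length(rates_here)) {
      drop_rates <- union(drop_rates, rates_here)
    } else {
      J[[i]][j] <- list(if (any(!hit)) terms[!hit] else NULL)
    }
  }
  if (length(drop_rates)) {
    for (i in seq_along(sp)) for (j in seq_along(sp)) {
      terms <- J[[i]][[j]]
      if (is.null(terms)) next
      keep <- vapply(terms, function(t) !any(t$vars %in% drop_rates), logical(1))
      J[[i]][j] <- list(if (any(keep)) terms[keep] else NULL)
    }
  }
  ex <- det_expand(J)
  mono <- ex$monomials
  uniform <- nrow(mono) == 0 || all(sign(mono$coef) == sign(mono$coef[1]))
  noff <- if (uniform) 0L else min(sum(mono$coef > 0), sum(mono$coef < 0))
  list(determinant_sign_uniform = uniform, n_offending = noff,
       monomials = mono, removed_rates = drop_rates)
}
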