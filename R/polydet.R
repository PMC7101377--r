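# Symbolic machinery for the Jacobian injectivity criterion: polynomial
# Jacobian entries of the steady-state map (conservation laws substituted),
# and an exact determinant expansion that keeps track, for every surviving
# monomial, of the permutations (and hence the cycles of the species
# influence graph) that produced it.
#
# A polynomial is a list of terms; a term is list(coef = numeric,
# vars = character vector of symbols with repeats). Monomial keys join the
# sorted symbols with "*".

term_key <- function(vars) paste(sort(vars), collapse = "*")

# Jacobian of the mass-action rate equations: J[[i]][[j]] is the term list of
# d f_i / d x_j (zero entries are NULL).
symbolic_jacobian_dynamics <- function(model) {
  sp <- model$species$name
  n <- length(sp)
  N <- stoichiometry(model)
  J <- lapply(seq_len(n), function(i) vector("list", n))
  add_term <- function(i, j, coef, vars) {
    J[[i]][[j]] <<- c(J[[i]][[j]], list(list(coef = coef, vars = vars)))
  }
  for (r in seq_along(model$reactions)) {
    rx <- model$reactions[[r]]
    rate_var <- if (rx$rate == "one") character(0) else rx$rate
    idx <- match(rx$reactants, sp)
    if (length(idx) == 0) next
    for (i in which(N[, r] != 0)) {
      if (length(idx) == 1) {
        add_term(i, idx[1], N[i, r], rate_var)
      } else if (idx[1] == idx[2]) {
        add_term(i, idx[1], 2 * N[i, r], c(rate_var, sp[idx[1]]))
      } else {
        add_term(i, idx[1], N[i, r], c(rate_var, sp[idx[2]]))
        add_term(i, idx[2], N[i, r], c(rate_var, sp[idx[1]]))
      }
    }
  }
  J
}

# Replace, for each conservation law, the rate equation of one species by the
# law itself. Determinant sign patterns (and hence the loop decomposition)
# depend on this choice, so it is fixed canonically: the law's free
# (unbound, unmodified) species in the cytosol when the law spans both
# compartments — the inactive pool the sweep also starts from — and the
# enzyme-substrate complex for a single-compartment (phosphatase) law;
# fallback, for custom networks, the last member in species order. The
# substituted map is the one whose injectivity precludes multistationarity;
# its Jacobian rows for replaced species are constant.
substituted_jacobian <- function(model) {
  J <- symbolic_jacobian_dynamics(model)
  sp <- model$species$name
  comp <- model$species$compartment
  L <- model$conservation$matrix
  replaced <- integer(nrow(L))
  used <- integer(0)
  pick_row <- function(members) {
    cand <- c(intersect(c("Ec", "Sc"), members),
              intersect(c("Y", "Yc", "X", "Xc"), members),
              rev(members))
    idx <- match(cand, sp)
    idx <- idx[!idx %in% used]
    if (length(idx) == 0) stop("cannot assign distinct rows to the conservation laws")
    idx[1]
  }
  for (l in seq_len(nrow(L))) {
    row <- pick_row(sp[L[l, ] != 0])
    used <- c(used, row)
    replaced[l] <- row
    J[[row]] <- lapply(seq_along(sp), function(j) {
      if (L[l, j] != 0) list(list(coef = as.numeric(L[l, j]), vars = character(0)))
      else NULL
    })
  }
  attr(J, "replaced_rows") <- replaced
  attr(J, "species") <- sp
  J
}

# merge terms with equal keys inside one entry (also drops exact cancels)
collapse_entry <- function(terms) {
  if (is.null(terms) || length(terms) == 0) return(NULL)
  keys <- vapply(terms, function(t) term_key(t$vars), character(1))
  coefs <- vapply(terms, function(t) t$coef, numeric(1))
  agg <- rowsum(coefs, keys)
  keep <- which(abs(agg[, 1]) > 1e-12)
  if (length(keep) == 0) return(NULL)
  lapply(keep, function(k) {
    key <- rownames(agg)[k]
    vars <- if (nzchar(key)) strsplit(key, "*", fixed = TRUE)[[1]] else character(0)
    list(coef = agg[k, 1], vars = vars)
  })
}

# Exact determinant expansion over permutations with nonzero support.
# Returns per-leaf records (one leaf = one permutation x one choice of term
# per entry): monomial key, coefficient (including permutation parity), the
# permutation id, and the per-row sign string of the chosen terms. Aggregated
# net coefficients decide which monomials survive.
det_expand <- function(J, term_cap = 5e6) {
  n <- length(J)
  rows <- lapply(seq_len(n), function(i) {
    cols <- which(!vapply(J[[i]], is.null, logical(1)))
    list(cols = cols, terms = lapply(cols, function(j) collapse_entry(J[[i]][[j]])))
  })
  acc <- new.env(parent = emptyenv())
  acc$keys <- vector("list", 0); acc$coefs <- vector("list", 0)
  acc$sigma_id <- vector("list", 0); acc$signs <- vector("list", 0)
  acc$sigmas <- list()
  acc$count <- 0
  acc$truncated <- FALSE
  used <- logical(n)
  sigma <- integer(n)

  dfs <- function(row, parity, coefs, vars, signs) {
    if (acc$truncated) return(invisible())
    if (row > n) {
      acc$sigmas[[length(acc$sigmas) + 1L]] <- sigma
      sid <- length(acc$sigmas)
      keys <- vapply(vars, term_key, character(1))
      acc$keys[[sid]] <- keys
      acc$coefs[[sid]] <- parity * coefs
      acc$sigma_id[[sid]] <- rep.int(sid, length(keys))
      acc$signs[[sid]] <- signs
      acc$count <- acc$count + length(keys)
      if (acc$count > term_cap) acc$truncated <- TRUE
      return(invisible())
    }
    r <- rows[[row]]
    for (k in seq_along(r$cols)) {
      c_ <- r$cols[k]
      if (used[c_]) next
      inv <- sum(used[seq_len(n) > c_])   # inversions added by this column
      terms <- r$terms[[k]]
      tc <- vapply(terms, function(t) t$coef, numeric(1))
      tv <- lapply(terms, function(t) t$vars)
      ts <- ifelse(tc > 0, "+", "-")
      nc <- as.vector(outer(coefs, tc))
      nv <- vector("list", length(nc))
      nsg <- character(length(nc))
      m <- length(coefs)
      for (b in seq_along(tc)) {
        for (a in seq_len(m)) {
          nv[[(b - 1L) * m + a]] <- c(vars[[a]], tv[[b]])
          nsg[(b - 1L) * m + a] <- paste0(signs[a], ts[b])
        }
      }
      used[c_] <<- TRUE
      sigma[row] <<- c_
      dfs(row + 1L, parity * (-1)^inv, nc, nv, nsg)
      used[c_] <<- FALSE
    }
    invisible()
  }
  dfs(1L, 1, 1, list(character(0)), "")

  keys <- as.character(unlist(acc$keys, use.names = FALSE))
  coefs <- as.numeric(unlist(acc$coefs, use.names = FALSE))
  sigma_id <- as.integer(unlist(acc$sigma_id, use.names = FALSE))
  signs <- as.character(unlist(acc$signs, use.names = FALSE))
  if (length(keys) == 0) {
    return(list(leaves = data.frame(key = character(0), coef = numeric(0),
                                    sigma_id = integer(0), signs = character(0)),
                sigmas = list(),
                monomials = data.frame(key = character(0), coef = numeric(0)),
                truncated = acc$truncated))
  }
  net <- rowsum(coefs, keys)
  surviving <- data.frame(key = rownames(net), coef = net[, 1],
                          stringsAsFactors = FALSE)
  surviving <- surviving[abs(surviving$coef) > 1e-9, ]
  rownames(surviving) <- NULL
  list(leaves = data.frame(key = keys, coef = coefs, sigma_id = sigma_id,
                           signs = signs, stringsAsFactors = FALSE),
       sigmas = acc$sigmas,
       monomials = surviving,
       truncated = acc$truncated)
}

# numeric evaluation of the surviving monomials at a named value assignment
eval_monomials <- function(monomials, values) {
  if (nrow(monomials) == 0) return(0)
  sum(vapply(seq_len(nrow(monomials)), function(i) {
    key <- monomials$key[i]
    v <- if (nzchar(key)) strsplit(key, "*", fixed = TRUE)[[1]] else character(0)
    monomials$coef[i] * prod(values[v])
  }, numeric(1)))
}

# decompose a permutation into its cycles (length >= 2), returned as integer
# vectors in sigma order i -> sigma(i) -> ...
permutation_cycles <- function(sigma) {
  n <- length(sigma)
  seen <- logical(n)
  out <- list()
  for (s in seq_len(n)) {
    if (seen[s] || sigma[s] == s) { seen[s] <- TRUE; next }
    cyc <- integer(0)
    i <- s
    while (!seen[i]) {
      seen[i] <- TRUE
      cyc <- c(cyc, i)
      i <- sigma[i]
    }
    if (length(cyc) >= 2) out[[length(out) + 1L]] <- cyc
  }
  out
}

canonical_cycle <- function(nodes, signs) {
  k <- which.min(nodes)
  rot <- function(v) if (k > 1) c(v[k:length(v)], v[seq_len(k - 1)]) else v
  list(nodes = rot(nodes), signs = rot(signs))
}

cycle_id <- function(nodes, signs) {
  paste(paste(nodes, collapse = ">"), paste(signs, collapse = ""), sep = "|")
}
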