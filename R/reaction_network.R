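#' Reaction network container
#'
#' A `reaction_network` holds one model variant: species (with compartment
#' tags), mass-action reactions, linear conservation laws, and the parameter
#' list split by class (biochemical, shuttling, concentration). The stimulus
#' is the total amount of kinase (a conserved total, `E_tot` in the
#' dimensional model, `c1` in the dimensionless ones) and the response is the
#' nuclear phosphorylated substrate (`Sp`).
#'
#' @param name model identifier string.
#' @param species data.frame with columns `name` and `compartment`
#'   (`"nucleus"` or `"cytosol"`).
#' @param reactions list of reactions; each a list with `reactants`
#'   (character, length 0-2, repeats allowed), `products` (character), and
#'   `rate` (rate-constant symbol). The symbol `"one"` denotes a rate pinned
#'   to 1 by the choice of time unit and is not a free parameter.
#' @param conservation list with `matrix` (laws x species, integer
#'   coefficients, species order as in `species`) and `totals` (character,
#'   one symbol per law: a concentration parameter, the stimulus symbol, or
#'   `"1"` for the scaled total substrate).
#' @param parameters data.frame with columns `symbol` and `class`
#'   (`"biochemical"`, `"shuttling"`, `"concentration"`).
#' @param stimulus symbol of the input parameter.
#' @param response species name of the observed output.
#'
#' @return an object of class `reaction_network`.
#' @export
reaction_network <- function(name, species, reactions, conservation,
                             parameters, stimulus, response) {
  stopifnot(is.data.frame(species), all(c("name", "compartment") %in% names(species)))
  stopifnot(is.list(reactions), length(reactions) >= 1)
  rate_syms <- vapply(reactions, function(r) r$rate, character(1))
  free_rates <- setdiff(rate_syms, "one")
  if (anyDuplicated(free_rates)) {
    stop("each rate-constant symbol must appear in exactly one reaction")
  }
  sp <- species$name
  for (r in reactions) {
    bad <- setdiff(c(r$reactants, r$products), sp)
    if (length(bad)) stop("unknown species in reaction: ", paste(bad, collapse = ", "))
  }
  L <- conservation$matrix
  stopifnot(is.matrix(L), ncol(L) == length(sp),
            length(conservation$totals) == nrow(L))
  colnames(L) <- sp
  net <- structure(
    list(name = name, species = species, reactions = reactions,
         conservation = list(matrix = L, totals = conservation$totals),
         parameters = parameters, stimulus = stimulus, response = response),
    class = "reaction_network")
  # conservation laws must be in the left null space of the stoichiometry
  N <- stoichiometry(net)
  if (nrow(L) > 0 && max(abs(L %*% N)) != 0) {
    stop("conservation laws are not invariant under the reaction stoichiometry")
  }
  net
}

#' Stoichiometric matrix of a network
#'
#' @param model a `reaction_network`.
#' @return integer matrix, species x reactions.
#' @export
stoichiometry <- function(model) {
  sp <- model$species$name
  N <- matrix(0L, nrow = length(sp), ncol = length(model$reactions),
              dimnames = list(sp, vapply(model$reactions, function(r) r$rate, character(1))))
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    for (s in r$reactants) N[s, j] <- N[s, j] - 1L
    for (s in r$products)  N[s, j] <- N[s, j] + 1L
  }
  N
}

#' Structural counts of a model
#'
#' Species count, number of independent dynamical variables (species minus
#' the rank of the conservation-law matrix), reaction count, and free
#' parameters per class.
#'
#' @param model a `reaction_network`.
#' @return a list with elements `species`, `independent_variables`,
#'   `reactions`, `parameters` (named vector by class) and
#'   `parameters_total`.
#' @export
structural_counts <- function(model) {
  stopifnot(inherits(model, "reaction_network"))
  L <- model$conservation$matrix
  r <- qr(L)$rank
  cls <- table(factor(model$parameters$class,
                      levels = c("biochemical", "shuttling", "concentration")))
  list(species = nrow(model$species),
       independent_variables = nrow(model$species) - r,
       reactions = length(model$reactions),
       parameters = c(cls),
       parameters_total = nrow(model$parameters))
}

#' @export
print.reaction_network <- function(x, ...) {
  sc <- structural_counts(x)
  cat("<reaction_network> ", x$name, "\n", sep = "")
  cat("  species:    ", sc$species, " (", sc$independent_variables,
      " independent)\n", sep = "")
  cat("  reactions:  ", sc$reactions, "\n", sep = "")
  cat("  parameters: ", sc$parameters_total, " (",
      paste(names(sc$parameters), sc$parameters, sep = "=", collapse = ", "),
      ")\n", sep = "")
  cat("  stimulus:   ", x$stimulus, "   response: ", x$response, "\n", sep = "")
  invisible(x)
}

#' Export a network as a plain-text reaction list
#'
#' One reaction per line, `"A + B -> C ; k"`.
#'
#' @param model a `reaction_network`.
#' @param path optional file to write to.
#' @return the lines, invisibly if `path` is given.
#' @export
export_reaction_list <- function(model, path = NULL) {
  fmt <- function(v) if (length(v) == 0) "0" else paste(v, collapse = " + ")
  lines <- vapply(model$reactions, function(r) {
    paste0(fmt(r$reactants), " -> ", fmt(r$products), " ; ", r$rate)
  }, character(1))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Conservation-law values of a state
#'
#' @param model a `reaction_network`.
#' @param state named or ordered numeric state vector.
#' @return numeric vector, one value per law.
#' @export
conservation_values <- function(model, state) {
  drop(model$conservation$matrix %*% as.numeric(state[model$species$name]))
}

# Numeric targets of the conservation laws for given parameters + stimulus.
law_targets <- function(model, params, stimulus) {
  vapply(model$conservation$totals, function(sym) {
    if (sym == "1") return(1)
    if (sym == model$stimulus) return(stimulus)
    unname(params[[sym]])
  }, numeric(1))
}

# resolve rate-constant values (named numeric) for the reactions
rate_values <- function(model, params) {
  syms <- vapply(model$reactions, function(r) r$rate, character(1))
  vals <- vapply(syms, function(s) {
    if (s == "one") 1 else {
      v <- params[[s]]
      if (is.null(v) || is.na(v)) stop("missing parameter value for rate ", s)
      unname(v)
    }
  }, numeric(1))
  names(vals) <- syms
  vals
}

check_params <- function(model, params) {
  need <- model$parameters$symbol
  params <- unlist(params)
  missing <- setdiff(need, names(params))
  if (length(missing)) stop("missing parameters: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(params), need)
  if (length(extra)) stop("unknown parameters: ", paste(extra, collapse = ", "))
  if (any(!is.finite(params)) || any(params <= 0)) {
    stop("all parameter values must be strictly positive and finite")
  }
  params[need]
}

#' Mass-action right-hand side
#'
#' Evaluates the time derivative of every species under mass-action kinetics.
#' The stimulus enters the dynamics only through the conservation laws (it is
#' a conserved total), so it does not appear in the rate evaluation; it is
#' accepted here to keep the calling convention uniform and to support
#' consistency checks.
#'
#' @param model a `reaction_network`.
#' @param params named numeric vector/list of free parameter values.
#' @param stimulus positive scalar, the input (conserved kinase total).
#' @param state numeric state vector (species order of the model), all
#'   entries finite and non-negative.
#' @return named numeric vector of derivatives.
#' @export
rhs <- function(model, params, stimulus, state) {
  stopifnot(inherits(model, "reaction_network"))
  params <- check_params(model, params)
  sp <- model$species$name
  state <- as.numeric(if (!is.null(names(state))) state[sp] else state)
  if (length(state) != length(sp)) stop("state length must match species count")
  if (any(!is.finite(state))) stop("state entries must be finite")
  if (any(state < 0)) stop("negative state entries (integrator failure upstream?)")
  if (!is.finite(stimulus) || stimulus < 0) stop("stimulus must be finite and non-negative")
  k <- rate_values(model, as.list(params))
  flux <- vapply(seq_along(model$reactions), function(j) {
    r <- model$reactions[[j]]
    unname(k[j]) * prod(state[match(r$reactants, sp)])
  }, numeric(1))
  d <- drop(stoichiometry(model) %*% flux)
  names(d) <- sp
  d
}
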