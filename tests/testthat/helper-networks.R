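# Shared fixtures: custom networks, random parameter draws, and small
# numerical utilities used across the test files. Everything is generated in
# code; nothing is read from disk.

# random positive parameter vector for a model, log-uniform in [lo, hi]
random_params <- function(model, seed, lo = 1e-2, hi = 1e2) {
  set.seed(seed)
  syms <- model$parameters$symbol
  setNames(10^runif(length(syms), log10(lo), log10(hi)), syms)
}

# random non-negative state consistent with the conservation laws: start from
# the canonical initial state and mix it by simulating a short time
random_consistent_state <- function(model, params, stimulus, seed) {
  set.seed(seed)
  st <- steady_state(model, params, stimulus, t_max = 10^runif(1, -1, 1),
                     tolerance = 0)
  st$state
}

# single-compartment phosphorylation-dephosphorylation cycle (no shuttling):
# the classical monostable futile cycle
single_cycle_network <- function() {
  sp <- data.frame(name = c("E", "X", "S", "Sp", "F", "Y"),
                   compartment = "nucleus", stringsAsFactors = FALSE)
  reactions <- list(
    list(reactants = c("S", "E"), products = "X", rate = "konE"),
    list(reactants = "X", products = c("S", "E"), rate = "koffE"),
    list(reactants = "X", products = c("Sp", "E"), rate = "kcatE"),
    list(reactants = c("Sp", "F"), products = "Y", rate = "konF"),
    list(reactants = "Y", products = c("Sp", "F"), rate = "koffF"),
    list(reactants = "Y", products = c("S", "F"), rate = "kcatF"))
  L <- matrix(0L, 3, 6, dimnames = list(c("E_law", "S_law", "F_law"), sp$name))
  L[1, c("E", "X")] <- 1L
  L[2, c("S", "Sp", "X", "Y")] <- 1L
  L[3, c("F", "Y")] <- 1L
  reaction_network(
    "CYCLE_1C", sp, reactions,
    list(matrix = L, totals = c("E_tot", "S_tot", "F_tot")),
    data.frame(symbol = c("konE", "koffE", "kcatE", "konF", "koffF", "kcatF",
                          "S_tot", "F_tot"),
               class = c(rep("biochemical", 6), "concentration", "concentration"),
               stringsAsFactors = FALSE),
    stimulus = "E_tot", response = "Sp")
}

# minimal model with the cytosolic binding reaction removed: breaks the
# relevant feedback loop structurally
minimal_without_binding <- function() {
  m <- build_model("MINIMAL")
  keep <- vapply(m$reactions, function(r) r$rate != "b2", logical(1))
  reaction_network(
    "MINIMAL_NO_B2", m$species, m$reactions[keep],
    list(matrix = m$conservation$matrix, totals = m$conservation$totals),
    m$parameters[m$parameters$symbol != "b2", ],
    stimulus = m$stimulus, response = m$response)
}

# a parameter set for which the minimal model is verifiably bistable,
# discovered once by coarse random search and confirmed by a
# two-initial-condition steady-state check in test-synthetic.R
bistable_minimal_params <- function() {
  c(b1 = 384.49312, b2 = 420.25450, b3 = 1.9844099, b4 = 0.17481798,
    s1 = 1.2718237e-03, s2 = 1.5938478e-03, s3 = 1.9867723e-02,
    s4 = 424.77659)
}

# a second verified bistable point (different loop position), used for the
# full-model lift
bistable_minimal_params_2 <- function() {
  c(b1 = 934.29544, b2 = 37.226174, b3 = 1.3506205e-03, b4 = 3.0509730e-02,
    s1 = 74.003544, s2 = 17.972188, s3 = 1.4428994e-03, s4 = 0.58946494)
}

# brute-force enumeration of all simple directed cycles of an adjacency list
# (independent oracle for the package's DFS enumeration)
brute_force_cycles <- function(adj, n) {
  cycles <- list()
  # enumerate all subsets and all cyclic orders
  for (size in 2:n) {
    subsets <- utils::combn(n, size, simplify = FALSE)
    for (ss in subsets) {
      perms <- if (size == 2) list(ss) else {
        # fix the smallest node first, permute the rest
        lapply(permn_small(ss[-1]), function(p) c(ss[1], p))
      }
      for (ord in perms) {
        nxt <- c(ord[-1], ord[1])
        ok <- all(vapply(seq_along(ord), function(i) nxt[i] %in% adj[[ord[i]]],
                         logical(1)))
        if (ok) cycles[[length(cycles) + 1L]] <- ord
      }
    }
  }
  cycles
}

permn_small <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i) {
    lapply(permn_small(v[-i]), function(p) c(v[i], p))
  }))
}
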