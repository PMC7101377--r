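#' Model variants
#'
#' Identifiers accepted by [build_model()]:
#' `"FULL_DIM"` (dimensional two-compartment phosphorylation cycle, 12
#' species), `"FULL_NONDIM"` (its dimensionless form, 21 free parameters),
#' `"MODEL_B"` (cytosolic phosphatase removed), `"MODEL_C"` (nuclear
#' dephosphorylation collapsed to a single step), `"MINIMAL"` (nuclear
#' phosphorylation collapsed to a single step and substrate shuttling made
#' irreversible; 5 independent variables, 8 parameters).
#'
#' @export
model_names <- function() c("FULL_DIM", "FULL_NONDIM", "MODEL_B", "MODEL_C", "MINIMAL")

rxn <- function(reactants, products, rate) {
  list(reactants = reactants, products = products, rate = rate)
}

law_matrix <- function(species, laws) {
  L <- matrix(0L, nrow = length(laws), ncol = length(species),
              dimnames = list(names(laws), species))
  for (i in seq_along(laws)) L[i, laws[[i]]] <- 1L
  L
}

# Fixed species ordering (documented): nuclear E, X, S, Sp, F, Y then the
# cytosolic counterparts. Sp is the phosphorylated substrate (S*).
full_species <- function() {
  data.frame(
    name = c("E", "X", "S", "Sp", "F", "Y", "Ec", "Xc", "Sc", "Spc", "Fc", "Yc"),
    compartment = rep(c("nucleus", "cytosol"), each = 6),
    stringsAsFactors = FALSE)
}

# enzymatic reactions for one compartment; suffix "" (nucleus) or "c"
enzyme_reactions <- function(sfx, rates) {
  s <- function(x) paste0(x, sfx)
  list(
    rxn(c(s("S"), s("E")), s("X"), rates[1]),
    rxn(s("X"), c(s("S"), s("E")), rates[2]),
    rxn(s("X"), c(s("Sp"), s("E")), rates[3]),
    rxn(c(s("Sp"), s("F")), s("Y"), rates[4]),
    rxn(s("Y"), c(s("Sp"), s("F")), rates[5]),
    rxn(s("Y"), c(s("S"), s("F")), rates[6]))
}

shuttle_reactions <- function(rates) {
  # out: nucleus -> cytosol; in: cytosol -> nucleus. Order S, Sp, E, X.
  list(
    rxn("S", "Sc", rates[1]),  rxn("Sc", "S", rates[2]),
    rxn("Sp", "Spc", rates[3]), rxn("Spc", "Sp", rates[4]),
    rxn("E", "Ec", rates[5]),  rxn("Ec", "E", rates[6]),
    rxn("X", "Xc", rates[7]),  rxn("Xc", "X", rates[8]))
}

build_full_dim <- function() {
  sp <- full_species()
  bio <- c("konE", "koffE", "kcatE", "konF", "koffF", "kcatF",
           "konEc", "koffEc", "kcatEc", "konFc", "koffFc", "kcatFc")
  shu <- c("koutS", "kinS", "koutSp", "kinSp", "koutE", "kinE", "koutX", "kinX")
  reactions <- c(enzyme_reactions("", bio[1:6]),
                 enzyme_reactions("c", bio[7:12]),
                 shuttle_reactions(shu))
  laws <- list(E_law = c("E", "X", "Ec", "Xc"),
               S_law = c("S", "Sp", "X", "Y", "Sc", "Spc", "Xc", "Yc"),
               F_law = c("F", "Y"),
               Fc_law = c("Fc", "Yc"))
  pars <- data.frame(
    symbol = c(bio, shu, "S_tot", "F_tot", "Fc_tot"),
    class = c(rep("biochemical", 12), rep("shuttling", 8), rep("concentration", 3)),
    stringsAsFactors = FALSE)
  reaction_network("FULL_DIM", sp, reactions,
                   list(matrix = law_matrix(sp$name, laws),
                        totals = c("E_tot", "S_tot", "F_tot", "Fc_tot")),
                   pars, stimulus = "E_tot", response = "Sp")
}

# Dimensionless parameter naming (fixed, documented):
#   b1..b5  = konE*S_tot, koffE, kcatE, konF*S_tot, koffF   (all / kcatF)
#   (kcatF itself scales time and becomes the pinned rate "one")
#   b6..b11 = konEc*S_tot, koffEc, kcatEc, konFc*S_tot, koffFc, kcatFc (/ kcatF)
#   s1..s8  = shuttling rates / kcatF, species order out/in for S, Sp, E, X
#   f1 = F_tot/S_tot, f2 = Fc_tot/S_tot; stimulus c1 = E_tot/S_tot.
build_full_nondim <- function() {
  sp <- full_species()
  bio <- c("b1", "b2", "b3", "b4", "b5", "one",
           "b6", "b7", "b8", "b9", "b10", "b11")
  shu <- paste0("s", 1:8)
  reactions <- c(enzyme_reactions("", bio[1:6]),
                 enzyme_reactions("c", bio[7:12]),
                 shuttle_reactions(shu))
  laws <- list(E_law = c("E", "X", "Ec", "Xc"),
               S_law = c("S", "Sp", "X", "Y", "Sc", "Spc", "Xc", "Yc"),
               F_law = c("F", "Y"),
               Fc_law = c("Fc", "Yc"))
  pars <- data.frame(
    symbol = c(paste0("b", 1:11), shu, "f1", "f2"),
    class = c(rep("biochemical", 11), rep("shuttling", 8), rep("concentration", 2)),
    stringsAsFactors = FALSE)
  reaction_network("FULL_NONDIM", sp, reactions,
                   list(matrix = law_matrix(sp$name, laws),
                        totals = c("c1", "1", "f1", "f2")),
                   pars, stimulus = "c1", response = "Sp")
}

build_model_b <- function() {
  sp <- full_species()
  sp <- sp[!sp$name %in% c("Fc", "Yc"), ]
  bio <- c("b1", "b2", "b3", "b4", "b5", "one", "b6", "b7", "b8")
  shu <- paste0("s", 1:8)
  reactions <- c(enzyme_reactions("", bio[1:6]),
                 enzyme_reactions("c", bio[7:9])[1:3],
                 shuttle_reactions(shu))
  # enzyme_reactions("c", ...) above needs only the kinase triple
  laws <- list(E_law = c("E", "X", "Ec", "Xc"),
               S_law = c("S", "Sp", "X", "Y", "Sc", "Spc", "Xc"),
               F_law = c("F", "Y"))
  pars <- data.frame(
    symbol = c(paste0("b", 1:8), shu, "f1"),
    class = c(rep("biochemical", 8), rep("shuttling", 8), "concentration"),
    stringsAsFactors = FALSE)
  reaction_network("MODEL_B", sp, reactions,
                   list(matrix = law_matrix(sp$name, laws),
                        totals = c("c1", "1", "f1")),
                   pars, stimulus = "c1", response = "Sp")
}

build_model_c <- function() {
  sp <- full_species()
  sp <- sp[!sp$name %in% c("Fc", "Yc", "Y"), ]
  reactions <- c(
    enzyme_reactions("", c("b1", "b2", "b3", NA, NA, NA))[1:3],
    list(rxn(c("Sp", "F"), c("S", "F"), "d1")),
    enzyme_reactions("c", c("b6", "b7", "b8", NA, NA, NA))[1:3],
    shuttle_reactions(paste0("s", 1:8)))
  laws <- list(E_law = c("E", "X", "Ec", "Xc"),
               S_law = c("S", "Sp", "X", "Sc", "Spc", "Xc"),
               F_law = "F")
  pars <- data.frame(
    symbol = c("b1", "b2", "b3", "d1", "b6", "b7", "b8", paste0("s", 1:8), "f1"),
    class = c(rep("biochemical", 7), rep("shuttling", 8), "concentration"),
    stringsAsFactors = FALSE)
  reaction_network("MODEL_C", sp, reactions,
                   list(matrix = law_matrix(sp$name, laws),
                        totals = c("c1", "1", "f1")),
                   pars, stimulus = "c1", response = "Sp")
}

# Minimal model: nuclear compartment {S, Sp, E} with single-step
# phosphorylation (b1) and a pseudo-first-order dephosphorylation whose rate
# sets the time unit (pinned "one"); cytosolic compartment {Sc, Spc, Ec, Xc}
# with the full enzymatic phosphorylation (b2 on, b3 off, b4 cat); enzyme
# shuttles reversibly (s1 out, s2 in), substrate shuttling is irreversible
# (s3: S -> Sc, s4: Spc -> Sp). Two conservation laws (substrate = 1,
# enzyme = c1) leave 5 independent variables.
build_minimal <- function() {
  sp <- data.frame(
    name = c("S", "Sp", "E", "Sc", "Spc", "Ec", "Xc"),
    compartment = c(rep("nucleus", 3), rep("cytosol", 4)),
    stringsAsFactors = FALSE)
  reactions <- list(
    rxn(c("S", "E"), c("Sp", "E"), "b1"),
    rxn("Sp", "S", "one"),
    rxn(c("Sc", "Ec"), "Xc", "b2"),
    rxn("Xc", c("Sc", "Ec"), "b3"),
    rxn("Xc", c("Spc", "Ec"), "b4"),
    rxn("E", "Ec", "s1"),
    rxn("Ec", "E", "s2"),
    rxn("S", "Sc", "s3"),
    rxn("Spc", "Sp", "s4"))
  laws <- list(E_law = c("E", "Ec", "Xc"),
               S_law = c("S", "Sp", "Sc", "Spc", "Xc"))
  pars <- data.frame(
    symbol = c(paste0("b", 1:4), paste0("s", 1:4)),
    class = c(rep("biochemical", 4), rep("shuttling", 4)),
    stringsAsFactors = FALSE)
  reaction_network("MINIMAL", sp, reactions,
                   list(matrix = law_matrix(sp$name, laws),
                        totals = c("c1", "1")),
                   pars, stimulus = "c1", response = "Sp")
}

#' Build one of the compartmentalized phosphorylation-cycle models
#'
#' @param name one of [model_names()].
#' @return a [reaction_network()].
#' @examples
#' m <- build_model("MINIMAL")
#' structural_counts(m)
#' @export
build_model <- function(name) {
  switch(name,
         FULL_DIM = build_full_dim(),
         FULL_NONDIM = build_full_nondim(),
         MODEL_B = build_model_b(),
         MODEL_C = build_model_c(),
         MINIMAL = build_minimal(),
         stop("unknown model '", name, "'; valid names: ",
              paste(model_names(), collapse = ", ")))
}

#' Nondimensionalize the dimensional full model
#'
#' Concentrations are scaled by the total substrate `S_tot` and time by
#' `1/kcatF` (the nuclear phosphatase catalytic rate). Bimolecular rates pick
#' up a factor `S_tot`; all rates are divided by `kcatF`. This yields the 21
#' free dimensionless parameters of `FULL_NONDIM` plus the stimulus
#' `c1 = E_tot/S_tot`.
#'
#' @param dimensional_params named vector/list with the 23 control parameters
#'   of `FULL_DIM` plus the stimulus `E_tot`.
#' @return a list with `params` (named numeric, length 21), `c1`, and the
#'   scales used (`conc_scale`, `time_scale`).
#' @export
nondimensionalize <- function(dimensional_params) {
  p <- unlist(dimensional_params)
  need <- c(build_full_dim()$parameters$symbol, "E_tot")
  missing <- setdiff(need, names(p))
  if (length(missing)) stop("missing parameters: ", paste(missing, collapse = ", "))
  if (any(p[need] <= 0) || any(!is.finite(p[need]))) {
    stop("all dimensional parameters must be strictly positive and finite")
  }
  S <- p[["S_tot"]]; kF <- p[["kcatF"]]
  bi <- function(k) p[[k]] * S / kF   # bimolecular on-rates
  un <- function(k) p[[k]] / kF       # unimolecular rates
  params <- c(
    b1 = bi("konE"), b2 = un("koffE"), b3 = un("kcatE"),
    b4 = bi("konF"), b5 = un("koffF"),
    b6 = bi("konEc"), b7 = un("koffEc"), b8 = un("kcatEc"),
    b9 = bi("konFc"), b10 = un("koffFc"), b11 = un("kcatFc"),
    s1 = un("koutS"), s2 = un("kinS"), s3 = un("koutSp"), s4 = un("kinSp"),
    s5 = un("koutE"), s6 = un("kinE"), s7 = un("koutX"), s8 = un("kinX"),
    f1 = p[["F_tot"]] / S, f2 = p[["Fc_tot"]] / S)
  list(params = params, c1 = p[["E_tot"]] / S,
       conc_scale = S, time_scale = 1 / kF)
}

#' Default initial state: all enzymes cytosolic and inactive
#'
#' The sweep's first relaxation starts with every shuttling-capable species in
#' the cytosol and all substrate unphosphorylated: free cytosolic kinase at
#' the stimulus total, free cytosolic substrate at the substrate total,
#' phosphatases free in their home compartments, everything else zero.
#'
#' @param model a `reaction_network`.
#' @param params named parameter values.
#' @param stimulus kinase total.
#' @return named numeric state vector.
#' @export
initial_state <- function(model, params, stimulus) {
  params <- as.list(unlist(params))
  x <- setNames(numeric(nrow(model$species)), model$species$name)
  tgt <- law_targets(model, params, stimulus)
  x["Ec"] <- tgt[[1]]  # kinase law first by construction
  x["Sc"] <- tgt[[2]]
  if ("F" %in% names(x)) x["F"] <- tgt[[3]]
  if ("Fc" %in% names(x)) x["Fc"] <- tgt[[4]]
  x
}
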