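# The 21-species / 21-reaction PINK1-Parkin-NDP52 mitophagy network.
#
# Two coupled feedback loops drive the system:
#   * PINK1/Parkin loop: active PINK1 dimers phosphorylate ubiquitin (r7)
#     and recruited Parkin (r11); phospho-Parkin mobilizes more ubiquitin
#     for phosphorylation (r5).
#   * Atg8/LIR loop: recruited NDP52 activates ULK1 (r14), driving
#     PtdIns(3)P production (r16) and Atg8 lipidation (r18); lipidated Atg8
#     recruits further NDP52 through its LIR motif independently of
#     ubiquitin (r20), closing the loop.

#' Species of the mitophagy network
#'
#' The canonical 21-species inventory: PINK1 monomer and active dimer; free,
#' pS65-Ub-bound and phosphorylated Parkin; the sequestered, available and
#' phosphorylated ubiquitin pools; free NDP52 and its pUb-, Atg8PE- and
#' ternary complexes; inactive/active ULK1; PtdIns and PtdIns(3)P;
#' unconjugated and lipidated Atg8; and three constant inputs (the
#' depolarization stimulus, Atg4 and a generic phosphatase).
#'
#' @return Character vector of length 21.
#' @export
mito_species <- function() {
  c("PINK1", "PINK1d", "Parkin", "Parkin_pUb", "pParkin",
    "Ub_pool", "Ub", "pUb",
    "NDP52", "NDP52_pUb", "NDP52_Atg8PE", "NDP52_pUb_Atg8PE",
    "ULK1i", "ULK1a", "PtdIns", "PtdIns3P", "Atg8", "Atg8PE",
    "Stim", "Atg4", "PPase")
}

.rx <- function(id, role, law, reactants = character(), products = character(),
                enzyme = NULL, basal = NULL, modifier = NULL,
                stoich_reactants = NULL) {
  list(id = id, role = role, law = law,
       reactants = reactants, products = products,
       stoich_reactants = if (is.null(stoich_reactants))
         setNames(rep(1L, length(reactants)), reactants) else stoich_reactants,
       enzyme = enzyme, basal = basal, modifier = modifier)
}

.mito_reactions <- function() {
  list(
    .rx(1L, "PINK1 synthesis (reconstructed housekeeping input)",
        "synthesis", products = "PINK1"),
    .rx(2L, "PINK1 monomer degradation", "first_order", reactants = "PINK1"),
    .rx(3L, "PINK1 dimer degradation (dimer stabilized, slower than r2)",
        "first_order", reactants = "PINK1d"),
    .rx(4L, "depolarization-gated PINK1 dimerization/activation",
        "mass_action", reactants = c("PINK1", "PINK1"), products = "PINK1d",
        modifier = "Stim", stoich_reactants = c(PINK1 = 2L)),
    .rx(5L, "phospho-Parkin promotes ubiquitin availability for PINK1",
        "michaelis_menten", reactants = "Ub_pool", products = "Ub",
        enzyme = "pParkin", basal = "r5_basal"),
    .rx(6L, "reversal of ubiquitin mobilization (opposes r5)",
        "michaelis_menten", reactants = "Ub", products = "Ub_pool",
        enzyme = "PPase"),
    .rx(7L, "PINK1 phosphorylates ubiquitin on Ser65",
        "michaelis_menten", reactants = "Ub", products = "pUb",
        enzyme = "PINK1d"),
    .rx(8L, "pS65-Ub dephosphorylation (opposes r7)",
        "michaelis_menten", reactants = "pUb", products = "Ub",
        enzyme = "PPase"),
    .rx(9L, "Parkin recruitment by pS65-Ub (reconstructed)",
        "mass_action", reactants = c("Parkin", "pUb"),
        products = "Parkin_pUb"),
    .rx(10L, "phospho-Parkin dephosphorylation (opposes r11)",
        "michaelis_menten", reactants = "pParkin", products = "Parkin",
        enzyme = "PPase"),
    .rx(11L, "PINK1 phosphorylates recruited Parkin (releases pS65-Ub)",
        "michaelis_menten", reactants = "Parkin_pUb",
        products = c("pParkin", "pUb"), enzyme = "PINK1d"),
    .rx(12L, "UBD binding of NDP52 to pS65-Ub",
        "mass_action", reactants = c("NDP52", "pUb"), products = "NDP52_pUb"),
    .rx(13L, "LIR binding of ubiquitin-bound NDP52 to Atg8PE",
        "mass_action", reactants = c("NDP52_pUb", "Atg8PE"),
        products = "NDP52_pUb_Atg8PE"),
    .rx(14L, "recruited NDP52 activates ULK1",
        "michaelis_menten", reactants = "ULK1i", products = "ULK1a",
        enzyme = c("NDP52_pUb", "NDP52_pUb_Atg8PE", "NDP52_Atg8PE"),
        basal = "r14_basal"),
    .rx(15L, "ULK1 inactivation (opposes r14)",
        "michaelis_menten", reactants = "ULK1a", products = "ULK1i",
        enzyme = "PPase"),
    .rx(16L, "ULK1-driven PI3K conversion of PtdIns to PtdIns(3)P",
        "michaelis_menten", reactants = "PtdIns", products = "PtdIns3P",
        enzyme = "ULK1a"),
    .rx(17L, "PtdIns(3)P turnover (opposes r16)",
        "michaelis_menten", reactants = "PtdIns3P", products = "PtdIns",
        enzyme = "PPase"),
    .rx(18L, "PtdIns(3)P-licensed Atg8 lipidation",
        "michaelis_menten", reactants = "Atg8", products = "Atg8PE",
        enzyme = "PtdIns3P"),
    .rx(19L, "Atg4-mediated Atg8 deconjugation (opposes r18)",
        "michaelis_menten", reactants = "Atg8PE", products = "Atg8",
        enzyme = "Atg4"),
    .rx(20L, "ubiquitin-independent LIR recruitment of NDP52 by Atg8PE",
        "mass_action", reactants = c("NDP52", "Atg8PE"),
        products = "NDP52_Atg8PE"),
    .rx(21L, "Atg8PE-recruited NDP52 engages pS65-Ub",
        "mass_action", reactants = c("NDP52_Atg8PE", "pUb"),
        products = "NDP52_pUb_Atg8PE")
  )
}

.reaction_param_names <- function(rx) {
  pre <- paste0("r", rx$id, "_")
  switch(rx$law,
    synthesis = paste0(pre, "v"),
    first_order = paste0(pre, "k"),
    mass_action = paste0(pre, c("kon", "koff")),
    michaelis_menten = c(paste0(pre, c("kc", "km")),
                         if (!is.null(rx$basal)) rx$basal)
  )
}

#' Conserved moieties of the mitophagy network
#'
#' Linear combinations of species whose totals are invariant under every
#' reaction (binding, phosphorylation, lipidation and conversion steps only
#' interconvert the members). PINK1 is excluded: it is synthesized and
#' degraded (reactions 1-3).
#'
#' @param net A `mito_network` (used only for species ordering).
#' @return Named list of coefficient vectors over the 21 species.
#' @export
conserved_moieties <- function(net = build_default_network()) {
  sp <- net$species
  vec <- function(members, coef = rep(1, length(members))) {
    v <- setNames(numeric(length(sp)), sp)
    v[members] <- coef
    v
  }
  list(
    NDP52  = vec(c("NDP52", "NDP52_pUb", "NDP52_Atg8PE", "NDP52_pUb_Atg8PE")),
    Parkin = vec(c("Parkin", "Parkin_pUb", "pParkin")),
    Ub     = vec(c("Ub_pool", "Ub", "pUb", "Parkin_pUb", "NDP52_pUb",
                   "NDP52_pUb_Atg8PE")),
    Atg8   = vec(c("Atg8", "Atg8PE", "NDP52_Atg8PE", "NDP52_pUb_Atg8PE")),
    ULK1   = vec(c("ULK1i", "ULK1a")),
    PtdIns = vec(c("PtdIns", "PtdIns3P"))
  )
}

#' Build the wild-type mitophagy network
#'
#' Assembles the 21-state reaction system: species list, reaction
#' specifications (rate-law assignment, substrates/products/enzymes),
#' stoichiometry matrix and conserved moieties. Parameters are validated
#' against the class bounds at construction.
#'
#' @param params Named parameter vector (see [default_parameters()]).
#' @param initial Initial/total concentrations (see
#'   [default_initial_state()]).
#' @param stim_level Stimulus level applied at t = 0 by
#'   [simulate_mitophagy()].
#' @param allow_zero Permit zeroed constants (used internally for variants).
#' @return An object of class `mito_network`.
#' @export
build_default_network <- function(params = default_parameters(),
                                  initial = default_initial_state(),
                                  stim_level = 1,
                                  allow_zero = FALSE) {
  validate_parameters(params, allow_zero = allow_zero)
  reactions <- .mito_reactions()
  ids <- vapply(reactions, `[[`, integer(1), "id")
  if (!identical(sort(ids), 1:21)) stop("reaction ids 1-21 must each be used exactly once")
  species <- mito_species()
  stopifnot(length(species) == 21L)
  if (!identical(sort(names(initial)), sort(species))) {
    stop("initial state must cover exactly the 21 model species")
  }
  needed <- unlist(lapply(reactions, .reaction_param_names))
  missing <- setdiff(needed, names(params))
  if (length(missing)) stop("missing parameters: ", paste(missing, collapse = ", "))

  S <- matrix(0, nrow = length(species), ncol = length(reactions),
              dimnames = list(species, paste0("r", ids)))
  for (rx in reactions) {
    j <- rx$id
    for (sp in names(rx$stoich_reactants)) {
      S[sp, j] <- S[sp, j] - rx$stoich_reactants[[sp]]
    }
    for (sp in rx$products) S[sp, j] <- S[sp, j] + 1
  }

  net <- structure(list(
    species = species,
    reactions = reactions,
    stoichiometry = S,
    params = params,
    initial = initial[species],
    stim_level = stim_level,
    variant = "WT"
  ), class = "mito_network")
  net$moieties <- conserved_moieties(net)
  net
}

#' Reaction rates of the network at a state
#'
#' Net rate (forward minus reverse) of each of the 21 reactions.
#'
#' @param net A `mito_network`.
#' @param x Named species state (nM).
#' @return Named numeric vector of length 21 (nM/s).
#' @export
reaction_rates <- function(net, x) {
  p <- net$params
  v <- numeric(21)
  for (rx in net$reactions) {
    pre <- paste0("r", rx$id, "_")
    rate <- switch(rx$law,
      synthesis = p[[paste0(pre, "v")]],
      first_order = p[[paste0(pre, "k")]] * x[[rx$reactants]],
      mass_action = {
        fwd <- p[[paste0(pre, "kon")]]
        for (sp in names(rx$stoich_reactants)) {
          fwd <- fwd * x[[sp]]^rx$stoich_reactants[[sp]]
        }
        if (!is.null(rx$modifier)) fwd <- fwd * x[[rx$modifier]]
        rev <- p[[paste0(pre, "koff")]]
        for (sp in rx$products) rev <- rev * x[[sp]]
        fwd - rev
      },
      michaelis_menten = {
        e <- sum(vapply(rx$enzyme, function(sp) x[[sp]], numeric(1)))
        if (!is.null(rx$basal)) e <- e + p[[rx$basal]]
        s <- x[[rx$reactants]]
        p[[paste0(pre, "kc")]] * e * s / (p[[paste0(pre, "km")]] + s)
      })
    v[rx$id] <- rate
  }
  setNames(v, paste0("r", 1:21))
}

#' Time derivatives of the species state
#'
#' Evaluates dx/dt = S v(x) for the full 21-state system. Constant input
#' species (Stim, Atg4, PPase) have zero derivative by construction.
#'
#' @param net A `mito_network`.
#' @param x Named species state (nM), non-negative.
#' @param t Time (s); the system is autonomous, `t` is accepted for
#'   integrator compatibility.
#' @return Named derivative vector (nM/s) of length 21.
#' @export
derivatives <- function(net, x, t = 0) {
  if (any(x < 0)) stop("species concentrations must be non-negative")
  drop(net$stoichiometry %*% reaction_rates(net, x))
}

#' Derive a receptor-variant or inhibitor-treated network
#'
#' * `LIR_V136S`: association constants of reactions 13 and 20 set to zero
#'   (the LIR-mutant receptor cannot bind lipidated Atg8).
#' * `UBD_C443K`: association constant of reaction 12 set to zero (no
#'   ubiquitin-dependent recruitment).
#' * `PI3K_INHIBITED`: forward (catalytic) rates of reactions 14-17 set to
#'   zero, including the basal ULK1 activation of reaction 14 (wortmannin
#'   logic: no PtdIns(3)P signalling downstream of receptor recruitment).
#' * `WT`: returns the network unchanged.
#'
#' All other parameters are identical to the input network.
#'
#' @param net A wild-type `mito_network`.
#' @param variant One of `"WT"`, `"LIR_V136S"`, `"UBD_C443K"`,
#'   `"PI3K_INHIBITED"`.
#' @return A `mito_network` with the variant tag and modified parameters.
#' @export
apply_variant <- function(net, variant) {
  stopifnot(inherits(net, "mito_network"))
  if (!identical(net$variant, "WT")) {
    stop("variants are derived from a wild-type network")
  }
  zero <- switch(variant,
    WT = character(),
    LIR_V136S = c("r13_kon", "r20_kon"),
    UBD_C443K = "r12_kon",
    PI3K_INHIBITED = c("r14_kc", "r14_basal", "r15_kc", "r16_kc", "r17_kc"),
    stop("unknown variant tag: ", variant)
  )
  out <- net
  out$params[zero] <- 0
  out$variant <- variant
  out
}

#' @export
print.mito_network <- function(x, ...) {
  cat(sprintf("<mito_network> %s: %d species, %d reactions\n",
              x$variant, length(x$species), length(x$reactions)))
  cat("  moieties:", paste(names(x$moieties), collapse = ", "), "\n")
  invisible(x)
}
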