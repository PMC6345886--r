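# Parameter set for the 21-reaction mitophagy network.
#
# Naming convention: "r<id>_<slot>" where slot is one of
#   kon   association constant of a mass-action step (nM^-1 s^-1)
#   koff  dissociation constant of a mass-action step (s^-1)
#   kc    catalytic constant of an enzymatic step (s^-1)
#   km    Michaelis constant (nM)
#   v     zeroth-order synthesis velocity (nM/s)
#   k     first-order degradation constant (s^-1)
#   basal basal enzyme-equivalent concentration (nM) added to the driving
#         enzyme of an activation step (receptor-independent background
#         activity)

.param_kind <- function(name) sub("^r[0-9]+_", "", name)

#' Biophysical bounds for rate-constant classes
#'
#' Association constants are diffusion-limited (0.1-10 nM^-1 s^-1), Michaelis
#' constants span 1-1000 nM, catalytic constants 1e-4 to 1 s^-1 and synthesis
#' velocities 0.001-10 nM/s. Dissociation/degradation constants and basal
#' activities are only required to be non-negative.
#'
#' @return A named list mapping parameter kind to `c(lower, upper)`.
#' @export
parameter_bounds <- function() {
  list(
    kon   = c(0.1, 10),
    km    = c(1, 1000),
    kc    = c(1e-4, 1),
    v     = c(0.001, 10),
    koff  = c(0, Inf),
    k     = c(0, Inf),
    basal = c(0, Inf)
  )
}

#' Reference parameter set for the wild-type mitophagy network
#'
#' Every constant lies inside the class bounds of [parameter_bounds()]. The
#' set was calibrated (see the package vignette) so that the unstimulated
#' network rests at a low-activity steady state (lipidated Atg8 below 1% of
#' the Atg8 pool) and depolarization triggers the switch-like,
#' feedback-amplified lipidation response.
#'
#' @return Named numeric vector of class `mito_parameters`.
#' @export
default_parameters <- function() {
  p <- c(
    # PINK1 turnover and stimulus-gated dimerization
    r1_v    = 0.01,    # PINK1 synthesis
    r2_k    = 0.001,   # monomer degradation
    r3_k    = 1e-4,    # dimer degradation (stabilized: < r2_k)
    r4_kon  = 0.1,  r4_koff = 0.001,
    # ubiquitin mobilization (pParkin-driven) and its reversal
    r5_kc   = 0.1,  r5_km = 100, r5_basal = 1,
    r6_kc   = 0.001, r6_km = 100,
    # ubiquitin (de)phosphorylation
    r7_kc   = 0.1,  r7_km = 200,
    r8_kc   = 0.002, r8_km = 100,
    # Parkin recruitment and (de)phosphorylation
    r9_kon  = 0.1,  r9_koff = 0.1,
    r10_kc  = 0.001, r10_km = 100,
    r11_kc  = 0.1,  r11_km = 100,
    # NDP52 ubiquitin-dependent recruitment (weak, micromolar-range UBD
    # affinity) and LIR binding of the ubiquitin-bound receptor
    r12_kon = 0.1,  r12_koff = 60,
    r13_kon = 0.1,  r13_koff = 1,
    # ULK1 -> PtdIns(3)P axis
    r14_kc  = 0.04,  r14_km = 500, r14_basal = 0.2,
    r15_kc  = 0.005, r15_km = 50,
    r16_kc  = 0.02,  r16_km = 500,
    r17_kc  = 0.01,  r17_km = 50,
    # Atg8 lipidation / deconjugation
    r18_kc  = 0.03,  r18_km = 300,
    r19_kc  = 0.02,  r19_km = 50,
    # ubiquitin-independent LIR recruitment and subsequent pUb engagement
    r20_kon = 0.1,  r20_koff = 20,
    r21_kon = 0.1,  r21_koff = 1
  )
  structure(p, class = c("mito_parameters", "numeric"))
}

#' Validate a parameter set against the declared bounds
#'
#' @param params Named numeric vector of rate constants.
#' @param allow_zero Permit individual constants to be exactly zero (used by
#'   variant networks that ablate reactions).
#' @return `params`, invisibly, after validation.
#' @export
validate_parameters <- function(params, allow_zero = FALSE) {
  if (is.null(names(params)) || any(!nzchar(names(params)))) {
    stop("parameters must be a fully named numeric vector")
  }
  if (any(!is.finite(params)) || any(params < 0)) {
    stop("parameters must be finite and non-negative")
  }
  bounds <- parameter_bounds()
  for (nm in names(params)) {
    kind <- .param_kind(nm)
    b <- bounds[[kind]]
    if (is.null(b)) stop("unknown parameter kind for '", nm, "'")
    val <- params[[nm]]
    if (allow_zero && val == 0) next
    if (val < b[1] || val > b[2]) {
      stop(sprintf("parameter %s = %g outside its class bounds [%g, %g]",
                   nm, val, b[1], b[2]))
    }
  }
  if (all(c("r3_k", "r2_k") %in% names(params)) &&
      params[["r3_k"]] >= params[["r2_k"]]) {
    stop("PINK1 dimer degradation (reaction 3) must be slower than monomer ",
         "degradation (reaction 2)")
  }
  invisible(params)
}

#' Initial (total) concentrations for the mitophagy model
#'
#' All pools start unbound/unmodified; the constant species Stim (the
#' depolarization switch), Atg4 and PPase hold their configured levels.
#'
#' @param stim Stimulus level placed in the state by the simulation protocol
#'   (0 = unstimulated).
#' @return Named numeric vector over the 21 model species (nM).
#' @export
default_initial_state <- function(stim = 0) {
  x <- setNames(numeric(length(mito_species())), mito_species())
  x["PINK1"]   <- 20
  x["Parkin"]  <- 100
  x["Ub_pool"] <- 150
  x["NDP52"]   <- 100
  x["ULK1i"]   <- 100
  x["PtdIns"]  <- 1000
  x["Atg8"]    <- 300
  x["Stim"]    <- stim
  x["Atg4"]    <- 50
  x["PPase"]   <- 50
  x
}
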