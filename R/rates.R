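#' Mass-action rate law
#'
#' Rate of a bimolecular association, `k_on * a * b`, in nM/s. Protein-protein
#' binding steps in the mitophagy network follow this law.
#'
#' @param k_on Association rate constant (nM^-1 s^-1).
#' @param a,b Reactant concentrations (nM).
#' @return Reaction rate (nM/s), linear in each reactant.
#' @examples
#' mass_action_rate(0.1, 10, 5) # 5 nM/s
#' @export
mass_action_rate <- function(k_on, a, b) {
  if (any(k_on < 0) || any(a < 0) || any(b < 0)) {
    stop("mass_action_rate() requires non-negative arguments")
  }
  k_on * a * b
}

#' Michaelis-Menten rate law
#'
#' Saturating rate `v_max * s / (k_m + s)` used for (de)phosphorylation and
#' other enzymatic conversion steps.
#'
#' @param v_max Maximal velocity (nM/s); for the kc*[E] form pass
#'   `kc * enzyme`.
#' @param k_m Michaelis constant (nM), strictly positive.
#' @param s Substrate concentration (nM).
#' @return Reaction rate (nM/s); saturates at `v_max` for `s >> k_m`.
#' @examples
#' michaelis_menten_rate(10, 100, 900) # 9 nM/s
#' michaelis_menten_rate(2, 50, 50)    # half-saturation: 1 nM/s
#' @export
michaelis_menten_rate <- function(v_max, k_m, s) {
  if (any(k_m <= 0)) stop("michaelis_menten_rate() requires k_m > 0")
  if (any(v_max < 0) || any(s < 0)) {
    stop("michaelis_menten_rate() requires v_max >= 0 and s >= 0")
  }
  v_max * s / (k_m + s)
}
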