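# Shared fixtures, built once per test run.

.fx <- new.env()

fx_network <- function() {
  if (is.null(.fx$net)) .fx$net <- build_default_network()
  .fx$net
}

fx_resting_state <- function() {
  if (is.null(.fx$xeq)) .fx$xeq <- equilibrate(fx_network())
  .fx$xeq
}

fx_wt_sim <- function() {
  if (is.null(.fx$sim)) {
    .fx$sim <- simulate_mitophagy(fx_network(), t_end = 7200, dt = 30,
                                  x0 = fx_resting_state())
  }
  .fx$sim
}

fx_image <- function() {
  if (is.null(.fx$img)) .fx$img <- generate_image_stack(image_scene(), seed = 42)
  .fx$img
}

# random non-negative species states for property-style checks
random_states <- function(n, seed = 7) {
  set.seed(seed)
  sp <- mito_species()
  lapply(seq_len(n), function(i) setNames(runif(length(sp), 0, 200), sp))
}
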