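# Serialization of networks and parameters.

#' Write a network configuration to YAML
#'
#' Serializes species, parameters, initial state, stimulus level and variant
#' tag. Reaction wiring is structural (versioned with the package) and is
#' reconstructed on read, so the round trip is lossless for everything a
#' user can configure.
#'
#' @param net A `mito_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
network_to_yaml <- function(net, path) {
  obj <- list(
    species = net$species,
    variant = net$variant,
    stim_level = net$stim_level,
    params = as.list(net$params),
    initial = as.list(net$initial)
  )
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' Read a network configuration from YAML
#'
#' @param path File written by [network_to_yaml()].
#' @return A `mito_network`.
#' @export
network_from_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  params <- structure(unlist(obj$params), class = c("mito_parameters", "numeric"))
  initial <- unlist(obj$initial)
  net <- build_default_network(params = params, initial = initial,
                               stim_level = obj$stim_level,
                               allow_zero = TRUE)
  net$variant <- obj$variant
  net
}

#' Export the stoichiometry matrix as CSV
#'
#' Species-by-reaction matrix with species names in the first column.
#'
#' @param net A `mito_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stoichiometry_csv <- function(net, path) {
  df <- data.frame(species = rownames(net$stoichiometry),
                   net$stoichiometry, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
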