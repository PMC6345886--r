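# Ratiometric mtKeima cytometry gating: a triangular gate aligned with the
# untreated bulk population, applied to treated samples to read the percent
# of 561 nm-shifted (acidified) cells.

#' Construct a cytometry event table
#'
#' @param data Data frame with per-event intensities: `ex488_em695`
#'   (488 nm-excited, neutral-pH mtKeima), `ex561_em670` (561 nm-excited,
#'   acidic mtKeima), and optionally `gfp` and `irfp670`.
#' @return A `facs_sample` data frame.
#' @export
facs_sample <- function(data) {
  need <- c("ex488_em695", "ex561_em670")
  if (!all(need %in% names(data))) {
    stop("event table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(data$ex488_em695 < 0) || any(data$ex561_em670 < 0)) {
    stop("intensities must be non-negative")
  }
  structure(as.data.frame(data), class = c("facs_sample", "data.frame"))
}

#' Pre-gate events on reporter expression
#'
#' Keeps GFP/Keima double-positive events (and iRFP670 triple-positive when
#' a threshold is supplied and the column exists).
#'
#' @param sample A `facs_sample`.
#' @param gfp_min,keima_min,irfp_min Positivity thresholds; `irfp_min = NULL`
#'   skips the iRFP670 requirement.
#' @return The filtered `facs_sample`.
#' @export
pregate_double_positive <- function(sample, gfp_min = 0, keima_min = 0,
                                    irfp_min = NULL) {
  keep <- sample$ex488_em695 + sample$ex561_em670 > keima_min
  if ("gfp" %in% names(sample)) keep <- keep & sample$gfp > gfp_min
  if (!is.null(irfp_min) && "irfp670" %in% names(sample)) {
    keep <- keep & sample$irfp670 > irfp_min
  }
  out <- sample[keep, , drop = FALSE]
  structure(out, class = c("facs_sample", "data.frame"))
}

.gate_coords <- function(sample) {
  x <- log10(pmax(sample$ex488_em695, 1e-6))
  y <- log10(pmax(sample$ex561_em670, 1e-6))
  cbind(x, y)
}

#' Build the triangular mtKeima gate from an untreated sample
#'
#' Operationalizes the manual gating rule: the gate's long edge is set
#' parallel to the principal axis of the untreated population (log10
#' intensities in the 488-excited x 561-excited plane), then translated
#' along the edge normal - toward the acidified (higher-561 / lower-488)
#' side - by the minimal amount that encloses at least `target_fraction`
#' percent of the untreated events. The enclosing side (and hence the
#' "positive" side, beyond the edge) is recorded in the gate metadata.
#'
#' @param untreated A `facs_sample` of untreated events (>= 100 after any
#'   pre-gating).
#' @param target_fraction Percentage of untreated events to enclose
#'   (default 99.8).
#' @return An `mtkeima_gate`: triangle `vertices` (log10 space), edge
#'   direction, outward normal, offset and construction metadata.
#' @export
build_mtkeima_gate <- function(untreated, target_fraction = 99.8) {
  stopifnot(inherits(untreated, "facs_sample"))
  if (nrow(untreated) < 100) stop("need >= 100 untreated events to build a gate")
  pts <- .gate_coords(untreated)
  if (any(apply(pts, 2, stats::var) < 1e-12)) {
    stop("degenerate untreated cloud: zero variance")
  }
  pc <- prcomp(pts, center = TRUE, scale. = FALSE)
  u <- pc$rotation[, 1]              # edge direction: principal axis
  nrm <- c(-u[2], u[1])              # edge normal
  if (sum(nrm * c(-1, 1)) < 0) nrm <- -nrm  # orient toward high-561/low-488
  centre <- colMeans(pts)
  s <- drop((pts - rep(centre, each = nrow(pts))) %*% nrm)
  t_along <- drop((pts - rep(centre, each = nrow(pts))) %*% u)
  n_ev <- length(s)
  k <- ceiling(target_fraction / 100 * n_ev)
  offset <- sort(s)[k] + 1e-9        # minimal translation enclosing k events
  # Triangle sized to contain every enclosed event comfortably.
  half_edge <- 2 * (max(abs(t_along)) + 1)
  depth <- 10 * (offset - min(s) + 1)
  edge_mid <- centre + offset * nrm
  vertices <- rbind(
    v1 = edge_mid + half_edge * u,
    v2 = edge_mid - half_edge * u,
    v3 = edge_mid - depth * nrm
  )
  colnames(vertices) <- c("log10_ex488", "log10_ex561")
  structure(list(
    vertices = vertices,
    edge_direction = unname(u),
    normal = unname(nrm),
    offset = offset,
    centre = unname(centre),
    target_fraction = target_fraction,
    positive_side = "beyond the long edge along the normal (high 561 / low 488)",
    space = "log10"
  ), class = "mtkeima_gate")
}

.point_in_triangle <- function(pts, v) {
  sign_area <- function(p1, p2, p) {
    (p2[1] - p1[1]) * (p[, 2] - p1[2]) - (p2[2] - p1[2]) * (p[, 1] - p1[1])
  }
  d1 <- sign_area(v[1, ], v[2, ], pts)
  d2 <- sign_area(v[2, ], v[3, ], pts)
  d3 <- sign_area(v[3, ], v[1, ], pts)
  has_neg <- (d1 < 0) | (d2 < 0) | (d3 < 0)
  has_pos <- (d1 > 0) | (d2 > 0) | (d3 > 0)
  !(has_neg & has_pos)
}

#' Test gate membership
#'
#' @param gate An `mtkeima_gate`.
#' @param sample A `facs_sample`.
#' @return Logical vector: event inside the triangular gate.
#' @export
in_gate <- function(gate, sample) {
  pts <- .gate_coords(sample)
  .point_in_triangle(pts, gate$vertices)
}

#' Percentage of mtKeima-positive events
#'
#' Events on the acidified (561-shifted) side of the untreated gate edge,
#' as a percentage of all events in the (pre-gated) sample.
#'
#' @param sample A `facs_sample` (pre-gated as configured; see
#'   [pregate_double_positive()]).
#' @param gate An `mtkeima_gate` built on the matching untreated sample.
#' @return Percentage in `[0, 100]`.
#' @export
percent_positive <- function(sample, gate) {
  if (nrow(sample) == 0) stop("no events after pre-gating")
  pts <- .gate_coords(sample)
  s <- drop((pts - rep(gate$centre, each = nrow(pts))) %*% gate$normal)
  100 * sum(s > gate$offset) / nrow(sample)
}

#' Serialize a gate to JSON
#'
#' @param gate An `mtkeima_gate`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gate_json <- function(gate, path) {
  obj <- unclass(gate)
  obj$vertices <- as.data.frame(obj$vertices)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a gate from JSON
#'
#' @param path File written by [write_gate_json()].
#' @return An `mtkeima_gate`.
#' @export
read_gate_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$vertices <- as.matrix(obj$vertices)
  obj$edge_direction <- as.numeric(obj$edge_direction)
  obj$normal <- as.numeric(obj$normal)
  obj$centre <- as.numeric(obj$centre)
  structure(obj, class = "mtkeima_gate")
}

#' @export
print.mtkeima_gate <- function(x, ...) {
  cat(sprintf("<mtkeima_gate> target %.1f%%, edge offset %.4f (log10 units)\n",
              x$target_fraction, x$offset))
  invisible(x)
}
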