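#' Per-pixel reliability for phase unwrapping
#'
#' Scores every pixel by the inverse root-sum-square of its wrapped
#' second differences taken over the horizontal, vertical and two
#' diagonal neighbour triples; smooth regions score high, noisy pixels
#' and residue neighbourhoods score low.  Vanishing second differences
#' map to the largest finite score (1e12) and the 1-pixel border, where
#' the stencil is undefined, is assigned the lowest score (0) so it is
#' merged last.
#'
#' @param wrapped A wrapped \code{\link{phase_map}}.
#' @return Object of class \code{reliability_map}: list with the
#'   nonnegative \code{values} matrix.
#' @export
reliability_map <- function(wrapped) {
  stopifnot(inherits(wrapped, "phase_map"))
  if (!wrapped$wrapped) stop("reliability_map expects a wrapped phase map")
  if (nrow(wrapped$values) < 3 || ncol(wrapped$values) < 3)
    stop("image must be at least 3x3")
  structure(list(values = .herraez_reliability(wrapped$values)),
            class = "reliability_map")
}

#' Reliability-sorted (Herraez) 2D phase unwrapping
#'
#' Unwraps a wrapped phase field by merging pixels in order of edge
#' reliability rather than along a continuous path: edges of the
#' 4-connected pixel graph are sorted by the summed reliability of their
#' endpoints (descending, stable, ties by row-major edge index) and
#' merged group-wise, adding the integer multiple of 2*pi to the smaller
#' group that brings the two sides within pi of each other across the
#' merged edge.  The output differs from the input by an integer
#' multiple of 2*pi at every pixel, and identical inputs give
#' bit-identical outputs.  The global 2*pi level is not fixed here; the
#' annular background subtraction in the index-mapping stage sets the
#' zero level.
#'
#' @param wrapped A wrapped \code{\link{phase_map}}.
#' @return An unwrapped \code{\link{phase_map}}.
#' @seealso \code{\link{unwrap_path}} for the simple row/column
#'   integration oracle used in validation.
#' @export
unwrap_phase <- function(wrapped) {
  stopifnot(inherits(wrapped, "phase_map"))
  if (!wrapped$wrapped) stop("unwrap_phase expects a wrapped phase map")
  if (nrow(wrapped$values) < 3 || ncol(wrapped$values) < 3)
    stop("image must be at least 3x3")
  phase_map(.herraez_unwrap(wrapped$values), wrapped = FALSE)
}

#' Path-integration unwrapping oracle
#'
#' Reference unwrapper for smooth noiseless fields: integrates wrapped
#' differences down the first column and then along each row.  Exact
#' whenever every neighbouring-pixel phase step of the true field is
#' below pi in magnitude; it has none of the robustness of
#' \code{\link{unwrap_phase}} and exists as an independent check.
#'
#' @param wrapped A wrapped \code{\link{phase_map}}.
#' @return An unwrapped \code{\link{phase_map}} anchored at pixel (1,1).
#' @export
unwrap_path <- function(wrapped) {
  stopifnot(inherits(wrapped, "phase_map"))
  w <- wrapped$values
  nr <- nrow(w); nc <- ncol(w)
  out <- matrix(0, nr, nc)
  out[, 1] <- w[1, 1] + c(0, cumsum(wrap_phase(diff(w[, 1]))))
  if (nc > 1) {
    dw <- wrap_phase(w[, -1, drop = FALSE] - w[, -nc, drop = FALSE])
    out[, -1] <- out[, 1] + t(apply(dw, 1, cumsum))
  }
  phase_map(out, wrapped = FALSE)
}
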