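#' Mapped curves
#'
#' A `mapped_curve` is the spline reconstruction of a transformed curve over
#' the original knot parameters: order 0 gives the first-order (piecewise
#' linear) spline through the mapped knots; order 1 gives, on each segment
#' `[t_i, t_{i+1}]`, the cubic Hermite piece matching the mapped positions
#' at both knots, the mapped right derivative at `t_i` and the mapped left
#' derivative at `t_{i+1}` (four constraints per segment). Position is
#' continuous across knots; first derivatives need not be, mirroring the
#' one-sided derivatives of the source polyline.
#'
#' The original arc-length parameters are kept: the jet action preserves
#' timestamps, so the mapped curve is generally not unit speed.
#'
#' @name mapped_curve
NULL

new_mapped_curve <- function(order, t, p, m_right = NULL, m_left = NULL) {
  structure(list(order = as.integer(order), t = as.double(t), p = as_points(p),
                 m_right = m_right, m_left = m_left),
            class = "mapped_curve")
}

#' @export
print.mapped_curve <- function(x, ...) {
  cat(sprintf("<mapped_curve: order %d, %d knots>\n", x$order, length(x$t)))
  invisible(x)
}

#' Zeroth-order mapping of a branch
#'
#' Transforms only the knot positions and reconnects them with a
#' first-order spline — the mapping performed by standard neuron-mapping
#' pipelines.
#'
#' @param branch a [polyline_branch()].
#' @param transform a `transform`.
#' @return A `mapped_curve` of order 0.
#' @export
map_zeroth <- function(branch, transform) {
  stopifnot(inherits(branch, "polyline_branch"))
  js <- apply_jet_action(jet_extension_from_polyline(branch, 0L), transform)
  new_mapped_curve(0L, js$t, js$x0)
}

#' First-order mapping of a branch
#'
#' Extends the branch to one-sided jets (chord-slope derivatives), pushes
#' positions through the transform and derivatives through its Jacobian,
#' then reconstructs each segment as the cubic Hermite interpolant of the
#' four mapped constraints.
#'
#' @param branch a [polyline_branch()].
#' @param transform a `transform`, `C^1` near the branch.
#' @return A `mapped_curve` of order 1.
#' @export
map_first <- function(branch, transform) {
  stopifnot(inherits(branch, "polyline_branch"))
  js <- apply_jet_action(jet_extension_from_polyline(branch, 1L), transform)
  mapped_curve_from_jets(js)
}

#' Build a mapped curve from an order-1 jet sequence
#'
#' Used both by [map_first()] (one-sided polyline jets) and for analytic
#' jets with two-sided derivatives.
#'
#' @param jets an order-1 (or order-2; second derivatives are ignored)
#'   `jet_sequence`, already transformed.
#' @return A `mapped_curve` of order 1.
#' @export
mapped_curve_from_jets <- function(jets) {
  stopifnot(inherits(jets, "jet_sequence"))
  if (jets$order < 1L) stop("order-1 jets required")
  new_mapped_curve(1L, jets$t, jets$x0,
                   m_right = jets$d_right, m_left = jets$d_left)
}

#' Evaluate a mapped curve at parameters
#'
#' @param curve a `mapped_curve`.
#' @param t numeric vector of parameters within the knot range.
#' @return `length(t) x 3` matrix of positions.
#' @export
eval_mapped_curve <- function(curve, t) {
  tk <- curve$t
  n <- length(tk)
  i <- findInterval(t, tk, rightmost.closed = TRUE)
  i[i < 1L] <- 1L
  i[i >= n] <- n - 1L
  h <- tk[i + 1L] - tk[i]
  s <- (t - tk[i]) / h
  p0 <- curve$p[i, , drop = FALSE]
  p1 <- curve$p[i + 1L, , drop = FALSE]
  if (curve$order == 0L) {
    p0 * (1 - s) + p1 * s
  } else {
    m0 <- curve$m_right[i, , drop = FALSE]
    m1 <- curve$m_left[i + 1L, , drop = FALSE]
    h00 <- (1 + 2 * s) * (1 - s)^2
    h10 <- s * (1 - s)^2
    h01 <- s^2 * (3 - 2 * s)
    h11 <- s^2 * (s - 1)
    p0 * h00 + m0 * (h10 * h) + p1 * h01 + m1 * (h11 * h)
  }
}

#' Sample a mapped curve at a given spacing
#'
#' Evaluates the spline on a parameter grid with steps of at most `spacing`
#' in the original arc-length parameter (each segment subdivided into equal
#' steps; knot parameters always included).
#'
#' @param curve a `mapped_curve`.
#' @param spacing maximum parameter step, microns (default 2).
#' @return A [polyline_branch()] through the sampled points, with attribute
#'   `"source_params"` holding the originating parameters (aligned with the
#'   branch knots; exact duplicates produced by a collapsing map are
#'   dropped from both).
#' @export
sample_curve <- function(curve, spacing = 2) {
  tq <- sampling_params(curve$t, spacing)
  pts <- eval_mapped_curve(curve, tq)
  points_to_branch(pts, tq)
}

# shared by sample_curve and map_dense_reference: branch + aligned source params
points_to_branch <- function(pts, tq) {
  br <- suppressWarnings(arc_length_parameterize(pts))
  attr(br, "source_params") <- tq[attr(br, "kept")]
  br
}

#' Densely mapped ground-truth reference of a branch
#'
#' Resamples the piecewise linear branch at arc-length intervals of at most
#' `spacing` (original knots always retained), maps every point through the
#' transform, and returns the dense mapped polyline. This is the
#' experiment's ground truth: the continuous mapping of the piecewise
#' linear trace, up to the sampling density.
#'
#' @param branch a [polyline_branch()].
#' @param transform a `transform`.
#' @param spacing maximum arc-length interval, microns (default 2).
#' @return A [polyline_branch()] of mapped dense samples with attribute
#'   `"source_params"` (original arc-length parameters).
#' @export
map_dense_reference <- function(branch, transform, spacing = 2) {
  stopifnot(inherits(branch, "polyline_branch"))
  tq <- sampling_params(branch$params, spacing)
  pts <- tf_evaluate(transform, polyline_point(branch, tq))
  points_to_branch(as_points(pts), tq)
}

#' Observed mapping error against the dense reference
#'
#' Maximum distance between the mapped spline and the true transformed
#' piecewise-linear curve, both evaluated on the shared parameter grid with
#' steps of at most `spacing` — the parameter-matched deviation
#' `max_t |f(t) - g(t)|` that the error bounds control.
#'
#' @param branch a [polyline_branch()].
#' @param transform a `transform`.
#' @param order mapping order, 0 or 1.
#' @param spacing evaluation grid step, microns (default 2).
#' @return Scalar maximum deviation, microns.
#' @export
mapping_error <- function(branch, transform, order = 0L, spacing = 2) {
  curve <- if (order == 0L) map_zeroth(branch, transform)
           else map_first(branch, transform)
  tq <- sampling_params(branch$params, spacing)
  truth <- as_points(tf_evaluate(transform, polyline_point(branch, tq)))
  approxed <- eval_mapped_curve(curve, tq)
  max(row_norms(truth - approxed))
}
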