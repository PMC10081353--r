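#' Discrete Frechet distance between two polylines
#'
#' The minimax distance over monotone couplings of the two knot sequences,
#' computed by the standard dynamic program over the coupling lattice. It
#' is symmetric, zero iff the sequences match pointwise under the trivial
#' coupling, and an upper bound to the continuous Frechet distance.
#'
#' @param p,q [polyline_branch()] objects or `n x 3` point matrices with at
#'   least one point each.
#' @param return_coupling logical; also return one optimal coupling as a
#'   two-column matrix of (index in p, index in q) pairs.
#' @return A list of class `frechet_result` with `distance` (microns) and,
#'   if requested, `coupling`.
#' @export
discrete_frechet <- function(p, q, return_coupling = FALSE) {
  P <- frechet_points(p)
  Q <- frechet_points(q)
  res <- frechet_dp(P, Q, isTRUE(return_coupling))
  structure(res, class = "frechet_result")
}

frechet_points <- function(x) {
  if (inherits(x, "polyline_branch")) x <- x$knots
  if (!is.matrix(x)) x <- as_points(x)
  if (nrow(x) < 1L) stop("curve must have at least one knot")
  storage.mode(x) <- "double"
  x
}

#' @export
print.frechet_result <- function(x, ...) {
  cat(sprintf("<frechet_result: %.6g um>\n", x$distance))
  invisible(x)
}
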