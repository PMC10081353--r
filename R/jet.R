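#' Jet sequences
#'
#' A `jet_sequence` holds time-stamped jet samples of a curve: arc-length
#' parameters `t`, positions `x0`, and (for order >= 1) first derivatives.
#' Because the source curves are piecewise linear, derivatives at interior
#' knots are one-sided: `d_right` is the derivative into the segment that
#' starts at the knot, `d_left` the derivative out of the segment that ends
#' there. A smooth (analytic) source gives two-sided jets where both agree,
#' and may also carry second derivatives `x2` for order 2.
#'
#' @param order jet order k in 0, 1, 2.
#' @param t numeric vector of non-decreasing parameters, microns.
#' @param x0 `n x 3` matrix of positions.
#' @param d_right,d_left `n x 3` matrices of one-sided first derivatives
#'   (row `n` of `d_right` and row 1 of `d_left` are `NA`: endpoints carry a
#'   single one-sided derivative). Required for order >= 1.
#' @param x2 optional `n x 3` matrix of second derivatives (order 2,
#'   two-sided analytic sources only).
#' @return An object of class `jet_sequence`.
#' @export
jet_sequence <- function(order, t, x0, d_right = NULL, d_left = NULL, x2 = NULL) {
  order <- as.integer(order)
  if (!order %in% 0:2) stop("order must be 0, 1 or 2")
  x0 <- as_points(x0)
  n <- nrow(x0)
  if (length(t) != n) stop("t length must match number of samples")
  if (is.unsorted(t)) stop("t must be non-decreasing")
  if (order >= 1L && (is.null(d_right) || is.null(d_left)))
    stop("order >= 1 requires one-sided derivatives")
  if (order == 2L && is.null(x2)) stop("order 2 requires second derivatives")
  structure(list(order = order, t = as.double(t), x0 = x0,
                 d_right = if (!is.null(d_right)) as_points(d_right),
                 d_left = if (!is.null(d_left)) as_points(d_left),
                 x2 = if (!is.null(x2)) as_points(x2)),
            class = "jet_sequence")
}

#' @export
print.jet_sequence <- function(x, ...) {
  cat(sprintf("<jet_sequence: order %d, %d samples>\n", x$order, nrow(x$x0)))
  invisible(x)
}

#' One-sided jets of a piecewise linear branch
#'
#' Computes one-sided derivatives at the knots from the first-order spline
#' representation: the right derivative at knot i is the chord slope
#' `(x_{i+1} - x_i) / (t_{i+1} - t_i)` and the left derivative the slope of
#' the preceding chord. For arc-length parameters every derivative is a
#' unit vector. Endpoints carry only their single one-sided derivative.
#'
#' Order 2 is not available from a polyline: second derivatives of a
#' first-order spline vanish between knots and are undefined at them.
#'
#' @param branch a [polyline_branch()].
#' @param order jet order, 0 or 1.
#' @return A `jet_sequence`.
#' @export
jet_extension_from_polyline <- function(branch, order = 1L) {
  stopifnot(inherits(branch, "polyline_branch"))
  order <- as.integer(order)
  if (order == 2L)
    stop("order 2 jets cannot be estimated from a polyline")
  if (order == 0L)
    return(jet_sequence(0L, branch$params, branch$knots))
  k <- branch$knots; t <- branch$params; n <- nrow(k)
  slopes <- (k[-1L, , drop = FALSE] - k[-n, , drop = FALSE]) / (t[-1L] - t[-n])
  d_right <- rbind(slopes, rep(NA_real_, 3L))
  d_left <- rbind(rep(NA_real_, 3L), slopes)
  jet_sequence(1L, t, k, d_right = d_right, d_left = d_left)
}

#' Two-sided jets of an analytic curve at given parameters
#'
#' @param curve an analytic curve from [make_curve()].
#' @param t parameters at which to take jets.
#' @param order jet order, 0, 1 or 2.
#' @return A `jet_sequence` with two-sided derivatives.
#' @export
jet_extension_from_curve <- function(curve, t, order = 1L) {
  stopifnot(inherits(curve, "analytic_curve"))
  order <- as.integer(order)
  x0 <- curve_position(curve, t)
  if (order == 0L) return(jet_sequence(0L, t, x0))
  d1 <- curve_derivative(curve, t, 1L)
  jet_sequence(order, t, x0, d_right = d1, d_left = d1,
               x2 = if (order == 2L) curve_derivative(curve, t, 2L))
}

#' Apply the jet-space action of a diffeomorphism
#'
#' For each sample the position maps through `phi`, first derivatives
#' through the Jacobian, and second derivatives pick up the Hessian
#' correction:
#' \deqn{x_0 \mapsto \phi(x_0),\quad x_1 \mapsto D\phi(x_0)\, x_1,\quad
#'       x_2 \mapsto D\phi(x_0)\, x_2 + D^2\phi(x_0)[x_1, x_1].}
#' Timestamps and derivative sidedness are unchanged. This is a genuine
#' group action: the identity fixes every sequence and composition of
#' transforms equals successive application.
#'
#' @param sequence a `jet_sequence`.
#' @param transform a `transform`, `C^k` near all sample positions.
#' @return The transformed `jet_sequence`.
#' @export
apply_jet_action <- function(sequence, transform) {
  stopifnot(inherits(sequence, "jet_sequence"), inherits(transform, "transform"))
  x0 <- sequence$x0
  n <- nrow(x0)
  y0 <- tryCatch(tf_evaluate(transform, x0), error = function(e) {
    # locate the offending sample for a precise message
    for (i in seq_len(n)) {
      ok <- tryCatch({ tf_evaluate(transform, x0[i, ]); TRUE },
                     error = function(e2) FALSE)
      if (!ok) stop(sprintf("sample %d is outside the transform domain", i),
                    call. = FALSE)
    }
    stop(conditionMessage(e), call. = FALSE)
  })
  y0 <- as_points(y0)
  out <- sequence
  out$x0 <- y0
  if (sequence$order >= 1L) {
    dr <- sequence$d_right; dl <- sequence$d_left
    x2 <- sequence$x2
    for (i in seq_len(n)) {
      J <- tf_jacobian(transform, x0[i, ])
      if (!all(is.na(dr[i, ]))) out$d_right[i, ] <- J %*% dr[i, ]
      if (!all(is.na(dl[i, ]))) out$d_left[i, ] <- J %*% dl[i, ]
      if (sequence$order == 2L) {
        H <- tf_hessian(transform, x0[i, ])
        v <- dr[i, ]  # two-sided for order-2 (analytic) jets
        corr <- vapply(1:3, function(ii) drop(t(v) %*% H[ii, , ] %*% v),
                       numeric(1))
        out$x2[i, ] <- J %*% x2[i, ] + corr
      }
    }
  }
  out
}
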