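#' Error bounds for zeroth- and first-order mapping
#'
#' A `bound_report` lists, per curve segment, its length and the bound on
#' the parameter-matched deviation `max_t |f(t) - g(t)|` between the true
#' transformed curve `f = phi o c` and the spline `g` reconstructed by the
#' mapping, plus the overall bound (the maximum over segments) and the
#' constants used.
#'
#' @name bound_report
NULL

new_bound_report <- function(per_segment, constants) {
  structure(list(per_segment = per_segment,
                 overall = if (nrow(per_segment)) max(per_segment$bound) else 0,
                 constants = constants),
            class = "bound_report")
}

#' @export
print.bound_report <- function(x, ...) {
  cat(sprintf("<bound_report: %d segments, overall %.6g um>\n",
              nrow(x$per_segment), x$overall))
  invisible(x)
}

# dense per-segment sampling step used to estimate maxima over continua
segment_steps <- function(len, step) pmin(step, len / 50)

# max over a dense sampling of the segment chord of fn(Jacobian at point)
segment_jac_max <- function(branch, transform, fn, step = 0.5) {
  n <- nrow(branch$knots)
  vapply(seq_len(n - 1L), function(i) {
    len <- branch$params[i + 1L] - branch$params[i]
    m <- max(2L, ceiling(len / segment_steps(len, step)) + 1L)
    w <- seq(0, 1, length.out = m)
    pts <- outer(1 - w, branch$knots[i, ]) + outer(w, branch$knots[i + 1L, ])
    max(vapply(seq_len(m), function(r) fn(tf_jacobian(transform, pts[r, ])),
               numeric(1)))
  }, numeric(1))
}

#' Zeroth-order mapping bound for piecewise C1 curves
#'
#' Per segment: `C * (t_i - t_{i-1}) * max |Dphi(c(t))|`, the Jacobian
#' spectral norm maximized over a dense sampling of the segment. This bound
#' applies to any arc-length-parameterized piecewise differentiable curve
#' but does not vanish for the identity map.
#'
#' @param branch a [polyline_branch()].
#' @param transform a `transform`, C1 near the branch.
#' @param C prefactor constant (default `sqrt(3)`).
#' @param step Jacobian sampling step along segments, microns.
#' @return A `bound_report`.
#' @export
bound_c1 <- function(branch, transform, C = sqrt(3), step = 0.5) {
  stopifnot(inherits(branch, "polyline_branch"))
  len <- diff(branch$params)
  jmax <- segment_jac_max(branch, transform, spectral_norm, step)
  per <- data.frame(segment = seq_along(len), length = len,
                    bound = C * len * jmax)
  new_bound_report(per, list(C = C, step = step, max_jac_norm = max(jmax)))
}

#' Zeroth-order mapping bound for piecewise linear curves
#'
#' Per segment i:
#' `(1/2) * max |Dphi(c(t)) - I| * (t_i - t_{i-1}) + |eps_i - eps_{i-1}|`
#' with `eps_i = c(t_i) - phi(c(t_i))`. Unlike [bound_c1()], this bound
#' tends to zero as the transform approaches the identity.
#'
#' @inheritParams bound_c1
#' @return A `bound_report`.
#' @export
bound_piecewise_linear <- function(branch, transform, step = 0.5) {
  stopifnot(inherits(branch, "polyline_branch"))
  len <- diff(branch$params)
  I3 <- diag(3)
  devmax <- segment_jac_max(branch, transform,
                            function(J) spectral_norm(J - I3), step)
  eps <- branch$knots - as_points(tf_evaluate(transform, branch$knots))
  n <- nrow(eps)
  deps <- row_norms(eps[-1L, , drop = FALSE] - eps[-n, , drop = FALSE])
  per <- data.frame(segment = seq_along(len), length = len,
                    bound = 0.5 * devmax * len + deps)
  new_bound_report(per, list(step = step, max_dev_norm = max(devmax)))
}

# finite-difference k-th derivatives of f(t) = phi(c(t)), per coordinate,
# evaluated at all t at once (one transform call over the whole stencil)
composed_derivatives <- function(curve, transform, t, h) {
  offs <- (-2:2) * h
  tt <- rep(t, each = 5L) + offs
  pts <- curve_position(curve, tt)
  f <- as_points(tf_evaluate(transform, pts))
  n <- length(t)
  idx <- function(k) f[seq(k, by = 5L, length.out = n), , drop = FALSE]
  fm2 <- idx(1L); fm1 <- idx(2L); f0 <- idx(3L); fp1 <- idx(4L); fp2 <- idx(5L)
  list(d2 = (fm1 - 2 * f0 + fp1) / h^2,
       d3 = (-fm2 + 2 * fm1 - 2 * fp1 + fp2) / (2 * h^3),
       d4 = (fm2 - 4 * fm1 + 6 * f0 - 4 * fp1 + fp2) / h^4)
}

#' Comparable bounds for zeroth- and first-order mapping of smooth curves
#'
#' For a C4 curve with analytically evaluable derivatives under a C4
#' transform, with `f = phi o c`, `delta` the maximal knot gap and
#' `h = delta / 2`:
#' order-1 (cubic Hermite) bound `= c4 * M4 * h^4` and order-0 bound
#' `= c4 * M4 * h^4 + c_lo * M3 * h^3 + c_lo * M2 * h^2`, where `M4` is the
#' largest coordinate-wise 4th derivative of `f` over the interval and
#' `M3`, `M2` the largest 3rd/2nd derivatives at the knots. The default
#' `c4 = sqrt(3)/24` combines the classical per-coordinate Hermite bound
#' `M4 delta^4 / 384` over three coordinates; `c_lo = sqrt(3)/2`. The
#' order-1 bound is structurally no larger than the order-0 bound.
#'
#' Derivatives of `f` are obtained by central finite differences of the
#' composed map on a stencil of half-width `2 * fd_h`.
#'
#' @param curve an [make_curve()] analytic curve.
#' @param knot_params strictly increasing knot parameters within the curve
#'   domain.
#' @param transform a `transform`, C4 near the curve.
#' @param c4,c_lo prefactor constants (see Details).
#' @param fd_h finite-difference step for derivatives of `f`, microns.
#' @param n_dense number of evaluation points for the interval maximum M4.
#' @return A list with `bound_report`s `order0` and `order1`; each report's
#'   constants record `M2`, `M3`, `M4`, `delta` and `h`.
#' @export
bound_smooth_orders <- function(curve, knot_params, transform,
                                c4 = sqrt(3) / 24, c_lo = sqrt(3) / 2,
                                fd_h = 0.05, n_dense = 201L) {
  stopifnot(inherits(curve, "analytic_curve"))
  t <- as.double(knot_params)
  if (is.unsorted(t, strictly = TRUE)) stop("knot_params must be strictly increasing")
  dense <- seq(t[1L], t[length(t)], length.out = n_dense)
  Dd <- composed_derivatives(curve, transform, dense, fd_h)
  Dk <- composed_derivatives(curve, transform, t, fd_h)
  M4 <- max(abs(Dd$d4))
  M3 <- max(abs(Dk$d3))
  M2 <- max(abs(Dk$d2))
  len <- diff(t)
  h_i <- len / 2
  consts <- list(c4 = c4, c_lo = c_lo, M2 = M2, M3 = M3, M4 = M4,
                 delta = max(len), h = max(len) / 2, fd_h = fd_h)
  b1 <- c4 * M4 * h_i^4
  b0 <- b1 + c_lo * M3 * h_i^3 + c_lo * M2 * h_i^2
  seg <- seq_along(len)
  list(order0 = new_bound_report(data.frame(segment = seg, length = len,
                                            bound = b0), consts),
       order1 = new_bound_report(data.frame(segment = seg, length = len,
                                            bound = b1), consts))
}

#' Length-linear zeroth-order bound and sampling-rate corollary
#'
#' Applies the piecewise-linear bound to a single straight segment of
#' length `L` anywhere in the transform's domain: the error is at most
#' `a L + b` with `a = (1/2) max |Dphi(x) - I|` and
#' `b = 2 max |x - phi(x)|`, maxima taken over the supplied sample grid
#' (`b` bounds `|eps_i - eps_{i-1}|` by the triangle inequality). Also
#' reports `L*(e)`, the largest integer segment length whose bound stays
#' below an error budget `e` — the minimum sampling rate that keeps
#' zeroth-order mapping error below `e` on straight stretches.
#'
#' @param transform a `transform`.
#' @param points `n x 3` matrix of domain sample positions, or a grid spec
#'   `list(origin, spacing, dim)`.
#' @param e error budget for the corollary, microns (default 1).
#' @return A list of class `affine_length_bound`: `slope` (`a`, per micron),
#'   `intercept` (`b`, microns), `e`, and `l_star` (largest integer L with
#'   `a L + b <= e`; `Inf` when `a = 0` and `b <= e`).
#' @export
affine_bound_in_length <- function(transform, points, e = 1) {
  pts <- expand_grid_points(points)
  I3 <- diag(3)
  dev <- vapply(seq_len(nrow(pts)), function(i)
    spectral_norm(tf_jacobian(transform, pts[i, ]) - I3), numeric(1))
  disp <- row_norms(pts - as_points(tf_evaluate(transform, pts)))
  a <- 0.5 * max(dev)
  b <- 2 * max(disp)
  structure(list(slope = a, intercept = b, e = e,
                 l_star = max_segment_length(a, b, e)),
            class = "affine_length_bound")
}

#' @export
print.affine_length_bound <- function(x, ...) {
  cat(sprintf("<zeroth-order bound ~ %.4g L + %.4g um; L*(%g um) = %s um>\n",
              x$slope, x$intercept, x$e, format(x$l_star)))
  invisible(x)
}

#' Evaluate a length-linear bound
#'
#' @param a slope, error per micron of segment length.
#' @param b intercept, microns.
#' @param L segment length(s), microns.
#' @return `a * L + b`, microns.
#' @export
length_bound_value <- function(a, b, L) a * L + b

#' Largest integer segment length within an error budget
#'
#' @inheritParams length_bound_value
#' @param e error budget, microns.
#' @return Largest integer `L >= 0` with `a L + b <= e`; `Inf` if `a = 0`
#'   and `b <= e`, `0` if even `L = 0` exceeds the budget.
#' @export
max_segment_length <- function(a, b, e) {
  if (b > e) return(0)
  if (a <= 0) return(Inf)
  floor((e - b) / a + 1e-12)
}
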