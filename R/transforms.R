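#' Coordinate transformations with evaluable derivatives
#'
#' A `transform` represents a map `phi: R^3 -> R^3` that can be evaluated
#' ([tf_evaluate()]) together with its Jacobian ([tf_jacobian()]) and,
#' where it exists, its Hessian ([tf_hessian()]). Concrete kinds are
#' [affine_transform()], [analytic_transform()], [displacement_field()] and
#' [compose_transforms()]. All coordinates are in microns.
#'
#' @name transform
NULL

#' Affine transformation
#'
#' `phi(x) = A x + b`. The Jacobian is constant (`A`) and the Hessian
#' vanishes, so affine maps send lines to lines: zeroth-order mapping of
#' piecewise linear curves is exact under them.
#'
#' @param matrix invertible 3x3 matrix `A`.
#' @param offset 3-vector `b`, microns.
#' @return A `transform` of kind `"affine"`.
#' @export
affine_transform <- function(matrix = diag(3), offset = c(0, 0, 0)) {
  matrix <- base::matrix(as.double(matrix), 3L, 3L)
  if (abs(det(matrix)) < .Machine$double.eps) stop("affine matrix must be invertible")
  structure(list(kind = "affine", matrix = matrix, offset = as.double(offset)),
            class = c("affine_transform", "transform"))
}

#' Identity transformation
#' @return The identity [affine_transform()].
#' @export
identity_transform <- function() affine_transform()

#' Analytic transformation
#'
#' Wraps a closed-form map with optional closed-form Jacobian and Hessian;
#' missing derivatives fall back to central finite differences with step
#' `h = max(1e-3, 1e-6 |x|)` microns per axis.
#'
#' @param fun function taking an `n x 3` matrix (or 3-vector) of positions
#'   and returning mapped positions of the same shape.
#' @param jacobian optional function of a single 3-vector returning the 3x3
#'   Jacobian `D phi`.
#' @param hessian optional function of a single 3-vector returning the
#'   3x3x3 array `H[i, j, k] = d^2 phi^i / dx_j dx_k`.
#' @return A `transform` of kind `"analytic"`.
#' @export
analytic_transform <- function(fun, jacobian = NULL, hessian = NULL) {
  stopifnot(is.function(fun))
  structure(list(kind = "analytic", fun = fun, jac = jacobian, hess = hessian),
            class = c("analytic_transform", "transform"))
}

#' Gridded displacement field transformation
#'
#' `phi(x) = x + u(x)` where the displacement `u` is stored on a regular 3D
#' grid and trilinearly interpolated between nodes. The Jacobian is
#' `I + Du` with `Du` the analytic gradient of the trilinear interpolant
#' (exact within each grid cell; points on a cell face use the gradient of
#' the cell with larger indices). The within-cell Hessian of a trilinear
#' interpolant has mixed partials only.
#'
#' @param origin 3-vector, position of grid node `(1,1,1)`, microns.
#' @param spacing 3 positive scalars, grid spacing per axis, microns.
#' @param values 4-D array `nx x ny x nz x 3` of displacement vectors,
#'   microns; at least 2 nodes per axis.
#' @param pad logical; if `TRUE`, points outside the grid get zero
#'   displacement instead of an out-of-domain error.
#' @return A `transform` of kind `"displacement_field"`.
#' @export
displacement_field <- function(origin, spacing, values, pad = FALSE) {
  origin <- as.double(origin); spacing <- as.double(spacing)
  if (length(origin) != 3L || length(spacing) != 3L || any(spacing <= 0))
    stop("origin and spacing must be 3-vectors, spacing > 0")
  d <- dim(values)
  if (length(d) != 4L || d[4L] != 3L || any(d[1:3] < 2L))
    stop("values must be an nx x ny x nz x 3 array with >= 2 nodes per axis")
  structure(list(kind = "displacement_field", origin = origin,
                 spacing = spacing, values = values, dim = d[1:3],
                 pad = isTRUE(pad)),
            class = c("displacement_field", "transform"))
}

#' Composition of two transformations
#'
#' `phi = outer o inner`, i.e. `phi(x) = outer(inner(x))`. The Jacobian and
#' Hessian follow the chain rule.
#'
#' @param outer,inner `transform` objects.
#' @return A `transform` of kind `"composition"`.
#' @export
compose_transforms <- function(outer, inner) {
  stopifnot(inherits(outer, "transform"), inherits(inner, "transform"))
  structure(list(kind = "composition", outer = outer, inner = inner),
            class = c("composed_transform", "transform"))
}

#' @export
print.transform <- function(x, ...) {
  cat(sprintf("<transform: %s>\n", x$kind)); invisible(x)
}

# ---- evaluation -----------------------------------------------------------

#' Evaluate a transformation
#'
#' @param transform a `transform`.
#' @param x 3-vector or `n x 3` matrix of positions, microns.
#' @return Mapped positions, same shape as `x`.
#' @export
tf_evaluate <- function(transform, x) UseMethod("tf_evaluate")

#' @export
tf_evaluate.affine_transform <- function(transform, x) {
  pts <- as_points(x)
  out <- pts %*% t(transform$matrix) +
    matrix(transform$offset, nrow(pts), 3L, byrow = TRUE)
  restore_shape(out, x)
}

#' @export
tf_evaluate.analytic_transform <- function(transform, x) {
  pts <- as_points(x)
  out <- transform$fun(pts)
  out <- as_points(out)
  if (nrow(out) != nrow(pts)) stop("analytic transform returned wrong shape")
  restore_shape(out, x)
}

#' @export
tf_evaluate.displacement_field <- function(transform, x) {
  pts <- as_points(x)
  restore_shape(pts + field_interp(transform, pts), x)
}

#' @export
tf_evaluate.composed_transform <- function(transform, x) {
  tf_evaluate(transform$outer, tf_evaluate(transform$inner, x))
}

# ---- Jacobian -------------------------------------------------------------

#' Jacobian of a transformation
#'
#' @param transform a `transform`.
#' @param x a single 3-vector position, microns.
#' @return The 3x3 Jacobian matrix `D phi(x)`.
#' @export
tf_jacobian <- function(transform, x) UseMethod("tf_jacobian")

#' @export
tf_jacobian.affine_transform <- function(transform, x) transform$matrix

#' @export
tf_jacobian.analytic_transform <- function(transform, x) {
  if (!is.null(transform$jac)) return(transform$jac(as.double(x)))
  fd_jacobian(function(p) tf_evaluate(transform, p), as.double(x))
}

#' @export
tf_jacobian.displacement_field <- function(transform, x) {
  diag(3) + field_gradient(transform, as.double(x))
}

#' @export
tf_jacobian.composed_transform <- function(transform, x) {
  y <- tf_evaluate(transform$inner, as.double(x))
  tf_jacobian(transform$outer, y) %*% tf_jacobian(transform$inner, x)
}

# ---- Hessian --------------------------------------------------------------

#' Hessian of a transformation
#'
#' @param transform a `transform`.
#' @param x a single 3-vector position, microns.
#' @return 3x3x3 array `H[i, j, k] = d^2 phi^i / dx_j dx_k`, symmetric in
#'   the last two indices.
#' @export
tf_hessian <- function(transform, x) UseMethod("tf_hessian")

#' @export
tf_hessian.affine_transform <- function(transform, x) array(0, c(3, 3, 3))

#' @export
tf_hessian.analytic_transform <- function(transform, x) {
  if (!is.null(transform$hess)) return(transform$hess(as.double(x)))
  fd_hessian(function(p) tf_jacobian(transform, p), as.double(x))
}

#' @export
tf_hessian.displacement_field <- function(transform, x) {
  field_hessian(transform, as.double(x))
}

#' @export
tf_hessian.composed_transform <- function(transform, x) {
  x <- as.double(x)
  y <- tf_evaluate(transform$inner, x)
  Jo <- tf_jacobian(transform$outer, y)
  Ji <- tf_jacobian(transform$inner, x)
  Ho <- tf_hessian(transform$outer, y)
  Hi <- tf_hessian(transform$inner, x)
  H <- array(0, c(3, 3, 3))
  for (i in 1:3) {
    # D^2(f o g)[i] = Ji' Ho[i] Ji + sum_p Jo[i,p] Hi[p]
    H[i, , ] <- t(Ji) %*% Ho[i, , ] %*% Ji
    for (p in 1:3) H[i, , ] <- H[i, , ] + Jo[i, p] * Hi[p, , ]
  }
  H
}

# ---- finite differences ---------------------------------------------------

fd_step <- function(x) max(1e-3, 1e-6 * sqrt(sum(x^2)))

fd_jacobian <- function(f, x, h = fd_step(x)) {
  J <- matrix(0, 3L, 3L)
  for (j in 1:3) {
    e <- c(0, 0, 0); e[j] <- h
    J[, j] <- (as.double(f(x + e)) - as.double(f(x - e))) / (2 * h)
  }
  J
}

# finite differences of a Jacobian-valued function -> 3x3x3, symmetrized
fd_hessian <- function(jac_fun, x, h = fd_step(x)) {
  H <- array(0, c(3, 3, 3))
  for (k in 1:3) {
    e <- c(0, 0, 0); e[k] <- h
    H[, , k] <- (jac_fun(x + e) - jac_fun(x - e)) / (2 * h)
  }
  (H + aperm(H, c(1, 3, 2))) / 2
}

# ---- trilinear interpolation ----------------------------------------------

# fractional grid coordinates (0-based), cell index and weights for points
# `pts`; errors on out-of-domain points unless the field pads
field_locate <- function(field, pts, tol = 1e-9) {
  n <- field$dim
  g <- sweep(sweep(pts, 2L, field$origin, "-"), 2L, field$spacing, "/")
  lo <- g < -tol
  hi <- sweep(g, 2L, n - 1, "-") > tol
  outside <- rowSums(lo | hi) > 0
  if (any(outside) && !field$pad) {
    stop(sprintf("point(s) outside displacement field domain (first at row %d)",
                 which(outside)[1L]), call. = FALSE)
  }
  g[g < 0] <- 0
  g <- pmin(g, matrix(n - 1, nrow(g), 3L, byrow = TRUE))
  # face convention: floor() puts a point on a face into the larger-index
  # cell; clamp so the top boundary uses the last cell
  i0 <- floor(g)
  for (j in 1:3) i0[, j] <- pmin(i0[, j], n[j] - 2)
  list(i0 = i0, w = g - i0, outside = outside)
}

# sum over the 8 cell corners with weight products; `wfun` supplies the
# per-axis weight (value or derivative) for corner offsets 0/1
field_cell_sum <- function(field, loc, wx, wy, wz) {
  npts <- nrow(loc$i0)
  out <- matrix(0, npts, 3L)
  v <- field$values
  n <- field$dim
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    w <- wx[, a + 1L] * wy[, b + 1L] * wz[, cc + 1L]
    ii <- loc$i0[, 1L] + a + 1L
    jj <- loc$i0[, 2L] + b + 1L
    kk <- loc$i0[, 3L] + cc + 1L
    for (d in 1:3)
      out[, d] <- out[, d] + w * v[cbind(ii, jj, kk, d)]
  }
  out
}

lin_w <- function(t) cbind(1 - t, t)          # weights for corner 0/1
lin_dw <- function(t, s) cbind(-1 / s, 1 / s)[rep(1L, length(t)), , drop = FALSE]

field_interp <- function(field, pts) {
  loc <- field_locate(field, pts)
  u <- field_cell_sum(field, loc,
                      lin_w(loc$w[, 1L]), lin_w(loc$w[, 2L]), lin_w(loc$w[, 3L]))
  if (any(loc$outside)) u[loc$outside, ] <- 0
  u
}

# Du at a single point: 3x3 matrix du_i/dx_j
field_gradient <- function(field, x) {
  loc <- field_locate(field, matrix(x, 1L))
  if (loc$outside[1L]) return(matrix(0, 3L, 3L))
  s <- field$spacing
  w <- lapply(1:3, function(j) lin_w(loc$w[, j]))
  dw <- lapply(1:3, function(j) lin_dw(loc$w[, j], s[j]))
  G <- matrix(0, 3L, 3L)
  for (j in 1:3) {
    f <- w; f[[j]] <- dw[[j]]
    G[, j] <- drop(field_cell_sum(field, loc, f[[1L]], f[[2L]], f[[3L]]))
  }
  G
}

# within-cell Hessian of the trilinear interpolant: mixed partials only
field_hessian <- function(field, x) {
  loc <- field_locate(field, matrix(x, 1L))
  H <- array(0, c(3, 3, 3))
  if (loc$outside[1L]) return(H)
  s <- field$spacing
  w <- lapply(1:3, function(j) lin_w(loc$w[, j]))
  dw <- lapply(1:3, function(j) lin_dw(loc$w[, j], s[j]))
  for (j in 1:3) for (k in 1:3) {
    if (j == k) next
    f <- w; f[[j]] <- dw[[j]]; f[[k]] <- dw[[k]]
    H[, j, k] <- drop(field_cell_sum(field, loc, f[[1L]], f[[2L]], f[[3L]]))
  }
  H
}

# ---- validation and statistics --------------------------------------------

#' Check that a transformation behaves like a diffeomorphism on samples
#'
#' Evaluates the Jacobian on a set of sample points and reports the minimum
#' Jacobian determinant, the maximum Jacobian spectral norm, and the maximum
#' spectral norm of `D phi - I` (for `phi = x + u(x)` this is `sup |Du|`).
#' The check fails if `det(D phi) <= 0` anywhere or if, for a displacement
#' field, `sup |Du| >= 1` (the sufficient condition `sup |Du| < 1`
#' guarantees `x + u(x)` is injective).
#'
#' @param transform a `transform`.
#' @param points `n x 3` matrix of validation sample positions, or a grid
#'   spec `list(origin, spacing, dim)` expanded to all grid nodes.
#' @return A list of class `diffeo_report` with `min_det`, `max_norm`,
#'   `max_dev_norm`, and logical `pass`.
#' @export
validate_diffeomorphism <- function(transform, points) {
  pts <- expand_grid_points(points)
  dets <- numeric(nrow(pts)); nrm <- numeric(nrow(pts)); dev <- numeric(nrow(pts))
  I3 <- diag(3)
  for (i in seq_len(nrow(pts))) {
    J <- tf_jacobian(transform, pts[i, ])
    dets[i] <- det(J)
    nrm[i] <- spectral_norm(J)
    dev[i] <- spectral_norm(J - I3)
  }
  is_field <- inherits(transform, "displacement_field")
  pass <- min(dets) > 0 && (!is_field || max(dev) < 1)
  structure(list(min_det = min(dets), max_norm = max(nrm),
                 max_dev_norm = max(dev), n_points = nrow(pts),
                 pass = pass),
            class = "diffeo_report")
}

#' @export
print.diffeo_report <- function(x, ...) {
  cat(sprintf("<diffeo_report: min det %.4g, max |Dphi| %.4g, sup |Du| %.4g, %s>\n",
              x$min_det, x$max_norm, x$max_dev_norm,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

expand_grid_points <- function(points) {
  if (is.matrix(points)) return(as_points(points))
  if (is.list(points) && all(c("origin", "spacing", "dim") %in% names(points))) {
    ax <- lapply(1:3, function(j)
      points$origin[j] + (seq_len(points$dim[j]) - 1) * points$spacing[j])
    g <- expand.grid(x = ax[[1L]], y = ax[[2L]], z = ax[[3L]])
    return(as.matrix(g))
  }
  as_points(points)
}

#' Per-node statistics of a displacement field
#'
#' At every grid node reports the displacement magnitude `|u|`, the log
#' Jacobian determinant `log det D phi` (local expansion/compression; its
#' spectral-norm analogue `log |D phi|` is the finite-time Lyapunov
#' exponent), the Jacobian spectral norm `|D phi|`, the deviation norm
#' `|D phi - I|`, and the displacement of a tangent vector
#' `|D phi v - v|` for the supplied `v`.
#'
#' @param field a [displacement_field()].
#' @param tangent 3-vector `v`; default `(1, 1, 1)`.
#' @return A list of class `field_statistics`: `per_node` data frame and
#'   `summary` (min/median/mean/max per statistic).
#' @export
field_statistics <- function(field, tangent = c(1, 1, 1)) {
  stopifnot(inherits(field, "displacement_field"))
  pts <- expand_grid_points(list(origin = field$origin, spacing = field$spacing,
                                 dim = field$dim))
  v <- as.double(tangent)
  n <- nrow(pts)
  umag <- row_norms(field_interp(field, pts))
  logdet <- numeric(n); jn <- numeric(n); devn <- numeric(n); tdisp <- numeric(n)
  I3 <- diag(3)
  for (i in seq_len(n)) {
    J <- tf_jacobian(field, pts[i, ])
    logdet[i] <- log(det(J))
    jn[i] <- spectral_norm(J)
    devn[i] <- spectral_norm(J - I3)
    tdisp[i] <- sqrt(sum((J %*% v - v)^2))
  }
  per_node <- data.frame(x = pts[, 1L], y = pts[, 2L], z = pts[, 3L],
                         u_mag = umag, log_det = logdet,
                         jac_norm = jn, dev_norm = devn,
                         tangent_disp = tdisp)
  stats <- c("u_mag", "log_det", "jac_norm", "dev_norm", "tangent_disp")
  summary <- do.call(rbind, lapply(stats, function(s) {
    v <- per_node[[s]]
    data.frame(statistic = s, min = min(v), median = median(v),
               mean = mean(v), max = max(v))
  }))
  structure(list(per_node = per_node, summary = summary, tangent = v),
            class = "field_statistics")
}

#' @export
print.field_statistics <- function(x, ...) {
  cat(sprintf("<field_statistics over %d grid nodes>\n", nrow(x$per_node)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# ---- JSON serialization ---------------------------------------------------

#' Read a transformation from a JSON file
#'
#' Supported kinds: `affine` (`matrix`: 9 numbers row-major, `offset`: 3),
#' `displacement_field` (`origin`, `spacing`, `dim`, `values` flattened with
#' x fastest then y, z, then component), and `composition`
#' (`outer`, `inner` nested objects).
#'
#' @param path JSON file path.
#' @param nonlinear_only logical; for a `composition` whose components
#'   include a displacement field, return only the nonlinear
#'   (displacement-field) component, the protocol used when an affine +
#'   deformation registration should act on traces through its deformation
#'   part alone.
#' @return A `transform`.
#' @export
read_transform <- function(path, nonlinear_only = FALSE) {
  spec <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  tf <- transform_from_spec(spec)
  if (nonlinear_only) tf <- extract_nonlinear(tf)
  tf
}

transform_from_spec <- function(spec) {
  switch(spec$kind,
    affine = affine_transform(matrix(as.double(spec$matrix), 3L, 3L, byrow = TRUE),
                              as.double(spec$offset)),
    displacement_field = {
      d <- as.integer(spec$dim)
      displacement_field(spec$origin, spec$spacing,
                         array(as.double(unlist(spec$values)), c(d, 3L)),
                         pad = isTRUE(spec$pad))
    },
    composition = compose_transforms(transform_from_spec(spec$outer),
                                     transform_from_spec(spec$inner)),
    stop("unknown transform kind: ", spec$kind))
}

extract_nonlinear <- function(tf) {
  if (inherits(tf, "displacement_field")) return(tf)
  if (inherits(tf, "composed_transform")) {
    for (part in list(tf$outer, tf$inner)) {
      hit <- tryCatch(extract_nonlinear(part), error = function(e) NULL)
      if (!is.null(hit)) return(hit)
    }
  }
  stop("transform has no displacement-field component")
}

#' Write a transformation to a JSON file
#'
#' Inverse of [read_transform()] for affine, displacement-field and
#' composed transforms.
#'
#' @param transform a `transform`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(transform_to_spec(transform), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

transform_to_spec <- function(tf) {
  if (inherits(tf, "affine_transform"))
    return(list(kind = "affine", matrix = as.double(t(tf$matrix)),
                offset = tf$offset))
  if (inherits(tf, "displacement_field"))
    return(list(kind = "displacement_field", origin = tf$origin,
                spacing = tf$spacing, dim = tf$dim,
                values = as.double(tf$values), pad = tf$pad))
  if (inherits(tf, "composed_transform"))
    return(list(kind = "composition", outer = transform_to_spec(tf$outer),
                inner = transform_to_spec(tf$inner)))
  stop("cannot serialize transform of kind ", tf$kind)
}
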