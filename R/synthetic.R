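#' Synthetic analytic curves
#'
#' Generates regular 3D curves with closed-form position and first two
#' derivatives, for validating mappings and bounds without real data.
#' Families:
#' \describe{
#'   \item{straight}{`c(t) = origin + t * direction`, unit speed.}
#'   \item{helix}{radius `r`, pitch `p`, arc-length parameterized
#'     (`|c'| = 1`).}
#'   \item{sinusoid}{`(t, a sin(2 pi t / lambda), 0)` plus origin.}
#'   \item{random_fourier}{a straight baseline plus seeded random Fourier
#'     perturbations with coefficients decaying as `1/m^2` over `m`
#'     harmonics, so the curve is smooth with bounded derivatives.}
#' }
#' Regularity (`|c'| > 0`) is verified by dense sampling; parameter
#' combinations producing a non-regular curve are rejected.
#'
#' @param family curve family (see Details).
#' @param length curve parameter length `L`, microns.
#' @param seed integer seed (random_fourier); same seed, same curve.
#' @param origin 3-vector starting offset.
#' @param direction 3-vector baseline direction (normalized internally).
#' @param radius,pitch helix geometry, microns.
#' @param amplitude sinusoid / Fourier amplitude scale, microns.
#' @param wavelength sinusoid wavelength, microns.
#' @param n_harmonics number of Fourier harmonics.
#' @return An object of class `analytic_curve` with callable `position`,
#'   `d1`, `d2` and the domain `[0, t_max]`.
#' @export
make_curve <- function(family = c("straight", "helix", "sinusoid", "random_fourier"),
                       length = 100, seed = NULL,
                       origin = c(0, 0, 0), direction = c(1, 0, 0),
                       radius = 20, pitch = 10,
                       amplitude = 10, wavelength = 50, n_harmonics = 4L) {
  family <- match.arg(family)
  stopifnot_scalar(length, "length", positive = TRUE)
  origin <- as.double(origin)
  dir <- as.double(direction); dir <- dir / sqrt(sum(dir^2))
  curve <- switch(family,
    straight = {
      pos <- function(t) outer(rep(1, base::length(t)), origin) + outer(t, dir)
      d1 <- function(t) outer(rep(1, base::length(t)), dir)
      d2 <- function(t) matrix(0, base::length(t), 3L)
      list(position = pos, d1 = d1, d2 = d2)
    },
    helix = {
      w <- 1 / sqrt(radius^2 + pitch^2)  # unit speed
      pos <- function(t) cbind(origin[1L] + radius * cos(w * t),
                               origin[2L] + radius * sin(w * t),
                               origin[3L] + pitch * w * t)
      d1 <- function(t) cbind(-radius * w * sin(w * t),
                              radius * w * cos(w * t),
                              rep(pitch * w, base::length(t)))
      d2 <- function(t) cbind(-radius * w^2 * cos(w * t),
                              -radius * w^2 * sin(w * t),
                              rep(0, base::length(t)))
      list(position = pos, d1 = d1, d2 = d2)
    },
    sinusoid = {
      k <- 2 * pi / wavelength
      pos <- function(t) cbind(origin[1L] + t,
                               origin[2L] + amplitude * sin(k * t),
                               rep(origin[3L], base::length(t)))
      d1 <- function(t) cbind(rep(1, base::length(t)),
                              amplitude * k * cos(k * t),
                              rep(0, base::length(t)))
      d2 <- function(t) cbind(rep(0, base::length(t)),
                              -amplitude * k^2 * sin(k * t),
                              rep(0, base::length(t)))
      list(position = pos, d1 = d1, d2 = d2)
    },
    random_fourier = {
      if (!is.null(seed)) set.seed(as.integer(seed))
      m <- seq_len(n_harmonics)
      # coefficients per coordinate and harmonic, decaying as 1/m^2
      A <- matrix(rnorm(3L * n_harmonics), 3L, n_harmonics) *
        rep(amplitude / m^2, each = 3L)
      B <- matrix(rnorm(3L * n_harmonics), 3L, n_harmonics) *
        rep(amplitude / m^2, each = 3L)
      km <- 2 * pi * m / length
      pos <- function(t) {
        S <- sin(outer(t, km)); C <- cos(outer(t, km))
        outer(rep(1, base::length(t)), origin) + outer(t, dir) +
          S %*% t(A) + C %*% t(B)
      }
      d1 <- function(t) {
        S <- sin(outer(t, km)); C <- cos(outer(t, km))
        outer(rep(1, base::length(t)), dir) +
          sweep(C, 2L, km, "*") %*% t(A) - sweep(S, 2L, km, "*") %*% t(B)
      }
      d2 <- function(t) {
        S <- sin(outer(t, km)); C <- cos(outer(t, km))
        -sweep(S, 2L, km^2, "*") %*% t(A) - sweep(C, 2L, km^2, "*") %*% t(B)
      }
      list(position = pos, d1 = d1, d2 = d2)
    })
  out <- structure(c(curve, list(family = family, t_max = length, seed = seed)),
                   class = "analytic_curve")
  speeds <- row_norms(curve_derivative(out, seq(0, length, length.out = 500L), 1L))
  if (!isTRUE(min(speeds) > 1e-6))
    stop("parameter combination yields a non-regular curve (|c'| ~ 0)")
  out
}

#' @export
print.analytic_curve <- function(x, ...) {
  cat(sprintf("<analytic_curve: %s, domain [0, %g] um>\n", x$family, x$t_max))
  invisible(x)
}

#' Evaluate an analytic curve
#' @param curve an `analytic_curve`.
#' @param t parameter values.
#' @return `length(t) x 3` matrix of positions.
#' @export
curve_position <- function(curve, t) curve$position(as.double(t))

#' Evaluate derivatives of an analytic curve
#' @inheritParams curve_position
#' @param order derivative order, 1 or 2.
#' @return `length(t) x 3` matrix.
#' @export
curve_derivative <- function(curve, t, order = 1L) {
  switch(as.character(order), "1" = curve$d1(as.double(t)),
         "2" = curve$d2(as.double(t)),
         stop("order must be 1 or 2"))
}

#' Sample knots along an analytic curve at a target arc-length period
#'
#' Inverts arc length numerically (fine chord quadrature) to place knots at
#' approximately equal arc-length steps, always including both endpoints,
#' and returns the arc-length-parameterized polyline through them. A period
#' at or above the curve length yields just the two endpoints.
#'
#' @param curve an `analytic_curve`.
#' @param period target arc-length spacing, microns.
#' @param n_dense number of quadrature samples for arc-length inversion.
#' @return A [polyline_branch()].
#' @export
sample_knots <- function(curve, period, n_dense = NULL) {
  stopifnot(inherits(curve, "analytic_curve"))
  stopifnot_scalar(period, "period", positive = TRUE)
  if (is.null(n_dense))
    n_dense <- max(1000L, ceiling(20 * curve$t_max / period))
  tg <- seq(0, curve$t_max, length.out = n_dense)
  pts <- curve_position(curve, tg)
  cl <- c(0, cumsum(row_norms(diff(pts))))
  total <- cl[n_dense]
  targets <- seq(0, total, by = period)
  if (total - targets[base::length(targets)] > 1e-9) targets <- c(targets, total)
  tq <- approx(cl, tg, xout = targets, ties = "ordered")$y
  arc_length_parameterize(curve_position(curve, tq))
}

#' Synthetic diffeomorphic deformation transforms and fields
#'
#' Builds displacement transforms `phi(x) = x + u(x)` that are guaranteed
#' diffeomorphisms by construction: each family has a closed-form bound on
#' `sup |Du|` and specs violating `sup |Du| < 1` are rejected. Families:
#' \describe{
#'   \item{gaussian_bump}{sum of `n_bumps` radial Gaussian bumps
#'     `a_m d_m exp(-|x - c_m|^2 / (2 sigma^2))` with random centers and
#'     unit directions; per-bump `sup |Du| = a_m / (sigma sqrt(e))`, summed
#'     over bumps.}
#'   \item{sinusoidal}{cyclically coupled sinusoids with
#'     `sup |Du| = 2 pi a / lambda`.}
#'   \item{polynomial_affine_perturbation}{`u(x) = M (x - x0)` with a random
#'     small matrix, `sup |Du| = |M|`.}
#' }
#'
#' @param family deformation family.
#' @param amplitude per-bump (or global) displacement amplitude `a`, microns.
#' @param sigma Gaussian length scale, microns.
#' @param wavelength sinusoidal wavelength `lambda`, microns.
#' @param grid grid spec `list(origin, spacing, dim)`; defaults to a
#'   100-micron-spacing grid, the scale at which brain registrations are
#'   typically computed.
#' @param n_bumps number of Gaussian bumps.
#' @param seed integer seed; same seed, same field.
#' @param realize `"grid"` returns a [displacement_field()] sampled on the
#'   grid (trilinearly interpolated when evaluated); `"analytic"` returns
#'   the smooth closed-form [analytic_transform()] with exact Jacobian and
#'   Hessian.
#' @param pad zero-displacement padding outside the grid (grid realization).
#' @return A `transform` (displacement field or analytic, per `realize`).
#' @export
make_field <- function(family = c("gaussian_bump", "sinusoidal",
                                  "polynomial_affine_perturbation"),
                       amplitude = 45, sigma = 300, wavelength = 600,
                       grid = NULL, n_bumps = 3L, seed = NULL,
                       realize = c("grid", "analytic"), pad = FALSE) {
  family <- match.arg(family)
  realize <- match.arg(realize)
  if (is.null(grid))
    grid <- list(origin = c(0, 0, 0), spacing = c(100, 100, 100),
                 dim = c(11L, 11L, 11L))
  extent <- grid$origin + (unlist(grid$dim) - 1) * grid$spacing
  if (!is.null(seed)) set.seed(as.integer(seed))
  tfa <- switch(family,
    gaussian_bump = {
      sup_du <- n_bumps * abs(amplitude) / (sigma * sqrt(exp(1)))
      if (sup_du >= 1)
        stop(sprintf("spec rejected: sup|Du| = %.3f >= 1 (amplitude too large for sigma)",
                     sup_du))
      centers <- sapply(1:3, function(j) runif(n_bumps, grid$origin[j], extent[j]))
      centers <- matrix(centers, n_bumps, 3L)
      dirs <- matrix(rnorm(3L * n_bumps), n_bumps, 3L)
      dirs <- dirs / row_norms(dirs)
      bump_transform(centers, rep(abs(amplitude), n_bumps), dirs, sigma)
    },
    sinusoidal = {
      k <- 2 * pi / wavelength
      if (abs(amplitude) * k >= 1)
        stop("spec rejected: sup|Du| = 2 pi a / lambda >= 1")
      phase <- runif(3L, 0, 2 * pi)
      a <- amplitude
      fun <- function(p) {
        p <- as_points(p)
        p + a * cbind(sin(k * p[, 2L] + phase[1L]),
                      sin(k * p[, 3L] + phase[2L]),
                      sin(k * p[, 1L] + phase[3L]))
      }
      jac <- function(x) {
        J <- diag(3)
        J[1L, 2L] <- a * k * cos(k * x[2L] + phase[1L])
        J[2L, 3L] <- a * k * cos(k * x[3L] + phase[2L])
        J[3L, 1L] <- a * k * cos(k * x[1L] + phase[3L])
        J
      }
      hess <- function(x) {
        H <- array(0, c(3, 3, 3))
        H[1L, 2L, 2L] <- -a * k^2 * sin(k * x[2L] + phase[1L])
        H[2L, 3L, 3L] <- -a * k^2 * sin(k * x[3L] + phase[2L])
        H[3L, 1L, 1L] <- -a * k^2 * sin(k * x[1L] + phase[3L])
        H
      }
      analytic_transform(fun, jac, hess)
    },
    polynomial_affine_perturbation = {
      M <- matrix(rnorm(9L, sd = 0.1), 3L, 3L)
      nm <- spectral_norm(M)
      if (nm >= 1) M <- M * (0.5 / nm)
      x0 <- (grid$origin + extent) / 2
      fun <- function(p) {
        p <- as_points(p)
        p + sweep(p, 2L, x0, "-") %*% t(M)
      }
      analytic_transform(fun, jacobian = function(x) diag(3) + M,
                         hessian = function(x) array(0, c(3, 3, 3)))
    })
  if (realize == "analytic") return(tfa)
  pts <- expand_grid_points(grid)
  u <- as_points(tf_evaluate(tfa, pts)) - pts
  d <- as.integer(unlist(grid$dim))
  displacement_field(grid$origin, grid$spacing, array(u, c(d, 3L)), pad = pad)
}

#' Closed-form Gaussian-bump displacement transform
#'
#' `phi(x) = x + sum_m a_m d_m exp(-|x - c_m|^2 / (2 sigma^2))` with exact
#' Jacobian and Hessian. The maximal gradient of a single bump is
#' `a / (sigma sqrt(e))`, so `sum_m a_m / (sigma sqrt(e)) < 1` guarantees a
#' diffeomorphism; violating specs are rejected.
#'
#' @param centers `m x 3` matrix of bump centers, microns.
#' @param amplitudes length-m vector of bump amplitudes, microns.
#' @param directions `m x 3` matrix of unit displacement directions.
#' @param sigma common length scale, microns.
#' @return An [analytic_transform()].
#' @export
bump_transform <- function(centers, amplitudes, directions, sigma) {
  centers <- as_points(centers)
  directions <- as_points(directions)
  amplitudes <- as.double(amplitudes)
  m <- nrow(centers)
  stopifnot(nrow(directions) == m, length(amplitudes) == m)
  stopifnot_scalar(sigma, "sigma", positive = TRUE)
  sup_du <- sum(abs(amplitudes)) / (sigma * sqrt(exp(1)))
  if (sup_du >= 1)
    stop(sprintf("spec rejected: sup|Du| = %.3f >= 1", sup_du))
  fun <- function(p) {
    p <- as_points(p)
    out <- p
    for (q in seq_len(m)) {
      r2 <- rowSums(sweep(p, 2L, centers[q, ], "-")^2)
      out <- out + outer(amplitudes[q] * exp(-r2 / (2 * sigma^2)),
                         directions[q, ])
    }
    out
  }
  jac <- function(x) {
    J <- diag(3)
    for (q in seq_len(m)) {
      dx <- x - centers[q, ]
      g <- amplitudes[q] * exp(-sum(dx^2) / (2 * sigma^2))
      J <- J + outer(directions[q, ], -dx / sigma^2) * g
    }
    J
  }
  hess <- function(x) {
    H <- array(0, c(3, 3, 3))
    for (q in seq_len(m)) {
      dx <- x - centers[q, ]
      g <- amplitudes[q] * exp(-sum(dx^2) / (2 * sigma^2))
      K <- (outer(dx, dx) / sigma^4 - diag(3) / sigma^2) * g
      for (i in 1:3) H[i, , ] <- H[i, , ] + directions[q, i] * K
    }
    H
  }
  analytic_transform(fun, jac, hess)
}
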