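test_that("piecewise-C1 bound: identity and uniform scaling closed forms", {
  br <- polyline_branch(cbind(c(0, 2, 4, 6), 0, 0) * 1.0)
  rep_id <- bound_c1(br, identity_transform())
  expect_equal(rep_id$overall, sqrt(3) * 2 * 1)
  expect_equal(rep_id$per_segment$bound, rep(sqrt(3) * 2, 3))

  s <- 2.5
  rep_s <- bound_c1(br, affine_transform(s * diag(3)))
  expect_equal(rep_s$overall, sqrt(3) * 2 * s)

  # configurable constant
  expect_equal(bound_c1(br, identity_transform(), C = 1)$overall, 2)
})

test_that("piecewise-linear bound vanishes for identity and pure translation", {
  set.seed(53)
  br <- arc_length_parameterize(matrix(runif(15, 0, 50), 5, 3))
  expect_equal(bound_piecewise_linear(br, identity_transform())$overall, 0)
  expect_equal(bound_piecewise_linear(
    br, affine_transform(diag(3), c(7, -3, 2)))$overall, 0, tolerance = 1e-12)
})

test_that("piecewise-linear bound decreases monotonically to 0 with bump amplitude", {
  set.seed(59)
  br <- arc_length_parameterize(matrix(runif(18, 20, 180), 6, 3))
  center <- matrix(c(100, 100, 100), 1); dir <- matrix(c(0, 1, 0), 1)
  amps <- c(40, 20, 10, 5, 0)
  bounds <- vapply(amps, function(a) {
    tf <- bump_transform(center, a, dir, 80)
    bound_piecewise_linear(br, tf)$overall
  }, numeric(1))
  expect_true(all(diff(bounds) < 1e-12))
  expect_equal(bounds[5], 0)
})

test_that("observed zeroth-order error never exceeds the Prop-style bounds", {
  set.seed(61)
  for (r in 1:40) {
    cur <- make_curve("random_fourier", length = runif(1, 60, 140),
                      seed = 1000 + r, amplitude = runif(1, 4, 12))
    br <- sample_knots(cur, runif(1, 4, 12))
    tf <- random_bump_transform(n_bumps = 2L, amplitude = 20, sigma = 70,
                                box = c(-50, 250))
    err <- mapping_error(br, tf, 0L)
    expect_lte(err, bound_c1(br, tf)$overall)
    expect_lte(err, bound_piecewise_linear(br, tf)$overall)
  }
})

test_that("smooth-curve bounds: cubic reproduction, straight/identity, and validity", {
  # cubic coordinate functions: 4th derivative is zero, Hermite is exact
  cubic <- structure(list(
    position = function(t) unname(cbind(t, 0.01 * t^3, 0.05 * t^2)),
    d1 = function(t) unname(cbind(rep(1, length(t)), 0.03 * t^2, 0.1 * t)),
    d2 = function(t) unname(cbind(rep(0, length(t)), 0.06 * t, rep(0.1, length(t)))),
    family = "custom", t_max = 10), class = "analytic_curve")
  tk <- seq(0, 10, by = 2.5)
  bs <- bound_smooth_orders(cubic, tk, identity_transform())
  expect_lt(bs$order1$overall, 1e-6)
  # first-order mapping of the analytic jet reproduces the cubic exactly
  js <- apply_jet_action(jet_extension_from_curve(cubic, tk, 1L),
                         identity_transform())
  mc <- mapped_curve_from_jets(js)
  td <- seq(0, 10, by = 0.1)
  expect_equal(eval_mapped_curve(mc, td), curve_position(cubic, td),
               tolerance = 1e-8)

  # straight curve under identity: all constants vanish
  st <- make_curve("straight", length = 50)
  bs2 <- bound_smooth_orders(st, seq(0, 50, by = 10), identity_transform())
  expect_lt(bs2$order0$overall, 1e-6)
  expect_lt(bs2$order1$overall, 1e-6)

  # f(t) = (sin t, cos t, t): both bounds dominate the observed deviation
  circ <- structure(list(
    position = function(t) unname(cbind(sin(t), cos(t), t)),
    d1 = function(t) unname(cbind(cos(t), -sin(t), rep(1, length(t)))),
    d2 = function(t) unname(cbind(-sin(t), -cos(t), rep(0, length(t)))),
    family = "custom", t_max = 2 * pi), class = "analytic_curve")
  for (delta in c(0.5, 1, 2)) {
    tk <- seq(0, 2 * pi, by = delta)
    if (max(tk) < 2 * pi) tk <- c(tk, 2 * pi)
    bs3 <- bound_smooth_orders(circ, tk, identity_transform())
    td <- seq(0, 2 * pi, length.out = 800)
    truth <- curve_position(circ, td)
    knotpos <- curve_position(circ, tk)
    lin <- sapply(1:3, function(j) approx(tk, knotpos[, j], xout = td)$y)
    err0 <- max(sqrt(rowSums((truth - lin)^2)))
    js <- jet_extension_from_curve(circ, tk, 1L)
    err1 <- max(sqrt(rowSums((truth - eval_mapped_curve(
      mapped_curve_from_jets(js), td))^2)))
    expect_lte(err0, bs3$order0$overall)
    expect_lte(err1, bs3$order1$overall)
    expect_lte(bs3$order1$overall, bs3$order0$overall)
  }
})

test_that("length-linear bound and sampling-rate corollary reproduce worked examples", {
  # printed registration constants: a = 0.011 per micron, b = 0.022 microns
  expect_equal(round(length_bound_value(0.011, 0.022, 10), 2), 0.13)
  expect_equal(length_bound_value(0.011, 0.022, 10), 0.132)
  expect_equal(round(length_bound_value(0.011, 0.022, 1000)), 11)
  expect_equal(length_bound_value(0.011, 0.022, 1000), 11.022)
  expect_equal(max_segment_length(0.011, 0.022, 1), 88)

  lb <- affine_bound_in_length(identity_transform(),
                               matrix(runif(30, 0, 100), 10, 3), e = 1)
  expect_equal(lb$slope, 0)
  expect_equal(lb$intercept, 0)
  expect_equal(lb$l_star, Inf)

  # the a L + b form bounds the per-segment piecewise-linear bound for any
  # straight segment inside the sampled domain
  set.seed(67)
  tf <- random_bump_transform(n_bumps = 2L, amplitude = 25, sigma = 90,
                              box = c(0, 200))
  grid <- jetmap:::expand_grid_points(list(origin = c(0, 0, 0),
                                           spacing = c(10, 10, 10),
                                           dim = c(21L, 21L, 21L)))
  lb2 <- affine_bound_in_length(tf, grid)
  for (r in 1:20) {
    p0 <- runif(3, 20, 180)
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    L <- runif(1, 5, 60)
    seg <- polyline_branch(rbind(p0, p0 + L * d))
    expect_lte(mapping_error(seg, tf, 0L, spacing = 0.5),
               length_bound_value(lb2$slope, lb2$intercept, L) + 1e-9)
  }
})

test_that("discrete Frechet matches hand values and the coupling-enumeration oracle", {
  P <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(discrete_frechet(P, P)$distance, 0)
  expect_equal(discrete_frechet(P, sweep(P, 2, c(0, -1, 0)))$distance, 1)

  set.seed(71)
  for (r in 1:50) {
    n <- sample(2:7, 1); m <- sample(2:7, 1)
    P <- matrix(runif(3 * n, 0, 10), n, 3)
    Q <- matrix(runif(3 * m, 0, 10), m, 3)
    res <- discrete_frechet(P, Q, return_coupling = TRUE)
    expect_equal(res$distance, frechet_bruteforce(P, Q))
    expect_equal(discrete_frechet(Q, P)$distance, res$distance)  # symmetry
    # returned coupling is monotone, complete, and realizes the distance
    cp <- res$coupling
    expect_equal(cp[1, ], c(1, 1))
    expect_equal(cp[nrow(cp), ], c(n, m))
    expect_true(all(diff(cp[, 1]) %in% 0:1) && all(diff(cp[, 2]) %in% 0:1))
    dmax <- max(sqrt(rowSums((P[cp[, 1], , drop = FALSE] -
                                Q[cp[, 2], , drop = FALSE])^2)))
    expect_equal(dmax, res$distance)
  }
  expect_error(discrete_frechet(matrix(numeric(0), 0, 3), P), "at least one")
})

test_that("coarser subsamplings of a curve do not decrease Frechet distance to truth", {
  set.seed(73)
  for (r in 1:10) {
    cur <- make_curve("random_fourier", length = 150, seed = 300 + r,
                      amplitude = 10)
    tf <- random_bump_transform()
    dense <- sample_knots(cur, 0.5)
    truth <- as.matrix(tf_evaluate(tf, dense$knots))
    d <- vapply(c(4, 8, 16, 32), function(per) {
      coarse <- sample_knots(cur, per)
      discrete_frechet(as.matrix(tf_evaluate(tf, coarse$knots)), truth)$distance
    }, numeric(1))
    expect_true(all(diff(d) > -1e-9))
  }
})
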