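test_that("evaluation: identity, affine arithmetic, constant field", {
  expect_equal(tf_evaluate(identity_transform(), c(3, -1, 2)), c(3, -1, 2))

  aff <- affine_transform(2 * diag(3), c(1, 0, 0))
  expect_equal(tf_evaluate(aff, c(1, 1, 1)), c(3, 2, 2))

  # constant displacement: trilinear of a constant is that constant anywhere
  v <- c(1, -2, 0.5)
  vals <- array(0, c(2, 2, 2, 3))
  for (d in 1:3) vals[, , , d] <- v[d]
  fld <- displacement_field(c(0, 0, 0), c(10, 10, 10), vals)
  x <- c(3.7, 8.21, 0.5)
  expect_equal(tf_evaluate(fld, x), x + v)
  expect_error(tf_evaluate(fld, c(50, 0, 0)), "outside")
  fld_pad <- displacement_field(c(0, 0, 0), c(10, 10, 10), vals, pad = TRUE)
  expect_equal(tf_evaluate(fld_pad, c(50, 0, 0)), c(50, 0, 0))
})

test_that("trilinear interpolation reproduces node values and is linear per axis", {
  set.seed(11)
  vals <- array(rnorm(4 * 3 * 2 * 3), c(4, 3, 2, 3))
  fld <- displacement_field(c(0, 0, 0), c(5, 4, 3), vals)
  for (i in 1:4) for (j in 1:3) for (k in 1:2) {
    x <- c((i - 1) * 5, (j - 1) * 4, (k - 1) * 3)
    expect_equal(tf_evaluate(fld, x) - x, vals[i, j, k, ], tolerance = 1e-12)
  }
  # linearity along x between two nodes
  p0 <- tf_evaluate(fld, c(0, 4, 3)) - c(0, 4, 3)
  p1 <- tf_evaluate(fld, c(5, 4, 3)) - c(5, 4, 3)
  pm <- tf_evaluate(fld, c(2, 4, 3)) - c(2, 4, 3)
  expect_equal(pm, p0 + 0.4 * (p1 - p0), tolerance = 1e-12)
})

test_that("jacobians match closed forms and a finite-difference oracle", {
  expect_equal(tf_jacobian(identity_transform(), c(1, 2, 3)), diag(3))

  # analytic phi(x,y,z) = (x^2, y, z): symbolic Jacobian diag(2x, 1, 1)
  sq <- squash_x_transform()
  expect_equal(tf_jacobian(sq, c(1, 2, 3)), diag(c(2, 1, 1)))

  aff <- random_affine()
  fd <- jetmap:::fd_jacobian(function(p) tf_evaluate(aff, p), c(5, -2, 1))
  expect_equal(fd, aff$matrix, tolerance = 1e-8)

  # FD oracle at random interior points for every transform kind
  set.seed(21)
  fld <- make_field("gaussian_bump", amplitude = 30, sigma = 150,
                    grid = list(origin = c(0, 0, 0), spacing = c(50, 50, 50),
                                dim = c(9L, 9L, 9L)), seed = 3)
  bump <- random_bump_transform()
  comp <- compose_transforms(bump, aff)
  for (tf in list(aff, bump, fld, comp)) {
    for (r in 1:25) {
      x <- runif(3, 60, 340)
      J <- tf_jacobian(tf, x)
      Jfd <- jetmap:::fd_jacobian(function(p) tf_evaluate(tf, p), x)
      expect_equal(J, Jfd, tolerance = 1e-4)
    }
  }
})

test_that("hessians: affine zero, symbolic example, trilinear mixed partials", {
  expect_equal(tf_hessian(random_affine(), c(1, 1, 1)), array(0, c(3, 3, 3)))

  H <- tf_hessian(squash_x_transform(), c(4, 5, 6))
  expected <- array(0, c(3, 3, 3)); expected[1, 1, 1] <- 2
  expect_equal(H, expected)

  # FD of the field Jacobian within one cell matches analytic mixed partials
  set.seed(5)
  vals <- array(rnorm(3 * 3 * 3 * 3, sd = 2), c(3, 3, 3, 3))
  fld <- displacement_field(c(0, 0, 0), c(10, 10, 10), vals)
  x <- c(4.2, 13.7, 6.1)
  Hfd <- jetmap:::fd_hessian(function(p) tf_jacobian(fld, p), x, h = 0.01)
  expect_equal(tf_hessian(fld, x), Hfd, tolerance = 1e-6)
  expect_equal(tf_hessian(fld, x), aperm(tf_hessian(fld, x), c(1, 3, 2)))
})

test_that("composition evaluates outer-after-inner and obeys the chain rule", {
  set.seed(31)
  phi <- random_bump_transform(); psi <- random_affine()
  comp <- compose_transforms(phi, psi)
  for (r in 1:20) {
    x <- runif(3, 0, 150)
    expect_equal(tf_evaluate(comp, x), tf_evaluate(phi, tf_evaluate(psi, x)))
    expect_equal(tf_jacobian(comp, x),
                 tf_jacobian(phi, tf_evaluate(psi, x)) %*% tf_jacobian(psi, x),
                 tolerance = 1e-10)
  }
  # Hessian chain rule against finite differences of the composed Jacobian
  x <- c(40, 80, 120)
  Hfd <- jetmap:::fd_hessian(function(p) tf_jacobian(comp, p), x, h = 1e-3)
  expect_equal(tf_hessian(comp, x), Hfd, tolerance = 1e-5)
})

test_that("validate_diffeomorphism flags orientation reversal and large gradients", {
  pts <- matrix(runif(60, 0, 100), 20, 3)
  rep_id <- validate_diffeomorphism(identity_transform(), pts)
  expect_true(rep_id$pass)
  expect_equal(rep_id$min_det, 1)
  expect_equal(rep_id$max_dev_norm, 0)

  flip <- affine_transform(diag(c(-1, 1, 1)))
  expect_false(validate_diffeomorphism(flip, pts)$pass)

  # bump with amplitude/sigma beyond the closed-form max gradient a/(sigma sqrt(e))
  a <- 50; sig <- 20  # a/(sig*sqrt(e)) ~ 1.52 >= 1
  expect_error(bump_transform(matrix(c(50, 50, 50), 1), a, matrix(c(1, 0, 0), 1), sig),
               "rejected")
  # construct the same field on a grid and let the validator catch it
  fun <- function(p) {
    p <- if (is.matrix(p)) p else matrix(p, 1)
    r2 <- rowSums(sweep(p, 2, c(50, 50, 50), "-")^2)
    p + outer(a * exp(-r2 / (2 * sig^2)), c(1, 0, 0))
  }
  grid <- list(origin = c(0, 0, 0), spacing = c(5, 5, 5), dim = c(21L, 21L, 21L))
  gp <- jetmap:::expand_grid_points(grid)
  u <- fun(gp) - gp
  fld <- displacement_field(grid$origin, grid$spacing,
                            array(u, c(21L, 21L, 21L, 3L)))
  expect_false(validate_diffeomorphism(fld, gp)$pass)
})

test_that("field statistics: identity, translation, linear expansion", {
  grid_dim <- c(3L, 3L, 3L)
  zero <- array(0, c(grid_dim, 3L))
  fld0 <- displacement_field(c(0, 0, 0), c(10, 10, 10), zero)
  st0 <- field_statistics(fld0)
  expect_true(all(st0$per_node$u_mag == 0))
  expect_true(all(abs(st0$per_node$log_det) < 1e-12))
  expect_true(all(st0$per_node$dev_norm < 1e-12))

  v <- c(3, 4, 0)
  trans <- array(rep(v, each = 27), c(grid_dim, 3L))
  stv <- field_statistics(displacement_field(c(0, 0, 0), c(10, 10, 10), trans))
  expect_true(all(abs(stv$per_node$u_mag - 5) < 1e-12))
  expect_true(all(abs(stv$per_node$log_det) < 1e-10))

  # u(x) = 0.1 x: D phi = 1.1 I, log det = 3 log 1.1 (closed form)
  gp <- jetmap:::expand_grid_points(list(origin = c(0, 0, 0),
                                         spacing = c(10, 10, 10), dim = grid_dim))
  lin <- array(0.1 * gp, c(grid_dim, 3L))
  stl <- field_statistics(displacement_field(c(0, 0, 0), c(10, 10, 10), lin),
                          tangent = c(1, 1, 1))
  expect_equal(stl$per_node$log_det, rep(3 * log(1.1), 27), tolerance = 1e-10)
  expect_equal(stl$per_node$tangent_disp, rep(0.1 * sqrt(3), 27), tolerance = 1e-10)
})

test_that("transforms serialize to JSON and back", {
  f <- withr::local_tempfile(fileext = ".json")
  aff <- affine_transform(matrix(c(1, 0.2, 0, 0, 1, 0, 0, 0, 1.5), 3, 3), c(1, 2, 3))
  write_transform(aff, f)
  aff2 <- read_transform(f)
  expect_equal(aff2$matrix, aff$matrix)
  expect_equal(aff2$offset, aff$offset)

  set.seed(13)
  fld <- make_field("gaussian_bump", amplitude = 20, sigma = 120,
                    grid = list(origin = c(-10, 0, 5), spacing = c(40, 50, 60),
                                dim = c(4L, 3L, 5L)), seed = 8)
  write_transform(fld, f)
  fld2 <- read_transform(f)
  expect_equal(fld2$values, fld$values)
  x <- c(30, 60, 100)
  expect_equal(tf_evaluate(fld2, x), tf_evaluate(fld, x))

  comp <- compose_transforms(aff, fld)
  write_transform(comp, f)
  expect_equal(tf_evaluate(read_transform(f), x), tf_evaluate(comp, x))
  # nonlinear-only extraction returns the displacement-field component
  nl <- read_transform(f, nonlinear_only = TRUE)
  expect_s3_class(nl, "displacement_field")
  expect_equal(tf_evaluate(nl, x), tf_evaluate(fld, x))
})
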