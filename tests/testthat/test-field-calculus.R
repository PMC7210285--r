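# Field calculus: finite-difference derivatives, RDG closed forms, Hessian
# eigenvalues, and the rho*sign(lambda2) classification.

test_that("finite differences are exact for low-order polynomials", {
  n <- 9
  h <- 0.5
  x <- (0:(n - 1)) * h
  lin <- array(rep(x, times = n * n), dim = c(n, n, n))
  g <- scalar_grid(rep(0, 3), diag(h, 3), lin)
  f <- grid_fields(g)
  inner <- 3:(n - 2)
  expect_equal(max(abs(f$gx[inner, inner, inner] - 1)), 0, tolerance = 1e-12)
  expect_equal(max(abs(f$gy[inner, inner, inner])), 0, tolerance = 1e-12)
  expect_equal(max(abs(f$laplacian[inner, inner, inner])), 0,
               tolerance = 1e-12)

  quad <- array(rep(x^2, times = n * n), dim = c(n, n, n))
  fq <- grid_fields(scalar_grid(rep(0, 3), diag(h, 3), quad + 1))
  expect_equal(max(abs(fq$laplacian[inner, inner, inner] - 2)), 0,
               tolerance = 1e-10)
})

test_that("short axes are rejected by the 5-point stencils", {
  g <- scalar_grid(rep(0, 3), diag(1, 3), array(1:(4 * 5 * 5) + 0.0,
                                                dim = c(4, 5, 5)))
  expect_error(grid_fields(g), "fewer than 5")
})

test_that("FD Laplacian of a sampled Gaussian matches the closed form", {
  m <- gaussian_atoms(matrix(0, 1, 3), 1, 1)
  g <- suppressWarnings(
    sample_to_grid(m, rep(-3, 3), diag(0.1875, 3), c(33, 33, 33)))
  f <- grid_fields(g)
  expect_equal(f$laplacian[17, 17, 17], -6 * (1 / pi)^1.5, tolerance = 0.01)
})

test_that("RDG matches its closed forms for hydrogenic and Gaussian densities", {
  r <- seq(0.1, 2, by = 0.25)
  pts <- cbind(r, 0, 0)
  # hydrogenic rho = exp(-2r)/pi: s = (3 pi)^(-1/3) exp(2r/3)
  hyd <- promolecular_density(geometry("H", matrix(0, 1, 3)))
  dh <- density_at(hyd, pts)
  s_h <- rdg(dh$rho, sqrt(rowSums(dh$grad^2)))
  expect_rel_equal(s_h, (3 * pi)^(-1 / 3) * exp(2 * r / 3), 1e-6)
  expect_equal((3 * pi)^(-1 / 3), 0.4734, tolerance = 1e-4)  # s at the nucleus
  # Gaussian: s = r rho^(-1/3) / (3 pi^2)^(1/3)
  m <- gaussian_atoms(matrix(0, 1, 3), 1, 1)
  dg <- density_at(m, pts)
  s_g <- rdg(dg$rho, sqrt(rowSums(dg$grad^2)))
  expect_rel_equal(s_g, r * dg$rho^(-1 / 3) / (3 * pi^2)^(1 / 3), 1e-6)
  d1 <- density_at(m, matrix(c(1, 0, 0), 1, 3))
  expect_equal(rdg(d1$rho, sqrt(sum(d1$grad^2))), 0.7996, tolerance = 1e-4)
  # homogeneous limit and the density floor
  expect_identical(rdg(0.3, 0), 0)
  expect_identical(rdg(1e-13, 1e-5), Inf)
})

test_that("FD RDG converges to the analytic RDG at the stencil order", {
  m <- gaussian_atoms(matrix(0, 1, 3), 1, 1)
  err <- vapply(c(0.25, 0.125), function(h) {
    n <- 2 * round(4 / h) + 1
    g <- suppressWarnings(
      sample_to_grid(m, rep(-(n - 1) / 2 * h, 3), diag(h, 3), c(n, n, n)))
    f <- grid_fields(g)
    i <- (n + 1) / 2 + round(1 / h)  # interior point near (1, 0, 0)
    x <- (i - (n + 1) / 2) * h
    d <- density_at(m, matrix(c(x, 0, 0), 1, 3))
    s_an <- rdg(d$rho, sqrt(sum(d$grad^2)))
    abs(f$rdg[i, (n + 1) / 2, (n + 1) / 2] - s_an) / s_an
  }, numeric(1))
  expect_gt(err[1] / err[2], 8)  # ~16 for a 4th-order stencil
})

test_that("hessian_eigen sorts, preserves the trace, and rejects asymmetry", {
  expect_equal(hessian_eigen(diag(c(-2, 0.5, -1))), c(-2, -1, 0.5))
  expect_equal(hessian_eigen(matrix(0, 3, 3)), c(0, 0, 0))
  # spherical Gaussian at r = 1: tangential pair -2 rho, radial +2 rho
  rho1 <- (1 / pi)^1.5 * exp(-1)
  h <- diag(c(2 * rho1, -2 * rho1, -2 * rho1))
  expect_equal(hessian_eigen(h),
               c(-0.1321328, -0.1321328, 0.1321328), tolerance = 1e-6)
  set.seed(4)
  for (i in 1:25) {
    a <- matrix(rnorm(9), 3, 3)
    hs <- a + t(a)
    ev <- hessian_eigen(hs)
    expect_true(all(diff(ev) >= 0))
    expect_lt(abs(sum(ev) - sum(diag(hs))) / max(abs(ev), 1), 1e-10)
  }
  expect_error(hessian_eigen(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3)),
               "asymmetric")
})

test_that("eigen-trace identity holds voxel-wise on random and fixture grids", {
  set.seed(7)
  vals <- array(stats::rlnorm(9^3), dim = c(9, 9, 9))
  f <- grid_fields(scalar_grid(rep(0, 3), diag(0.4, 3), vals))
  scale <- max(abs(f$laplacian))
  expect_lt(max(abs(f$lambda1 + f$lambda2 + f$lambda3 - f$laplacian)) / scale,
            1e-8)
  fd <- dimer_fixture()$fields
  scale_d <- max(abs(fd$laplacian))
  expect_lt(max(abs(fd$lambda1 + fd$lambda2 + fd$lambda3 - fd$laplacian)) /
              scale_d, 1e-8)
  expect_true(all(fd$lambda1 <= fd$lambda2 & fd$lambda2 <= fd$lambda3))
  expect_true(all(fd$rdg >= 0))
  expect_equal(abs(fd$signed_rho), fd$rho, tolerance = 1e-14)
})

test_that("NCI classification follows the signed-density bands", {
  expect_identical(as.character(classify_nci(-0.05)), "bonding")
  expect_identical(as.character(classify_nci(0.01)), "vdW")
  expect_identical(as.character(classify_nci(0.05)), "repulsion")
  # boundary values belong to the vdW class
  expect_identical(as.character(classify_nci(c(-0.02, 0.02))),
                   c("vdW", "vdW"))
  # monotone: increasing signed density never steps a label backwards
  x <- sort(runif(200, -0.1, 0.1))
  lab <- as.integer(classify_nci(x))
  expect_true(all(diff(lab) >= 0))
})
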