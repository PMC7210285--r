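# vdW volume extraction: mask filters, connected components, measurement,
# and random-point sampling.

test_that("the dimer mask contains the midpoint voxel and respects thresholds", {
  dx <- dimer_fixture()
  mask <- build_vdw_mask(dx$fields)
  mid <- volsource:::point_to_voxel(dx$grid, matrix(0, 1, 3))
  expect_true(mask[mid])
  expect_true(mid %in% dx$volume$voxels)
  # raising the lower density bound to the upper one empties the mask
  expect_warning(m2 <- build_vdw_mask(dx$fields, rho_window = c(1e-3, 1e-3)),
                 "empty")
  expect_false(any(m2))
})

test_that("a single atom's mask excludes the nuclear region", {
  gx <- gauss_fixture()
  mask <- build_vdw_mask(gx$fields, s_iso = Inf)
  nuc <- volsource:::point_to_voxel(gx$grid, matrix(0, 1, 3))
  expect_false(mask[nuc])  # rho at the nucleus far exceeds 1e-3
})

test_that("mask filters commute", {
  dx <- dimer_fixture()
  f <- dx$fields
  m_s <- is.finite(f$rdg) & f$rdg <= 0.5
  m_rho <- f$rho >= 1e-6 & f$rho <= 1e-3
  m_band <- abs(f$signed_rho) <= 0.02
  combined <- build_vdw_mask(f)
  expect_identical(combined, (m_band & m_rho) & m_s)
  expect_identical(combined, (m_s & m_band) & m_rho)
})

test_that("connected components follow 26-connectivity and periodic wrap", {
  mask <- array(FALSE, dim = c(10, 10, 10))
  mask[2:4, 2:4, 2:4] <- TRUE
  mask[7:9, 7:9, 7:9] <- TRUE
  lab <- label_components(mask)
  expect_identical(max(lab), 2L)
  expect_identical(as.integer(table(lab[lab > 0])), c(27L, 27L))

  # touching at one corner merges under 26-connectivity
  mask2 <- array(FALSE, dim = c(10, 10, 10))
  mask2[2:4, 2:4, 2:4] <- TRUE
  mask2[5:7, 5:7, 5:7] <- TRUE
  expect_identical(max(label_components(mask2)), 1L)

  # a component crossing a face is whole on a periodic grid only
  mask3 <- array(FALSE, dim = c(10, 6, 6))
  mask3[c(1, 10), 3, 3] <- TRUE
  expect_identical(max(label_components(mask3, periodic = FALSE)), 2L)
  expect_identical(max(label_components(mask3, periodic = TRUE)), 1L)
})

test_that("volume and electron count come from direct voxel quadrature", {
  # constant density: n_e is exactly rho * V, V counts voxels
  grid <- pocket_fixture(integer(0), n = 6, h = 0.1)
  grid$values[] <- 1e-4
  f <- grid_fields(grid)
  v <- vdw_volume(f, s_iso = Inf, rho_window = c(5e-5, 2e-4), component = NA)
  expect_identical(length(v$voxels), 216L)
  expect_equal(v$V, 216 * 1e-3, tolerance = 1e-12)
  expect_equal(v$n_e, 216 * 1e-4 * 1e-3, tolerance = 1e-9)
  expect_error(measure_volume(structure(list(voxels = integer()),
                                        class = "vdw_volume")), "empty")
})

test_that("dimer n_e is confirmed by a half-spacing quadrature oracle", {
  dx <- dimer_fixture()
  v <- dx$volume
  # independent oracle: subdivide each member voxel 2x2x2 and sum the
  # analytic density at the subcentres
  idx0 <- arrayInd(v$voxels, dx$grid$shape) - 1L
  h <- 0.1875
  sub <- as.matrix(expand.grid(c(-0.25, 0.25), c(-0.25, 0.25),
                               c(-0.25, 0.25))) * h
  tot <- 0
  for (s in seq_len(nrow(sub))) {
    pts <- sweep(idx0 %*% dx$grid$axes, 2, dx$grid$origin + sub[s, ], "+")
    tot <- tot + sum(density_at(dx$model, pts)$rho) * voxel_volume(dx$grid) / 8
  }
  expect_equal(v$n_e, tot, tolerance = 0.01)
})

test_that("uniform sampling is reproducible and uniform over voxels", {
  grid <- pocket_fixture(cbind(c(3, 4), 3, 3))
  f <- grid_fields(grid)
  v <- vdw_volume(f, s_iso = Inf, rho_window = c(1e-5, 1e-3), band = Inf,
                  component = NA)
  expect_identical(length(v$voxels), 2L)
  s1 <- sample_points(v, 1000, seed = 9)
  s2 <- sample_points(v, 1000, seed = 9)
  expect_identical(s1$points, s2$points)
  expect_identical(s1$voxel, s2$voxel)
  # all points lie inside member voxels
  expect_true(all(volsource:::point_to_voxel(grid, s1$points) %in% v$voxels))
  # binomial check: 5000 +- 3 sigma per voxel at N = 10^4
  s3 <- sample_points(v, 1e4, seed = 10)
  counts <- table(factor(s3$voxel, levels = v$voxels))
  expect_true(all(abs(counts - 5000) < 3 * sqrt(1e4 * 0.25)))
})

test_that("metropolis sampling reaches the uniform target", {
  grid <- pocket_fixture(cbind(c(3, 4), 3, 3))
  f <- grid_fields(grid)
  v <- vdw_volume(f, s_iso = Inf, rho_window = c(1e-5, 1e-3), band = Inf,
                  component = NA)
  s <- sample_points(v, 1e4, seed = 3, method = "metropolis")
  freq <- as.numeric(table(factor(s$voxel, levels = v$voxels))) / 1e4
  expect_true(all(abs(freq - 0.5) < 0.05))
  expect_identical(
    sample_points(v, 50, seed = 5, method = "metropolis")$points,
    sample_points(v, 50, seed = 5, method = "metropolis")$points)
})

test_that("points below the density floor are inadmissible", {
  grid <- pocket_fixture(cbind(c(3, 4), 3, 3), rho_pocket = 1e-8)
  f <- grid_fields(grid)
  v <- vdw_volume(f, s_iso = Inf, rho_window = c(1e-9, 1e-7), band = Inf,
                  component = NA)
  expect_error(sample_points(v, 10, seed = 1), "no admissible voxels")
})

test_that("RDG error propagation is the stated combination", {
  expect_identical(rdg_relative_error(0, 0.5), 0)
  expect_equal(rdg_relative_error(0.01 * 0.5, 0.5), 0.01 * sqrt(1 + 16 / 9),
               tolerance = 1e-12)  # 0.016667
  expect_equal(rdg_relative_error(0.02, 0.4), 2 * rdg_relative_error(0.01, 0.4),
               tolerance = 1e-12)
})
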