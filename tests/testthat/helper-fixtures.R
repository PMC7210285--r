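# Shared fixtures, built once per test run and cached. All synthetic: the
# analytic Gaussian models provide closed-form oracles for every stage.

.fixture_cache <- new.env(parent = emptyenv())

with_fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# single Gaussian atom (alpha = 1, 1 electron) on a +-6 bohr, 64^3 box
gauss_fixture <- function() {
  with_fixture("gauss64", function() {
    model <- gaussian_atoms(matrix(0, 1, 3), alpha = 1, nelec = 1)
    grid <- sample_to_grid(model, rep(-6, 3), diag(12 / 63, 3), c(64, 64, 64))
    geom <- geometry("H", matrix(0, 1, 3))
    list(model = model, geom = geom, grid = grid,
         fields = grid_fields(grid),
         partition = bader_basins(grid, geom = geom))
  })
}

# symmetric vdW dimer (separation 6, alpha = 1) at 0.1875 bohr spacing
dimer_fixture <- function() {
  with_fixture("dimer", function() {
    dx <- dimer_density_grid()
    dx$fields <- grid_fields(dx$grid)
    dx$partition <- bader_basins(dx$grid, geom = dx$geometry)
    dx$volume <- vdw_volume(dx$fields)
    dx
  })
}

# the same dimer on a coarser lattice with the vdW volume widened to the
# whole density window (s filter off): a few thousand voxels, small enough
# for the exhaustive quadrature oracle
shell_fixture <- function() {
  with_fixture("shell", function() {
    dx <- dimer_density_grid(spacing = 0.32)
    dx$fields <- grid_fields(dx$grid)
    dx$partition <- bader_basins(dx$grid, geom = dx$geometry)
    dx$volume <- vdw_volume(dx$fields, s_iso = Inf)
    dx
  })
}

# constant-density grid plus a hand-picked low-density pocket: gives full
# control over which voxels enter the vdW mask
pocket_fixture <- function(pocket_idx, rho_pocket = 1e-4, n = 6, h = 0.1) {
  vals <- array(1, dim = c(n, n, n))
  vals[pocket_idx] <- rho_pocket
  grid <- scalar_grid(rep(0, 3), diag(h, 3), vals)
  grid
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / abs(expected)), tol)
}
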