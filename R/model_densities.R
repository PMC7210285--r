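# Analytic model densities with closed-form gradient and Laplacian.
# These are the synthetic-data generators: every downstream stage (fields,
# vdW volume, basins, source function) can be validated against their exact
# derivatives without any externally computed density.

#' Gaussian-atom model density
#'
#' A sum of spherical Gaussians, one per centre:
#' rho_a(r) = nelec * (alpha/pi)^(3/2) * exp(-alpha |r - c|^2),
#' which integrates exactly to `nelec` electrons. The Laplacian is
#' (4 alpha^2 r^2 - 6 alpha) * rho_a.
#'
#' @param centers numeric matrix (n x 3) of centres in Bohr.
#' @param alpha Gaussian exponents (1/bohr^2), recycled to n.
#' @param nelec electrons per centre, recycled to n.
#' @return an object of class `gaussian_model`.
#' @export
gaussian_atoms <- function(centers, alpha = 1, nelec = 1) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  n <- nrow(centers)
  alpha <- rep_len(as.numeric(alpha), n)
  nelec <- rep_len(as.numeric(nelec), n)
  if (n > 0 && (any(alpha <= 0) || any(nelec <= 0))) {
    stop("alpha and nelec must be positive")
  }
  structure(list(centers = centers, alpha = alpha, nelec = nelec),
            class = c("gaussian_model", "model_density"))
}

# Exponential-shell parameters for the built-in promolecular model.
# Slater-screening construction: a 1s core pair with exponent a1 = Z - 0.3125
# contributes 2*(a1^3/pi) exp(-2 a1 r); the remaining Z-2 electrons form a
# valence shell exp(-Zeff2 r) normalised to Z-2 electrons, Zeff2 from Slater's
# rules for the n=2 shell. Crude but strictly positive, monotonically
# decaying, and exactly normalised -- all the promolecular contract requires.
promol_shells <- function(Z) {
  if (Z == 1) {
    return(list(c = 1 / pi, zeta = 0.5))
  }
  if (!Z %in% c(6L, 7L, 8L)) {
    stop("promolecular model is tabulated for H, C, N, O only")
  }
  a1 <- Z - 0.3125
  zeta1 <- 1 / (2 * a1)
  c1 <- 2 * a1^3 / pi
  nval <- Z - 2
  zeff2 <- Z - 2 * 0.85 - (nval - 1) * 0.35
  zeta2 <- 1 / zeff2
  c2 <- nval / (8 * pi * zeta2^3)  # integral of c*exp(-r/zeta) is 8 pi c zeta^3
  list(c = c(c1, c2), zeta = c(zeta1, zeta2))
}

#' Promolecular model density
#'
#' The sum of unrelaxed spherical atomic densities, each a sum of exponential
#' shells `c_i exp(-r/zeta_i)` from a small built-in table (H, C, N, O). This
#' is the cheap surrogate density customarily used for reduced-density-
#' gradient analysis when no quantum-chemical density is at hand.
#'
#' @param geom a `vsf_geometry` with only H, C, N, O atoms.
#' @return an object of class `promolecular_model`.
#' @export
promolecular_density <- function(geom) {
  stopifnot(inherits(geom, "vsf_geometry"))
  shells <- lapply(geom$Z, promol_shells)
  structure(list(geometry = geom, shells = shells),
            class = c("promolecular_model", "model_density"))
}

#' Evaluate a model density and its derivatives at points
#'
#' Returns the density, Cartesian gradient and Laplacian from closed-form
#' expressions; these serve as the oracle for the finite-difference field
#' calculus.
#'
#' @param model a `model_density`.
#' @param points numeric matrix (n x 3), Bohr.
#' @return `list(rho, grad, laplacian)` with `grad` an n x 3 matrix.
#' @export
density_at <- function(model, points) UseMethod("density_at")

#' @export
density_at.gaussian_model <- function(model, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  stopifnot(all(is.finite(points)))
  n <- nrow(points)
  rho <- numeric(n)
  grad <- matrix(0, n, 3)
  lap <- numeric(n)
  for (a in seq_len(nrow(model$centers))) {
    d <- sweep(points, 2, model$centers[a, ], "-")
    r2 <- rowSums(d * d)
    al <- model$alpha[a]
    rho_a <- model$nelec[a] * (al / pi)^1.5 * exp(-al * r2)
    rho <- rho + rho_a
    grad <- grad + d * (-2 * al * rho_a)
    lap <- lap + (4 * al^2 * r2 - 6 * al) * rho_a
  }
  list(rho = rho, grad = grad, laplacian = lap)
}

#' @export
density_at.promolecular_model <- function(model, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  stopifnot(all(is.finite(points)))
  n <- nrow(points)
  rho <- numeric(n)
  grad <- matrix(0, n, 3)
  lap <- numeric(n)
  coords <- model$geometry$coords
  for (a in seq_len(nrow(coords))) {
    d <- sweep(points, 2, coords[a, ], "-")
    r <- sqrt(rowSums(d * d))
    r_safe <- pmax(r, 1e-10)
    sh <- model$shells[[a]]
    for (s in seq_along(sh$c)) {
      f <- sh$c[s] * exp(-r / sh$zeta[s])
      rho <- rho + f
      # radial derivative -f/zeta; Laplacian f'' + 2 f'/r
      grad <- grad + d * (-f / (sh$zeta[s] * r_safe))
      lap <- lap + f * (1 / sh$zeta[s]^2 - 2 / (sh$zeta[s] * r_safe))
    }
  }
  list(rho = rho, grad = grad, laplacian = lap)
}

#' Sample a model density onto a grid
#'
#' Evaluates the model at every voxel centre. Under the closed-system
#' contract the density must have decayed at the box boundary; a boundary
#' maximum above `boundary_tol` triggers a warning naming the value.
#'
#' @param model a `model_density`.
#' @param origin,axes,shape grid definition (Bohr; `axes` rows are step
#'   vectors; `shape` three voxel counts).
#' @param boundary_tol closed-system boundary threshold (e/bohr^3).
#' @param periodic flag attached to the returned grid.
#' @return a `scalar_grid` of the density.
#' @export
sample_to_grid <- function(model, origin, axes, shape,
                           boundary_tol = 1e-8, periodic = FALSE) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  tmp <- scalar_grid(origin, axes, array(0, dim = shape), periodic = periodic)
  pts <- voxel_centers(tmp)
  rho <- density_at(model, pts)$rho
  arr <- array(rho, dim = shape)
  if (!periodic && prod(shape) > 1) {
    face_max <- max(arr[c(1, shape[1]), , ], arr[, c(1, shape[2]), ],
                    arr[, , c(1, shape[3])])
    if (face_max > boundary_tol) {
      warning(sprintf(
        "density at grid boundary reaches %.3g e/bohr^3 (> %.1g); %s",
        face_max, boundary_tol,
        "the closed-system contract needs a larger box"))
    }
  }
  scalar_grid(origin, axes, arr, periodic = periodic)
}

#' Symmetric two-centre van der Waals fixture
#'
#' Two identical Gaussian atoms on the x axis at `+-separation/2`, emulating a
#' vdW-bound dimer: the midplane carries a low-density, low-gradient region
#' whose density must fall inside the sampling window (below 1e-3 e/bohr^3),
#' otherwise the two atoms are close enough to overlap covalently and the
#' constructor refuses.
#'
#' @param separation centre-to-centre distance, Bohr.
#' @param alpha Gaussian exponent (1/bohr^2).
#' @param nelec electrons per centre (length 1 or 2).
#' @return `list(geometry, model)`.
#' @export
make_vdw_dimer_fixture <- function(separation = 6, alpha = 1, nelec = c(1, 1)) {
  nelec <- rep_len(nelec, 2)
  centers <- rbind(c(-separation / 2, 0, 0), c(separation / 2, 0, 0))
  model <- gaussian_atoms(centers, alpha = alpha, nelec = nelec)
  mid_rho <- density_at(model, matrix(0, 1, 3))$rho
  if (mid_rho > 1e-3) {
    stop(sprintf(
      "midpoint density %.3g e/bohr^3 exceeds 1e-3: separation too small for a vdW fixture",
      mid_rho))
  }
  elem <- .ELEMENTS[pmax(1L, round(nelec))]
  list(geometry = geometry(elem, centers, Z = pmax(1L, as.integer(round(nelec)))),
       model = model)
}

#' Dimer fixture sampled onto a mirror-symmetric grid
#'
#' Builds the two-Gaussian dimer and samples it on an odd-count grid whose
#' central voxel sits exactly at the midpoint, so mirror symmetry about the
#' x = 0 plane is exact to floating point. The box extends `pad` Bohr beyond
#' each nucleus (default 4.8, enough for an alpha = 1 Gaussian to fall below
#' the 1e-8 boundary threshold).
#'
#' @param separation,alpha,nelec passed to [make_vdw_dimer_fixture()].
#' @param spacing voxel edge, Bohr.
#' @param pad box padding beyond the nuclei, Bohr.
#' @return `list(geometry, model, grid)`.
#' @export
dimer_density_grid <- function(separation = 6, alpha = 1, nelec = c(1, 1),
                               spacing = 0.1875, pad = 4.8) {
  fx <- make_vdw_dimer_fixture(separation, alpha, nelec)
  half <- c(separation / 2 + pad, pad, pad)
  nhalf <- ceiling(half / spacing)
  shape <- 2L * as.integer(nhalf) + 1L
  origin <- -nhalf * spacing
  grid <- sample_to_grid(fx$model, origin, diag(spacing, 3), shape)
  list(geometry = fx$geometry, model = fx$model, grid = grid)
}
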