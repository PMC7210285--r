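# The source function and its volumetric extension. The local source
# LS(r, r') = -(1/4pi) lap(r') / |r - r'| integrated over a basin gives
# SF(r, Omega), the basin's contribution to the density at r; summed over all
# basins it reconstructs rho(r) (Green-function identity for a closed system
# whose density decays at the boundary). Integrating SF over the vdW volume
# by Monte Carlo gives the volumetric source function VSF(V_vdW, Omega).

#' Local source kernel
#'
#' `LS(r, r') = -(1/4pi) * lap(r') / |r - r'|`: a negative Laplacian at `r'`
#' is a *source* (enriching the density at `r`), a positive one a *sink*.
#' The coincident case errors; inside [sf_at_point()] the self-cell is
#' handled by the equal-volume-sphere rule instead.
#'
#' @param laplacian Laplacian of the density at `r'` (e/bohr^5).
#' @param r,r_prime points in Bohr (vectors of length 3 or n x 3 matrices).
#' @return LS values, e/bohr^6 (density per unit source volume).
#' @export
local_source <- function(laplacian, r, r_prime) {
  r <- matrix(as.numeric(r), ncol = 3)
  r_prime <- matrix(as.numeric(r_prime), ncol = 3)
  d <- sqrt(rowSums((r - r_prime)^2))
  if (any(d == 0)) {
    stop("local source is singular at r = r'; use sf_at_point's self-cell rule")
  }
  -laplacian / (4 * pi * d)
}

# shared validation + dispatch into the compiled SF accumulator
.sf_eval <- function(points, partition, laplacian, grid) {
  points <- matrix(as.numeric(points), ncol = 3)
  stopifnot(inherits(partition, "basin_partition"))
  lap <- if (inherits(laplacian, "scalar_grid")) laplacian$values else laplacian
  stopifnot(length(lap) == prod(grid$shape))
  self <- point_to_voxel(grid, points) - 1L
  .sf_eval_cpp(points, self, as.vector(lap), grid$shape, grid$origin,
               grid$axes, voxel_volume(grid), partition$label,
               as.integer(partition$frac_index - 1L), partition$frac_w,
               grid$periodic)
}

#' Source function of every basin at reference points
#'
#' `SF(r, Omega) = -(1/4pi) sum_vox w(vox, Omega) lap(vox) V_vox / |r - r_vox|`
#' over *all* voxels (no cutoff radius: full reconstruction is what makes the
#' reliability parameter meaningful), with the voxel containing `r` replaced
#' by the equal-volume-sphere correction `-lap * R^2 / 2`,
#' `R = (3 V_vox / 4 pi)^(1/3)`.
#'
#' @param points n x 3 matrix of reference points, Bohr (inside the grid).
#' @param partition a `basin_partition`.
#' @param laplacian the Laplacian field: 3-D array or `scalar_grid` matching
#'   the partition's grid.
#' @param grid the grid (defaults to the partition's).
#' @return n x M matrix of SF values (e/bohr^3).
#' @export
sf_at_point <- function(points, partition, laplacian, grid = partition$grid) {
  .sf_eval(points, partition, laplacian, grid)
}

#' Density reconstruction check at reference points
#'
#' Sums the source function over all basins and compares with the
#' (trilinearly interpolated) density at the same points.
#'
#' @inheritParams sf_at_point
#' @param rho_grid density grid for the reference values.
#' @return `list(rho_hat, rho_ref, rel_error, sf)`.
#' @export
reconstruct_density <- function(points, partition, laplacian,
                                rho_grid = partition$grid,
                                grid = partition$grid) {
  sf <- .sf_eval(points, partition, laplacian, grid)
  rho_hat <- rowSums(sf)
  rho_ref <- interp_grid(rho_grid, matrix(as.numeric(points), ncol = 3))
  list(rho_hat = rho_hat, rho_ref = rho_ref,
       rel_error = abs(rho_hat - rho_ref) / abs(rho_ref), sf = sf)
}

#' Monte-Carlo volumetric source function
#'
#' `VSF(V_vdW, Omega) ~ V_vdW * mean_i SF(r_i, Omega)` over the sampled
#' points. The electron count `n_e` in the denominators of VSF% and of the
#' Gatti reliability parameter
#' `f1 = 100 * (n_e - sum_Omega VSF) / n_e`
#' is the direct density quadrature over the volume, so f1 is a genuine
#' reconstruction check, not a tautology. The Monte-Carlo standard error per
#' basin is `V_vdW * sd(SF) / sqrt(N)`.
#'
#' @param volume a `vdw_volume`.
#' @param sample a `point_sample` drawn from it.
#' @param partition a `basin_partition`.
#' @param laplacian Laplacian field (array or `scalar_grid`).
#' @return an object of class `vsf_result`: `vsf`, `vsf_percent`,
#'   `mc_stderr`, `n_e`, `V`, `f1`, `N`, `seed`, `method`, `sf_samples`.
#' @export
vsf_monte_carlo <- function(volume, sample, partition, laplacian) {
  stopifnot(inherits(volume, "vdw_volume"), inherits(sample, "point_sample"))
  me <- measure_volume(volume)
  if (me$n_e <= 0) stop("n_e is zero: VSF% and f1 are undefined")
  sf <- .sf_eval(sample$points, partition, laplacian, volume$grid)
  vsf <- me$V * colMeans(sf)
  stderr <- me$V * apply(sf, 2, stats::sd) / sqrt(sample$n)
  if (sample$n == 1) stderr <- rep(NA_real_, length(vsf))
  structure(list(
    vsf = vsf,
    vsf_percent = 100 * vsf / me$n_e,
    mc_stderr = stderr,
    n_e = me$n_e, V = me$V,
    f1 = 100 * (me$n_e - sum(vsf)) / me$n_e,
    N = sample$n, seed = sample$seed, method = sample$method,
    sf_samples = sf,
    atom_of_basin = partition$atom_of_basin
  ), class = "vsf_result")
}

#' Exhaustive quadrature oracle for the VSF
#'
#' Evaluates the source function at every member voxel centre and sums with
#' the voxel volume — the brute-force reference the Monte-Carlo estimate is
#' checked against. The midpoint sum is promoted to the voxel-average rule
#' through the identity `lap SF(r, Omega) = w(r, Omega) * lap rho(r)` (the
#' Poisson structure of the source function), keeping the oracle consistent
#' with the voxel-average `n_e` of [measure_volume()]. Refuses volumes above
#' `max_voxels`.
#'
#' @param volume a `vdw_volume` (at most `max_voxels` voxels).
#' @param partition a `basin_partition`.
#' @param laplacian Laplacian field.
#' @param max_voxels size guard.
#' @return list with per-basin `vsf`, plus `n_e`, `V`, `f1`.
#' @export
vsf_quadrature <- function(volume, partition, laplacian, max_voxels = 1e4) {
  stopifnot(inherits(volume, "vdw_volume"))
  nv <- length(volume$voxels)
  if (nv == 0) stop("empty vdW volume")
  if (nv > max_voxels) {
    stop("volume has ", nv, " voxels (> ", max_voxels,
         "); use vsf_monte_carlo instead")
  }
  grid <- volume$grid
  idx0 <- arrayInd(volume$voxels, grid$shape) - 1L
  centers <- sweep(idx0 %*% grid$axes, 2, grid$origin, "+")
  sf <- .sf_eval(centers, partition, laplacian, grid)
  # voxel-average correction per basin: (h^2/24) w(v, Omega) lap(v)
  h2m <- mean(rowSums(grid$axes^2))
  w <- basin_weights(partition, volume$voxels)
  corr <- colSums(w * (volume$laplacian * (h2m / 24)))
  vsf <- (colSums(sf) + corr) * voxel_volume(grid)
  me <- measure_volume(volume)
  list(vsf = vsf, n_e = me$n_e, V = me$V,
       f1 = 100 * (me$n_e - sum(vsf)) / me$n_e)
}

#' @export
print.vsf_result <- function(x, ...) {
  cat(sprintf("VSF over V = %.4f bohr^3 (n_e = %.6g e, N = %d %s samples)\n",
              x$V, x$n_e, x$N, x$method))
  tab <- data.frame(basin = seq_along(x$vsf), VSF = x$vsf,
                    VSF_percent = x$vsf_percent, stderr = x$mc_stderr)
  print(tab, row.names = FALSE, digits = 5)
  cat(sprintf("sum VSF = %.6g e, f1 = %.3f%%\n", sum(x$vsf), x$f1))
  invisible(x)
}
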