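# Extraction of the van der Waals interaction volume V_vdW from a field
# bundle: RDG isovalue + density window + rho*sign(lambda2) band filters,
# connected-component isolation, volume/electron-count measurement, and
# random-point sampling inside the volume.

#' Boolean vdW mask from a field bundle
#'
#' A voxel belongs to the vdW volume iff `s <= s_iso`,
#' `rho_min <= rho <= rho_max` and `|rho*sign(lambda2)| <= band`. Defaults:
#' RDG isovalue 0.5 (the customary midpoint of the 0.45-0.55 range for
#' computed densities), density window 1e-6 to 1e-3 e/bohr^3, band 0.02 a.u.
#'
#' @param fields a `vsf_fields` bundle.
#' @param s_iso RDG isovalue.
#' @param rho_window length-2 numeric, density window in e/bohr^3.
#' @param band rho*sign(lambda2) half-width, a.u.
#' @return logical 3-D array.
#' @export
build_vdw_mask <- function(fields, s_iso = 0.5, rho_window = c(1e-6, 1e-3),
                           band = 0.02) {
  stopifnot(inherits(fields, "vsf_fields"), length(rho_window) == 2)
  mask <- is.finite(fields$rdg) & fields$rdg <= s_iso &
    fields$rho >= rho_window[1] & fields$rho <= rho_window[2] &
    abs(fields$signed_rho) <= band
  if (!any(mask)) {
    warning("vdW mask is empty under the given thresholds")
  }
  mask
}

#' Label connected components of a voxel mask
#'
#' 26-connectivity; components are numbered by descending voxel count
#' (label 1 is the largest). Periodic grids wrap across faces.
#'
#' @param mask logical 3-D array.
#' @param periodic logical.
#' @return integer 3-D array of labels (0 outside the mask).
#' @export
label_components <- function(mask, periodic = FALSE) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  lab <- .label_components_cpp(as.vector(mask), dim(mask), isTRUE(periodic))
  array(lab, dim(mask))
}

#' Build a vdW interaction volume
#'
#' Applies the three NCI filters, isolates connected components and selects
#' one (by default the largest), and measures its volume and electron
#' content by direct voxel quadrature.
#'
#' @param fields a `vsf_fields` bundle.
#' @param s_iso,rho_window,band filter thresholds (see [build_vdw_mask()]).
#' @param component which component to keep (1 = largest); `NA` keeps the
#'   whole mask.
#' @return an object of class `vdw_volume` with elements `voxels` (1-based
#'   flat indices), `V` (bohr^3), `n_e` (electrons by quadrature),
#'   `thresholds`, `n_components`, `component`, and grid bookkeeping. An
#'   empty selection yields a zero-voxel volume (with a warning upstream).
#' @export
vdw_volume <- function(fields, s_iso = 0.5, rho_window = c(1e-6, 1e-3),
                       band = 0.02, component = 1L) {
  mask <- build_vdw_mask(fields, s_iso, rho_window, band)
  grid <- fields$grid
  lab <- label_components(mask, grid$periodic)
  ncomp <- max(lab)
  if (is.na(component)) {
    sel <- which(as.vector(mask))
  } else {
    sel <- which(as.vector(lab) == component)
  }
  vv <- voxel_volume(grid)
  rho_sel <- as.vector(fields$rho)[sel]
  # voxel-average quadrature: the voxel mean of rho is the midpoint value
  # plus (1/24) sum_i h_i^2 d2rho/dx_i^2 + O(h^4), so n_e matches the true
  # integral (and hence the Monte-Carlo route) to fourth order
  h2 <- rowSums(grid$axes^2)
  corr <- (h2[1] * as.vector(fields$hxx)[sel] +
             h2[2] * as.vector(fields$hyy)[sel] +
             h2[3] * as.vector(fields$hzz)[sel]) / 24
  lap_sel <- as.vector(fields$laplacian)[sel]
  structure(list(
    voxels = sel,
    V = length(sel) * vv,
    n_e = sum(rho_sel + corr) * vv,
    n_e_midpoint = sum(rho_sel) * vv,
    rho = rho_sel,
    laplacian = lap_sel,
    thresholds = list(s_iso = s_iso, rho_window = rho_window, band = band),
    component = component,
    n_components = ncomp,
    component_sizes = if (ncomp > 0) tabulate(as.vector(lab)[as.vector(lab) > 0]) else integer(),
    grid = grid
  ), class = "vdw_volume")
}

#' @export
print.vdw_volume <- function(x, ...) {
  cat(sprintf(
    "VdwVolume: %d voxels, V = %.4f bohr^3, n_e = %.6g e (%d component%s)\n",
    length(x$voxels), x$V, x$n_e, x$n_components,
    if (x$n_components == 1) "" else "s"))
  invisible(x)
}

#' Volume and electron count of a vdW volume
#'
#' `V_vdW` is voxel count times voxel volume; `n_e` is the direct density
#' quadrature over member voxels (voxel-average rule: midpoint value plus
#' the `h^2/24` Laplacian correction, fourth-order accurate) — the reference
#' value against which the Monte-Carlo route is checked. The plain midpoint
#' sum is kept as `n_e_midpoint`.
#'
#' @param volume a `vdw_volume`.
#' @return `list(V, n_e)`.
#' @export
measure_volume <- function(volume) {
  stopifnot(inherits(volume, "vdw_volume"))
  if (length(volume$voxels) == 0) stop("empty vdW volume")
  list(V = volume$V, n_e = volume$n_e)
}

# 26-neighbour flat-index offsets usable for the Metropolis walk
.neighbor_offsets <- function() {
  o <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  as.matrix(o[!(o$di == 0 & o$dj == 0 & o$dk == 0), ])
}

#' Sample random points inside a vdW volume
#'
#' `uniform`: a member voxel is chosen uniformly and the point jittered
#' uniformly within it — exact sampling of the uniform density on the volume.
#' `metropolis`: a Metropolis-Hastings random walk over member voxels with a
#' uniform target (symmetric 26-neighbour proposals, rejected moves stay),
#' with burn-in and thinning to reduce autocorrelation; provided to mirror
#' convergence assessments done with that sampler. Points whose voxel density
#' falls below `rho_reject` are rejected and redrawn. Fully reproducible
#' under a fixed seed.
#'
#' @param volume a `vdw_volume`.
#' @param n number of points (>= 1).
#' @param seed integer RNG seed.
#' @param method `"uniform"` or `"metropolis"`.
#' @param burn_in,thin Metropolis parameters.
#' @param rho_reject density floor for admissible points (e/bohr^3).
#' @return an object of class `point_sample`: list with `points` (n x 3,
#'   Bohr), `voxel` (1-based flat indices), `n`, `seed`, `method`.
#' @export
sample_points <- function(volume, n, seed = 42L,
                          method = c("uniform", "metropolis"),
                          burn_in = 100L, thin = 5L, rho_reject = 1e-6) {
  method <- match.arg(method)
  stopifnot(inherits(volume, "vdw_volume"), n >= 1)
  admissible <- volume$voxels[volume$rho >= rho_reject]
  if (length(admissible) == 0) {
    stop("no admissible voxels: all member densities below ", rho_reject)
  }
  grid <- volume$grid
  nvec <- grid$shape
  set.seed(as.integer(seed))
  if (method == "uniform") {
    vox <- admissible[sample.int(length(admissible), n, replace = TRUE)]
  } else {
    member <- array(FALSE, nvec)
    member[admissible] <- TRUE
    offs <- .neighbor_offsets()
    ijk <- arrayInd(admissible[1], nvec)  # deterministic start: first voxel
    cur <- as.integer(ijk)
    steps <- burn_in + n * thin
    moves <- offs[sample.int(nrow(offs), steps, replace = TRUE), , drop = FALSE]
    keep <- matrix(0L, n, 3)
    kept <- 0L
    for (t in seq_len(steps)) {
      prop <- cur + moves[t, ]
      if (grid$periodic) {
        prop <- ((prop - 1L) %% nvec) + 1L
      }
      inside <- all(prop >= 1L & prop <= nvec)
      if (inside && member[prop[1], prop[2], prop[3]]) cur <- prop
      if (t > burn_in && (t - burn_in) %% thin == 0) {
        kept <- kept + 1L
        keep[kept, ] <- cur
      }
    }
    vox <- as.integer(keep[, 1] + nvec[1] * (keep[, 2] - 1L) +
                        nvec[1] * nvec[2] * (keep[, 3] - 1L))
  }
  jit <- matrix(stats::runif(3 * n, -0.5, 0.5), n, 3)
  idx0 <- arrayInd(vox, nvec) - 1L
  pts <- sweep((idx0 + jit) %*% grid$axes, 2, grid$origin, "+")
  structure(list(points = pts, voxel = vox, n = as.integer(n),
                 seed = as.integer(seed), method = method),
            class = "point_sample")
}

#' Relative RDG error from a density fluctuation
#'
#' Propagates a density uncertainty `delta_rho` into a relative RDG error as
#' `sqrt((d/rho)^2 + c (d/rho)^2)` with `c = (4/3)^2` from the rho^(4/3)
#' term. A convergence diagnostic (reported against the sample size), not a
#' rigorous error bar.
#'
#' @param delta_rho density fluctuation, e/bohr^3.
#' @param rho density, e/bohr^3 (> 0).
#' @param c coefficient of the second term, default `(4/3)^2`.
#' @return relative RDG error (dimensionless).
#' @export
rdg_relative_error <- function(delta_rho, rho, c = (4 / 3)^2) {
  stopifnot(all(rho > 0))
  (delta_rho / rho) * sqrt(1 + c)
}
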