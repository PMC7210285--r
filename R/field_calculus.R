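# Finite-difference field calculus on volumetric grids: gradient, Hessian,
# Laplacian, ordered Hessian eigenvalues, the reduced density gradient (RDG)
# and the rho*sign(lambda2) classification field.

# first derivative along one lattice axis (unit fractional spacing).
# Interior: 5-point central stencil, O(h^4). Non-periodic boundaries: one- or
# two-sided stencils of O(h^2). Periodic grids wrap and stay O(h^4).
d1_axis <- function(arr, axis, periodic = FALSE) {
  dm <- dim(arr)
  n <- dm[axis]
  if (n < 5) stop("grid axis ", axis, " has fewer than 5 points; ",
                  "the 5-point stencils need >= 5")
  perm <- c(axis, setdiff(1:3, axis))
  x <- aperm(arr, perm)
  m <- matrix(x, n)
  out <- matrix(0, n, ncol(m))
  if (periodic) {
    im2 <- ((seq_len(n) - 3) %% n) + 1
    im1 <- ((seq_len(n) - 2) %% n) + 1
    ip1 <- (seq_len(n) %% n) + 1
    ip2 <- ((seq_len(n) + 1) %% n) + 1
    out <- (m[im2, , drop = FALSE] - 8 * m[im1, , drop = FALSE] +
              8 * m[ip1, , drop = FALSE] - m[ip2, , drop = FALSE]) / 12
  } else {
    i <- 3:(n - 2)
    out[i, ] <- (m[i - 2, , drop = FALSE] - 8 * m[i - 1, , drop = FALSE] +
                   8 * m[i + 1, , drop = FALSE] - m[i + 2, , drop = FALSE]) / 12
    out[1, ] <- (-3 * m[1, ] + 4 * m[2, ] - m[3, ]) / 2
    out[2, ] <- (m[3, ] - m[1, ]) / 2
    out[n - 1, ] <- (m[n, ] - m[n - 2, ]) / 2
    out[n, ] <- (3 * m[n, ] - 4 * m[n - 1, ] + m[n - 2, ]) / 2
  }
  aperm(array(out, dm[perm]), order(perm))
}

# eigenvalues of a field of symmetric 3x3 matrices, ascending, vectorised
# (trigonometric closed form; the trace is preserved exactly by construction).
eig3_sym <- function(h11, h12, h13, h22, h23, h33) {
  q <- (h11 + h22 + h33) / 3
  p1 <- h12^2 + h13^2 + h23^2
  a <- h11 - q; b <- h22 - q; c <- h33 - q
  p2 <- a^2 + b^2 + c^2 + 2 * p1
  p <- sqrt(p2 / 6)
  ps <- ifelse(p > 0, p, 1)
  b11 <- a / ps; b22 <- b / ps; b33 <- c / ps
  b12 <- h12 / ps; b13 <- h13 / ps; b23 <- h23 / ps
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  l3 <- q + 2 * p * cos(phi)
  l1 <- q + 2 * p * cos(phi + 2 * pi / 3)
  # trace-preserving middle eigenvalue, clamped into [l1, l3] against rounding
  l2 <- pmin(pmax(3 * q - l1 - l3, l1), l3)
  zero <- p == 0
  if (any(zero)) {
    l1[zero] <- q[zero]; l2[zero] <- q[zero]; l3[zero] <- q[zero]
  }
  list(l1 = l1, l2 = l2, l3 = l3)
}

#' Ordered eigenvalues of a symmetric 3x3 Hessian
#'
#' Returns `(lambda1, lambda2, lambda3)` in ascending order; the sum equals
#' the trace (the Laplacian) to floating-point accuracy by construction.
#'
#' @param h symmetric 3x3 numeric matrix.
#' @param sym_tol maximum allowed asymmetry.
#' @return numeric length 3, ascending.
#' @export
hessian_eigen <- function(h, sym_tol = 1e-8) {
  h <- matrix(as.numeric(h), 3, 3)
  if (max(abs(h - t(h))) > sym_tol) {
    stop("Hessian is asymmetric beyond tolerance ", sym_tol)
  }
  e <- eig3_sym(h[1, 1], h[1, 2], h[1, 3], h[2, 2], h[2, 3], h[3, 3])
  c(e$l1, e$l2, e$l3)
}

#' Reduced density gradient
#'
#' `s = |grad rho| / (2 (3 pi^2)^(1/3) rho^(4/3))`, the dimensionless measure
#' of deviation from a homogeneous electron distribution. Densities at or
#' below `rho_floor` give `Inf` (such points are excluded from volume masks).
#'
#' @param rho density, e/bohr^3.
#' @param grad_norm gradient magnitude, e/bohr^4.
#' @param rho_floor density floor below which s is reported as `Inf`.
#' @return dimensionless s, same shape as `rho`.
#' @export
rdg <- function(rho, grad_norm, rho_floor = 1e-12) {
  cf <- 2 * (3 * pi^2)^(1 / 3)
  s <- grad_norm / (cf * pmax(rho, rho_floor)^(4 / 3))
  s[rho <= rho_floor] <- Inf
  s
}

#' Classify an interaction point by rho * sign(lambda2)
#'
#' Bonding below `-band`, steric repulsion above `+band`, van der Waals in
#' between; the exact boundary values are assigned to the vdW class.
#'
#' @param signed_rho the field rho * sign(lambda2), a.u.
#' @param band classification half-width, default 0.02 a.u.
#' @return factor with levels `bonding`, `vdW`, `repulsion`.
#' @export
classify_nci <- function(signed_rho, band = 0.02) {
  stopifnot(all(is.finite(signed_rho)))
  lab <- ifelse(signed_rho < -band, "bonding",
                ifelse(signed_rho > band, "repulsion", "vdW"))
  factor(lab, levels = c("bonding", "vdW", "repulsion"))
}

#' Full derivative field bundle of a density grid
#'
#' Computes by finite differences the Cartesian gradient, Hessian, Laplacian,
#' ordered Hessian eigenvalues, RDG and the rho*sign(lambda2) classification
#' field. Derivatives are taken along the lattice axes (5-point interior
#' stencils; one-sided at non-periodic boundaries; periodic grids wrap) and
#' transformed to Cartesian form through the inverse cell matrix, so
#' non-orthogonal cells are handled.
#'
#' The sign of lambda2 is snapped to +1 where |lambda2| falls below
#' `lambda2_tol`: the vdW regime is characterised by lambda2 ~ 0 and a bare
#' `sign()` would be noise-driven there.
#'
#' @param grid a `scalar_grid` of the density.
#' @param lambda2_tol snap tolerance for sign(lambda2).
#' @param rho_floor density floor for the RDG.
#' @return an object of class `vsf_fields`: list with 3-D arrays `rho`,
#'   `gx`, `gy`, `gz`, `grad_norm`, `laplacian`, `lambda1..3`, `rdg`,
#'   `signed_rho`, plus the originating `grid`.
#' @export
grid_fields <- function(grid, lambda2_tol = 1e-10, rho_floor = 1e-12) {
  stopifnot(inherits(grid, "scalar_grid"))
  per <- grid$periodic
  v <- grid$values
  gu <- lapply(1:3, function(a) d1_axis(v, a, per))
  # Hessian in lattice coordinates; axis operators commute, so H is symmetric
  hu <- list()
  for (a in 1:3) for (b in a:3) {
    hu[[paste0(a, b)]] <- d1_axis(gu[[b]], a, per)
  }
  B <- solve(grid$axes)  # grad_x = B %*% grad_u
  gx <- B[1, 1] * gu[[1]] + B[1, 2] * gu[[2]] + B[1, 3] * gu[[3]]
  gy <- B[2, 1] * gu[[1]] + B[2, 2] * gu[[2]] + B[2, 3] * gu[[3]]
  gz <- B[3, 1] * gu[[1]] + B[3, 2] * gu[[2]] + B[3, 3] * gu[[3]]
  # H_x = B H_u B^T, expanded per component
  HU <- function(a, b) if (a <= b) hu[[paste0(a, b)]] else hu[[paste0(b, a)]]
  hx <- list()
  for (r in 1:3) for (s in r:3) {
    acc <- 0
    for (a in 1:3) for (b in 1:3) {
      acc <- acc + B[r, a] * B[s, b] * HU(a, b)
    }
    hx[[paste0(r, s)]] <- acc
  }
  lap <- hx[["11"]] + hx[["22"]] + hx[["33"]]
  ev <- eig3_sym(hx[["11"]], hx[["12"]], hx[["13"]],
                 hx[["22"]], hx[["23"]], hx[["33"]])
  gn <- sqrt(gx^2 + gy^2 + gz^2)
  s <- array(rdg(as.vector(v), as.vector(gn), rho_floor), dim = dim(v))
  l2 <- ev$l2
  sgn <- sign(l2)
  sgn[abs(l2) < lambda2_tol] <- 1  # lambda2 ~ 0 counts as non-negative
  structure(list(
    grid = grid, rho = v, gx = gx, gy = gy, gz = gz, grad_norm = gn,
    laplacian = lap,
    hxx = hx[["11"]], hyy = hx[["22"]], hzz = hx[["33"]],
    lambda1 = array(ev$l1, dim(v)), lambda2 = array(ev$l2, dim(v)),
    lambda3 = array(ev$l3, dim(v)),
    rdg = s, signed_rho = v * sgn, lambda2_tol = lambda2_tol
  ), class = "vsf_fields")
}

#' @export
print.vsf_fields <- function(x, ...) {
  cat(sprintf("FieldBundle on %d x %d x %d grid (rho, grad, Hessian eigenvalues, RDG)\n",
              dim(x$rho)[1], dim(x$rho)[2], dim(x$rho)[3]))
  invisible(x)
}
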