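# Volumetric grid data model and Gaussian cube / XYZ input-output.
# Internal unit is atomic units (Bohr, e/bohr^3) everywhere; conversion from
# Angstrom happens only at the I/O boundary.

#' Bohr per Angstrom conversion constant
#' @keywords internal
BOHR_PER_ANG <- 1.8897259886

.ELEMENTS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr"
)

element_to_z <- function(symbols) {
  z <- match(symbols, .ELEMENTS)
  if (anyNA(z)) {
    bad <- unique(symbols[is.na(z)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         "; supported: ", paste(.ELEMENTS, collapse = " "), call. = FALSE)
  }
  z
}

#' Molecular geometry in atomic units
#'
#' Holds chemical symbols, atomic numbers and Cartesian nuclear positions in
#' Bohr. These nuclei are the attractors whose atomic basins partition the
#' electron density.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix, one row per atom, columns x, y, z in Bohr.
#' @param Z optional integer atomic numbers; derived from `elements` if absent.
#' @return an object of class `vsf_geometry`.
#' @export
geometry <- function(elements, coords, Z = NULL) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  if (is.null(Z)) Z <- element_to_z(elements)
  stopifnot(length(elements) == nrow(coords), length(Z) == nrow(coords))
  if (any(Z < 1)) stop("atomic numbers must be >= 1")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  structure(list(elements = as.character(elements), Z = as.integer(Z),
                 coords = coords),
            class = "vsf_geometry")
}

#' @export
print.vsf_geometry <- function(x, ...) {
  cat("Geometry:", length(x$Z), "atoms (", paste(x$elements, collapse = " "),
      "), coordinates in Bohr\n")
  invisible(x)
}

#' Volumetric scalar field on a regular lattice
#'
#' A 3-D scalar field (electron density or any derived field) sampled at voxel
#' centres `origin + i*a1 + j*a2 + k*a3` with zero-based indices. The flag
#' `periodic` records whether the lattice tiles space (plane-wave densities)
#' or is an isolated box decaying at its boundary.
#'
#' @param origin numeric length 3, Bohr.
#' @param axes 3x3 numeric matrix, rows are the three voxel step vectors (Bohr).
#' @param values 3-D numeric array; `values[i, j, k]` sits at
#'   `origin + (i-1)*a1 + (j-1)*a2 + (k-1)*a3`.
#' @param periodic logical flag.
#' @return an object of class `scalar_grid`.
#' @export
scalar_grid <- function(origin, axes, values, periodic = FALSE) {
  origin <- as.numeric(origin)
  axes <- matrix(as.numeric(axes), 3, 3)
  stopifnot(length(origin) == 3, length(dim(values)) == 3)
  if (abs(det(axes)) <= 0) stop("voxel volume |det(axes)| must be positive")
  if (!all(is.finite(values))) stop("grid values must all be finite")
  structure(list(origin = origin, axes = axes, shape = dim(values),
                 values = values, periodic = isTRUE(periodic)),
            class = "scalar_grid")
}

#' @export
print.scalar_grid <- function(x, ...) {
  cat(sprintf("ScalarGrid %d x %d x %d, voxel volume %.6g bohr^3, %s\n",
              x$shape[1], x$shape[2], x$shape[3], voxel_volume(x),
              if (x$periodic) "periodic" else "non-periodic"))
  invisible(x)
}

#' Voxel volume of a grid in bohr^3
#' @param grid a `scalar_grid`.
#' @export
voxel_volume <- function(grid) abs(det(grid$axes))

#' Cartesian centres of all voxels (n_voxels x 3, Bohr), first index fastest
#' @param grid a `scalar_grid`.
#' @export
voxel_centers <- function(grid) {
  n <- grid$shape
  idx <- cbind(
    rep.int(seq_len(n[1]) - 1L, n[2] * n[3]),
    rep.int(rep(seq_len(n[2]) - 1L, each = n[1]), n[3]),
    rep(seq_len(n[3]) - 1L, each = n[1] * n[2])
  )
  sweep(idx %*% grid$axes, 2, grid$origin, "+")
}

# fractional (zero-based, possibly non-integer) lattice coordinates of points
point_to_frac <- function(grid, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  sweep(points, 2, grid$origin, "-") %*% solve(grid$axes)
}

# 1-based flat voxel index of the voxel containing each point (nearest centre)
point_to_voxel <- function(grid, points) {
  u <- round(point_to_frac(grid, points))
  n <- grid$shape
  if (grid$periodic) {
    u <- u %% matrix(n, nrow(u), 3, byrow = TRUE)
  }
  bad <- u[, 1] < 0 | u[, 1] >= n[1] | u[, 2] < 0 | u[, 2] >= n[2] |
    u[, 3] < 0 | u[, 3] >= n[3]
  if (any(bad)) stop("point(s) outside the grid")
  as.integer(u[, 1] + n[1] * (u[, 2] + n[2] * u[, 3]) + 1)
}

# trilinear interpolation of grid values at arbitrary interior points
interp_grid <- function(grid, points) {
  u <- point_to_frac(grid, points)
  n <- grid$shape
  u <- pmin(pmax(u, 0), matrix(n - 1L, nrow(u), 3, byrow = TRUE) - 1e-9)
  i0 <- pmin(floor(u), matrix(n - 2L, nrow(u), 3, byrow = TRUE))
  f <- u - i0
  v <- grid$values
  out <- numeric(nrow(u))
  for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
    w <- (if (di) f[, 1] else 1 - f[, 1]) *
      (if (dj) f[, 2] else 1 - f[, 2]) *
      (if (dk) f[, 3] else 1 - f[, 3])
    out <- out + w * v[cbind(i0[, 1] + di + 1, i0[, 2] + dj + 1,
                             i0[, 3] + dk + 1)]
  }
  out
}

#' Read a Gaussian cube file
#'
#' Parses the standard cube convention: two comment lines; atom count plus
#' origin; three axis records (voxel count and step vector); atom records
#' (Z, charge, x, y, z); then values with the third lattice index fastest.
#' Positive axis counts mean Bohr; negative counts are the Angstrom dialect
#' and are converted (1 Angstrom = 1.8897259886 Bohr), with the conversion
#' recorded in the returned grid's `angstrom_input` attribute.
#'
#' @param path file path.
#' @param periodic logical, attached to the returned grid (the cube format
#'   itself does not encode periodicity).
#' @return `list(geometry =, grid =)`.
#' @export
read_cube <- function(path, periodic = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop("malformed cube header: fewer than 3 lines")
  numtok <- function(i) {
    if (i > length(lines)) {
      stop("malformed cube header: file ends before line ", i, call. = FALSE)
    }
    toks <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    val <- suppressWarnings(as.numeric(toks))
    if (anyNA(val)) stop("malformed cube header at line ", i, ": '",
                         lines[i], "'", call. = FALSE)
    val
  }
  l3 <- numtok(3)
  if (length(l3) < 4) stop("malformed cube header at line 3: '", lines[3], "'")
  natoms_raw <- as.integer(l3[1])
  natoms <- abs(natoms_raw)
  origin <- l3[2:4]
  axes <- matrix(0, 3, 3)
  counts <- integer(3)
  ang <- logical(3)
  for (a in 1:3) {
    la <- numtok(3 + a)
    if (length(la) < 4) stop("malformed cube axis record at line ", 3 + a)
    counts[a] <- abs(as.integer(la[1]))
    ang[a] <- la[1] < 0
    axes[a, ] <- la[2:4] * (if (ang[a]) BOHR_PER_ANG else 1)
  }
  if (any(counts < 1)) stop("malformed cube axis record: zero voxel count")
  if (any(ang)) origin <- origin * BOHR_PER_ANG
  atom_lines <- lines[seq.int(7, length.out = natoms)]
  if (length(atom_lines) < natoms || any(!nzchar(trimws(atom_lines)))) {
    stop("cube declares ", natoms, " atoms but atom records are missing")
  }
  atoms <- lapply(seq_len(natoms), function(i) {
    val <- suppressWarnings(as.numeric(
      strsplit(trimws(atom_lines[i]), "[[:space:]]+")[[1]]))
    if (length(val) < 5 || anyNA(val[1:5])) {
      stop("malformed cube atom record at line ", 6 + i, ": '",
           atom_lines[i], "'", call. = FALSE)
    }
    val[1:5]
  })
  atoms <- do.call(rbind, atoms)
  coords <- atoms[, 3:5, drop = FALSE] * (if (any(ang)) BOHR_PER_ANG else 1)
  geom <- geometry(.ELEMENTS[atoms[, 1]], coords, Z = as.integer(atoms[, 1]))
  first_val <- 7 + natoms
  # MO-cube dialect: negative atom count flags one extra record line
  if (natoms_raw < 0) first_val <- first_val + 1
  nexp <- prod(counts)
  if (first_val > length(lines)) {
    stop("cube declares ", nexp, " values but the file ends after the header")
  }
  vals <- scan(text = paste(lines[first_val:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nexp) {
    stop("cube declares ", nexp, " values but ", length(vals), " were found")
  }
  # cube order: first lattice index slowest, third fastest -> R array i fastest
  arr <- aperm(array(vals, dim = rev(counts)), 3:1)
  grid <- scalar_grid(origin, axes, arr, periodic = periodic)
  attr(grid, "angstrom_input") <- any(ang)
  list(geometry = geom, grid = grid)
}

#' Write a Gaussian cube file
#'
#' Values are written in scientific notation with six significant digits, six
#' per line, third lattice index fastest, so that `read_cube()` round-trips
#' the grid to that precision.
#'
#' @param geom a `vsf_geometry`.
#' @param grid a `scalar_grid` (finite values only).
#' @param path output path.
#' @param comment first comment line.
#' @export
write_cube <- function(geom, grid, path, comment = "volsource cube") {
  if (!all(is.finite(grid$values))) {
    stop("refusing to write a cube with non-finite values")
  }
  n <- grid$shape
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(comment, "scalar field, atomic units"), con)
  writeLines(sprintf("%5d%12.6f%12.6f%12.6f", nrow(geom$coords),
                     grid$origin[1], grid$origin[2], grid$origin[3]), con)
  for (a in 1:3) {
    writeLines(sprintf("%5d%12.6f%12.6f%12.6f", n[a],
                       grid$axes[a, 1], grid$axes[a, 2], grid$axes[a, 3]), con)
  }
  for (i in seq_len(nrow(geom$coords))) {
    writeLines(sprintf("%5d%12.6f%12.6f%12.6f%12.6f", geom$Z[i],
                       as.numeric(geom$Z[i]), geom$coords[i, 1],
                       geom$coords[i, 2], geom$coords[i, 3]), con)
  }
  vals <- as.vector(aperm(grid$values, 3:1))  # third index fastest on disk
  txt <- sprintf("%13.5E", vals)
  pad <- (-length(txt)) %% 6
  if (pad) txt <- c(txt, rep("", pad))
  writeLines(apply(matrix(txt, ncol = 6, byrow = TRUE), 1, paste0,
                   collapse = ""), con)
  invisible(path)
}

#' Read an XYZ geometry file
#'
#' Standard XYZ: atom count, comment, then `element x y z` in Angstrom.
#' Coordinates are converted to Bohr.
#'
#' @param path file path.
#' @return a `vsf_geometry`.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1) stop("empty XYZ file")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1) stop("malformed XYZ count line: '", lines[1], "'")
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) {
    stop("XYZ declares ", n, " atoms but only ", length(body),
         " atom lines found")
  }
  toks <- strsplit(trimws(body[seq_len(n)]), "[[:space:]]+")
  sym <- vapply(toks, `[`, "", 1)
  xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  if (!all(is.finite(xyz))) stop("malformed XYZ coordinates")
  geometry(sym, xyz * BOHR_PER_ANG)
}

#' Write an XYZ file, optionally with one extra per-atom data column
#'
#' Coordinates are converted from Bohr to Angstrom. An `extra` vector (for
#' example per-atom VSF%) is appended as a fifth column, the common convention
#' for property colouring in molecular viewers.
#'
#' @param geom a `vsf_geometry`.
#' @param path output path.
#' @param extra optional numeric per-atom column.
#' @param comment comment line.
#' @export
write_xyz <- function(geom, path, extra = NULL, comment = "") {
  n <- nrow(geom$coords)
  ang <- geom$coords / BOHR_PER_ANG
  rows <- sprintf("%-3s %14.8f %14.8f %14.8f", geom$elements,
                  ang[, 1], ang[, 2], ang[, 3])
  if (!is.null(extra)) {
    stopifnot(length(extra) == n)
    rows <- paste0(rows, sprintf(" %12.6f", extra))
  }
  writeLines(c(as.character(n), comment, rows), path)
  invisible(path)
}
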