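# End-to-end pipeline: density -> derivative fields -> vdW volume -> atomic
# basins -> Monte-Carlo volumetric source function, wrapped in a classed
# result with print/summary/plot methods and plain-text report writers.

#' Volumetric source function analysis of a density
#'
#' Runs the full workflow: derivative fields and RDG, vdW-volume extraction
#' (RDG isovalue, density window, rho*sign(lambda2) band, connected-component
#' selection), Yu-Trinkle basin partition, point sampling inside the volume,
#' and the Monte-Carlo volumetric source function with VSF%, the electron
#' count of the volume and the Gatti reliability parameter f1.
#'
#' @param input a cube file path, or a `scalar_grid` of the density.
#' @param geom a `vsf_geometry` (required when `input` is a grid; taken from
#'   the cube otherwise).
#' @param periodic treat the grid as periodic.
#' @param s_iso RDG isovalue (customary range 0.45-0.55).
#' @param rho_window density window in e/bohr^3.
#' @param band rho*sign(lambda2) half-width, a.u.
#' @param component connected component to analyse (1 = largest; `NA` = all).
#' @param n_samples Monte-Carlo sample size (>= 1000 recommended; the
#'   integration error plateaus by about 1000 points).
#' @param seed RNG seed, recorded in every output.
#' @param method sampling method, `"uniform"` or `"metropolis"`.
#' @param f1_warn warn when |f1| exceeds this percentage (reconstruction
#'   quality flag).
#' @param verbose print per-stage progress.
#' @return an object of class `vsf`.
#' @export
vsf <- function(input, geom = NULL, periodic = FALSE, s_iso = 0.5,
                rho_window = c(1e-6, 1e-3), band = 0.02, component = 1L,
                n_samples = 1000L, seed = 42L,
                method = c("uniform", "metropolis"), f1_warn = 5,
                verbose = FALSE) {
  method <- match.arg(method)
  stopifnot(s_iso > 0, length(rho_window) == 2, rho_window[1] <= rho_window[2],
            band >= 0, n_samples >= 1)
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(input)) {
    say("reading cube %s", input)
    cb <- read_cube(input, periodic = periodic)
    grid <- cb$grid
    if (is.null(geom)) geom <- cb$geometry
  } else {
    grid <- input
    grid$periodic <- isTRUE(periodic) || grid$periodic
  }
  stopifnot(inherits(grid, "scalar_grid"))
  if (is.null(geom)) stop("a geometry is required when input is a grid")

  config <- list(periodic = grid$periodic, s_iso = s_iso,
                 rho_window = rho_window, band = band,
                 component = component, n_samples = as.integer(n_samples),
                 seed = as.integer(seed), method = method)

  say("computing derivative fields")
  fields <- grid_fields(grid)
  say("extracting vdW volume")
  volume <- withCallingHandlers(
    vdw_volume(fields, s_iso = s_iso, rho_window = rho_window, band = band,
               component = component),
    warning = function(w) {
      say("note: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  if (length(volume$voxels) == 0) {
    say("empty vdW volume; returning a degenerate result")
    out <- structure(list(geometry = geom, config = config, fields = NULL,
                          volume = volume, partition = NULL, result = NULL,
                          empty = TRUE), class = "vsf")
    return(out)
  }

  say("partitioning into atomic basins (%d voxels)", prod(grid$shape))
  partition <- bader_basins(grid, geom = geom)
  say("sampling %d points (%s, seed %d)", n_samples, method, seed)
  sample <- sample_points(volume, n_samples, seed = seed, method = method,
                          rho_reject = max(1e-6, rho_window[1]))
  say("evaluating the volumetric source function")
  result <- vsf_monte_carlo(volume, sample, partition, fields$laplacian)
  if (is.finite(result$f1) && abs(result$f1) > f1_warn) {
    warning(sprintf(
      "reliability parameter f1 = %.2f%% exceeds %.1f%%: %s", result$f1,
      f1_warn, "the density reconstruction inside V_vdW is poor"))
  }
  structure(list(geometry = geom, config = config, fields = fields,
                 volume = volume, partition = partition, sample = sample,
                 result = result, empty = FALSE),
            class = "vsf")
}

# per-atom aggregation of per-basin quantities (several maxima can map to
# one atom for heavy or diffuse model atoms)
.atom_table <- function(x) {
  if (x$empty) {
    return(data.frame(atom = integer(), element = character(),
                      VSF = numeric(), VSF_percent = numeric(),
                      mc_stderr = numeric()))
  }
  res <- x$result
  map <- x$partition$atom_of_basin
  if (is.null(map)) map <- seq_along(res$vsf)
  natom <- nrow(x$geometry$coords)
  agg <- function(v) as.vector(tapply(v, factor(map, levels = seq_len(natom)),
                                      sum, default = 0))
  data.frame(
    atom = seq_len(natom),
    element = x$geometry$elements,
    VSF = agg(res$vsf),
    VSF_percent = agg(res$vsf_percent),
    mc_stderr = sqrt(agg(res$mc_stderr^2))
  )
}

#' Per-atom VSF report table
#'
#' One row per atom (index, element, VSF, VSF%, Monte-Carlo standard error)
#' with footer quantities `n_e`, `sum VSF`, `f1`, `V_vdW`, `N`, `seed`
#' attached as an attribute and written as trailing comment rows by
#' [write_vsf_outputs()].
#'
#' @param x a `vsf` object.
#' @return a data.frame with attribute `footer`.
#' @export
report_table <- function(x) {
  stopifnot(inherits(x, "vsf"))
  tab <- .atom_table(x)
  footer <- if (x$empty) {
    list(n_e = 0, sum_VSF = 0, f1 = NA_real_, V_vdW = 0,
         N = x$config$n_samples, seed = x$config$seed)
  } else {
    list(n_e = x$result$n_e, sum_VSF = sum(x$result$vsf), f1 = x$result$f1,
         V_vdW = x$result$V, N = x$result$N, seed = x$result$seed)
  }
  attr(tab, "footer") <- footer
  tab
}

#' @export
print.vsf <- function(x, ...) {
  cat("Volumetric source function analysis\n")
  print(x$geometry)
  with(x$config, cat(sprintf(
    "thresholds: s <= %.3g, %.1e <= rho <= %.1e e/bohr^3, band %.3g a.u.\n",
    s_iso, rho_window[1], rho_window[2], band)))
  if (x$empty) {
    cat("vdW volume: EMPTY under these thresholds (0 components)\n")
    return(invisible(x))
  }
  print(x$volume)
  tab <- report_table(x)
  print(tab, row.names = FALSE, digits = 5)
  f <- attr(tab, "footer")
  cat(sprintf("n_e = %.6g e, sum VSF = %.6g e, f1 = %.3f%% (N = %d, seed = %d)\n",
              f$n_e, f$sum_VSF, f$f1, f$N, f$seed))
  invisible(x)
}

#' @export
summary.vsf <- function(object, ...) {
  print(object)
  if (!object$empty) {
    cat(sprintf("basin populations: %s (total %.4f e)\n",
                paste(sprintf("%.4f", object$partition$populations),
                      collapse = ", "),
                sum(object$partition$populations)))
    cat(sprintf("components found: %d; analysed: %s\n",
                object$volume$n_components,
                as.character(object$config$component)))
  }
  invisible(object)
}

#' Running-mean convergence plot of the Monte-Carlo VSF
#'
#' Plots the running estimate `V * cummean(SF)` per basin against the sample
#' count; the estimate should plateau by about 1000 points.
#'
#' @param x a `vsf` object.
#' @param ... passed to `matplot`.
#' @export
plot.vsf <- function(x, ...) {
  if (x$empty) stop("nothing to plot: empty vdW volume")
  sf <- x$result$sf_samples
  run <- apply(sf, 2, function(v) cumsum(v) / seq_along(v)) * x$result$V
  graphics::matplot(run, type = "l", lty = 1,
                    xlab = "Monte-Carlo samples",
                    ylab = "running VSF estimate (e)", ...)
  graphics::abline(h = x$result$vsf, lty = 3)
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Writes `result.json` (full effective config, thresholds, seed, per-basin
#' and per-atom results), `atoms.tsv` (the report table with footer rows),
#' `mask.cube` (vdW volume membership for external viewers) and
#' `colored.xyz` (geometry with VSF% as an extra column). All plain text;
#' re-running the pipeline from the embedded config reproduces them.
#'
#' @param x a `vsf` object.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_vsf_outputs <- function(x, dir) {
  stopifnot(inherits(x, "vsf"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- report_table(x)
  footer <- attr(tab, "footer")
  payload <- list(
    config = x$config,
    n_components = if (x$empty) 0L else x$volume$n_components,
    V_vdW = footer$V_vdW, n_e = footer$n_e, f1 = footer$f1,
    sum_VSF = footer$sum_VSF,
    basins = if (x$empty) NULL else list(
      vsf = x$result$vsf, vsf_percent = x$result$vsf_percent,
      mc_stderr = x$result$mc_stderr,
      populations = x$partition$populations,
      atom_of_basin = x$partition$atom_of_basin),
    atoms = tab
  )
  json_path <- file.path(dir, "result.json")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  tsv_path <- file.path(dir, "atoms.tsv")
  con <- file(tsv_path, "w")
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  for (k in names(footer)) {
    writeLines(sprintf("# %s\t%s", k, format(footer[[k]], digits = 10)), con)
  }
  close(con)
  paths <- c(json_path, tsv_path)
  if (!x$empty) {
    mask <- array(0, x$volume$grid$shape)
    mask[x$volume$voxels] <- 1
    mask_path <- file.path(dir, "mask.cube")
    write_cube(x$geometry,
               scalar_grid(x$volume$grid$origin, x$volume$grid$axes, mask),
               mask_path, comment = "vdW volume membership mask")
    xyz_path <- file.path(dir, "colored.xyz")
    write_xyz(x$geometry, xyz_path, extra = tab$VSF_percent,
              comment = "VSF% per atom in the last column")
    paths <- c(paths, mask_path, xyz_path)
  }
  invisible(paths)
}
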