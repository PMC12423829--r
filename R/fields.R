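#' Coulomb constant, kcal A mol^-1 e^-2
#'
#' The conversion constant k in E_C = k q1 q2 / r for charges in
#' elementary units, distance in Angstrom and energy in kcal/mol.
#' @export
COULOMB_K <- 332.0636

#' Probe specification for molecular interaction fields
#'
#' The default probe is an sp3-carbon-like site carrying +1 elementary
#' charge (epsilon 0.1094 kcal/mol, sigma 3.4 A), the common choice for
#' CoMFA-style steric/electrostatic fields. Energies are clamped to
#' +/- `truncation` to tame the r^-12 singularity at atomic positions.
#'
#' @param charge probe charge, e (default +1).
#' @param lj_epsilon probe LJ well depth, kcal/mol (default 0.1094).
#' @param lj_sigma probe LJ diameter, A (default 3.4).
#' @param truncation cap on |energy|, kcal/mol (default 30).
#' @return list of class `probe_spec`.
#' @export
probe_spec <- function(charge = 1, lj_epsilon = 0.1094, lj_sigma = 3.4,
                       truncation = 30) {
  stopifnot(truncation > 0, lj_epsilon >= 0, lj_sigma > 0)
  structure(list(charge = charge, lj_epsilon = lj_epsilon,
                 lj_sigma = lj_sigma, truncation = truncation),
            class = "probe_spec")
}

#' Build an axis-aligned energy grid around aligned ensembles
#'
#' The box covers every atom of every conformer of every ensemble plus a
#' margin on each side; along each axis the number of points is
#' `ceil(extent / spacing) + 1`.
#'
#' @param ensembles list of aligned [conformer_ensemble()] objects (or a
#'   single one).
#' @param spacing grid spacing in Angstrom (default 1.0).
#' @param margin margin beyond the atomic extent on every side, Angstrom
#'   (default 4.0).
#' @return list of class `energy_grid`: `origin`, `spacing`, `dims`.
#' @export
build_grid <- function(ensembles, spacing = 1.0, margin = 4.0) {
  if (inherits(ensembles, "conformer_ensemble")) ensembles <- list(ensembles)
  stopifnot(length(ensembles) >= 1, spacing > 0, margin >= 0)
  all_xyz <- do.call(rbind, unlist(lapply(ensembles, `[[`, "conformers"),
                                   recursive = FALSE))
  lo <- apply(all_xyz, 2, min) - margin
  hi <- apply(all_xyz, 2, max) + margin
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  structure(list(origin = lo, spacing = spacing, dims = dims),
            class = "energy_grid")
}

#' Cartesian coordinates of every grid point
#'
#' Points are ordered with the x index varying fastest, then y, then z.
#'
#' @param grid an `energy_grid`.
#' @return (nx*ny*nz) x 3 matrix of coordinates in Angstrom.
#' @export
grid_coordinates <- function(grid) {
  ax <- lapply(1:3, function(d)
    grid$origin[d] + grid$spacing * (seq_len(grid$dims[d]) - 1))
  pts <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                     KEEP.OUT.ATTRS = FALSE)
  unname(as.matrix(pts))
}

#' Probe interaction energies of one conformer at grid points
#'
#' At each point the Lennard-Jones energy is
#' `sum_atoms 4 eps_ij ((sig_ij/r)^12 - (sig_ij/r)^6)` with
#' Lorentz-Berthelot combination (arithmetic-mean sigma, geometric-mean
#' epsilon), and the Coulomb energy `k sum_atoms q_i q_probe / r_i` with
#' k = 332.0636 kcal A mol^-1 e^-2. Both are clamped to the probe's
#' truncation; points closer than 1e-6 A to an atom take the clamped
#' value.
#'
#' @param coords n_atoms x 3 conformer coordinates (Angstrom).
#' @param charges,eps,sigma per-atom charge (e), LJ epsilon (kcal/mol)
#'   and sigma (A).
#' @param points m x 3 matrix of evaluation points (a bare vector of
#'   length 3 is accepted).
#' @param probe a [probe_spec()].
#' @return m x 2 matrix with columns `LJ`, `C` (kcal/mol).
#' @export
probe_energies <- function(coords, charges, eps, sigma, points,
                           probe = probe_spec()) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  sig_ij <- (sigma + probe$lj_sigma) / 2
  eps_ij <- sqrt(eps * probe$lj_epsilon)
  m <- nrow(points); n <- nrow(coords)
  d2 <- outer(rowSums(points^2), rowSums(coords^2), "+") -
    2 * points %*% t(coords)
  r <- sqrt(pmax(d2, 1e-12))
  r <- pmax(r, 1e-6)
  sr6 <- (matrix(sig_ij, m, n, byrow = TRUE) / r)^6
  elj <- rowSums(4 * matrix(eps_ij, m, n, byrow = TRUE) * (sr6^2 - sr6))
  ec <- COULOMB_K * probe$charge *
    rowSums(matrix(charges, m, n, byrow = TRUE) / r)
  tr <- probe$truncation
  cbind(LJ = pmin(pmax(elj, -tr), tr), C = pmin(pmax(ec, -tr), tr))
}

#' Field descriptor matrix over a series of aligned ensembles
#'
#' One row per molecule; columns are (grid point, energy type) pairs,
#' named `LJ_<i>` and `C_<i>` by grid-point index. In 3D mode the
#' designated single conformer of each ensemble is used; in 4D mode the
#' energies are arithmetic means over the conformational ensemble
#' profile.
#'
#' @param ensembles list of aligned [conformer_ensemble()] objects.
#' @param grid an [build_grid()] result.
#' @param probe a [probe_spec()].
#' @param mode `"4d"` (ensemble mean, default) or `"3d"`.
#' @param conformer_index conformer used in 3D mode (default 1).
#' @return numeric matrix (molecules x 2*grid points) with attributes
#'   `"grid"`, `"probe"`, `"mode"`.
#' @export
field_matrix <- function(ensembles, grid, probe = probe_spec(),
                         mode = c("4d", "3d"), conformer_index = 1) {
  mode <- match.arg(mode)
  pts <- grid_coordinates(grid)
  rows <- lapply(ensembles, function(e) {
    confs <- if (mode == "3d") e$conformers[conformer_index] else
      e$conformers
    acc <- 0
    for (co in confs)
      acc <- acc + probe_energies(co, e$partial_charges, e$lj_epsilon,
                                  e$lj_sigma, pts, probe)
    en <- acc / length(confs)
    c(en[, "LJ"], en[, "C"])
  })
  m <- do.call(rbind, rows)
  npts <- nrow(pts)
  colnames(m) <- c(paste0("LJ_", seq_len(npts)), paste0("C_", seq_len(npts)))
  rownames(m) <- vapply(ensembles, `[[`, character(1), "molecule_id")
  attr(m, "grid") <- grid
  attr(m, "probe") <- probe
  attr(m, "mode") <- mode
  m
}

#' Prune low-information field columns
#'
#' Drops columns whose variance is below `variance_floor` (grid points
#' far from every molecule see almost identical energies), then walks
#' mutually correlated groups (|r| above `correlation_ceiling`) keeping,
#' within each group, the column most correlated with the response.
#'
#' @param m field descriptor matrix.
#' @param y response (pIC50) used to arbitrate within correlated groups.
#' @param variance_floor minimum column variance (default 1e-4).
#' @param correlation_ceiling |r| above which two columns are redundant
#'   (default 0.99).
#' @return pruned matrix; pruning trace in attribute `"trace"` (column,
#'   reason, and the surviving twin for correlation-pruned columns).
#' @export
prune_columns <- function(m, y, variance_floor = 1e-4,
                          correlation_ceiling = 0.99) {
  v <- apply(m, 2, stats::var)
  low <- v < variance_floor
  trace <- data.frame(column = character(0), reason = character(0),
                      survivor = character(0), stringsAsFactors = FALSE)
  if (any(low))
    trace <- data.frame(column = colnames(m)[low],
                        reason = "variance below floor",
                        survivor = NA_character_,
                        stringsAsFactors = FALSE)
  keep <- colnames(m)[!low]
  if (!length(keep))
    stop("all columns pruned (variance_floor = ", variance_floor,
         ", correlation_ceiling = ", correlation_ceiling, ")")
  mm <- m[, keep, drop = FALSE]
  ry <- abs(suppressWarnings(stats::cor(mm, y)))[, 1]
  ord <- order(ry, decreasing = TRUE)
  chosen <- character(0)
  for (j in ord) {
    cn <- keep[j]
    twin <- NA_character_
    for (c0 in chosen) {
      if (abs(suppressWarnings(stats::cor(mm[, cn], mm[, c0]))) >
          correlation_ceiling) { twin <- c0; break }
    }
    if (!is.na(twin)) {
      trace <- rbind(trace, data.frame(column = cn,
                                       reason = "correlated with survivor",
                                       survivor = twin,
                                       stringsAsFactors = FALSE))
    } else chosen <- c(chosen, cn)
  }
  out <- m[, colnames(m)[colnames(m) %in% chosen], drop = FALSE]
  for (a in c("grid", "probe", "mode")) attr(out, a) <- attr(m, a)
  attr(out, "trace") <- trace
  out
}

#' Representative surviving column for (possibly pruned) field columns
#'
#' After [prune_columns()], a column may have been dropped in favor of a
#' near-identical twin. This maps each requested column to itself when it
#' survived, or to the recorded surviving twin otherwise — the grid
#' location that stands for it in the fitted model.
#'
#' @param pruned matrix returned by [prune_columns()].
#' @param columns column names to resolve.
#' @return character vector of surviving column names (`NA` when a
#'   column was removed for low variance).
#' @export
pruned_representative <- function(pruned, columns) {
  trace <- attr(pruned, "trace")
  vapply(columns, function(cn) {
    if (cn %in% colnames(pruned)) return(cn)
    hit <- trace$survivor[trace$column == cn]
    if (length(hit) && !is.na(hit[1])) hit[1] else NA_character_
  }, character(1))
}

#' Write a scalar grid field as a Gaussian cube file
#'
#' Standard cube layout: two comment lines, atom-count/origin line,
#' three axis lines, atom lines, then values in z-fastest order.
#' Lengths are converted from Angstrom to Bohr as the format requires.
#'
#' @param values numeric vector over grid points in the package's
#'   x-fastest order (see [grid_coordinates()]).
#' @param grid the `energy_grid`.
#' @param path output path.
#' @param comment first comment line.
#' @return `path`, invisibly.
#' @export
write_cube <- function(values, grid, path, comment = "field") {
  b <- 1 / 0.529177210903  # Angstrom -> Bohr
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  stopifnot(length(values) == nx * ny * nz)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(comment, "generated by kmosar"), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", 0,
                     grid$origin[1] * b, grid$origin[2] * b,
                     grid$origin[3] * b), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", nx, grid$spacing * b, 0, 0),
             con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", ny, 0, grid$spacing * b, 0),
             con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", nz, 0, 0, grid$spacing * b),
             con)
  # reorder x-fastest -> z-fastest
  arr <- array(values, dim = c(nx, ny, nz))
  for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
    row <- arr[ix, iy, ]
    writeLines(paste(sprintf("%13.5e", row), collapse = " "), con)
  }
  invisible(path)
}

#' Read back a cube file written by [write_cube()]
#'
#' @param path cube file path.
#' @return list with `grid` (an `energy_grid`) and `values` in the
#'   package's x-fastest order.
#' @export
read_cube <- function(path) {
  lines <- readLines(path)
  b <- 0.529177210903
  hdr <- function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  h3 <- hdr(lines[3]); hx <- hdr(lines[4]); hy <- hdr(lines[5])
  hz <- hdr(lines[6])
  natoms <- h3[1]
  dims <- c(hx[1], hy[1], hz[1])
  grid <- structure(list(origin = h3[2:4] * b, spacing = hx[2] * b,
                         dims = as.integer(dims)), class = "energy_grid")
  vals <- as.numeric(unlist(strsplit(trimws(
    lines[(7 + natoms):length(lines)]), "\\s+")))
  arr <- array(0, dim = dims)
  k <- 0
  for (ix in seq_len(dims[1])) for (iy in seq_len(dims[2])) {
    arr[ix, iy, ] <- vals[(k + 1):(k + dims[3])]
    k <- k + dims[3]
  }
  list(grid = grid, values = as.numeric(arr))
}
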