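test_that("grid construction matches box arithmetic", {
  atom <- conformer_ensemble("a", "C", list(matrix(0, 1, 3)),
                             partial_charges = 0)
  g <- build_grid(atom, spacing = 1, margin = 3)
  expect_equal(g$dims, c(7L, 7L, 7L))
  expect_equal(g$origin, c(-3, -3, -3))
  pts <- grid_coordinates(g)
  expect_equal(nrow(pts), 343)
  expect_equal(pts[1, ], c(-3, -3, -3))
  expect_equal(pts[343, ], c(3, 3, 3))

  # diatomic, spacing 0.5, margin 2: x extent 1+4=5 -> 11 points, y/z 9
  di <- generate_toy_geometry("diatomic")
  e <- conformer_ensemble("d", di$atom_elements, list(di$coordinates),
                          di$partial_charges, di$lj_epsilon, di$lj_sigma)
  g2 <- build_grid(e, spacing = 0.5, margin = 2)
  expect_equal(g2$dims, c(11L, 9L, 9L))

  # union property: box contains every ensemble
  ens <- synthetic_congeneric_ensembles(3, 2, seed = 1)
  g3 <- build_grid(ens, spacing = 1, margin = 2)
  xyz <- do.call(rbind, unlist(lapply(ens, `[[`, "conformers"),
                               recursive = FALSE))
  hi <- g3$origin + (g3$dims - 1) * g3$spacing
  expect_true(all(sweep(xyz, 2, g3$origin, `-`) >= 0))
  expect_true(all(sweep(xyz, 2, hi, `-`) <= 0))
  expect_error(build_grid(ens, spacing = 0), "spacing")
})

test_that("probe energies match Lennard-Jones and Coulomb closed forms", {
  probe <- probe_spec(charge = 1, lj_epsilon = 0.1, lj_sigma = 3.0,
                      truncation = 1e6)
  co <- matrix(0, 1, 3)
  sig_ij <- 3.0; eps_ij <- 0.1  # atom params equal probe params
  # LJ zero crossing at r = sigma_ij
  e1 <- probe_energies(co, 0, 0.1, 3.0, c(sig_ij, 0, 0), probe)
  expect_equal(unname(e1[1, "LJ"]), 0, tolerance = 1e-10)
  # LJ minimum -eps at r = 2^(1/6) sigma
  e2 <- probe_energies(co, 0, 0.1, 3.0, c(2^(1 / 6) * sig_ij, 0, 0), probe)
  expect_equal(unname(e2[1, "LJ"]), -eps_ij, tolerance = 1e-10)
  # Coulomb: unit charges at 1 A
  e3 <- probe_energies(co, 1, 0, 3.0, c(1, 0, 0),
                       probe_spec(charge = 1, lj_epsilon = 0,
                                  truncation = 1e6))
  expect_equal(unname(e3[1, "C"]), 332.0636, tolerance = 1e-10)
  # plug-in brute force: eps_ij = 0.1, sig_ij = 3, r = 6
  e4 <- probe_energies(co, 0, 0.1, 3.0, c(6, 0, 0), probe)
  expect_equal(unname(e4[1, "LJ"]),
               4 * 0.1 * ((3 / 6)^12 - (3 / 6)^6), tolerance = 1e-12)
  expect_equal(round(unname(e4[1, "LJ"]), 6), -0.006152)
})

test_that("energies are truncated and decay monotonically far out", {
  probe <- probe_spec(truncation = 30)
  co <- matrix(0, 1, 3)
  # near-singular point is clamped
  e <- probe_energies(co, 1, 0.1, 3.0, c(1e-9, 0, 0), probe)
  expect_equal(abs(unname(e[1, "LJ"])), 30)
  # beyond the LJ minimum both magnitudes decay to zero (charge small
  # enough that no point is clamped)
  rs <- seq(4, 15, by = 0.5)
  en <- probe_energies(co, 0.2, 0.1, 3.0, cbind(rs, 0, 0), probe)
  expect_true(all(diff(abs(en[, "LJ"])) < 0))
  expect_true(all(diff(abs(en[, "C"])) < 0))
  expect_lt(abs(en[length(rs), "LJ"]), 1e-3)
})

test_that("4D matrices equal the mean of per-conformer 3D matrices", {
  ens <- synthetic_congeneric_ensembles(4, 3, seed = 9)
  grid <- build_grid(ens, spacing = 1.5, margin = 3)
  f4 <- field_matrix(ens, grid, mode = "4d")
  f3 <- lapply(1:3, function(k)
    field_matrix(ens, grid, mode = "3d", conformer_index = k))
  expect_equal(f4, Reduce(`+`, lapply(f3, unclass)) / 3,
               tolerance = 1e-12, ignore_attr = TRUE)

  # identical conformers: 4D equals 3D exactly
  one <- ens[[1]]
  one$conformers <- rep(one$conformers[1], 3)
  g1 <- build_grid(one, spacing = 2, margin = 3)
  expect_equal(field_matrix(list(one), g1, mode = "4d"),
               field_matrix(list(one), g1, mode = "3d"),
               ignore_attr = TRUE)

  # zero probe charge kills every Coulomb column
  f0 <- field_matrix(ens, grid, probe_spec(charge = 0), mode = "4d")
  expect_true(all(f0[, grepl("^C_", colnames(f0))] == 0))
})

test_that("field descriptors are invariant under joint rigid motion", {
  ens <- synthetic_congeneric_ensembles(2, 2, seed = 13)
  grid <- build_grid(ens, spacing = 1.5, margin = 3)
  pts <- grid_coordinates(grid)
  set.seed(30)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  shift <- c(2, -1, 5)
  move <- function(m) sweep(m %*% t(R), 2, shift, "+")
  probe <- probe_spec()
  for (e in ens) {
    orig <- probe_energies(e$conformers[[1]], e$partial_charges,
                           e$lj_epsilon, e$lj_sigma, pts, probe)
    moved <- probe_energies(move(e$conformers[[1]]), e$partial_charges,
                            e$lj_epsilon, e$lj_sigma, move(pts), probe)
    expect_equal(orig, moved, tolerance = 1e-8)
  }
})

test_that("pruning removes flat and duplicated columns, keeps causal ones", {
  fx <- fx_field()
  fm <- fx$matrix
  # far-corner grid points carry almost no variance and are pruned
  pr <- prune_columns(fm, fx$planted$y)
  expect_lt(ncol(pr), ncol(fm))
  v <- apply(fm, 2, stats::var)
  expect_true(all(v[colnames(pr)] >= 1e-4))
  # a duplicated column never survives alongside its twin, and both
  # remain resolvable to a surviving representative
  dup <- cbind(fm[, 1:20], DUPE = fm[, 10])
  prd <- prune_columns(dup, fx$planted$y, variance_floor = 0)
  expect_lte(sum(colnames(prd) %in% c(colnames(fm)[10], "DUPE")), 1)
  expect_false(anyNA(pruned_representative(prd, c(colnames(fm)[10],
                                                  "DUPE"))))
  # causal columns (or their recorded twins) survive
  reps <- pruned_representative(pr, fx$planted$causal)
  expect_false(anyNA(reps))
})

test_that("cube files round-trip grids and values", {
  ens <- synthetic_congeneric_ensembles(1, 1, seed = 3)
  grid <- build_grid(ens, spacing = 2, margin = 2)
  vals <- rnorm(prod(grid$dims))
  path <- withr::local_tempfile(fileext = ".cube")
  write_cube(vals, grid, path)
  back <- read_cube(path)
  expect_equal(back$grid$dims, grid$dims)
  expect_equal(back$grid$origin, grid$origin, tolerance = 1e-5)
  expect_equal(back$values, vals, tolerance = 1e-4)
})
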