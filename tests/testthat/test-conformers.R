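test_that("rigid molecules give tight ensembles, flexible ones do not", {
  rigid <- embed_and_sample(list(molecule_id = "bz", smiles = "c1ccccc1"),
                            n_conformers = 5, seed = 3)
  ref <- rigid$conformers[[1]]
  for (co in rigid$conformers[-1])
    expect_lt(coord_rmsd(co, ref), 0.1)

  single <- embed_and_sample(list(molecule_id = "x", smiles = "CCO"),
                             n_conformers = 1, seed = 1)
  expect_length(single$conformers, 1)
})

test_that("butane-like ensembles populate several torsion basins", {
  but <- embed_and_sample(list(molecule_id = "bu", smiles = "CCCC"),
                          n_conformers = 20, seed = 6)
  # central C-C-C-C torsion over the ensemble
  tors <- vapply(but$conformers, function(co) {
    heavy <- which(but$atom_elements != "H")[1:4]
    b1 <- co[heavy[2], ] - co[heavy[1], ]
    b2 <- co[heavy[3], ] - co[heavy[2], ]
    b3 <- co[heavy[4], ] - co[heavy[3], ]
    n1 <- pracma::cross(b1, b2); n2 <- pracma::cross(b2, b3)
    atan2(sum(pracma::cross(n1, n2) * b2 / sqrt(sum(b2^2))),
          sum(n1 * n2)) * 180 / pi
  }, numeric(1))
  basin <- cut(tors, breaks = c(-180, -120, 0, 120, 180))
  expect_gte(length(unique(basin)), 2)
})

test_that("ensembles are deterministic and charge-consistent", {
  e1 <- embed_and_sample(list(molecule_id = "m", smiles = "CCOC(=O)C"),
                         n_conformers = 4, seed = 11)
  e2 <- embed_and_sample(list(molecule_id = "m", smiles = "CCOC(=O)C"),
                         n_conformers = 4, seed = 11)
  expect_equal(e1, e2)
  expect_lt(abs(sum(e1$partial_charges)), 1e-6)
  expect_length(e1$lj_sigma, length(e1$atom_elements))
})

test_that("Kabsch superposition recovers exact rigid motions", {
  set.seed(21)
  A <- matrix(rnorm(15), 5, 3)
  # identity
  f <- kabsch(A, A)
  expect_lt(f$rmsd, 1e-12)
  expect_equal(f$rotation, diag(3), tolerance = 1e-9)
  # reference shifted by (1, 2, 3): recovered translation, zero RMSD
  f2 <- kabsch(A, sweep(A, 2, c(1, 2, 3), "+"))
  expect_lt(f2$rmsd, 1e-10)
  expect_equal(f2$translation, c(1, 2, 3), tolerance = 1e-9)
  # 90 degree rotation about z of a triangle: closed-form oracle
  tri <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  Rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  f3 <- kabsch(tri, tri %*% t(Rz))
  expect_lt(f3$rmsd, 1e-9)
  expect_equal(f3$rotation, Rz, tolerance = 1e-9)
  # collinear map rejected
  line <- cbind(1:4, 2 * (1:4), 3 * (1:4))
  expect_error(kabsch(line, line), "collinear")
})

test_that("Kabsch agrees with an independent reference implementation", {
  skip_if_not_installed("bio3d")
  set.seed(22)
  A <- matrix(rnorm(24), 8, 3)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  B <- sweep(A %*% t(R), 2, c(1, 2, 3), "+")
  f <- kabsch(A, B)
  ref <- bio3d::fit.xyz(fixed = as.numeric(t(B)),
                        mobile = as.numeric(t(A)),
                        fixed.inds = 1:24, mobile.inds = 1:24)
  expect_equal(as.numeric(t(f$coords)), as.numeric(ref),
               tolerance = 1e-6)
})

test_that("aligning an ensemble reports per-conformer RMSD", {
  ens <- synthetic_congeneric_ensembles(2, 3, seed = 4)
  ref <- ens[[1]]$conformers[[1]]
  al <- align_to_reference(ens[[2]], ref)
  expect_length(attr(al, "rmsd"), 3)
  # self-alignment: zero RMSD, unchanged coordinates
  al2 <- align_to_reference(ens[[1]], ens[[1]]$conformers[[1]])
  expect_lt(attr(al2, "rmsd")[1], 1e-10)
})
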