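test_that("descriptor values match chemical definitions on references", {
  rec <- data.frame(molecule_id = c("benzene", "ethane", "aspirin"),
                    smiles = c("c1ccccc1", "CC", "CC(=O)Oc1ccccc1C(=O)O"),
                    stringsAsFactors = FALSE)
  ph <- compute_physchem(rec)
  bz <- ph[ph$molecule_id == "benzene", ]
  expect_equal(bz$nrings, 1L)
  expect_equal(bz$nar, 1L)
  expect_equal(bz$hba, 0L)
  expect_equal(bz$hbd, 0L)
  expect_equal(bz$nrb, 0L)
  et <- ph[ph$molecule_id == "ethane", ]
  expect_equal(et$tpsa, 0)
  asp <- ph[ph$molecule_id == "aspirin", ]
  expect_equal(asp$mw, 180.157, tolerance = 1e-3)
  expect_gte(asp$nrb, 2L)
})

test_that("parse failures are reported and skipped, not fatal", {
  rec <- data.frame(molecule_id = c("ok", "bad"),
                    smiles = c("CCO", "xyzzy"), stringsAsFactors = FALSE)
  ph <- compute_physchem(rec)
  expect_equal(ph$molecule_id, "ok")
  expect_equal(attr(ph, "failed"), "bad")
})

test_that("counts are non-negative and aromatic rings bounded by rings", {
  ph <- fx_physchem_small()
  expect_true(all(ph$nrings >= 0 & ph$nar >= 0 & ph$hba >= 0 &
                    ph$hbd >= 0 & ph$nrb >= 0))
  expect_true(all(ph$nar <= ph$nrings))
  expect_true(all(ph$tpsa >= 0))
})

test_that("pearson matches the hand-computed oracle and its identities", {
  expect_equal(pearson(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson(c(1, 2, 3), c(6, 4, 2)), -1.0)
  # oracle: cov = 1.5, sd_x = 1, sd_y = sqrt(7/3)
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 4)), 1.5 / sqrt(7 / 3),
               tolerance = 1e-12)
  expect_equal(round(pearson(c(1, 2, 3), c(1, 2, 4)), 5), 0.98198)
  expect_warning(r0 <- pearson(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_true(is.na(r0))
  # pearson(x, a x + b) = sign(a)
  set.seed(3)
  x <- rnorm(20)
  for (a in c(-2.5, 0.3, 7)) {
    expect_equal(suppressWarnings(pearson(x, a * x + 1)), sign(a),
                 tolerance = 1e-12)
  }
})

test_that("correlation matrix is symmetric, bounded and PSD", {
  ph <- fx_physchem_small()
  keep <- vapply(ph[-1], function(x) stats::sd(x) > 0, logical(1))
  r <- correlation_matrix(ph[c(TRUE, keep)], fx_records_small()$pic50)
  expect_equal(r, t(r), tolerance = 1e-12)
  expect_true(all(abs(r) <= 1 + 1e-12))
  expect_true(all(diag(r) == 1))
  expect_gte(min(eigen(r, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  long <- correlation_long(r)
  expect_equal(nrow(long), sum(upper.tri(r)))
})

test_that("summaries agree with direct computation and class tallies", {
  ph <- fx_physchem_small()
  cls <- fx_records_small()$activity_class
  sm <- summarize_physchem(ph, cls)
  expect_equal(sm$mean[sm$descriptor == "logp"],
               round(mean(ph$logp), 3))
  expect_equal(sm$max[sm$descriptor == "mw"], round(max(ph$mw), 3))
  const <- summarize_physchem(data.frame(molecule_id = "x", v = 3.14))
  expect_equal(const$mean, const$min)
  expect_equal(const$mean, const$max)
  # expectation over the enumerated scaffold x substituent library,
  # weighted by the generated family sizes, pins the sample mean MW
  clean <- attr(fx_table_small(), "clean")
  fams <- unique(clean$family)
  scaf <- default_scaffolds()[fams]
  subs <- default_substituents()
  fam_means <- vapply(fams, function(f) {
    combos <- expand.grid(a = subs, b = subs, stringsAsFactors = FALSE)
    smi <- mapply(function(a, b) {
      s <- gsub("{R1}", a, scaf[[f]], fixed = TRUE)
      gsub("{R2}", b, s, fixed = TRUE)
    }, combos$a, combos$b)
    mean(compute_physchem(data.frame(molecule_id = seq_along(smi),
                                     smiles = smi))$mw)
  }, numeric(1))
  expected <- sum(fam_means * table(clean$family)[fams]) / nrow(clean)
  expect_lt(abs(mean(ph$mw) - expected) / expected, 0.05)
})
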