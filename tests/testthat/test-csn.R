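test_that("tanimoto matches hand-computed overlaps", {
  a <- c(1, 1, 1, 1, 0, 0, 0)
  b <- c(1, 1, 0, 0, 1, 1, 1)
  expect_equal(tanimoto(a, b), 2 / 7)
  expect_equal(tanimoto(a, a), 1.0)
  expect_equal(tanimoto(c(1, 0), c(0, 1)), 0.0)
  expect_warning(t0 <- tanimoto(c(0, 0), c(0, 0)), "empty")
  expect_equal(t0, 0)
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "length")
})

test_that("tanimoto_matrix agrees with the pairwise definition", {
  set.seed(14)
  fps <- matrix(rbinom(6 * 32, 1, 0.3), 6, 32)
  s <- tanimoto_matrix(fps)
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(s[i, j], suppressWarnings(tanimoto(fps[i, ], fps[j, ])))
  expect_equal(s, t(s))
})

test_that("threshold extremes give edgeless and complete graphs", {
  rec <- fx_records_small()[1:10, ]
  fps <- fp2_fingerprints(rec$smiles, rec$molecule_id)
  net_hi <- build_csn(rec, fps, edge_threshold = 1.01)
  expect_equal(igraph::ecount(net_hi$graph), 0)
  expect_equal(max(igraph::V(net_hi$graph)$component), 10)
  net_lo <- build_csn(rec, fps, edge_threshold = 0)
  expect_equal(igraph::ecount(net_lo$graph), choose(10, 2))
})

test_that("planted families come back as pure components at Tc 0.68", {
  rec <- fx_records_small()
  net <- build_csn(rec, edge_threshold = 0.68)
  g <- net$graph
  expect_gte(max(igraph::V(g)$component), 3)
  # every component is pure in family label
  split_fam <- split(igraph::V(g)$family, igraph::V(g)$component)
  expect_true(all(vapply(split_fam, function(f)
    length(unique(f)) == 1, logical(1))))
  # every edge satisfies the threshold; no self loops
  expect_true(all(igraph::E(g)$tc >= 0.68))
  expect_false(igraph::any_loop(g))
  # community partition covers all nodes exactly once
  expect_length(igraph::V(g)$community, nrow(rec))
  expect_false(anyNA(igraph::V(g)$community))
})

test_that("component count is monotone in the edge threshold", {
  set.seed(15)
  for (rep in 1:20) {
    fps <- matrix(rbinom(12 * 64, 1, runif(1, 0.2, 0.5)), 12, 64)
    rownames(fps) <- paste0("m", 1:12)
    rec <- data.frame(molecule_id = rownames(fps),
                      smiles = NA, pic50 = rnorm(12),
                      stringsAsFactors = FALSE)
    comps <- vapply(c(0.2, 0.4, 0.6, 0.8), function(th)
      max(igraph::V(build_csn(rec, fps, th)$graph)$component),
      numeric(1))
    expect_true(all(diff(comps) >= 0))
  }
})

test_that("tier statistics count pairs and sum to 100 percent", {
  # clique of 5 sharing 40 bits, one unique bit each: tc = 40/42 >= 0.9
  fps <- matrix(1, 5, 45)
  fps[, 1:5] <- diag(5)
  rownames(fps) <- paste0("c", 1:5)
  rec <- data.frame(molecule_id = paste0("c", 1:5), smiles = NA,
                    pic50 = rnorm(5), stringsAsFactors = FALSE)
  net <- build_csn(rec, fps, edge_threshold = 0.5)
  ts <- tier_statistics(net$graph)
  expect_equal(sum(ts$n_pairs), igraph::ecount(net$graph))
  expect_equal(sum(ts$percent), 100, tolerance = 0.011)
  # arithmetic oracle: 29 of 265 edges in the top tier is 10.94%
  expect_equal(round(100 * 29 / 265, 2), 10.94)
  # hand-counted 2/1/1 tier split
  g <- igraph::make_full_graph(4)
  igraph::E(g)$tc <- c(0.95, 0.92, 0.8, 0.5, 0.6, 0.65)
  ts2 <- tier_statistics(g)
  expect_equal(ts2$n_pairs, c(2L, 1L, 3L))
  expect_equal(ts2$percent, c(33.33, 16.67, 50.00))
})

test_that("network exports round-trip", {
  rec <- fx_records_small()[1:15, ]
  net <- build_csn(rec)
  dir <- withr::local_tempdir()
  paths <- write_csn(net, dir)
  edges <- utils::read.csv(file.path(dir, "csn_edges.csv"))
  expect_equal(nrow(edges), igraph::ecount(net$graph))
  nodes <- utils::read.csv(file.path(dir, "csn_nodes.csv"))
  expect_equal(nrow(nodes), 15)
  g2 <- igraph::read_graph(file.path(dir, "csn.graphml"),
                           format = "graphml")
  expect_equal(igraph::ecount(g2), igraph::ecount(net$graph))
})
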