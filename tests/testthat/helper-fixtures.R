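# Shared fixtures, generated once per test run and memoized.
.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fx)) assign(name, force(expr), envir = .fx)
  get(name, envir = .fx)
}

# 60-compound, 3-family planted activity set and its curation
fx_table_small <- function() fixture("table_small", {
  generate_activity_table(planted_sar_spec(n_compounds = 60,
                                           n_families = 3, seed = 11))
})

fx_records_small <- function() fixture("records_small",
                                       curate(fx_table_small()))

fx_physchem_small <- function() fixture("physchem_small",
                                        compute_physchem(fx_records_small()))

# small planted classification problem (no chemistry, fast)
fx_class_data <- function() fixture("class_data", {
  set.seed(71)
  n <- 120
  X <- data.frame(f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n),
                  f4 = rnorm(n), f5 = rnorm(n))
  y <- as.integer(X$f1 + 0.8 * X$f2 - 0.6 * X$f3 + rnorm(n, 0, 0.4) > 0)
  list(X = X, y = y)
})

fx_forest <- function() fixture("forest", {
  d <- fx_class_data()
  forest_fit(d$X, d$y, n_trees = 40, max_depth = 5, seed = 5)
})

# congeneric field-QSAR fixture: ensembles, grid, matrix, planted response
fx_field <- function() fixture("field", {
  ens <- synthetic_congeneric_ensembles(n_compounds = 24, n_conformers = 5,
                                        seed = 2)
  grid <- build_grid(ens, spacing = 1.0, margin = 4.0)
  fm <- field_matrix(ens, grid, mode = "4d")
  planted <- plant_field_response(fm, noise_sd = 0.3, seed = 3)
  list(ensembles = ens, grid = grid, matrix = fm, planted = planted)
})

# reference Shapley computation: recursive cover-weighted expectation over
# an rpart frame plus the permutation formula, independent of the compiled
# enumeration path
shap_bruteforce <- function(fit, x, feature_names) {
  frame <- fit$frame
  nodes <- as.integer(rownames(frame))
  ylev <- attr(fit, "ylevels")
  pcol <- 1 + length(ylev) + which(ylev == "1")
  expect_node <- function(node_id, fixed) {
    i <- match(node_id, nodes)
    if (frame$var[i] == "<leaf>") return(frame$yval2[i, pcol])
    k <- sum(frame$var[seq_len(i)] != "<leaf>")
    sp <- fit$splits[k, ]
    vn <- as.character(frame$var[i])
    goes_left_lt <- sp["ncat"] < 0
    li <- node_id * 2L; ri <- node_id * 2L + 1L
    if (vn %in% names(fixed)) {
      lt <- fixed[[vn]] < sp["index"]
      nxt <- if ((lt && goes_left_lt) || (!lt && !goes_left_lt)) li else ri
      return(expect_node(nxt, fixed))
    }
    nl <- frame$n[match(li, nodes)]; nr <- frame$n[match(ri, nodes)]
    (nl * expect_node(li, fixed) + nr * expect_node(ri, fixed)) / (nl + nr)
  }
  v_of <- function(subset) {
    expect_node(1L, as.list(x[subset]))
  }
  p <- length(feature_names)
  phi <- numeric(p); names(phi) <- feature_names
  perms <- combinat_perms(feature_names)
  for (perm in perms) {
    prev <- character(0)
    for (f in perm) {
      phi[f] <- phi[f] + (v_of(c(prev, f)) - v_of(prev))
      prev <- c(prev, f)
    }
  }
  phi / length(perms)
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in combinat_perms(v[-i]))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}
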