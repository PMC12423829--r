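#' @useDynLib kmosar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Flatten one fitted rpart tree into parallel arrays for the C++ Shapley
# engine: per node 0-based feature index (-1 for leaves), threshold,
# child indices, training cover and leaf value (class-1 frequency).
# rpart stores "x < thresh goes left" when ncat == -1; children are
# swapped when ncat == +1 so the flattened rule is always "< goes left".
flatten_rpart <- function(fit, feature_names) {
  frame <- fit$frame
  nodes <- as.integer(rownames(frame))
  ylev <- attr(fit, "ylevels")
  prob_col <- 1 + length(ylev) + which(ylev == "1")
  value <- frame$yval2[, prob_col]
  n_nodes <- nrow(frame)
  feat <- integer(n_nodes); thresh <- numeric(n_nodes)
  left <- integer(n_nodes); right <- integer(n_nodes)
  is_split <- frame$var != "<leaf>"
  split_rows <- which(is_split)
  splits <- fit$splits
  for (k in seq_along(split_rows)) {
    i <- split_rows[k]
    feat[i] <- match(as.character(frame$var[i]), feature_names) - 1L
    thresh[i] <- splits[k, "index"]
    l <- match(as.character(nodes[i] * 2L), rownames(frame))
    r <- match(as.character(nodes[i] * 2L + 1L), rownames(frame))
    if (splits[k, "ncat"] > 0) { tmp <- l; l <- r; r <- tmp }
    left[i] <- l - 1L; right[i] <- r - 1L
  }
  feat[!is_split] <- -1L
  list(feat = feat, thresh = thresh, left = left, right = right,
       cover = as.numeric(frame$n), value = as.numeric(value))
}

#' Exact Shapley explanation of an ensemble prediction
#'
#' Computes exact Shapley attributions of the ensemble's class-1
#' probability for one compound by full coalition enumeration: for every
#' feature subset S the expected tree output is evaluated with features
#' in S fixed to the query values and the rest marginalized using the
#' trees' training cover weights (the path-dependent value function of
#' tree-Shapley). Attributions satisfy additivity exactly:
#' `base_value + sum(contributions) = predicted probability`.
#'
#' @param model a `kmo_forest`.
#' @param x one compound: named numeric vector or 1-row data.frame
#'   covering all model features.
#' @return object of class `shap_explanation`: `base_value` (expected
#'   model output over training cover), `contributions` (named, signed),
#'   `feature_values`, `prediction`.
#' @export
explain <- function(model, x) {
  stopifnot(inherits(model, "kmo_forest"))
  fn <- model$feature_names
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    x <- unlist(x[1, , drop = TRUE])
  }
  if (!all(fn %in% names(x)))
    stop("query row lacks model features: ",
         paste(setdiff(fn, names(x)), collapse = ", "))
  xv <- as.numeric(x[fn])
  p <- length(fn)
  if (p > 16)
    stop("exact coalition enumeration supports at most 16 features (got ",
         p, ")")
  flat <- lapply(model$trees, function(t) flatten_rpart(t$fit, fn))
  res <- shap_enumerate(flat, xv, p)
  structure(list(base_value = res$base_value,
                 contributions = stats::setNames(as.numeric(res$phi), fn),
                 feature_values = stats::setNames(xv, fn),
                 prediction = res$fx),
            class = "shap_explanation")
}

#' @export
print.shap_explanation <- function(x, ...) {
  cat("Shapley explanation (class-1 probability)\n")
  cat(sprintf("  E[f(x)] (base value): %.4f\n", x$base_value))
  ord <- order(abs(x$contributions), decreasing = TRUE)
  for (i in ord)
    cat(sprintf("  %-12s = %8.4f  ->  %+0.4f\n",
                names(x$contributions)[i], x$feature_values[i],
                x$contributions[i]))
  cat(sprintf("  prediction f(x): %.4f\n", x$prediction))
  invisible(x)
}

#' Dataset context for a waterfall-style explanation
#'
#' For side-by-side display next to a query compound's explanation:
#' the dataset molecule most similar to the query (maximum Tanimoto
#' coefficient on path fingerprints) and the most active dataset
#' molecule.
#'
#' @param query_smiles SMILES of the query compound.
#' @param records curated records with `molecule_id`, `smiles`, `pic50`.
#' @return list with `most_similar` (id, smiles, tc) and `most_active`
#'   (id, smiles, pic50).
#' @export
explanation_context <- function(query_smiles, records) {
  fps <- fp2_fingerprints(c(records$smiles, query_smiles),
                          c(records$molecule_id, ".query"))
  q <- fps[".query", ]
  tcs <- vapply(records$molecule_id, function(id)
    tanimoto(fps[id, ], q), numeric(1))
  best <- which.max(tcs)
  top <- which.max(records$pic50)
  list(most_similar = list(molecule_id = records$molecule_id[best],
                           smiles = records$smiles[best],
                           tc = unname(tcs[best])),
       most_active = list(molecule_id = records$molecule_id[top],
                          smiles = records$smiles[top],
                          pic50 = records$pic50[top]))
}
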