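#' Pretreat a raw descriptor matrix
#'
#' Removes non-numeric columns, columns containing missing values, and
#' quasi-constant columns (most frequent value covering more than
#' `quasi_constant` of the rows; a strictly constant column is the
#' limiting case). Every removal is recorded in the selection trace.
#'
#' @param m data.frame or matrix of raw descriptors.
#' @param quasi_constant dominance fraction above which a column is
#'   dropped (default 0.99).
#' @return numeric data.frame of surviving columns; the trace (stage,
#'   column, reason) is attached as attribute `"trace"`.
#' @export
pretreat <- function(m, quasi_constant = 0.99) {
  m <- as.data.frame(m)
  trace <- data.frame(stage = character(0), column = character(0),
                      criterion = character(0), stringsAsFactors = FALSE)
  drop <- function(cols, stage, why) {
    if (length(cols))
      trace <<- rbind(trace, data.frame(stage = stage, column = cols,
                                        criterion = why,
                                        stringsAsFactors = FALSE))
    m[setdiff(names(m), cols)]
  }
  num <- vapply(m, is.numeric, logical(1))
  m <- drop(names(m)[!num], "pretreat", "non-numeric")
  has_na <- vapply(m, function(x) anyNA(x), logical(1))
  m <- drop(names(m)[has_na], "pretreat", "missing values")
  dominant <- vapply(m, function(x) max(table(x)) / length(x), numeric(1))
  m <- drop(names(m)[dominant > quasi_constant], "pretreat",
            sprintf("quasi-constant (> %g dominant)", quasi_constant))
  if (ncol(m) == 0) {
    last <- if (nrow(trace)) trace$criterion[nrow(trace)] else "empty input"
    stop("pretreatment removed every column (last stage: ", last, ")")
  }
  attr(m, "trace") <- trace
  m
}

#' Mutual information between a numeric feature and a discrete label
#'
#' Plug-in estimate in bits: the feature is discretized into
#' equal-frequency bins and MI computed from the joint empirical
#' distribution with the label. For a feature identical to a binary
#' label this returns the label entropy (1 bit for balanced classes);
#' for an independent feature it is near 0.
#'
#' @param x numeric feature.
#' @param y discrete label (any type with few levels).
#' @param bins number of equal-frequency bins (default 8, reduced when
#'   `x` has few distinct values).
#' @return mutual information in bits.
#' @export
mutual_information <- function(x, y, bins = 8) {
  stopifnot(length(x) == length(y))
  ux <- unique(x)
  if (length(ux) <= bins) {
    xb <- factor(x)
  } else {
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1)))
    xb <- cut(x, breaks = br, include.lowest = TRUE)
  }
  tab <- table(xb, y)
  pj <- tab / sum(tab)
  px <- rowSums(pj); py <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log2(pj[nz] / outer(px, py)[nz]))
}

#' Two-stage feature selection: mutual information, then importance
#'
#' Stage 1 ranks features by mutual information with the binary label
#' and retains those above the median of the positive MI scores. Stage 2
#' fits a random forest on the survivors and retains features whose
#' normalized Gini importance (importances sum to 1) exceeds
#' `importance_cutoff`. Both stages and all scores are recorded in the
#' selection trace. The result is invariant to input column order
#' (columns are processed in sorted-name order and reported in input
#' order).
#'
#' @param m pretreated numeric feature data.frame.
#' @param labels binary 0/1 labels.
#' @param importance_cutoff normalized importance threshold
#'   (default 0.120).
#' @param seed RNG seed for the importance forest.
#' @return data.frame of selected columns; attribute `"trace"` holds a
#'   data.frame (stage, column, score, kept).
#' @export
select_features <- function(m, labels, importance_cutoff = 0.120,
                            seed = 42L) {
  m <- as.data.frame(m)
  labels <- as.integer(labels)
  ord_names <- sort(names(m))
  mi <- vapply(ord_names, function(cn) mutual_information(m[[cn]], labels),
               numeric(1))
  pos <- mi[mi > 0]
  mi_cut <- if (length(pos)) stats::median(pos) else 0
  keep1 <- names(mi)[mi >= mi_cut & mi > 0]
  trace <- data.frame(stage = "mutual_information", column = names(mi),
                      score = unname(mi), kept = names(mi) %in% keep1,
                      stringsAsFactors = FALSE)
  if (!length(keep1)) {
    top <- utils::head(sort(mi, decreasing = TRUE), 5)
    stop("no feature passed the mutual-information stage; top scores: ",
         paste(sprintf("%s=%.3f", names(top), top), collapse = ", "))
  }
  set.seed(seed)
  rf <- randomForest::randomForest(
    x = m[, keep1, drop = FALSE], y = factor(labels), importance = FALSE,
    ntree = 500)
  imp_raw <- rf$importance[, "MeanDecreaseGini"]
  imp <- imp_raw[order(names(imp_raw))] / sum(imp_raw)
  keep2 <- names(imp)[imp > importance_cutoff]
  trace <- rbind(trace,
                 data.frame(stage = "importance", column = names(imp),
                            score = unname(imp), kept = names(imp) %in% keep2,
                            stringsAsFactors = FALSE))
  if (!length(keep2)) {
    top <- utils::head(sort(imp, decreasing = TRUE), 5)
    stop("no feature above importance cutoff ", importance_cutoff,
         "; top scores: ",
         paste(sprintf("%s=%.3f", names(top), top), collapse = ", "))
  }
  out <- m[, names(m)[names(m) %in% keep2], drop = FALSE]
  attr(out, "trace") <- trace
  out
}
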