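#' Leverage-based applicability domain
#'
#' The leverage of a compound with descriptor row x is
#' `h = x' (X'X)^-1 x`, with X the training descriptor matrix (used as
#' the descriptor pipeline emits it; set `scale = TRUE` to autoscale
#' both sets with training parameters). The warning threshold is
#' `h* = 3 p / n` (p descriptors, n training compounds); a compound with
#' `h >= h*` lies outside the applicability domain. For p = 8 selected
#' descriptors and n = 109 training compounds this gives the classic
#' h* = 0.220.
#'
#' @param train_matrix numeric matrix/data.frame of training descriptors
#'   (full column rank).
#' @param query_matrix optional matrix of query (test) descriptors with
#'   the same columns.
#' @param scale autoscale columns using training mean/SD (default FALSE).
#' @return object of class `leverage_result`: data.frame `values`
#'   (molecule row, set, h, in_domain) plus `h_star`, `p`, `n`.
#' @export
leverage <- function(train_matrix, query_matrix = NULL, scale = FALSE) {
  X <- as.matrix(train_matrix)
  storage.mode(X) <- "double"
  if (scale) {
    ctr <- colMeans(X); sds <- apply(X, 2, stats::sd)
    X <- sweep(sweep(X, 2, ctr), 2, sds, "/")
  }
  p <- ncol(X); n <- nrow(X)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("training matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  xtx_inv <- solve(crossprod(X))
  h_of <- function(M) rowSums((M %*% xtx_inv) * M)
  h_star <- 3 * p / n
  vals <- data.frame(id = rownames(X) %||% paste0("train", seq_len(n)),
                     set = "train", h = unname(h_of(X)),
                     stringsAsFactors = FALSE)
  if (!is.null(query_matrix)) {
    Q <- as.matrix(query_matrix)
    if (!identical(colnames(Q), colnames(X)) &&
        !is.null(colnames(Q)) && !is.null(colnames(X)))
      Q <- Q[, colnames(X), drop = FALSE]
    storage.mode(Q) <- "double"
    if (scale) Q <- sweep(sweep(Q, 2, ctr), 2, sds, "/")
    vals <- rbind(vals,
                  data.frame(id = rownames(Q) %||%
                               paste0("query", seq_len(nrow(Q))),
                             set = "test", h = unname(h_of(Q)),
                             stringsAsFactors = FALSE))
  }
  vals$in_domain <- vals$h < h_star
  structure(list(values = vals, h_star = h_star, p = p, n = n),
            class = "leverage_result")
}

#' @export
print.leverage_result <- function(x, ...) {
  cat(sprintf("Leverage applicability domain: p = %d, n = %d, h* = %.3f\n",
              x$p, x$n, x$h_star))
  tab <- table(x$values$set, x$values$in_domain)
  print(tab)
  invisible(x)
}

#' Applicability-domain report
#'
#' @param result a `leverage_result`.
#' @return list with per-set in/out counts and the outlier table (id,
#'   set, h) sorted by decreasing leverage.
#' @export
ad_report <- function(result) {
  stopifnot(inherits(result, "leverage_result"))
  v <- result$values
  counts <- do.call(rbind, lapply(split(v, v$set), function(d)
    data.frame(set = d$set[1], n = nrow(d), in_domain = sum(d$in_domain),
               outliers = sum(!d$in_domain), stringsAsFactors = FALSE)))
  rownames(counts) <- NULL
  out <- v[!v$in_domain, c("id", "set", "h")]
  out <- out[order(-out$h), , drop = FALSE]
  rownames(out) <- NULL
  list(h_star = result$h_star, counts = counts, outliers = out)
}

#' Export Williams-style scatter data
#'
#' @param result a `leverage_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ad_csv <- function(result, path) {
  v <- result$values
  v$threshold <- result$h_star
  utils::write.csv(v[, c("id", "set", "h", "threshold")], path,
                   row.names = FALSE)
  invisible(path)
}
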