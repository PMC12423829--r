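#' Tanimoto coefficient between two binary fingerprints
#'
#' `|a & b| / |a | b|`. Two all-zero fingerprints have no defined
#' similarity; by convention 0 is returned with a warning.
#'
#' @param a,b 0/1 integer vectors of equal length.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b))
    stop("fingerprints differ in length (", length(a), " vs ", length(b), ")")
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) {
    warning("both fingerprints empty; Tanimoto set to 0 by convention")
    return(0)
  }
  sum(a & b) / u
}

#' Pairwise Tanimoto similarity matrix
#'
#' Vectorized over a fingerprint matrix (rows = molecules).
#'
#' @param fps 0/1 matrix, one fingerprint per row.
#' @return symmetric similarity matrix with unit diagonal.
#' @export
tanimoto_matrix <- function(fps) {
  m <- as.matrix(fps); storage.mode(m) <- "double"
  inter <- tcrossprod(m)
  ones <- rowSums(m)
  uni <- outer(ones, ones, "+") - inter
  s <- ifelse(uni > 0, inter / uni, 0)
  diag(s) <- 1
  rownames(s) <- colnames(s) <- rownames(fps)
  s
}

# similarity tier of an edge, following the standard display convention:
# thick >= 0.9, medium in (0.7, 0.9), thin <= 0.7 (boundary 0.7 is thin)
edge_tier <- function(tc) {
  ifelse(tc >= 0.9, "thick", ifelse(tc > 0.7, "medium", "thin"))
}

#' Build a chemical space network
#'
#' Nodes are compounds (with pIC50 attribute); an undirected edge joins
#' two compounds when their fingerprint Tanimoto coefficient reaches the
#' edge threshold (0.68 by default). Connected components are numbered
#' by decreasing size; communities are found by greedy modularity
#' maximization within the thresholded graph; each edge carries a
#' similarity tier for display (thick Tc >= 0.9, medium 0.7 < Tc < 0.9,
#' thin Tc <= 0.7).
#'
#' @param records curated records with `molecule_id`, `smiles`, `pic50`
#'   (and optionally `family`).
#' @param fingerprints optional precomputed 0/1 matrix with rownames
#'   matching `molecule_id`; FP2 path fingerprints are computed when
#'   absent.
#' @param edge_threshold minimum Tanimoto coefficient for an edge
#'   (default 0.68).
#' @return object of class `csn`: an igraph graph with node attributes
#'   `pic50`, `component`, `community` and edge attributes `tc`, `tier`,
#'   plus `edge_threshold`.
#' @export
build_csn <- function(records, fingerprints = NULL, edge_threshold = 0.68) {
  if (is.null(fingerprints))
    fingerprints <- fp2_fingerprints(records$smiles, records$molecule_id)
  if (is.null(rownames(fingerprints)))
    rownames(fingerprints) <- records$molecule_id
  sim <- tanimoto_matrix(fingerprints[records$molecule_id, , drop = FALSE])
  n <- nrow(records)
  idx <- which(upper.tri(sim) & sim >= edge_threshold, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = records$molecule_id)
  if ("pic50" %in% names(records))
    g <- igraph::set_vertex_attr(g, "pic50", value = records$pic50)
  if ("family" %in% names(records))
    g <- igraph::set_vertex_attr(g, "family", value = records$family)
  if (nrow(idx)) {
    g <- igraph::add_edges(g, as.vector(t(idx)))
    tc <- sim[idx]
    g <- igraph::set_edge_attr(g, "tc", value = tc)
    g <- igraph::set_edge_attr(g, "tier", value = edge_tier(tc))
  }
  comp <- igraph::components(g)
  # components numbered by decreasing size, ties by smallest member index
  ord <- order(-comp$csize, vapply(seq_along(comp$csize), function(k)
    min(which(comp$membership == k)), numeric(1)))
  relabel <- match(comp$membership, ord)
  g <- igraph::set_vertex_attr(g, "component", value = relabel)
  cm <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$tc)
  g <- igraph::set_vertex_attr(g, "community",
                               value = igraph::membership(cm))
  structure(list(graph = g, edge_threshold = edge_threshold),
            class = "csn")
}

#' @export
print.csn <- function(x, ...) {
  g <- x$graph
  cat(sprintf("Chemical space network: %d nodes, %d edges (Tc >= %.2f)\n",
              igraph::vcount(g), igraph::ecount(g), x$edge_threshold))
  cat(sprintf("  components: %d, communities: %d\n",
              max(igraph::V(g)$component),
              length(unique(igraph::V(g)$community))))
  invisible(x)
}

#' Extract one connected component of a network as a subgraph
#'
#' @param csn a `csn` object.
#' @param k component number (1 = largest).
#' @return igraph subgraph.
#' @export
csn_component <- function(csn, k = 1) {
  g <- csn$graph
  igraph::induced_subgraph(g, igraph::V(g)[igraph::V(g)$component == k])
}

#' Similarity-tier statistics of a (sub)graph
#'
#' Counts and percentages of edges in the three display tiers
#' (Tc >= 0.9; 0.7 < Tc < 0.9; Tc <= 0.7), percentages rounded to 2
#' decimals. A subgraph of fewer than 2 nodes has no pairs and yields an
#' empty table.
#'
#' @param subgraph an igraph graph with edge attribute `tc`.
#' @return data.frame: tier, n_pairs, percent.
#' @export
tier_statistics <- function(subgraph) {
  tiers <- c("thick", "medium", "thin")
  if (igraph::vcount(subgraph) < 2 || igraph::ecount(subgraph) == 0)
    return(data.frame(tier = tiers, n_pairs = 0L, percent = NA_real_))
  tc <- igraph::E(subgraph)$tc
  cnt <- table(factor(edge_tier(tc), levels = tiers))
  data.frame(tier = tiers, n_pairs = as.integer(cnt),
             percent = round(100 * as.integer(cnt) / length(tc), 2))
}

#' Export a network: edge list, node table and GraphML
#'
#' Also computes seeded Fruchterman-Reingold layout coordinates so plots
#' are reproducible.
#'
#' @param csn a `csn` object.
#' @param dir output directory (created if needed).
#' @param seed layout seed (default 42).
#' @return invisible character vector of written paths.
#' @export
write_csn <- function(csn, dir, seed = 42L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- csn$graph
  el <- igraph::as_edgelist(g)
  edges <- data.frame(i = el[, 1], j = el[, 2],
                      tc = igraph::E(g)$tc, tier = igraph::E(g)$tier,
                      stringsAsFactors = FALSE)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- data.frame(id = igraph::V(g)$name,
                      pic50 = igraph::V(g)$pic50 %||% NA_real_,
                      component = igraph::V(g)$component,
                      community = igraph::V(g)$community,
                      x = xy[, 1], y = xy[, 2], stringsAsFactors = FALSE)
  p1 <- file.path(dir, "csn_edges.csv")
  p2 <- file.path(dir, "csn_nodes.csv")
  p3 <- file.path(dir, "csn.graphml")
  utils::write.csv(edges, p1, row.names = FALSE)
  utils::write.csv(nodes, p2, row.names = FALSE)
  igraph::write_graph(g, p3, format = "graphml")
  invisible(c(p1, p2, p3))
}
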