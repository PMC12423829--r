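#' Train/test split with PCA similarity map and k-means clustering
#'
#' Computes molecular fingerprints, the pairwise Tanimoto similarity
#' matrix, its top-2 principal components as a 2D chemical-space
#' embedding, k-means cluster labels on that embedding, and a seeded
#' random train/test assignment. The assignment is redrawn (bounded
#' retries) until every cluster contains at least one training compound,
#' so no chemical-space region is represented only in the test set.
#'
#' @param records curated records with `molecule_id` and `smiles`.
#' @param n_test number of test compounds (default 28).
#' @param k_clusters number of k-means clusters (default 5).
#' @param seed RNG seed (default 42).
#' @param fp_type `"atompair"` (default) or `"fp2"`.
#' @return data.frame: `molecule_id`, `set` ("train"/"test"), `pc1`,
#'   `pc2`, `cluster`.
#' @export
split_and_map <- function(records, n_test = 28, k_clusters = 5,
                          seed = 42L, fp_type = c("atompair", "fp2")) {
  n <- nrow(records)
  stopifnot(n_test < n)
  if (k_clusters > n) stop("k_clusters exceeds the number of compounds")
  fp_type <- match.arg(fp_type)
  fps <- switch(fp_type,
                atompair = atompair_fingerprints(records$smiles,
                                                 records$molecule_id),
                fp2 = fp2_fingerprints(records$smiles, records$molecule_id))
  sim <- tanimoto_matrix(fps)
  pc <- stats::prcomp(sim, center = TRUE, scale. = FALSE)
  emb <- pc$x[, 1:2, drop = FALSE]
  set.seed(seed)
  km <- stats::kmeans(emb, centers = k_clusters, nstart = 10)
  cluster <- km$cluster
  for (try in 1:100) {
    test_idx <- sample(n, n_test)
    is_train <- !(seq_len(n) %in% test_idx)
    if (all(seq_len(k_clusters) %in% cluster[is_train])) break
  }
  if (!all(seq_len(k_clusters) %in% cluster[is_train]))
    stop("could not place a training compound in every cluster")
  data.frame(molecule_id = records$molecule_id,
             set = ifelse(is_train, "train", "test"),
             pc1 = unname(emb[, 1]), pc2 = unname(emb[, 2]),
             cluster = unname(cluster), stringsAsFactors = FALSE)
}
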