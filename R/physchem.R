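#' Compute the eight physicochemical and topological descriptors
#'
#' For each compound: Crippen-type octanol-water LogP, molecular weight
#' (g/mol), ring count (smallest set of smallest rings), aromatic ring
#' count, hydrogen-bond acceptor and donor counts, rotatable bond count
#' (acyclic single bonds between non-terminal heavy atoms) and topological
#' polar surface area (A^2). LogP/MW/TPSA/HBA/HBD come from the OpenBabel
#' property engine; ring counts from ChemmineR; rotatable bonds from the
#' connection table.
#'
#' Compounds that fail to parse are listed in the `"failed"` attribute and
#' skipped; computation continues for the rest.
#'
#' @param records data.frame with `molecule_id` and `smiles` columns
#'   (e.g. the output of [curate()]).
#' @return data.frame with columns `molecule_id`, `logp`, `mw`, `nrings`,
#'   `nar`, `hba`, `hbd`, `nrb`, `tpsa`; toolkit version recorded in the
#'   `"toolkit"` attribute.
#' @export
compute_physchem <- function(records) {
  stopifnot(all(c("molecule_id", "smiles") %in% names(records)))
  ok <- is_valid_smiles(records$smiles)
  failed <- records$molecule_id[!ok]
  rec <- records[ok, , drop = FALSE]
  sdf <- sdf_from_smiles(rec$smiles, rec$molecule_id)
  p <- ChemmineR::propOB(sdf)
  rg <- ChemmineR::rings(sdf, type = "count", arom = TRUE)
  if (is.null(dim(rg))) rg <- matrix(rg, nrow = 1,
                                     dimnames = list(NULL, names(rg)))
  nrb <- vapply(seq_along(sdf), function(i)
    count_rotatable_bonds(sdf[[i]]), numeric(1))
  out <- data.frame(molecule_id = rec$molecule_id,
                    logp = p$logP, mw = p$MW,
                    nrings = as.integer(rg[, "RINGS"]),
                    nar = as.integer(rg[, "AROMATIC"]),
                    hba = as.integer(p$HBA2), hbd = as.integer(p$HBD),
                    nrb = as.integer(nrb), tpsa = p$TPSA,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "failed") <- failed
  attr(out, "toolkit") <- paste0("OpenBabel via ChemmineOB ",
                                 as.character(utils::packageVersion("ChemmineOB")))
  out
}

# rotatable bond: single, not in a ring (i.e. a bridge of the bond graph),
# both ends heavy atoms with >= 2 heavy neighbours
count_rotatable_bonds <- function(sdf_mol) {
  bb <- ChemmineR::bondblock(sdf_mol)
  ab <- ChemmineR::atomblock(sdf_mol)
  if (is.null(dim(bb)) || nrow(bb) == 0) return(0)
  el <- gsub("_.*", "", rownames(ab))
  heavy <- el != "H"
  g <- igraph::graph_from_edgelist(cbind(bb[, 1], bb[, 2]), directed = FALSE)
  bridges <- igraph::bridges(g)
  bridge_idx <- as.integer(bridges)
  # heavy-atom degree per atom
  deg_h <- vapply(seq_len(nrow(ab)), function(a) {
    nb <- c(bb[bb[, 1] == a, 2], bb[bb[, 2] == a, 1])
    sum(heavy[nb])
  }, numeric(1))
  n <- 0
  for (b in seq_len(nrow(bb))) {
    i <- bb[b, 1]; j <- bb[b, 2]
    if (bb[b, 3] != 1) next                 # single bonds only
    if (!(b %in% bridge_idx)) next          # ring bonds rotate nothing
    if (!heavy[i] || !heavy[j]) next
    if (deg_h[i] < 2 || deg_h[j] < 2) next  # terminal bonds
    n <- n + 1
  }
  n
}

#' Pearson product-moment correlation
#'
#' Thin, validating wrapper around the textbook coefficient: errors on
#' length mismatch or fewer than 3 points, and reports zero-variance
#' input as undefined (`NA` with a warning) rather than 0.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return the correlation coefficient, or `NA` if undefined.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: Pearson correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "pearson")
}

#' Pearson correlation matrix of descriptors and activity
#'
#' @param physchem descriptor table from [compute_physchem()].
#' @param pic50 optional pIC50 vector aligned with `physchem` rows; when
#'   given, appended as an extra variable.
#' @return symmetric correlation matrix with unit diagonal; constant
#'   columns (undefined correlation) are excluded.
#' @export
correlation_matrix <- function(physchem, pic50 = NULL) {
  m <- as.matrix(physchem[, setdiff(names(physchem), "molecule_id")])
  if (!is.null(pic50)) m <- cbind(m, pic50 = pic50)
  # constant columns have no defined correlation and are excluded
  const <- apply(m, 2, stats::sd) == 0
  r <- stats::cor(m[, !const, drop = FALSE], method = "pearson")
  diag(r) <- 1
  r
}

#' Export a correlation matrix in long format
#'
#' One row per unordered variable pair, for bubble-heatmap style plots.
#'
#' @param r correlation matrix.
#' @return data.frame with columns `var1`, `var2`, `r`, `abs_r`.
#' @export
correlation_long <- function(r) {
  idx <- which(upper.tri(r), arr.ind = TRUE)
  data.frame(var1 = rownames(r)[idx[, 1]], var2 = colnames(r)[idx[, 2]],
             r = r[idx], abs_r = abs(r[idx]), stringsAsFactors = FALSE)
}

#' Summarize descriptors overall and by activity class
#'
#' @param physchem descriptor table from [compute_physchem()].
#' @param activity_class optional 0/1 vector aligned with rows; when
#'   given, per-class means are included.
#' @return data.frame with one row per descriptor: mean, min, max (3
#'   decimals) and, when classes are supplied, `mean_active` /
#'   `mean_inactive`.
#' @export
summarize_physchem <- function(physchem, activity_class = NULL) {
  vars <- setdiff(names(physchem), "molecule_id")
  out <- do.call(rbind, lapply(vars, function(v) {
    x <- physchem[[v]]
    row <- data.frame(descriptor = v, mean = round(mean(x), 3),
                      min = round(min(x), 3), max = round(max(x), 3),
                      stringsAsFactors = FALSE)
    if (!is.null(activity_class)) {
      row$mean_active <- round(mean(x[activity_class == 1]), 3)
      row$mean_inactive <- round(mean(x[activity_class == 0]), 3)
    }
    row
  }))
  rownames(out) <- NULL
  out
}
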