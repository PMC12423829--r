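#' Canonicalize SMILES strings
#'
#' Converts each SMILES to the OpenBabel canonical form used throughout the
#' package for structure identity (deduplication, fixture checks). Strings
#' that do not parse return `NA` rather than raising, so callers can log the
#' offending entries.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n"))),
      error = function(e) ""
    )
    out <- sub("[\t ].*$", "", trimws(out))
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

#' Test whether SMILES strings parse
#'
#' @param smiles character vector.
#' @return logical vector, `TRUE` where the toolkit accepts the structure.
#' @export
is_valid_smiles <- function(smiles) {
  !is.na(canonical_smiles(smiles))
}

#' Build an SDFset from SMILES with stable compound ids
#'
#' @param smiles character vector of valid SMILES.
#' @param ids compound identifiers (defaults to names or seq_along).
#' @return a [ChemmineR::SDFset] with `cid` set to `ids`.
#' @keywords internal
sdf_from_smiles <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- if (!is.null(names(smiles))) names(smiles) else
    paste0("M", seq_along(smiles))
  ids <- as.character(ids)
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, ids)))
  suppressWarnings(ChemmineR::cid(sdf) <- ids)
  sdf
}

#' Path-based (FP2) fingerprints as a 0/1 matrix
#'
#' OpenBabel FP2 fingerprints: 1024-bit hashed linear fragments up to 7
#' atoms. This is the path-based topological fingerprint used for the
#' chemical space network; atom-pair fingerprints (see
#' [atompair_fingerprints()]) serve the train/test similarity map.
#'
#' @param smiles character vector of valid SMILES.
#' @param ids row names for the matrix.
#' @return integer 0/1 matrix, one row per molecule, 1024 columns.
#' @export
fp2_fingerprints <- function(smiles, ids = NULL) {
  sdf <- sdf_from_smiles(smiles, ids)
  m <- ChemmineR::fingerprintOB(sdf, "FP2")@fpma
  storage.mode(m) <- "integer"
  rownames(m) <- ChemmineR::cid(sdf)
  m
}

#' Atom-pair fingerprints as a 0/1 matrix
#'
#' ChemmineR atom-pair descriptors folded to a fixed-length binary
#' fingerprint. Used for the PCA similarity map of the train/test split.
#'
#' @inheritParams fp2_fingerprints
#' @param bits fingerprint length (default 1024).
#' @return integer 0/1 matrix.
#' @export
atompair_fingerprints <- function(smiles, ids = NULL, bits = 1024) {
  sdf <- sdf_from_smiles(smiles, ids)
  ap <- ChemmineR::sdf2ap(sdf)
  # desc2fp's numeric descnames shortcut needs the apfp dataset attached;
  # load it explicitly so the package works without library(ChemmineR)
  e <- new.env()
  utils::data("apfp", package = "ChemmineR", envir = e)
  fp <- ChemmineR::desc2fp(ap, descnames = utils::head(e$apfp, bits),
                           type = "matrix")
  storage.mode(fp) <- "integer"
  rownames(fp) <- ChemmineR::cid(sdf)
  fp
}
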