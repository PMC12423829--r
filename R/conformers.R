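#' Per-element Lennard-Jones parameters
#'
#' A compact table of well depths (kcal/mol) and diameters (Angstrom)
#' for the organic elements, at generic force-field magnitudes. Used to
#' decorate conformer ensembles for the grid engine.
#'
#' @param elements character vector of element symbols.
#' @return data.frame with columns `epsilon`, `sigma`.
#' @export
lj_parameters <- function(elements) {
  tab <- list(H  = c(0.0157, 2.50), C = c(0.0860, 3.40),
              N  = c(0.1700, 3.25), O = c(0.2100, 2.96),
              F  = c(0.0610, 2.95), S = c(0.2500, 3.56),
              Cl = c(0.2650, 3.52), Br = c(0.3200, 3.73),
              P  = c(0.2000, 3.74), I = c(0.4000, 3.98))
  unknown <- setdiff(unique(elements), names(tab))
  if (length(unknown))
    stop("no LJ parameters for element(s): ",
         paste(unknown, collapse = ", "))
  m <- do.call(rbind, tab[elements])
  data.frame(epsilon = m[, 1], sigma = m[, 2])
}

#' Construct a conformer ensemble
#'
#' @param molecule_id identifier.
#' @param atom_elements element symbols (length n_atoms).
#' @param conformers list of n_atoms x 3 coordinate matrices (Angstrom),
#'   all sharing atom count and ordering.
#' @param partial_charges per-atom charges in elementary charge units.
#' @param lj_epsilon,lj_sigma per-atom LJ parameters; derived from
#'   [lj_parameters()] when omitted.
#' @param formal_charge molecular formal charge the partial charges must
#'   sum to (default: their rounded sum).
#' @return object of class `conformer_ensemble`.
#' @export
conformer_ensemble <- function(molecule_id, atom_elements, conformers,
                               partial_charges, lj_epsilon = NULL,
                               lj_sigma = NULL, formal_charge = NULL) {
  na <- length(atom_elements)
  stopifnot(length(conformers) >= 1,
            all(vapply(conformers, function(c0)
              is.matrix(c0) && nrow(c0) == na && ncol(c0) == 3,
              logical(1))),
            length(partial_charges) == na)
  if (is.null(lj_epsilon) || is.null(lj_sigma)) {
    lj <- lj_parameters(atom_elements)
    lj_epsilon <- lj_epsilon %||% lj$epsilon
    lj_sigma <- lj_sigma %||% lj$sigma
  }
  if (is.null(formal_charge)) formal_charge <- round(sum(partial_charges))
  if (abs(sum(partial_charges) - formal_charge) > 1e-6)
    stop("partial charges sum to ", signif(sum(partial_charges), 6),
         ", expected formal charge ", formal_charge)
  structure(list(molecule_id = molecule_id, atom_elements = atom_elements,
                 conformers = lapply(conformers, unname),
                 partial_charges = as.numeric(partial_charges),
                 lj_epsilon = as.numeric(lj_epsilon),
                 lj_sigma = as.numeric(lj_sigma)),
            class = "conformer_ensemble")
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf("Conformer ensemble %s: %d atoms, %d conformers\n",
              x$molecule_id, length(x$atom_elements), length(x$conformers)))
  invisible(x)
}

# Seeded 3D embedding + Gasteiger charges through the RDKit
# distance-geometry embedder (ETKDG) followed by MMFF cleanup, driven as
# a subprocess of the installed `python`. ETKDG accepts an explicit
# random seed, making the base geometry exactly reproducible — the
# property the ensemble contract requires and which force-field builders
# with internal stochastic conformer searches cannot provide.
embed3d_script <- '
import sys
from rdkit import Chem
from rdkit.Chem import AllChem
mol = Chem.MolFromSmiles(sys.argv[1])
if mol is None:
    sys.exit(3)
mol = Chem.AddHs(mol)
if AllChem.EmbedMolecule(mol, randomSeed=int(sys.argv[2])) != 0:
    sys.exit(4)
AllChem.MMFFOptimizeMolecule(mol)
AllChem.ComputeGasteigerCharges(mol)
conf = mol.GetConformer()
for a in mol.GetAtoms():
    p = conf.GetAtomPosition(a.GetIdx())
    print("ATOM", a.GetSymbol(), repr(p.x), repr(p.y), repr(p.z),
          repr(a.GetDoubleProp("_GasteigerCharge")))
for b in mol.GetBonds():
    t = {"SINGLE": "1", "DOUBLE": "2", "TRIPLE": "3",
         "AROMATIC": "ar"}.get(str(b.GetBondType()), "1")
    print("BOND", b.GetBeginAtomIdx() + 1, b.GetEndAtomIdx() + 1, t)
'

embed3d_rdkit <- function(smiles, seed = 1L) {
  out <- suppressWarnings(system2("python",
                                  c("-c", shQuote(embed3d_script),
                                    shQuote(smiles), as.integer(seed)),
                                  stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("3D embedding failed for '", smiles, "' (exit ", status, ")")
  fields <- strsplit(out, " ", fixed = TRUE)
  atoms <- fields[vapply(fields, `[[`, character(1), 1) == "ATOM"]
  bonds <- fields[vapply(fields, `[[`, character(1), 1) == "BOND"]
  if (!length(atoms)) stop("3D embedding returned no atoms for '",
                           smiles, "'")
  list(elements = vapply(atoms, `[[`, character(1), 2),
       coords = t(vapply(atoms, function(f) as.numeric(f[3:5]),
                         numeric(3))),
       charges = vapply(atoms, function(f) as.numeric(f[6]), numeric(1)),
       bonds = data.frame(
         i = vapply(bonds, function(f) as.integer(f[2]), integer(1)),
         j = vapply(bonds, function(f) as.integer(f[3]), integer(1)),
         type = vapply(bonds, function(f) f[4], character(1)),
         stringsAsFactors = FALSE))
}

# rotatable bonds as (i, j) pairs plus the atom set distal to j:
# acyclic single bonds between non-terminal heavy atoms
rotatable_torsions <- function(bonds, elements) {
  if (nrow(bonds) == 0) return(list())
  heavy <- elements != "H"
  g <- igraph::graph_from_edgelist(cbind(bonds$i, bonds$j),
                                   directed = FALSE)
  bridge_idx <- as.integer(igraph::bridges(g))
  deg_h <- vapply(seq_along(elements), function(a) {
    nb <- c(bonds$j[bonds$i == a], bonds$i[bonds$j == a])
    sum(heavy[nb])
  }, numeric(1))
  out <- list()
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]
    if (bonds$type[b] != "1" || !(b %in% bridge_idx)) next
    if (!heavy[i] || !heavy[j] || deg_h[i] < 2 || deg_h[j] < 2) next
    g2 <- igraph::delete_edges(g, b)
    comp <- igraph::components(g2)$membership
    moving <- which(comp == comp[j] & seq_along(comp) != j)
    out[[length(out) + 1]] <- list(i = i, j = j, moving = moving)
  }
  out
}

# rotate points about the axis a->b by angle theta (radians)
rotate_about_axis <- function(coords, a, b, theta) {
  ax <- (b - a) / sqrt(sum((b - a)^2))
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  sweep(sweep(coords, 2, a) %*% t(R), 2, a, "+")
}

#' Embed a molecule in 3D and sample a conformer ensemble
#'
#' A stand-in for a dynamics-derived conformational ensemble profile:
#' the molecule is embedded in 3D with the seeded RDKit
#' distance-geometry embedder (ETKDG + MMFF cleanup, via the installed
#' `python`), Gasteiger partial charges are assigned, and additional
#' conformers are
#' generated by seeded torsion sampling — every rotatable bond is set to
#' a random staggered basin (-60/180/+60 degrees) plus jitter. Rigid
#' molecules therefore yield near-identical conformers, while flexible
#' ones populate several torsion basins.
#'
#' @param record one-row data.frame (or list) with `molecule_id` and
#'   `smiles`.
#' @param n_conformers ensemble size (default 10).
#' @param seed RNG seed.
#' @param torsion_jitter_sd jitter around each basin, degrees (default 10).
#' @return a [conformer_ensemble()].
#' @export
embed_and_sample <- function(record, n_conformers = 10, seed = 1L,
                             torsion_jitter_sd = 10) {
  stopifnot(n_conformers >= 1)
  geo <- tryCatch(embed3d_rdkit(record$smiles, seed),
                  error = function(e)
                    stop("3D embedding failed for ", record$molecule_id,
                         ": ", conditionMessage(e)))
  charges <- geo$charges
  # remove numerical drift so the ensemble is exactly neutral/integral
  charges <- charges - (sum(charges) - round(sum(charges))) /
    length(charges)
  tors <- rotatable_torsions(geo$bonds, geo$elements)
  set.seed(seed)
  confs <- vector("list", n_conformers)
  confs[[1]] <- geo$coords
  basins <- c(-60, 60, 180) * pi / 180
  if (n_conformers > 1) for (k in 2:n_conformers) {
    co <- geo$coords
    for (t in tors) {
      theta <- sample(basins, 1) +
        stats::rnorm(1, 0, torsion_jitter_sd * pi / 180)
      co[t$moving, ] <- rotate_about_axis(co[t$moving, , drop = FALSE],
                                          co[t$i, ], co[t$j, ], theta)
    }
    confs[[k]] <- co
  }
  lj <- lj_parameters(geo$elements)
  conformer_ensemble(record$molecule_id, geo$elements, confs, charges,
                     lj$epsilon, lj$sigma)
}

#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' `mobile` onto `reference` over the mapped atom pairs.
#'
#' @param mobile,reference n x 3 coordinate matrices.
#' @param atom_map two-column integer matrix of (mobile, reference) atom
#'   index pairs, at least 3 non-collinear pairs; defaults to the
#'   identity map.
#' @return list with `rotation` (3x3), `translation` (length 3), the
#'   transformed full `coords`, and `rmsd` over mapped atoms.
#' @export
kabsch <- function(mobile, reference, atom_map = NULL) {
  if (is.null(atom_map))
    atom_map <- cbind(seq_len(nrow(mobile)), seq_len(nrow(reference)))
  stopifnot(nrow(atom_map) >= 3)
  A <- mobile[atom_map[, 1], , drop = FALSE]
  B <- reference[atom_map[, 2], , drop = FALSE]
  if (qr(sweep(A, 2, colMeans(A)))$rank < 2)
    stop("mapped atoms are collinear; superposition is degenerate")
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cb - as.numeric(R %*% ca)
  fit <- sweep(mobile %*% t(R), 2, trans, "+")
  rmsd <- sqrt(mean(rowSums((fit[atom_map[, 1], , drop = FALSE] - B)^2)))
  list(rotation = R, translation = trans, coords = fit, rmsd = rmsd)
}

#' Align every conformer of an ensemble onto a reference conformer
#'
#' Rigid (rotation + translation) least-squares superposition of each
#' conformer onto the reference over the mapped atoms, as used to bring
#' a whole series into the frame of its most active member before grid
#' descriptor calculation.
#'
#' @param ensemble a [conformer_ensemble()].
#' @param reference_conformer n_ref x 3 coordinate matrix.
#' @param atom_map two-column (ensemble, reference) atom index map;
#'   identity by default.
#' @return the ensemble with aligned conformers; per-conformer RMSDs in
#'   attribute `"rmsd"`.
#' @export
align_to_reference <- function(ensemble, reference_conformer,
                               atom_map = NULL) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  fits <- lapply(ensemble$conformers, kabsch, reference = reference_conformer,
                 atom_map = atom_map)
  ensemble$conformers <- lapply(fits, `[[`, "coords")
  attr(ensemble, "rmsd") <- vapply(fits, `[[`, numeric(1), "rmsd")
  ensemble
}

#' Pairwise RMSD between two conformers (no refitting)
#' @param a,b n x 3 coordinate matrices.
#' @return root-mean-square deviation in Angstrom.
#' @export
coord_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))
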