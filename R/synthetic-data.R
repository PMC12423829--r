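#' Default scaffold library
#'
#' Five structurally distinct, asymmetric parent scaffolds (a benzamide,
#' an aryl sulfonamide, a urea-ether, a furoate ester and a
#' thiazolyl-piperazine urea) written as SMILES templates with two
#' numbered attachment slots `{R1}`, `{R2}`. The cores are diverse
#' enough that path-fingerprint Tanimoto similarity across families
#' stays below the standard network edge threshold (0.68) while members
#' within a family stay connected above it, and each scaffold is
#' asymmetric so swapping R1/R2 never yields the same canonical
#' structure.
#'
#' @return named character vector of scaffold templates.
#' @export
default_scaffolds <- function() c(
  benzamide   = "O=C(Nc1ccc{R1}cc1)c1ccc{R2}cc1",
  sulfonamide = "O=S(=O)(Nc1ccc{R1}cc1)c1ccc{R2}cc1",
  ureaether   = "O=C(Nc1ccc{R1}cc1)NCCOc1ccc{R2}cc1",
  furanester  = "O=C(OCC1CCN(c2ccc{R2}cc2)CC1)c1cc{R1}co1",
  thiazolepip = "O=C(Nc1ncc{R1}s1)N1CCN(Cc2ccc{R2}cc2)CC1"
)

#' Default substituent library
#'
#' Ring substituents spanning the classic medicinal-chemistry vocabulary:
#' halogens, methyl, methoxy, trifluoromethyl and carboxyl, plus hydrogen
#' as the unsubstituted reference. Fragments are written as SMILES branch
#' strings inserted at a scaffold slot.
#'
#' @return named character vector of substituent fragments.
#' @export
default_substituents <- function() c(
  H = "", F = "(F)", Cl = "(Cl)", Br = "(Br)", Me = "(C)",
  OMe = "(OC)", CF3 = "(C(F)(F)F)", COOH = "(C(=O)O)"
)

#' Default planted substituent effects (pIC50 increments)
#'
#' Keys are `"slot:substituent"`; hydrogen is the zero reference. Para
#' (R1) halogens carry the largest positive increments, mirroring the
#' halogen-driven SAR typical of hydrophobic enzyme pockets; carboxyl is
#' penalized.
#'
#' @return named numeric vector.
#' @export
default_effects <- function() c(
  "R1:F" = 0.6, "R1:Cl" = 0.9, "R1:Br" = 0.8, "R1:CF3" = 1.1,
  "R1:Me" = 0.2, "R1:OMe" = 0.35, "R1:COOH" = -0.6,
  "R2:F" = 0.3, "R2:Cl" = 0.5, "R2:Br" = 0.4, "R2:CF3" = 0.6,
  "R2:Me" = 0.1, "R2:OMe" = 0.2, "R2:COOH" = -0.4
)

#' Specification for a planted structure-activity dataset
#'
#' Bundles everything [generate_activity_table()] needs: library sizes,
#' planted effect coefficients, noise level and injection rates for the
#' dirty rows that give curation work to do.
#'
#' @param n_compounds number of distinct compounds (default 137).
#' @param n_families number of scaffold families, at least 3 (default 5).
#' @param scaffolds scaffold template library (see [default_scaffolds()]).
#' @param substituents substituent fragment library.
#' @param effects named pIC50 increments, keys `"slot:substituent"`.
#' @param baselines per-family baseline pIC50 (recycled to `n_families`).
#' @param noise_sd Gaussian noise on pIC50, in pIC50 units (default 0.3).
#' @param dup_fraction fraction of duplicate rows injected (default 0.05).
#' @param missing_fraction fraction of missing-IC50 rows injected (0.05).
#' @param ranged_fraction fraction of ranged-IC50 rows injected (0.02).
#' @param seed RNG seed.
#' @return an object of class `planted_sar_spec`.
#' @export
planted_sar_spec <- function(n_compounds = 137, n_families = 5,
                             scaffolds = default_scaffolds(),
                             substituents = default_substituents(),
                             effects = default_effects(),
                             baselines = c(7.1, 6.8, 7.3, 6.6, 7.0),
                             noise_sd = 0.3,
                             dup_fraction = 0.05, missing_fraction = 0.05,
                             ranged_fraction = 0.02, seed = 1L) {
  stopifnot(n_compounds >= 1, n_families >= 3,
            length(scaffolds) >= n_families,
            length(substituents) >= 1, noise_sd >= 0)
  bad <- !is_valid_smiles(vapply(scaffolds[seq_len(n_families)], function(s)
    render_compound(s, c(R1 = "", R2 = "")), character(1)))
  if (any(bad))
    stop("invalid scaffold chemistry: ",
         paste(scaffolds[seq_len(n_families)][bad], collapse = ", "))
  structure(list(n_compounds = n_compounds, n_families = n_families,
                 scaffolds = scaffolds[seq_len(n_families)],
                 substituents = substituents, effects = effects,
                 baselines = rep_len(baselines, n_families),
                 noise_sd = noise_sd, dup_fraction = dup_fraction,
                 missing_fraction = missing_fraction,
                 ranged_fraction = ranged_fraction, seed = as.integer(seed)),
            class = "planted_sar_spec")
}

# substitute R-group fragments into a scaffold template
render_compound <- function(template, frags) {
  for (slot in names(frags))
    template <- gsub(paste0("{", slot, "}"), frags[[slot]], template,
                     fixed = TRUE)
  template
}

#' Generate a planted structure-activity table
#'
#' Draws `n_compounds` distinct molecules from the scaffold/substituent
#' libraries, assigns each a pIC50 equal to its family baseline plus the
#' planted substituent increments plus Gaussian noise (clamped to
#' \[3, 11\]), back-computes IC50 in nM, and injects a stated fraction of
#' duplicate, missing-value and ranged rows so that curation is
#' non-trivial. Deterministic for a fixed seed.
#'
#' @param spec a [planted_sar_spec()].
#' @return data.frame with columns `molecule_id`, `smiles`, `ic50_nM`
#'   (character, may contain range qualifiers), `family`, plus the truth
#'   columns `pic50_true` (NA on injected rows). The planted indicator
#'   design matrix is attached as attribute `"design"` and the clean
#'   (pre-injection) table as attribute `"clean"`.
#' @export
generate_activity_table <- function(spec) {
  stopifnot(inherits(spec, "planted_sar_spec"))
  set.seed(spec$seed)
  n <- spec$n_compounds
  nf <- spec$n_families
  subs <- spec$substituents
  n_combo <- length(subs)^2

  # family sizes: first family holds ~30% so one congeneric series is large
  sizes <- if (n >= 10) {
    first <- max(ceiling(0.3 * n), min(20, n - nf + 1))
    rest <- n - first
    base <- rest %/% (nf - 1)
    c(first, rep(base, nf - 1) + c(rep(1, rest %% (nf - 1)),
                                   rep(0, nf - 1 - rest %% (nf - 1))))
  } else {
    tabulate(rep(seq_len(nf), length.out = n), nf)
  }
  if (any(sizes > n_combo))
    stop("family size ", max(sizes), " exceeds ", n_combo,
         " available substituent combinations")

  rows <- list(); design_rows <- list(); k <- 0
  eff_names <- names(spec$effects)
  for (f in seq_len(nf)) {
    if (sizes[f] == 0) next
    combos <- expand.grid(R1 = names(subs), R2 = names(subs),
                          stringsAsFactors = FALSE)
    pick <- combos[sample(nrow(combos), sizes[f]), , drop = FALSE]
    for (i in seq_len(nrow(pick))) {
      k <- k + 1
      frags <- c(R1 = unname(subs[[pick$R1[i]]]),
                 R2 = unname(subs[[pick$R2[i]]]))
      smi <- render_compound(spec$scaffolds[[f]], frags)
      keys <- paste0(c("R1:", "R2:"), c(pick$R1[i], pick$R2[i]))
      effect <- sum(spec$effects[intersect(keys, eff_names)])
      ind <- as.numeric(eff_names %in% keys)
      fam_ind <- as.numeric(seq_len(nf) == f)
      pic <- spec$baselines[f] + effect +
        if (spec$noise_sd > 0) stats::rnorm(1, 0, spec$noise_sd) else 0
      pic <- min(max(pic, 3), 11)
      rows[[k]] <- data.frame(
        molecule_id = sprintf("K%03d", k), smiles = smi,
        family = names(spec$scaffolds)[f], pic50_true = pic,
        stringsAsFactors = FALSE)
      design_rows[[k]] <- c(fam_ind, ind)
    }
  }
  tab <- do.call(rbind, rows)
  if (!all(is_valid_smiles(tab$smiles))) {
    bad <- tab$smiles[!is_valid_smiles(tab$smiles)]
    stop("invalid generated fragment chemistry: ",
         paste(utils::head(bad, 3), collapse = ", "))
  }
  tab$ic50_nM <- formatC(pic50_to_ic50(tab$pic50_true),
                         format = "g", digits = 10)
  design <- do.call(rbind, design_rows)
  colnames(design) <- c(paste0("family:", names(spec$scaffolds)), eff_names)
  rownames(design) <- tab$molecule_id
  clean <- tab

  # inject dirty rows
  n_dup <- round(spec$dup_fraction * n)
  n_mis <- round(spec$missing_fraction * n)
  n_rng <- round(spec$ranged_fraction * n)
  inject <- list()
  if (n_dup > 0) {
    src <- tab[sample(n, n_dup), , drop = FALSE]
    src$molecule_id <- sprintf("DUP%03d", seq_len(n_dup))
    inject <- c(inject, list(src))
  }
  if (n_mis > 0) {
    src <- tab[sample(n, n_mis), , drop = FALSE]
    src$molecule_id <- sprintf("MIS%03d", seq_len(n_mis))
    src$ic50_nM <- NA_character_
    src$pic50_true <- NA_real_
    inject <- c(inject, list(src))
  }
  if (n_rng > 0) {
    src <- tab[sample(n, n_rng), , drop = FALSE]
    src$molecule_id <- sprintf("RNG%03d", seq_len(n_rng))
    src$ic50_nM <- ">10000"
    src$pic50_true <- NA_real_
    inject <- c(inject, list(src))
  }
  out <- rbind(tab, do.call(rbind, inject))
  out <- out[sample(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  out <- out[, c("molecule_id", "smiles", "ic50_nM", "family", "pic50_true")]
  attr(out, "design") <- design
  attr(out, "clean") <- clean
  out
}

#' Write a generated activity table as CSV
#' @param tab table from [generate_activity_table()].
#' @param path output CSV path (columns molecule_id, smiles, ic50_nM).
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(tab, path) {
  utils::write.csv(tab[, c("molecule_id", "smiles", "ic50_nM")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Hard-coded toy geometries for field-engine oracles
#'
#' Three fixtures with coordinates, Gasteiger-scale charges and
#' Lennard-Jones parameters chosen so grid-energy tests have closed-form
#' answers: a unit-separation diatomic with unit charges, a neutral bent
#' triatomic, and a planar 12-atom aromatic-like ring.
#'
#' @param name one of `"diatomic"`, `"water_like"`, `"benzene_like"`.
#' @return list with `atom_elements`, `coordinates` (n x 3 matrix, in
#'   Angstrom), `partial_charges` (e), `lj_epsilon` (kcal/mol),
#'   `lj_sigma` (Angstrom).
#' @export
generate_toy_geometry <- function(name = c("diatomic", "water_like",
                                           "benzene_like")) {
  if (!name[1] %in% c("diatomic", "water_like", "benzene_like"))
    stop("unknown geometry '", name[1],
         "'; alternatives: diatomic, water_like, benzene_like")
  name <- name[1]
  if (name == "diatomic") {
    g <- list(atom_elements = c("C", "C"),
              coordinates = rbind(c(0, 0, 0), c(1, 0, 0)),
              partial_charges = c(1, -1),
              lj_epsilon = c(0.1, 0.1), lj_sigma = c(3.0, 3.0))
  } else if (name == "water_like") {
    a <- 104.5 * pi / 180; r <- 0.9572
    g <- list(atom_elements = c("O", "H", "H"),
              coordinates = rbind(c(0, 0, 0),
                                  c(r, 0, 0),
                                  c(r * cos(a), r * sin(a), 0)),
              partial_charges = c(-0.8, 0.4, 0.4),
              lj_epsilon = c(0.152, 0.02, 0.02),
              lj_sigma = c(3.15, 1.1, 1.1))
  } else {
    th <- seq(0, 2 * pi, length.out = 7)[1:6]
    cc <- cbind(1.396 * cos(th), 1.396 * sin(th), 0)
    hh <- cbind(2.480 * cos(th), 2.480 * sin(th), 0)
    g <- list(atom_elements = c(rep("C", 6), rep("H", 6)),
              coordinates = rbind(cc, hh),
              partial_charges = c(rep(-0.115, 6), rep(0.115, 6)),
              lj_epsilon = c(rep(0.086, 6), rep(0.015, 6)),
              lj_sigma = c(rep(3.4, 6), rep(2.5, 6)))
  }
  stopifnot(nrow(g$coordinates) == length(g$atom_elements),
            length(g$partial_charges) == length(g$atom_elements))
  g
}

#' Synthetic congeneric conformer ensembles for field-QSAR validation
#'
#' Builds a congeneric series on a rigid planar aromatic-like scaffold:
#' every member shares the 12-atom ring of [generate_toy_geometry()] and
#' carries pseudo-substituents at the para and meta positions whose
#' Lennard-Jones size/depth and partial charge vary across the series.
#' Conformers are seeded Gaussian perturbations of the substituent and
#' ring coordinates, standing in for a dynamics-derived conformational
#' ensemble profile. All members are aligned by construction (common
#' scaffold frame), so the series can feed the grid engine directly.
#'
#' @param n_compounds series size (default 24).
#' @param n_conformers conformers per member (default 5).
#' @param jitter_sd coordinate perturbation SD in Angstrom (default 0.1).
#' @param seed RNG seed.
#' @return list of conformer ensembles (see [conformer_ensemble()]).
#' @export
synthetic_congeneric_ensembles <- function(n_compounds = 24,
                                           n_conformers = 5,
                                           jitter_sd = 0.1, seed = 1L) {
  set.seed(seed)
  base <- generate_toy_geometry("benzene_like")
  # substituent vocabulary: (sigma, epsilon, charge) spanning H..Br-like
  vocab <- data.frame(
    el = c("H", "F", "Cl", "Br", "C", "O"),
    sigma = c(2.5, 2.95, 3.5, 3.7, 3.4, 3.1),
    eps = c(0.015, 0.061, 0.265, 0.32, 0.086, 0.17),
    q = c(0.1, -0.25, -0.15, -0.1, 0.0, -0.35))
  para_dir <- base$coordinates[1, ] / sqrt(sum(base$coordinates[1, ]^2))
  meta_dir <- base$coordinates[3, ] / sqrt(sum(base$coordinates[3, ]^2))
  lapply(seq_len(n_compounds), function(i) {
    vp <- vocab[sample(nrow(vocab), 1), ]
    vm <- vocab[sample(nrow(vocab), 1), ]
    # substituents replace the para/meta hydrogens (sites 7 and 9)
    coords <- base$coordinates
    coords[7, ] <- (1.396 + 1.5) * para_dir
    coords[9, ] <- (1.396 + 1.5) * meta_dir
    charges <- base$partial_charges
    eps <- base$lj_epsilon
    sig <- base$lj_sigma
    charges[7] <- vp$q; charges[9] <- vm$q
    eps[7] <- vp$eps;   eps[9] <- vm$eps
    sig[7] <- vp$sigma; sig[9] <- vm$sigma
    elements <- base$atom_elements
    elements[7] <- vp$el; elements[9] <- vm$el
    # neutralize: spread the residual charge over the ring carbons
    charges[1:6] <- charges[1:6] - sum(charges) / 6
    confs <- lapply(seq_len(n_conformers), function(j) {
      coords + matrix(stats::rnorm(length(coords), 0, jitter_sd),
                      ncol = 3)
    })
    conformer_ensemble(sprintf("S%03d", i), elements, confs,
                       partial_charges = charges, lj_epsilon = eps,
                       lj_sigma = sig)
  })
}

#' Plant a linear activity response on computed field descriptors
#'
#' Selects `k` well-separated, high-variance columns of a field
#' descriptor matrix as the causal steric/electrostatic features and
#' builds pIC50 as a linear function of their standardized values plus
#' Gaussian noise. The result is the ground truth for parameter-recovery
#' tests of the PLS stage.
#'
#' @param fmat field descriptor matrix (molecules x grid columns).
#' @param k number of causal columns (default 3).
#' @param coefs coefficients on the standardized causal columns
#'   (recycled to length `k`; default `c(1, -0.8, 0.6)`).
#' @param noise_sd Gaussian noise SD in pIC50 units (default 0.3).
#' @param baseline intercept pIC50 (default 6.5).
#' @param max_abs_cor maximum |correlation| allowed between chosen causal
#'   columns (default 0.8).
#' @param seed RNG seed.
#' @return list with `y` (pIC50), `causal` (column names), `coefs`,
#'   `baseline`.
#' @export
plant_field_response <- function(fmat, k = 3, coefs = c(1, -0.8, 0.6),
                                 noise_sd = 0.3, baseline = 6.5,
                                 max_abs_cor = 0.8, seed = 1L) {
  set.seed(seed)
  v <- apply(fmat, 2, stats::var)
  ord <- order(v, decreasing = TRUE)
  chosen <- integer(0)
  for (j in ord) {
    if (length(chosen) == k) break
    if (v[j] <= 1e-10) break
    ok <- all(vapply(chosen, function(c0)
      abs(stats::cor(fmat[, j], fmat[, c0])) < max_abs_cor, logical(1)))
    if (ok) chosen <- c(chosen, j)
  }
  if (length(chosen) < k)
    stop("could not find ", k, " sufficiently independent columns")
  coefs <- rep_len(coefs, k)
  z <- scale(fmat[, chosen, drop = FALSE])
  y <- baseline + as.numeric(z %*% coefs) +
    stats::rnorm(nrow(fmat), 0, noise_sd)
  list(y = y, causal = colnames(fmat)[chosen], coefs = coefs,
       baseline = baseline)
}
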