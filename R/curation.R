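#' Convert IC50 in nM to pIC50
#'
#' pIC50 is the negative base-10 logarithm of the molar IC50:
#' `-log10(ic50 * 1e-9)`. Higher values mean more potent inhibition.
#'
#' @param ic50 positive IC50 values in nM.
#' @return pIC50 values.
#' @export
ic50_to_pic50 <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    stop("ic50 must be finite and > 0 (in nM)")
  -log10(ic50 * 1e-9)
}

#' Convert pIC50 back to IC50 in nM
#' @param pic50 pIC50 values.
#' @return IC50 in nM.
#' @export
pic50_to_ic50 <- function(pic50) 10^(-pic50) * 1e9

#' Assign the binary activity class
#'
#' Compounds at or above the potency cutoff are "actives" (1), the rest
#' "inactives" (0). The default cutoff of pIC50 7.6 (IC50 about 25 nM)
#' separates potent enzyme inhibitors from the remainder of a screening
#' series.
#'
#' @param pic50 finite pIC50 values.
#' @param cutoff class boundary on the pIC50 scale (default 7.6).
#' @return integer vector of 0/1 classes.
#' @export
assign_class <- function(pic50, cutoff = 7.6) {
  if (any(!is.finite(pic50))) stop("pic50 must be finite")
  as.integer(pic50 >= cutoff)
}

#' Curate a raw activity table into modeling-ready compound records
#'
#' Reproduces the standard refinement of a ChEMBL-style activity dump:
#' rows with missing IC50, ranged IC50 qualifiers (">", "<", or an interval),
#' or unparseable SMILES are removed; duplicate canonical structures are
#' merged (geometric mean of concordant IC50s, i.e. all within one log
#' unit) or dropped entirely when their measurements disagree by more than
#' a log unit. Every removal is logged with a reason.
#'
#' @param raw data.frame with columns `molecule_id`, `smiles`, `ic50_nM`
#'   (character or numeric; range qualifiers kept as text), optionally
#'   `family`.
#' @param cutoff pIC50 activity cutoff passed to [assign_class()].
#' @return data.frame of curated records with columns `molecule_id`,
#'   `smiles` (canonical), `ic50_nM`, `pic50`, `activity_class`, and
#'   `family` if present, ordered by `molecule_id`. The curation log is
#'   attached as attribute `"log"` (data.frame: molecule_id, reason).
#' @export
curate <- function(raw, cutoff = 7.6) {
  stopifnot(is.data.frame(raw),
            all(c("molecule_id", "smiles", "ic50_nM") %in% names(raw)))
  raw$molecule_id <- as.character(raw$molecule_id)
  ic_txt <- trimws(as.character(raw$ic50_nM))
  log <- data.frame(molecule_id = character(0), reason = character(0),
                    stringsAsFactors = FALSE)
  note <- function(ids, reason) {
    if (!length(ids)) return(log)
    rbind(log, data.frame(molecule_id = ids, reason = reason,
                          stringsAsFactors = FALSE))
  }

  missing_ic <- is.na(raw$ic50_nM) | !nzchar(ic_txt) |
    toupper(ic_txt) %in% c("NA", "NAN")
  log <- note(raw$molecule_id[missing_ic], "missing IC50")

  ranged <- !missing_ic & grepl("[<>~]|\\d\\s*-\\s*\\d", ic_txt)
  log <- note(raw$molecule_id[ranged], "ranged IC50")

  keep <- !missing_ic & !ranged
  ic_num <- suppressWarnings(as.numeric(ic_txt))
  bad_num <- keep & (is.na(ic_num) | ic_num <= 0)
  log <- note(raw$molecule_id[bad_num], "non-numeric or non-positive IC50")
  keep <- keep & !bad_num

  can <- rep(NA_character_, nrow(raw))
  can[keep] <- canonical_smiles(raw$smiles[keep])
  bad_smi <- keep & is.na(can)
  log <- note(raw$molecule_id[bad_smi], "unparseable SMILES")
  keep <- keep & !bad_smi

  df <- data.frame(molecule_id = raw$molecule_id[keep],
                   smiles = can[keep],
                   ic50_nM = ic_num[keep],
                   stringsAsFactors = FALSE)
  if ("family" %in% names(raw)) df$family <- as.character(raw$family)[keep]

  # duplicate canonical structures: merge concordant, drop discordant
  out <- list(); i <- 0
  for (s in unique(df$smiles)) {
    rows <- df[df$smiles == s, , drop = FALSE]
    if (nrow(rows) > 1) {
      lg <- log10(rows$ic50_nM)
      if (max(lg) - min(lg) <= 1) {
        survivor <- rows[order(rows$molecule_id)[1], , drop = FALSE]
        survivor$ic50_nM <- 10^mean(lg)   # geometric mean
        log <- note(setdiff(rows$molecule_id, survivor$molecule_id),
                    "duplicate structure (merged into survivor)")
        rows <- survivor
      } else {
        log <- note(rows$molecule_id, "duplicate structure, discordant IC50s")
        next
      }
    }
    i <- i + 1; out[[i]] <- rows
  }
  if (i == 0) {
    top <- if (nrow(log)) names(sort(table(log$reason), decreasing = TRUE))[1]
           else "empty input"
    stop("curation removed every record; dominant reason: ", top)
  }
  df <- do.call(rbind, out)
  df <- df[order(df$molecule_id), , drop = FALSE]
  rownames(df) <- NULL
  df$pic50 <- ic50_to_pic50(df$ic50_nM)
  df$activity_class <- assign_class(df$pic50, cutoff)
  attr(df, "log") <- log
  attr(df, "canonicalization") <- "OpenBabel canonical SMILES (ChemmineOB)"
  df
}

#' Write a curated table and its curation log
#'
#' @param records curated data.frame from [curate()].
#' @param csv_path output CSV path.
#' @param log_path optional path for the plain-text curation log.
#' @return `csv_path`, invisibly.
#' @export
write_curated <- function(records, csv_path, log_path = NULL) {
  utils::write.csv(records, csv_path, row.names = FALSE)
  if (!is.null(log_path)) {
    lg <- attr(records, "log")
    hdr <- paste0("# canonicalization: ",
                  attr(records, "canonicalization") %||% "unknown")
    writeLines(c(hdr, sprintf("%s\t%s", lg$molecule_id, lg$reason)), log_path)
  }
  invisible(csv_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
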