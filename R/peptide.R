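# Peptide physicochemistry: Kyte-Doolittle GRAVY, net charge vs pH, and
# isoelectric point by charge bisection.
#
# Peptides are treated as linear with free termini (no disulfide
# cyclization, no C-terminal amidation), matching the ProtParam convention.
# The biological oxytocin nonapeptide is cyclic and C-terminally amidated;
# this divergence is documented in the vignette.

# Kyte & Doolittle (1982) hydropathy values
.KD <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
         Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
         L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
         S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

.aa_chars <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(ch), .AA_LETTERS)
  if (length(bad)) {
    stop("unknown residue(s): ", paste(bad, collapse = ", "))
  }
  ch
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the residues of a sequence.  More
#' negative values indicate a more hydrophilic molecule.
#'
#' @param sequence Amino-acid string (standard 20 letters).
#' @return A value in `[-4.5, 4.5]`.
#' @examples
#' gravy("CYIQNCPLG")  # consensus mammalian oxytocin: 0.3333
#' gravy("CYIQNCPPG")  # Pro8 variant is more hydrophilic
#' @export
gravy <- function(sequence) {
  mean(.KD[.aa_chars(sequence)])
}

#' pKa sets for charge calculations
#'
#' `"bjellqvist"` (default) is the set used by the ExPASy ProtParam tool,
#' including its residue-specific N- and C-terminal pKa values;
#' `"emboss"` is the EMBOSS `iep` set.  Both are shipped as editable CSV
#' tables under `inst/extdata` (`group,residue,pKa`, residue `*` = default
#' for the group) and can be replaced with [read_pka_table()].
#'
#' @param name `"bjellqvist"` or `"emboss"`.
#' @return A `pka_set` list with elements `sidechain_pos`, `sidechain_neg`
#'   (named numeric vectors), `nterm`, `cterm` (named vectors with a `*`
#'   default), and `name`.
#' @export
pka_set <- function(name = c("bjellqvist", "emboss")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("pka_", name, ".csv"),
                      package = "oxtkit", mustWork = TRUE)
  read_pka_table(path, name = name)
}

#' @rdname pka_set
#' @param path CSV path with columns `group,residue,pKa`; `group` is one of
#'   `sidechain_pos`, `sidechain_neg`, `nterm`, `cterm`.
#' @export
read_pka_table <- function(path, name = basename(path)) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("group", "residue", "pKa") %in% names(df)))
  pick <- function(g) {
    sub <- df[df$group == g, ]
    setNames(sub$pKa, sub$residue)
  }
  out <- list(sidechain_pos = pick("sidechain_pos"),
              sidechain_neg = pick("sidechain_neg"),
              nterm = pick("nterm"), cterm = pick("cterm"), name = name)
  if (!"*" %in% names(out$nterm) || !"*" %in% names(out$cterm)) {
    stop("pKa table must provide '*' defaults for nterm and cterm")
  }
  structure(out, class = "pka_set")
}

.term_pka <- function(tab, residue) {
  if (residue %in% names(tab)) tab[[residue]] else tab[["*"]]
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch sum: the N-terminus and K/R/H side chains
#' contribute `+1/(1 + 10^(pH - pKa))`; the C-terminus and D/E/C/Y side
#' chains contribute `-1/(1 + 10^(pKa - pH))`.  Monotonically non-increasing
#' in pH.
#'
#' @param sequence Amino-acid string.
#' @param pH pH in `(0, 14)`.
#' @param pka A [pka_set()].
#' @return Net charge in elementary charge units.
#' @export
net_charge <- function(sequence, pH, pka = pka_set()) {
  ch <- .aa_chars(sequence)
  stopifnot(pH > 0, pH < 14)
  pos_pka <- c(.term_pka(pka$nterm, ch[1L]),
               unname(pka$sidechain_pos[ch[ch %in% names(pka$sidechain_pos)]]))
  neg_pka <- c(.term_pka(pka$cterm, ch[length(ch)]),
               unname(pka$sidechain_neg[ch[ch %in% names(pka$sidechain_neg)]]))
  sum(1 / (1 + 10^(pH - pos_pka))) - sum(1 / (1 + 10^(neg_pka - pH)))
}

#' Isoelectric point by charge bisection
#'
#' The pH at which [net_charge()] crosses zero, found by bisection on
#' `(0, 14)`.  A crossing is guaranteed because every peptide carries both
#' termini and the charge is monotone in pH.
#'
#' @inheritParams net_charge
#' @param tol Bisection stopping width in pH units (default 0.001).
#' @return The pI in pH units.
#' @examples
#' isoelectric_point("CYIQNCPLG")
#' @export
isoelectric_point <- function(sequence, pka = pka_set(), tol = 0.001) {
  lo <- 1e-6; hi <- 14 - 1e-6
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physicochemical profile of peptides
#'
#' GRAVY, isoelectric point, and net charge at a reference pH for each
#' sequence.  The default reference pH of 7.3 approximates brain tissue; a
#' pI below it means the molecule carries a net negative charge there.
#'
#' @param sequences Named character vector (or amino-acid `seq_alignment`)
#'   of peptide sequences without gaps.
#' @param reference_pH pH for the net-charge column (default 7.3).
#' @param pka A [pka_set()].
#' @return A data frame with columns `name`, `sequence`, `gravy`, `pI`,
#'   `charge_at_reference`, plus attribute `reference_pH`.
#' @export
peptide_profile <- function(sequences, reference_pH = 7.3, pka = pka_set()) {
  seqs <- unclass(sequences)
  nm <- names(seqs) %||% paste0("peptide", seq_along(seqs))
  out <- data.frame(
    name = nm,
    sequence = unname(seqs),
    gravy = vapply(seqs, gravy, numeric(1)),
    pI = vapply(seqs, isoelectric_point, numeric(1), pka = pka),
    charge_at_reference = vapply(seqs, net_charge, numeric(1),
                                 pH = reference_pH, pka = pka),
    row.names = NULL)
  attr(out, "reference_pH") <- reference_pH
  attr(out, "pka_set") <- pka$name
  out
}
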