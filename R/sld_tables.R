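## Atomic and residue-level scattering tables.
##
## Bound coherent neutron scattering lengths (fm) from the standard
## neutron-data compilations; electron counts and atomic weights for the
## X-ray and mass bookkeeping.  Residue rows carry explicit atom inventories
## (C,H,N,O,P,S counts of the in-chain monomer, i.e. monomer minus water for
## amino acids, nucleoside + HPO3 - H2O for deoxynucleotides) so that any
## residue-level quantity can be audited against a per-atom sum.

# fm; H is 1H, D is 2H
.nucsas_b_coh <- c(H = -3.7390, D = 6.6710, C = 6.6460, N = 9.3600,
                   O = 5.8030, P = 5.1300, S = 2.8470)

.nucsas_electrons <- c(H = 1, D = 1, C = 6, N = 7, O = 8, P = 15, S = 16)

.nucsas_atwt <- c(H = 1.00794, D = 2.01410, C = 12.0107, N = 14.0067,
                  O = 15.9994, P = 30.9738, S = 32.0650)

## Amino-acid residues (in peptide chain).  n_labile counts exchangeable
## hydrogens consistent with the neutral formula: one backbone amide H
## (none for Pro) plus side-chain OH/NH/NH2/SH/COOH protons.
.nucsas_aa_table <- data.frame(
  code = c("A","R","N","D","C","E","Q","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V"),
  C = c(3, 6, 4, 4, 3, 5, 5, 2, 6, 6,  6, 6, 5, 9, 5, 3, 4, 11, 9, 5),
  H = c(5,12, 6, 5, 5, 7, 8, 3, 7,11, 11,12, 9, 9, 7, 5, 7, 10, 9, 9),
  N = c(1, 4, 2, 1, 1, 1, 2, 1, 3, 1,  1, 2, 1, 1, 1, 1, 1,  2, 1, 1),
  O = c(1, 1, 2, 3, 1, 3, 2, 1, 1, 1,  1, 1, 1, 1, 1, 2, 2,  1, 2, 1),
  P = 0L,
  S = c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0,  0, 0, 1, 0, 0, 0, 0,  0, 0, 0),
  n_labile = c(1, 5, 3, 2, 2, 2, 3, 1, 2, 1,
               1, 3, 1, 1, 0, 2, 2, 2, 2, 1),
  stringsAsFactors = FALSE
)

## Deoxynucleotide residues in a DNA strand (free-acid phosphodiester form):
## nucleoside + HPO3 - H2O.  n_labile = base NH/NH2 protons plus the single
## phosphate OH of the free-acid form (all fast-exchanging).
.nucsas_dna_table <- data.frame(
  code = c("A", "C", "G", "T"),
  C = c(10,  9, 10, 10),
  H = c(12, 12, 12, 13),
  N = c(5, 3, 5, 2),
  O = c(5, 6, 6, 7),
  P = 1L,
  S = 0L,
  n_labile = c(3, 3, 4, 2),
  stringsAsFactors = FALSE
)

.nucsas_mw_row <- function(row) {
  sum(unlist(row[c("C","H","N","O","P","S")]) *
        .nucsas_atwt[c("C","H","N","O","P","S")])
}

## Scattering length (fm) of one residue with n_labile * frac_exchanged
## hydrogens replaced by deuterium; electron count; molecular weight.
.nucsas_residue_props <- function(tab) {
  el <- c("C","H","N","O","P","S")
  counts <- as.matrix(tab[, el])
  list(
    b_h       = drop(counts %*% .nucsas_b_coh[el]),
    b_per_exch = tab$n_labile * (.nucsas_b_coh["D"] - .nucsas_b_coh["H"]),
    electrons = drop(counts %*% .nucsas_electrons[el]),
    mw        = drop(counts %*% .nucsas_atwt[el]),
    n_labile  = tab$n_labile,
    code      = tab$code
  )
}

#' Residue scattering tables
#'
#' Returns the residue-level scattering table used by the contrast
#' calculator, with explicit atom inventories (C, H, N, O, P, S counts of
#' the in-chain monomer), labile-hydrogen counts, bound coherent scattering
#' length at zero exchange (`b_h`, fm), electron counts and molecular
#' weights.  Exposed so the tables can be audited against per-atom sums.
#'
#' @param which `"aa"` for the 20 amino-acid residues, `"dna"` for the four
#'   deoxynucleotide residues, `"atoms"` for the atomic constants.
#' @return A `data.frame` (residues) or named numeric vector (atoms).
#' @export
sas_residue_table <- function(which = c("aa", "dna", "atoms")) {
  which <- match.arg(which)
  if (which == "atoms") {
    return(rbind(b_coh_fm = .nucsas_b_coh,
                 electrons = .nucsas_electrons[names(.nucsas_b_coh)],
                 atomic_weight = .nucsas_atwt[names(.nucsas_b_coh)]))
  }
  tab <- if (which == "aa") .nucsas_aa_table else .nucsas_dna_table
  p <- .nucsas_residue_props(tab)
  cbind(tab, b_h_fm = p$b_h, electrons = p$electrons, mw = p$mw)
}
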