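## Built-in compositions.
##
## The DNA positioning sequences (Widom 601 and the alpha-satellite repeat)
## are the standard published reconstitution sequences.  The histone chains
## shipped here are SYNTHETIC histone-like sequences: deterministic strings
## with the lengths and approximate residue composition (lysine/arginine
## rich, ~110 Da mean residue mass) of the core histones H3, H4, H2A and
## H2B, suitable for contrast and molecular-weight bookkeeping exercises.
## They are not the biological sequences.

#' Built-in DNA positioning sequences
#'
#' @param which `"601"` (Widom 601) or `"alpha_sat"` (alpha-satellite).
#' @return single-strand sequence string (145 bp).
#' @export
nucleosome_dna_sequence <- function(which = c("601", "alpha_sat")) {
  which <- match.arg(which)
  seqs <- c(
    "601" = paste0(
      "ATCAGAATCCCGGTGCCGAGGCCGCTCAATTGGTCGTAGACAGCTCTAGCACCGCTTAAACGCAC",
      "GTACGCGCTGTCCCCCGCGTTTTAACCGCCAAGGGGATTACTCCCTAGTCTCCAGGCACGTGTCA",
      "GATATATACATCGAT"),
    "alpha_sat" = paste0(
      "ATCAATATCCACCTGCAGATTCTACCAAAAGTGTATTTGGAAACTGCTCCATCAAAAGGCATGTT",
      "CAGCTCTGTGAGTGAAACTCCATCATCACAAAGAATATTCTGAGAATGCTTCCGTTTGCCTTTTA",
      "TATGAACTTCCTGAT"))
  unname(seqs[which])
}

# deterministic histone-like chain: motif repeated and trimmed
.histone_like <- function(motif, len) {
  s <- paste(rep(motif, ceiling(len / nchar(motif))), collapse = "")
  substr(s, 1, len)
}

#' Synthetic histone-like octamer chains
#'
#' Deterministic synthetic sequences with core-histone lengths (135, 102,
#' 129, 125 residues) and a lysine/arginine-rich composition; two copies of
#' each chain build an octamer of roughly 108 kDa.  Documented as synthetic
#' stand-ins, not biological sequences.
#'
#' @return named character vector of four chains.
#' @export
synthetic_histone_chains <- function() {
  c(H3  = .histone_like("ARTKQLATKAARKSAPGGVKKPHRYRPGT", 135),
    H4  = .histone_like("SGRGKGGKGLGKGGAKRHRKVLRDNIQGI", 102),
    H2A = .histone_like("SGRGKQGGKARAKAKTRSSRAGLQFPVGR", 129),
    H2B = .histone_like("PEPAKSAPAPKKGSKKAVTKAQKKDGKKR", 125))
}

#' Default nucleosome core particle composition
#'
#' Two copies each of the four synthetic histone-like chains wrapped by
#' 147 bp of DNA (by default the 145 bp Widom-601 strand padded with one
#' extra A/T base pair at each end), with the standard mass densities
#' (protein 1.35, DNA 1.69 g/cm^3) and 50% labile-H exchange.
#'
#' @param dna `"601"`, `"alpha_sat"`, an explicit sequence string, or a bare
#'   base-pair count.
#' @param exchange_fraction labile-H exchange fraction.
#' @return a [composition_spec].
#' @export
nucleosome_composition <- function(dna = "601", exchange_fraction = 0.5) {
  chains <- as.list(synthetic_histone_chains())
  if (is.numeric(dna))
    return(composition_spec(protein_chains = chains, protein_copies = 2L,
                            dna_basepairs = dna,
                            exchange_fraction = exchange_fraction))
  seq1 <- if (dna %in% c("601", "alpha_sat"))
    paste0("A", nucleosome_dna_sequence(dna), "T") else dna
  composition_spec(protein_chains = chains, protein_copies = 2L,
                   dna_sequence = seq1,
                   exchange_fraction = exchange_fraction)
}
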