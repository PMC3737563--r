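# Nucleotide / amino-acid primitives shared by all modules.

# IUPAC nucleotide alphabet and Watson-Crick complement (ambiguity codes map
# to the complement of the set they denote).
IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "V", "D", "H", "N")
IUPAC_FROM <- "ACGTRYSWKMBVDHNacgtryswkmbvdhn"
IUPAC_TO   <- "TGCAYRSWMKVBHDNtgcayrswmkvbhdn"

#' Validate a nucleotide sequence
#'
#' Checks that `s` is a single non-empty string over the DNA alphabet.
#' With `iupac = TRUE` the full IUPAC ambiguity alphabet (including the
#' wildcard `n`) is accepted; otherwise only unambiguous `A/C/G/T`.
#'
#' @param s character scalar, 5'->3'.
#' @param iupac allow IUPAC ambiguity codes.
#' @param what label used in error messages.
#' @return `s`, invisibly, after validation.
#' @keywords internal
validate_dna <- function(s, iupac = FALSE, what = "sequence") {
  if (!is.character(s) || length(s) != 1L || is.na(s))
    stop(what, " must be a single character string", call. = FALSE)
  if (!nzchar(s))
    stop(what, " must be non-empty", call. = FALSE)
  allowed <- if (iupac) IUPAC_CHARS else c("A", "C", "G", "T")
  chars <- toupper(strsplit(s, "", fixed = TRUE)[[1L]])
  bad <- which(!(chars %in% allowed))
  if (length(bad)) {
    stop(sprintf("invalid character '%s' at position %d of %s",
                 strsplit(s, "", fixed = TRUE)[[1L]][bad[1L]], bad[1L], what),
         call. = FALSE)
  }
  invisible(s)
}

#' Reverse complement of a DNA sequence
#'
#' Watson-Crick reverse complement. IUPAC ambiguity codes are mapped to the
#' complement of the base set they denote (e.g. `R` -> `Y`, `N`/`n` -> itself);
#' case is preserved so that degenerate motifs written with a lowercase `n`
#' wildcard survive a round trip.
#'
#' @param s character scalar, 5'->3'.
#' @return the reverse complement, 5'->3'.
#' @examples
#' revcomp("ACTC")                 # "GAGT"
#' revcomp(revcomp("TTnAAnnnTCAA")) # involution
#' @export
revcomp <- function(s) {
  validate_dna(s, iupac = TRUE)
  comp <- chartr(IUPAC_FROM, IUPAC_TO, s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

# --- molecular weights ------------------------------------------------------

# Average masses (Da) of 2'-deoxyribonucleosides (5'-OH, 3'-OH) and of the
# internal phosphodiester bridge (+HPO3 -H2O). An n-mer single strand with
# free 5'- and 3'-hydroxyls then weighs sum(nucleosides) + (n-1) * bridge,
# matching the vendor convention for synthetic (unphosphorylated) oligos.
DNA_NUCLEOSIDE_MASS <- c(A = 251.24, C = 227.22, G = 267.24, T = 242.23)
DNA_BRIDGE_MASS <- 61.96

#' Average mass of a single DNA strand
#'
#' Mass of a synthetic single-stranded oligo with 5'-OH and 3'-OH termini
#' (no terminal phosphate), using average atomic masses. Ambiguity codes
#' have no defined mass and raise an error.
#'
#' @param s character scalar over `A/C/G/T`.
#' @return mass in Da.
#' @export
dna_strand_mw <- function(s) {
  validate_dna(s, iupac = FALSE)
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  sum(DNA_NUCLEOSIDE_MASS[chars]) + (n - 1L) * DNA_BRIDGE_MASS
}

# Average residue masses (Da): amino acid minus one water; protein mass is
# sum(residues) + one water. Standard 20-letter alphabet.
AA_RESIDUE_MASS <- c(
  G = 57.0519,  A = 71.0788,  S = 87.0782,  P = 97.1167,  V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
WATER_MASS <- 18.0153

#' Average mass of a protein sequence
#'
#' Sum of average residue masses plus one water; any N-terminal Met is
#' counted as written (not cleaved).
#'
#' @param aa_seq character scalar over the standard 20-letter alphabet.
#' @return mass in Da.
#' @examples
#' protein_mw("G")  # glycine, 75.07 Da
#' @export
protein_mw <- function(aa_seq) {
  if (!is.character(aa_seq) || length(aa_seq) != 1L || is.na(aa_seq) ||
      !nzchar(aa_seq))
    stop("aa_seq must be a non-empty character string", call. = FALSE)
  chars <- strsplit(toupper(aa_seq), "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% names(AA_RESIDUE_MASS)))
  if (length(bad))
    stop(sprintf("unknown amino-acid letter '%s' at position %d",
                 chars[bad[1L]], bad[1L]), call. = FALSE)
  sum(AA_RESIDUE_MASS[chars]) + WATER_MASS
}

#' Translate a DNA sequence
#'
#' Standard genetic code, reading frame 1-3 on the given strand. Translation
#' stops at the first stop codon; a trailing partial codon is ignored with a
#' warning.
#'
#' @param nt character scalar over `A/C/G/T`.
#' @param frame reading frame (1, 2 or 3).
#' @return amino-acid string.
#' @export
translate_dna <- function(nt, frame = 1L) {
  validate_dna(nt, iupac = FALSE)
  if (!frame %in% 1:3) stop("frame must be 1, 2 or 3", call. = FALSE)
  s <- toupper(substring(nt, frame))
  n <- nchar(s)
  if (n < 3L) stop("sequence shorter than one codon in this frame", call. = FALSE)
  if (n %% 3L != 0L) {
    warning("trailing partial codon ignored", call. = FALSE)
    s <- substr(s, 1L, n - n %% 3L)
  }
  codons <- substring(s, seq(1L, nchar(s), by = 3L), seq(3L, nchar(s), by = 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  stop_at <- which(aa == "*")
  if (length(stop_at)) aa <- aa[seq_len(stop_at[1L] - 1L)]
  paste(aa, collapse = "")
}

#' Chip budget for direct-capture SPR
#'
#' Number of conventional streptavidin chips consumed by a series of test-DNA
#' injections under direct biotin capture, where each chip offers a fixed
#' number of test flow cells and must be discarded once they are used (the
#' cost the reusable-capture protocol avoids).
#'
#' @param n_injections total test-DNA injections.
#' @param per_chip test injections a chip accommodates (default 3: three test
#'   flow cells plus one reference).
#' @return number of chips.
#' @examples
#' chip_budget(138)  # 46
#' @export
chip_budget <- function(n_injections, per_chip = 3L) {
  if (n_injections < 0 || per_chip < 1)
    stop("n_injections must be >= 0 and per_chip >= 1", call. = FALSE)
  as.integer(ceiling(n_injections / per_chip))
}
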