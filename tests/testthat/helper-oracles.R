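# Independent oracles used across the suite. These never call the code
# paths they check.

# Strand mass from atomic composition: element masses and deoxynucleoside
# formulas; a 5'-OH/3'-OH n-mer is sum(nucleosides) + (n-1)*(HPO3 - H2O).
oracle_strand_mw <- function(s) {
  el <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, P = 30.973762)
  formula_mass <- function(counts) sum(el[names(counts)] * counts)
  nucleoside <- c(
    A = formula_mass(c(C = 10, H = 13, N = 5, O = 3)),
    C = formula_mass(c(C = 9,  H = 13, N = 3, O = 4)),
    G = formula_mass(c(C = 10, H = 13, N = 5, O = 4)),
    T = formula_mass(c(C = 10, H = 14, N = 2, O = 5)))
  bridge <- formula_mass(c(H = 1, P = 1, O = 3)) - formula_mass(c(H = 2, O = 1))
  chars <- strsplit(toupper(s), "")[[1]]
  sum(nucleoside[chars]) + (length(chars) - 1) * bridge
}

# Brute-force degenerate motif matcher: slide over every position on both
# strands, compare defined positions only.
oracle_scan <- function(seq, motif) {
  seq <- toupper(seq)
  match_at <- function(s, pat) {
    n <- nchar(s); m <- nchar(pat)
    pat_c <- strsplit(pat, "")[[1]]
    def <- pat_c %in% c("A", "C", "G", "T")
    hits <- integer(0)
    for (i in seq_len(n - m + 1)) {
      w <- strsplit(substr(s, i, i + m - 1), "")[[1]]
      if (all(w[def] == pat_c[def])) hits <- c(hits, i)
    }
    hits
  }
  pat <- toupper(motif)
  fwd <- match_at(seq, pat)
  rev <- match_at(seq, redcat::revcomp(pat))
  rbind(
    if (length(fwd)) data.frame(start = fwd, strand = "+"),
    if (length(rev)) data.frame(start = rev, strand = "-"))
}

# Brute-force grid search for the steady-state 1:1 fit.
oracle_grid_fit <- function(conc, resp, kd_range, rmax_range, n_grid = 200) {
  kds <- seq(kd_range[1], kd_range[2], length.out = n_grid)
  rmaxs <- seq(rmax_range[1], rmax_range[2], length.out = n_grid)
  best <- c(kd = NA, rmax = NA, ss = Inf)
  for (kd in kds) {
    pred0 <- conc / (kd + conc)
    for (rm in rmaxs) {
      ss <- sum((resp - rm * pred0)^2)
      if (ss < best["ss"]) best <- c(kd = kd, rmax = rm, ss = ss)
    }
  }
  best
}

# The two operator footprints printed as 24-mers, used throughout.
FP_A <- "CAATACTTGAACTCTCAATCTTTA"
FP_B <- "ATTTTGTTTAATGTTCAAGGAACC"
START_A <- "ACTCCAATACTTGAACTCTCAATCTTTACGTGCCGT"
START_B <- "ACGCCGATTTTGTTTAATGTTCAAGGAACCGTCTCG"
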