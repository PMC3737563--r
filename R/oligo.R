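# Double-stranded test oligomers and the capture linker.

#' Construct a double-stranded test oligomer
#'
#' An `OligoDuplex` holds the forward strand of the duplex core (5'->3'), the
#' complementary reverse strand (5'->3'), an optional single-stranded
#' overhang used for hybridization to the chip-bound capture linker, and the
#' 1-based inclusive coordinates of the core on the source region's forward
#' strand.
#'
#' @param forward forward-strand core sequence, 5'->3'.
#' @param name identifier.
#' @param region_start,region_end 1-based inclusive coordinates on the source
#'   region (forward strand). Defaults to `1..nchar(forward)`.
#' @param overhang single-stranded overhang sequence ("" for none).
#' @param overhang_host which strand carries the overhang at its 3' end:
#'   `"none"`, `"reverse_3prime"` (standard capture orientation) or
#'   `"forward_3prime"` (inverted orientation used for left-hand
#'   footprinting).
#' @return an object of class `OligoDuplex`.
#' @export
oligo_duplex <- function(forward, name = "oligo",
                         region_start = 1L,
                         region_end = region_start + nchar(forward) - 1L,
                         overhang = "",
                         overhang_host = c("none", "reverse_3prime",
                                           "forward_3prime")) {
  validate_dna(forward, iupac = FALSE, what = "forward strand")
  overhang_host <- match.arg(overhang_host)
  if (nzchar(overhang)) {
    validate_dna(overhang, iupac = FALSE, what = "overhang")
    if (overhang_host == "none")
      stop("overhang supplied but overhang_host is 'none'", call. = FALSE)
  } else if (overhang_host != "none") {
    stop("overhang_host set but overhang is empty", call. = FALSE)
  }
  if (region_end - region_start + 1L != nchar(forward))
    stop("region coordinates do not match forward-strand length", call. = FALSE)
  structure(list(name = as.character(name),
                 forward = toupper(forward),
                 reverse = revcomp(forward),
                 overhang = toupper(overhang),
                 overhang_host = overhang_host,
                 region_start = as.integer(region_start),
                 region_end = as.integer(region_end)),
            class = "OligoDuplex")
}

#' @export
print.OligoDuplex <- function(x, ...) {
  cat(sprintf("OligoDuplex '%s' [%d-%d], %d bp core", x$name,
              x$region_start, x$region_end, nchar(x$forward)))
  if (x$overhang_host != "none")
    cat(sprintf(", %d nt overhang on %s", nchar(x$overhang), x$overhang_host))
  cat("\n  fwd 5'-", x$forward, "-3'\n  rev 5'-", x$reverse, "-3'\n", sep = "")
  invisible(x)
}

#' Full synthesized strands of a duplex
#'
#' Returns the two strands as they would be ordered for synthesis, i.e. with
#' the overhang appended to the 3' end of its host strand.
#'
#' @param d an `OligoDuplex`.
#' @return list with elements `forward` and `reverse` (each 5'->3').
#' @export
duplex_strands <- function(d) {
  stopifnot(inherits(d, "OligoDuplex"))
  fwd <- d$forward
  rev <- d$reverse
  if (d$overhang_host == "forward_3prime") fwd <- paste0(fwd, d$overhang)
  if (d$overhang_host == "reverse_3prime") rev <- paste0(rev, d$overhang)
  list(forward = fwd, reverse = rev)
}

# Placeholder 20-mer complementary to the chip-bound biotinylated linker.
# The linker is an experiment-specific config value, never used by any
# design or analysis logic beyond length/mass bookkeeping.
DEFAULT_LINKER_SEQ <- "CTACCTAATCGGCACTCGTC"

#' Capture-linker specification
#'
#' The 20-nt sequence appended to one strand of every test duplex so that it
#' can hybridize to the permanently chip-bound biotinylated single-stranded
#' linker.
#'
#' @param linker_complement 20-nt sequence, 5'->3'.
#' @param description free-text provenance note.
#' @return an object of class `LinkerSpec`.
#' @export
linker_spec <- function(linker_complement = DEFAULT_LINKER_SEQ,
                        description = "package placeholder linker complement") {
  validate_dna(linker_complement, iupac = FALSE, what = "linker_complement")
  if (nchar(linker_complement) != 20L)
    stop("linker_complement must be exactly 20 nt", call. = FALSE)
  structure(list(linker_complement = toupper(linker_complement),
                 description = description),
            class = "LinkerSpec")
}

#' Attach the capture linker to a duplex
#'
#' Appends the linker-complement to the 3' end of the chosen strand. The
#' standard orientation places it on the reverse strand; placing it on the
#' forward strand instead inverts the duplex on the chip, which is how the
#' left-hand footprint boundary is brought to the free end.
#'
#' @param d an `OligoDuplex` without an existing overhang.
#' @param linker a `LinkerSpec` (or 20-nt character).
#' @param host `"reverse_3prime"`, `"forward_3prime"` or `"none"` (no-op with
#'   a warning).
#' @return the duplex with the overhang attached.
#' @export
attach_linker <- function(d, linker = linker_spec(),
                          host = c("reverse_3prime", "forward_3prime", "none")) {
  stopifnot(inherits(d, "OligoDuplex"))
  host <- match.arg(host)
  if (is.character(linker)) linker <- linker_spec(linker)
  stopifnot(inherits(linker, "LinkerSpec"))
  if (host == "none") {
    warning("host = 'none': duplex returned unchanged", call. = FALSE)
    return(d)
  }
  if (d$overhang_host != "none")
    stop("duplex already carries an overhang; strip_linker() it first",
         call. = FALSE)
  d$overhang <- linker$linker_complement
  d$overhang_host <- host
  d
}

#' Remove the capture overhang from a duplex
#'
#' @param d an `OligoDuplex`.
#' @return the duplex core without overhang; inverse of [attach_linker()].
#' @export
strip_linker <- function(d) {
  stopifnot(inherits(d, "OligoDuplex"))
  d$overhang <- ""
  d$overhang_host <- "none"
  d
}

#' Average mass of a duplex as captured
#'
#' Mass of both synthesized strands, including the single-stranded overhang
#' if present (the chip-bound linker itself is not part of the captured
#' species). This is the ligand molecular weight entering the theoretical
#' Rmax.
#'
#' @param d an `OligoDuplex`, or a character forward strand (treated as a
#'   blunt duplex).
#' @return mass in Da.
#' @export
dna_mw <- function(d) {
  if (is.character(d)) d <- oligo_duplex(d)
  stopifnot(inherits(d, "OligoDuplex"))
  s <- duplex_strands(d)
  dna_strand_mw(s$forward) + dna_strand_mw(s$reverse)
}
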