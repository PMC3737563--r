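# Oligomer panel design: tiling, truncation series, substitution panels.

#' Tile a region into overlapping capture fragments
#'
#' Divides a region into fragments of length `fragment_length` stepped by
#' `fragment_length - site_length`, so that every window of `site_length`
#' (the longest binding site that must be fully contained somewhere) lies
#' entirely within at least one fragment. If the last regular fragment does
#' not reach the end of the region, one additional end-anchored fragment is
#' appended.
#'
#' @param region region sequence (character, forward strand) .
#' @param fragment_length fragment length F in nt.
#' @param site_length guaranteed fully-contained site length L in nt
#'   (the inter-fragment overlap).
#' @param name_prefix fragment name prefix.
#' @return an object of class `TilingPanel` with ordered `fragments`
#'   (a list of [oligo_duplex()] objects).
#' @examples
#' p <- tile_region(strrep("ACGT", 30), 29, 22)  # 120-nt region
#' length(p$fragments)
#' @export
tile_region <- function(region, fragment_length, site_length,
                        name_prefix = "frag") {
  validate_dna(region, iupac = FALSE, what = "region")
  region <- toupper(region)
  n <- nchar(region)
  f <- as.integer(fragment_length)
  l <- as.integer(site_length)
  if (l > f) stop("site_length must not exceed fragment_length", call. = FALSE)
  if (f > n) stop("fragment_length exceeds region length", call. = FALSE)
  step <- f - l
  # step 0 (L = F) degenerates to a fragment at every offset
  starts <- if (f < n) seq.int(1L, n - f + 1L, by = max(step, 1L)) else 1L
  if (starts[length(starts)] + f - 1L < n)
    starts <- c(starts, n - f + 1L)  # end-anchored final fragment
  frags <- lapply(seq_along(starts), function(i) {
    s <- starts[i]
    oligo_duplex(substr(region, s, s + f - 1L),
                 name = sprintf("%s_%02d", name_prefix, i),
                 region_start = s, region_end = s + f - 1L)
  })
  structure(list(region = region, region_length = n,
                 fragment_length = f, site_length = l, step = step,
                 fragments = frags),
            class = "TilingPanel")
}

#' @export
print.TilingPanel <- function(x, ...) {
  cat(sprintf("TilingPanel: %d-nt region, F=%d, L=%d, step=%d, %d fragments\n",
              x$region_length, x$fragment_length, x$site_length, x$step,
              length(x$fragments)))
  invisible(x)
}

#' Serial truncation series for footprint mapping
#'
#' Builds the series of progressively shorter duplexes used to map one
#' boundary of a binding-site footprint. For the right-hand (RH) boundary the
#' forward strand is truncated from its 3' end (reverse strand from its 5'
#' end) and the capture linker sits on the reverse strand, leaving the RH end
#' of the site at the free end of the construct. For the left-hand (LH)
#' boundary the duplex is first inverted on the chip by moving the linker to
#' the forward strand's 3' end, and the forward strand is truncated from its
#' 5' end (reverse strand from its 3' end).
#'
#' @param start starting `OligoDuplex` (any existing overhang is replaced).
#' @param side `"RH"` or `"LH"`, defined relative to the forward strand.
#' @param step truncation increment in nt (default 2, the mapping
#'   resolution).
#' @param max_delta largest truncation in nt.
#' @param linker a [linker_spec()].
#' @param min_length smallest core length allowed after truncation.
#' @return an object of class `TruncationSeries`; `members` is an ordered
#'   list of `list(delta =, oligo =)`, delta ascending from 0.
#' @export
make_truncation_series <- function(start, side = c("RH", "LH"), step = 2L,
                                   max_delta, linker = linker_spec(),
                                   min_length = 10L) {
  stopifnot(inherits(start, "OligoDuplex"))
  side <- match.arg(side)
  step <- as.integer(step)
  max_delta <- as.integer(max_delta)
  if (step < 1L) stop("step must be >= 1", call. = FALSE)
  if (max_delta >= nchar(start$forward))
    stop("max_delta must be smaller than the duplex length", call. = FALSE)
  if (nchar(start$forward) - max_delta < min_length)
    stop(sprintf("truncation to %d nt would undercut min_length = %d nt",
                 nchar(start$forward) - max_delta, min_length), call. = FALSE)
  core <- strip_linker(start)
  host <- if (side == "RH") "reverse_3prime" else "forward_3prime"
  deltas <- seq.int(0L, max_delta, by = step)
  members <- lapply(deltas, function(delta) {
    len <- nchar(core$forward)
    if (side == "RH") {
      fwd <- substr(core$forward, 1L, len - delta)
      o <- oligo_duplex(fwd, name = sprintf("%s_%s_d%d", core$name, side, delta),
                        region_start = core$region_start,
                        region_end = core$region_end - delta)
    } else {
      fwd <- substr(core$forward, delta + 1L, len)
      o <- oligo_duplex(fwd, name = sprintf("%s_%s_d%d", core$name, side, delta),
                        region_start = core$region_start + delta,
                        region_end = core$region_end)
    }
    list(delta = delta, oligo = attach_linker(o, linker, host))
  })
  structure(list(side = side, step = step, members = members),
            class = "TruncationSeries")
}

#' @export
print.TruncationSeries <- function(x, ...) {
  cat(sprintf("TruncationSeries (%s boundary): deltas %s\n", x$side,
              paste(vapply(x$members, `[[`, 0L, "delta"), collapse = ", ")))
  invisible(x)
}

#' Trim a duplex to a called footprint
#'
#' Removes `delta_lh` bases from the 5' end and `delta_rh` bases from the 3'
#' end of the forward strand (coordinates adjusted accordingly); the deltas
#' are the truncations at which each boundary was called.
#'
#' @param start starting `OligoDuplex`.
#' @param delta_rh,delta_lh truncations in nt (non-negative).
#' @return the footprint `OligoDuplex` (no overhang).
#' @examples
#' fp <- apply_footprint(oligo_duplex("ACTCCAATACTTGAACTCTCAATCTTTACGTGCCGT"),
#'                       delta_rh = 8, delta_lh = 4)
#' fp$forward  # 24-mer
#' @export
apply_footprint <- function(start, delta_rh, delta_lh) {
  stopifnot(inherits(start, "OligoDuplex"))
  if (delta_rh < 0 || delta_lh < 0)
    stop("deltas must be non-negative", call. = FALSE)
  len <- nchar(start$forward)
  if (delta_rh + delta_lh >= len)
    stop("deltas remove the whole duplex", call. = FALSE)
  fwd <- substr(start$forward, delta_lh + 1L, len - delta_rh)
  oligo_duplex(fwd, name = paste0(start$name, "_fp"),
               region_start = start$region_start + delta_lh,
               region_end = start$region_end - delta_rh)
}

#' Single-base substitution panel
#'
#' For every targeted position, generates the three variants in which the
#' wild-type base is replaced by each alternative, keeping the reverse
#' strand complementary; wild-type replicates are included as internal
#' controls for each measurement batch.
#'
#' @param wt wild-type `OligoDuplex`.
#' @param positions 1-based positions on the forward strand (no duplicates).
#' @param replicates number of wild-type control replicates.
#' @return an object of class `SubstitutionPanel` with `wild_type`,
#'   `variants` (list of `list(position =, alt_base =, oligo =)`) and
#'   `controls`.
#' @export
make_substitution_panel <- function(wt, positions, replicates = 1L) {
  stopifnot(inherits(wt, "OligoDuplex"))
  positions <- as.integer(positions)
  if (anyDuplicated(positions))
    stop("duplicate positions in substitution panel", call. = FALSE)
  if (any(positions < 1L | positions > nchar(wt$forward)))
    stop("positions outside the wild-type duplex", call. = FALSE)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  variants <- list()
  for (pos in positions) {
    ref <- substr(wt$forward, pos, pos)
    for (alt in setdiff(bases, ref)) {
      fwd <- wt$forward
      substr(fwd, pos, pos) <- alt
      variants[[length(variants) + 1L]] <- list(
        position = pos, alt_base = alt,
        oligo = oligo_duplex(fwd,
                             name = sprintf("%s_%s%d%s", wt$name, ref, pos, alt),
                             region_start = wt$region_start,
                             region_end = wt$region_end,
                             overhang = wt$overhang,
                             overhang_host = wt$overhang_host))
    }
  }
  controls <- lapply(seq_len(replicates), function(i) {
    o <- wt
    o$name <- sprintf("%s_wt_rep%d", wt$name, i)
    o
  })
  structure(list(wild_type = wt, variants = variants, controls = controls),
            class = "SubstitutionPanel")
}

#' Export a set of duplexes as a TSV panel
#'
#' One row per duplex with columns `name, forward_5to3, reverse_5to3,
#' overhang_host, region_start, region_end, delta, side` (the last two empty
#' unless the input is a `TruncationSeries`). Strands are written as
#' synthesized, i.e. including any overhang.
#'
#' @param x a `TilingPanel`, `TruncationSeries`, `SubstitutionPanel`, or list
#'   of `OligoDuplex`.
#' @param path output file; `""` returns the data frame invisibly printed
#'   nowhere.
#' @return the panel data frame, invisibly.
#' @export
write_panel_tsv <- function(x, path) {
  rows <- panel_table(x)
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}

#' @rdname write_panel_tsv
#' @export
panel_table <- function(x) {
  items <- if (inherits(x, "TilingPanel")) {
    lapply(x$fragments, function(o) list(oligo = o, delta = NA, side = NA))
  } else if (inherits(x, "TruncationSeries")) {
    lapply(x$members, function(m) list(oligo = m$oligo, delta = m$delta,
                                       side = x$side))
  } else if (inherits(x, "SubstitutionPanel")) {
    c(lapply(x$variants, function(v) list(oligo = v$oligo, delta = NA, side = NA)),
      lapply(x$controls, function(o) list(oligo = o, delta = NA, side = NA)))
  } else if (is.list(x)) {
    lapply(x, function(o) list(oligo = o, delta = NA, side = NA))
  } else stop("unsupported panel type", call. = FALSE)
  do.call(rbind, lapply(items, function(it) {
    s <- duplex_strands(it$oligo)
    data.frame(name = it$oligo$name,
               forward_5to3 = s$forward, reverse_5to3 = s$reverse,
               overhang_host = it$oligo$overhang_host,
               region_start = it$oligo$region_start,
               region_end = it$oligo$region_end,
               delta = it$delta, side = it$side,
               stringsAsFactors = FALSE)
  }))
}
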