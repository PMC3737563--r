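# Consensus derivation, palindrome annotation and genome scanning.

DEFINED_BASES <- c("A", "C", "G", "T")

#' Derive a degenerate consensus from aligned binding sites
#'
#' Aligns the sequences without gaps: each sequence after the first is slid
#' against the first to the offset maximizing the number of identical
#' aligned columns (ties broken by the smallest offset). Columns covered by
#' all sequences where every base agrees keep that base; all other columns
#' become the wildcard `n`. The ends are then trimmed inward until the motif
#' both starts and ends with at least `min_block` consecutive defined bases,
#' discarding isolated conserved positions at the margins.
#'
#' @param seqs character vector of two or more sites, same orientation.
#' @param min_block minimum run of defined bases required at each end.
#' @return object of class `ConsensusMotif`: `iupac` (lowercase `n`
#'   wildcard), `offsets` (per input, relative to the first), `start`
#'   (position of the motif's first column in the first sequence's frame)
#'   and `conserved` (defined positions within the motif). An empty motif
#'   (with a warning) results when no window satisfies `min_block`.
#' @examples
#' derive_consensus(c("CAATACTTGAACTCTCAATCTTTA",
#'                    "ATTTTGTTTAATGTTCAAGGAACC"))$iupac
#' @export
derive_consensus <- function(seqs, min_block = 2L) {
  if (length(seqs) < 2L) stop("need at least 2 sequences", call. = FALSE)
  for (s in seqs) validate_dna(s, iupac = FALSE)
  seqs <- toupper(seqs)
  mats <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
  len1 <- length(mats[[1L]])

  best_offset <- function(chars) {
    lenk <- length(chars)
    offs <- seq.int(-(lenk - 1L), len1 - 1L)
    score <- vapply(offs, function(o) {
      cols <- intersect(seq_len(len1), seq_len(lenk) + o)
      if (!length(cols)) return(0L)
      sum(mats[[1L]][cols] == chars[cols - o])
    }, 0L)
    offs[which.max(score)]  # first max = smallest offset
  }
  offsets <- c(0L, vapply(mats[-1L], best_offset, 0L))

  # columns (frame of sequence 1) covered by every sequence
  covered <- Reduce(intersect, lapply(seq_along(mats), function(k) {
    seq_len(length(mats[[k]])) + offsets[k]
  }))
  covered <- covered[covered >= 1L]
  if (!length(covered)) {
    warning("sequences do not overlap at the chosen offsets", call. = FALSE)
    return(empty_motif(offsets, seqs))
  }
  cols <- vapply(covered, function(c) {
    bases <- vapply(seq_along(mats), function(k) mats[[k]][c - offsets[k]], "")
    if (all(bases == bases[1L])) bases[1L] else "n"
  }, "")

  # trim: drop leading/trailing wildcards and defined runs shorter than
  # min_block until a qualifying run anchors each end
  defined <- cols %in% DEFINED_BASES
  runs <- rle(defined)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  anchor <- which(runs$values & runs$lengths >= min_block)
  if (!length(anchor)) {
    warning("no conserved block of length >= min_block; empty consensus",
            call. = FALSE)
    return(empty_motif(offsets, seqs))
  }
  lo <- starts[anchor[1L]]
  hi <- ends[anchor[length(anchor)]]
  motif <- paste(cols[lo:hi], collapse = "")
  structure(list(iupac = motif, offsets = offsets,
                 start = covered[lo],
                 conserved = which(strsplit(motif, "")[[1L]] %in% DEFINED_BASES),
                 inputs = seqs),
            class = "ConsensusMotif")
}

empty_motif <- function(offsets, seqs) {
  structure(list(iupac = "", offsets = offsets, start = NA_integer_,
                 conserved = integer(0), inputs = seqs),
            class = "ConsensusMotif")
}

#' @export
print.ConsensusMotif <- function(x, ...) {
  cat(sprintf("ConsensusMotif: '%s' (%d defined of %d positions)\n",
              x$iupac, length(x$conserved), nchar(x$iupac)))
  invisible(x)
}

#' Annotate the palindromic pairing of a site or motif
#'
#' Positions `i` and `M + 1 - i` of an M-long site face each other across
#' the dyad of an inverted repeat. Each such pair is flagged complementary
#' when both positions are defined bases and Watson-Crick complementary.
#'
#' @param site character sequence (IUPAC `n` allowed) or `ConsensusMotif`.
#' @return data frame of class `PalindromePairing`: columns `i`, `j`,
#'   `base_i`, `base_j`, `complementary`. The central position of an
#'   odd-length site is unpaired and omitted.
#' @export
annotate_palindrome <- function(site) {
  if (inherits(site, "ConsensusMotif")) site <- site$iupac
  validate_dna(site, iupac = TRUE)
  chars <- toupper(strsplit(site, "", fixed = TRUE)[[1L]])
  m <- length(chars)
  if (m < 2L) stop("site must be at least 2 nt", call. = FALSE)
  i <- seq_len(m %/% 2L)
  j <- m + 1L - i
  comp <- chartr("ACGT", "TGCA", chars[i])
  df <- data.frame(i = i, j = j, base_i = chars[i], base_j = chars[j],
                   complementary = chars[i] %in% DEFINED_BASES &
                     chars[j] %in% DEFINED_BASES & comp == chars[j],
                   stringsAsFactors = FALSE)
  class(df) <- c("PalindromePairing", "data.frame")
  df
}

#' Scan sequences for a degenerate motif
#'
#' Finds every (possibly overlapping) exact match of the IUPAC pattern on
#' the requested strands; `n`/`N` matches any base. Reverse-strand hits are
#' reported with forward-strand (leftmost) coordinates, with the matched
#' sequence read on the hit strand. Hits are deduplicated by (contig,
#' start, strand) and ordered the same way.
#'
#' @param target named character vector of sequences, a
#'   `Biostrings::DNAStringSet`, or the path to a FASTA file.
#' @param motif `ConsensusMotif` or IUPAC character pattern.
#' @param strands `"both"`, `"+"` or `"-"`.
#' @return data frame of class `MotifHits`: contig, start, end (1-based
#'   inclusive), strand, match, score (number of defined bases in the
#'   pattern).
#' @export
scan_sequence <- function(target, motif, strands = c("both", "+", "-")) {
  strands <- match.arg(strands)
  if (inherits(motif, "ConsensusMotif")) motif <- motif$iupac
  if (!nzchar(motif)) stop("motif is empty", call. = FALSE)
  validate_dna(motif, iupac = TRUE, what = "motif")
  if (is.character(target) && length(target) == 1L && file.exists(target) &&
      grepl("\\.(fa|fasta|fna)$", target, ignore.case = TRUE))
    target <- read_fasta(target)
  if (is.character(target)) {
    if (is.null(names(target)))
      names(target) <- paste0("seq", seq_along(target))
    target <- Biostrings::DNAStringSet(toupper(target))
  }
  stopifnot(inherits(target, "DNAStringSet"))
  pat <- toupper(motif)
  score <- sum(strsplit(pat, "")[[1L]] %in% DEFINED_BASES)
  hit_rows <- list()
  scan_one <- function(contig, subj, pattern, strand) {
    m <- Biostrings::matchPattern(pattern, subj, fixed = "subject")
    if (!length(m)) return(NULL)
    seqs <- as.character(m)
    if (strand == "-") seqs <- vapply(seqs, revcomp, "", USE.NAMES = FALSE)
    data.frame(contig = contig, start = BiocGenerics::start(m),
               end = BiocGenerics::end(m), strand = strand, match = seqs,
               score = score, stringsAsFactors = FALSE)
  }
  for (k in seq_along(target)) {
    contig <- names(target)[k]
    subj <- target[[k]]
    if (strands %in% c("both", "+"))
      hit_rows[[length(hit_rows) + 1L]] <- scan_one(contig, subj, pat, "+")
    if (strands %in% c("both", "-"))
      hit_rows[[length(hit_rows) + 1L]] <-
        scan_one(contig, subj, revcomp(pat), "-")
  }
  hits <- do.call(rbind, hit_rows)
  if (is.null(hits))
    hits <- data.frame(contig = character(0), start = integer(0),
                       end = integer(0), strand = character(0),
                       match = character(0), score = integer(0))
  hits <- hits[!duplicated(hits[c("contig", "start", "strand")]), ]
  hits <- hits[order(hits$contig, hits$start, hits$strand), ]
  rownames(hits) <- NULL
  class(hits) <- c("MotifHits", "data.frame")
  hits
}

#' Annotate motif hits with their nearest downstream feature
#'
#' For each hit, finds on each strand the nearest feature whose start (5'
#' end in the feature's orientation) lies downstream of the hit, the usual
#' geometry of an operator ahead of the gene it controls. The reported
#' distance is the number of nucleotides between the hit and that feature
#' start; a hit overlapping a feature gets distance 0 and `inside = TRUE`.
#' Hits with no feature within `window` are flagged `no_context`.
#'
#' @param hits a `MotifHits` data frame from [scan_sequence()].
#' @param features a data frame with columns contig, start, end, strand,
#'   name (1-based inclusive), or the path to a BED or GFF3 file.
#' @param window maximum distance searched, nt.
#' @return `hits` with columns feature, distance, feature_strand, inside,
#'   no_context appended.
#' @export
report_context <- function(hits, features, window = 5000L) {
  if (is.character(features)) features <- read_features(features)
  need <- c("contig", "start", "end", "strand", "name")
  if (!all(need %in% names(features)))
    stop("features must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  n <- nrow(hits)
  hits$feature <- NA_character_
  hits$distance <- NA_integer_
  hits$feature_strand <- NA_character_
  hits$inside <- FALSE
  hits$no_context <- TRUE
  if (!n || !nrow(features)) return(hits)
  for (i in seq_len(n)) {
    f <- features[features$contig == hits$contig[i], , drop = FALSE]
    if (!nrow(f)) next
    overlap <- f$start <= hits$end[i] & f$end >= hits$start[i]
    dist <- ifelse(f$strand == "-",
                   hits$start[i] - f$end - 1L,   # downstream = leftward
                   f$start - hits$end[i] - 1L)   # downstream = rightward
    dist[overlap] <- 0L
    cand <- which((overlap | dist >= 0L) & dist <= window)
    if (!length(cand)) next
    best <- cand[which.min(dist[cand])]
    hits$feature[i] <- f$name[best]
    hits$distance[i] <- dist[best]
    hits$feature_strand[i] <- f$strand[best]
    hits$inside[i] <- overlap[best]
    hits$no_context[i] <- FALSE
  }
  hits
}

# --- standard-format I/O ----------------------------------------------------

#' Read a (multi-)FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences (names truncated at
#'   the first whitespace).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector, or a list of `OligoDuplex` (both full
#'   strands of each duplex are written).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.list(seqs) && all(vapply(seqs, inherits, TRUE, "OligoDuplex"))) {
    out <- unlist(lapply(seqs, function(d) {
      s <- duplex_strands(d)
      stats::setNames(c(s$forward, s$reverse),
                      paste0(d$name, c("_fwd", "_rev")))
    }))
    seqs <- out
  }
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read genomic features from BED or GFF3
#'
#' Minimal readers for the two plain-text feature formats; BED intervals are
#' converted to 1-based inclusive coordinates. A malformed line raises an
#' error naming its line number.
#'
#' @param path `.bed`, `.gff`, `.gff3` file.
#' @return data frame: contig, start, end, strand, name.
#' @export
read_features <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^(#|$)", lines))
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE)
  rows <- lapply(keep, function(ln) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (is_gff) {
      if (length(f) < 9L)
        stop(sprintf("malformed GFF3 line %d: expected 9 fields, got %d",
                     ln, length(f)), call. = FALSE)
      start <- suppressWarnings(as.integer(f[4L]))
      end <- suppressWarnings(as.integer(f[5L]))
      if (is.na(start) || is.na(end))
        stop(sprintf("malformed GFF3 line %d: non-numeric coordinates", ln),
             call. = FALSE)
      name <- sub(".*(?:ID|Name|locus_tag)=([^;]+).*", "\\1", f[9L])
      if (name == f[9L]) name <- f[3L]
      data.frame(contig = f[1L], start = start, end = end,
                 strand = if (f[7L] %in% c("+", "-")) f[7L] else "+",
                 name = name, stringsAsFactors = FALSE)
    } else {
      if (length(f) < 3L)
        stop(sprintf("malformed BED line %d: expected >= 3 fields, got %d",
                     ln, length(f)), call. = FALSE)
      start <- suppressWarnings(as.integer(f[2L]))
      end <- suppressWarnings(as.integer(f[3L]))
      if (is.na(start) || is.na(end))
        stop(sprintf("malformed BED line %d: non-numeric coordinates", ln),
             call. = FALSE)
      data.frame(contig = f[1L], start = start + 1L, end = end,
                 strand = if (length(f) >= 6L && f[6L] %in% c("+", "-"))
                   f[6L] else "+",
                 name = if (length(f) >= 4L) f[4L] else ".",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      name = character(0))
  out
}

#' Write motif hits as BED6
#'
#' Name is the matched sequence, score the number of defined-base matches.
#'
#' @param hits a `MotifHits` data frame.
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", hits$contig, hits$start - 1L,
                   hits$end, hits$match, hits$score, hits$strand)
  writeLines(lines, path)
  invisible(path)
}
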