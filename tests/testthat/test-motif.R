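# Consensus derivation, palindrome annotation, genome scanning, context.

test_that("consensus of the two operator footprints is the dodecamer", {
  m <- derive_consensus(c(FP_A, FP_B))
  expect_equal(m$iupac, "TTnAAnnnTCAA")
  expect_equal(m$offsets, c(0L, 0L))
  expect_equal(m$start, 7)  # columns 7-18 of the 24-mer frame
  # order invariance
  expect_equal(derive_consensus(c(FP_B, FP_A))$iupac, m$iupac)
  # identity
  expect_equal(derive_consensus(c(FP_A, FP_A))$iupac, FP_A)
  # nothing conserved -> empty motif with a warning
  expect_warning(e <- derive_consensus(c("AAAA", "TTTT")), "min_block")
  expect_equal(e$iupac, "")
  expect_error(derive_consensus("ACGT"), "at least 2")
})

test_that("consensus alignment finds shifted and multi-sequence blocks", {
  # same site embedded at different offsets
  core <- "TTGAACTCTCAA"
  s1 <- paste0("GGGG", core, "CCGG")
  s2 <- paste0("CC", core, "GGGGAA")
  m <- derive_consensus(c(s1, s2))
  expect_true(grepl(core, m$iupac, fixed = TRUE))
  expect_equal(m$offsets[2], 2L)
  # three sequences agree only on the planted core
  set.seed(8)
  trio <- vapply(1:3, function(i)
    paste0(random_dna(3), core, random_dna(3)), "")
  expect_true(grepl(core, derive_consensus(trio)$iupac, fixed = TRUE))
})

test_that("palindrome annotation flags complementary symmetric pairs", {
  pp <- annotate_palindrome("TTnAAnnnTCAA")
  comp <- pp[pp$complementary, c("i", "j")]
  expect_equal(unname(as.matrix(comp)),
               matrix(c(1L, 12L, 2L, 11L, 4L, 9L), ncol = 2, byrow = TRUE))
  # perfect palindrome: every pair complementary
  expect_true(all(annotate_palindrome("GAATTC")$complementary))
  # symmetrized 22-mer built from the operator's right half: positions
  # 6/17, 7/16 and 9/14 pair complementarily across the dyad
  rh_half <- substr(FP_A, 14, 24)
  sym22 <- paste0(revcomp(rh_half), rh_half)
  expect_equal(nchar(sym22), 22)
  pp22 <- annotate_palindrome(sym22)
  for (pair in list(c(6, 17), c(7, 16), c(9, 14)))
    expect_true(pp22$complementary[pp22$i == pair[1] & pp22$j == pair[2]])
  # odd length leaves the centre unpaired
  expect_equal(nrow(annotate_palindrome("ACGTA")), 2)
})

test_that("scan finds IUPAC matches on both strands with leftmost starts", {
  site <- "TTGAAGGGTCAA"  # one instantiation of the consensus
  hit <- scan_sequence(c(chr = paste0("CCC", site, "GGG")), "TTnAAnnnTCAA")
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 4)
  expect_equal(hit$strand, "+")
  expect_equal(hit$match, site)
  expect_equal(hit$score, 8)
  rc <- scan_sequence(c(chr = revcomp(paste0("CCC", site, "GGG"))),
                      "TTnAAnnnTCAA")
  expect_equal(nrow(rc), 1)
  expect_equal(rc$strand, "-")
  expect_equal(rc$start, 4)  # leftmost base on the forward strand
  expect_equal(rc$match, site)
  expect_error(scan_sequence(c(a = "ACGT"), ""), "empty")
})

test_that("scan equals the brute-force matcher on random 10-kb sequences", {
  for (s in 1:3) {
    g <- with_seed(s, random_dna(10000, gc = 0.5))
    hits <- scan_sequence(c(chr = g), "TTnAAnnnTCAA")
    oracle <- oracle_scan(g, "TTnAAnnnTCAA")
    if (is.null(oracle)) {
      expect_equal(nrow(hits), 0)
    } else {
      oracle <- oracle[order(oracle$start, oracle$strand), ]
      expect_equal(hits$start, oracle$start)
      expect_equal(hits$strand, oracle$strand)
    }
  }
})

test_that("scanning a reverse-complemented target mirrors the hits", {
  g <- with_seed(4, random_dna(20000, gc = 0.45))
  fwd <- scan_sequence(c(chr = g), "TTnAAnnnTCAA")
  rev <- scan_sequence(c(chr = revcomp(g)), "TTnAAnnnTCAA")
  expect_equal(nrow(fwd), nrow(rev))
  n <- nchar(g); m <- nchar("TTnAAnnnTCAA")
  mirrored <- sort(n - m + 2 - rev$start[rev$strand == "-"])
  expect_equal(sort(fwd$start[fwd$strand == "+"]), mirrored)
})

test_that("hit frequency on uniform sequence matches the 2n/4^8 rate", {
  n <- 400000
  g <- with_seed(10, random_dna(n, gc = 0.5))
  hits <- scan_sequence(c(chr = g), "TTnAAnnnTCAA")
  expected <- 2 * n * (1 / 4)^8
  expect_lt(abs(nrow(hits) - expected), 4 * sqrt(expected) + 1)
})

test_that("report_context finds the nearest downstream feature", {
  hits <- scan_sequence(c(chr = paste0(strrep("G", 100), "TTGAAGGGTCAA",
                                       strrep("C", 300))), "TTnAAnnnTCAA")
  expect_equal(hits$start, 101)
  expect_equal(hits$end, 112)
  # feature starting 80 nt downstream of the hit end (geometry of an
  # operator 80 nt upstream of its gene)
  feats <- data.frame(contig = "chr", start = 193, end = 350, strand = "+",
                      name = "geneA")
  ann <- report_context(hits, feats)
  expect_equal(ann$feature, "geneA")
  expect_equal(ann$distance, 80)
  expect_false(ann$inside)
  # hit inside a feature: distance 0 and flagged inside
  inside <- report_context(hits, data.frame(contig = "chr", start = 50,
                                            end = 200, strand = "+",
                                            name = "geneB"))
  expect_equal(inside$distance, 0)
  expect_true(inside$inside)
  # empty feature table: flagged no-context
  none <- report_context(hits, data.frame(contig = character(0),
                                          start = integer(0),
                                          end = integer(0),
                                          strand = character(0),
                                          name = character(0)))
  expect_true(none$no_context)
  # minus-strand feature upstream-left geometry
  mfeat <- data.frame(contig = "chr", start = 10, end = 60, strand = "-",
                      name = "geneC")
  mann <- report_context(hits, mfeat)
  expect_equal(mann$feature, "geneC")
  expect_equal(mann$distance, 101 - 60 - 1)
})

test_that("feature files parse from BED and GFF3 with line-number errors", {
  bed <- file.path(tempdir(), "f.bed")
  writeLines(c("chr\t192\t350\tgeneA\t0\t+", "chr\t400\t500\tgeneB\t0\t-"),
             bed)
  f <- read_features(bed)
  expect_equal(f$start, c(193, 401))  # 1-based conversion
  expect_equal(f$name, c("geneA", "geneB"))
  gff <- file.path(tempdir(), "f.gff3")
  writeLines(c("##gff-version 3",
               "chr\tsrc\tgene\t193\t350\t.\t+\t.\tID=geneA;Name=geneA"),
             gff)
  g <- read_features(gff)
  expect_equal(g$start, 193)
  expect_equal(g$name, "geneA")
  writeLines("chr\tonly_two", bed)
  expect_error(read_features(bed), "line 1")
  # BED6 hit export round-trips through the reader
  hits <- scan_sequence(c(chr = paste0("CC", "TTGAAGGGTCAA", "AA")),
                        "TTnAAnnnTCAA")
  out <- file.path(tempdir(), "hits.bed")
  write_hits_bed(hits, out)
  back <- read_features(out)
  expect_equal(back$start, hits$start)
  expect_equal(back$end, hits$end)
})

test_that("FASTA I/O round-trips sequences and duplexes", {
  fa <- file.path(tempdir(), "x.fa")
  write_fasta(c(one = "ACGTACGT", two = "GGGCCC"), fa)
  back <- read_fasta(fa)
  expect_equal(back, c(one = "ACGTACGT", two = "GGGCCC"))
  d <- attach_linker(oligo_duplex("ACGTACGTACGT", name = "dup"),
                     linker_spec(), "reverse_3prime")
  write_fasta(list(d), fa)
  strands <- read_fasta(fa)
  expect_named(strands, c("dup_fwd", "dup_rev"))
  expect_equal(unname(strands["dup_rev"]),
               paste0(revcomp("ACGTACGTACGT"), linker_spec()$linker_complement))
})
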