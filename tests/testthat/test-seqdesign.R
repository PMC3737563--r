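# Oligomer design: reverse complement, tiling, linkers, truncations,
# substitutions and molecular weights.

test_that("revcomp matches hand computations and is an involution", {
  expect_equal(revcomp("ACTC"), "GAGT")
  expect_equal(revcomp("ATTTTGTTTAATGTTCAAGGAACC"), "GGTTCCTTGAACATTAAACAAAAT")
  expect_equal(revcomp("RYSWKMN"), "NKMWSRY")
  set.seed(11)
  for (i in 1:25) {
    s <- random_dna(sample(1:60, 1))
    expect_equal(revcomp(revcomp(s)), s)
  }
  expect_error(revcomp("ACXG"), "'X' at position 3")
  expect_error(revcomp(""), "non-empty")
})

test_that("tile_region reproduces the printed panel geometry", {
  p <- tile_region(random_dna(119), 29, 22)
  expect_s3_class(p, "TilingPanel")
  expect_length(p$fragments, 14)
  expect_equal(p$step, 7)
  expect_equal(p$fragments[[1]]$region_start, 1)
  expect_equal(p$fragments[[14]]$region_end, 119)
  # fragments 5 and 6 (the merge used to start footprinting) span 29-64
  expect_equal(p$fragments[[5]]$region_start, 29)
  expect_equal(p$fragments[[6]]$region_end, 64)
})

test_that("tile_region end-anchors, covers all windows and counts correctly", {
  p <- tile_region(random_dna(40), 29, 22)
  expect_equal(vapply(p$fragments, `[[`, 0L, "region_start"), c(1L, 8L, 12L))
  # exhaustive coverage oracle on randomized geometries
  set.seed(7)
  for (i in 1:25) {
    f <- sample(10:60, 1)
    l <- sample(5:f, 1)
    n <- sample(f:300, 1)
    p <- tile_region(random_dna(n), f, l)
    starts <- vapply(p$fragments, `[[`, 0L, "region_start")
    ends <- vapply(p$fragments, `[[`, 0L, "region_end")
    expect_false(is.unsorted(starts))
    expect_equal(ends[length(ends)], n)
    covered <- vapply(seq_len(n - l + 1), function(w)
      any(starts <= w & ends >= w + l - 1), TRUE)
    expect_true(all(covered))
    if (f < n && f > l)
      expect_gte(length(p$fragments), ceiling((n - f) / (f - l)) + 1)
  }
  # single fragment when the region is exactly one fragment long
  expect_length(tile_region(random_dna(29), 29, 22)$fragments, 1)
  expect_error(tile_region(random_dna(20), 29, 22), "exceeds region")
  expect_error(tile_region(random_dna(40), 29, 30), "site_length")
})

test_that("attach_linker / strip_linker round-trip and validate", {
  d <- oligo_duplex("ACTCCAATACTTGAACTCTCAATCTTTA", name = "t")
  lk <- linker_spec()
  std <- attach_linker(d, lk, "reverse_3prime")
  s <- duplex_strands(std)
  expect_equal(nchar(s$reverse), nchar(s$forward) + 20)
  expect_equal(std$reverse, revcomp(std$forward))  # core invariant
  inv <- attach_linker(d, lk, "forward_3prime")
  expect_equal(nchar(duplex_strands(inv)$forward), nchar(d$forward) + 20)
  expect_equal(strip_linker(std), d)
  expect_error(attach_linker(std, lk, "reverse_3prime"), "already")
  expect_warning(attach_linker(d, lk, "none"), "unchanged")
  expect_error(linker_spec("ACGT"), "exactly 20 nt")
})

test_that("truncation series trim the correct ends and keep coordinates", {
  start <- oligo_duplex(START_A, name = "OA", region_start = 29)
  rh <- make_truncation_series(start, "RH", step = 2, max_delta = 12)
  deltas <- vapply(rh$members, `[[`, 0L, "delta")
  expect_equal(deltas, seq(0L, 12L, 2L))
  lens <- vapply(rh$members, function(m) nchar(m$oligo$forward), 0L)
  expect_equal(diff(lens), rep(-2L, 6))
  expect_equal(rh$members[[1]]$oligo$forward, START_A)  # delta 0 = start
  d8 <- rh$members[[which(deltas == 8)]]$oligo
  expect_equal(d8$forward, "ACTCCAATACTTGAACTCTCAATCTTTA")
  expect_equal(d8$overhang_host, "reverse_3prime")
  expect_true(all(vapply(rh$members, function(m)
    m$oligo$region_start == start$region_start, TRUE)))

  lh <- make_truncation_series(start, "LH", step = 2, max_delta = 12)
  d4 <- lh$members[[3]]$oligo
  expect_equal(d4$forward, "CAATACTTGAACTCTCAATCTTTACGTGCCGT")
  expect_equal(d4$overhang_host, "forward_3prime")
  expect_true(all(vapply(lh$members, function(m)
    m$oligo$region_end == start$region_end, TRUE)))
  expect_error(make_truncation_series(start, "RH", max_delta = 30),
               "min_length")
})

test_that("apply_footprint reproduces the printed 24-mers and commutes", {
  expect_equal(apply_footprint(oligo_duplex(START_A), 8, 4)$forward, FP_A)
  expect_equal(apply_footprint(oligo_duplex(START_B), 6, 6)$forward, FP_B)
  s <- oligo_duplex(START_A, region_start = 29)
  expect_equal(apply_footprint(s, 0, 0)$forward, s$forward)
  # truncating RH then LH equals one apply_footprint call
  rh <- make_truncation_series(s, "RH", max_delta = 8)
  rh8 <- strip_linker(rh$members[[5]]$oligo)
  lh <- make_truncation_series(rh8, "LH", max_delta = 4)
  two_step <- strip_linker(lh$members[[3]]$oligo)
  direct <- apply_footprint(s, 8, 4)
  expect_equal(two_step$forward, direct$forward)
  expect_equal(two_step$region_start, direct$region_start)
  expect_error(apply_footprint(s, -2, 0), "non-negative")
  expect_error(apply_footprint(s, 20, 20), "whole duplex")
})

test_that("substitution panels enumerate all single-base alternatives", {
  wt <- oligo_duplex(FP_A, name = "OA")
  pos <- c(6, 7, 9, 10, 14, 15, 16, 17)
  panel <- make_substitution_panel(wt, pos, replicates = 2)
  expect_length(panel$variants, 24)  # 8 positions x 3 alternatives
  expect_length(panel$controls, 2)
  for (v in panel$variants) {
    diff_at <- which(strsplit(v$oligo$forward, "")[[1]] !=
                       strsplit(wt$forward, "")[[1]])
    expect_equal(diff_at, v$position)
    expect_equal(v$oligo$reverse, revcomp(v$oligo$forward))
  }
  one <- make_substitution_panel(oligo_duplex("AAAA"), 2)
  expect_setequal(vapply(one$variants, `[[`, "", "alt_base"), c("C", "G", "T"))
  expect_error(make_substitution_panel(wt, c(3, 3)), "duplicate")
})

test_that("DNA masses agree with the atomic-composition oracle", {
  for (s in c("A", "C", "G", "T", "ACGT", FP_A, START_B))
    expect_equal(dna_strand_mw(s), oracle_strand_mw(s),
                 tolerance = 1e-4)
  d <- oligo_duplex(FP_A)
  expect_equal(dna_mw(d), dna_strand_mw(d$forward) + dna_strand_mw(d$reverse))
  # overhang counts toward the captured-ligand mass
  dl <- attach_linker(d, linker_spec(), "reverse_3prime")
  expect_gt(dna_mw(dl), dna_mw(d))
  # monotone in length
  set.seed(3)
  s <- random_dna(30)
  masses <- vapply(5:30, function(k) dna_strand_mw(substr(s, 1, k)), 0)
  expect_true(all(diff(masses) > 0))
  expect_error(dna_strand_mw("ACGN"), "invalid character 'N'")
})

test_that("protein masses use average residue masses plus one water", {
  expect_equal(protein_mw("G"), 75.07, tolerance = 1e-3)
  expect_equal(protein_mw("GG"), 2 * 57.0519 + 18.0153, tolerance = 1e-3)
  # additivity of residues
  expect_equal(protein_mw("MGK") - protein_mw("MG"),
               protein_mw("K") - 18.0153, tolerance = 1e-6)
  expect_error(protein_mw(""), "non-empty")
  expect_error(protein_mw("MGX"), "'X' at position 3")
})

test_that("translation follows the standard code with stop handling", {
  expect_equal(translate_dna("ATGGGT"), "MG")
  expect_equal(translate_dna("ATGTAA"), "M")
  expect_equal(translate_dna("ATGTAAGGG"), "M")  # stops at first stop
  expect_warning(out <- translate_dna("ATGGGTA"), "partial codon")
  expect_equal(out, "MG")
  set.seed(5)
  s <- random_dna(33)
  expect_equal(translate_dna(revcomp(revcomp(s))), translate_dna(s))
})

test_that("chip budget is a ceiling division", {
  expect_equal(chip_budget(138), 46L)
  expect_equal(chip_budget(4, 3), 2L)
  expect_equal(chip_budget(0), 0L)
})

test_that("panel TSV export covers all panel types", {
  p <- tile_region(random_dna(60), 29, 22)
  tsv <- file.path(tempdir(), "panel.tsv")
  write_panel_tsv(p, tsv)
  df <- read.delim(tsv)
  expect_equal(nrow(df), length(p$fragments))
  expect_named(df, c("name", "forward_5to3", "reverse_5to3", "overhang_host",
                     "region_start", "region_end", "delta", "side"))
  series <- make_truncation_series(oligo_duplex(START_A), "RH", max_delta = 6)
  df2 <- panel_table(series)
  expect_equal(df2$delta, c(0, 2, 4, 6))
  expect_true(all(df2$side == "RH"))
})
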