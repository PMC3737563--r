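# Seeded synthetic experiments with known ground truth. These emulate the
# shape of reusable-capture SPR data (capture plateau, 1:1 association and
# dissociation, salt washes, strip) so that every analysis stage can be
# exercised without instrument data; they make no claim to reproduce any
# actually recorded response values.

#' Declare a binding site planted in a synthetic region
#'
#' @param start 1-based start of the site on the region's forward strand.
#' @param length site length, nt.
#' @param ka,kd 1:1 association/dissociation rate constants of the site
#'   (defaults give a low-nanomolar KD typical of a repressor-operator
#'   interaction).
#' @param name identifier.
#' @return object of class `PlantedSite`.
#' @export
planted_site <- function(start, length = 22L, ka = 1e6, kd = 1.3e-3,
                         name = sprintf("site_%d", start)) {
  if (start < 1L || length < 1L) stop("invalid site geometry", call. = FALSE)
  structure(list(name = name, start = as.integer(start),
                 end = as.integer(start + length - 1L),
                 length = as.integer(length), ka = ka, kd = kd, KD = kd / ka),
            class = "PlantedSite")
}

# Fraction of a site contained in a fragment window, mapped to a response
# scale: zero below `threshold` containment, then linear up to 1 at full
# containment. A fixture convention, not a claim about SPR physics.
containment_scale <- function(frag_start, frag_end, site, threshold = 0.6) {
  contained <- max(0L, min(frag_end, site$end) - max(frag_start, site$start) + 1L)
  f <- contained / site$length
  if (f < threshold) 0 else (f - threshold) / (1 - threshold)
}

#' Generate a synthetic tiling screen
#'
#' Tiles the region, then simulates one reusable-capture cycle per fragment,
#' concentration and replicate (plus a matched reference-cell cycle). A
#' fragment responds at the full theoretical Rmax (times the isotherm
#' occupancy) when it fully contains a planted site; partial containment is
#' scaled by a declared containment function (zero below 60% of the site
#' contained, then linear). Capture levels are jittered around
#' `capture_ru`.
#'
#' @param region region sequence (forward strand, `A/C/G/T`).
#' @param sites list of [planted_site()]; must not overlap one another.
#' @param fragment_length,site_length tiling parameters (nt).
#' @param concentrations_nM protein dimer concentrations, nM.
#' @param replicates cycles per fragment x concentration.
#' @param capture_ru nominal DNA capture level, RU.
#' @param mw_analyte analyte (protein dimer) mass, Da.
#' @param linker a [linker_spec()].
#' @param noise_sd per-sample Gaussian noise, RU.
#' @param containment_threshold containment fraction below which a fragment
#'   gives no response.
#' @param seed integer seed; the bundle is reproducible byte-for-byte.
#' @return an `ExperimentBundle`: `panel`, `panel_info`, `cycles` (test and
#'   reference `SensorgramCycle`s), `cycle_table`, `truth`, `seed`.
#' @export
generate_screening_experiment <- function(region, sites,
                                          fragment_length = 29L,
                                          site_length = 22L,
                                          concentrations_nM = c(10, 50, 100),
                                          replicates = 2L,
                                          capture_ru = 400,
                                          mw_analyte = 41046,
                                          linker = linker_spec(),
                                          noise_sd = 2,
                                          containment_threshold = 0.6,
                                          seed = 1L) {
  validate_dna(region, iupac = FALSE, what = "region")
  for (s in sites) stopifnot(inherits(s, "PlantedSite"))
  if (length(sites) > 1L) {
    ord <- order(vapply(sites, `[[`, 0L, "start"))
    sites <- sites[ord]
    starts <- vapply(sites, `[[`, 0L, "start")
    ends <- vapply(sites, `[[`, 0L, "end")
    if (any(starts[-1L] <= ends[-length(ends)]))
      stop("planted sites overlap", call. = FALSE)
  }
  if (length(sites) && max(vapply(sites, `[[`, 0L, "end")) > nchar(region))
    stop("site extends beyond the region", call. = FALSE)

  panel <- tile_region(region, fragment_length, site_length)
  panel_info <- do.call(rbind, lapply(panel$fragments, function(fr) {
    cap <- attach_linker(fr, linker, "reverse_3prime")
    data.frame(fragment = fr$name, region_start = fr$region_start,
               region_end = fr$region_end, mw_ligand = dna_mw(cap),
               stringsAsFactors = FALSE)
  }))

  with_seed(seed, {
    cycles <- list()
    rows <- list()
    for (i in seq_along(panel$fragments)) {
      fr <- panel$fragments[[i]]
      scales <- vapply(sites, function(s)
        containment_scale(fr$region_start, fr$region_end, s,
                          containment_threshold), 0)
      best <- if (length(scales) && max(scales) > 0) which.max(scales) else 0L
      for (conc in concentrations_nM) {
        for (rep in seq_len(replicates)) {
          cap_i <- max(10, stats::rnorm(1, capture_ru, 0.05 * capture_ru))
          rmax_t <- theoretical_rmax(mw_analyte, panel_info$mw_ligand[i], cap_i)
          eff_rmax <- if (best > 0L) scales[best] * rmax_t else 0
          params <- if (best > 0L && eff_rmax > 0)
            kinetic_params(sites[[best]]$ka, sites[[best]]$kd, eff_rmax)
          else kinetic_params(1e6, 1e-3, 1e-9)  # no site: flat trace
          sched <- injection_schedule(conc * 1e-9, capture_ru = cap_i)
          id <- sprintf("scr_%s_c%g_r%d", fr$name, conc, rep)
          test <- simulate_cycle(params, sched, noise_sd = 0,
                                 cycle_id = id, flow_cell = "FC_test")
          test$response <- test$response + stats::rnorm(length(test$time), 0,
                                                        noise_sd)
          ref <- sensorgram_cycle(paste0(id, "_ref"), "FC_ref", test$time,
                                  stats::rnorm(length(test$time), 0,
                                               noise_sd / 2),
                                  test$phases)
          cycles[[id]] <- test
          cycles[[paste0(id, "_ref")]] <- ref
          rows[[length(rows) + 1L]] <- data.frame(
            cycle_id = id, fragment = fr$name, conc_nM = conc,
            replicate = rep, capture_ru = cap_i, stringsAsFactors = FALSE)
        }
      }
    }
    expected_hits <- lapply(sites, function(s) {
      panel_info$fragment[panel_info$region_start <= s$start &
                          panel_info$region_end >= s$end]
    })
    names(expected_hits) <- vapply(sites, `[[`, "", "name")
    structure(list(kind = "screening", region = toupper(region),
                   panel = panel, panel_info = panel_info,
                   cycles = cycles, cycle_table = do.call(rbind, rows),
                   mw_analyte = mw_analyte,
                   truth = list(sites = sites, expected_hits = expected_hits),
                   seed = as.integer(seed)),
              class = "ExperimentBundle")
  })
}

#' Analyze a synthetic (or imported) tiling screen
#'
#' For each test cycle: reference subtraction, injection-baseline zeroing,
#' screening report-point extraction, and normalization by the theoretical
#' Rmax computed from the measured capture level and the fragment's ligand
#' mass. Replicates are averaged.
#'
#' @param bundle a screening `ExperimentBundle`.
#' @return a [screening_result()].
#' @export
analyze_screening <- function(bundle) {
  stopifnot(inherits(bundle, "ExperimentBundle"), bundle$kind == "screening")
  tab <- bundle$cycle_table
  pct <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    test <- bundle$cycles[[tab$cycle_id[i]]]
    ref <- bundle$cycles[[paste0(tab$cycle_id[i], "_ref")]]
    corr <- double_reference(test, ref)
    rp_raw <- extract_report_points(corr, report_convention("screening"))
    rp <- extract_report_points(zero_at_injection(corr),
                                report_convention("screening"))
    info <- bundle$panel_info[bundle$panel_info$fragment == tab$fragment[i], ]
    rmax <- theoretical_rmax(bundle$mw_analyte, info$mw_ligand,
                             max(rp_raw$capture_ru, 1))
    pct[i] <- suppressWarnings(normalize_response(rp$bind_ru, rmax))
  }
  agg <- stats::aggregate(pct,
                          by = list(fragment = tab$fragment,
                                    conc_nM = tab$conc_nM), FUN = mean)
  info <- bundle$panel_info[match(agg$fragment, bundle$panel_info$fragment), ]
  screening_result(agg$fragment, info$region_start, info$region_end,
                   agg$conc_nM, agg$x)
}

#' Generate a synthetic truncation (footprinting) experiment
#'
#' Builds the truncation series for one boundary and simulates one cycle per
#' member. Members that have not yet crossed the true boundary share the
#' reference kinetics; each truncation step beyond it multiplies the
#' dissociation rate by `kd_factor` and increases both salt-wash removal
#' fractions by `salt_increment` (a declared effect model mirroring the
#' observation that cutting into a site speeds dissociation and weakens salt
#' resistance).
#'
#' @param start starting `OligoDuplex`.
#' @param side `"RH"` or `"LH"`.
#' @param true_delta ground-truth boundary truncation, nt.
#' @param step,max_delta series geometry, nt.
#' @param ka,kd reference kinetics.
#' @param kd_factor fold-increase of `kd` per step beyond the boundary.
#' @param salt_increment added salt-wash removal fraction per step beyond.
#' @param base_salt_removal length-2 removal fractions inside the site.
#' @param conc_nM protein concentration, nM.
#' @param capture_ru,mw_analyte,linker,noise_sd,seed as in
#'   [generate_screening_experiment()].
#' @return an `ExperimentBundle` of kind `"truncation"`.
#' @export
generate_truncation_experiment <- function(start, side, true_delta,
                                           step = 2L, max_delta = 12L,
                                           ka = 1e6, kd = 2.4e-3,
                                           kd_factor = 3,
                                           salt_increment = 0.15,
                                           base_salt_removal = c(0.2, 0.2),
                                           conc_nM = 100,
                                           capture_ru = 400,
                                           mw_analyte = 41046,
                                           linker = linker_spec(),
                                           noise_sd = 2,
                                           seed = 1L) {
  series <- make_truncation_series(start, side, step = step,
                                   max_delta = max_delta, linker = linker)
  with_seed(seed, {
    cycles <- list()
    rows <- list()
    for (m in series$members) {
      steps_beyond <- max(0, ceiling((m$delta - true_delta) / step))
      kd_i <- kd * kd_factor^steps_beyond
      removal <- pmin(0.95, base_salt_removal + salt_increment * steps_beyond)
      cap_i <- max(10, stats::rnorm(1, capture_ru, 0.05 * capture_ru))
      mw_ligand <- dna_mw(m$oligo)
      rmax_t <- theoretical_rmax(mw_analyte, mw_ligand, cap_i)
      params <- kinetic_params(ka, kd_i, rmax_t)
      sched <- injection_schedule(conc_nM * 1e-9, capture_ru = cap_i,
                                  salt_removal = removal)
      id <- sprintf("trunc_%s_d%d", side, m$delta)
      test <- simulate_cycle(params, sched, noise_sd = 0, cycle_id = id)
      test$response <- test$response + stats::rnorm(length(test$time), 0,
                                                    noise_sd)
      ref <- sensorgram_cycle(paste0(id, "_ref"), "FC_ref", test$time,
                              stats::rnorm(length(test$time), 0, noise_sd / 2),
                              test$phases)
      cycles[[id]] <- test
      cycles[[paste0(id, "_ref")]] <- ref
      rows[[length(rows) + 1L]] <- data.frame(
        cycle_id = id, delta = m$delta, mw_ligand = mw_ligand,
        capture_ru = cap_i, stringsAsFactors = FALSE)
    }
    structure(list(kind = "truncation", side = side, series = series,
                   cycle_table = do.call(rbind, rows), cycles = cycles,
                   mw_analyte = mw_analyte,
                   truth = list(true_delta = as.integer(true_delta),
                                ka = ka, kd = kd, kd_factor = kd_factor,
                                salt_increment = salt_increment),
                   seed = as.integer(seed)),
              class = "ExperimentBundle")
  })
}

#' Analyze a synthetic truncation experiment
#'
#' @param bundle a truncation `ExperimentBundle`.
#' @return a [truncation_metrics()] table.
#' @export
analyze_truncation <- function(bundle) {
  stopifnot(inherits(bundle, "ExperimentBundle"), bundle$kind == "truncation")
  tab <- bundle$cycle_table
  out <- lapply(seq_len(nrow(tab)), function(i) {
    test <- bundle$cycles[[tab$cycle_id[i]]]
    ref <- bundle$cycles[[paste0(tab$cycle_id[i], "_ref")]]
    corr <- double_reference(test, ref)
    rp_raw <- extract_report_points(corr, report_convention("screening"))
    rp <- extract_report_points(zero_at_injection(corr),
                                report_convention("screening"))
    rmax <- theoretical_rmax(bundle$mw_analyte, tab$mw_ligand[i],
                             max(rp_raw$capture_ru, 1))
    ret <- suppressWarnings(retention_fractions(rp))
    data.frame(delta = tab$delta[i],
               norm_max = suppressWarnings(normalize_response(rp$bind_ru, rmax)),
               retained_dissoc = ret$retained_dissoc,
               retained_salt1 = ret$retained_salt1,
               retained_salt2 = ret$retained_salt2)
  })
  df <- do.call(rbind, out)
  truncation_metrics(df$delta, df$norm_max, df$retained_dissoc,
                     df$retained_salt1, df$retained_salt2)
}

#' Generate a synthetic steady-state affinity dataset
#'
#' Steady-state 1:1 responses with i.i.d. Gaussian noise, replicated at each
#' concentration of the series.
#'
#' @param kd_eq true KD, M.
#' @param rmax true saturating response, RU.
#' @param conc_nM concentration series, nM (default: the eight-point
#'   two-fold series 0.39-50 nM).
#' @param replicates replicates per concentration.
#' @param noise_sd Gaussian noise sd, RU.
#' @param seed integer seed.
#' @return data frame: conc_nM, replicate, response_ru.
#' @export
generate_affinity_dataset <- function(kd_eq, rmax,
                                      conc_nM = c(0.39, 0.78, 1.56, 3.13,
                                                  6.25, 12.5, 25, 50),
                                      replicates = 3L, noise_sd = 0,
                                      seed = 1L) {
  if (kd_eq <= 0 || rmax <= 0) stop("kd_eq and rmax must be > 0", call. = FALSE)
  with_seed(seed, {
    df <- expand.grid(replicate = seq_len(replicates), conc_nM = conc_nM)
    df <- df[c("conc_nM", "replicate")]
    df <- df[order(df$conc_nM, df$replicate), ]
    mu <- steady_state_response(df$conc_nM * 1e-9, kd_eq, rmax)
    df$response_ru <- mu + stats::rnorm(nrow(df), 0, noise_sd)
    rownames(df) <- NULL
    df
  })
}

#' Write an experiment bundle to disk
#'
#' Emits the plain-text file set for a bundle: `region.fa` (screening only),
#' `panel.tsv`, `sensorgrams.csv` with its `sensorgrams.phases.json`
#' sidecar, and `truth.json`. Writing the same bundle twice is
#' byte-identical.
#'
#' @param bundle an `ExperimentBundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ExperimentBundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (bundle$kind == "screening") {
    write_fasta(c(region = bundle$region), file.path(dir, "region.fa"))
    write_panel_tsv(bundle$panel, file.path(dir, "panel.tsv"))
  } else if (bundle$kind == "truncation") {
    write_panel_tsv(bundle$series, file.path(dir, "panel.tsv"))
  }
  write_sensorgrams(bundle$cycles, file.path(dir, "sensorgrams.csv"))
  truth <- bundle$truth
  truth$seed <- bundle$seed
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Paper-like synthetic screening region
#'
#' Builds a synthetic 119-nt intergenic region with two non-overlapping
#' 22-nt operator-like sites planted where the default 29/22 tiling contains
#' each fully in exactly two adjacent fragments (mirroring a two-peak
#' screen), on a GC-rich random background typical of a streptomycete
#' genome.
#'
#' @param seed integer seed.
#' @param gc background GC fraction.
#' @return list with `region` (character) and `sites` (list of
#'   [planted_site()], the stronger site first).
#' @export
paperlike_screening_region <- function(seed = 1L, gc = 0.72) {
  with_seed(seed, {
    region <- random_dna(119L, gc = gc)
    # 22-nt cores of the two mapped operator footprints
    site1 <- "AATACTTGAACTCTCAATCTTT"   # KD ~ 1.3 nM
    site2 <- "TTTTGTTTAATGTTCAAGGAAC"   # KD ~ 2.4 nM
    substr(region, 36L, 57L) <- site1
    substr(region, 78L, 99L) <- site2
    list(region = region,
         sites = list(planted_site(36L, 22L, ka = 1e6, kd = 1.3e-3,
                                   name = "siteA"),
                      planted_site(78L, 22L, ka = 1e6, kd = 2.4e-3,
                                   name = "siteB")))
  })
}

#' Random DNA sequence
#'
#' @param n length, nt.
#' @param gc GC fraction.
#' @return character sequence.
#' @export
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Synthetic chromosome stand-in for genome scanning
#'
#' Builds a SYNTHETIC GC-rich chromosome carrying exactly five instances of
#' a degenerate motif: two adjacent ones inside a planted "intergenic"
#' region (the geometry of a pair of operators ahead of divergent genes) and
#' three isolated ones elsewhere. Incidental background matches on either
#' strand are removed by point mutation, so the planted instances are the
#' only hits. This is a stand-in for a real chromosome, which cannot be
#' redistributed with the package; it preserves the counting task, not the
#' biology.
#'
#' @param motif IUPAC motif to plant (default the pseudopalindromic
#'   dodecamer consensus).
#' @param genome_length chromosome length, nt.
#' @param gc background GC fraction.
#' @param seed integer seed.
#' @return list: `genome` (named character), `planted` (data frame of
#'   planted positions with an `intergenic` flag).
#' @export
synthetic_genome_scan_fixture <- function(motif = "TTnAAnnnTCAA",
                                          genome_length = 100000L,
                                          gc = 0.72, seed = 1L) {
  with_seed(seed, {
    genome <- random_dna(genome_length, gc = gc)
    pat_chars <- strsplit(toupper(motif), "")[[1L]]
    matches_iupac <- function(s) {
      sc <- strsplit(s, "")[[1L]]
      def <- pat_chars %in% DEFINED_BASES
      all(sc[def] == pat_chars[def])
    }
    instantiate <- function() {
      repeat {
        chars <- pat_chars
        wild <- !chars %in% DEFINED_BASES
        chars[wild] <- sample(DEFINED_BASES, sum(wild), replace = TRUE)
        inst <- paste(chars, collapse = "")
        # reject instances that also match on the minus strand, so every
        # planted site yields exactly one hit
        if (!matches_iupac(revcomp(inst))) return(inst)
      }
    }
    # two "intergenic" sites ~20 nt apart, then three isolated sites
    if (genome_length < 2000L)
      stop("genome_length too short for the planted layout", call. = FALSE)
    mid <- as.integer(genome_length %/% 2)
    starts <- as.integer(c(mid, mid + 32L,
                           round(0.12 * genome_length),
                           round(0.64 * genome_length),
                           round(0.91 * genome_length)))
    intergenic <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
    for (s in starts) {
      inst <- instantiate()
      substr(genome, s, s + nchar(inst) - 1L) <- inst
    }
    planted_iv <- cbind(starts, starts + nchar(motif) - 1L)
    outside_planted <- function(pos)
      all(pos < planted_iv[, 1] | pos > planted_iv[, 2])
    # scrub incidental matches (either strand): mutate every hit position
    # lying outside the planted intervals to G/C until only the five
    # planted instances remain
    repeat {
      hits <- scan_sequence(c(chrS = genome), motif, strands = "both")
      planted_hit <- hits$start %in% starts & hits$strand == "+" &
        hits$end %in% planted_iv[, 2]
      extra <- hits[!planted_hit, , drop = FALSE]
      if (!nrow(extra)) break
      for (i in seq_len(nrow(extra))) {
        for (pos in seq.int(extra$start[i], extra$end[i])) {
          if (!outside_planted(pos)) next
          cur <- substr(genome, pos, pos)
          substr(genome, pos, pos) <- if (cur == "G") "C" else "G"
        }
      }
    }
    list(genome = c(chrS = genome),
         planted = data.frame(start = starts,
                              end = starts + nchar(motif) - 1L,
                              intergenic = intergenic))
  })
}
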