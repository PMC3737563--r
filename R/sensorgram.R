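# Sensorgram representation, referencing, report points and normalization.

PHASE_ORDER <- c("capture", "wash", "association", "dissociation",
                 "salt_wash_1", "salt_wash_2", "strip")

#' Construct a sensorgram cycle
#'
#' One capture/bind/regenerate cycle on one flow cell: a time series of
#' responses (RU) plus named phase windows. Phase windows must appear in the
#' canonical order capture, wash, association, dissociation, salt_wash_1,
#' salt_wash_2, strip (any subset) and must not overlap.
#'
#' @param cycle_id identifier.
#' @param flow_cell `"FC_test"` or `"FC_ref"`.
#' @param time numeric vector, strictly increasing, seconds.
#' @param response numeric vector, response units.
#' @param phases named list of `c(t_start, t_end)` windows.
#' @return an object of class `SensorgramCycle`.
#' @export
sensorgram_cycle <- function(cycle_id, flow_cell = c("FC_test", "FC_ref"),
                             time, response, phases = list()) {
  flow_cell <- match.arg(flow_cell)
  if (length(time) != length(response))
    stop("time and response differ in length", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (length(phases)) {
    known <- intersect(PHASE_ORDER, names(phases))
    if (length(setdiff(names(phases), PHASE_ORDER)))
      stop("unknown phase name(s): ",
           paste(setdiff(names(phases), PHASE_ORDER), collapse = ", "),
           call. = FALSE)
    bounds <- do.call(rbind, phases[known])
    if (any(bounds[, 2] < bounds[, 1]))
      stop("phase windows must have t_end >= t_start", call. = FALSE)
    if (length(known) > 1L && any(diff(as.vector(t(bounds))) < -1e-9))
      stop("phase windows overlap or are out of order", call. = FALSE)
    phases <- phases[known]
  }
  structure(list(cycle_id = as.character(cycle_id), flow_cell = flow_cell,
                 time = as.numeric(time), response = as.numeric(response),
                 phases = phases),
            class = "SensorgramCycle")
}

#' @export
print.SensorgramCycle <- function(x, ...) {
  cat(sprintf("SensorgramCycle '%s' (%s): %d samples, %.1f-%.1f s, phases: %s\n",
              x$cycle_id, x$flow_cell, length(x$time), min(x$time), max(x$time),
              paste(names(x$phases), collapse = ", ")))
  invisible(x)
}

cycle_response_at <- function(cycle, t, phase = "report point") {
  if (t < min(cycle$time) - 1e-9 || t > max(cycle$time) + 1e-9)
    stop(sprintf("%s time %.2f s outside sampled range of cycle '%s'",
                 phase, t, cycle$cycle_id), call. = FALSE)
  stats::approx(cycle$time, cycle$response, xout = t, rule = 2)$y
}

#' Double referencing of a test cycle
#'
#' Subtracts the reference flow cell, then a buffer-only (test minus
#' reference) blank, removing both surface and bulk refractive-index
#' contributions: `corrected(t) = [test - ref](t) - [buffer_test -
#' buffer_ref](t)`. All cycles are linearly interpolated onto the test
#' cycle's time grid restricted to the common time range. Buffer cycles may
#' be `NULL` (plain single referencing). Negative corrected responses are
#' retained.
#'
#' @param test,ref test and reference flow-cell cycles.
#' @param buffer_test,buffer_ref buffer-only cycles, or `NULL`.
#' @return a corrected `SensorgramCycle` (phases from `test`).
#' @export
double_reference <- function(test, ref, buffer_test = NULL, buffer_ref = NULL) {
  cycles <- Filter(Negate(is.null), list(test, ref, buffer_test, buffer_ref))
  lapply(cycles, function(x) stopifnot(inherits(x, "SensorgramCycle")))
  lo <- max(vapply(cycles, function(x) min(x$time), 0))
  hi <- min(vapply(cycles, function(x) max(x$time), 0))
  if (lo >= hi)
    stop("cycles do not share an overlapping time range", call. = FALSE)
  grid <- test$time[test$time >= lo - 1e-9 & test$time <= hi + 1e-9]
  on_grid <- function(x) {
    if (is.null(x)) return(numeric(length(grid)))
    stats::approx(x$time, x$response, xout = grid, rule = 2)$y
  }
  corrected <- (on_grid(test) - on_grid(ref)) -
    (on_grid(buffer_test) - on_grid(buffer_ref))
  sensorgram_cycle(paste0(test$cycle_id, "_corr"), test$flow_cell,
                   grid, corrected, test$phases)
}

#' Zero a cycle at the start of the protein injection
#'
#' Subtracts the pre-injection baseline (the response at the end of the
#' post-capture wash, or of the capture window if no wash is recorded) from
#' the whole trace, so that protein-phase report points read directly as
#' protein response.
#'
#' @param cycle a `SensorgramCycle` containing an `association` phase.
#' @return the baseline-shifted cycle.
#' @export
zero_at_injection <- function(cycle) {
  stopifnot(inherits(cycle, "SensorgramCycle"))
  t0 <- if (!is.null(cycle$phases$wash)) cycle$phases$wash[2]
        else if (!is.null(cycle$phases$capture)) cycle$phases$capture[2]
        else stop("no capture/wash phase to define the injection baseline",
                  call. = FALSE)
  base <- cycle_response_at(cycle, t0, "injection baseline")
  cycle$response <- cycle$response - base
  cycle
}

#' Report-point convention
#'
#' Screening experiments read the binding response 10 s after the end of the
#' protein injection (early dissociation, where bulk effects have decayed);
#' affinity experiments read 4 s before the end of the injection (steady
#' state).
#'
#' @param mode `"screening"` or `"affinity"`.
#' @return an object of class `ReportConvention` with the fixed offset (s)
#'   relative to the end of injection.
#' @export
report_convention <- function(mode = c("screening", "affinity")) {
  mode <- match.arg(mode)
  structure(list(mode = mode, offset = if (mode == "screening") 10 else -4),
            class = "ReportConvention")
}

#' Extract report points from a cycle
#'
#' Reads, by linear interpolation on the sampled trace: `capture_ru` at the
#' end of the post-capture wash (or capture window), `bind_ru` at the end of
#' the association phase plus the convention's offset, and `dissoc_ru`,
#' `salt1_ru`, `salt2_ru` at the ends of the dissociation and salt-wash
#' windows. Values are raw trace responses; apply [zero_at_injection()]
#' first if protein-only responses are wanted.
#'
#' @param cycle a `SensorgramCycle`.
#' @param conv a [report_convention()].
#' @return one-row data frame: cycle_id, capture_ru, bind_ru, dissoc_ru,
#'   salt1_ru, salt2_ru (absent phases give `NA`).
#' @export
extract_report_points <- function(cycle, conv = report_convention("screening")) {
  stopifnot(inherits(cycle, "SensorgramCycle"), inherits(conv, "ReportConvention"))
  ph <- cycle$phases
  if (is.null(ph$association))
    stop("cycle has no association phase", call. = FALSE)
  at_end <- function(name) {
    if (is.null(ph[[name]])) return(NA_real_)
    cycle_response_at(cycle, ph[[name]][2], name)
  }
  cap_t <- if (!is.null(ph$wash)) ph$wash[2] else ph$capture[2]
  data.frame(
    cycle_id = cycle$cycle_id,
    capture_ru = if (is.null(cap_t)) NA_real_
                 else cycle_response_at(cycle, cap_t, "capture"),
    bind_ru = cycle_response_at(cycle, ph$association[2] + conv$offset,
                                "binding report point"),
    dissoc_ru = at_end("dissociation"),
    salt1_ru = at_end("salt_wash_1"),
    salt2_ru = at_end("salt_wash_2"),
    stringsAsFactors = FALSE)
}

#' Theoretical maximum response
#'
#' The largest analyte response a captured ligand surface can give,
#' `Rmax = (MW_analyte / MW_ligand) * captured_RU * stoichiometry`, here with
#' the analyte a protein dimer, the ligand the captured test DNA including
#' its single-stranded overhang, and a default stoichiometry of one dimer
#' per duplex.
#'
#' @param mw_analyte analyte molecular weight (Da).
#' @param mw_ligand ligand molecular weight (Da).
#' @param captured_ru ligand capture level (RU).
#' @param stoichiometry analytes bound per ligand.
#' @return Rmax in RU.
#' @export
theoretical_rmax <- function(mw_analyte, mw_ligand, captured_ru,
                             stoichiometry = 1) {
  vals <- c(mw_analyte, mw_ligand, captured_ru, stoichiometry)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all Rmax inputs must be positive and finite", call. = FALSE)
  (mw_analyte / mw_ligand) * captured_ru * stoichiometry
}

#' Normalize a binding response to percent of theoretical Rmax
#'
#' @param bind_ru binding response (RU).
#' @param rmax theoretical Rmax (RU), positive.
#' @return percentage; values above 100 are allowed with a warning
#'   (super-stoichiometric signal).
#' @export
normalize_response <- function(bind_ru, rmax) {
  if (!is.finite(rmax) || rmax <= 0)
    stop("rmax must be positive", call. = FALSE)
  pct <- 100 * bind_ru / rmax
  if (any(pct > 100 + 1e-9, na.rm = TRUE))
    warning("normalized response exceeds 100% of theoretical Rmax",
            call. = FALSE)
  pct
}

#' Retention of bound protein through dissociation and salt washes
#'
#' Fractions of the binding report point still present at the end of the
#' dissociation phase and after each of two salt washes, reported as
#' percentages of `bind_ru`.
#'
#' @param row one row from [extract_report_points()] (zeroed at injection).
#' @return data frame with retained_dissoc, retained_salt1, retained_salt2
#'   (percent) and a `flagged` logical (TRUE when bind_ru is not positive,
#'   in which case the fractions are `NA`).
#' @export
retention_fractions <- function(row) {
  need <- c("bind_ru", "dissoc_ru", "salt1_ru", "salt2_ru")
  stopifnot(all(need %in% names(row)))
  if (!is.finite(row$bind_ru) || row$bind_ru <= 0) {
    warning("bind_ru is not positive; retention undefined", call. = FALSE)
    return(data.frame(retained_dissoc = NA_real_, retained_salt1 = NA_real_,
                      retained_salt2 = NA_real_, flagged = TRUE))
  }
  data.frame(retained_dissoc = 100 * row$dissoc_ru / row$bind_ru,
             retained_salt1 = 100 * row$salt1_ru / row$bind_ru,
             retained_salt2 = 100 * row$salt2_ru / row$bind_ru,
             flagged = FALSE)
}

# --- CSV / sidecar I/O ------------------------------------------------------

#' Write sensorgram cycles to CSV (with a JSON phase sidecar)
#'
#' The CSV has header `cycle,flow_cell,time_s,response_ru`; phase windows go
#' to a JSON sidecar mapping each cycle id to its named `[t_start, t_end]`
#' windows. Numbers are written with fixed formatting so that regeneration
#' from the same inputs is byte-identical.
#'
#' @param cycles list of `SensorgramCycle`.
#' @param csv_path output CSV path.
#' @param phases_path output JSON sidecar path (default: csv path with
#'   `.phases.json`).
#' @return `csv_path`, invisibly.
#' @export
write_sensorgrams <- function(cycles, csv_path,
                              phases_path = sub("\\.csv$", ".phases.json",
                                                csv_path)) {
  if (inherits(cycles, "SensorgramCycle")) cycles <- list(cycles)
  con <- file(csv_path, "wb")
  writeLines("cycle,flow_cell,time_s,response_ru", con)
  for (cy in cycles) {
    writeLines(sprintf("%s,%s,%.3f,%.4f", cy$cycle_id, cy$flow_cell,
                       cy$time, cy$response), con)
  }
  close(con)
  phases <- lapply(cycles, function(cy) lapply(cy$phases, as.numeric))
  names(phases) <- vapply(cycles, `[[`, "", "cycle_id")
  jsonlite::write_json(phases, phases_path, digits = NA, auto_unbox = FALSE)
  invisible(csv_path)
}

#' Read sensorgram cycles from CSV (+ JSON phase sidecar)
#'
#' @param csv_path CSV with header `cycle,flow_cell,time_s,response_ru`.
#' @param phases_path JSON sidecar as written by [write_sensorgrams()];
#'   `NULL` for no phases.
#' @return named list of `SensorgramCycle`.
#' @export
read_sensorgrams <- function(csv_path,
                             phases_path = sub("\\.csv$", ".phases.json",
                                               csv_path)) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("cycle", "flow_cell", "time_s", "response_ru")
  if (!all(need %in% names(df)))
    stop("sensorgram CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  phases_all <- if (!is.null(phases_path) && file.exists(phases_path))
    jsonlite::read_json(phases_path, simplifyVector = TRUE) else list()
  ids <- unique(df$cycle)
  cycles <- lapply(ids, function(id) {
    sub <- df[df$cycle == id, ]
    ph <- phases_all[[as.character(id)]]
    ph <- if (is.null(ph)) list() else lapply(as.list(ph), as.numeric)
    sensorgram_cycle(id, sub$flow_cell[1L], sub$time_s, sub$response_ru, ph)
  })
  names(cycles) <- ids
  cycles
}
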