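# From normalized responses to biology: hit calling, hit merging and
# footprint boundary calling.

#' Screening result table
#'
#' Normalized percent-of-Rmax responses of a tiling panel at each protein
#' concentration. One row per fragment x concentration (replicates already
#' averaged).
#'
#' @param fragment fragment names.
#' @param region_start,region_end fragment coordinates.
#' @param conc_nM protein (dimer) concentration, nM.
#' @param pct_rmax normalized response, percent of theoretical Rmax.
#' @return data frame of class `ScreeningResult`, ordered by region_start
#'   then concentration.
#' @export
screening_result <- function(fragment, region_start, region_end, conc_nM,
                             pct_rmax) {
  df <- data.frame(fragment = fragment, region_start = region_start,
                   region_end = region_end, conc_nM = conc_nM,
                   pct_rmax = pct_rmax, stringsAsFactors = FALSE)
  df <- df[order(df$region_start, df$conc_nM), ]
  rownames(df) <- NULL
  class(df) <- c("ScreeningResult", "data.frame")
  df
}

#' Call screening hits
#'
#' A fragment is a hit when its normalized response at the top protein
#' concentration reaches approximately 100 percent of the theoretical Rmax;
#' "approximately" is operationalized as `>= threshold_pct` (default 90).
#'
#' @param s a [screening_result()].
#' @param top_conc concentration (nM) at which hits are judged.
#' @param threshold_pct hit threshold, percent of theoretical Rmax.
#' @return character vector of hit fragment names, ordered by position.
#' @export
call_hits <- function(s, top_conc = 100, threshold_pct = 90) {
  stopifnot(inherits(s, "ScreeningResult"))
  sub <- s[abs(s$conc_nM - top_conc) < 1e-9, ]
  if (!nrow(sub))
    stop(sprintf("concentration %g nM not present in screening result",
                 top_conc), call. = FALSE)
  agg <- stats::aggregate(pct_rmax ~ fragment + region_start, data = sub, mean)
  agg <- agg[order(agg$region_start), ]
  agg$fragment[agg$pct_rmax >= threshold_pct]
}

#' Merge runs of adjacent hit fragments into starting oligomers
#'
#' Consecutive hit fragments in the panel are merged into a single duplex
#' spanning from the first hit's start to the last hit's end; separate
#' (non-consecutive) runs yield separate duplexes, treated as independent
#' candidate sites.
#'
#' @param hits character vector of hit fragment names (from [call_hits()]).
#' @param panel the `TilingPanel` the hits came from.
#' @return list of merged `OligoDuplex`, one per run of consecutive hits.
#' @export
merge_adjacent_hits <- function(hits, panel) {
  stopifnot(inherits(panel, "TilingPanel"))
  if (!length(hits)) stop("empty hit list", call. = FALSE)
  frag_names <- vapply(panel$fragments, `[[`, "", "name")
  idx <- match(hits, frag_names)
  if (anyNA(idx))
    stop("hit fragment(s) not found in panel: ",
         paste(hits[is.na(idx)], collapse = ", "), call. = FALSE)
  idx <- sort(idx)
  run_id <- cumsum(c(1L, diff(idx) != 1L))
  lapply(split(idx, run_id), function(run) {
    s <- panel$fragments[[run[1L]]]$region_start
    e <- panel$fragments[[run[length(run)]]]$region_end
    oligo_duplex(substr(panel$region, s, e),
                 name = sprintf("site_%d_%d", s, e),
                 region_start = s, region_end = e)
  })
}

#' Truncation-series metrics table
#'
#' Per series member: the normalized maximum response and the retention of
#' bound protein through the dissociation phase and the two salt washes.
#'
#' @param delta truncation, nt (must include 0, the reference).
#' @param norm_max normalized maximum response, percent of theoretical Rmax.
#' @param retained_dissoc,retained_salt1,retained_salt2 retention, percent
#'   of the binding report point.
#' @return data frame of class `TruncationMetrics`, deltas ascending.
#' @export
truncation_metrics <- function(delta, norm_max, retained_dissoc,
                               retained_salt1, retained_salt2) {
  df <- data.frame(delta = as.integer(delta), norm_max = norm_max,
                   retained_dissoc = retained_dissoc,
                   retained_salt1 = retained_salt1,
                   retained_salt2 = retained_salt2)
  df <- df[order(df$delta), ]
  rownames(df) <- NULL
  class(df) <- c("TruncationMetrics", "data.frame")
  df
}

#' Call a footprint boundary from truncation metrics
#'
#' Walking out from the full-length reference (delta 0), a truncation passes
#' while (a) its normalized maximum response is at least
#' `(100 - tol_response_pct)` percent of the reference's, and (b) each
#' retention metric is within `tol_retention_pts` percentage points of the
#' reference's. The chosen boundary is the largest delta for which every
#' truncation up to and including it passes: the first member that binds
#' detectably worse, or releases protein faster in dissociation or salt, has
#' crossed into the site. The resolution of the call is the truncation step.
#'
#' @param m a [truncation_metrics()] table.
#' @param side `"RH"` or `"LH"`.
#' @param tol_response_pct relative response tolerance, percent.
#' @param tol_retention_pts retention tolerance, percentage points.
#' @return object of class `BoundaryCall`: `side`, `chosen_delta`,
#'   `resolution` (nt) and a per-delta, per-metric `rationale` data frame.
#' @export
call_boundary <- function(m, side = c("RH", "LH"), tol_response_pct = 10,
                          tol_retention_pts = 10) {
  stopifnot(inherits(m, "TruncationMetrics"))
  side <- match.arg(side)
  if (!0L %in% m$delta)
    stop("reference member (delta = 0) missing from metrics", call. = FALSE)
  ref <- m[m$delta == 0L, ]
  if (!is.finite(ref$norm_max) || ref$norm_max < 50)
    stop("reference member fails QC (norm_max < 50%); series invalid",
         call. = FALSE)
  rationale <- data.frame(
    delta = m$delta,
    pass_norm_max = m$norm_max >= (1 - tol_response_pct / 100) * ref$norm_max,
    pass_dissoc = abs(m$retained_dissoc - ref$retained_dissoc) <= tol_retention_pts,
    pass_salt1 = abs(m$retained_salt1 - ref$retained_salt1) <= tol_retention_pts,
    pass_salt2 = abs(m$retained_salt2 - ref$retained_salt2) <= tol_retention_pts)
  rationale$pass <- rationale$pass_norm_max & rationale$pass_dissoc &
    rationale$pass_salt1 & rationale$pass_salt2
  passing_prefix <- cumprod(rationale$pass) > 0  # contiguous from delta 0
  chosen <- max(rationale$delta[passing_prefix])
  resolution <- if (nrow(m) > 1L) min(diff(m$delta)) else NA_integer_
  structure(list(side = side, chosen_delta = chosen, resolution = resolution,
                 rationale = rationale),
            class = "BoundaryCall")
}

#' @export
print.BoundaryCall <- function(x, ...) {
  cat(sprintf("BoundaryCall: %s boundary at delta %d (resolution %s nt)\n",
              x$side, x$chosen_delta, x$resolution))
  invisible(x)
}

#' Assemble a footprint from the two boundary calls
#'
#' @param start the starting `OligoDuplex` both truncation series came from.
#' @param rh,lh `BoundaryCall`s for the right- and left-hand boundaries.
#' @return the footprint `OligoDuplex`, with a `resolution` attribute (nt).
#' @export
assemble_footprint <- function(start, rh, lh) {
  stopifnot(inherits(rh, "BoundaryCall"), inherits(lh, "BoundaryCall"))
  if (rh$side != "RH" || lh$side != "LH")
    stop("rh/lh arguments have the wrong sides", call. = FALSE)
  fp <- apply_footprint(start, rh$chosen_delta, lh$chosen_delta)
  attr(fp, "resolution") <- max(rh$resolution, lh$resolution)
  fp
}
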