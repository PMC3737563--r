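# 1:1 Langmuir binding: kinetic cycle simulation and steady-state fitting.

#' Kinetic parameters for a 1:1 interaction
#'
#' @param ka association rate constant, 1/(M s).
#' @param kd dissociation rate constant, 1/s.
#' @param rmax saturating response, RU.
#' @return object of class `KineticParams`; `KD = kd / ka` (M).
#' @export
kinetic_params <- function(ka, kd, rmax) {
  if (ka <= 0 || kd < 0 || rmax <= 0)
    stop("require ka > 0, kd >= 0, rmax > 0", call. = FALSE)
  structure(list(ka = ka, kd = kd, rmax = rmax, KD = kd / ka),
            class = "KineticParams")
}

#' Injection schedule for one simulated cycle
#'
#' Defines the phase layout of a capture/bind/regenerate cycle: DNA capture,
#' stabilization wash, protein association (`t_on..t_off`), dissociation,
#' two salt washes and a strip back to baseline.
#'
#' @param concentration analyte concentration, M.
#' @param capture_ru DNA capture level, RU.
#' @param t_capture,t_wash,t_assoc,t_diss,t_salt,t_strip phase durations, s
#'   (both salt washes last `t_salt`).
#' @param salt_removal fractions of remaining protein removed instantaneously
#'   at the start of each salt wash (length 2).
#' @param dt sampling interval, s.
#' @return object of class `InjectionSchedule` with phase windows and
#'   derived `t_on`, `t_off`, `t_end`.
#' @export
injection_schedule <- function(concentration, capture_ru = 400,
                               t_capture = 60, t_wash = 30, t_assoc = 120,
                               t_diss = 150, t_salt = 30, t_strip = 30,
                               salt_removal = c(0.2, 0.2), dt = 1) {
  if (concentration < 0) stop("concentration must be >= 0", call. = FALSE)
  if (length(salt_removal) != 2L || any(salt_removal < 0 | salt_removal > 1))
    stop("salt_removal must be two fractions in [0, 1]", call. = FALSE)
  edges <- cumsum(c(0, t_capture, t_wash, t_assoc, t_diss, t_salt, t_salt,
                    t_strip))
  phases <- list(capture = edges[1:2], wash = edges[2:3],
                 association = edges[3:4], dissociation = edges[4:5],
                 salt_wash_1 = edges[5:6], salt_wash_2 = edges[6:7],
                 strip = edges[7:8])
  structure(list(concentration = concentration, capture_ru = capture_ru,
                 phases = phases, t_on = edges[3], t_off = edges[4],
                 t_end = edges[8], salt_removal = salt_removal, dt = dt),
            class = "InjectionSchedule")
}

#' Steady-state response of the 1:1 binding isotherm
#'
#' `R_eq = Rmax * C / (KD + C)`: half-saturation at `C = KD`.
#'
#' @param concentration analyte concentration(s), M.
#' @param kd_eq equilibrium dissociation constant KD, M (> 0).
#' @param rmax saturating response, RU.
#' @return equilibrium response(s), RU.
#' @export
steady_state_response <- function(concentration, kd_eq, rmax) {
  if (!is.finite(kd_eq) || kd_eq <= 0) stop("KD must be > 0", call. = FALSE)
  if (any(concentration < 0)) stop("concentrations must be >= 0", call. = FALSE)
  rmax * concentration / (kd_eq + concentration)
}

#' Simulate one reusable-capture cycle with 1:1 kinetics
#'
#' Closed-form 1:1 Langmuir kinetics on top of a DNA-capture plateau:
#' association `R(t) = Req (1 - exp(-(ka C + kd)(t - t_on)))` with
#' `Req = ka C Rmax / (ka C + kd)`; exponential dissociation with rate `kd`;
#' each salt wash instantaneously removes its declared fraction of the
#' remaining protein (the trace is held flat within wash windows); the strip
#' returns the surface to baseline. i.i.d. Gaussian noise is added to every
#' sample.
#'
#' @param params a [kinetic_params()].
#' @param sched an [injection_schedule()].
#' @param noise_sd Gaussian noise sd, RU (>= 0).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param cycle_id,flow_cell passed to the cycle object.
#' @return a `SensorgramCycle` for the test flow cell.
#' @export
simulate_cycle <- function(params, sched, noise_sd = 0, seed = NULL,
                           cycle_id = "sim", flow_cell = "FC_test") {
  stopifnot(inherits(params, "KineticParams"),
            inherits(sched, "InjectionSchedule"))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  ph <- sched$phases
  time <- seq(0, sched$t_end, by = sched$dt)
  C <- sched$concentration
  kobs <- params$ka * C + params$kd
  req <- if (kobs > 0) params$ka * C * params$rmax / kobs else 0
  cap <- sched$capture_ru
  tau_cap <- max(ph$capture[2] - ph$capture[1], 1) / 8  # fast capture ramp

  protein_at_toff <- req * (1 - exp(-kobs * (sched$t_off - sched$t_on)))
  protein_at_disse <- protein_at_toff *
    exp(-params$kd * (ph$dissociation[2] - ph$dissociation[1]))
  after_salt1 <- protein_at_disse * (1 - sched$salt_removal[1])
  after_salt2 <- after_salt1 * (1 - sched$salt_removal[2])

  r <- numeric(length(time))
  for (i in seq_along(time)) {
    t <- time[i]
    r[i] <- if (t <= ph$capture[2]) {
      cap * (1 - exp(-(t - ph$capture[1]) / tau_cap))
    } else if (t <= ph$wash[2]) {
      cap
    } else if (t <= ph$association[2]) {
      cap + req * (1 - exp(-kobs * (t - sched$t_on)))
    } else if (t <= ph$dissociation[2]) {
      cap + protein_at_toff * exp(-params$kd * (t - sched$t_off))
    } else if (t <= ph$salt_wash_1[2]) {
      cap + after_salt1
    } else if (t <= ph$salt_wash_2[2]) {
      cap + after_salt2
    } else {
      (cap + after_salt2) * exp(-(t - ph$strip[1]) / 2)  # strip to baseline
    }
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) r <- r + with_seed(seed, stats::rnorm(length(r), 0, noise_sd))
    else r <- r + stats::rnorm(length(r), 0, noise_sd)
  }
  sensorgram_cycle(cycle_id, flow_cell, time, r, ph)
}

#' Fit a steady-state 1:1 affinity model
#'
#' Unweighted nonlinear least squares of `R = Rmax * C / (KD + C)` on
#' (concentration, response) points; replicates are fitted pooled.
#' Initialization: `Rmax0 = max(R)`, `KD0` = the concentration whose response
#' is nearest half of `Rmax0`. Standard errors come from the Jacobian at the
#' optimum. A fit that fails to converge, or that pins `KD` at the parameter
#' bound, is flagged `converged = FALSE` with a diagnostic message.
#'
#' @param concentration analyte concentrations, M.
#' @param response responses, RU.
#' @return an object of class `AffinityFit`: `kd_eq`, `rmax`, `se_kd`,
#'   `se_rmax`, `residual_ss`, `n_points`, `converged`, `message`.
#' @export
fit_kd <- function(concentration, response) {
  if (length(concentration) != length(response))
    stop("concentration and response differ in length", call. = FALSE)
  ok <- is.finite(concentration) & is.finite(response)
  concentration <- concentration[ok]; response <- response[ok]
  n_conc <- length(unique(concentration))
  if (n_conc < 2L) stop("need at least 2 distinct concentrations", call. = FALSE)
  if (n_conc < 3L)
    warning("fewer than 3 distinct concentrations; fit poorly constrained",
            call. = FALSE)
  rmax0 <- max(response)
  if (rmax0 <= 0 || stats::sd(response) == 0) {
    return(structure(list(kd_eq = NA_real_, rmax = NA_real_, se_kd = NA_real_,
                          se_rmax = NA_real_, residual_ss = NA_real_,
                          n_points = length(response), converged = FALSE,
                          message = "degenerate data: responses carry no information"),
                     class = "AffinityFit"))
  }
  kd0 <- concentration[which.min(abs(response - rmax0 / 2))]
  if (kd0 <= 0) kd0 <- min(concentration[concentration > 0])
  lower_kd <- min(concentration[concentration > 0]) / 1e4
  df <- data.frame(C = concentration, R = response)
  fit <- tryCatch(
    stats::nls(R ~ rmax * C / (kd_eq + C), data = df,
               start = list(rmax = rmax0, kd_eq = kd0),
               algorithm = "port",
               lower = c(rmax = 0, kd_eq = lower_kd),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(kd_eq = NA_real_, rmax = NA_real_, se_kd = NA_real_,
                          se_rmax = NA_real_, residual_ss = NA_real_,
                          n_points = nrow(df), converged = FALSE,
                          message = paste("fit failed:", conditionMessage(fit))),
                     class = "AffinityFit"))
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(rmax = NA_real_, kd_eq = NA_real_))
  at_bound <- est["kd_eq"] <= lower_kd * (1 + 1e-6)
  structure(list(kd_eq = unname(est["kd_eq"]), rmax = unname(est["rmax"]),
                 se_kd = unname(se["kd_eq"]), se_rmax = unname(se["rmax"]),
                 residual_ss = sum(stats::resid(fit)^2), n_points = nrow(df),
                 converged = !at_bound,
                 message = if (at_bound) "KD estimate at parameter bound" else "ok"),
            class = "AffinityFit")
}

#' @export
print.AffinityFit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("AffinityFit: KD = %.3g M (se %.2g), Rmax = %.4g RU (se %.2g), n = %d\n",
                x$kd_eq, x$se_kd, x$rmax, x$se_rmax, x$n_points))
  } else {
    cat("AffinityFit: NOT converged -", x$message, "\n")
  }
  invisible(x)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's
#' RNG state. All seeded generators in the package use this, so fixtures
#' are reproducible without clobbering the session's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  expr
}
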