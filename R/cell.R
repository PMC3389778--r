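#' Full model right-hand side
#'
#' Evaluates the assembled ~75-state derivative at one point; mainly useful
#' for tests and diagnostics (the integrator calls the compiled entry point
#' directly).
#'
#' @param t time (ms).
#' @param y named or unnamed state vector over [gp_state_names()].
#' @param params a [gp_parameters()] object.
#' @param mode `"current_clamp"`, `"voltage_clamp"` or `"ap_clamp"`.
#' @param istim stimulus current (uA/uF, inward negative), current clamp only.
#' @param vslope imposed dV/dt for AP clamp.
#' @return named numeric vector of derivatives.
#' @export
gp_rhs <- function(t, y, params, mode = c("current_clamp", "voltage_clamp",
                                          "ap_clamp"),
                   istim = 0, vslope = 0) {
  mode <- match.arg(mode)
  m <- match(mode, c("current_clamp", "voltage_clamp", "ap_clamp")) - 1L
  y <- as_state(y)
  dy <- .cpp_rhs(t, unname(y), param_vector(params), m, istim, vslope)
  setNames(dy, .cpp_state_names())
}

as_state <- function(y) {
  nm <- .cpp_state_names()
  if (!is.null(names(y))) {
    missing <- setdiff(nm, names(y))
    if (length(missing)) {
      abort(paste0("state vector missing: ", paste(missing, collapse = ", ")))
    }
    y <- y[nm]
  } else if (length(y) != length(nm)) {
    abort(sprintf("state vector must have length %d", length(nm)))
  }
  as.numeric(y)
}

# ---- segment-level integration ---------------------------------------------
# A segment is a maximal interval over which the right-hand side is smooth:
#   list(duration, mode = 0/1/2, stim = c(amp, t0, dur, period, n),
#        table = NULL | list(t = , v = ))
# Times inside a segment are local (start at 0).
MAXTAB <- 4096

run_segment <- function(y, seg, pv, rtol, atol, sample_ms, keep = TRUE) {
  ntab <- if (is.null(seg$table)) 0L else length(seg$table$t)
  if (ntab > MAXTAB) {
    abort(sprintf("clamp table too long (%d > %d points per segment)",
                  ntab, MAXTAB))
  }
  ctx <- c(seg$mode,
           if (is.null(seg$stim)) c(0, 0, 0, 0, 0) else seg$stim,
           ntab)
  # fixed-size layout expected by the compiled initialiser
  tab <- numeric(2 * MAXTAB)
  if (ntab > 0) {
    tab[seq_len(ntab)] <- seg$table$t
    tab[MAXTAB + seq_len(ntab)] <- seg$table$v
  }
  parms <- c(pv, ctx, tab)
  if (seg$mode != 0 && !is.null(seg$table)) {
    # align the integrated V state with the clamp at segment entry
    y[1] <- seg$table$v[1]
  }
  times <- unique(c(seq(0, seg$duration, by = sample_ms), seg$duration))
  out <- deSolve::vode(
    y = unname(y), times = times, func = "gp_derivs", parms = parms,
    dllname = "gpmyocyte", initfunc = "gp_initmod",
    rtol = rtol, atol = atol, maxsteps = 100000
  )
  if (attr(out, "istate")[1] < 0) {
    abort(sprintf(
      "solver failure in segment (mode %d) at t ~ %.3f ms; last |V| = %.3f",
      seg$mode, out[nrow(out), 1], out[nrow(out), 2]))
  }
  list(times = out[, 1], states = out[, -1, drop = FALSE],
       final = out[nrow(out), -1])
}

#' Simulate a protocol
#'
#' Integrates the whole-cell model through a stimulation or clamp protocol
#' with a stiff multistep solver (relative tolerance `1e-7`, per-state-scaled
#' absolute tolerance `1e-9` by default) and returns the uniformly sampled
#' state trajectory together with the derived currents and fluxes.
#'
#' @param protocol a protocol object from one of the constructors
#'   ([pacing_protocol()], [voltage_step_protocol()], [ap_clamp_protocol()],
#'   ...), or anything [as_segments()] understands.
#' @param params a [gp_parameters()] object.
#' @param y0 initial state; defaults to the shipped 1 Hz end-diastolic state.
#' @param sample_ms output sampling interval (ms); 1 ms default.
#' @param rtol,atol_scale solver tolerances (`atol = atol_scale` times the
#'   per-state magnitude scale).
#' @param derived if `TRUE` (default), append derived outputs (currents,
#'   fluxes, subspace Ca2+, availability, force) to the returned tibble.
#' @return a tibble of class `gp_result`: `time` plus one column per state
#'   (and derived output), with the parameters and protocol stored in
#'   attributes.
#' @export
simulate_protocol <- function(protocol, params = gp_parameters(),
                              y0 = gp_initial_state(), sample_ms = 1,
                              rtol = 1e-7, atol_scale = 1e-9,
                              derived = TRUE) {
  segs <- as_segments(protocol, params)
  y <- as_state(y0)
  pv <- param_vector(params)
  atol <- pmax(atol_scale * unname(state_scales()), 1e-16)
  t_off <- 0
  all_t <- list(); all_y <- list()
  for (i in seq_along(segs)) {
    seg <- segs[[i]]
    if (seg$duration <= 0) next
    res <- run_segment(y, seg, pv, rtol, atol, sample_ms)
    idx <- if (i < length(segs)) seq_len(length(res$times) - 1) else
      seq_along(res$times)
    all_t[[i]] <- res$times[idx] + t_off
    all_y[[i]] <- res$states[idx, , drop = FALSE]
    t_off <- t_off + seg$duration
    y <- res$final
  }
  times <- do.call(c, all_t)
  states <- do.call(rbind, all_y)
  colnames(states) <- .cpp_state_names()
  out <- dplyr::bind_cols(tibble(time = times), as_tibble(states))
  if (derived) {
    dv <- .cpp_derived(states, pv)
    out <- dplyr::bind_cols(out, as_tibble(dv))
  }
  zsum <- rowSums(states[, caru_state_names(), drop = FALSE])
  if (any(abs(zsum - 1) > 1e-6)) {
    warn(sprintf("release-unit occupancy drifted (max |sum - 1| = %.2e)",
                 max(abs(zsum - 1))))
  }
  structure(out,
            class = c("gp_result", class(out)),
            params = params, protocol = protocol,
            final_state = setNames(as.numeric(y), .cpp_state_names()))
}

#' @export
print.gp_result <- function(x, ...) {
  cat(sprintf("<gp_result: %d samples over %.1f ms, %d columns>\n",
              nrow(x), max(x$time) - min(x$time), ncol(x)))
  NextMethod()
}

#' Final state of a simulation
#' @param result a `gp_result`.
#' @return named state vector at the last sample.
#' @export
final_state <- function(result) {
  attr(result, "final_state")
}

#' Pace to steady state
#'
#' Applies periodic stimuli at a fixed basic cycle length until the
#' end-diastolic state stops changing: the convergence criterion is
#' `max |delta y| / scale < tol` between consecutive beats (per-state
#' magnitude scales), with a cap on the number of beats.
#'
#' @param params a [gp_parameters()] object.
#' @param bcl basic cycle length (ms).
#' @param y0 starting state.
#' @param tol convergence tolerance (default `1e-4`).
#' @param max_beats cap on the number of beats (default 1000).
#' @param min_beats minimum number of beats before convergence may be
#'   declared.
#' @param stim_amp,stim_dur stimulus current (uA/uF) and duration (ms).
#' @param rtol,atol_scale solver tolerances as in [simulate_protocol()].
#' @return list of class `gp_steady` with elements `state` (end-diastolic
#'   state), `beats`, `converged`, `residual` and `residuals` (per-beat
#'   trajectory of the criterion).
#' @export
pace_to_steady_state <- function(params = gp_parameters(), bcl = 1000,
                                 y0 = gp_initial_state(), tol = 1e-4,
                                 max_beats = 1000, min_beats = 2,
                                 stim_amp = -80, stim_dur = 0.5,
                                 rtol = 1e-7, atol_scale = 1e-9) {
  if (bcl <= 0) abort("bcl must be positive")
  pv <- param_vector(params)
  scales <- unname(state_scales())
  atol <- pmax(atol_scale * scales, 1e-16)
  y <- as_state(y0)
  segs <- list(
    list(duration = stim_dur, mode = 0,
         stim = c(stim_amp, 0, stim_dur, 0, 1)),
    list(duration = bcl - stim_dur, mode = 0, stim = NULL)
  )
  residuals <- numeric(0)
  converged <- FALSE
  for (beat in seq_len(max_beats)) {
    y_prev <- y
    for (seg in segs) {
      res <- run_segment(y, seg, pv, rtol, atol, sample_ms = seg$duration)
      y <- res$final
    }
    resid <- max(abs(y - y_prev) / scales)
    residuals <- c(residuals, resid)
    if (beat >= min_beats && resid < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf(
      "pacing did not converge in %d beats (residual %.3g, tol %.3g)",
      max_beats, residuals[length(residuals)], tol))
  }
  structure(list(state = setNames(as.numeric(y), .cpp_state_names()),
                 beats = length(residuals), converged = converged,
                 residual = residuals[length(residuals)],
                 residuals = residuals, bcl = bcl),
            class = "gp_steady")
}

#' @export
print.gp_steady <- function(x, ...) {
  cat(sprintf("<gp_steady: BCL %g ms, %d beats, %s (residual %.3g)>\n",
              x$bcl, x$beats,
              if (x$converged) "converged" else "NOT converged", x$residual))
  invisible(x)
}

#' Derived currents and fluxes at a state
#'
#' Evaluates all membrane currents, Ca2+ fluxes, subspace concentrations and
#' force outputs at one (or more) state vector(s) without integrating.
#'
#' @param y a named state vector, or a matrix with one state per row.
#' @param params a [gp_parameters()] object.
#' @return a tibble with one row per state.
#' @export
gp_currents <- function(y, params = gp_parameters()) {
  if (is.null(dim(y))) y <- matrix(as_state(y), nrow = 1)
  as_tibble(.cpp_derived(y, param_vector(params)))
}
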