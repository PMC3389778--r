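#' Run a voltage-step family
#'
#' Runs each test potential of a step family from the holding potential and
#' records, per step, the peak (most negative) L-type current and the peak
#' ensemble LCC and RyR fluxes.  Cytosolic and SR Ca2+ follow their own
#' dynamics during the pulses.
#'
#' @param family a [voltage_step_family()] protocol.
#' @param params a [gp_parameters()] object.
#' @param y0 initial state (end-diastolic state recommended).
#' @param sample_ms sampling interval within the pulse.
#' @param keep_traces if `TRUE`, attach the per-step `gp_result`s.
#' @return tibble with one row per test potential: `test`, `i_cal_peak`,
#'   `j_lcc_peak`, `j_ryr_peak`, `t_peak_ical`.
#' @export
run_voltage_step_family <- function(family, params = gp_parameters(),
                                    y0 = gp_initial_state(),
                                    sample_ms = 0.5, keep_traces = FALSE) {
  stopifnot(family$variant == "voltage_step_family")
  traces <- list()
  rows <- lapply(family$tests, function(vt) {
    pr <- voltage_step_protocol(holding = family$holding, test = vt,
                                duration = family$duration,
                                hold_ms = family$hold_ms,
                                post_ms = family$post_ms)
    res <- simulate_protocol(pr, params, y0 = y0, sample_ms = sample_ms)
    pulse <- dplyr::filter(res, .data$time >= family$hold_ms)
    if (keep_traces) traces[[as.character(vt)]] <<- pulse
    tibble(
      test = vt,
      i_cal_peak = min(pulse$i_cal),
      t_peak_ical = pulse$time[which.min(pulse$i_cal)] - family$hold_ms,
      j_lcc_peak = max(pulse$j_lcc),
      j_ryr_peak = max(pulse$j_ryr)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (keep_traces) attr(out, "traces") <- traces
  out
}

#' S1-S2 APD restitution
#'
#' Paces to steady state at the S1 cycle length, saves the state at the end
#' of the action potential (APD90 crossing of the final S1 beat), then for
#' each diastolic interval restarts from that state, waits DI, applies a
#' single premature stimulus and measures the resulting APD90.  DIs shorter
#' than the refractory period are recorded as no-capture (`NA`), not errors.
#'
#' @param protocol an [s1s2_protocol()].
#' @param params a [gp_parameters()] object.
#' @param y0 starting state for the S1 pacing.
#' @param steady an optional pre-computed `gp_steady` at the S1 cycle length
#'   (skips the pacing stage).
#' @param apd_fraction repolarisation fraction defining APD (default 0.9).
#' @param max_beats pacing cap for the S1 stage.
#' @return tibble with `di`, `apd`, `ca_peak`; S1 reference values in
#'   attributes `apd_s1` and `ca_peak_s1`.
#' @export
run_s1s2_restitution <- function(protocol, params = gp_parameters(),
                                 y0 = gp_initial_state(), steady = NULL,
                                 apd_fraction = 0.9, max_beats = 300) {
  stopifnot(protocol$variant == "s1s2")
  bcl <- protocol$s1_bcl
  if (is.null(steady)) {
    steady <- pace_to_steady_state(params, bcl = bcl, y0 = y0,
                                   max_beats = max_beats)
  }
  # one more S1 beat, sampled finely, to locate the end of the AP
  beat <- simulate_protocol(pacing_protocol(bcl = bcl, n_beats = 1),
                            params, y0 = steady$state, sample_ms = 1)
  apd_s1 <- apd(beat$time, beat$V, fraction = apd_fraction)
  ca_s1 <- max(beat$cai)
  if (is.na(apd_s1)) abort("no S1 action potential detected")
  t_end <- apd_end_time(beat$time, beat$V, fraction = apd_fraction)
  state_end <- state_at(beat, t_end)

  rows <- lapply(protocol$di_list, function(di) {
    pre <- if (di > 0) {
      simulate_protocol(list_segments(list(list(duration = di, mode = 0,
                                                stim = NULL))),
                        params, y0 = state_end, sample_ms = min(di, 5),
                        derived = FALSE)
    } else NULL
    ystart <- if (is.null(pre)) state_end else final_state(pre)
    s2 <- simulate_protocol(pacing_protocol(bcl = max(bcl, 2 * apd_s1 + di),
                                            n_beats = 1),
                            params, y0 = ystart, sample_ms = 1)
    tibble(di = di,
           apd = apd(s2$time, s2$V, fraction = apd_fraction),
           ca_peak = max(s2$cai))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "apd_s1") <- apd_s1
  attr(out, "ca_peak_s1") <- ca_s1
  out
}

# wrap a raw segment list so simulate_protocol() accepts it
list_segments <- function(segs) structure(segs, class = "gp_segments")

# state at (nearest sample of) time t
state_at <- function(result, t) {
  i <- which.min(abs(result$time - t))
  nm <- .cpp_state_names()
  setNames(as.numeric(result[i, nm]), nm)
}

#' Frequency staircase (stepwise increase in pacing rate)
#'
#' Paces to steady state at the first cycle length, then spends a fixed
#' simulated time at each subsequent cycle length; APD90, peak cytosolic
#' Ca2+, peak and accumulated force and mean Na+ are recorded from the last
#' beat of each step.
#'
#' @param protocol a [frequency_staircase()].
#' @param params,y0 as elsewhere.
#' @param max_beats pacing cap for the initial steady state.
#' @return tibble with one row per cycle length: `bcl`, `apd`, `ca_peak`,
#'   `force_peak`, `force_accum` (time-integral of normalized force over the
#'   last beat / beat duration), `nai_mean`, `nadh_mean`.
#' @export
run_frequency_staircase <- function(protocol, params = gp_parameters(),
                                    y0 = gp_initial_state(),
                                    max_beats = 400) {
  stopifnot(protocol$variant == "staircase")
  bcls <- protocol$bcls
  steady <- pace_to_steady_state(params, bcl = bcls[1], y0 = y0,
                                 max_beats = max_beats)
  y <- steady$state
  rows <- list()
  for (bcl in bcls) {
    n <- max(1, round(protocol$step_s * 1000 / bcl))
    if (n > 1) {
      # burn-in beats at coarse sampling
      burn <- simulate_protocol(pacing_protocol(bcl = bcl, n_beats = n - 1),
                                params, y0 = y, sample_ms = bcl / 2,
                                derived = FALSE)
      y <- final_state(burn)
    }
    last <- simulate_protocol(pacing_protocol(bcl = bcl, n_beats = 1),
                              params, y0 = y, sample_ms = 1)
    y <- final_state(last)
    rows[[as.character(bcl)]] <- tibble(
      bcl = bcl,
      apd = apd(last$time, last$V),
      ca_peak = max(last$cai),
      force_peak = max(last$stress),
      force_accum = mean(last$stress),
      nai_mean = mean(last$nai),
      nadh_mean = mean(last$nadh)
    )
  }
  dplyr::bind_rows(rows)
}

#' Workload-transition run
#'
#' Three-phase pacing (baseline, high workload, recovery) from
#' baseline-frequency steady-state initial conditions, sampled coarsely for
#' the slow energetic variables.
#'
#' @param protocol a [workload_transition()].
#' @param params,y0 as elsewhere.
#' @param sample_ms output sampling (default 10 ms).
#' @param max_beats cap for the baseline steady state.
#' @return a `gp_result` spanning the full protocol.
#' @export
run_workload_transition <- function(protocol, params = gp_parameters(),
                                    y0 = gp_initial_state(), sample_ms = 10,
                                    max_beats = 300) {
  stopifnot(protocol$variant == "workload")
  base_bcl <- 1000 / protocol$base_freq
  high_bcl <- 1000 / protocol$high_freq
  steady <- pace_to_steady_state(params, bcl = base_bcl, y0 = y0,
                                 max_beats = max_beats)
  phases <- list(
    c(base_bcl, protocol$phase_s[1]),
    c(high_bcl, protocol$phase_s[2]),
    c(base_bcl, protocol$phase_s[3])
  )
  segs <- list()
  for (ph in phases) {
    n <- max(1, round(ph[2] * 1000 / ph[1]))
    for (b in seq_len(n)) {
      segs <- c(segs, list(
        list(duration = 0.5, mode = 0, stim = c(-80, 0, 0.5, 0, 1)),
        list(duration = ph[1] - 0.5, mode = 0, stim = NULL)
      ))
    }
  }
  simulate_protocol(list_segments(segs), params, y0 = steady$state,
                    sample_ms = sample_ms)
}
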