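#' Protocol constructors
#'
#' Protocols are declarative descriptions of stimulation and clamp
#' experiments; [simulate_protocol()] compiles them to integrable segments.
#' All protocols serialise losslessly to YAML via [protocol_to_yaml()].
#'
#' @name protocols
NULL

new_protocol <- function(variant, ...) {
  structure(list(variant = variant, ...), class = "gp_protocol")
}

#' @describeIn protocols periodic current-clamp pacing.
#' @param bcl basic cycle length (ms).
#' @param n_beats number of stimuli.
#' @param stim_amp stimulus amplitude (uA/uF, inward negative).
#' @param stim_dur stimulus duration (ms).
#' @param tail_ms extra unstimulated time appended after the last beat.
#' @export
pacing_protocol <- function(bcl = 1000, n_beats = 10, stim_amp = -80,
                            stim_dur = 0.5, tail_ms = 0) {
  if (bcl <= stim_dur) abort("bcl must exceed the stimulus duration")
  if (n_beats < 1) abort("need at least one beat")
  new_protocol("pacing", bcl = bcl, n_beats = n_beats, stim_amp = stim_amp,
               stim_dur = stim_dur, tail_ms = tail_ms)
}

#' @describeIn protocols a single voltage step from a holding potential.
#' @param holding holding potential (mV).
#' @param test test potential (mV).
#' @param duration test-pulse duration (ms).
#' @param hold_ms time at the holding potential before the step.
#' @param post_ms time back at holding after the step.
#' @export
voltage_step_protocol <- function(holding = -40, test = 0, duration = 400,
                                  hold_ms = 400, post_ms = 0) {
  check_voltage_range(c(holding, test))
  new_protocol("voltage_step", holding = holding, test = test,
               duration = duration, hold_ms = hold_ms, post_ms = post_ms)
}

#' @describeIn protocols family of voltage steps (I-V / availability
#'   protocols).
#' @param tests vector of test potentials (mV).
#' @export
voltage_step_family <- function(holding = -40, tests = seq(-40, 60, by = 5),
                                duration = 400, hold_ms = 400, post_ms = 0) {
  if (!length(tests)) abort("test-potential list must not be empty")
  check_voltage_range(c(holding, tests))
  new_protocol("voltage_step_family", holding = holding, tests = tests,
               duration = duration, hold_ms = hold_ms, post_ms = post_ms)
}

check_voltage_range <- function(v) {
  if (any(v < -100 | v > 80)) {
    abort("voltage steps must lie within [-100, 80] mV")
  }
  invisible(v)
}

#' @describeIn protocols action-potential clamp from a two-column waveform.
#' @param waveform data frame with columns `time_ms`, `voltage_mV` (or a file
#'   path understood by [read_ap_waveform()]).
#' @param n_repeats how many times to replay the waveform.
#' @param period_ms replay period; defaults to the waveform span.
#' @export
ap_clamp_protocol <- function(waveform, n_repeats = 1, period_ms = NULL) {
  if (is.character(waveform)) waveform <- read_ap_waveform(waveform)
  if (!all(c("time_ms", "voltage_mV") %in% names(waveform))) {
    abort("waveform needs columns time_ms and voltage_mV")
  }
  if (any(diff(waveform$time_ms) <= 0)) {
    abort("waveform time column must be strictly increasing")
  }
  new_protocol("ap_clamp", waveform = as_tibble(waveform),
               n_repeats = n_repeats,
               period_ms = period_ms %||% max(waveform$time_ms))
}

#' Read an AP-clamp waveform file
#'
#' Two-column CSV with header `time_ms,voltage_mV`; time must be strictly
#' increasing.  Format errors report the offending line.
#'
#' @param path file path.
#' @return tibble with `time_ms`, `voltage_mV`.
#' @export
read_ap_waveform <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_ms", "voltage_mV") %in% names(df))) {
    abort("waveform file must have header 'time_ms,voltage_mV'")
  }
  bad <- which(diff(df$time_ms) <= 0)
  if (length(bad)) {
    abort(sprintf("waveform time is not strictly increasing at line %d",
                  bad[1] + 2L))
  }
  as_tibble(df[c("time_ms", "voltage_mV")])
}

#' @describeIn protocols S1-S2 restitution: pace to steady state at the S1
#'   cycle length, save the end-of-AP state, then probe single premature
#'   stimuli at the listed diastolic intervals.
#' @param s1_bcl S1 cycle length (ms).
#' @param di_list increasing positive diastolic intervals (ms).
#' @export
s1s2_protocol <- function(s1_bcl = 2000,
                          di_list = c(25, 50, 75, 100, 150, 200, 300, 400,
                                      600, 1000, 1500, 2000, 3000, 5000)) {
  if (any(di_list <= 0) || any(diff(di_list) <= 0)) {
    abort("diastolic intervals must be positive and increasing")
  }
  new_protocol("s1s2", s1_bcl = s1_bcl, di_list = di_list)
}

#' @describeIn protocols stepwise frequency staircase: steady state at the
#'   first cycle length, then a fixed simulated time at each subsequent one,
#'   recording at the end of every step.
#' @param bcls cycle lengths (ms), decreasing.
#' @param step_s simulated seconds spent at each cycle length.
#' @export
frequency_staircase <- function(bcls = c(3000, 2000, 1500, 1000, 700, 500, 300),
                                step_s = 180) {
  new_protocol("staircase", bcls = bcls, step_s = step_s)
}

#' @describeIn protocols workload transition: low-frequency pacing, a
#'   high-workload period, then recovery at the low frequency.
#' @param high_freq high-workload pacing frequency (Hz).
#' @param base_freq baseline frequency (Hz).
#' @param phase_s durations (s) of the baseline, high-workload and recovery
#'   phases.
#' @export
workload_transition <- function(high_freq = 2, base_freq = 0.25,
                                phase_s = c(100, 200, 200)) {
  if (high_freq <= 0) abort("high_freq must be positive")
  new_protocol("workload", high_freq = high_freq, base_freq = base_freq,
               phase_s = phase_s)
}

#' @export
print.gp_protocol <- function(x, ...) {
  cat("<gp_protocol:", x$variant, ">\n")
  invisible(x)
}

# ---- compilation to segments ------------------------------------------------

#' Compile a protocol to integrable segments
#'
#' Internal representation used by [simulate_protocol()]; exported for
#' diagnostics.  Each segment is smooth for the integrator (stimulus edges
#' and clamp steps always fall on segment boundaries).
#'
#' @param protocol a `gp_protocol`.
#' @param params parameters (unused by most variants).
#' @return list of segment lists.
#' @export
as_segments <- function(protocol, params = NULL) {
  if (inherits(protocol, "gp_segments")) return(protocol)
  if (!inherits(protocol, "gp_protocol")) {
    abort("not a protocol object")
  }
  segs <- switch(protocol$variant,
    pacing = {
      out <- list()
      for (b in seq_len(protocol$n_beats)) {
        out <- c(out, list(
          list(duration = protocol$stim_dur, mode = 0,
               stim = c(protocol$stim_amp, 0, protocol$stim_dur, 0, 1)),
          list(duration = protocol$bcl - protocol$stim_dur, mode = 0,
               stim = NULL)
        ))
      }
      if (protocol$tail_ms > 0) {
        out <- c(out, list(list(duration = protocol$tail_ms, mode = 0,
                                stim = NULL)))
      }
      out
    },
    voltage_step = {
      list(
        list(duration = protocol$hold_ms, mode = 1,
             table = list(t = 0, v = protocol$holding)),
        list(duration = protocol$duration, mode = 1,
             table = list(t = 0, v = protocol$test)),
        if (protocol$post_ms > 0)
          list(duration = protocol$post_ms, mode = 1,
               table = list(t = 0, v = protocol$holding))
      )
    },
    ap_clamp = {
      wf <- protocol$waveform
      t0 <- wf$time_ms - wf$time_ms[1]
      out <- list()
      for (r in seq_len(protocol$n_repeats)) {
        out <- c(out, list(
          list(duration = max(t0), mode = 2, table = list(t = t0,
                                                          v = wf$voltage_mV))))
        gap <- protocol$period_ms - max(t0)
        if (gap > 0) {
          out <- c(out, list(list(
            duration = gap, mode = 1,
            table = list(t = 0, v = wf$voltage_mV[length(t0)]))))
        }
      }
      out
    },
    abort(paste0("protocol variant '", protocol$variant,
                 "' is run by its dedicated runner, not simulate_protocol()"))
  )
  segs[!vapply(segs, is.null, logical(1))]
}

# ---- serialisation ----------------------------------------------------------

#' Serialise / deserialise protocols
#'
#' Round-trips any protocol through YAML without loss.
#'
#' @param protocol a `gp_protocol`.
#' @param text YAML text produced by `protocol_to_yaml()`.
#' @export
protocol_to_yaml <- function(protocol) {
  x <- unclass(protocol)
  if (!is.null(x$waveform)) x$waveform <- as.list(x$waveform)
  yaml::as.yaml(x)
}

#' @rdname protocol_to_yaml
#' @export
protocol_from_yaml <- function(text) {
  x <- yaml::yaml.load(text)
  if (!is.null(x$waveform)) x$waveform <- as_tibble(x$waveform)
  for (nm in names(x)) {
    if (is.list(x[[nm]]) && nm != "waveform") x[[nm]] <- unlist(x[[nm]])
  }
  structure(x, class = "gp_protocol")
}

# ---- synthetic clamp waveforms ----------------------------------------------

#' Synthetic AP-clamp waveforms
#'
#' Generates idealised action-potential waveforms for clamp experiments and
#' tests: a guinea-pig-like slow plateau (no phase-1 notch) or a canine-like
#' spike-notch-dome morphology.
#'
#' @param type waveform family.
#' @param apd90 approximate APD90 of the waveform (ms).
#' @param v_rest,v_peak resting and peak potentials (mV).
#' @param dt sample interval (ms).
#' @param span total duration (ms).
#' @return tibble with `time_ms`, `voltage_mV`.
#' @export
synthetic_ap_waveform <- function(type = c("guinea_pig", "canine"),
                                  apd90 = 190, v_rest = -86, v_peak = 48,
                                  dt = 1, span = apd90 + 300) {
  type <- match.arg(type)
  t <- seq(0, span, by = dt)
  upstroke <- 1 / (1 + exp(-(t - 2) / 0.4))
  if (type == "guinea_pig") {
    # slow mono-exponential plateau decay, then sigmoidal repolarisation
    plateau <- 0.92 * exp(-t / (apd90 * 1.9))
    repol <- 1 / (1 + exp((t - apd90 * 0.97) / (apd90 * 0.045)))
    shape <- upstroke * (0.08 + plateau) * repol
  } else {
    notch <- 1 - 0.45 * exp(-((t - 8) / 6)^2)
    dome <- 0.75 * exp(-t / (apd90 * 2.4)) + 0.1
    repol <- 1 / (1 + exp((t - apd90 * 0.95) / (apd90 * 0.05)))
    shape <- upstroke * pmin(1, notch * dome / 0.85) * repol
  }
  v <- v_rest + (v_peak - v_rest) * pmax(0, pmin(1, shape))
  tibble(time_ms = t, voltage_mV = v)
}
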