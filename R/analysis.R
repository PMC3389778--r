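#' Action potential duration
#'
#' APD at a repolarisation fraction, measured from the time of maximum
#' upstroke velocity (default) or from the start of the trace
#' (stimulus-onset reference).  The repolarisation level is
#' `V_peak - fraction * (V_peak - V_rest)` with the resting potential taken
#' just before the upstroke; the crossing is located by linear
#' interpolation.  Returns `NA` ("no capture") if no action potential is
#' detected.
#'
#' @param time,v time (ms) and membrane potential (mV) of a trace containing
#'   one action potential.
#' @param fraction repolarisation fraction (0.9 for APD90).
#' @param ref `"upstroke"` or `"stimulus"` time reference.
#' @return duration in ms, or `NA` for no capture.
#' @export
apd <- function(time, v, fraction = 0.9, ref = c("upstroke", "stimulus")) {
  ref <- match.arg(ref)
  stopifnot(length(time) == length(v), fraction > 0, fraction <= 1)
  dv <- diff(v) / diff(time)
  i_up <- which.max(dv)
  i_peak <- which.max(v)
  v_peak <- v[i_peak]
  v_rest <- v[max(1, i_up - 1)]
  if (v_peak - v_rest < 10 || v_peak < -40) return(NA_real_)  # no capture
  t0 <- if (ref == "upstroke") time[i_up] else time[1]
  v_target <- v_peak - fraction * (v_peak - v_rest)
  after <- seq(i_peak, length(v))
  below <- after[which(v[after] <= v_target)]
  if (!length(below)) return(NA_real_)
  i2 <- below[1]
  if (i2 == i_peak) return(time[i2] - t0)
  i1 <- i2 - 1
  t_cross <- time[i1] + (v_target - v[i1]) * (time[i2] - time[i1]) /
    (v[i2] - v[i1])
  t_cross - t0
}

# absolute time at which the AP reaches the repolarisation fraction
apd_end_time <- function(time, v, fraction = 0.9) {
  a <- apd(time, v, fraction = fraction, ref = "upstroke")
  if (is.na(a)) return(NA_real_)
  dv <- diff(v) / diff(time)
  time[which.max(dv)] + a
}

#' Transient metrics
#'
#' Peak, time to peak from the start of the trace, delay relative to the
#' membrane-potential peak, time of decay to half amplitude, and diastolic
#' value, for any transient column of a simulated beat.
#'
#' @param time sample times (ms).
#' @param x transient (e.g. cytosolic Ca2+ or stress).
#' @param v optional membrane potential for the delay-from-V-peak metric.
#' @return one-row tibble.
#' @export
transient_metrics <- function(time, x, v = NULL) {
  i_peak <- which.max(x)
  peak <- x[i_peak]
  diastolic <- min(x[seq_len(max(1, i_peak))])
  half <- diastolic + 0.5 * (peak - diastolic)
  after <- seq(i_peak, length(x))
  below <- after[which(x[after] <= half)]
  t_half <- if (length(below)) time[below[1]] - time[i_peak] else NA_real_
  delay <- if (!is.null(v)) time[i_peak] - time[which.max(v)] else NA_real_
  tibble(peak = peak, t_peak = time[i_peak] - time[1],
         delay_from_v_peak = delay, t_half_decay = t_half,
         diastolic = diastolic)
}

#' Excitation-contraction coupling gain curve
#'
#' Runs a voltage-clamp family and reports, per test potential, the peak
#' ensemble LCC trigger flux, the peak RyR release flux and their ratio (the
#' ECC gain).  In this local-control formulation the release-flux peak sits
#' at more negative potentials than the trigger-flux peak and the gain falls
#' monotonically with depolarisation.
#'
#' @param params a [gp_parameters()] object.
#' @param tests test potentials (mV).
#' @param y0 initial state.
#' @param ... passed to [run_voltage_step_family()].
#' @return tibble of class `gp_gain_curve` with `test`, `j_lcc_peak`,
#'   `j_ryr_peak`, `gain`.
#' @export
ecc_gain_curve <- function(params = gp_parameters(),
                           tests = seq(-40, 60, by = 5),
                           y0 = gp_initial_state(), ...) {
  fam <- voltage_step_family(tests = tests)
  res <- run_voltage_step_family(fam, params, y0 = y0, ...)
  out <- dplyr::mutate(res, gain = .data$j_ryr_peak /
                         pmax(.data$j_lcc_peak, .Machine$double.eps))
  class(out) <- c("gp_gain_curve", class(out))
  out
}

#' Integrated Ca2+ removal flux fractions
#'
#' Trapezoid-integrates the cytosolic Ca2+ removal pathways on the 1-ms
#' output grid over a window of a steady-state beat (default: from the
#' cytosolic Ca2+ transient peak to end-diastole, i.e. the end of the trace)
#' and reports each pathway's share of the total removed, plus the
#' mitochondrial return bolus relative to the net removal.
#'
#' @param result a `gp_result` covering one steady-state cycle starting at
#'   the stimulus.
#' @param window `"relaxation"` (Ca peak to end-diastole) or `"cycle"` (full
#'   beat).
#' @return one-row tibble: `serca`, `ncx`, `sl_pump` (fractions of removal),
#'   `mito_return` (bolus / net removal), plus the raw integrals.
#' @export
integrated_flux_fractions <- function(result,
                                      window = c("relaxation", "cycle")) {
  window <- match.arg(window)
  i0 <- if (window == "relaxation") which.max(result$cai) else 1L
  idx <- seq(i0, nrow(result))
  tt <- result$time[idx]
  serca <- trapz(tt, result$j_up[idx])
  ncx <- trapz(tt, -result$j_ncx_ca[idx])       # removal positive
  slp <- trapz(tt, -result$j_pca_ca[idx])
  mito_net <- trapz(tt, result$j_mncx[idx] - result$j_uni[idx]) # return > 0
  total <- serca + ncx + slp
  tibble(serca = serca / total, ncx = ncx / total, sl_pump = slp / total,
         mito_return = mito_net / total,
         int_serca = serca, int_ncx = ncx, int_sl_pump = slp,
         int_mito_return = mito_net)
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' Fractional SR Ca2+ release
#'
#' One minus the ratio of total systolic to total diastolic SR Ca2+, where
#' total SR Ca2+ is free plus calsequestrin-bound NSR Ca2+ (the `ca_sr_total`
#' derived output).  Diastolic content is taken at the start of the beat
#' (end-diastole), systolic content at its minimum.
#'
#' @param result a `gp_result` for one steady-state beat.
#' @return fraction in [0, 1].
#' @export
fractional_release <- function(result) {
  dia <- result$ca_sr_total[1]
  sys <- min(result$ca_sr_total)
  max(0, 1 - sys / dia)
}

#' Recirculation fraction
#'
#' Share of the Ca2+ contributing to the steady-state transient that is
#' derived from (and returned to) the SR stores, the complement being
#' transsarcolemmal.  At steady state the Ca2+ resequestered into the SR
#' equals the Ca2+ released, and the Ca2+ extruded across the sarcolemma
#' equals the Ca2+ that entered, so the ratio of integrated SERCA
#' resequestration to resequestration-plus-export (Na+/Ca2+ exchange) over
#' the relaxation phase approximates the SR-derived share of cycled Ca2+.
#'
#' @param result a `gp_result` for one steady-state beat.
#' @return fraction in [0, 1].
#' @export
recirculation_fraction <- function(result) {
  f <- integrated_flux_fractions(result, window = "relaxation")
  f$int_serca / (f$int_serca + f$int_ncx)
}

#' Single-exponential restitution fit
#'
#' Least-squares fit of `apd = offset - amplitude * exp(-di / tau)` to an
#' APD-restitution data set.  Uses `nls` with a Levenberg-Marquardt fallback;
#' the fit is deterministic for fixed data.
#'
#' @param di diastolic intervals (ms).
#' @param apd measured APD90 values (ms); `NA` (no capture) rows are
#'   dropped.
#' @return object of class `gp_expfit` with `tidy()` and `glance()` methods.
#' @export
fit_single_exponential <- function(di, apd) {
  keep <- is.finite(di) & is.finite(apd)
  di <- di[keep]; apd <- apd[keep]
  if (length(di) < 4) abort("need at least 4 points for the exponential fit")
  offset0 <- max(apd)
  amp0 <- max(offset0 - min(apd), 1)
  tau0 <- diff(range(di)) / 3
  df <- data.frame(di = di, apd = apd)
  fit <- tryCatch(
    nls(apd ~ offset - amplitude * exp(-di / tau), data = df,
        start = list(offset = offset0, amplitude = amp0, tau = tau0),
        control = list(maxiter = 200, warnOnly = FALSE)),
    error = function(e) {
      if (requireNamespace("minpack.lm", quietly = TRUE)) {
        minpack.lm::nlsLM(apd ~ offset - amplitude * exp(-di / tau), data = df,
                          start = list(offset = offset0, amplitude = amp0,
                                       tau = tau0),
                          control = minpack.lm::nls.lm.control(maxiter = 500))
      } else {
        stop(e)
      }
    }
  )
  structure(list(fit = fit, data = df), class = "gp_expfit")
}

#' @export
print.gp_expfit <- function(x, ...) {
  cf <- coef(x$fit)
  cat(sprintf(
    "<single-exponential restitution fit: tau = %.1f ms, offset = %.1f ms, amplitude = %.1f ms>\n",
    cf[["tau"]], cf[["offset"]], cf[["amplitude"]]))
  invisible(x)
}

#' Broom-style tidiers for restitution fits
#'
#' @param x a `gp_expfit`.
#' @param ... unused.
#' @return `tidy()` gives one row per coefficient (`term`, `estimate`,
#'   `std.error`); `glance()` gives one-row fit summaries.
#' @export
tidy.gp_expfit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2])
}

#' @rdname tidy.gp_expfit
#' @export
glance.gp_expfit <- function(x, ...) {
  r <- stats::resid(x$fit)
  tibble(tau = coef(x$fit)[["tau"]],
         sigma = sqrt(mean(r^2)),
         n = nrow(x$data),
         converged = TRUE)
}

#' Tidying generics
#'
#' Minimal `tidy()`/`glance()` generics (broom-compatible) for the fitted
#' objects this package produces.
#'
#' @param x an object.
#' @param ... passed to methods.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Peak open-open subspace Ca2+ during release
#'
#' Maximum of the algebraic open-LCC/open-RyR subspace Ca2+ over the samples
#' of a beat at which that configuration is substantially occupied (within
#' `occ_frac` of its per-beat occupancy maximum).  Conditioning on occupancy
#' restricts the metric to actual release events: outside them the
#' configuration is (essentially) never realised, while its hypothetical
#' subspace level diverges at diastolic potentials where the single-channel
#' driving force is maximal.
#'
#' @param result a `gp_result` for one beat with derived outputs.
#' @param occ_frac occupancy threshold relative to the per-beat maximum.
#' @return subspace Ca2+ in mM.
#' @export
subspace_oo_peak <- function(result, occ_frac = 0.5) {
  thr <- occ_frac * max(result$p_oo)
  max(result$ca_ss_oo[result$p_oo >= thr])
}
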