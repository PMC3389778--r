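p <- ref_params()

test_that("the resting cell is electrically quiet after a long quiescent
           interval", {
  y <- gp_initial_state("paced_1hz")
  res <- simulate_protocol(
    structure(list(list(duration = 10000, mode = 0, stim = NULL)),
              class = "gp_segments"),
    p, y0 = y, sample_ms = 100, derived = FALSE)
  dy <- gp_rhs(0, final_state(res), p)
  expect_lt(abs(dy["V"]), 0.01)
})

test_that("simulations are deterministic for identical inputs", {
  y <- gp_initial_state("paced_1hz")
  r1 <- simulate_protocol(pacing_protocol(bcl = 500, n_beats = 2), p, y0 = y)
  r2 <- simulate_protocol(pacing_protocol(bcl = 500, n_beats = 2), p, y0 = y)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
})

test_that("ten 1 Hz action potentials integrate cleanly with occupancies
           normalised", {
  y <- gp_initial_state("paced_1hz")
  res <- simulate_protocol(pacing_protocol(bcl = 1000, n_beats = 10), p,
                           y0 = y, sample_ms = 5)
  expect_equal(max(res$time), 10000)
  expect_gte(nrow(res), 2001)
  zsum <- rowSums(as.matrix(res[, sprintf("z%02d", 1:40)]))
  expect_lt(max(abs(zsum - 1)), 1e-6)
  expect_gt(max(res$V), 30)     # every beat captured
  expect_lt(min(res$V), -80)
})

test_that("APD90 is insensitive to a 10x tightening of solver tolerances", {
  y <- gp_initial_state("paced_1hz")
  beat <- function(rtol, atol_scale) {
    r <- simulate_protocol(pacing_protocol(bcl = 1000, n_beats = 2), p,
                           y0 = y, rtol = rtol, atol_scale = atol_scale,
                           sample_ms = 0.5)
    apd(r$time[r$time >= 1000], r$V[r$time >= 1000])
  }
  a1 <- beat(1e-7, 1e-9)
  a2 <- beat(1e-8, 1e-10)
  expect_lt(abs(a1 - a2), 0.5)
})

test_that("ionic bookkeeping: concentration changes match integrated membrane
           currents over a beat", {
  # the fast Na+ spike needs sub-millisecond quadrature
  coarse <- ref_beat()
  p <- attr(coarse, "params")
  res <- simulate_protocol(pacing_protocol(bcl = 1000, n_beats = 1), p,
                           y0 = final_state(coarse), sample_ms = 0.1)
  cf1 <- 1e-3 * p$acap * p$cmem / (p$vmyo * p$faraday)
  tz <- function(y) sum(diff(res$time) * (head(y, -1) + tail(y, -1)) / 2)
  # Na: INa + INab + 3 INCX + 3 INaK plus the mitochondrial loop
  dna_pred <- -cf1 * tz(res$i_na + res$i_nab + 3 * res$i_ncx + 3 * res$i_nak) -
    tz(3 * res$j_mncx - res$j_nhe)
  dna <- res$nai[nrow(res)] - res$nai[1]
  expect_lt(abs(dna_pred - dna), 1e-4 + 0.01 * abs(dna))
  # K: all K currents minus twice the pump, plus the stimulus carried as K+
  stim_int <- -80 * 0.5                      # uA/uF * ms
  ik <- res$i_kr + res$i_ks + res$i_k1 + res$i_kp + res$i_katp + res$i_to -
    2 * res$i_nak
  dk_pred <- -cf1 * (tz(ik) + stim_int)
  dk <- res$ki[nrow(res)] - res$ki[1]
  expect_lt(abs(dk_pred - dk), 1e-4 + 0.01 * abs(dk))
})

test_that("pacing to steady state converges and returns a reproducible
           end-diastolic state", {
  st <- pace_to_steady_state(p, bcl = 1000, y0 = gp_initial_state("paced_1hz"),
                             tol = 5e-4, max_beats = 60)
  expect_true(st$converged)
  expect_lt(st$residual, 5e-4)
  # restarting from the converged state returns promptly
  st2 <- pace_to_steady_state(p, bcl = 1000, y0 = st$state, tol = 5e-4,
                              max_beats = 10, min_beats = 1)
  expect_lte(st2$beats, 2)
})
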