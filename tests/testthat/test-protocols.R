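p <- ref_params()

test_that("protocols serialise to YAML and back without loss", {
  prs <- list(
    pacing_protocol(bcl = 700, n_beats = 3),
    voltage_step_family(tests = c(-20, 0, 20)),
    s1s2_protocol(di_list = c(50, 100, 200)),
    frequency_staircase(),
    workload_transition(high_freq = 1.5),
    ap_clamp_protocol(synthetic_ap_waveform(apd90 = 150, dt = 5))
  )
  for (pr in prs) {
    rt <- protocol_from_yaml(protocol_to_yaml(pr))
    expect_equal(unclass(rt), unclass(pr), tolerance = 1e-6)
  }
})

test_that("protocol validation catches bad inputs", {
  expect_error(voltage_step_family(tests = numeric(0)), "empty")
  expect_error(voltage_step_family(tests = c(0, 120)), "mV")
  expect_error(s1s2_protocol(di_list = c(100, 50)), "increasing")
  expect_error(pacing_protocol(bcl = 0.2, stim_dur = 0.5), "exceed")
  expect_error(workload_transition(high_freq = 0), "positive")
})

test_that("AP-clamp waveform files are validated with line numbers", {
  good <- tempfile(fileext = ".csv")
  wf <- synthetic_ap_waveform(apd90 = 120, dt = 2)
  utils::write.csv(wf, good, row.names = FALSE)
  rt <- read_ap_waveform(good)
  expect_equal(rt$voltage_mV, wf$voltage_mV)
  bad <- tempfile(fileext = ".csv")
  wf2 <- wf; wf2$time_ms[10] <- wf2$time_ms[8]
  utils::write.csv(wf2, bad, row.names = FALSE)
  expect_error(read_ap_waveform(bad), "line 11")
  nohdr <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), nohdr)
  expect_error(read_ap_waveform(nohdr), "header")
})

test_that("synthetic waveforms have the requested morphology", {
  gp <- synthetic_ap_waveform("guinea_pig", apd90 = 190)
  expect_equal(apd(gp$time_ms, gp$voltage_mV), 190, tolerance = 0.12)
  cn <- synthetic_ap_waveform("canine", apd90 = 250)
  # canine morphology has a phase-1 notch: an early local minimum below the
  # subsequent dome
  early <- cn$voltage_mV[cn$time_ms > 5 & cn$time_ms < 40]
  dome <- max(cn$voltage_mV[cn$time_ms > 40 & cn$time_ms < 120])
  expect_lt(min(early), dome - 3)
})

test_that("clamping at a constant resting potential leaves the model
           quiescent", {
  y <- gp_initial_state("paced_1hz")
  wf <- tibble::tibble(time_ms = c(0, 2000), voltage_mV = c(-86, -86))
  res <- simulate_protocol(ap_clamp_protocol(wf), p, y0 = y, sample_ms = 10)
  expect_lt(max(res$cai) / min(res$cai), 1.2)
  expect_lt(max(abs(res$i_cal)), 0.05)
})

test_that("clamping with the model's own AP reproduces the free-running Ca
           transient", {
  y <- gp_initial_state("paced_1hz")
  burn <- simulate_protocol(pacing_protocol(bcl = 1000, n_beats = 2), p,
                            y0 = y, sample_ms = 10, derived = FALSE)
  free <- simulate_protocol(pacing_protocol(bcl = 1000, n_beats = 1), p,
                            y0 = final_state(burn))
  wf <- tibble::tibble(time_ms = free$time, voltage_mV = free$V)
  clamped <- simulate_protocol(ap_clamp_protocol(wf), p,
                               y0 = final_state(burn))
  expect_equal(max(clamped$cai), max(free$cai), tolerance = 0.02)
})

test_that("premature stimuli below the refractory period are reported as
           no-capture", {
  y <- gp_initial_state("paced_1hz")
  # an immediate re-stimulus right after an AP upstroke cannot capture
  segs <- structure(list(
    list(duration = 0.5, mode = 0, stim = c(-80, 0, 0.5, 0, 1)),
    list(duration = 40, mode = 0, stim = NULL),
    list(duration = 0.5, mode = 0, stim = c(-80, 0, 0.5, 0, 1)),
    list(duration = 300, mode = 0, stim = NULL)
  ), class = "gp_segments")
  res <- simulate_protocol(segs, p, y0 = y, derived = FALSE)
  s2 <- dplyr::filter(res, .data$time > 40)
  expect_true(is.na(apd(s2$time, s2$V)) || apd(s2$time, s2$V) < 150)
})
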