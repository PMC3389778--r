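test_that("APD on a synthetic triangular AP matches the closed form", {
  # linear rise 0 -> 100 mV over 0..10 ms, linear fall back over 10..200 ms:
  # APD90 crosses 10 mV at t = 10 + 190*0.9 = 181 ms after the upstroke
  t <- seq(0, 250, by = 0.5)
  v <- ifelse(t <= 10, 10 * t, pmax(0, 100 - (t - 10) * (100 / 190)))
  a <- apd(t, v, fraction = 0.9)
  expect_equal(a, 181, tolerance = 0.01)
  # time-shift invariance
  expect_equal(apd(t + 137, v), a)
  # fraction ordering on a monotone repolarisation
  expect_lt(apd(t, v, fraction = 0.5), apd(t, v, fraction = 0.9))
  # stimulus-referenced APD is longer when the upstroke is delayed
  expect_gte(apd(t, v, ref = "stimulus"), a)
})

test_that("no-capture traces yield NA", {
  t <- seq(0, 100, by = 1)
  expect_true(is.na(apd(t, rep(-85, length(t)))))
  expect_true(is.na(apd(t, -85 + 3 * sin(t / 10))))
})

test_that("transient metrics recover designed features of a synthetic
           transient", {
  t <- seq(0, 800, by = 1)
  x <- 1e-4 + 4e-4 * pmax(0, (1 - exp(-(t - 20) / 30)) * exp(-(t - 20) / 150))
  v <- ifelse(t >= 5 & t <= 8, 40, -80)
  m <- transient_metrics(t, x, v)
  expect_equal(m$diastolic, 1e-4)
  expect_gt(m$peak, 3e-4)
  expect_equal(m$delay_from_v_peak, m$t_peak - 5)
  i_pk <- which.max(x)
  i_half <- which(x <= m$diastolic + 0.5 * (m$peak - m$diastolic) &
                    t > t[i_pk])[1]
  expect_equal(m$t_half_decay, t[i_half] - t[i_pk], tolerance = 1.5)
})

test_that("the exponential restitution fit recovers known parameters", {
  di <- c(25, 50, 75, 100, 150, 200, 300, 500, 800, 1500)
  apd_true <- 220 - 80 * exp(-di / 100)
  fit <- fit_single_exponential(di, apd_true)
  expect_equal(coef(fit$fit)[["tau"]], 100, tolerance = 0.01)
  expect_equal(coef(fit$fit)[["offset"]], 220, tolerance = 0.01)
  td <- tidy(fit)
  expect_setequal(td$term, c("offset", "amplitude", "tau"))
  expect_equal(glance(fit)$tau, 100, tolerance = 0.01)
  # adding a far-plateau point barely moves tau
  fit2 <- fit_single_exponential(c(di, 5000), c(apd_true, 220))
  expect_lt(abs(coef(fit2$fit)[["tau"]] - 100), 1)
  expect_error(fit_single_exponential(di[1:3], apd_true[1:3]), "4 points")
})

test_that("integrated removal fractions sum to one by construction", {
  res <- ref_beat()
  f <- integrated_flux_fractions(res)
  expect_equal(f$serca + f$ncx + f$sl_pump, 1, tolerance = 1e-12)
  expect_true(all(c(f$serca, f$ncx, f$sl_pump) > 0))
  fc <- integrated_flux_fractions(res, window = "cycle")
  expect_equal(fc$serca + fc$ncx + fc$sl_pump, 1, tolerance = 1e-12)
})

test_that("fractional release is zero without release and positive on a
           normal beat", {
  res <- ref_beat()
  expect_gt(fractional_release(res), 0.1)
  # disable release: no SR depletion
  p0 <- gp_parameters(ryr_v1 = 0)
  y <- gp_initial_state("paced_1hz")
  quiet <- simulate_protocol(pacing_protocol(bcl = 1000, n_beats = 1), p0,
                             y0 = y)
  expect_lt(fractional_release(quiet), 0.02)
})

test_that("recirculation fraction lies between the SERCA share and one", {
  res <- ref_beat()
  f <- integrated_flux_fractions(res)
  r <- recirculation_fraction(res)
  expect_gt(r, f$serca)
  expect_lt(r, 1)
})
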