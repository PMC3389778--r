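p <- ref_params()

test_that("subspace Ca equals cytosolic Ca with both channels closed and is
           monotone in NSR load with the RyR open", {
  for (v in c(-80, -20, 0, 40)) {
    expect_equal(subspace_ca(FALSE, FALSE, v, 1e-4, 0.7, p), 1e-4)
  }
  loads <- seq(0.2, 2, length.out = 10)
  css <- subspace_ca(FALSE, TRUE, 0, 1e-4, loads, p)
  expect_true(all(diff(css) > 0))
  expect_error(subspace_ca(TRUE, TRUE, 0, -1e-4, 0.7, p), "positive")
  expect_error(subspace_ca(TRUE, TRUE, Inf, 1e-4, 0.7, p), "finite")
})

test_that("algebraic subspace Ca matches the relaxed explicit dyadic ODE", {
  # relaxation oracle: integrate dCa_ss/dt = J_L + J_R + g_x (Ca_i - Ca_ss)
  # to steady state with the same rate laws and compare
  for (cfg in list(c(TRUE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))) {
    v <- 0; cai <- 1e-4; cansr <- 0.7
    vr <- p$ryr_nclust * p$ryr_v1
    rhs <- function(t, y, parms) {
      jl <- if (cfg[1]) gpmyocyte:::.cpp_lcc_unitary_flux(v, y[1], gpmyocyte:::param_vector(p)) else 0
      jr <- if (cfg[2]) vr * (cansr - y[1]) else 0
      list(jl + jr + p$xfer_rate * (cai - y[1]))
    }
    out <- deSolve::lsoda(c(ca = cai), c(0, 0.05), rhs, parms = NULL,
                          rtol = 1e-12, atol = 1e-15)
    expect_equal(unname(out[2, 2]),
                 subspace_ca(cfg[1], cfg[2], v, cai, cansr, p),
                 tolerance = 1e-3)
  }
})

test_that("the joint generator has non-negative off-diagonal rates and zero
           row sums across the physiological range", {
  for (v in c(-90, -40, 0, 30, 60)) {
    for (ca in c(5e-5, 5e-4, 5e-3)) {
      q <- caru_generator(v, ca, 0.7, p)
      expect_lt(max(abs(rowSums(q))), 1e-12)
      off <- q; diag(off) <- 0
      expect_true(all(off >= 0))
    }
  }
})

test_that("deterministic occupancies agree with the matrix exponential at
           clamped conditions", {
  skip_if_not_installed("Matrix")
  q <- caru_generator(0, 1e-4, 0.7, p)
  z0 <- numeric(40); z0[1] <- 1
  rel <- caru_relaxation(c(0, 5, 20, 100), 0, 1e-4, 0.7, p)
  for (i in 2:4) {
    t <- rel$time[i]
    ze <- as.numeric(z0 %*% as.matrix(Matrix::expm(q * t)))
    expect_equal(as.numeric(rel[i, -1]), ze, tolerance = 1e-6)
  }
})

test_that("Gillespie pairs converge to the deterministic occupancies", {
  times <- c(0, 5, 20, 100)
  n <- 20000
  occ <- stochastic_pair_oracle(times, 0, 1e-4, 0.7, p, n_pairs = n, seed = 42)
  rel <- caru_relaxation(times, 0, 1e-4, 0.7, p)
  for (i in 2:4) {
    pr <- pmin(pmax(as.numeric(rel[i, -1]), 0), 1)
    se <- sqrt(pr * (1 - pr) / n)
    diff <- abs(as.numeric(occ[i, -1]) - pr)
    expect_true(all(diff <= 3 * se + 5 / n))
  }
})

test_that("the stochastic oracle is frozen by its seed and by zero rates", {
  a <- stochastic_pair_oracle(c(0, 10), 0, 1e-4, 0.7, p, n_pairs = 50, seed = 7)
  b <- stochastic_pair_oracle(c(0, 10), 0, 1e-4, 0.7, p, n_pairs = 50, seed = 7)
  expect_identical(a, b)
  p0 <- gp_parameters(lcc_a0 = 0, lcc_b0 = 0, lcc_f = 0, lcc_g = 0,
                      lcc_gamma = 0, lcc_vdi0 = 0, lcc_rec0 = 0,
                      lcc_rec_ped = 0, ryr_kap = 0, ryr_kam = 0, ryr_kbp = 0,
                      ryr_kbm = 0, ryr_kcp = 0, ryr_krec = 0)
  frozen <- stochastic_pair_oracle(c(0, 50), 0, 1e-4, 0.7, p0,
                                   n_pairs = 1, seed = 1, init_state = 7)
  expect_equal(frozen$z07, c(1, 1))
})

test_that("ensemble fluxes respect normalisation, the GHK null potential and
           the occupancy weighting", {
  z <- numeric(40); z[1] <- 1
  expect_error(caru_fluxes(z * 0.5, 0, 1e-4, 0.7, p), "normalized")
  # GHK null potential: 0.341 Cao = ca_ss exp(2V/RT_F)
  rtf <- 8.314 * p$temp / p$faraday
  cass <- 1e-4
  vnull <- 0.5 * rtf * log(0.341 * p$cao / cass)
  expect_lt(abs(gpmyocyte:::.cpp_lcc_unitary_flux(vnull, cass, gpmyocyte:::param_vector(p))), 1e-10)
  # 50/50 closed-closed and open-open: averaged subspace Ca is the mean
  z2 <- numeric(40); z2[1] <- 0.5; z2[4 * 4 + 2 + 1] <- 0.5
  css_cc <- subspace_ca(FALSE, FALSE, 0, 1e-4, 0.7, p)
  css_oo <- subspace_ca(TRUE, TRUE, 0, 1e-4, 0.7, p)
  expect_equal(average_subspace_ca(z2, 0, 1e-4, 0.7, p),
               (css_cc + css_oo) / 2)
  # all mass closed-closed: averaged subspace Ca returns ca_i
  expect_equal(average_subspace_ca(z, -80, 2e-4, 0.7, p), 2e-4)
  # whole-cell current scales linearly with the number of release units
  z3 <- numeric(40); z3[4 * 4 + 1] <- 1   # open LCC, rested RyR
  f1 <- caru_fluxes(z3, 10, 1e-4, 0.7, p)
  p2 <- gp_parameters(n_caru = 2 * p$n_caru)
  f2 <- caru_fluxes(z3, 10, 1e-4, 0.7, p2)
  expect_equal(f2$i_cal, 2 * f1$i_cal)
  expect_gte(f1$j_ryr, 0)
})

test_that("release-unit occupancy stays normalised through a paced beat", {
  res <- ref_beat()
  zsum <- rowSums(as.matrix(res[, sprintf("z%02d", 1:40)]))
  expect_lt(max(abs(zsum - 1)), 1e-6)
})
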