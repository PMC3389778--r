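p <- ref_params()

# a quiescent state with chosen ionic concentrations
make_state <- function(V = -86, cai = 1e-4, ...) {
  y <- gp_initial_state("rest")
  y["V"] <- V; y["cai"] <- cai
  dots <- list(...)
  y[names(dots)] <- unlist(dots)
  y
}

test_that("every K+ current vanishes at the K+ reversal potential", {
  rtf <- 8.314 * p$temp / p$faraday
  y <- make_state()
  ek <- rtf * log(p$ko / y["ki"])
  y["V"] <- ek
  # force the gates open so a non-zero driving force would show up
  y["xr"] <- 1; y["xs1"] <- 1; y["xs2"] <- 1; y["xto"] <- 1; y["yto"] <- 1
  cur <- gp_currents(y, gp_parameters(gto = 0.2))
  for (nm in c("i_kr", "i_k1", "i_kp", "i_katp", "i_to")) {
    expect_lt(abs(cur[[nm]]), 1e-10)
  }
  # IKs reverses at its own (Na-permeable) reversal potential instead
  eks <- rtf * log((p$ko + p$prnak * p$nao) / (y["ki"] + p$prnak * y["nai"]))
  y["V"] <- eks
  expect_lt(abs(gp_currents(y, p)$i_ks), 1e-10)
})

test_that("the NCX allosteric factor saturates at high cytosolic Ca", {
  # at saturating Ca the current matches the limit with the activation
  # site removed (Km -> 0)
  y <- make_state(V = -40, cai = 0.05)
  i_sat <- gp_currents(y, p)$i_ncx
  i_lim <- gp_currents(y, gp_parameters(ncx_kmcaact = 1e-12))$i_ncx
  expect_equal(i_sat, i_lim, tolerance = 1e-3)
  # and the factor suppresses the exchanger at low Ca
  y2 <- make_state(V = -40, cai = 1e-5)
  r <- gp_currents(y2, p)$i_ncx /
    gp_currents(y2, gp_parameters(ncx_kmcaact = 1e-12))$i_ncx
  expect_lt(abs(r), 0.3)
})

test_that("pump fluxes are strictly positive for positive substrates", {
  y <- make_state()
  cur <- gp_currents(y, p)
  expect_gt(cur$i_nak, 0)
  expect_gt(cur$i_pca, 0)
})

test_that("gates relax to a fixed point under a long voltage clamp", {
  y <- gp_initial_state("rest")
  res <- simulate_protocol(voltage_step_protocol(holding = -30, test = -30,
                                                 duration = 10, hold_ms = 4000),
                           p, y0 = y, sample_ms = 10)
  dy <- gp_rhs(0, final_state(res), p, mode = "voltage_clamp")
  for (g in c("m", "h", "j", "xr", "xs1", "xs2", "xto", "yto")) {
    expect_lt(abs(dy[g]), 1e-5)
  }
})

test_that("gates and occupancies remain in [0,1] through pacing", {
  res <- ref_beat()
  gates <- c("m", "h", "j", "xr", "xs1", "xs2", "xto", "yto",
             sprintf("z%02d", 1:40))
  vals <- as.matrix(res[, gates])
  expect_gte(min(vals), -1e-6)
  expect_lte(max(vals), 1 + 1e-6)
})

test_that("both IKs formulations are selectable and differ in kinetics", {
  y <- gp_initial_state("rest")
  p1 <- set_iks_variant(p, "viswanathan99")
  p2 <- set_iks_variant(p, "zeng95")
  expect_equal(p1$iks_variant, 0)
  expect_equal(p2$iks_variant, 1)
  pr <- voltage_step_protocol(holding = -80, test = 20, duration = 500,
                              hold_ms = 100)
  r1 <- simulate_protocol(pr, p1, y0 = y)
  r2 <- simulate_protocol(pr, p2, y0 = y)
  i1 <- r1$i_ks[r1$time > 100]
  i2 <- r2$i_ks[r2$time > 100]
  expect_gt(max(abs(i1 - i2)), 1e-3)
  expect_error(gp_parameters(iks_variant = 2), "iks_variant")
})

test_that("the optional fast transient outward current behaves per contract", {
  y <- gp_initial_state("paced_1hz")
  expect_error(enable_ito_fast(p, -0.1), "non-negative")
  p_on <- enable_ito_fast(p, 0.2)
  expect_equal(p_on$gto, 0.2)
  r_off <- simulate_protocol(pacing_protocol(bcl = 1000, n_beats = 1), p, y0 = y)
  r_on <- simulate_protocol(pacing_protocol(bcl = 1000, n_beats = 1), p_on,
                            y0 = y)
  expect_lt(max(abs(r_off$i_to)), 1e-12)   # zero conductance, zero current
  expect_gt(max(r_on$i_to), 0.5)
  # rapid phase-1 repolarisation: V drops below the control plateau within
  # 20 ms of the upstroke
  i20 <- which(r_on$time >= 22)[1]
  expect_lt(r_on$V[i20], r_off$V[i20] - 5)
  # the Ca transient peaks earlier with the early-repolarising AP
  expect_lt(which.max(r_on$cai), which.max(r_off$cai))
})

test_that("steady-state availability with Ca-dependent inactivation lies below
           the VDI-only curve", {
  y <- attr(ref_beat(), "final_state")
  p_vdi <- gp_parameters(lcc_cdi_on = 0)
  for (vt in c(-10, 10, 30)) {
    pr <- voltage_step_protocol(holding = -40, test = vt, duration = 400,
                                hold_ms = 200)
    a_full <- min(simulate_protocol(pr, p, y0 = y)$lcc_avail)
    a_vdi <- min(simulate_protocol(pr, p_vdi, y0 = y)$lcc_avail)
    expect_lt(a_full, a_vdi)
  }
})
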