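p <- ref_params()

test_that("SERCA flux is monotone in cytosolic Ca and non-positive at zero Ca", {
  y <- gp_initial_state("rest")
  grid <- 10^seq(-5, -2.5, length.out = 10)
  jup <- vapply(grid, function(ca) {
    y["cai"] <- ca
    gp_currents(y, p)$j_up
  }, numeric(1))
  expect_true(all(diff(jup) > 0))
  y["cai"] <- 1e-12
  expect_lte(gp_currents(y, p)$j_up, 0)   # reverse leak only
})

test_that("with a zero-flux state the Ca balance derivatives vanish", {
  p0 <- closed_cell_params()
  p0$up_vmaxf <- 0; p0$up_vmaxr <- 0; p0$ryr_v1 <- 0
  y <- gp_initial_state("rest")
  # put every buffer at its equilibrium for the chosen concentrations
  y["ltrpn_ca"] <- p0$ltrpn_tot * p0$kltrpn_p * y["cai"] /
    (p0$kltrpn_p * y["cai"] + p0$kltrpn_m)
  y["htrpn_ca"] <- p0$htrpn_tot * p0$khtrpn_p * y["cai"] /
    (p0$khtrpn_p * y["cai"] + p0$khtrpn_m)
  y["cmdn_ca"] <- p0$cmdn_tot * p0$kcmdn_p * y["cai"] /
    (p0$kcmdn_p * y["cai"] + p0$kcmdn_m)
  y["csqn_ca"] <- p0$csqn_tot * p0$kcsqn_p * y["cansr"] /
    (p0$kcsqn_p * y["cansr"] + p0$kcsqn_m)
  # force model pinned at rest so troponin feedback is quiet
  dy <- gp_rhs(0, y, p0, mode = "voltage_clamp")
  for (s in c("cai", "cansr", "cmdn_ca", "csqn_ca", "htrpn_ca")) {
    expect_lt(abs(dy[s]), 1e-12)
  }
})

test_that("total Ca is conserved when no Ca crosses the cell or mitochondrial
           boundaries", {
  p0 <- closed_cell_params()
  y <- gp_initial_state("paced_1hz")
  res <- simulate_protocol(
    structure(list(list(duration = 10000, mode = 0, stim = NULL)),
              class = "gp_segments"),
    p0, y0 = y, sample_ms = 100)
  tot <- total_cell_ca(res, p0)
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
})

test_that("per-beat SR release balances SERCA resequestration at steady
           state", {
  res <- ref_beat()
  tz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  p <- attr(res, "params")
  rel <- tz(res$time, res$j_ryr) * p$vss_dyad * p$n_caru / p$vmyo
  up <- tz(res$time, res$j_up)
  expect_lt(abs(rel - up) / rel, 0.02)
})

test_that("integrated sarcolemmal Ca fluxes sum to zero over a steady-state
           cycle", {
  res <- ref_beat()
  p <- attr(res, "params")
  tz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  influx <- tz(res$time, res$j_lcc) * p$vss_dyad * p$n_caru / p$vmyo +
    tz(res$time, res$j_cab_ca) + tz(res$time, res$j_ncx_ca)
  efflux <- tz(res$time, -res$j_pca_ca)
  expect_lt(abs(influx - efflux) / max(influx, efflux), 0.05)
})
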