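# Shared fixtures: computed once per test run and cached.
.cache <- new.env(parent = emptyenv())

# The whole-model acceptance checks intentionally leave some expectations red
# (documented model limitations); lift the progress reporter's failure cap so
# every file still runs and reports.
local({
  lift <- function(r) {
    if (is.null(r)) return(invisible())
    if (!is.null(r$reporters)) lapply(r$reporters, lift)
    try({
      if (!is.null(r$max_fail)) r$max_fail <- .Machine$integer.max
    }, silent = TRUE)
    invisible()
  }
  lift(testthat::get_reporter())
  try(testthat::set_max_fails(Inf), silent = TRUE)
})

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

ref_params <- function(...) gp_parameters(...)

# a steady(ish) 1 Hz beat: shipped end-diastolic state + a couple of beats
ref_beat <- function() {
  cached("ref_beat", {
    p <- ref_params()
    y <- gp_initial_state("paced_1hz")
    burn <- simulate_protocol(pacing_protocol(bcl = 1000, n_beats = 2),
                              p, y0 = y, sample_ms = 10, derived = FALSE)
    simulate_protocol(pacing_protocol(bcl = 1000, n_beats = 1),
                      p, y0 = final_state(burn))
  })
}

# closed-cell parameter set: no Ca2+ crosses the sarcolemma or the
# mitochondrial inner membrane
closed_cell_params <- function() {
  gp_parameters(lcc_perm = 0, gcab = 0, ncx_vmax = 0, ipca_max = 0,
                vuni_max = 0, vmnc_max = 0)
}

# total cell Ca2+ referenced to cytosolic volume (free + buffered + SR + matrix)
total_cell_ca <- function(res, p) {
  vr_nsr <- p$vnsr / p$vmyo
  vr_mit <- p$vmito / p$vmyo
  res$cai + res$ltrpn_ca + res$htrpn_ca + res$cmdn_ca +
    (res$cansr + res$csqn_ca) * vr_nsr +
    (res$cam / p$fm_ca) * vr_mit
}
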