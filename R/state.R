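#' State vector utilities
#'
#' The dynamic state comprises membrane potential, Hodgkin-Huxley gates, the
#' 40 joint LCC-RyR occupancies (`z01`..`z40`, indexed
#' `(lcc_state - 1) * 4 + ryr_state` following the release-unit diagram),
#' ionic concentrations, buffer occupancies, crossbridge states, cytosolic
#' energetic intermediates and the mitochondrial states.
#'
#' @return `gp_state_names()` returns the canonical state names in order.
#' @export
gp_state_names <- function() {
  .cpp_state_names()
}

# per-state magnitude scales used for absolute solver tolerances and for the
# steady-state convergence criterion
state_scales <- function() {
  nm <- .cpp_state_names()
  s <- rep(1, length(nm))
  names(s) <- nm
  s["V"] <- 100
  s[c("cai", "cam")] <- 1e-3
  s["cansr"] <- 1
  s[c("nai", "ki", "atpi", "crp", "nam")] <- 10
  s["dpsi"] <- 100
  s[c("ltrpn_ca", "htrpn_ca", "cmdn_ca")] <- 0.1
  s["csqn_ca"] <- 1
  s[c("cit", "isoc", "akg", "scoa", "suc", "fum", "mal", "oaa")] <- 0.1
  s
}

#' Initial conditions
#'
#' `gp_initial_state("paced_1hz")` loads the versioned end-diastolic state
#' obtained by pre-pacing the reference parameter set to steady state at
#' 1 Hz (shipped as a plain-text state file).  `"rest"` returns an
#' approximate quiescent state useful as a starting point for long
#' equilibrations.
#'
#' @param type which shipped state to load.
#' @return named numeric vector over [gp_state_names()].
#' @export
gp_initial_state <- function(type = c("paced_1hz", "rest")) {
  type <- match.arg(type)
  nm <- .cpp_state_names()
  if (type == "paced_1hz") {
    file <- system.file("extdata", "state_1hz.csv", package = "gpmyocyte")
    df <- utils::read.csv(file, stringsAsFactors = FALSE)
    y <- setNames(df$value, df$state)
    if (!identical(sort(names(y)), sort(nm))) {
      abort("shipped state file does not match the model state layout")
    }
    return(y[nm])
  }
  y <- setNames(numeric(length(nm)), nm)
  y["V"] <- -86
  y["m"] <- 0.0013; y["h"] <- 0.99; y["j"] <- 0.99
  y["xr"] <- 2e-4; y["xs1"] <- 2e-3; y["xs2"] <- 2e-3
  y["xto"] <- 0; y["yto"] <- 1
  y["z01"] <- 1                      # all release units closed and rested
  y["cai"] <- 1e-4; y["cansr"] <- 0.8
  y["nai"] <- 6.3; y["ki"] <- 140
  y["ltrpn_ca"] <- 0.0064; y["htrpn_ca"] <- 0.1355
  y["cmdn_ca"] <- 0.002
  y["csqn_ca"] <- 3 * 0.8 / (0.8 + 0.63)
  y["xb_n0"] <- 0.98; y["xb_p0"] <- 0.02
  y["atpi"] <- 7.5; y["crp"] <- 18
  y["cam"] <- 2e-4; y["nam"] <- 1.5
  y["nadh"] <- 0.5; y["adpm"] <- 0.05; y["dpsi"] <- 150
  y["cit"] <- 0.1; y["isoc"] <- 0.045; y["akg"] <- 0.05; y["scoa"] <- 0.05
  y["suc"] <- 0.05; y["fum"] <- 0.05; y["mal"] <- 0.1; y["oaa"] <- 0.002
  y
}

# occupancy slice helpers -----------------------------------------------------
caru_state_names <- function() sprintf("z%02d", 1:40)

# logical masks over the 40 joint states
caru_masks <- function() {
  l <- rep(1:10, each = 4)   # LCC state: 1..5 normal C0..C3,O; 6..10 inactivated
  r <- rep(1:4, times = 10)  # RyR state: 1 rested, 2 primed, 3 open, 4 inactivated
  list(
    lcc = l, ryr = r,
    lcc_open = l == 5,
    ryr_open = r == 3,
    lcc_avail = l <= 5
  )
}
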