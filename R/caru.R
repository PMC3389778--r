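#' Dyadic subspace Ca2+ for a release-unit configuration
#'
#' Computes the rapid-equilibrium (algebraic) dyadic subspace Ca2+
#' concentration for one of the four dyad macro-configurations.  The subspace
#' balance is linear in subspace Ca2+ for fixed gating, so the equilibrium is
#' available in closed form: with both channels closed it equals cytosolic
#' Ca2+; an open LCC adds the GHK trigger flux and an open RyR cluster adds
#' the release flux driven by the NSR-subspace gradient.
#'
#' @param lcc_open,ryr_open logical; the dyad configuration.
#' @param v membrane potential (mV).
#' @param ca_i cytosolic Ca2+ (mM), must be positive.
#' @param ca_nsr network-SR Ca2+ (mM), must be positive.
#' @param params a [gp_parameters()] object.
#' @return subspace Ca2+ in mM (vectorised over `v`, `ca_i`, `ca_nsr`).
#' @export
subspace_ca <- function(lcc_open, ryr_open, v, ca_i, ca_nsr, params) {
  stopifnot(is.logical(lcc_open), is.logical(ryr_open))
  if (any(!is.finite(v))) abort("membrane potential must be finite")
  if (any(ca_i <= 0) || any(ca_nsr <= 0)) {
    abort("concentrations must be positive")
  }
  pv <- param_vector(params)
  n <- max(length(v), length(ca_i), length(ca_nsr))
  v <- rep_len(v, n); ca_i <- rep_len(ca_i, n); ca_nsr <- rep_len(ca_nsr, n)
  vapply(seq_len(n), function(i) {
    .cpp_subspace_ca(lcc_open, ryr_open, v[i], ca_i[i], ca_nsr[i], pv)
  }, numeric(1))
}

#' Infinitesimal generator of the 40-state release unit
#'
#' Builds the 40 x 40 transition-rate matrix of the joint LCC-RyR Markov
#' chain at clamped membrane potential and Ca2+ concentrations.  Entry
#' `Q[i, j]` is the rate from joint state `i` to `j`; rows sum to zero.
#' RyR activation and LCC Ca2+-dependent inactivation rates use the
#' configuration-appropriate subspace Ca2+ from [subspace_ca()], which is how
#' the strong coupling between trigger and release arises.
#'
#' @inheritParams subspace_ca
#' @return a 40 x 40 matrix.
#' @export
caru_generator <- function(v, ca_i, ca_nsr, params) {
  if (!is.finite(v)) abort("membrane potential must be finite")
  if (ca_i <= 0 || ca_nsr <= 0) abort("concentrations must be positive")
  .cpp_generator(v, ca_i, ca_nsr, param_vector(params))
}

#' Ensemble release-unit fluxes
#'
#' Given an occupancy distribution over the 40 joint states, returns the
#' ensemble LCC trigger flux and RyR release flux (mM/ms referenced to
#' subspace volume) and the whole-cell L-type current density obtained by
#' scaling the trigger flux by the number of release units.
#'
#' @param occupancy numeric length-40 occupancy vector, normalised to 1.
#' @inheritParams subspace_ca
#' @return a tibble with columns `j_lcc`, `j_ryr`, `i_cal`, `ca_ss_avg`.
#' @export
caru_fluxes <- function(occupancy, v, ca_i, ca_nsr, params) {
  res <- .cpp_caru_fluxes(occupancy, v, ca_i, ca_nsr, param_vector(params))
  tibble(j_lcc = res$j_lcc, j_ryr = res$j_ryr, i_cal = res$i_cal,
         ca_ss_avg = res$ca_ss_avg)
}

#' Probability-weighted average subspace Ca2+
#'
#' Weights the four macro-configuration subspace Ca2+ values by the occupancy
#' of the corresponding joint states.
#'
#' @inheritParams caru_fluxes
#' @return average subspace Ca2+ in mM.
#' @export
average_subspace_ca <- function(occupancy, v, ca_i, ca_nsr, params) {
  res <- .cpp_caru_fluxes(occupancy, v, ca_i, ca_nsr, param_vector(params))
  res$ca_ss_avg
}

#' Deterministic occupancy relaxation at clamped inputs
#'
#' Integrates the release-unit master equation alone (all other model states
#' clamped) -- the deterministic counterpart of the stochastic pair oracle.
#'
#' @param times output time grid (ms).
#' @inheritParams subspace_ca
#' @param init initial occupancy (length 40, defaults to all mass in the
#'   closed-rested joint state).
#' @return tibble with `time` and the 40 occupancy columns.
#' @export
caru_relaxation <- function(times, v, ca_i, ca_nsr, params, init = NULL) {
  if (is.null(init)) {
    init <- numeric(40)
    init[1] <- 1
  }
  q <- caru_generator(v, ca_i, ca_nsr, params)
  rhs <- function(t, y, parms) list(as.vector(y %*% parms))
  out <- deSolve::lsoda(init, times, rhs, parms = q,
                        rtol = 1e-10, atol = 1e-12)
  colnames(out) <- c("time", caru_state_names())
  as_tibble(as.data.frame(out))
}

#' Stochastic single-pair oracle
#'
#' Gillespie simulation of `n_pairs` independent LCC-RyR pairs under the
#' identical rate laws as the deterministic 40-state master equation, with
#' membrane potential and Ca2+ inputs prescribed as (piecewise-constant)
#' traces on the supplied time grid.  As `n_pairs` grows the empirical
#' occupancy converges to the deterministic solution; the same seed always
#' reproduces the same trajectories.
#'
#' @param times sample time grid (ms).
#' @param v_trace,ca_i_trace,ca_nsr_trace input traces on `times` (scalars
#'   are recycled).
#' @param params a [gp_parameters()] object.
#' @param n_pairs number of independent pairs (>= 1).
#' @param seed RNG seed (integer).
#' @param init_state initial joint state index in 1..40.
#' @return tibble with `time` and empirical occupancy columns `z01`..`z40`.
#' @export
stochastic_pair_oracle <- function(times, v_trace, ca_i_trace, ca_nsr_trace,
                                   params, n_pairs = 1000, seed = 1,
                                   init_state = 1) {
  if (n_pairs < 1) abort("n_pairs must be >= 1")
  if (!init_state %in% 1:40) abort("init_state must be in 1..40")
  n <- length(times)
  v_trace <- rep_len(v_trace, n)
  ca_i_trace <- rep_len(ca_i_trace, n)
  ca_nsr_trace <- rep_len(ca_nsr_trace, n)
  set.seed(seed)
  occ <- .cpp_gillespie(times, v_trace, ca_i_trace, ca_nsr_trace,
                        param_vector(params), as.integer(n_pairs),
                        as.integer(init_state) - 1L)
  colnames(occ) <- caru_state_names()
  dplyr::bind_cols(tibble(time = times), as_tibble(occ))
}
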