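#' Model parameters
#'
#' Loads the versioned reference parameter set shipped with the package and
#' applies optional overrides.  Every parameter carries units and a provenance
#' tag (`printed`, `cited-source` or `calibrated`) recorded in the parameter
#' file; [gp_param_table()] exposes them as a tibble.
#'
#' @param ... named scalar overrides, e.g. `gp_parameters(gkr = 0.04)`.
#' @param overrides a named list of overrides (alternative to `...`).
#' @param file path to a parameter YAML file; defaults to the packaged
#'   reference set.
#' @return a named list of class `gp_params` with one numeric value per model
#'   parameter.
#' @examples
#' p <- gp_parameters()
#' p$n_caru
#' p25 <- gp_parameters(vuni_scale = 0.25)  # 75% uniporter block overlay
#' @export
gp_parameters <- function(..., overrides = list(), file = NULL) {
  raw <- gp_param_table(file = file)
  values <- setNames(as.list(raw$value), raw$name)
  dots <- list(...)
  overrides <- c(overrides, dots)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      abort("parameter overrides must be named")
    }
    unknown <- setdiff(names(overrides), names(values))
    if (length(unknown)) {
      abort(paste0("unknown parameter(s): ", paste(unknown, collapse = ", ")))
    }
    for (nm in names(overrides)) {
      v <- overrides[[nm]]
      if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
        abort(paste0("override for '", nm, "' must be a finite numeric scalar"))
      }
      values[[nm]] <- as.numeric(v)
    }
  }
  validate_params(values)
  structure(values, class = "gp_params")
}

#' @rdname gp_parameters
#' @export
gp_param_table <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "parameters.yaml", package = "gpmyocyte")
  }
  doc <- yaml::read_yaml(file)
  pars <- doc$parameters
  canon <- .cpp_param_names()
  missing <- setdiff(canon, names(pars))
  if (length(missing)) {
    abort(paste0("parameter file is missing: ", paste(missing, collapse = ", ")))
  }
  tibble(
    name = canon,
    value = vapply(pars[canon], function(x) as.numeric(x$value), numeric(1)),
    units = vapply(pars[canon], function(x) x$units %||% "", character(1)),
    provenance = vapply(pars[canon], function(x) x$provenance %||% "", character(1)),
    note = vapply(pars[canon], function(x) x$note %||% "", character(1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_params <- function(values) {
  must_pos <- c(
    "faraday", "temp", "acap", "cmem", "vmyo", "vnsr", "vmito", "vss_dyad",
    "n_caru", "ko", "nao", "cao", "xfer_rate", "ltrpn_tot", "htrpn_tot",
    "cmdn_tot", "nad_tot", "adn_tot_m", "adn_tot_c", "cr_tot", "force_norm",
    "xs_area"
  )
  for (nm in must_pos) {
    if (values[[nm]] <= 0) abort(paste0("parameter '", nm, "' must be > 0"))
  }
  if (values$vuni_scale < 0 || values$vuni_scale > 1) {
    abort("vuni_scale must lie in [0, 1]")
  }
  if (values$gto < 0) abort("Ito conductance must be non-negative")
  if (!values$iks_variant %in% c(0, 1)) {
    abort("iks_variant must be 0 (two-gate) or 1 (single-gate)")
  }
  invisible(values)
}

# canonical numeric vector in the order the compiled code expects
param_vector <- function(params) {
  stopifnot(inherits(params, "gp_params"))
  unlist(params[.cpp_param_names()], use.names = FALSE)
}

#' Select the slow delayed-rectifier formulation
#'
#' The model ships two interchangeable formulations of the slow delayed
#' rectifier K+ current: the reference two-gate formulation (one fast, one
#' slow activation gate) and the older single-gate formulation whose faster
#' deactivation speeds up APD restitution.
#'
#' @param params a `gp_params` object.
#' @param variant `"viswanathan99"` (two-gate, reference) or `"zeng95"`.
#' @return the parameter object with the variant flag set.
#' @export
set_iks_variant <- function(params, variant = c("viswanathan99", "zeng95")) {
  variant <- match.arg(variant)
  params$iks_variant <- if (variant == "zeng95") 1 else 0
  params
}

#' Enable the optional fast transient outward current
#'
#' Adds the Ca2+-independent fast transient outward K+ current (one
#' activation and one slower inactivation Hodgkin-Huxley gate).  The current
#' is absent in guinea pig and off by default; enabling it reshapes the early
#' action potential toward the spike-notch-dome morphology of species that
#' express it.
#'
#' @param params a `gp_params` object.
#' @param conductance channel conductance in mS/uF (reference value 0.2).
#' @export
enable_ito_fast <- function(params, conductance = 0.2) {
  if (!is.numeric(conductance) || length(conductance) != 1 ||
      !is.finite(conductance) || conductance < 0) {
    abort("Ito conductance must be a non-negative scalar")
  }
  params$gto <- conductance
  params
}
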