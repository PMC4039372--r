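#' @importFrom stats setNames
NULL

# Canonical species order; the compiled right-hand side and the stoichiometry
# matrix both index species in this order.
.SPECIES <- c("m_wc1", "m_frq", "m_vvd",
              "WCC_d", "WCC_a", "WCC_aa", "WCC_p",
              "FRQ_c", "FRQ_n", "FRQ_p",
              "VVD_d", "VVD_a", "VVD_aa", "HET")

.MRNA_SPECIES <- c(vvd = "m_vvd", frq = "m_frq", wc1 = "m_wc1")
.VVD_SPECIES <- c("VVD_d", "VVD_a", "VVD_aa")

# Canonical parameter order (the compiled code receives them in this order,
# followed by the current light intensity).
.PARAM_NAMES <- c(
  "ka_wcc", "ka_vvd", "kd_wcc", "kd_vvd",
  "kdim_wcc", "kundim_wcc", "kpad_wcc",
  "kdim_vvd", "kundim_vvd", "kpad_vvd",
  "l1", "lm1", "l5",
  "bas_wc1", "vmax_wc1", "K_wc1",
  "vmax_frq", "K_frq", "vc_frq", "K_cbox",
  "vmax_vvd", "K_vvd", "bas_vvd", "hill_lre", "hill_cbox",
  "dm_wc1", "dm_frq", "dm_vvd",
  "ktl_wc1", "ktl_frq", "ktl_vvd",
  "dg_wcc_d", "dg_wcc_a", "dg_wcc_aa", "dg_wcc_p", "dg_het",
  "dg_vvd_d", "dg_vvd_a", "dg_vvd_aa",
  "dg_frq_c", "dg_frq_n", "dg_frq_p",
  "kin_frq", "kph", "K_ph", "kdp", "K_dp", "kpf")

.HALF_SAT <- c("K_wc1", "K_frq", "K_cbox", "K_vvd", "K_ph", "K_dp")

# Parameters that involve VVD function: its synthesis and turnover,
# photoactivation and adduct decay, homodimerization, and the
# heterodimerization/futile-cycle constants. Frozen out in the mutant stage
# of the two-stage fit and the only free set in the VVD stage.
.VVD_PARAMS <- c("ktl_vvd", "dg_vvd_d", "dg_vvd_a", "dg_vvd_aa",
                 "ka_vvd", "kd_vvd", "kdim_vvd", "kundim_vvd", "kpad_vvd",
                 "l1", "lm1", "l5")

#' Model species names
#'
#' @return Character vector of the 14 species, mRNAs first.
#' @export
model_species <- function() .SPECIES

#' Model parameter names
#'
#' @return Character vector of the rate-constant and regulation parameters,
#'   in canonical order.
#' @export
model_parameter_names <- function() .PARAM_NAMES

#' Names of the VVD-related parameters
#'
#' The parameters governing VVD synthesis, turnover, photocycle,
#' homodimerization and heterodimerization with WCC (including the futile
#' cycle constants l1, lm1 and l5). These are the free set in the second
#' stage of [two_stage_fit()].
#'
#' @return Character vector.
#' @export
vvd_parameter_names <- function() .VVD_PARAMS

#' Construct a model parameter set
#'
#' All rates are first-order (min^-1), second-order (conc^-1 min^-1), or
#' zero-order (conc min^-1) as implied by the reaction list in
#' [reaction_fluxes()]; light-activation constants are per minute per
#' umol photons m^-2 s^-1. Concentrations are in arbitrary units anchored by
#' the convention that normalized wild-type vvd mRNA equals 1 at the first
#' light-on event.
#'
#' @param ... named parameter values overriding the calibrated defaults
#'   (see [default_parameters()]).
#' @param base optional existing `model_parameters` object (or named numeric
#'   vector) used instead of the defaults as the starting point.
#' @return A named numeric vector of class `model_parameters`.
#' @export
model_parameters <- function(..., base = default_parameters()) {
  p <- as_model_parameters(base)
  dots <- c(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots))))
      stop("all parameter overrides must be named")
    unknown <- setdiff(names(dots), .PARAM_NAMES)
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(dots)] <- as.numeric(dots)
  }
  validate_parameters(p)
  p
}

#' @rdname model_parameters
#' @param x object to coerce (named numeric vector covering every parameter).
#' @export
as_model_parameters <- function(x) {
  v <- unclass(x)
  missing <- setdiff(.PARAM_NAMES, names(v))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "))
  structure(setNames(as.numeric(v[.PARAM_NAMES]), .PARAM_NAMES),
            class = "model_parameters")
}

validate_parameters <- function(p) {
  if (any(!is.finite(p))) stop("parameters must be finite")
  if (any(p < 0)) stop("rate constants must be >= 0")
  if (any(p[.HALF_SAT] <= 0)) stop("half-saturation constants must be > 0")
  invisible(p)
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Model parameters (", length(x), " rate/regulation constants)\n",
      sep = "")
  print(setNames(as.numeric(x), names(unclass(x))))
  invisible(x)
}

#' Calibrated default parameter set
#'
#' The package's reference parameterization, calibrated against the packaged
#' synthetic light-step data so that the model reproduces the canonical
#' photoadaptation phenotypes: sub-30-min first mRNA peaks, repeated
#' responsiveness of the wild type to the 2/20/200 light staircase, loss of
#' re-responsiveness in the vvd-null and slow-cycling variants, a ~6 h
#' wild-type refractory period, fast (<1 h) wild-type light-to-dark mRNA
#' shut-off versus ~4 h in the mutant, an increasing steady-state vvd mRNA
#' dose response, and free-running circadian oscillation of frq in darkness.
#'
#' @return A `model_parameters` vector.
#' @export
default_parameters <- function() {
  structure(.DEFAULT_PARAMS, class = "model_parameters")
}

#' Model variants
#'
#' `wild_type` leaves parameters untouched. `vvd_null` emulates a
#' loss-of-function vvd allele that is transcribed but yields no functional
#' protein: only VVD translation is zeroed, vvd gene transcription is
#' intact. `slow_cycling` stabilizes the WCC*-VVD* heterodimer by dividing
#' the photoadduct-decay rate l5 (and only l5) by `slow_cycling_factor`.
#'
#' @param kind one of `"wild_type"`, `"vvd_null"`, `"slow_cycling"`.
#' @param slow_cycling_factor factor by which l5 is slowed (default 10).
#' @return An object of class `model_variant`.
#' @export
model_variant <- function(kind = c("wild_type", "vvd_null", "slow_cycling"),
                          slow_cycling_factor = 10) {
  kind <- match.arg(kind)
  stopifnot(slow_cycling_factor > 0)
  structure(list(kind = kind, slow_cycling_factor = slow_cycling_factor),
            class = "model_variant")
}

#' @export
print.model_variant <- function(x, ...) {
  cat("Model variant:", x$kind)
  if (x$kind == "slow_cycling")
    cat(" (l5 / ", x$slow_cycling_factor, ")", sep = "")
  cat("\n")
  invisible(x)
}

as_variant <- function(variant) {
  if (inherits(variant, "model_variant")) return(variant)
  if (is.character(variant) && length(variant) == 1)
    return(model_variant(variant))
  stop("variant must be a model_variant or a variant name")
}

#' Apply a variant transform to a parameter set
#'
#' Returns a transformed copy; every field not documented as modified by the
#' variant is preserved bit-for-bit.
#'
#' @param params a `model_parameters` vector.
#' @param variant a [model_variant()] or variant name.
#' @return A `model_parameters` vector.
#' @export
apply_variant <- function(params, variant) {
  params <- as_model_parameters(params)
  variant <- as_variant(variant)
  switch(variant$kind,
    wild_type = params,
    vvd_null = {
      params["ktl_vvd"] <- 0
      params
    },
    slow_cycling = {
      params["l5"] <- params["l5"] / variant$slow_cycling_factor
      params
    },
    stop("unknown variant kind: ", variant$kind))
}

#' Read / write parameter sets as structured text
#'
#' Parameters are stored as a flat YAML mapping whose keys are exactly the
#' [model_parameter_names()]; unknown keys are rejected.
#'
#' @param path file path.
#' @return `read_parameters()` returns a `model_parameters` vector.
#' @export
read_parameters <- function(path) {
  v <- yaml::read_yaml(path)
  unknown <- setdiff(names(v), .PARAM_NAMES)
  if (length(unknown))
    stop("unknown parameter key(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  as_model_parameters(unlist(v))
}

#' @rdname read_parameters
#' @param params a `model_parameters` vector.
#' @export
write_parameters <- function(params, path) {
  params <- as_model_parameters(params)
  yaml::write_yaml(as.list(setNames(as.numeric(params), names(unclass(params)))),
                   path, precision = 15)
  invisible(path)
}
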