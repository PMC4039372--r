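# Reaction network of the photoadaptation model.
#
# Three coupled modules: a transcription module (light activation of WCC,
# homodimerization, LRE/C-box driven transcription of wc-1, frq, vvd), a
# photoadduct-decay module (futile cycling of the WCC*-VVD* heterodimer and
# adduct-triggered dissociation of both homodimers), and a phosphorylation
# module (FRQ-mediated inactivation of dark WCC that closes the circadian
# negative feedback loop).
#
# Each reaction is declared once, with its mass-action/Hill rate law and its
# stoichiometry; the R right-hand side is literally S %*% flux. The compiled
# C right-hand side in src/vvd_model.c mirrors this list and is
# cross-checked against it in the test suite.

hill_fn <- function(x, K, h) {
  if (x <= 0) return(0)
  xh <- x^h
  xh / (K^h + xh)
}

# One row per reaction: name, rate law, stoichiometry (named, sparse).
.REACTIONS <- list(
  list("wcc_activation",      function(s, p, I) p["ka_wcc"] * I * s["WCC_d"],
       c(WCC_d = -1, WCC_a = 1)),
  list("wcc_adduct_decay",    function(s, p, I) p["kd_wcc"] * s["WCC_a"],
       c(WCC_a = -1, WCC_d = 1)),
  list("vvd_activation",      function(s, p, I) p["ka_vvd"] * I * s["VVD_d"],
       c(VVD_d = -1, VVD_a = 1)),
  list("vvd_adduct_decay",    function(s, p, I) p["kd_vvd"] * s["VVD_a"],
       c(VVD_a = -1, VVD_d = 1)),
  list("wcc_homodimerization", function(s, p, I) p["kdim_wcc"] * s["WCC_a"]^2,
       c(WCC_a = -2, WCC_aa = 1)),
  list("wcc_homodimer_dissociation",
       function(s, p, I) p["kundim_wcc"] * s["WCC_aa"],
       c(WCC_aa = -1, WCC_a = 2)),
  list("wcc_homodimer_adduct_dissociation",
       function(s, p, I) p["kpad_wcc"] * s["WCC_aa"],
       c(WCC_aa = -1, WCC_a = 1, WCC_d = 1)),
  list("vvd_homodimerization", function(s, p, I) p["kdim_vvd"] * s["VVD_a"]^2,
       c(VVD_a = -2, VVD_aa = 1)),
  list("vvd_homodimer_dissociation",
       function(s, p, I) p["kundim_vvd"] * s["VVD_aa"],
       c(VVD_aa = -1, VVD_a = 2)),
  list("vvd_homodimer_adduct_dissociation",
       function(s, p, I) p["kpad_vvd"] * s["VVD_aa"],
       c(VVD_aa = -1, VVD_a = 1, VVD_d = 1)),
  list("het_association",
       function(s, p, I) p["l1"] * s["WCC_a"] * s["VVD_a"],
       c(WCC_a = -1, VVD_a = -1, HET = 1)),
  list("het_dissociation",    function(s, p, I) p["lm1"] * s["HET"],
       c(HET = -1, WCC_a = 1, VVD_a = 1)),
  # futile cycle: photoadduct decay in either heterodimer partner, each at
  # rate l5; decay in WCC returns dark WCC to the light-activatable pool
  list("het_adduct_decay_in_wcc", function(s, p, I) p["l5"] * s["HET"],
       c(HET = -1, WCC_d = 1, VVD_a = 1)),
  list("het_adduct_decay_in_vvd", function(s, p, I) p["l5"] * s["HET"],
       c(HET = -1, WCC_a = 1, VVD_d = 1)),
  list("tx_wc1_basal",        function(s, p, I) p["bas_wc1"],
       c(m_wc1 = 1)),
  list("tx_wc1_lre",
       function(s, p, I) p["vmax_wc1"] * hill_fn(s["WCC_aa"], p["K_wc1"], p["hill_lre"]),
       c(m_wc1 = 1)),
  list("tx_frq_lre",
       function(s, p, I) p["vmax_frq"] * hill_fn(s["WCC_aa"], p["K_frq"], p["hill_lre"]),
       c(m_frq = 1)),
  # C-box: dark-form WCC sustains frq transcription; no dark drive for vvd
  list("tx_frq_cbox",
       function(s, p, I) p["vc_frq"] * hill_fn(s["WCC_d"], p["K_cbox"], p["hill_cbox"]),
       c(m_frq = 1)),
  list("tx_vvd_lre",
       function(s, p, I) p["vmax_vvd"] * hill_fn(s["WCC_aa"], p["K_vvd"], p["hill_lre"]),
       c(m_vvd = 1)),
  # small transcriptional leak; anchors the t = 0 normalization (dark vvd
  # mRNA is low but measurable). WCC does not drive vvd in the dark.
  list("tx_vvd_basal",        function(s, p, I) p["bas_vvd"],
       c(m_vvd = 1)),
  list("deg_m_wc1",           function(s, p, I) p["dm_wc1"] * s["m_wc1"],
       c(m_wc1 = -1)),
  list("deg_m_frq",           function(s, p, I) p["dm_frq"] * s["m_frq"],
       c(m_frq = -1)),
  list("deg_m_vvd",           function(s, p, I) p["dm_vvd"] * s["m_vvd"],
       c(m_vvd = -1)),
  list("tl_wc1",              function(s, p, I) p["ktl_wc1"] * s["m_wc1"],
       c(WCC_d = 1)),
  list("tl_frq",              function(s, p, I) p["ktl_frq"] * s["m_frq"],
       c(FRQ_c = 1)),
  list("tl_vvd",              function(s, p, I) p["ktl_vvd"] * s["m_vvd"],
       c(VVD_d = 1)),
  list("deg_wcc_d",           function(s, p, I) p["dg_wcc_d"] * s["WCC_d"],
       c(WCC_d = -1)),
  list("deg_wcc_a",           function(s, p, I) p["dg_wcc_a"] * s["WCC_a"],
       c(WCC_a = -1)),
  list("deg_wcc_aa",          function(s, p, I) p["dg_wcc_aa"] * s["WCC_aa"],
       c(WCC_aa = -1)),
  list("deg_wcc_p",           function(s, p, I) p["dg_wcc_p"] * s["WCC_p"],
       c(WCC_p = -1)),
  list("deg_het",             function(s, p, I) p["dg_het"] * s["HET"],
       c(HET = -1)),
  list("deg_vvd_d",           function(s, p, I) p["dg_vvd_d"] * s["VVD_d"],
       c(VVD_d = -1)),
  list("deg_vvd_a",           function(s, p, I) p["dg_vvd_a"] * s["VVD_a"],
       c(VVD_a = -1)),
  list("deg_vvd_aa",          function(s, p, I) p["dg_vvd_aa"] * s["VVD_aa"],
       c(VVD_aa = -1)),
  list("deg_frq_c",           function(s, p, I) p["dg_frq_c"] * s["FRQ_c"],
       c(FRQ_c = -1)),
  list("deg_frq_n",           function(s, p, I) p["dg_frq_n"] * s["FRQ_n"],
       c(FRQ_n = -1)),
  list("deg_frq_p",           function(s, p, I) p["dg_frq_p"] * s["FRQ_p"],
       c(FRQ_p = -1)),
  list("frq_nuclear_import",  function(s, p, I) p["kin_frq"] * s["FRQ_c"],
       c(FRQ_c = -1, FRQ_n = 1)),
  # FRQ_n-catalysed, Michaelis in the WCC substrate (near-zero-order when
  # WCC_d >> K_ph, the regime that sustains the circadian relaxation cycle)
  list("wcc_phosphorylation",
       function(s, p, I) p["kph"] * s["FRQ_n"] * s["WCC_d"] /
         (p["K_ph"] + s["WCC_d"]),
       c(WCC_d = -1, WCC_p = 1)),
  # saturable release of phosphorylated WCC (zero-order regime when
  # WCC_p >> K_dp); the linear law is the K_dp -> Inf limit
  list("wcc_dephosphorylation",
       function(s, p, I) p["kdp"] * s["WCC_p"] / (1 + s["WCC_p"] / p["K_dp"]),
       c(WCC_p = -1, WCC_d = 1)),
  list("frq_phosphorylation", function(s, p, I) p["kpf"] * s["FRQ_n"],
       c(FRQ_n = -1, FRQ_p = 1))
)

#' Reaction names of the model network
#'
#' @return Character vector, one entry per elementary reaction, in the order
#'   used by [reaction_fluxes()] and [stoichiometry_matrix()].
#' @export
reaction_names <- function() vapply(.REACTIONS, `[[`, "", 1)

#' Stoichiometry matrix
#'
#' @return Integer matrix (species x reactions); column r holds the net
#'   change of each species caused by one firing of reaction r.
#' @export
stoichiometry_matrix <- function() {
  S <- matrix(0L, nrow = length(.SPECIES), ncol = length(.REACTIONS),
              dimnames = list(.SPECIES, reaction_names()))
  for (r in seq_along(.REACTIONS)) {
    st <- .REACTIONS[[r]][[3]]
    S[names(st), r] <- as.integer(st)
  }
  S
}

as_state <- function(state) {
  if (is.null(names(state))) {
    if (length(state) != length(.SPECIES))
      stop("state must have ", length(.SPECIES), " entries")
    state <- setNames(as.numeric(state), .SPECIES)
  } else {
    missing <- setdiff(.SPECIES, names(state))
    if (length(missing))
      stop("state is missing species: ", paste(missing, collapse = ", "))
    state <- setNames(as.numeric(state[.SPECIES]), .SPECIES)
  }
  state
}

#' Dark all-zero initial state
#'
#' @return Named numeric vector over [model_species()], all zero. Mostly a
#'   starting point for dark equilibration.
#' @export
zero_state <- function() setNames(numeric(length(.SPECIES)), .SPECIES)

#' Reaction fluxes at a given state
#'
#' Evaluates the rate law of every elementary reaction at the given state,
#' parameters and light intensity.
#'
#' @param state named numeric vector over [model_species()] (or unnamed in
#'   canonical order); all entries must be >= 0.
#' @param params a `model_parameters` vector.
#' @param intensity light intensity (umol m^-2 s^-1).
#' @return Named numeric vector of fluxes, one per reaction.
#' @export
reaction_fluxes <- function(state, params, intensity) {
  state <- as_state(state)
  if (any(state < 0)) stop("invalid state: negative concentration(s) for ",
                           paste(names(state)[state < 0], collapse = ", "))
  params <- as_model_parameters(params)
  if (!is.finite(intensity) || intensity < 0)
    stop("intensity must be finite and >= 0")
  setNames(vapply(.REACTIONS, function(r) as.numeric(r[[2]](state, params, intensity)),
                  0), reaction_names())
}

#' ODE right-hand side of the 14-species model
#'
#' The time derivative of every species, computed as the stoichiometry
#' matrix applied to the reaction flux vector. A pure function of the state,
#' the protocol intensity at time `t`, and the parameters. This is the
#' reference implementation; [simulate_trajectory()] integrates a compiled
#' equivalent that is tested against it.
#'
#' @param state named numeric state vector.
#' @param t time (minutes).
#' @param params a `model_parameters` vector.
#' @param protocol a [light_protocol()].
#' @return Named numeric vector of d(state)/dt.
#' @export
model_rhs <- function(state, t, params, protocol) {
  flux <- reaction_fluxes(state, params, intensity_at(protocol, t))
  drop(stoichiometry_matrix() %*% flux)
}

# Compiled right-hand side, evaluated directly (no solver); internal, used
# to verify the C implementation against model_rhs().
compiled_rhs <- function(state, params, intensity) {
  out <- .C("vvd_rhs_eval", y = as.double(as_state(state)),
            pars = as.double(c(as.numeric(as_model_parameters(params)),
                               intensity)),
            ydot = double(14), PACKAGE = "vvdadapt")
  setNames(out$ydot, .SPECIES)
}

compiled_simplified_rhs <- function(state, params, intensity) {
  out <- .C("simp_rhs_eval", y = as.double(as.numeric(state)),
            pars = as.double(c(as.numeric(params), intensity)),
            ydot = double(4), PACKAGE = "vvdadapt")
  setNames(out$ydot, .SIMP_SPECIES)
}
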