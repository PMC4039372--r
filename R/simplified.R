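# Simplified WCC-VVD model: the four-variable core of the adaptation motif.
#
# State: WCC_d (light-activatable pool), WCC_a (light-activated), VVD
# (inhibitor, lumped synthesis driven by WCC_a), CPLX (WCC_a-VVD complex).
# The complex decays by photoadduct loss at rate kc, returning dark-form
# WCC to the activatable pool — the futile cycle stripped to essentials.

.SIMP_SPECIES <- c("WCC_d", "WCC_a", "VVD", "CPLX")
.SIMP_PARAM_NAMES <- c("ka", "r", "pv", "kon", "kc",
                       "sw", "dW", "dA", "dV", "dC")

#' Simplified-model parameter set
#'
#' @param ... named overrides of the defaults.
#' @return Named numeric vector of class `simplified_parameters` with
#'   fields `ka` (light activation, per min per intensity unit), `r`
#'   (photoadduct decay of free activated WCC), `pv` (VVD production driven
#'   by activated WCC), `kon` (complex association), `kc` (complex
#'   photoadduct decay returning activatable WCC), `sw` (constitutive WCC
#'   synthesis) and degradation rates `dW`, `dA`, `dV`, `dC`.
#' @export
simplified_parameters <- function(...) {
  p <- c(ka = 0.05, r = 0.005, pv = 0.05, kon = 10, kc = 0.01,
         sw = 0.01, dW = 0.01, dA = 0.012, dV = 0.008, dC = 0.002)
  dots <- c(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), .SIMP_PARAM_NAMES)
    if (length(unknown))
      stop("unknown simplified parameter(s): ",
           paste(unknown, collapse = ", "))
    p[names(dots)] <- as.numeric(dots)
  }
  if (any(p < 0)) stop("simplified-model rates must be >= 0")
  structure(p, class = "simplified_parameters")
}

#' Right-hand side of the simplified model
#'
#' Reference R implementation; [simulate_simplified()] integrates the
#' compiled equivalent.
#'
#' @param state named vector over `WCC_d`, `WCC_a`, `VVD`, `CPLX`.
#' @param params a [simplified_parameters()] vector.
#' @param intensity light intensity.
#' @return Named derivative vector.
#' @export
simplified_rhs <- function(state, params, intensity) {
  s <- state
  if (is.null(names(s))) s <- setNames(as.numeric(s), .SIMP_SPECIES)
  p <- params
  v_act <- p["ka"] * intensity * s["WCC_d"]
  v_dec <- p["r"] * s["WCC_a"]
  v_on <- p["kon"] * s["WCC_a"] * s["VVD"]
  v_kc <- p["kc"] * s["CPLX"]
  d <- c(p["sw"] - v_act + v_dec + v_kc - p["dW"] * s["WCC_d"],
         v_act - v_dec - v_on - p["dA"] * s["WCC_a"],
         p["pv"] * s["WCC_a"] - v_on + v_kc - p["dV"] * s["VVD"],
         v_on - v_kc - p["dC"] * s["CPLX"])
  setNames(as.numeric(d), .SIMP_SPECIES)
}

#' Simulate the simplified model under a light protocol
#'
#' @param params a [simplified_parameters()] vector.
#' @param protocol a [light_protocol()].
#' @param t_grid strictly increasing output grid (minutes).
#' @param initial named state vector or `"dark_equilibrated"` (the dark
#'   fixed point `WCC_d = sw/dW`, all activated species 0).
#' @param rtol,atol solver tolerances.
#' @return A `trajectory`-like object with a 4-column state matrix.
#' @export
simulate_simplified <- function(params, protocol, t_grid,
                                initial = "dark_equilibrated",
                                rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(protocol, "light_protocol"))
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing with at least 2 points")
  if (identical(initial, "dark_equilibrated")) {
    y0 <- c(WCC_d = unname(params["sw"] / params["dW"]),
            WCC_a = 0, VVD = 0, CPLX = 0)
  } else {
    if (is.null(names(initial))) names(initial) <- .SIMP_SPECIES
    y0 <- initial[.SIMP_SPECIES]
  }
  st <- .simulate_core(y0, t_grid, params, protocol, rtol, atol,
                       func = "simp_derivs", initfunc = "simp_initmod")
  colnames(st) <- .SIMP_SPECIES
  new_trajectory(t_grid, st, protocol,
                 list(kind = "simplified"), params)
}
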