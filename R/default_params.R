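# Calibrated default parameter values (see default_parameters() for the
# phenotypes the calibration reproduces and the methods vignette for the
# calibration rationale). Units: min^-1, conc^-1 min^-1 or conc min^-1 as
# dictated by each rate law; light-activation constants per minute per
# umol photons m^-2 s^-1.
.DEFAULT_PARAMS <- c(
  ka_wcc = 0.25, ka_vvd = 0.503,
  kd_wcc = 0.005, kd_vvd = 0.0211,
  kdim_wcc = 8.55, kundim_wcc = 0.289, kpad_wcc = 0.01,
  kdim_vvd = 3.68, kundim_vvd = 0.0316, kpad_vvd = 0.002,
  l1 = 25.6, lm1 = 0.118, l5 = 0.15,
  bas_wc1 = 0.003, vmax_wc1 = 0.0058, K_wc1 = 0.071,
  vmax_frq = 0.1, K_frq = 0.071, vc_frq = 0.02, K_cbox = 0.5,
  vmax_vvd = 2.13, K_vvd = 0.303, bas_vvd = 6e-5,
  hill_lre = 2, hill_cbox = 2,
  dm_wc1 = 0.03, dm_frq = 0.05, dm_vvd = 0.109,
  ktl_wc1 = 0.0511, ktl_frq = 0.02, ktl_vvd = 0.949,
  dg_wcc_d = 0.00205, dg_wcc_a = 0.0108, dg_wcc_aa = 0.0108,
  dg_wcc_p = 0.0015, dg_het = 3e-4,
  dg_vvd_d = 0.016, dg_vvd_a = 0.0045, dg_vvd_aa = 0.0045,
  dg_frq_c = 0.004, dg_frq_n = 0.002, dg_frq_p = 0.02,
  kin_frq = 0.002, kph = 0.06, K_ph = 20, kdp = 0.002, K_dp = 50,
  kpf = 0.002)

# Alternative clock-block calibration that sustains a free-running rhythm
# in darkness (see oscillatory_parameters()).
.OSCILLATORY_CLOCK <- c(
  vc_frq = 0.0694615, K_cbox = 2.39919, hill_cbox = 4,
  vmax_frq = 0.0637784, ktl_frq = 0.0250046, kin_frq = 0.000841037,
  kph = 0.0208585, K_ph = 0.0626528, kdp = 0.00542416, K_dp = 3.00176,
  kpf = 0.00127741, dg_frq_c = 0.00278398, dg_frq_n = 0.00222007,
  dg_wcc_p = 0.000196262, dm_frq = 0.04)

#' Alternative calibration with a self-sustained circadian oscillator
#'
#' The default parameter set prioritizes the photoadaptation phenotypes;
#' under it the FRQ-WCC feedback loop in constant darkness is damped. This
#' alternative re-tunes only the phosphorylation/clock block (steeper
#' C-box activation, near-zero-order FRQ-catalysed WCC phosphorylation,
#' slower FRQ turnover) so that frq mRNA shows a robust free-running
#' rhythm with a circadian-range period and a phase delay of several
#' hours in the vvd-null mutant. The trade-off — the strong dark clock
#' gates the photoresponse and degrades the fidelity of the VVD-set
#' refractory period — is discussed in the methods vignette.
#'
#' @return A `model_parameters` vector.
#' @export
oscillatory_parameters <- function() {
  model_parameters(.OSCILLATORY_CLOCK, base = default_parameters())
}
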