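#' @importFrom utils modifyList
NULL

# In-silico reproductions of the canonical photoadaptation experiments.
# Every report is a pure function of (parameters, protocol settings); no
# randomness is involved, so a report regenerates bit-identically from its
# recorded config.

new_report <- function(id, variants, protocol, metrics, trajectories,
                       config) {
  structure(list(id = id, variants = variants, protocol = protocol,
                 metrics = metrics, trajectories = trajectories,
                 config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment '", x$id, "' (variants: ",
      paste(x$variants, collapse = ", "), ")\n", sep = "")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Write an experiment report to disk
#'
#' @param report an `experiment_report`.
#' @param dir output directory (created if needed); the metrics table goes
#'   to `<id>_metrics.csv` and each trajectory to `<id>_<name>.csv`.
#' @return Invisibly, the metrics file path.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mpath <- file.path(dir, paste0(report$id, "_metrics.csv"))
  utils::write.csv(report$metrics, mpath, row.names = FALSE)
  for (nm in names(report$trajectories))
    utils::write.csv(report$trajectories[[nm]],
                     file.path(dir, paste0(report$id, "_", nm, ".csv")),
                     row.names = FALSE)
  invisible(mpath)
}

# step response heights above the pre-step level, for one mRNA species
.step_responses <- function(tr, step_times, t_end, species = "m_vvd") {
  bounds <- c(step_times, t_end)
  out <- lapply(seq_along(step_times), function(k) {
    w <- c(bounds[k], bounds[k + 1])
    v0 <- tr$state[which.min(abs(tr$time - w[1])), species]
    pk <- peak_metrics(tr, species, w)
    data.frame(step = k, peak_time = pk$peak_time,
               peak_value = pk$peak_value,
               response = pk$peak_value - v0)
  })
  do.call(rbind, out)
}

#' Light-staircase experiment
#'
#' Simulates the three-step light-induction protocol (2, 20, 200
#' umol m^-2 s^-1) for the given variants and reports per-step vvd-mRNA
#' peak heights, peak times and the step-2/step-1 and step-3/step-1
#' response ratios — the staircase readout of repeated responsiveness.
#'
#' @param params a `model_parameters` vector.
#' @param variants variants to simulate.
#' @param protocol the staircase protocol.
#' @param t_end end of simulation (minutes).
#' @return An `experiment_report`; metrics has one row per variant.
#' @export
exp_lightstep <- function(params, variants = c("wild_type", "vvd_null",
                                               "slow_cycling"),
                          protocol = lightstep_protocol(), t_end = 1460) {
  params <- as_model_parameters(params)
  grid <- seq(0, t_end, by = 2)
  rows <- list(); trajs <- list()
  for (v in variants) {
    tr <- simulate_trajectory(params, v, protocol, grid)
    st <- .step_responses(tr, protocol$start_time, t_end)
    rows[[v]] <- data.frame(
      variant = v,
      peak1_time = st$peak_time[1], peak1 = st$peak_value[1],
      peak2 = st$peak_value[2], peak3 = st$peak_value[3],
      ratio_step2 = st$response[2] / st$response[1],
      ratio_step3 = st$response[3] / st$response[1])
    trajs[[v]] <- as.data.frame(tr)
  }
  new_report("lightstep", variants, protocol, do.call(rbind, rows),
             trajs, list(params = params, t_end = t_end))
}

#' Two-pulse refractory experiment
#'
#' Two identical light pulses separated by a dark interval; reports the
#' second/first vvd-mRNA peak ratio per variant and interval, plus the
#' recovery of the light-activatable WCC pool during the dark gap.
#'
#' @param params a `model_parameters` vector.
#' @param dark_intervals dark gaps to test (minutes); default 30 min and
#'   6 h.
#' @param variants variants to simulate.
#' @param pulse_intensity,pulse_duration pulse shape.
#' @return An `experiment_report`.
#' @export
exp_two_pulse <- function(params, dark_intervals = c(30, 360),
                          variants = c("wild_type", "vvd_null"),
                          pulse_intensity = 20, pulse_duration = 30) {
  params <- as_model_parameters(params)
  rows <- list(); trajs <- list()
  for (v in variants) for (gap in dark_intervals) {
    prot <- two_pulse_protocol(gap, pulse_intensity, pulse_duration)
    t2 <- pulse_duration + gap
    tend <- t2 + pulse_duration + 120
    tr <- simulate_trajectory(params, v, prot, seq(0, tend, by = 1))
    w <- pulse_duration + 60
    p1 <- peak_metrics(tr, "m_vvd", c(0, min(w, t2)))$peak_value
    p2 <- peak_metrics(tr, "m_vvd", c(t2, t2 + w))$peak_value
    # WCC_d recovery over the dark gap
    i_start <- which.min(abs(tr$time - pulse_duration))
    i_end <- which.min(abs(tr$time - t2))
    rows[[paste(v, gap)]] <- data.frame(
      variant = v, dark_interval = gap,
      peak1 = p1, peak2 = p2, peak_ratio = p2 / p1,
      wccd_after_pulse = tr$state[i_start, "WCC_d"],
      wccd_end_of_dark = tr$state[i_end, "WCC_d"])
    trajs[[paste0(v, "_gap", gap)]] <- as.data.frame(tr)
  }
  new_report("two_pulse", variants, NULL, do.call(rbind, rows), trajs,
             list(params = params, dark_intervals = dark_intervals,
                  pulse_intensity = pulse_intensity,
                  pulse_duration = pulse_duration))
}

#' Light-to-dark transfer experiment
#'
#' Two days of constant light followed by darkness; reports the time for
#' vvd and frq mRNA to come within 10% of their dark baselines, per
#' variant, and the long-run dark levels (frq settles at a C-box-driven
#' basal level, vvd collapses to its leak floor).
#'
#' @param params a `model_parameters` vector.
#' @param variants variants to simulate.
#' @param light_intensity growth light (default 20).
#' @param light_days days of light before transfer.
#' @param follow_min minutes of darkness simulated after the transfer.
#' @return An `experiment_report`.
#' @export
exp_light_to_dark <- function(params, variants = c("wild_type", "vvd_null"),
                              light_intensity = 20, light_days = 2,
                              follow_min = 1440) {
  params <- as_model_parameters(params)
  off <- light_days * 1440
  prot <- constant_light_protocol(light_intensity, lights_off = off)
  rows <- list(); trajs <- list()
  for (v in variants) {
    # integrate through the whole light phase so the transfer state is the
    # true constant-light steady state
    grid <- c(seq(0, off - 10, by = 30), seq(off - 8, off + follow_min,
                                             by = 2))
    tr_full <- simulate_trajectory(params, v, prot, grid)
    keep <- tr_full$time >= off - 10
    tr <- tr_full
    tr$time <- tr_full$time[keep]
    tr$state <- tr_full$state[keep, , drop = FALSE]
    res <- sapply(c(vvd = "m_vvd", frq = "m_frq"), function(sp) {
      vals <- tr$state[, sp]; tt <- tr$time
      sel <- tt >= off
      base <- min(vals[sel])
      v0 <- vals[which.min(abs(tt - off))]
      thr <- base + 0.1 * abs(v0 - base)
      idx <- which(sel & vals <= thr)
      if (!length(idx)) NA_real_ else tt[min(idx)] - off
    })
    iend <- nrow(tr$state)
    rows[[v]] <- data.frame(
      variant = v, t_baseline_vvd = res[["vvd"]],
      t_baseline_frq = res[["frq"]],
      dark_level_vvd = tr$state[iend, "m_vvd"],
      dark_level_frq = tr$state[iend, "m_frq"])
    trajs[[v]] <- as.data.frame(tr)
  }
  new_report("light_to_dark", variants, prot, do.call(rbind, rows), trajs,
             list(params = params, light_intensity = light_intensity,
                  light_days = light_days, follow_min = follow_min))
}

#' Steady-state dose-response experiment
#'
#' vvd mRNA after 48 h of constant light at each intensity, normalized to
#' the level at the lowest intensity, for the wild type, the slow-cycling
#' variant and the vvd-null mutant.
#'
#' @param params a `model_parameters` vector.
#' @param intensities light levels (umol m^-2 s^-1).
#' @param growth_hours constant-light growth time before reading the
#'   steady state (default 48 h).
#' @return An `experiment_report`; metrics has one row per
#'   variant x intensity with the normalized level.
#' @export
exp_dose_response <- function(params, intensities = c(2, 20, 200),
                              growth_hours = 48) {
  params <- as_model_parameters(params)
  t_read <- growth_hours * 60
  variants <- c("wild_type", "slow_cycling", "vvd_null")
  rows <- list()
  for (v in variants) {
    lev <- vapply(intensities, function(I)
      simulate_trajectory(params, v, constant_light_protocol(I),
                          c(0, t_read))$state[2, "m_vvd"], 0)
    rows[[v]] <- data.frame(variant = v, intensity = intensities,
                            vvd_mrna = lev,
                            normalized = lev / lev[1])
  }
  new_report("dose_response", variants, NULL, do.call(rbind, rows),
             list(), list(params = params, intensities = intensities,
                          growth_hours = growth_hours))
}

#' Futile-cycle (slow-cycling) experiment
#'
#' Compares the slow-cycling model against wild type and vvd-null on the
#' light staircase: identity of the first vvd-mRNA peak, loss of the
#' step-2 response, the size of the light-activatable WCC pool under
#' constant light, and the net flux through the WCC*-VVD* association/
#' dissociation reaction during the adaptation phase and at steady state
#' (forward throughout: back-dissociation never fuels the activatable
#' pool; the futile cycle runs through photoadduct decay instead).
#'
#' @param params a `model_parameters` vector.
#' @param pool_intensity light level for the steady-state pool comparison.
#' @return An `experiment_report`.
#' @export
exp_slow_cycle <- function(params, pool_intensity = 20) {
  params <- as_model_parameters(params)
  prot <- lightstep_protocol()
  grid <- seq(0, 1460, by = 1)
  tr_wt <- simulate_trajectory(params, "wild_type", prot, grid)
  tr_sc <- simulate_trajectory(params, "slow_cycling", prot, grid)
  st_wt <- .step_responses(tr_wt, prot$start_time, 1460)
  st_sc <- .step_responses(tr_sc, prot$start_time, 1460)
  pool <- vapply(c(wild_type = "wild_type", slow_cycling = "slow_cycling",
                   vvd_null = "vvd_null"), function(v)
    simulate_trajectory(params, v, constant_light_protocol(pool_intensity),
                        c(0, 2880))$state[2, "WCC_d"], 0)
  # net heterodimer flux l1*WCC_a*VVD_a - lm1*HET in the wild type:
  # during the adaptation phase (shortly after the first step) and at the
  # constant-light steady state
  het_flux <- function(state) {
    fl <- reaction_fluxes(pmax(state, 0), params, 0)  # mass-action parts
    # association/dissociation do not depend on intensity
    unname(fl["het_association"] - fl["het_dissociation"])
  }
  i_adapt <- which.min(abs(tr_wt$time - 60))
  ss <- simulate_trajectory(params, "wild_type",
                            constant_light_protocol(pool_intensity),
                            c(0, 2880))$state[2, ]
  metrics <- data.frame(
    first_peak_wt = st_wt$peak_value[1],
    first_peak_sc = st_sc$peak_value[1],
    first_peak_rel_diff = abs(st_sc$peak_value[1] - st_wt$peak_value[1]) /
      st_wt$peak_value[1],
    ratio_step2_wt = st_wt$response[2] / st_wt$response[1],
    ratio_step2_sc = st_sc$response[2] / st_sc$response[1],
    pool_wt = pool[["wild_type"]], pool_sc = pool[["slow_cycling"]],
    pool_nv = pool[["vvd_null"]],
    het_net_flux_adaptation = het_flux(tr_wt$state[i_adapt, ]),
    het_net_flux_steady = het_flux(ss))
  new_report("slow_cycle", c("wild_type", "slow_cycling", "vvd_null"),
             prot, metrics,
             list(wild_type = as.data.frame(tr_wt),
                  slow_cycling = as.data.frame(tr_sc)),
             list(params = params, pool_intensity = pool_intensity))
}

#' Adaptation-motif scan over the simplified model
#'
#' Scans a 2-D grid of VVD production rate (`pv`) and complex
#' photoadduct-decay rate (`kc`) of the simplified WCC-VVD model under a
#' two-step light protocol, classifying each point as `no_adaptation`
#' (activated WCC does not settle back below half its first peak),
#' `adaptation_only` (settles, but no second-step response), or
#' `full_motif` (settles and responds to the step-up).
#'
#' @param pv_grid,kc_grid grids of production / complex-decay rates.
#' @param base_params a [simplified_parameters()] vector supplying the
#'   remaining rates.
#' @param step_protocol two-step protocol (default 2 then 20
#'   umol m^-2 s^-1 at t = 0 and 1440 min).
#' @param adapt_threshold settled/peak ratio defining adaptation
#'   (default 0.5).
#' @param response_threshold step-2/step-1 response ratio defining
#'   re-responsiveness (default 0.2).
#' @return An `experiment_report`; metrics has one row per grid point.
#' @export
exp_adaptation_scan <- function(pv_grid = 10^seq(-3, 0, length.out = 7),
                                kc_grid = 10^seq(-4, -1, length.out = 7),
                                base_params = simplified_parameters(),
                                step_protocol = light_protocol(c(0, 1440),
                                                               c(2, 20)),
                                adapt_threshold = 0.5,
                                response_threshold = 0.2) {
  grid <- expand.grid(pv = pv_grid, kc = kc_grid)
  step2 <- step_protocol$start_time[2]
  tend <- step2 + 720
  tt <- seq(0, tend, by = 2)
  cls <- character(nrow(grid))
  r2 <- numeric(nrow(grid)); settle <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- base_params
    p["pv"] <- grid$pv[i]; p["kc"] <- grid$kc[i]
    tr <- simulate_simplified(p, step_protocol, tt)
    a <- tr$state[, "WCC_a"]
    w1 <- tt <= step2
    pk1 <- max(a[w1])
    v_settle <- a[which.min(abs(tt - step2))]
    pk2 <- max(a[!w1]) - v_settle
    settle[i] <- v_settle / pk1
    r2[i] <- pk2 / pk1
    cls[i] <- if (settle[i] > adapt_threshold) "no_adaptation"
      else if (r2[i] < response_threshold) "adaptation_only"
      else "full_motif"
  }
  metrics <- cbind(grid, settled_fraction = settle, step2_ratio = r2,
                   class = cls)
  new_report("adaptation_scan", "simplified", step_protocol, metrics,
             list(),
             list(base_params = base_params, pv_grid = pv_grid,
                  kc_grid = kc_grid, adapt_threshold = adapt_threshold,
                  response_threshold = response_threshold))
}

#' Free-running rhythm after light-to-dark transfer
#'
#' Simulates the light-to-dark protocol followed by several days of
#' darkness and reports the free-running frq-mRNA period and the phase of
#' the first dark peak for wild type and vvd-null, plus the mutant's phase
#' delay.
#'
#' @param params a `model_parameters` vector.
#' @param light_days days of constant light (20 umol m^-2 s^-1) before the
#'   transfer.
#' @param dd_days days of darkness simulated.
#' @return An `experiment_report`.
#' @export
exp_dd_phase <- function(params, light_days = 2, dd_days = 6) {
  params <- as_model_parameters(params)
  off <- light_days * 1440
  prot <- constant_light_protocol(20, lights_off = off)
  rows <- list()
  for (v in c("wild_type", "vvd_null")) {
    grid <- c(seq(0, off - 30, by = 30),
              seq(off, off + dd_days * 1440, by = 10))
    tr <- simulate_trajectory(params, v, prot, grid)
    pp <- circadian_phase_and_period(tr, "m_frq", transfer_time = off)
    rows[[v]] <- data.frame(variant = v, period_h = pp$period_h,
                            phase_h = pp$phase_h)
  }
  metrics <- do.call(rbind, rows)
  metrics$phase_delay_h <- metrics$phase_h - metrics$phase_h[1]
  new_report("dd_phase", c("wild_type", "vvd_null"), prot, metrics,
             list(), list(params = params, light_days = light_days,
                          dd_days = dd_days))
}
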