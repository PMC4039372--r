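p_default <- default_parameters()

test_that("light staircase: wild type keeps responding, mutants do not", {
  rep <- exp_lightstep(p_default)
  m <- rep$metrics
  wt <- m[m$variant == "wild_type", ]
  nv <- m[m$variant == "vvd_null", ]
  sc <- m[m$variant == "slow_cycling", ]
  expect_lte(wt$peak1_time, 30)
  expect_gt(wt$ratio_step2, 0.2)
  expect_gt(wt$ratio_step3, 0.2)
  expect_lt(nv$ratio_step2, wt$ratio_step2 / 3)
  expect_lt(sc$ratio_step2, 0.2)
  expect_lt(nv$ratio_step3, 0.2)
})

test_that("dose response: wild type rises, mutants stay near flat", {
  rep <- exp_dose_response(p_default)
  m <- rep$metrics
  wt <- m[m$variant == "wild_type", ]
  sc <- m[m$variant == "slow_cycling", ]
  nv <- m[m$variant == "vvd_null", ]
  expect_gt(wt$normalized[wt$intensity == 200], 3)
  expect_lt(sc$normalized[sc$intensity == 200],
            wt$normalized[wt$intensity == 200] / 2)
  expect_lt(abs(nv$normalized[nv$intensity == 200] - 1), 0.35)
  # monotone rise in the wild type
  expect_true(all(diff(wt$normalized) > 0))
})

test_that("two-pulse experiment shows VVD-dependent refractoriness", {
  rep <- exp_two_pulse(p_default)
  m <- rep$metrics
  wt30 <- m[m$variant == "wild_type" & m$dark_interval == 30, ]
  wt360 <- m[m$variant == "wild_type" & m$dark_interval == 360, ]
  nv30 <- m[m$variant == "vvd_null" & m$dark_interval == 30, ]
  expect_lt(wt30$peak_ratio, 0.35)         # suppressed after 30 min dark
  expect_gt(wt360$peak_ratio, wt30$peak_ratio)  # restored by 6 h dark
  expect_gt(nv30$peak_ratio, 0.5)          # mutant responds immediately
  # light-activatable pool recovers faster in the wild type
  expect_gt(wt360$wccd_end_of_dark,
            m[m$variant == "vvd_null" & m$dark_interval == 360,
              "wccd_end_of_dark"])
})

test_that("light-to-dark shut-off is fast in wt, slow in the mutant", {
  rep <- exp_light_to_dark(p_default)
  m <- rep$metrics
  wt <- m[m$variant == "wild_type", ]
  nv <- m[m$variant == "vvd_null", ]
  expect_lte(wt$t_baseline_vvd, 60)
  expect_gt(nv$t_baseline_frq, 2 * wt$t_baseline_frq)
  expect_gt(nv$t_baseline_frq, 120)
  # long-run darkness: frq keeps a C-box basal level, vvd collapses
  expect_gt(wt$dark_level_frq, 10 * wt$dark_level_vvd)
})

test_that("slow-cycling model: first response intact, futile cycle broken", {
  rep <- exp_slow_cycle(p_default)
  m <- rep$metrics
  expect_lt(m$first_peak_rel_diff, 0.02)
  expect_lt(m$ratio_step2_sc, m$ratio_step2_wt / 2)
  expect_gt(m$pool_wt, 2 * m$pool_sc)
  # stabilized heterodimer leaves the pool near the vvd-null level
  expect_lt(abs(log(m$pool_sc / m$pool_nv)), log(15))
  # heterodimer association runs forward during adaptation and never
  # reverses: dissociation cannot fuel the activatable pool
  expect_gt(m$het_net_flux_adaptation, 0)
  expect_gte(m$het_net_flux_steady, 0)
})

test_that("adaptation scan classifies the simplified-model grid sensibly", {
  rep <- exp_adaptation_scan(pv_grid = c(0, 0.01, 0.05, 0.2),
                             kc_grid = c(1e-5, 1e-3, 1e-2, 5e-2))
  m <- rep$metrics
  # no VVD production: never adapts, anywhere on that axis
  expect_true(all(m$class[m$pv == 0] == "no_adaptation"))
  # substantial production but (near) frozen complex decay: inhibition
  # without re-responsiveness, the slow-cycling phenotype
  expect_true("adaptation_only" %in%
                m$class[m$pv == 0.05 & m$kc <= 1e-3])
  # high production and fast decay: the full motif
  expect_equal(m$class[m$pv == 0.2 & m$kc == 5e-2], "full_motif")
  # monotone severity along the kc axis at high production: once the
  # motif is complete it stays complete as kc grows
  sev <- c(no_adaptation = 0, adaptation_only = 1, full_motif = 2)
  for (pv in unique(m$pv[m$pv > 0])) {
    s <- sev[m$class[m$pv == pv][order(m$kc[m$pv == pv])]]
    expect_true(all(diff(s) >= 0), label = paste("monotone in kc at pv", pv))
  }
})

test_that("experiment reports regenerate identically from their config", {
  r1 <- exp_dose_response(p_default, intensities = c(2, 20))
  r2 <- do.call(exp_dose_response, c(list(r1$config$params),
                                     r1$config["intensities"]))
  expect_identical(r1$metrics, r2$metrics)
})

test_that("reports write a metrics table and trajectory exports", {
  dir <- withr::local_tempdir()
  rep <- exp_dose_response(p_default, intensities = c(2, 20))
  write_report(rep, dir)
  m <- utils::read.csv(file.path(dir, "dose_response_metrics.csv"))
  expect_equal(nrow(m), 6)
  expect_true(all(c("variant", "intensity", "normalized") %in% names(m)))
})
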