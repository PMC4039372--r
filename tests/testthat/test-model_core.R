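test_that("rhs equals stoichiometry matrix times reaction fluxes", {
  set.seed(1)
  p <- default_parameters()
  S <- stoichiometry_matrix()
  for (i in 1:1000) {
    y <- random_state()
    I <- runif(1, 0, 200)
    fl <- reaction_fluxes(y, p, I)
    expect_equal(drop(S %*% fl),
                 model_rhs(y, 0, p, light_protocol(0, I)),
                 tolerance = 1e-12)
  }
})

test_that("compiled right-hand side matches the R reference exactly", {
  set.seed(2)
  p <- default_parameters()
  for (i in 1:200) {
    y <- random_state()
    I <- sample(c(0, 2, 20, 200), 1)
    r_ref <- model_rhs(y, 0, p, light_protocol(0, I))
    r_c <- vvdadapt:::compiled_rhs(y, p, I)
    expect_equal(r_c, r_ref, tolerance = 1e-12)
  }
})

test_that("at an all-zero state only the basal transcription fluxes fire", {
  fl <- reaction_fluxes(zero_state(), default_parameters(), 20)
  nonzero <- names(fl)[fl > 0]
  expect_setequal(nonzero, c("tx_wc1_basal", "tx_vvd_basal"))
})

test_that("in darkness the light-activation and WCC-driven vvd fluxes vanish", {
  # VVD-free dark state: activated species absent, WCC dark forms present
  y <- zero_state()
  y["m_wc1"] <- 0.1; y["WCC_d"] <- 1.5; y["WCC_p"] <- 0.3
  fl <- reaction_fluxes(y, default_parameters(), 0)
  expect_equal(unname(fl["wcc_activation"]), 0)
  expect_equal(unname(fl["vvd_activation"]), 0)
  # no dark, WCC-driven activation of vvd (the LRE needs the light-activated
  # homodimer); only the constitutive leak remains
  expect_equal(unname(fl["tx_vvd_lre"]), 0)
  expect_gt(unname(fl["tx_frq_cbox"]), 0)
})

test_that("negative concentrations are rejected as invalid states", {
  y <- zero_state(); y["FRQ_c"] <- -0.1
  expect_error(reaction_fluxes(y, default_parameters(), 0),
               "invalid state.*FRQ_c")
})

test_that("WC-1 bookkeeping: total WC-1 change = translation - degradation", {
  set.seed(3)
  p <- default_parameters()
  for (i in 1:50) {
    y <- random_state()
    I <- runif(1, 0, 200)
    d <- model_rhs(y, 0, p, light_protocol(0, I))
    fl <- reaction_fluxes(y, p, I)
    total_wc1_change <- d["WCC_d"] + d["WCC_a"] + 2 * d["WCC_aa"] +
      d["WCC_p"] + d["HET"]
    expected <- fl["tl_wc1"] - fl["deg_wcc_d"] - fl["deg_wcc_a"] -
      2 * fl["deg_wcc_aa"] - fl["deg_wcc_p"] - fl["deg_het"]
    expect_equal(unname(total_wc1_change), unname(expected),
                 tolerance = 1e-10)
  }
})

test_that("the VVD-free subspace is absorbing in the vvd-null variant", {
  p <- apply_variant(default_parameters(), "vvd_null")
  y <- random_state()
  y[c("VVD_d", "VVD_a", "VVD_aa", "HET")] <- 0
  d <- model_rhs(y, 0, p, light_protocol(0, 200))
  expect_equal(unname(d[c("VVD_d", "VVD_a", "VVD_aa", "HET")]),
               c(0, 0, 0, 0))
})

test_that("with light off and no activated species, none appear", {
  p <- default_parameters()
  y <- zero_state()
  y[c("m_wc1", "m_frq", "m_vvd")] <- c(0.1, 0.2, 0.01)
  y[c("WCC_d", "FRQ_c", "VVD_d")] <- c(1, 0.5, 0.2)
  tr <- simulate_trajectory(p, "wild_type", light_protocol(),
                            seq(0, 500, 50), initial = y)
  activated <- tr$state[, c("WCC_a", "WCC_aa", "VVD_a", "VVD_aa", "HET")]
  expect_true(all(abs(activated) < 1e-12))
})
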