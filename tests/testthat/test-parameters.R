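test_that("variant transforms change exactly the documented fields", {
  p <- default_parameters()

  expect_identical(apply_variant(p, "wild_type"), p)

  sc <- apply_variant(p, model_variant("slow_cycling",
                                       slow_cycling_factor = 10))
  changed <- names(p)[as.numeric(sc) != as.numeric(p)]
  expect_identical(changed, "l5")
  expect_equal(unname(sc["l5"]), unname(p["l5"]) / 10)

  nv <- apply_variant(p, "vvd_null")
  changed <- names(p)[as.numeric(nv) != as.numeric(p)]
  expect_identical(changed, "ktl_vvd")
  expect_equal(unname(nv["ktl_vvd"]), 0)
  # vvd gene transcription machinery untouched: the mutant allele is
  # transcribed, only the protein is missing
  expect_identical(nv[c("vmax_vvd", "K_vvd", "bas_vvd", "dm_vvd")],
                   p[c("vmax_vvd", "K_vvd", "bas_vvd", "dm_vvd")])
})

test_that("slow_cycling_factor scales l5 as requested", {
  p <- default_parameters()
  sc <- apply_variant(p, model_variant("slow_cycling",
                                       slow_cycling_factor = 4))
  expect_equal(unname(sc["l5"]), unname(p["l5"]) / 4)
})

test_that("parameter construction validates values and names", {
  expect_error(model_parameters(nonexistent_rate = 1), "unknown parameter")
  expect_error(model_parameters(ka_wcc = -1), ">= 0")
  expect_error(model_parameters(K_vvd = 0), "> 0")
  p <- model_parameters(l1 = 3.5)
  expect_equal(unname(p["l1"]), 3.5)
  expect_s3_class(p, "model_parameters")
})

test_that("parameter sets round-trip through YAML text files", {
  p <- model_parameters(l5 = 0.01234567890123, ka_wcc = 1e-7)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, path)
  p2 <- read_parameters(path)
  expect_equal(as.numeric(p2), as.numeric(p), tolerance = 1e-12)
  expect_identical(names(unclass(p2)), model_parameter_names())
})

test_that("unknown keys in a parameter file are rejected", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("ka_wcc: 0.1", "bogus_rate: 3"), path)
  expect_error(read_parameters(path), "bogus_rate")
})

test_that("VVD-related and non-VVD parameter sets partition the rates", {
  expect_length(intersect(vvd_parameter_names(),
                          non_vvd_parameter_names()), 0)
  expect_setequal(c(vvd_parameter_names(), non_vvd_parameter_names(),
                    "hill_lre", "hill_cbox"),
                  model_parameter_names())
})

test_that("the packaged parameter file matches the calibrated defaults", {
  path <- system.file("extdata", "calibrated_params.yaml",
                      package = "vvdadapt")
  expect_true(nzchar(path))
  expect_equal(as.numeric(read_parameters(path)),
               as.numeric(default_parameters()), tolerance = 1e-12)
})
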