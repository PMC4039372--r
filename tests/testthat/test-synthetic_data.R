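test_that("noise-free generation reproduces the model output exactly", {
  p <- default_parameters()
  ds <- generate_timecourse(p, strains = "wt",
                            protocol = light_protocol(0, 2),
                            sample_times = c(0, 30, 60, 120),
                            noise_cv = 0, probe_efficiencies =
                              c(vvd = 1, frq = 1, wc1 = 1),
                            n_replicates = 1, seed = 1)
  tr <- simulate_trajectory(p, "wild_type", light_protocol(0, 2),
                            c(0, 30, 60, 120))
  norm <- tr$state[1, "m_vvd"]
  for (g in c("vvd", "frq", "wc1")) {
    sp <- c(vvd = "m_vvd", frq = "m_frq", wc1 = "m_wc1")[[g]]
    obs <- ds$data$level[ds$data$gene == g]
    expect_equal(obs, unname(tr$state[, sp] / norm), tolerance = 1e-10)
  }
})

test_that("the lognormal noise model has the requested CV", {
  # Monte-Carlo check: many replicates at a single time point
  p <- default_parameters()
  ds <- generate_timecourse(p, strains = "wt",
                            protocol = light_protocol(0, 2),
                            sample_times = c(0, 30), noise_cv = 0.2,
                            n_replicates = 10000, seed = 9)
  x <- ds$data$level[ds$data$gene == "frq" & ds$data$time == 30]
  emp_cv <- sd(x) / mean(x)
  expect_lt(abs(emp_cv - 0.2) / 0.2, 0.05)
})

test_that("normalization anchors mean wild-type vvd at t = 0 to one", {
  ds <- generate_timecourse(default_parameters(), noise_cv = 0.3,
                            seed = 10)
  wt0 <- ds$data$level[ds$data$strain == "wt" & ds$data$gene == "vvd" &
                         ds$data$time == 0]
  expect_equal(mean(wt0), 1, tolerance = 1e-12)
  expect_true(all(ds$data$level > 0))
})

test_that("identical seeds give identical datasets, different seeds differ", {
  p <- default_parameters()
  a <- generate_timecourse(p, seed = 11)
  b <- generate_timecourse(p, seed = 11)
  expect_identical(a$data, b$data)
  c <- generate_timecourse(p, seed = 12)
  expect_false(identical(a$data$level, c$data$level))
})

test_that("datasets round-trip through CSV with metadata sidecar", {
  ds <- generate_timecourse(default_parameters(), seed = 13,
                            sample_times = c(0, 30, 60))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  ds2 <- read_dataset(path)
  expect_equal(ds2$data$level, ds$data$level, tolerance = 1e-12)
  expect_equal(ds2$data[c("time", "strain", "gene", "replicate")],
               ds$data[c("time", "strain", "gene", "replicate")])
  expect_equal(as.data.frame(ds2$meta$protocol),
               as.data.frame(ds$meta$protocol))
  expect_equal(as.numeric(ds2$meta$true_params),
               as.numeric(ds$meta$true_params), tolerance = 1e-12)
})

test_that("reading is keyed by column names, not order", {
  ds <- generate_timecourse(default_parameters(), seed = 14,
                            sample_times = c(0, 30))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  df <- utils::read.csv(path)
  utils::write.csv(df[, rev(names(df))], path, row.names = FALSE,
                   quote = FALSE)
  ds2 <- read_dataset(path)
  expect_equal(ds2$data$level, ds$data$level, tolerance = 1e-12)
})

test_that("malformed dataset files are rejected with row information", {
  ds <- generate_timecourse(default_parameters(), seed = 15,
                            sample_times = c(0, 30))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  df <- utils::read.csv(path)

  bad <- df; bad$level[3] <- -1
  utils::write.csv(bad, path, row.names = FALSE, quote = FALSE)
  expect_error(read_dataset(path), "row 3")

  utils::write.csv(df[, setdiff(names(df), "gene")], path,
                   row.names = FALSE, quote = FALSE)
  expect_error(read_dataset(path), "missing column.*gene")

  dup <- rbind(df, df[1, ])
  utils::write.csv(dup, path, row.names = FALSE, quote = FALSE)
  expect_error(read_dataset(path), "duplicate")
})
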