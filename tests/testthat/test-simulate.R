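test_that("the dark fixed point is stationary without the clock feedback", {
  p <- clockless_params()
  ss <- steady_state(p, "wild_type", constant_intensity = 0)
  expect_false(ss$oscillatory)
  expect_true(ss$converged)
  # re-simulate 48 h of darkness from the fixed point: nothing moves
  tr <- simulate_trajectory(p, "wild_type", light_protocol(),
                            seq(0, 2880, 60), initial = ss$state)
  drift <- apply(abs(sweep(tr$state, 2, tr$state[1, ])), 2, max)
  expect_lt(max(drift / pmax(abs(ss$state), 1e-6)), 1e-5)
})

test_that("steady state re-simulated stays put (self-consistency)", {
  p <- default_parameters()
  ss <- steady_state(p, "wild_type", constant_intensity = 20)
  expect_false(ss$oscillatory)
  tr <- simulate_trajectory(p, "wild_type", constant_light_protocol(20),
                            c(0, 1000), initial = ss$state)
  rel <- abs(tr$state[2, ] - ss$state) / pmax(abs(ss$state), 1e-8)
  expect_lt(max(rel), 1e-4)
})

test_that("lsoda solution matches a fixed-step RK4 integration", {
  # independent integrator: classical RK4 at dt = 0.01 min over the
  # compiled derivative evaluator
  p <- default_parameters()
  y0 <- dark_equilibrated_state(p)
  I <- 2
  dt <- 0.01
  t_end <- 200
  y <- y0
  for (i in seq_len(t_end / dt)) {
    k1 <- vvdadapt:::compiled_rhs(y, p, I)
    k2 <- vvdadapt:::compiled_rhs(y + dt / 2 * k1, p, I)
    k3 <- vvdadapt:::compiled_rhs(y + dt / 2 * k2, p, I)
    k4 <- vvdadapt:::compiled_rhs(y + dt * k3, p, I)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  tr <- simulate_trajectory(p, "wild_type", light_protocol(0, I),
                            c(0, t_end), initial = y0)
  rel <- abs(tr$state[2, ] - y) / pmax(abs(y), 1e-8)
  expect_lt(max(rel), 1e-5)
})

test_that("trajectories stay non-negative from random non-negative starts", {
  set.seed(5)
  p <- default_parameters()
  for (i in 1:5) {
    y0 <- random_state()
    tr <- simulate_trajectory(p, "wild_type", lightstep_protocol(),
                              seq(0, 1440, 20), initial = y0)
    expect_gt(min(tr$state), -1e-8)
  }
})

test_that("refining the output grid does not change shared points", {
  p <- default_parameters()
  coarse <- simulate_trajectory(p, "wild_type", lightstep_protocol(),
                                seq(0, 600, 50))
  fine <- simulate_trajectory(p, "wild_type", lightstep_protocol(),
                              seq(0, 600, 10))
  shared <- match(coarse$time, fine$time)
  rel <- abs(fine$state[shared, ] - coarse$state) /
    pmax(abs(coarse$state), 1e-8)
  expect_lt(max(rel), 1e-5)
})

test_that("peak metrics find the right extrema", {
  # monotone rising signal peaks at the window end
  sig <- list(time = 0:100, value = (0:100)^1.5)
  pm <- peak_metrics(sig, window = c(0, 100))
  expect_equal(pm$peak_time, 100)
  expect_equal(pm$terminal_value, pm$peak_value)
  # constructed triangle peaking at t = 30
  tri <- list(time = 0:100, value = 30 - abs(30 - (0:100)))
  expect_equal(peak_metrics(tri, window = c(0, 100))$peak_time, 30)
  # agreement with a dense-grid argmax oracle on random smooth signals
  set.seed(6)
  for (i in 1:10) {
    tt <- seq(0, 10, by = 0.01)
    a <- runif(3); b <- runif(3, 0.5, 3)
    f <- function(t) a[1] * sin(b[1] * t) + a[2] * sin(b[2] * t + 1) +
      a[3] * sin(b[3] * t + 2)
    pm <- peak_metrics(list(time = tt, value = f(tt)), window = c(0, 10))
    expect_equal(pm$peak_time, tt[which.max(f(tt))])
  }
  expect_error(peak_metrics(sig, window = c(200, 300)), "empty window")
})

test_that("circadian analysis recovers the period of a synthetic rhythm", {
  tt <- seq(0, 5 * 22 * 60, by = 10)
  sig <- list(time = tt, value = 2 + sin(2 * pi * tt / (22 * 60)))
  out <- circadian_phase_and_period(sig, transfer_time = 0)
  expect_equal(out$period_h, 22, tolerance = 0.01)
  expect_equal(out$phase_h, 22 / 4, tolerance = 0.05)
  flat <- list(time = tt, value = rep(1, length(tt)))
  expect_error(circadian_phase_and_period(flat), "oscillation")
})

test_that("a non-degradable inhibitor makes the refractory period exceed a day", {
  p <- model_parameters(dg_vvd_d = 0, dg_vvd_a = 0, dg_vvd_aa = 0)
  # VVD-free dark start: the inhibitor made during pulse 1 then persists
  # forever, so the photosystem never recovers
  y0 <- dark_equilibrated_state(apply_variant(p, "vvd_null"))
  expect_equal(refractory_period(p, "wild_type", max_interval = 1440,
                                 initial = y0), Inf)
})
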