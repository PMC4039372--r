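#' @importFrom deSolve ode
NULL

new_trajectory <- function(time, state, protocol, variant, params) {
  structure(list(time = time, state = state, protocol = protocol,
                 variant = variant, params = params),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Model trajectory: ", length(x$time), " time points, t in [",
      min(x$time), ", ", max(x$time), "] min, variant ",
      x$variant$kind, "\n", sep = "")
  invisible(x)
}

#' Tidy export of a trajectory
#'
#' @param x a trajectory from [simulate_trajectory()].
#' @param ... unused.
#' @return A long data.frame with columns `time`, `variant`, `species`,
#'   `value`.
#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time = rep(x$time, times = ncol(x$state)),
             variant = x$variant$kind,
             species = rep(colnames(x$state), each = length(x$time)),
             value = as.vector(x$state),
             row.names = NULL)
}

# Integrate the compiled model over one constant-intensity span.
.integrate_span <- function(y0, times, params, intensity, rtol, atol,
                            func = "vvd_derivs", initfunc = "vvd_initmod") {
  if (length(times) == 1) return(matrix(y0, nrow = 1))
  out <- deSolve::ode(y = y0, times = times, func = func,
                      parms = c(as.numeric(params), intensity),
                      dllname = "vvdadapt", initfunc = initfunc,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    stop("ODE solver failed near t = ", max(out[, 1]),
         " min (intensity ", intensity, ")")
  unname(out[, -1, drop = FALSE])
}

# Piecewise integration across the protocol's constant-intensity segments.
.simulate_core <- function(y0, t_grid, params, protocol, rtol, atol,
                           func = "vvd_derivs", initfunc = "vvd_initmod") {
  t0 <- t_grid[1]
  tend <- t_grid[length(t_grid)]
  breaks <- protocol$start_time
  breaks <- breaks[breaks > t0 & breaks < tend]
  bounds <- unique(c(t0, breaks, tend))
  nsp <- length(y0)
  res <- matrix(NA_real_, nrow = length(t_grid), ncol = nsp)
  if (t_grid[1] == t0) res[1, ] <- y0
  y <- y0
  for (k in seq_len(length(bounds) - 1)) {
    a <- bounds[k]; b <- bounds[k + 1]
    inside <- t_grid[t_grid > a & t_grid <= b]
    times <- unique(c(a, inside, b))
    out <- .integrate_span(y, times, params, intensity_at(protocol, a),
                           rtol, atol, func, initfunc)
    y <- pmax(out[nrow(out), ], 0)  # clip solver round-off below zero
    if (length(inside))
      res[match(inside, t_grid), ] <- out[match(inside, times), ]
  }
  res
}

#' Dark-equilibrated initial state
#'
#' Mirrors the culture history of the light-step experiments: growth in
#' constant light followed by transfer to constant darkness for 24 h before
#' light induction. The state is obtained by integrating to the light steady
#' state and then 24 h of darkness.
#'
#' @param params a `model_parameters` vector (variant already applied).
#' @param light_intensity growth light level (umol m^-2 s^-1), default 20.
#' @param light_hours,dark_hours pre-history durations (hours).
#' @param rtol,atol solver tolerances.
#' @return Named state vector over [model_species()].
#' @export
dark_equilibrated_state <- function(params, light_intensity = 20,
                                    light_hours = 48, dark_hours = 24,
                                    rtol = 1e-8, atol = 1e-12) {
  params <- as_model_parameters(params)
  pre <- light_protocol(c(0, light_hours * 60),
                        c(light_intensity, 0))
  tend <- (light_hours + dark_hours) * 60
  st <- .simulate_core(zero_state(), c(0, tend), params, pre, rtol, atol)
  setNames(pmax(st[2, ], 0), .SPECIES)
}

#' Simulate the model under a light protocol
#'
#' Integrates the 14-species ODE system with a stiff-capable solver
#' (`lsoda`), segment by segment across the piecewise-constant light
#' protocol so that intensity switches are handled exactly.
#'
#' @param params a `model_parameters` vector (base parameter set).
#' @param variant a [model_variant()] or variant name; applied to `params`
#'   before integration.
#' @param protocol a [light_protocol()].
#' @param t_grid strictly increasing output time grid (minutes). The
#'   initial state is placed at `t_grid[1]`: protocol segments before the
#'   first grid point are never integrated, so a grid must start at (or
#'   before) the earliest event whose effect should be simulated.
#' @param initial `"dark_equilibrated"` (default; see
#'   [dark_equilibrated_state()]) or a named state vector.
#' @param rtol,atol solver tolerances (defaults 1e-8, 1e-12).
#' @return A `trajectory` object; see [as.data.frame.trajectory()].
#' @export
simulate_trajectory <- function(params, variant = "wild_type", protocol,
                                t_grid, initial = "dark_equilibrated",
                                rtol = 1e-8, atol = 1e-12) {
  params <- as_model_parameters(params)
  variant <- as_variant(variant)
  stopifnot(inherits(protocol, "light_protocol"))
  if (length(t_grid) < 2 || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing with at least 2 points")
  p <- apply_variant(params, variant)
  if (identical(initial, "dark_equilibrated")) {
    y0 <- dark_equilibrated_state(p, rtol = rtol, atol = atol)
  } else {
    y0 <- as_state(initial)
  }
  st <- .simulate_core(y0, t_grid, p, protocol, rtol, atol)
  colnames(st) <- .SPECIES
  new_trajectory(t_grid, st, protocol, variant, p)
}

#' Steady state under constant light
#'
#' Finds the attractor of the model at a fixed light intensity by long
#' integration followed by a Newton polish of the algebraic fixed-point
#' condition. In constant darkness the circadian feedback loop can sustain
#' a limit cycle; this is detected (frq-mRNA peak-to-trough ratio > 1.2
#' over the final two simulated cycles) and flagged instead of being forced
#' into a spurious fixed point.
#'
#' @param params a `model_parameters` vector.
#' @param variant variant to apply.
#' @param constant_intensity light level >= 0.
#' @param t_settle integration time used to approach the attractor (min).
#' @param tol residual tolerance on max |d state/dt|.
#' @return A list with `state` (named vector; for a limit cycle, the final
#'   integrated state), `oscillatory` (logical), `residual`, `converged`.
#' @export
steady_state <- function(params, variant = "wild_type", constant_intensity,
                         t_settle = 20000, tol = 1e-9) {
  stopifnot(constant_intensity >= 0)
  params <- as_model_parameters(params)
  variant <- as_variant(variant)
  p <- apply_variant(params, variant)
  protocol <- light_protocol(0, constant_intensity)
  y0 <- dark_equilibrated_state(p)
  st <- .simulate_core(y0, c(0, t_settle), p, protocol, 1e-10, 1e-14)
  y <- pmax(st[2, ], 0)
  # probe for sustained oscillation over two further circadian cycles
  probe_t <- seq(0, 2 * 1440, by = 10)
  probe <- .simulate_core(y, probe_t, p, protocol, 1e-8, 1e-12)
  frq <- probe[, match("m_frq", .SPECIES)]
  ptr <- if (min(frq) > 0) max(frq) / min(frq) else Inf
  if (is.finite(ptr) && ptr > 1.2) {
    return(list(state = setNames(y, .SPECIES), oscillatory = TRUE,
                residual = NA_real_, converged = FALSE))
  }
  y <- pmax(probe[nrow(probe), ], 0)
  # Newton polish on the reference right-hand side
  y <- setNames(y, .SPECIES)
  for (it in 1:20) {
    f <- model_rhs(y, 0, p, protocol)
    if (max(abs(f)) < tol) break
    J <- .rhs_jacobian(y, p, constant_intensity)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    y_new <- y + step
    if (any(y_new < -1e-12)) {
      y_new <- pmax(y_new, 0)
    }
    f_new <- model_rhs(pmax(y_new, 0), 0, p, protocol)
    if (max(abs(f_new)) >= max(abs(f))) break
    y <- setNames(pmax(y_new, 0), .SPECIES)
  }
  res <- max(abs(model_rhs(y, 0, p, protocol)))
  if (res > sqrt(tol))
    warning("steady_state: residual ", signif(res, 3), " exceeds tolerance")
  list(state = y, oscillatory = FALSE, residual = res,
       converged = res < sqrt(tol))
}

# finite-difference Jacobian of the rhs at fixed intensity
.rhs_jacobian <- function(y, p, intensity) {
  protocol <- light_protocol(0, intensity)
  n <- length(y)
  f0 <- model_rhs(y, 0, p, protocol)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- max(1e-7, 1e-6 * abs(y[j]))
    yp <- y; yp[j] <- yp[j] + h
    J[, j] <- (model_rhs(yp, 0, p, protocol) - f0) / h
  }
  J
}

#' Peak metrics of a signal within a time window
#'
#' @param trajectory a `trajectory`, or a list/data.frame with `time` and
#'   `value` components.
#' @param species species (or observable column) name; ignored when a
#'   time/value signal is supplied.
#' @param window numeric length-2 vector `(t_min, t_max)` in minutes.
#' @return List with `peak_time`, `peak_value`, `terminal_value` (value at
#'   the window end).
#' @export
peak_metrics <- function(trajectory, species = "m_vvd",
                         window = range(trajectory$time)) {
  sig <- .as_signal(trajectory, species)
  if (length(window) != 2 || window[1] >= window[2])
    stop("window must be an increasing length-2 vector")
  sel <- sig$time >= window[1] & sig$time <= window[2]
  if (!any(sel)) stop("empty window: no trajectory points in [",
                      window[1], ", ", window[2], "]")
  tt <- sig$time[sel]; vv <- sig$value[sel]
  i <- which.max(vv)
  list(peak_time = tt[i], peak_value = vv[i],
       terminal_value = vv[length(vv)])
}

.as_signal <- function(trajectory, species) {
  if (inherits(trajectory, "trajectory")) {
    j <- match(species, colnames(trajectory$state))
    if (is.na(j)) stop("unknown species: ", species)
    list(time = trajectory$time, value = trajectory$state[, j])
  } else if (!is.null(trajectory$time) && !is.null(trajectory$value)) {
    list(time = as.numeric(trajectory$time),
         value = as.numeric(trajectory$value))
  } else stop("trajectory must be a trajectory object or a time/value list")
}

#' Refractory period of the photoresponse
#'
#' Runs the two-pulse protocol (default 20 umol m^-2 s^-1, 30-min pulses)
#' across a bisection over the dark interval and returns the smallest dark
#' interval for which the second vvd-mRNA peak reaches at least
#' `recovery_fraction` of the first peak.
#'
#' @param params a `model_parameters` vector.
#' @param variant variant to apply.
#' @param pulse_intensity,pulse_duration pulse light level and length.
#' @param recovery_fraction required second/first peak ratio, in (0, 1].
#' @param max_interval largest dark interval searched (default 24 h); if
#'   even that does not recover, `Inf` is returned (reported as "> 24 h"),
#'   not an error.
#' @param precision bisection stopping width (minutes).
#' @param initial initial state passed to [simulate_trajectory()]; the
#'   default culture history carries VVD made during the light phase, so
#'   limit cases without any pre-existing VVD need an explicit VVD-free
#'   state.
#' @return Dark interval in minutes (possibly `Inf`).
#' @export
refractory_period <- function(params, variant = "wild_type",
                              pulse_intensity = 20, pulse_duration = 30,
                              recovery_fraction = 0.5,
                              max_interval = 1440, precision = 5,
                              initial = "dark_equilibrated") {
  stopifnot(recovery_fraction > 0, recovery_fraction <= 1)
  ratio <- function(gap) {
    .two_pulse_ratio(params, variant, gap, pulse_intensity, pulse_duration,
                     initial = initial)
  }
  lo <- pulse_duration / 2
  hi <- max_interval
  if (ratio(lo) >= recovery_fraction) return(lo)
  if (ratio(hi) < recovery_fraction) return(Inf)
  while (hi - lo > precision) {
    mid <- (lo + hi) / 2
    if (ratio(mid) >= recovery_fraction) hi <- mid else lo <- mid
  }
  hi
}

# second/first vvd-mRNA peak ratio in a two-pulse protocol
.two_pulse_ratio <- function(params, variant, dark_interval,
                             pulse_intensity = 20, pulse_duration = 30,
                             species = "m_vvd",
                             initial = "dark_equilibrated") {
  prot <- two_pulse_protocol(dark_interval, pulse_intensity, pulse_duration)
  t2 <- pulse_duration + dark_interval
  tend <- t2 + pulse_duration + 120
  tr <- simulate_trajectory(params, variant, prot,
                            t_grid = seq(0, tend, by = 1),
                            initial = initial)
  w <- pulse_duration + 60  # mRNA peak lags the pulse
  p1 <- peak_metrics(tr, species, c(0, min(w, t2)))$peak_value
  p2 <- peak_metrics(tr, species, c(t2, t2 + w))$peak_value
  p2 / p1
}

#' Free-running circadian period and phase
#'
#' Detects successive maxima of frq mRNA (by default) in a
#' constant-darkness trajectory. The period is the mean inter-peak interval
#' and the phase is the time of the first maximum after the light-to-dark
#' transfer.
#'
#' @param trajectory a `trajectory` in constant darkness, or a time/value
#'   list; must span at least two peaks.
#' @param species species to analyse (default frq mRNA).
#' @param transfer_time time of the light-to-dark transfer (minutes).
#' @return List with `period_h`, `phase_h` (hours) and `peak_times` (min).
#' @export
circadian_phase_and_period <- function(trajectory, species = "m_frq",
                                       transfer_time = 0) {
  sig <- .as_signal(trajectory, species)
  sel <- sig$time >= transfer_time
  tt <- sig$time[sel]; vv <- sig$value[sel]
  pk <- .local_maxima(tt, vv)
  if (length(pk) < 2)
    stop("no sustained oscillation: fewer than 2 peaks detected")
  list(period_h = mean(diff(pk)) / 60,
       phase_h = (pk[1] - transfer_time) / 60,
       peak_times = pk)
}

# interior local maxima with quadratic refinement; small ripples below 1%
# of the signal range are ignored
.local_maxima <- function(tt, vv) {
  n <- length(vv)
  if (n < 3) return(numeric(0))
  rng <- diff(range(vv))
  if (rng <= 0) return(numeric(0))
  idx <- which(vv[2:(n - 1)] > vv[1:(n - 2)] & vv[2:(n - 1)] >= vv[3:n]) + 1
  # prominence filter relative to neighbouring minima
  keep <- vapply(idx, function(i) {
    lo <- max(1, i - 50); hi <- min(n, i + 50)
    (vv[i] - min(vv[lo:hi])) > 0.01 * rng
  }, TRUE)
  idx <- idx[keep]
  vapply(idx, function(i) {
    if (i == 1 || i == n) return(tt[i])
    # quadratic interpolation through the three bracketing samples
    y1 <- vv[i - 1]; y2 <- vv[i]; y3 <- vv[i + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom >= 0) return(tt[i])
    dt <- (tt[i + 1] - tt[i - 1]) / 2
    tt[i] + 0.5 * dt * (y1 - y3) / denom
  }, 0)
}

#' Derived observables of a trajectory
#'
#' Computes the quantities reported throughout the photoadaptation
#' analyses: normalized mRNA levels for vvd/frq/wc-1, the light-activatable
#' WCC pool (dark-form WCC), total WCC protein (WC-1 content summed over
#' all WCC species) and total VVD protein.
#'
#' @param trajectory a `trajectory`.
#' @param mrna_norm normalization constant for mRNA levels: the wild-type
#'   vvd mRNA level at the first light-on event. Use
#'   [mrna_normalizer()] for the conventional anchor, or 1 for raw model
#'   units.
#' @return A data.frame with columns `time`, `variant`, `observable`,
#'   `value`.
#' @export
observables <- function(trajectory, mrna_norm = 1) {
  st <- trajectory$state
  obs <- cbind(
    vvd_mrna = st[, "m_vvd"] / mrna_norm,
    frq_mrna = st[, "m_frq"] / mrna_norm,
    wc1_mrna = st[, "m_wc1"] / mrna_norm,
    light_activatable_wcc = st[, "WCC_d"],
    total_wcc = st[, "WCC_d"] + st[, "WCC_a"] + 2 * st[, "WCC_aa"] +
      st[, "WCC_p"] + st[, "HET"],
    total_vvd = st[, "VVD_d"] + st[, "VVD_a"] + 2 * st[, "VVD_aa"] +
      st[, "HET"])
  data.frame(time = rep(trajectory$time, times = ncol(obs)),
             variant = trajectory$variant$kind,
             observable = rep(colnames(obs), each = length(trajectory$time)),
             value = as.vector(obs), row.names = NULL)
}

#' Conventional mRNA normalization constant
#'
#' The wild-type vvd mRNA level at the first light-on event (t = 0 after
#' dark equilibration), the anchor of the convention that sets this value
#' to 1.
#'
#' @param params a `model_parameters` vector.
#' @return Scalar normalizer in raw model units.
#' @export
mrna_normalizer <- function(params) {
  y0 <- dark_equilibrated_state(as_model_parameters(params))
  as.numeric(y0["m_vvd"])
}
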