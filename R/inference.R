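#' @importFrom stats optim rnorm runif var cov dist
NULL

#' Likelihood specification for time-course fitting
#'
#' Binds a dataset to the model: which variant each strain maps to, the
#' residual scale, and the probe-efficiency factors used to map model mRNA
#' species onto measured levels. Residuals are Gaussian on the chosen scale
#' with a per-gene error variance profiled analytically (multiplicative
#' qPCR noise makes the log scale the default).
#'
#' @param dataset a `timecourse_dataset` (see [generate_timecourse()]).
#' @param scale `"log"` (default) or `"linear"` residual scale.
#' @param strain_variants named map from strain labels to model variants.
#' @param base_params parameter set supplying values for all parameters not
#'   being fitted.
#' @return An object of class `likelihood_spec`.
#' @export
likelihood_spec <- function(dataset, scale = c("log", "linear"),
                            strain_variants = c(wt = "wild_type",
                                                vvd_null = "vvd_null"),
                            base_params = default_parameters()) {
  stopifnot(inherits(dataset, "timecourse_dataset"))
  scale <- match.arg(scale)
  strains <- unique(dataset$data$strain)
  unmapped <- setdiff(strains, names(strain_variants))
  if (length(unmapped))
    stop("no variant mapping for strain(s): ",
         paste(unmapped, collapse = ", "))
  eff <- dataset$meta$probe_efficiencies
  if (is.null(eff)) eff <- c(vvd = 1, frq = 1, wc1 = 1)
  protocol <- dataset$meta$protocol
  if (is.null(protocol)) stop("dataset metadata must carry the protocol")
  structure(list(dataset = dataset, scale = scale,
                 strain_variants = strain_variants[strains],
                 probe_efficiencies = eff, protocol = protocol,
                 normalized = is.finite(dataset$meta$normalization %||% NA),
                 base_params = as_model_parameters(base_params)),
            class = "likelihood_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# model predictions aligned with the dataset rows
.predict_levels <- function(params, spec) {
  df <- spec$dataset$data
  times <- sort(unique(c(0, df$time)))
  pred <- numeric(nrow(df))
  norm <- 1
  if (spec$normalized) {
    # the data are anchored to mean wt vvd at t = 0; apply the same
    # convention to the model predictions
    wt_tr <- simulate_trajectory(params, "wild_type", spec$protocol, times)
    norm <- wt_tr$state[match(0, times), "m_vvd"] *
      spec$probe_efficiencies[["vvd"]]
    if (!is.finite(norm) || norm <= 0) return(NULL)
  }
  for (s in names(spec$strain_variants)) {
    tr <- simulate_trajectory(params, spec$strain_variants[[s]],
                              spec$protocol, times)
    for (g in .GENES) {
      sel <- df$strain == s & df$gene == g
      if (!any(sel)) next
      mu <- tr$state[match(df$time[sel], times), .MRNA_SPECIES[[g]]] *
        spec$probe_efficiencies[[g]] / norm
      pred[sel] <- mu
    }
  }
  pred
}

#' Log-likelihood of a parameter set
#'
#' Gaussian log-likelihood of the observed levels given the model
#' predictions, on the scale chosen in the likelihood spec, with the per-gene error
#' variance profiled analytically (its maximum-likelihood value is plugged
#' in). A solver failure yields `-Inf` with a warning, so rejection-based
#' fitting treats such proposals as impossible.
#'
#' @param params a `model_parameters` vector.
#' @param spec a [likelihood_spec()].
#' @return Scalar log-likelihood; attribute `"sigma"` carries the profiled
#'   per-gene error SDs.
#' @export
log_likelihood <- function(params, spec) {
  stopifnot(inherits(spec, "likelihood_spec"))
  params <- as_model_parameters(params)
  pred <- tryCatch(.predict_levels(params, spec), error = function(e) {
    warning("simulation failed during likelihood evaluation: ",
            conditionMessage(e), call. = FALSE)
    NULL
  })
  if (is.null(pred)) return(-Inf)
  df <- spec$dataset$data
  if (spec$scale == "log") {
    if (any(pred <= 0)) return(-Inf)
    resid <- log(df$level) - log(pred)
  } else {
    resid <- df$level - pred
  }
  ll <- 0
  sigma <- c()
  for (g in unique(df$gene)) {
    r <- resid[df$gene == g]
    n <- length(r)
    s2 <- sum(r^2) / n
    if (s2 <= 0) s2 <- 1e-12
    ll <- ll - n / 2 * (log(2 * pi * s2) + 1)
    sigma[g] <- sqrt(s2)
  }
  structure(ll, sigma = sigma)
}

new_fit_result <- function(estimate, free, logLik, stage, seed, ...) {
  structure(c(list(estimate = estimate, free = free, logLik = logLik,
                   stage = stage, seed = seed), list(...)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Model fit (", x$stage, "): ", length(x$free),
      " free parameter(s), logLik = ", format(x$logLik), "\n", sep = "")
  if (length(x$free))
    print(signif(setNames(as.numeric(x$estimate[x$free]), x$free), 4))
  if (!is.null(x$acceptance_rate))
    cat("MCMC acceptance rate:", round(x$acceptance_rate, 3), "\n")
  invisible(x)
}

.set_free <- function(base, free, th) {
  p <- unclass(base)
  p[free] <- exp(th)
  as_model_parameters(p)
}

#' Maximum-likelihood fit by multi-start local optimization
#'
#' Optimizes the chosen free parameters in natural-log space with
#' Nelder-Mead, restarted from randomly perturbed starting points; the best
#' restart wins. Deterministic for a fixed seed.
#'
#' @param spec a [likelihood_spec()].
#' @param free character vector of free parameter names (subset of
#'   [model_parameter_names()]); empty means evaluate the base parameters.
#' @param base_params starting/fixed parameter values (defaults to the
#'   spec's base).
#' @param n_restarts number of starts (the first is unperturbed).
#' @param seed integer seed for the restart perturbations.
#' @param spread SD of the log-scale perturbation of restart points.
#' @param control passed to [stats::optim()].
#' @return A `fit_result` with the best estimate, its log-likelihood and a
#'   per-restart diagnostic table.
#' @export
fit_mle <- function(spec, free, base_params = spec$base_params,
                    n_restarts = 3, seed = 1, spread = 0.5,
                    control = list(maxit = 400)) {
  base_params <- as_model_parameters(base_params)
  unknown <- setdiff(free, .PARAM_NAMES)
  if (length(unknown)) stop("unknown free parameter(s): ",
                            paste(unknown, collapse = ", "))
  if (length(free) == 0) {
    return(new_fit_result(base_params, free,
                          as.numeric(log_likelihood(base_params, spec)),
                          stage = "single", seed = seed))
  }
  if (any(base_params[free] <= 0))
    stop("free parameters must have positive starting values")
  nll <- function(th) {
    ll <- suppressWarnings(log_likelihood(.set_free(base_params, free, th),
                                          spec))
    if (!is.finite(ll)) 1e10 else -as.numeric(ll)
  }
  set.seed(seed)
  th0 <- log(as.numeric(base_params[free]))
  starts <- lapply(seq_len(n_restarts), function(i)
    if (i == 1) th0 else th0 + rnorm(length(free), 0, spread))
  one_dim <- length(free) == 1
  runs <- lapply(starts, function(s)
    tryCatch(
      if (one_dim)
        optim(s, nll, method = "Brent", lower = s - 3 * log(10),
              upper = s + 3 * log(10))
      else optim(s, nll, method = "Nelder-Mead", control = control),
      error = function(e) list(value = Inf, convergence = NA,
                               message = conditionMessage(e))))
  vals <- vapply(runs, function(r) r$value, 0)
  if (all(!is.finite(vals) | vals >= 1e10))
    stop("all ", n_restarts, " restarts failed; best objective: ",
         min(vals))
  best <- runs[[which.min(vals)]]
  est <- .set_free(base_params, free, best$par)
  new_fit_result(est, free, -best$value, stage = "single", seed = seed,
                 restarts = data.frame(
                   restart = seq_len(n_restarts),
                   nll = vals,
                   convergence = vapply(runs, function(r)
                     as.numeric(r$convergence %||% NA), 0)))
}

#' Adaptive random-walk Metropolis sampler
#'
#' Generic Metropolis sampler with multivariate normal proposals whose
#' covariance is adapted to the empirical chain covariance during a burn-in
#' phase and frozen afterwards (keeping the post-adaptation chain
#' Markovian).
#'
#' @param log_target function of a numeric vector returning a log-density
#'   (may be `-Inf`).
#' @param init numeric starting vector.
#' @param n_iter total iterations.
#' @param seed integer seed.
#' @param adapt_until iteration after which the proposal is frozen
#'   (default: half of `n_iter`).
#' @param init_scale initial proposal SD per coordinate.
#' @return List with `samples` (n_iter x d matrix), `log_target` trace,
#'   `acceptance_rate` (post-adaptation), `accept_trace`.
#' @export
adaptive_metropolis <- function(log_target, init, n_iter, seed = 1,
                                adapt_until = floor(n_iter / 2),
                                init_scale = 0.1) {
  set.seed(seed)
  d <- length(init)
  chain <- matrix(NA_real_, n_iter, d)
  lt <- numeric(n_iter)
  cur <- init
  cur_lt <- log_target(cur)
  if (!is.finite(cur_lt)) stop("log_target is not finite at init")
  sigma <- diag(init_scale^2, d)
  chol_sigma <- chol(sigma)
  accepted <- logical(n_iter)
  sd_scale <- 2.38^2 / d
  for (i in seq_len(n_iter)) {
    prop <- cur + drop(rnorm(d) %*% chol_sigma)
    prop_lt <- log_target(prop)
    if (is.finite(prop_lt) && log(runif(1)) < prop_lt - cur_lt) {
      cur <- prop; cur_lt <- prop_lt; accepted[i] <- TRUE
    }
    chain[i, ] <- cur
    lt[i] <- cur_lt
    if (i <= adapt_until && i >= 50 && i %% 50 == 0) {
      emp <- cov(chain[seq_len(i), , drop = FALSE])
      sigma <- sd_scale * emp + diag(1e-10, d)
      ch <- tryCatch(chol(sigma), error = function(e) NULL)
      if (!is.null(ch)) chol_sigma <- ch
    }
  }
  post <- accepted[(adapt_until + 1):n_iter]
  list(samples = chain, log_target = lt,
       acceptance_rate = mean(post), accept_trace = accepted)
}

# split-chain potential scale reduction factor on the post-burn-in half
.split_rhat <- function(samples, burn) {
  kept <- samples[(burn + 1):nrow(samples), , drop = FALSE]
  n <- floor(nrow(kept) / 2)
  if (n < 2) return(rep(NA_real_, ncol(samples)))
  a <- kept[seq_len(n), , drop = FALSE]
  b <- kept[(n + 1):(2 * n), , drop = FALSE]
  vapply(seq_len(ncol(kept)), function(j) {
    m <- c(mean(a[, j]), mean(b[, j]))
    w <- mean(c(var(a[, j]), var(b[, j])))
    if (w == 0) return(1)
    bvar <- n * var(m)
    sqrt(((n - 1) / n * w + bvar / n) / w)
  }, 0)
}

#' Bayesian fit by adaptive Metropolis MCMC
#'
#' Samples the free parameters (in natural-log space) under independent
#' log-uniform priors spanning `prior_decades` decades around the base
#' value of each parameter, using [adaptive_metropolis()]. Reports the
#' post-adaptation acceptance rate and a split-chain potential scale
#' reduction diagnostic; acceptance below 1% sets a warning flag.
#'
#' @param spec a [likelihood_spec()].
#' @param free free parameter names.
#' @param n_iter chain length.
#' @param seed integer seed; identical seeds give identical chains.
#' @param base_params fixed values for non-free parameters and prior
#'   centres for free ones.
#' @param prior_decades total width of each log-uniform prior, in decades
#'   (default 6: three decades either side of the base value).
#' @param prior_only if `TRUE` the likelihood is switched off and the
#'   chain samples the prior (a sampler diagnostic).
#' @param adapt_until iteration at which proposal adaptation stops.
#' @return A `fit_result` with `samples` (natural-log scale, one column per
#'   free parameter), `log_post` trace, `acceptance_rate`, `rhat`,
#'   `low_acceptance` flag, and the posterior-mean `estimate`.
#' @export
fit_mcmc <- function(spec, free, n_iter = 2000, seed = 1,
                     base_params = spec$base_params, prior_decades = 6,
                     prior_only = FALSE,
                     adapt_until = floor(n_iter / 2)) {
  base_params <- as_model_parameters(base_params)
  unknown <- setdiff(free, .PARAM_NAMES)
  if (length(unknown)) stop("unknown free parameter(s): ",
                            paste(unknown, collapse = ", "))
  if (!length(free)) stop("fit_mcmc needs at least one free parameter")
  if (any(base_params[free] <= 0))
    stop("free parameters must have positive base values")
  th0 <- log(as.numeric(base_params[free]))
  half <- prior_decades / 2 * log(10)
  lower <- th0 - half
  upper <- th0 + half
  log_post <- function(th) {
    if (any(th < lower | th > upper)) return(-Inf)
    if (prior_only) return(0)
    suppressWarnings(
      as.numeric(log_likelihood(.set_free(base_params, free, th), spec)))
  }
  run <- adaptive_metropolis(log_post, th0, n_iter, seed = seed,
                             adapt_until = adapt_until)
  colnames(run$samples) <- free
  post_mean <- colMeans(run$samples[(adapt_until + 1):n_iter, ,
                                    drop = FALSE])
  est <- .set_free(base_params, free, post_mean)
  new_fit_result(est, free,
                 as.numeric(suppressWarnings(log_likelihood(est, spec))),
                 stage = "single", seed = seed,
                 samples = run$samples, log_post = run$log_target,
                 acceptance_rate = run$acceptance_rate,
                 rhat = setNames(.split_rhat(run$samples, adapt_until),
                                 free),
                 low_acceptance = run$acceptance_rate < 0.01,
                 burn = adapt_until)
}

#' Non-VVD model parameters
#'
#' The complement of [vvd_parameter_names()] among the fittable rate
#' constants; the Hill coefficients are structural and excluded.
#'
#' @return Character vector.
#' @export
non_vvd_parameter_names <- function() {
  setdiff(.PARAM_NAMES, c(.VVD_PARAMS, "hill_lre", "hill_cbox"))
}

#' Two-stage mutant-then-wild-type fit
#'
#' Stage 1 fits the non-VVD parameters against the vvd-null mutant data
#' (where VVD protein is absent, so VVD-related parameters are
#' unidentifiable and held fixed). Stage 2 freezes every stage-1 value and
#' fits only the VVD-related parameters ([vvd_parameter_names()]) against
#' the wild-type data.
#'
#' @param mutant_dataset `timecourse_dataset` with strain `vvd_null`.
#' @param wt_dataset `timecourse_dataset` with strain `wt`, sharing the
#'   mutant dataset's protocol.
#' @param config list of options: `method` (`"mle"` or `"mcmc"`),
#'   `free_mutant` (default [non_vvd_parameter_names()]), `free_vvd`
#'   (default [vvd_parameter_names()]), `base_params`, `scale`, `seed`,
#'   `n_restarts` (MLE), `n_iter` (MCMC).
#' @return List with elements `mutant_stage` and `vvd_stage`
#'   (`fit_result`s, stage-tagged); every non-VVD parameter of the
#'   `vvd_stage` estimate is bit-identical to the `mutant_stage` estimate.
#' @export
two_stage_fit <- function(mutant_dataset, wt_dataset, config = list()) {
  cfg <- modifyList(list(method = "mle",
                         free_mutant = non_vvd_parameter_names(),
                         free_vvd = vvd_parameter_names(),
                         base_params = default_parameters(),
                         scale = "log", seed = 1, n_restarts = 2,
                         n_iter = 2000), config)
  p1 <- mutant_dataset$meta$protocol
  p2 <- wt_dataset$meta$protocol
  if (!isTRUE(all.equal(as.data.frame(p1), as.data.frame(p2))))
    stop("mutant and wild-type datasets must share the light protocol")
  bad <- intersect(cfg$free_mutant, vvd_parameter_names())
  if (length(bad))
    stop("free_mutant must not contain VVD-related parameter(s): ",
         paste(bad, collapse = ", "))

  spec1 <- likelihood_spec(mutant_dataset, scale = cfg$scale,
                           base_params = cfg$base_params)
  fit1 <- if (cfg$method == "mle") {
    fit_mle(spec1, cfg$free_mutant, base_params = cfg$base_params,
            n_restarts = cfg$n_restarts, seed = cfg$seed)
  } else {
    fit_mcmc(spec1, cfg$free_mutant, n_iter = cfg$n_iter,
             seed = cfg$seed, base_params = cfg$base_params)
  }
  fit1$stage <- "mutant_stage"

  spec2 <- likelihood_spec(wt_dataset, scale = cfg$scale,
                           base_params = fit1$estimate)
  fit2 <- if (cfg$method == "mle") {
    fit_mle(spec2, cfg$free_vvd, base_params = fit1$estimate,
            n_restarts = cfg$n_restarts, seed = cfg$seed + 1)
  } else {
    fit_mcmc(spec2, cfg$free_vvd, n_iter = cfg$n_iter,
             seed = cfg$seed + 1, base_params = fit1$estimate)
  }
  fit2$stage <- "vvd_stage"
  frozen <- setdiff(.PARAM_NAMES, cfg$free_vvd)
  stopifnot(identical(as.numeric(fit2$estimate[frozen]),
                      as.numeric(fit1$estimate[frozen])))
  list(mutant_stage = fit1, vvd_stage = fit2)
}

#' Subset a dataset by strain
#'
#' Keeps the shared normalization and metadata, so a jointly normalized
#' dataset can be split into the mutant and wild-type fitting inputs.
#'
#' @param dataset a `timecourse_dataset`.
#' @param strains strain labels to keep.
#' @return A `timecourse_dataset`.
#' @export
subset_dataset <- function(dataset, strains) {
  stopifnot(inherits(dataset, "timecourse_dataset"))
  keep <- dataset$data$strain %in% strains
  if (!any(keep)) stop("no observations for strain(s): ",
                       paste(strains, collapse = ", "))
  out <- dataset
  out$data <- dataset$data[keep, , drop = FALSE]
  rownames(out$data) <- NULL
  out$meta$strains <- strains
  out
}
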