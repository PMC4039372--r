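#' @importFrom stats rlnorm
#' @importFrom utils read.csv write.csv
NULL

.GENES <- c("vvd", "frq", "wc1")
.STRAINS <- c(wt = "wild_type", vvd_null = "vvd_null")
.DATASET_COLS <- c("time", "strain", "gene", "replicate", "level")

#' Default qRT-PCR sampling grid for the light-step protocol
#'
#' Dense sampling (every 15 min) for the first two hours after each light
#' step, then hourly, mirroring the sampling density of the calibration
#' experiments.
#'
#' @param step_times light-step times (minutes).
#' @param t_end end of sampling (minutes).
#' @return Sorted numeric vector of sampling times.
#' @export
default_sample_times <- function(step_times = c(0, 300, 1000),
                                 t_end = 1440) {
  tt <- unlist(lapply(step_times, function(s) seq(s, s + 120, by = 15)))
  tt <- c(tt, seq(0, t_end, by = 60))
  sort(unique(tt[tt <= t_end]))
}

#' Generate a synthetic qRT-PCR time-course dataset
#'
#' Simulates each strain under the light protocol, reads the three mRNAs at
#' the sampling times, applies gene-specific probe-efficiency factors,
#' multiplies by lognormal measurement noise with a fixed coefficient of
#' variation, and normalizes the whole dataset so that the mean wild-type
#' vvd level at t = 0 equals 1.
#'
#' @param true_params a `model_parameters` vector used as ground truth.
#' @param strains character subset of `c("wt", "vvd_null")`.
#' @param protocol a [light_protocol()].
#' @param sample_times sampling times (minutes), within the protocol span.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   noise (>= 0; 0 gives the noise-free model output).
#' @param probe_efficiencies named multipliers for `vvd`, `frq`, `wc1`
#'   applied before normalization (the qPCR probe-efficiency correction).
#' @param n_replicates technical replicates per (time, strain, gene).
#' @param seed integer seed; identical seeds give identical datasets.
#' @return An object of class `timecourse_dataset`: list with `data` (a
#'   data.frame with columns time, strain, gene, replicate, level) and
#'   `meta` (protocol, noise model, seed, true parameters, normalization
#'   constant in raw model units).
#' @export
generate_timecourse <- function(true_params,
                                strains = c("wt", "vvd_null"),
                                protocol = lightstep_protocol(),
                                sample_times = default_sample_times(),
                                noise_cv = 0.2,
                                probe_efficiencies = c(vvd = 1, frq = 0.7,
                                                       wc1 = 0.4),
                                n_replicates = 3,
                                seed = 1) {
  true_params <- as_model_parameters(true_params)
  unknown <- setdiff(strains, names(.STRAINS))
  if (length(unknown)) stop("unknown strain(s): ",
                            paste(unknown, collapse = ", "))
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  missing_eff <- setdiff(.GENES, names(probe_efficiencies))
  if (length(missing_eff)) stop("probe_efficiencies must cover: ",
                                paste(missing_eff, collapse = ", "))
  stopifnot(n_replicates >= 1)
  sample_times <- sort(unique(as.numeric(sample_times)))

  grid <- sort(unique(c(0, sample_times)))
  means <- list()
  for (s in strains) {
    tr <- simulate_trajectory(true_params, .STRAINS[[s]], protocol, grid)
    means[[s]] <- tr$state[, .MRNA_SPECIES, drop = FALSE]
  }
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  rows <- vector("list", 0)
  for (s in strains) for (g in .GENES) {
    mu <- means[[s]][match(sample_times, grid), .MRNA_SPECIES[[g]]] *
      probe_efficiencies[[g]]
    for (r in seq_len(n_replicates)) {
      noise <- if (noise_cv > 0)
        rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
      else rep(1, length(mu))
      rows[[length(rows) + 1]] <- data.frame(
        time = sample_times, strain = s, gene = g, replicate = r,
        level = as.numeric(mu) * noise)
    }
  }
  df <- do.call(rbind, rows)
  # anchor: mean wild-type vvd at t = 0 set to 1
  norm <- NA_real_
  if ("wt" %in% strains && 0 %in% sample_times) {
    norm <- mean(df$level[df$strain == "wt" & df$gene == "vvd" &
                            df$time == 0])
    df$level <- df$level / norm
  }
  structure(list(
    data = df,
    meta = list(protocol = protocol, noise_cv = noise_cv,
                probe_efficiencies = probe_efficiencies,
                n_replicates = n_replicates, seed = seed,
                true_params = true_params, normalization = norm,
                strains = strains)),
    class = "timecourse_dataset")
}

#' @export
print.timecourse_dataset <- function(x, ...) {
  cat("Synthetic qRT-PCR time course: ", nrow(x$data), " observations (",
      length(unique(x$data$time)), " time points, strains ",
      paste(unique(x$data$strain), collapse = "/"), ", CV ",
      x$meta$noise_cv, ")\n", sep = "")
  invisible(x)
}

#' Write / read a time-course dataset
#'
#' The observations go to a CSV with fixed column names
#' (time, strain, gene, replicate, level); the metadata (protocol, noise
#' model, seed, true parameters, normalization) goes to a YAML sidecar at
#' `<path>.meta.yaml`. `read_dataset()` restores both and validates the
#' table: required columns (in any order), positive numeric levels, and no
#' duplicate (time, strain, gene, replicate) keys; violations are reported
#' with the offending row number.
#'
#' @param dataset a `timecourse_dataset`.
#' @param path CSV file path.
#' @return `read_dataset()` returns a `timecourse_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "timecourse_dataset"))
  write.csv(dataset$data, path, row.names = FALSE, quote = FALSE)
  meta <- dataset$meta
  meta$protocol <- list(start_time = as.numeric(meta$protocol$start_time),
                        intensity = as.numeric(meta$protocol$intensity))
  if (!is.null(meta$true_params))
    meta$true_params <- as.list(setNames(as.numeric(meta$true_params),
                                         names(unclass(meta$true_params))))
  meta$probe_efficiencies <- as.list(meta$probe_efficiencies)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"), precision = 15)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.DATASET_COLS, names(df))
  if (length(missing))
    stop("dataset file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  df <- df[, .DATASET_COLS]
  if (!is.numeric(df$level) || any(!is.finite(df$level))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df$level))))[1]
    stop("non-numeric level at row ", bad)
  }
  if (any(df$level <= 0))
    stop("non-positive level at row ", which(df$level <= 0)[1],
         " (qPCR levels must be > 0)")
  key <- paste(df$time, df$strain, df$gene, df$replicate)
  if (anyDuplicated(key))
    stop("duplicate (time, strain, gene, replicate) key at row ",
         anyDuplicated(key))
  meta_path <- paste0(path, ".meta.yaml")
  meta <- NULL
  if (file.exists(meta_path)) {
    meta <- yaml::read_yaml(meta_path)
    meta$protocol <- light_protocol(unlist(meta$protocol$start_time),
                                    unlist(meta$protocol$intensity))
    if (!is.null(meta$true_params))
      meta$true_params <- as_model_parameters(unlist(meta$true_params))
    if (!is.null(meta$probe_efficiencies))
      meta$probe_efficiencies <- unlist(meta$probe_efficiencies)
  }
  structure(list(data = df, meta = meta), class = "timecourse_dataset")
}
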