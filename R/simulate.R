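#' Simulate a multispecies community time series with planted scales
#'
#' Generates a biovolume matrix whose taxa fall into groups sharing a
#' fluctuation period ("scale") plus a set of stochastic taxa with no shared
#' temporal structure. Taxon `j` in scale group `g` has log-biovolume
#' `baseline_j + amplitude * sin(2*pi*t/period_g + phase_j) + N(0, noise_sd)`
#' with taxon phases jittered within `+/- phase_jitter` around a common
#' group phase, so the group stays coherent enough to load on one canonical
#' axis. Stochastic taxa are pure noise on the log scale with marginal
#' standard deviation matched to the signal taxa (`sqrt(amplitude^2/2 +
#' noise_sd^2)`), so stochasticity is detectable only as the absence of
#' shared temporal structure, not as lower variance. Biovolume is the
#' exponential of the log signal: strictly positive, right-skewed.
#'
#' The defaults emulate a 24-month window with three planted scales
#' (biennial, annual, semi-annual), group sizes 8/6/4 and 20 stochastic
#' taxa.
#'
#' @param n_time number of monthly time steps.
#' @param scale_periods fluctuation period (months) per planted scale, slow
#'   to fast.
#' @param species_per_scale taxa per scale group (same length as
#'   `scale_periods`).
#' @param n_stochastic number of noise-only taxa.
#' @param amplitude sinusoid amplitude on the log scale.
#' @param noise_sd residual log-scale noise of the signal taxa.
#' @param phase_jitter half-width of the within-group phase jitter
#'   (radians).
#' @param scale_phases optional vector of fixed group phases (radians, one
#'   per scale); `NULL` (default) draws each group phase uniformly. Fixed
#'   phases give controlled fixtures: with harmonically nested periods the
#'   exponential link generates harmonic overtones, and random phases can
#'   align a slow group's overtone with a faster group's fundamental.
#' @param baseline_sd spread of taxon log-baselines.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @return List: `community` (a [community_ts()]) and `truth` (class
#'   `synthetic_truth`: `taxon_scale` label per taxon — `"scale1"`.. or
#'   `"stochastic"` —, `scale_periods`, `seed`).
#' @examples
#' sim <- simulate_community(seed = 7)
#' table(sim$truth$taxon_scale)
#' @export
simulate_community <- function(n_time = 24, scale_periods = c(24, 12, 6),
                               species_per_scale = c(8, 6, 4),
                               n_stochastic = 20, amplitude = 1.5,
                               noise_sd = 0.5, phase_jitter = pi / 8,
                               scale_phases = NULL, baseline_sd = 0.5,
                               seed = 1L) {
  if (length(scale_periods) != length(species_per_scale))
    stop("scale_periods and species_per_scale must have the same length")
  if (any(scale_periods <= 0)) stop("periods must be positive")
  if (any(scale_periods < 2)) stop("periods below 2 steps are not resolvable")
  if (n_time < 2 * max(scale_periods))
    warning("n_time < 2 * max(scale_periods): the slowest scale completes ",
            "fewer than two cycles and may be hard to separate from a trend")
  set.seed(as.integer(seed))
  t <- seq_len(n_time)
  n_scales <- length(scale_periods)
  n_signal <- sum(species_per_scale)
  n_taxa <- n_signal + n_stochastic

  # marginal sd of a sinusoid of this amplitude plus its residual noise
  signal_sd <- sqrt(amplitude^2 / 2 + noise_sd^2)

  logY <- matrix(NA_real_, n_time, n_taxa)
  labels <- character(n_taxa)
  j <- 0L
  if (!is.null(scale_phases) && length(scale_phases) != n_scales)
    stop("scale_phases must have one phase per scale")
  for (g in seq_len(n_scales)) {
    group_phase <- if (is.null(scale_phases)) runif(1, 0, 2 * pi)
                   else scale_phases[g]
    for (s in seq_len(species_per_scale[g])) {
      j <- j + 1L
      phase <- group_phase + runif(1, -phase_jitter, phase_jitter)
      base <- rnorm(1, 0, baseline_sd)
      logY[, j] <- base + amplitude * sin(2 * pi * t / scale_periods[g] + phase) +
        rnorm(n_time, 0, noise_sd)
      labels[j] <- paste0("scale", g)
    }
  }
  for (s in seq_len(n_stochastic)) {
    j <- j + 1L
    base <- rnorm(1, 0, baseline_sd)
    logY[, j] <- base + rnorm(n_time, 0, signal_sd)
    labels[j] <- "stochastic"
  }
  taxa <- sprintf("sp%02d_%s", seq_len(n_taxa), labels)
  cts <- community_ts(exp(logY), taxa = taxa)
  truth <- structure(list(taxon_scale = stats::setNames(labels, taxa),
                          scale_periods = scale_periods, seed = seed),
                     class = "synthetic_truth")
  list(community = cts, truth = truth)
}

#' Simulate a hydrological driver with seasonality and a regime step
#'
#' `value_t = base + seasonal_amplitude * sin(2*pi*t/12) + step_size *
#' 1[t >= step_time] + N(0, noise_sd)`: a within-year seasonal cycle
#' superposed on a supraseasonal step change, emulating a flooded-area
#' series that switches between a wet and a dry hydrological state.
#'
#' @param n_time number of monthly steps.
#' @param base baseline level.
#' @param seasonal_amplitude amplitude of the annual cycle.
#' @param step_time index of the first step in the new regime.
#' @param step_size signed size of the regime step (negative for a drying
#'   shift).
#' @param noise_sd observation noise.
#' @param seed integer seed.
#' @return List: `driver` (a [driver_series()]) and `truth`
#'   (`shift_point`, `seed`).
#' @examples
#' d <- simulate_driver(step_size = -8, seed = 3)
#' plot(stars(d$driver, l = 12))
#' @export
simulate_driver <- function(n_time = 48, base = 10, seasonal_amplitude = 1,
                            step_time = 25, step_size = -5, noise_sd = 0.3,
                            seed = 1L) {
  if (step_time <= 1 || step_time > n_time)
    stop("step_time must be in (1, n_time]")
  set.seed(as.integer(seed))
  t <- seq_len(n_time)
  v <- base + seasonal_amplitude * sin(2 * pi * t / 12) +
    step_size * (t >= step_time) + rnorm(n_time, 0, noise_sd)
  truth <- structure(list(shift_point = step_time, seed = seed),
                     class = "synthetic_truth")
  list(driver = driver_series(v, times = t), truth = truth)
}

#' Two-state (wet/dry) simulation preset
#'
#' Generates, for each of `n_sites` sites, a wet-state window with three
#' planted temporal scales and a dry-state window with fewer scales and more
#' stochastic taxa, plus a driver with a drying step between the windows —
#' the structural contrast the resilience analysis is designed to detect.
#'
#' @param n_sites number of sites.
#' @param seed integer seed; site and state streams are derived from it.
#' @return List with `communities` (list of [community_ts()], one per
#'   site-state, with `site_id`/`state_id` set), `driver`, `truths`.
#' @export
simulate_two_states <- function(n_sites = 3, seed = 1L) {
  seed <- as.integer(seed)
  sites <- paste0("S", seq_len(n_sites))
  communities <- list(); truths <- list()
  for (i in seq_len(n_sites)) {
    wet <- simulate_community(seed = seed + 1000L * i)
    dry <- simulate_community(scale_periods = c(24, 12),
                              species_per_scale = c(8, 6),
                              n_stochastic = 34,
                              seed = seed + 1000L * i + 500L)
    wet$community$site_id <- dry$community$site_id <- sites[i]
    wet$community$state_id <- "wet"; dry$community$state_id <- "dry"
    communities[[paste0(sites[i], ".wet")]] <- wet$community
    communities[[paste0(sites[i], ".dry")]] <- dry$community
    truths[[paste0(sites[i], ".wet")]] <- wet$truth
    truths[[paste0(sites[i], ".dry")]] <- dry$truth
  }
  drv <- simulate_driver(seed = seed)
  list(communities = communities, driver = drv$driver, truths = truths)
}
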