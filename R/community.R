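#' Community time series
#'
#' A `community_ts` holds one window of a multispecies time series: a matrix
#' of non-negative biovolumes (mm^3 L^-1) with one row per equidistant time
#' step (months) and one column per taxon.
#'
#' @param biovolume numeric matrix, rows = time steps, columns = taxa.
#' @param times strictly increasing, equidistant numeric time stamps; defaults
#'   to `1:nrow(biovolume)` (1-based month indices).
#' @param taxa taxon labels; defaults to the column names of `biovolume`.
#' @param site_id,state_id optional labels carried through the analysis.
#'
#' @return An object of class `community_ts` with elements `biovolume`,
#'   `times`, `taxa`, `site_id`, `state_id`.
#' @examples
#' y <- matrix(rlnorm(24 * 3), 24, 3, dimnames = list(NULL, paste0("sp", 1:3)))
#' cts <- community_ts(y, site_id = "MM", state_id = "wet")
#' cts
#' @export
community_ts <- function(biovolume, times = NULL, taxa = NULL,
                         site_id = NA_character_, state_id = NA_character_) {
  biovolume <- as.matrix(biovolume)
  storage.mode(biovolume) <- "double"
  if (is.null(times)) times <- seq_len(nrow(biovolume))
  if (is.null(taxa)) {
    taxa <- colnames(biovolume)
    if (is.null(taxa)) taxa <- paste0("taxon", seq_len(ncol(biovolume)))
  }
  colnames(biovolume) <- taxa
  rownames(biovolume) <- times
  obj <- structure(
    list(biovolume = biovolume, times = as.numeric(times), taxa = taxa,
         site_id = site_id, state_id = state_id),
    class = "community_ts")
  validate_community_ts(obj)
}

validate_community_ts <- function(x) {
  y <- x$biovolume
  if (nrow(y) < 3L)
    stop("community time series needs at least 3 time steps, got ", nrow(y))
  if (length(x$times) != nrow(y))
    stop("length(times) must equal nrow(biovolume)")
  if (anyDuplicated(x$taxa))
    stop("duplicate taxon labels: ",
         paste(unique(x$taxa[duplicated(x$taxa)]), collapse = ", "))
  d <- diff(x$times)
  if (any(d <= 0))
    stop("times must be strictly increasing")
  if (length(unique(round(d, 8))) > 1L) {
    bad <- which(abs(d - d[1]) > 1e-8)[1]
    stop(sprintf("times must be equidistant: gap %g between t=%g and t=%g differs from step %g",
                 d[bad], x$times[bad], x$times[bad + 1], d[1]))
  }
  if (anyNA(y) || any(!is.finite(y)))
    stop("biovolume contains missing or non-finite values")
  if (any(y < 0)) {
    idx <- which(y < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative biovolume at time %s, taxon '%s'",
                 rownames(y)[idx[1]], colnames(y)[idx[2]]))
  }
  x
}

#' @export
print.community_ts <- function(x, ...) {
  cat("Community time series", if (!is.na(x$site_id)) paste0("[site ", x$site_id,
      if (!is.na(x$state_id)) paste0(", state ", x$state_id), "]"), "\n")
  cat(sprintf("  %d time steps (%g..%g), %d taxa\n",
              nrow(x$biovolume), min(x$times), max(x$times), length(x$taxa)))
  cat(sprintf("  total biovolume %.4g, %d empty cells\n",
              sum(x$biovolume), sum(x$biovolume == 0)))
  invisible(x)
}

#' Read a community table from CSV
#'
#' Wide dialect: first column holds the time stamp, remaining columns one
#' taxon each. Long dialect: columns `time`, `taxon`, `biovolume`; unlisted
#' (time, taxon) combinations are filled with zero.
#'
#' @param path CSV file (RFC 4180, UTF-8, decimal point).
#' @param dialect `"wide"` or `"long"`.
#' @inheritParams community_ts
#' @return A validated [community_ts()].
#' @seealso [write_community()]
#' @export
read_community <- function(path, dialect = c("wide", "long"),
                           site_id = NA_character_, state_id = NA_character_) {
  dialect <- match.arg(dialect)
  df <- read.csv(path, check.names = FALSE)
  if (dialect == "wide") {
    times <- df[[1]]
    y <- as.matrix(df[, -1, drop = FALSE])
  } else {
    need <- c("time", "taxon", "biovolume")
    if (!all(need %in% names(df)))
      stop("long dialect needs columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(df[c("time", "taxon")]))
      stop("duplicate (time, taxon) pairs in long table")
    times <- sort(unique(df$time))
    taxa <- unique(df$taxon)
    y <- matrix(0, length(times), length(taxa), dimnames = list(times, taxa))
    y[cbind(match(df$time, times), match(df$taxon, taxa))] <- df$biovolume
  }
  community_ts(y, times = times, site_id = site_id, state_id = state_id)
}

#' Write a community table as wide CSV
#'
#' @param cts a [community_ts()].
#' @param path output file.
#' @return `path`, invisibly. Reading the file back reproduces the cell
#'   values exactly (values are written with full precision).
#' @export
write_community <- function(cts, path) {
  num <- apply(cts$biovolume, 2, sprintf, fmt = "%.17g")  # lossless round trip
  df <- data.frame(time = cts$times, num, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Univariate driver series
#'
#' @param values finite numeric driver values (e.g. flooded area in ha).
#' @param times time stamps, default `1:length(values)`.
#' @return An object of class `driver_series`.
#' @export
driver_series <- function(values, times = seq_along(values)) {
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have the same length")
  if (anyNA(values) || any(!is.finite(values)))
    stop("driver values must be finite")
  structure(list(times = as.numeric(times), values = values),
            class = "driver_series")
}

#' @export
print.driver_series <- function(x, ...) {
  cat(sprintf("Driver series: %d steps, range [%.4g, %.4g]\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Read / write a driver series (CSV with columns time, value)
#' @inheritParams read_community
#' @return [driver_series()] for `read_driver`; `path` invisibly for
#'   `write_driver`.
#' @export
read_driver <- function(path) {
  df <- read.csv(path)
  driver_series(df[[2]], times = df[[1]])
}

#' @rdname read_driver
#' @param drv a [driver_series()].
#' @export
write_driver <- function(drv, path) {
  write.csv(data.frame(time = drv$times,
                       value = sprintf("%.17g", drv$values)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a community series into state windows
#'
#' Cuts the series into non-overlapping time windows (e.g. the wet and dry
#' state delimited on the driver) and drops, per window, taxa that are absent
#' (all-zero) throughout the window: they are unobserved in that state, so
#' per-state taxon totals may differ.
#'
#' @param cts a [community_ts()].
#' @param windows data frame with columns `start`, `end` (inclusive time
#'   stamps) and `state` (labels), such as returned by
#'   [states_from_regimes()].
#' @param renumber if `TRUE` (default) each window's times are renumbered
#'   1..n so downstream temporal eigenfunctions are built per window.
#' @return List of `community_ts`, one per window, named by state label.
#' @export
split_by_state <- function(cts, windows, renumber = TRUE) {
  windows <- as.data.frame(windows)
  stopifnot(all(c("start", "end", "state") %in% names(windows)))
  o <- order(windows$start)
  windows <- windows[o, ]
  if (any(windows$end < windows$start))
    stop("window with end before start")
  if (nrow(windows) > 1 &&
      any(windows$start[-1] <= windows$end[-nrow(windows)]))
    stop("windows overlap")
  out <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    keep <- cts$times >= windows$start[i] & cts$times <= windows$end[i]
    if (!any(keep)) stop("empty window: ", windows$start[i], "-", windows$end[i])
    y <- cts$biovolume[keep, , drop = FALSE]
    present <- colSums(y) > 0
    if (any(!present))
      message(sprintf("window '%s': dropping %d all-zero taxa (%s)",
                      windows$state[i], sum(!present),
                      paste(colnames(y)[!present], collapse = ", ")))
    y <- y[, present, drop = FALSE]
    tms <- if (renumber) seq_len(nrow(y)) else cts$times[keep]
    out[[i]] <- community_ts(y, times = tms, site_id = cts$site_id,
                             state_id = as.character(windows$state[i]))
  }
  names(out) <- windows$state
  out
}

#' Analysis configuration
#'
#' Bundles every tunable of the pipeline with validated defaults; read and
#' written as flat YAML so each run can log its fully resolved configuration.
#'
#' @param alpha_axis significance level for the global RDA test, forward
#'   selection and canonical-axis tests.
#' @param alpha_species significance level for the per-taxon Spearman tests.
#' @param n_permutations permutations per test (>= 99).
#' @param seed integer RNG seed.
#' @param stars_cutoff_length STARS cut-off length `l` (months); default 12
#'   so a full seasonal cycle cannot masquerade as a regime.
#' @param stars_alpha STARS sequential t-test level.
#' @param stars_huber Huber tuning constant for robust regime means.
#' @param p_adjust_method multiplicity correction for the Spearman screen
#'   (`"none"` by default, matching plain per-taxon screening).
#' @return A named list of class `scalescape_config`.
#' @export
analysis_config <- function(alpha_axis = 0.05, alpha_species = 0.05,
                            n_permutations = 999, seed = 1L,
                            stars_cutoff_length = 12L, stars_alpha = 0.05,
                            stars_huber = 1, p_adjust_method = "none") {
  cfg <- list(alpha_axis = alpha_axis, alpha_species = alpha_species,
              n_permutations = as.integer(n_permutations), seed = as.integer(seed),
              stars_cutoff_length = as.integer(stars_cutoff_length),
              stars_alpha = stars_alpha, stars_huber = stars_huber,
              p_adjust_method = p_adjust_method)
  for (a in c("alpha_axis", "alpha_species", "stars_alpha"))
    if (cfg[[a]] <= 0 || cfg[[a]] >= 1) stop(a, " must be in (0, 1)")
  if (cfg$n_permutations < 99L) stop("n_permutations must be >= 99")
  if (cfg$stars_cutoff_length < 2L) stop("stars_cutoff_length must be >= 2")
  if (cfg$stars_huber <= 0) stop("stars_huber must be positive")
  class(cfg) <- "scalescape_config"
  cfg
}

#' @rdname analysis_config
#' @param path YAML file with any subset of the configuration keys.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(analysis_config)))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(analysis_config, vals)
}

#' @rdname analysis_config
#' @param cfg a `scalescape_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.scalescape_config <- function(x, ...) {
  cat("scalescape analysis configuration\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  invisible(x)
}
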