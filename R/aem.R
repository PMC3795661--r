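#' Asymmetric eigenvector maps for a linear time series
#'
#' Builds temporal eigenfunctions from the directional connectivity of a
#' linear sequence of `n` equidistant time steps. Time step `i` is reached
#' through all `i - 1` earlier links, giving the 0/1 incidence matrix of
#' [time_incidence()]; its columns are centred and decomposed by SVD. The
#' left singular vectors are the AEM variables: the first models a linear
#' trend and successive ones capture fluctuations of increasingly shorter
#' period. Eigenfunctions modelling positive temporal autocorrelation —
#' Moran's I under consecutive-step contiguity above its null expectation
#' `-1/(n-1)` — are flagged `retained`; these are the usable temporal
#' predictors (for `n = 24` there are exactly 12). Column signs are fixed so
#' each eigenfunction's first non-zero element is positive.
#'
#' @param n_time number of equidistant time steps (>= 3).
#' @return Object of class `aem_basis`: `n_time`, `incidence`,
#'   `eigenfunctions` (columns unit-norm, orthogonal, named AEM1..),
#'   `eigenvalues` (squared singular values, descending), `morans_i`,
#'   `retained` (logical), `expected_i` (the Moran null expectation).
#' @examples
#' b <- aem(24)
#' sum(b$retained)      # 12 temporal predictors
#' @export
aem <- function(n_time) {
  E <- time_incidence(n_time)
  Ec <- scale(E, center = TRUE, scale = FALSE)
  sv <- svd(Ec)
  keep <- sv$d > max(sv$d) * 1e-10
  U <- sv$u[, keep, drop = FALSE]
  d <- sv$d[keep]

  # sign convention: first non-zero element of each column positive
  for (k in seq_len(ncol(U))) {
    nz <- which(abs(U[, k]) > 1e-12)[1]
    if (!is.na(nz) && U[nz, k] < 0) U[, k] <- -U[, k]
  }
  colnames(U) <- paste0("AEM", seq_len(ncol(U)))

  mi <- apply(U, 2, moran_i_line)
  e0 <- -1 / (n_time - 1)

  structure(list(n_time = n_time, incidence = E, eigenfunctions = U,
                 eigenvalues = d^2, morans_i = mi, retained = mi > e0,
                 expected_i = e0),
            class = "aem_basis")
}

#' Directional incidence matrix of a linear time sequence
#'
#' Row `i` marks the links (columns) traversed to reach time step `i` from
#' the origin: columns `1..i-1` are 1, the rest 0; row 1 is all zero. Row
#' sums are therefore `0, 1, ..., n - 1`.
#'
#' @param n_time number of time steps (>= 3).
#' @return `n_time x (n_time - 1)` binary matrix.
#' @export
time_incidence <- function(n_time) {
  n_time <- as.integer(n_time)
  if (n_time < 3L) stop("n_time must be >= 3")
  E <- matrix(0, n_time, n_time - 1L)
  for (i in 2:n_time) E[i, seq_len(i - 1L)] <- 1
  E
}

# Moran's I with binary weights linking consecutive steps of a line
moran_i_line <- function(z) {
  n <- length(z)
  zc <- z - mean(z)
  num <- 2 * sum(zc[-n] * zc[-1])     # both directions of each of n-1 links
  s0 <- 2 * (n - 1)
  (n / s0) * num / sum(zc^2)
}

#' Retained temporal predictors of an AEM basis
#'
#' @param basis an [aem()] result.
#' @return Matrix of the retained (positively autocorrelated) eigenfunctions,
#'   ordered slow to fast.
#' @export
aem_predictors <- function(basis) {
  basis$eigenfunctions[, basis$retained, drop = FALSE]
}

#' @export
print.aem_basis <- function(x, ...) {
  cat(sprintf("AEM temporal basis: n = %d steps, %d eigenfunctions, %d retained\n",
              x$n_time, ncol(x$eigenfunctions), sum(x$retained)))
  cat(sprintf("  Moran's I range %.3f..%.3f (null expectation %.4f)\n",
              min(x$morans_i), max(x$morans_i), x$expected_i))
  invisible(x)
}

#' @export
plot.aem_basis <- function(x, k = 1:min(4, sum(x$retained)), ...) {
  U <- aem_predictors(x)[, k, drop = FALSE]
  matplot(seq_len(x$n_time), U, type = "l", lty = 1, xlab = "time step",
          ylab = "eigenfunction", ...)
  legend("topright", colnames(U), col = seq_along(k), lty = 1, bty = "n",
         cex = 0.8)
  invisible(x)
}
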