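#' Hellinger transformation
#'
#' Square root of the row-wise relative abundances: cell (i, j) becomes
#' `sqrt(y_ij / rowsum_i)`, so every row has unit sum of squares. Makes
#' Euclidean-based ordination appropriate for abundance/biovolume data.
#'
#' @param Y non-negative matrix, rows = samples; every row sum must be
#'   positive.
#' @return Transformed matrix of the same dimension.
#' @export
hellinger <- function(Y) {
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop("Hellinger transform needs non-negative values")
  rs <- rowSums(Y)
  if (any(rs <= 0)) {
    bad <- which(rs <= 0)
    stop("zero-sum row(s): ", paste(bad, collapse = ", "),
         "; the transform is undefined for empty samples")
  }
  sqrt(sweep(Y, 1, rs, "/"))
}

#' Ezekiel-adjusted R-squared
#'
#' `1 - (1 - r2) * (n - 1) / (n - m - 1)`: penalizes the number of
#' predictors. May be negative for weak fits; it is reported as computed.
#'
#' @param r2 unadjusted fraction of variance explained.
#' @param n number of samples (time steps).
#' @param m number of predictors.
#' @return Adjusted fraction.
#' @export
adjusted_r2 <- function(r2, n, m) {
  if (n <= m + 1) stop("need n > m + 1 (n = ", n, ", m = ", m, ")")
  1 - (1 - r2) * (n - 1) / (n - m - 1)
}

# Core least-squares RDA of a (centred) response on predictor columns.
# Returns eigen-decomposition of the fitted variation.
rda_core <- function(Yt, X) {
  Yc <- scale(as.matrix(Yt), center = TRUE, scale = FALSE)
  Xc <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  n <- nrow(Yc); m <- ncol(Xc)
  if (n != nrow(Xc)) stop("response and predictors disagree on sample count")
  qrx <- qr(Xc)
  if (qrx$rank < m) {
    dep <- colnames(Xc)[qrx$pivot[(qrx$rank + 1):m]]
    if (is.null(dep)) dep <- qrx$pivot[(qrx$rank + 1):m]
    stop("collinear predictors: ", paste(dep, collapse = ", "))
  }
  B <- qr.coef(qrx, Yc)
  Yfit <- qr.fitted(qrx, Yc)
  ss_tot <- sum(Yc^2)
  ss_fit <- sum(Yfit^2)
  sv <- svd(Yfit)
  keep <- sv$d > max(sv$d, .Machine$double.eps) * 1e-8
  d <- sv$d[keep]
  axes <- seq_along(d)
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  # reproducible axis orientation: largest-|loading| species positive
  for (k in axes) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) { V[, k] <- -V[, k]; U[, k] <- -U[, k] }
  }
  lc <- U %*% diag(d, length(d))
  colnames(lc) <- colnames(V) <- paste0("RDA", axes)
  rownames(V) <- colnames(Yt)
  list(coefficients = B, fitted = Yfit, Yc = Yc, Xc = Xc, qrx = qrx,
       eig = d^2 / (n - 1), lc_scores = lc, species_scores = V,
       ss_tot = ss_tot, ss_fit = ss_fit, r2 = ss_fit / ss_tot,
       n = n, m = m)
}

# pseudo-F for the global model
pseudo_f <- function(ss_fit, ss_tot, n, m) {
  ss_res <- max(ss_tot - ss_fit, 0)        # guard floating fuzz at saturation
  (ss_fit / m) / (ss_res / (n - m - 1))
}

#' Global permutation test of an RDA model
#'
#' Tests the joint explanatory power of the predictors: the observed
#' pseudo-F, `(SS_fit / m) / (SS_res / (n - m - 1))`, is compared with its
#' distribution under unrestricted random row permutations of the response.
#' The p-value uses the `+1` correction, so the smallest attainable value is
#' `1 / (n_perm + 1)`.
#'
#' @param Yt (transformed) response matrix.
#' @param X predictor matrix.
#' @param n_perm number of permutations (>= 99).
#' @param seed optional integer seed for reproducible permutations.
#' @return List: `statistic` (pseudo-F), `p_value`, `r2`, `n_perm`.
#' @export
rda_perm_test <- function(Yt, X, n_perm = 999, seed = NULL) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (!is.null(seed)) set.seed(seed)
  Yc <- scale(as.matrix(Yt), center = TRUE, scale = FALSE)
  Xc <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  n <- nrow(Yc); m <- qr(Xc)$rank
  Q <- qr.Q(qr(Xc))[, seq_len(m), drop = FALSE]
  ss_tot <- sum(Yc^2)
  ssf <- function(Y) sum((crossprod(Q, Y))^2)
  f_obs <- pseudo_f(ssf(Yc), ss_tot, n, m)
  f_perm <- vapply(seq_len(n_perm), function(i) {
    Yp <- Yc[sample.int(n), , drop = FALSE]
    pseudo_f(ssf(Yp), ss_tot, n, m)
  }, numeric(1))
  p <- (sum(f_perm >= f_obs) + 1) / (n_perm + 1)
  list(statistic = f_obs, p_value = p,
       r2 = ssf(Yc) / ss_tot, n_perm = n_perm)
}

#' Forward selection of temporal predictors with a double stopping criterion
#'
#' Classic forward selection on the candidate predictors: at each step the
#' candidate giving the largest increase in explained variation is tested by
#' permutation (Freedman-Lane residual permutation under the current model).
#' Selection stops when (a) the best candidate's p-value exceeds `alpha`, or
#' (b) adding it would push the cumulative adjusted R-squared above the
#' adjusted R-squared of the global model containing all candidates — the
#' overshooting candidate is rejected. Selection is only attempted when the
#' global model itself is significant at `alpha`; otherwise the selection is
#' empty.
#'
#' @param Yt (transformed) response matrix.
#' @param candidates matrix of candidate predictors (e.g.
#'   [aem_predictors()]).
#' @param alpha stopping significance level.
#' @param n_perm permutations per test.
#' @param seed optional integer seed.
#' @return List: `selected` (column indices in selection order), `order`
#'   (data frame with per-step R2, cumulative adjusted R2, F and p),
#'   `global` (global test result incl. `adj_r2`), `aborted` (`TRUE` when
#'   the global gate failed).
#' @export
forward_select <- function(Yt, candidates, alpha = 0.05, n_perm = 999,
                           seed = NULL) {
  X <- as.matrix(candidates)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (!is.null(seed)) set.seed(seed)
  Yc <- scale(as.matrix(Yt), center = TRUE, scale = FALSE)
  n <- nrow(Yc); p_all <- ncol(X)
  ss_tot <- sum(Yc^2)

  glob <- rda_perm_test(Yc, X, n_perm = n_perm)
  glob$adj_r2 <- adjusted_r2(glob$r2, n, p_all)
  if (glob$p_value > alpha)
    return(list(selected = integer(0), order = NULL, global = glob,
                aborted = TRUE))

  ssf <- function(Y, Q) sum((crossprod(Q, Y))^2)
  sel <- integer(0)
  steps <- list()
  repeat {
    remaining <- setdiff(seq_len(p_all), sel)
    if (!length(remaining) || length(sel) >= n - 2) break
    Q_red <- if (length(sel))
      qr.Q(qr(scale(X[, sel, drop = FALSE], center = TRUE, scale = FALSE)))
    else NULL
    ss_red <- if (length(sel)) ssf(Yc, Q_red) else 0

    ss_cand <- vapply(remaining, function(j) {
      Xc <- scale(X[, c(sel, j), drop = FALSE], center = TRUE, scale = FALSE)
      ssf(Yc, qr.Q(qr(Xc)))
    }, numeric(1))
    best <- remaining[which.max(ss_cand)]
    ss_full <- max(ss_cand)
    m_full <- length(sel) + 1L

    # partial pseudo-F of the best candidate given the current set
    part_f <- function(Y, Qf, ssr) {
      ssfull <- ssf(Y, Qf)
      ss_res <- max(sum(Y^2) - ssfull, 0)
      ((ssfull - ssr) / 1) / (ss_res / (n - m_full - 1))
    }
    Q_full <- qr.Q(qr(scale(X[, c(sel, best), drop = FALSE],
                            center = TRUE, scale = FALSE)))
    f_obs <- part_f(Yc, Q_full, ss_red)

    # Freedman-Lane: permute residuals of the current (reduced) model;
    # with an empty model this is plain row permutation of the response
    f_perm <- if (length(sel)) {
      fit_red <- Q_red %*% crossprod(Q_red, Yc)
      res_red <- Yc - fit_red
      vapply(seq_len(n_perm), function(i) {
        Yp <- fit_red + res_red[sample.int(n), , drop = FALSE]
        Yp <- scale(Yp, center = TRUE, scale = FALSE)
        part_f(Yp, Q_full, ssf(Yp, Q_red))
      }, numeric(1))
    } else {
      vapply(seq_len(n_perm), function(i) {
        Yp <- Yc[sample.int(n), , drop = FALSE]
        part_f(Yp, Q_full, 0)
      }, numeric(1))
    }
    p_val <- (sum(f_perm >= f_obs) + 1) / (n_perm + 1)
    if (p_val > alpha) break
    adj <- adjusted_r2(ss_full / ss_tot, n, m_full)
    if (adj > glob$adj_r2) break       # double stop: reject the overshoot
    sel <- c(sel, best)
    steps[[length(steps) + 1L]] <- data.frame(
      variable = colnames(X)[best], index = best,
      r2_cum = ss_full / ss_tot, adj_r2_cum = adj, F = f_obs, p_value = p_val)
  }
  list(selected = sel,
       order = if (length(steps)) do.call(rbind, steps) else NULL,
       global = glob, aborted = FALSE)
}

#' Sequential permutation tests of canonical axes
#'
#' Tests the canonical axes one at a time in decreasing order of eigenvalue:
#' axis k is tested with the structure of axes 1..k-1 held fixed, by
#' Freedman-Lane permutation of the residuals from the reduced model (the
#' response regressed on the earlier axes' site scores). Testing stops at
#' the first non-significant axis; the number of significant leading axes is
#' the model's temporal scale count.
#'
#' @param core an internal fitted RDA structure (from the model object).
#' @param alpha significance level.
#' @param n_perm permutations per axis.
#' @param seed optional integer seed.
#' @return Data frame: per axis eigenvalue, pseudo-F, p-value (NA once
#'   testing has stopped), and a `significant` flag.
#' @keywords internal
test_axes <- function(core, alpha = 0.05, n_perm = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Yc <- core$Yc; n <- core$n; m <- core$m
  n_axes <- length(core$eig)
  ss_res <- max(core$ss_tot - core$ss_fit, 0)
  ms_res <- ss_res / (n - m - 1)
  p_vals <- rep(NA_real_, n_axes)
  f_vals <- core$eig * (n - 1) / ms_res
  Q_x <- qr.Q(core$qrx)[, seq_len(m), drop = FALSE]

  for (k in seq_len(n_axes)) {
    Z <- if (k > 1) core$lc_scores[, seq_len(k - 1), drop = FALSE] else NULL
    if (is.null(Z)) {
      fit_red <- 0 * Yc; res_red <- Yc
    } else {
      qz <- qr(scale(Z, center = TRUE, scale = FALSE))
      fit_red <- qr.fitted(qz, Yc)
      res_red <- Yc - fit_red
    }
    f_perm <- vapply(seq_len(n_perm), function(i) {
      Yp <- fit_red + res_red[sample.int(n), , drop = FALSE]
      Yp <- scale(Yp, center = TRUE, scale = FALSE)
      Yfit_p <- Q_x %*% crossprod(Q_x, Yp)
      if (!is.null(Z)) {
        # first eigenvalue of the fitted variation beyond the fixed axes
        Yfit_p <- Yfit_p - qr.fitted(qz, Yfit_p)
      }
      ss1 <- svd(Yfit_p, nu = 0, nv = 0)$d[1]^2     # SS along the leading free axis
      ssfp <- sum((crossprod(Q_x, Yp))^2)
      ss1 / (max(sum(Yp^2) - ssfp, 0) / (n - m - 1))
    }, numeric(1))
    p_vals[k] <- (sum(f_perm >= f_vals[k]) + 1) / (n_perm + 1)
    if (p_vals[k] > alpha) break
  }
  sig <- !is.na(p_vals) & p_vals <= alpha
  # significance is the leading run: stop at first non-significant axis
  if (any(!sig)) sig[seq(from = which(!sig)[1], to = n_axes)] <- FALSE
  data.frame(axis = paste0("RDA", seq_len(n_axes)), eigenvalue = core$eig,
             F = f_vals, p_value = p_vals, significant = sig)
}
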