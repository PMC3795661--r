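#' Sequential t-test analysis of regime shifts (STARS)
#'
#' Detects step changes in the mean of a univariate series by Rodionov's
#' sequential t-test. With cut-off length `l` and level `alpha`, the critical
#' difference between the means of two adjacent regimes is
#' `diff = qt(1 - alpha/2, 2l - 2) * sqrt(2 * sigma2_l / l)`, where
#' `sigma2_l` is the average sample variance over all consecutive windows of
#' length `l`. Each new observation falling outside the current regime mean
#' +/- `diff` opens a candidate shift; a regime shift index (RSI) then
#' accumulates the Huber-weighted normalized exceedances over the following
#' `l` points. The candidate is confirmed if the RSI stays positive through
#' that window, otherwise it is rejected and the point absorbed into the
#' current regime. Regime means are Huber-weighted so single outliers do not
#' masquerade as regimes.
#'
#' @param x a [driver_series()] or numeric vector.
#' @param l cut-off length: the minimum duration (in steps) a regime must
#'   persist. For monthly data spanning seasonal cycles use `l = 12` or more,
#'   so seasonal troughs are not flagged as regimes.
#' @param alpha significance level of the sequential t-test.
#' @param huber Huber tuning constant: deviations beyond `huber` standard
#'   deviations from a regime mean are down-weighted proportionally.
#' @return Object of class `stars_fit`: `shift_indices` (1-based index of
#'   the first point of each new regime), `regime_means`, `regimes` (regime
#'   id per point), `rsi` (regime shift index per time point; positive at
#'   confirmed shifts), `diff` (critical difference), `sigma2_l`, `params`.
#' @references Rodionov, S.N. (2004) A sequential algorithm for testing
#'   climate regime shifts. Geophysical Research Letters 31, L09204.
#' @examples
#' x <- c(rnorm(15), rnorm(15, mean = 4))
#' stars(x, l = 10)
#' @export
stars <- function(x, l = 12L, alpha = 0.05, huber = 1) {
  v <- if (inherits(x, "driver_series")) x$values else as.numeric(x)
  n <- length(v)
  l <- as.integer(l)
  if (l < 2L) stop("l must be >= 2")
  if (n < 2L * l) stop("series length (", n, ") must be at least 2*l = ", 2L * l)

  # average variance of consecutive l-length windows
  nw <- n - l + 1L
  sigma2_l <- mean(vapply(seq_len(nw), function(i) var(v[i:(i + l - 1L)]),
                          numeric(1)))
  sigma_l <- sqrt(sigma2_l)
  crit_diff <- qt(1 - alpha / 2, df = 2L * l - 2L) * sqrt(2 * sigma2_l / l)

  huber_mean <- function(z) {
    if (sigma_l == 0) return(mean(z))
    m <- mean(z)
    for (it in 1:5) {
      dev <- (z - m) / sigma_l
      w <- ifelse(abs(dev) > huber, huber / abs(dev), 1)
      m_new <- sum(w * z) / sum(w)
      if (abs(m_new - m) < 1e-12) break
      m <- m_new
    }
    m
  }

  rsi <- numeric(n)
  shift_indices <- integer(0)
  regime_start <- 1L
  cur_mean <- huber_mean(v[seq_len(min(l, n))])

  i <- l + 1L
  while (i <= n) {
    dev <- v[i] - cur_mean
    if (sigma2_l > 0 && abs(dev) > crit_diff && i + l - 1L <= n) {
      # candidates whose l-length confirmation window would run past the end
      # of the series cannot be confirmed and are absorbed (tentative shifts
      # are not reported)
      up <- dev > 0
      crit_level <- cur_mean + if (up) crit_diff else -crit_diff
      jmax <- i + l - 1L
      r <- 0
      confirmed <- TRUE
      for (j in i:jmax) {
        xs <- (v[j] - crit_level) / (sigma_l * l)
        if (!up) xs <- -xs
        w <- 1
        zdev <- abs(v[j] - crit_level) / sigma_l
        if (zdev > huber) w <- huber / zdev
        r <- r + w * xs
        if (r < 0) { confirmed <- FALSE; break }
      }
      if (confirmed) {
        rsi[i] <- r
        shift_indices <- c(shift_indices, i)
        regime_start <- i
        cur_mean <- huber_mean(v[i:jmax])
        i <- i + 1L
        next
      } else {
        rsi[i] <- 0
        cur_mean <- huber_mean(v[regime_start:i])   # absorb the outlier
      }
    } else {
      cur_mean <- huber_mean(v[regime_start:i])
    }
    i <- i + 1L
  }

  bounds <- c(1L, shift_indices, n + 1L)
  regimes <- rep(seq_len(length(bounds) - 1L),
                 times = diff(bounds))
  regime_means <- vapply(split(v, regimes), huber_mean, numeric(1))

  structure(list(shift_indices = shift_indices,
                 regime_means = unname(regime_means),
                 regimes = regimes, rsi = rsi, diff = crit_diff,
                 sigma2_l = sigma2_l, values = v,
                 params = list(l = l, alpha = alpha, huber = huber)),
            class = "stars_fit")
}

#' @export
print.stars_fit <- function(x, ...) {
  cat(sprintf("STARS (l = %d, alpha = %g, huber = %g): %d regime(s)\n",
              x$params$l, x$params$alpha, x$params$huber,
              length(x$regime_means)))
  if (length(x$shift_indices))
    cat("  shifts at index:", paste(x$shift_indices, collapse = ", "), "\n")
  cat("  regime means:", paste(signif(x$regime_means, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.stars_fit <- function(x, ...) {
  plot.default(seq_along(x$values), x$values, type = "l", col = "grey50",
               xlab = "time", ylab = "driver", ...)
  step_means <- x$regime_means[x$regimes]
  lines(seq_along(x$values), step_means, col = "black", lwd = 2, type = "s")
  abline(v = x$shift_indices - 0.5, lty = 3)
  invisible(x)
}

#' Turn detected regimes into state windows
#'
#' @param fit a [stars()] result.
#' @param labels one state name per regime, in temporal order.
#' @return Data frame (`start`, `end`, `state`) suitable for
#'   [split_by_state()]. Windows are expressed on the index scale of the
#'   series handed to [stars()].
#' @export
states_from_regimes <- function(fit, labels) {
  n_reg <- length(fit$regime_means)
  if (length(labels) != n_reg)
    stop("need exactly ", n_reg, " state labels, got ", length(labels))
  bounds <- c(1L, fit$shift_indices, length(fit$values) + 1L)
  data.frame(start = bounds[-length(bounds)], end = bounds[-1] - 1L,
             state = as.character(labels))
}
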