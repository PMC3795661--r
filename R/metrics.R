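#' Per-sample community metrics
#'
#' For each time step: taxon richness S (taxa with positive biovolume),
#' Shannon entropy H (nats, on biovolume proportions), its number equivalent
#' D = exp(H) (effective number of equally abundant taxa), evenness
#' E = D / S (mathematically independent of richness), and total biovolume.
#' A time step with no positive biovolume is flagged `undefined` and its
#' metrics are `NA`, never silently zero.
#'
#' @param cts a [community_ts()].
#' @return Data frame with one row per time step: `site`, `state`, `time`,
#'   `richness`, `shannon`, `diversity`, `evenness`, `total_biovolume`,
#'   `undefined`.
#' @examples
#' cts <- community_ts(matrix(c(1, 1, 2, 4, 0, 0), 2, 3, byrow = TRUE))
#' community_metrics(cts)
#' @export
community_metrics <- function(cts) {
  y <- cts$biovolume
  S <- rowSums(y > 0)
  total <- rowSums(y)
  # vegan::diversity() drops single-column matrices to vectors, so handle
  # the one-taxon community explicitly (H is identically 0 there)
  H_raw <- if (ncol(y) == 1L) rep(0, nrow(y))
           else vegan::diversity(y, index = "shannon")
  H <- ifelse(total > 0, H_raw, NA_real_)
  D <- exp(H)
  E <- D / S
  undef <- total <= 0
  H[undef] <- D[undef] <- E[undef] <- NA_real_
  data.frame(site = cts$site_id, state = cts$state_id, time = cts$times,
             richness = as.integer(S), shannon = H, diversity = D,
             evenness = E, total_biovolume = total, undefined = undef,
             row.names = NULL)
}

#' Two-factor repeated-measures ANOVA with Huynh-Feldt correction
#'
#' Fits the fully within-subject two-factor repeated-measures decomposition
#' (subjects crossed with state and time) used to contrast a community metric
#' between alternative states: effects State, Time and State x Time, each
#' tested against its own subject-interaction error stratum, with Type III
#' sums of squares (identical to Type I here because the design must be
#' balanced). Sphericity is handled by the Huynh-Feldt epsilon, estimated per
#' within-subject effect from the sample covariance of the orthonormal
#' effect contrasts and applied to numerator and denominator degrees of
#' freedom (capped at 1).
#'
#' @param data data frame with one row per observation.
#' @param value name of the metric column.
#' @param subject,state,time names of the factor columns (subjects are
#'   typically sites).
#' @param log_transform if `TRUE`, analyse `log(x + 1)` (used for strictly
#'   positive right-skewed metrics such as total biovolume).
#' @return An object of class `rm_anova` wrapping the effect table
#'   (uncorrected and epsilon-corrected df, SS, MS, F, P, epsilon).
#' @examples
#' d <- expand.grid(subject = 1:4, state = c("wet", "dry"), time = 1:6)
#' d$y <- rnorm(nrow(d)) + as.numeric(d$state == "dry")
#' rm_anova(d, "y")
#' @export
rm_anova <- function(data, value, subject = "subject", state = "state",
                     time = "time", log_transform = FALSE) {
  f_sub <- factor(data[[subject]])
  f_sta <- factor(data[[state]])
  f_tim <- factor(data[[time]])
  y <- data[[value]]
  if (log_transform) y <- log(y + 1)
  if (anyNA(y)) stop("metric contains NA; drop undefined time steps first")

  n <- nlevels(f_sub); a <- nlevels(f_sta); b <- nlevels(f_tim)
  tab <- table(f_sub, f_sta, f_tim)
  if (any(tab != 1L))
    stop("design must be complete and balanced (one observation per ",
         "subject x state x time cell); drop incomplete subjects")

  # subject-by-cell matrix, cells ordered state (slow) x time (fast)
  M <- matrix(NA_real_, n, a * b)
  cell <- (as.integer(f_sta) - 1L) * b + as.integer(f_tim)
  M[cbind(as.integer(f_sub), cell)] <- y

  contr <- function(k) {           # orthonormal contrasts, k levels
    cm <- stats::contr.helmert(k)
    sweep(cm, 2, sqrt(colSums(cm^2)), "/")
  }
  ones <- function(k) matrix(1 / sqrt(k), k, 1)
  Ca <- contr(a); Cb <- contr(b)
  eff <- list(
    State          = kronecker(Ca, ones(b)),
    Time           = kronecker(ones(a), Cb),
    `State x Time` = kronecker(Ca, Cb))

  rows <- lapply(names(eff), function(nm) {
    Tm <- M %*% eff[[nm]]                    # n x d contrast scores
    d <- ncol(Tm)
    mu <- colMeans(Tm)
    ss_eff <- n * sum(mu^2)
    ss_err <- sum(sweep(Tm, 2, mu)^2)
    # clamp floating-point fuzz from constant input to an exact zero
    tol0 <- 1e-20 * max(1, sum(M^2))
    if (ss_eff < tol0) ss_eff <- 0
    if (ss_err < tol0) ss_err <- 0
    df1 <- d; df2 <- d * (n - 1)
    ms_eff <- ss_eff / df1; ms_err <- ss_err / df2
    Fv <- if (ms_err > 0) ms_eff / ms_err else NA_real_
    S <- cov(Tm)
    eps_gg <- sum(diag(S))^2 / (d * sum(S^2))
    # Huynh & Feldt correction for a single-group repeated-measures design
    eps_hf <- (n * d * eps_gg - 2) / (d * (n - 1 - d * eps_gg))
    eps_hf <- min(1, max(eps_hf, 1 / d))
    if (!is.finite(eps_hf)) eps_hf <- 1
    P <- if (is.na(Fv)) NA_real_ else pf(Fv, df1 * eps_hf, df2 * eps_hf,
                                         lower.tail = FALSE)
    data.frame(effect = nm, df_num = df1 * eps_hf, df_den = df2 * eps_hf,
               SS = ss_eff, MS = ms_eff, SS_error = ss_err, MS_error = ms_err,
               F = Fv, P = P, epsilon_hf = eps_hf, eps_gg = eps_gg,
               df_num_unc = df1, df_den_unc = df2)
  })
  tab <- do.call(rbind, rows)

  gm <- mean(M)
  structure(list(table = tab, n_subjects = n, n_states = a, n_times = b,
                 ss_total = sum((M - gm)^2),
                 ss_subjects = a * b * sum((rowMeans(M) - gm)^2),
                 log_transform = log_transform, value = value),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, digits = 4, ...) {
  cat(sprintf("Repeated-measures ANOVA of '%s'%s (%d subjects, %d states, %d times)\n",
              x$value, if (x$log_transform) " [log(x+1)]" else "",
              x$n_subjects, x$n_states, x$n_times))
  tab <- x$table
  out <- data.frame(
    `d.f.` = sprintf("%.2f, %.2f", tab$df_num, tab$df_den),
    MS = signif(tab$MS, digits), F = signif(tab$F, digits),
    P = signif(tab$P, digits), eps_HF = round(tab$epsilon_hf, 3),
    row.names = tab$effect, check.names = FALSE)
  print(out)
  invisible(x)
}
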