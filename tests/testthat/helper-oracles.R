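# Independent oracles, coded separately from the package internals.

# Brute-force two-within-factor repeated-measures decomposition by explicit
# summation over cell means (subjects x state x time, balanced).
brute_rm_anova <- function(d, value = "y") {
  y <- d[[value]]
  s <- factor(d$subject); a <- factor(d$state); b <- factor(d$time)
  n <- nlevels(s); A <- nlevels(a); B <- nlevels(b)
  gm <- mean(y)
  m_a  <- tapply(y, a, mean);        m_b  <- tapply(y, b, mean)
  m_s  <- tapply(y, s, mean)
  m_ab <- tapply(y, list(a, b), mean)
  m_as <- tapply(y, list(a, s), mean)
  m_bs <- tapply(y, list(b, s), mean)
  ss_state <- n * B * sum((m_a - gm)^2)
  ss_time  <- n * A * sum((m_b - gm)^2)
  ss_int <- n * sum((m_ab - outer(m_a, m_b, "+") + gm)^2)
  ss_state_err <- B * sum((m_as - outer(m_a, m_s, "+") + gm)^2)
  ss_time_err  <- A * sum((m_bs - outer(m_b, m_s, "+") + gm)^2)
  fit3 <- numeric(length(y))
  for (i in seq_along(y)) {
    fit3[i] <- m_ab[a[i], b[i]] + m_as[a[i], s[i]] + m_bs[b[i], s[i]] -
      m_a[a[i]] - m_b[b[i]] - m_s[s[i]] + gm
  }
  ss_int_err <- sum((y - fit3)^2)
  data.frame(
    effect = c("State", "Time", "State x Time"),
    SS = c(ss_state, ss_time, ss_int),
    SS_error = c(ss_state_err, ss_time_err, ss_int_err),
    df1 = c(A - 1, B - 1, (A - 1) * (B - 1)),
    df2 = c((A - 1) * (n - 1), (B - 1) * (n - 1), (A - 1) * (B - 1) * (n - 1)))
}

# One-shot SVD oracle for the AEM basis: incidence built by a different
# construction (logical outer product), centred with sweep.
svd_aem_oracle <- function(n) {
  E <- 1 * outer(seq_len(n), seq_len(n - 1), function(i, j) i > j)
  Ec <- sweep(E, 2, colMeans(E))
  sv <- svd(Ec)
  keep <- sv$d > max(sv$d) * 1e-10
  list(U = sv$u[, keep, drop = FALSE], d = sv$d[keep])
}

# Per-column regression oracle for the RDA R2: fit each response column on
# the predictors with lm() and pool the fitted sums of squares.
r2_by_columns <- function(Y, X) {
  Yc <- scale(Y, scale = FALSE)
  ss_fit <- 0; ss_tot <- 0
  for (j in seq_len(ncol(Yc))) {
    fit <- lm(Yc[, j] ~ X)
    ss_fit <- ss_fit + sum(fitted(fit)^2)
    ss_tot <- ss_tot + sum(Yc[, j]^2)
  }
  ss_fit / ss_tot
}

# All permutations of 1..k (k small)
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_perms(v[-i]), function(r) c(v[i], r))))
}

# Fraction of signal taxa assigned to the axis matching their planted scale,
# under the best bijective axis-to-scale matching (confusion-matrix style).
matched_accuracy <- function(truth, assignment, n_groups) {
  signal <- truth != "stochastic"
  axes <- setdiff(unique(assignment), "Stochastic")
  if (!length(axes)) return(0)
  conf <- table(factor(truth[signal], paste0("scale", seq_len(n_groups))),
                factor(assignment[signal], axes))
  best <- 0
  for (p in all_perms(seq_along(axes))) {
    hits <- sum(vapply(seq_len(min(n_groups, length(axes))),
                       function(g) conf[g, p[g]], numeric(1)))
    best <- max(best, hits)
  }
  best / sum(signal)
}

# small helper: community object from a plain matrix without warnings
quiet_sim <- function(...) suppressWarnings(simulate_community(...))
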