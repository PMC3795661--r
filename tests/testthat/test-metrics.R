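test_that("diversity identities hold on closed-form cases", {
  # single taxon
  m1 <- community_metrics(community_ts(matrix(5, 3, 1)))
  expect_equal(m1$richness, rep(1L, 3))
  expect_equal(m1$shannon, rep(0, 3))
  expect_equal(m1$diversity, rep(1, 3))
  expect_equal(m1$evenness, rep(1, 3))
  expect_equal(m1$total_biovolume, rep(5, 3))
  # maximum evenness: four equal taxa
  m4 <- community_metrics(community_ts(matrix(2, 3, 4)))
  expect_equal(m4$shannon, rep(log(4), 3))
  expect_equal(m4$diversity, rep(4, 3))
  expect_equal(m4$evenness, rep(1, 3))
  # hand evaluation: p = (1/4, 1/4, 1/2)
  m <- community_metrics(community_ts(matrix(c(1, 1, 2), 3, 3, byrow = TRUE)))
  expect_equal(m$shannon[1], 1.0397208, tolerance = 1e-6)
  expect_equal(m$diversity[1], 2.8284271, tolerance = 1e-6)
  expect_equal(m$evenness[1], 0.9428090, tolerance = 1e-6)
})

test_that("metric identities and permutation invariance on random data", {
  set.seed(20)
  y <- matrix(rlnorm(24 * 9), 24, 9)
  y[y < 0.4] <- 0
  y[1, ] <- c(1, rep(0, 8))          # keep every row occupied
  m <- community_metrics(community_ts(y))
  expect_equal(m$diversity, exp(m$shannon))
  expect_equal(m$evenness, m$diversity / m$richness)
  expect_true(all(m$diversity <= m$richness + 1e-12))
  expect_true(all(m$evenness > 0 & m$evenness <= 1 + 1e-12))
  perm <- sample(ncol(y))
  m2 <- community_metrics(community_ts(y[, perm]))
  expect_equal(m2[c("richness", "shannon", "total_biovolume")],
               m[c("richness", "shannon", "total_biovolume")])
})

test_that("an all-zero time step is flagged undefined, not zeroed", {
  y <- matrix(1, 3, 2); y[2, ] <- 0
  m <- community_metrics(community_ts(y))
  expect_true(m$undefined[2])
  expect_true(is.na(m$shannon[2]) && is.na(m$evenness[2]))
  expect_false(any(m$undefined[-2]))
})

test_that("rm-ANOVA matches the brute-force summation oracle", {
  set.seed(31)
  for (rep in 1:3) {
    d <- expand.grid(subject = factor(1:3), state = factor(c("w", "d")),
                     time = factor(1:4))
    d$y <- rnorm(nrow(d), sd = 2) + rep(rnorm(3), 8)[as.integer(d$subject)]
    fit <- rm_anova(d, "y")
    ora <- brute_rm_anova(d)
    expect_equal(fit$table$SS, ora$SS, tolerance = 1e-10)
    expect_equal(fit$table$SS_error, ora$SS_error, tolerance = 1e-10)
    expect_equal(fit$table$df_num_unc, ora$df1)
    expect_equal(fit$table$df_den_unc, ora$df2)
    expect_equal(fit$table$MS, ora$SS / ora$df1, tolerance = 1e-10)
    expect_equal(fit$table$F, (ora$SS / ora$df1) / (ora$SS_error / ora$df2),
                 tolerance = 1e-10)
    # conservation: total SS decomposes into subjects + effects + errors
    expect_equal(fit$ss_total,
                 fit$ss_subjects + sum(fit$table$SS) + sum(fit$table$SS_error),
                 tolerance = 1e-10)
  }
})

test_that("rm-ANOVA agrees with the multivariate reference implementation", {
  set.seed(5)
  n <- 6; b <- 6
  d <- expand.grid(subject = factor(1:n), state = factor(c("s1", "s2")),
                   time = factor(1:b))
  d$y <- rnorm(nrow(d)) + as.numeric(d$time) / 3 * (d$state == "s2") +
    rep(rnorm(n), 2 * b)[as.integer(d$subject)]
  fit <- rm_anova(d, "y")
  M <- matrix(0, n, 2 * b)
  cell <- (as.integer(d$state) - 1) * b + as.integer(d$time)
  M[cbind(as.integer(d$subject), cell)] <- d$y
  A <- car::Anova(lm(M ~ 1),
                  idata = data.frame(state = factor(rep(c("s1", "s2"), each = b)),
                                     time = factor(rep(1:b, 2))),
                  idesign = ~ state * time, type = 3)
  s <- summary(A, multivariate = FALSE)
  u <- s$univariate.tests
  expect_equal(fit$table$SS, unname(u[c("state", "time", "state:time"), "Sum Sq"]),
               tolerance = 1e-8)
  expect_equal(fit$table$F, unname(u[c("state", "time", "state:time"), "F value"]),
               tolerance = 1e-8)
  adj <- s$pval.adjustments
  expect_equal(fit$table$epsilon_hf[2:3], unname(adj[, "HF eps"]),
               tolerance = 1e-8)
  expect_equal(fit$table$P[2:3], unname(adj[, "Pr(>F[HF])"]), tolerance = 1e-8)
})

test_that("sphericity is exact for two-level factors and degenerate input flags", {
  set.seed(8)
  d <- expand.grid(subject = factor(1:5), state = factor(c("w", "d")),
                   time = factor(1:2))
  d$y <- rnorm(nrow(d))
  fit <- rm_anova(d, "y")
  expect_equal(fit$table$epsilon_hf, rep(1, 3))   # d = 1: sphericity trivial
  expect_equal(fit$table$df_num, fit$table$df_num_unc)
  # constant response: zero mean squares, undefined F
  d$y <- 3
  fit0 <- rm_anova(d, "y")
  expect_true(all(fit0$table$MS == 0))
  expect_true(all(is.na(fit0$table$F)))
  # incomplete design is refused
  expect_error(rm_anova(d[-1, ], "y"), "balanced")
})

test_that("for clearly significant effects the corrected P is conservative", {
  # the df correction inflates the p-value of an effect whose F is well above
  # 1 (around F = 1 the two fractional-df distributions can cross)
  set.seed(77)
  for (rep in 1:5) {
    d <- expand.grid(subject = factor(1:5), state = factor(c("w", "d")),
                     time = factor(1:6))
    d$y <- rnorm(nrow(d), sd = 0.3) +
      as.numeric(d$time) * (1 + 0.5 * rnorm(5)[as.integer(d$subject)])
    fit <- rm_anova(d, "y")
    with(fit$table, {
      p_unc <- pf(F, df_num_unc, df_den_unc, lower.tail = FALSE)
      strong <- F > 2
      expect_true(all(P[strong] >= p_unc[strong] - 1e-9))
      expect_true(any(epsilon_hf < 1))      # correction actually engaged
    })
  }
})
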