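test_that("normality screen keeps normal samples and rejects skewed ones", {
  set.seed(71)
  p_norm <- replicate(100, ks_normality(rnorm(1000), B = 500)$p)
  expect_gte(sum(p_norm > 0.05), 90)
  p_exp <- replicate(100, ks_normality(rexp(1000), B = 500)$p)
  expect_gte(sum(p_exp < 0.05), 95)

  r <- ks_normality(rnorm(50))
  expect_gte(r$statistic, 0)
  expect_lte(r$statistic, 1)
  # statistic agrees with the reference Lilliefors implementation
  x <- rnorm(200)
  expect_equal(ks_normality(x)$statistic,
               unname(nortest::lillie.test(x)$statistic))
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(1:4), "at least 5")
})

test_that("Friedman statistic matches the rank formula in closed cases", {
  m_tied <- matrix(rep(c(2, 2, 2, 2), 6), 6, 4, byrow = TRUE)
  r <- friedman_rm(m_tied, p_method = "chisq")
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  # strictly increasing rows: ranks 1..4 per row, Q = 30 at n = 10
  set.seed(72)
  m_ord <- t(apply(matrix(rnorm(40), 10, 4), 1, sort))
  expect_equal(friedman_rm(m_ord, p_method = "chisq")$statistic, 30)

  # agrees with the base-R implementation on untied data
  set.seed(73)
  m <- matrix(rnorm(60), 12, 5)
  ref <- stats::friedman.test(m)
  mine <- friedman_rm(m, p_method = "chisq")
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p, ref$p.value)
})

test_that("exact Friedman p matches a brute-force permutation oracle", {
  perm3 <- matrix(c(1,2,3, 1,3,2, 2,1,3, 2,3,1, 3,1,2, 3,2,1),
                  ncol = 3, byrow = TRUE)
  oracle_p <- function(m) {
    stat <- function(mm) unname(stats::friedman.test(mm)$statistic)
    s_obs <- stat(m)
    idx <- expand.grid(1:6, 1:6, 1:6, 1:6)
    hits <- 0
    for (r in seq_len(nrow(idx))) {
      mm <- m
      for (s in 1:4) mm[s, ] <- m[s, perm3[idx[r, s], ]]
      if (stat(mm) >= s_obs - 1e-9) hits <- hits + 1
    }
    hits / nrow(idx)
  }
  set.seed(74)
  for (i in 1:3) {
    m <- matrix(rnorm(12), 4, 3)
    expect_equal(friedman_rm(m, p_method = "exact")$p, oracle_p(m),
                 tolerance = 1e-12)
  }
})

test_that("Friedman is invariant under monotone within-subject transforms", {
  set.seed(75)
  m <- matrix(rnorm(40, mean = 5), 10, 4)
  a <- friedman_rm(m, p_method = "chisq")
  b <- friedman_rm(exp(m / 2), p_method = "chisq")
  expect_equal(a$statistic, b$statistic)
})

test_that("GG-corrected RM-ANOVA matches aov and bounds epsilon", {
  set.seed(76)
  X <- matrix(rnorm(30 * 4), 30, 4) + rnorm(30)
  X[, 4] <- X[, 4] + 1   # a real condition effect, so F > 1
  r <- rm_anova_gg(X)
  df <- data.frame(y = as.vector(X), cond = factor(rep(1:4, each = 30)),
                   s = factor(rep(1:30, 4)))
  a <- summary(stats::aov(y ~ cond + Error(s / cond), data = df))
  F_ref <- a[["Error: s:cond"]][[1]]["cond", "F value"]
  p_unc <- a[["Error: s:cond"]][[1]]["cond", "Pr(>F)"]
  expect_equal(r$statistic, F_ref, tolerance = 1e-10)
  expect_gte(r$epsilon, 1 / 3)
  expect_lte(r$epsilon, 1)
  expect_gte(r$p, p_unc)  # the correction can only make p larger

  # sphericity holds for exchangeable data: epsilon near 1 at large n
  set.seed(77)
  Xc <- matrix(rnorm(200 * 4), 200, 4) + rnorm(200)
  expect_gt(rm_anova_gg(Xc)$epsilon, 0.95)

  # k = 2: sphericity is vacuous
  expect_equal(rm_anova_gg(matrix(rnorm(40), 20, 2))$epsilon, 1)
})

test_that("Bonferroni post hocs scale raw p by the number of pairs", {
  set.seed(78)
  m <- matrix(rnorm(15 * 4), 15, 4, dimnames = list(NULL, letters[1:4]))
  m[, 4] <- m[, 4] + 2
  ph <- posthoc_t_bonferroni(m)
  expect_true(isSymmetric(ph))
  expect_equal(diag(ph), rep(1, 4), ignore_attr = TRUE)
  raw <- stats::t.test(m[, 1], m[, 4], paired = TRUE)$p.value
  expect_equal(ph["a", "d"], min(1, 6 * raw))
  expect_true(all(ph >= pmin(1, raw)))  # adjusted never below raw

  m_id <- cbind(a = m[, 1], b = m[, 1])
  expect_warning(ph_id <- posthoc_t_bonferroni(m_id), "zero-variance")
  expect_equal(ph_id["a", "b"], 1)
})

test_that("Cohen's d uses the pooled SD and is anti-symmetric", {
  expect_equal(cohens_d(c(1, 2, 3), c(3, 4, 5)), -2)
  expect_equal(cohens_d(c(5, 6), c(5, 6)), 0)
  a <- rnorm(10)
  b <- rnorm(12, 1)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
  expect_error(cohens_d(c(1, 1), c(1, 1)), "zero pooled SD")
})

test_that("the mixed model recovers a noiseless speed slope exactly", {
  speeds <- c(1.41, 0.86, 0.31, 0.19)
  n <- 40
  set.seed(79)
  b_i <- rnorm(n, 0, 0.5)
  mod <- rep(c(0, 1), length.out = n)
  dat <- expand.grid(subject_id = seq_len(n), speed = speeds)
  dat$moderator <- mod[dat$subject_id]
  dat$z_scl <- 0.2 - 0.8 * dat$speed + 0 * dat$moderator + b_i[dat$subject_id]
  fit <- suppressWarnings(
    mixed_mediation(dat, "z_scl", "speed", "moderator"))
  expect_equal(fit$beta[fit$term == "speed"], -0.8, tolerance = 5e-4)

  dat$moderator <- 1
  expect_error(mixed_mediation(dat, "z_scl", "speed", "moderator"),
               "constant")
})

test_that("study analysis picks the test by the normality screen", {
  set.seed(80)
  n <- 24
  feats <- expand.grid(subject_id = sprintf("s%02d", 1:n),
                       label = c("a", "b", "c"))
  feats$gaussian <- rnorm(nrow(feats)) +
    rep(rnorm(n), 3) + as.numeric(feats$label == "c")
  feats$skewed <- rexp(nrow(feats))^2
  feats$subject_id <- as.character(feats$subject_id)
  feats$label <- as.character(feats$label)
  res <- analyze_study(feats, feature_cols = c("gaussian", "skewed"),
                       labels = c("a", "b", "c"))
  expect_equal(res$gaussian$test_used, "rm_anova_gg")
  expect_equal(res$skewed$test_used, "friedman")
  expect_true(all(dim(res$gaussian$posthoc) == c(3, 3)))

  expect_error(analyze_study(feats[feats$label == "a", ],
                             feature_cols = "gaussian", labels = "a"),
               "at least 2")
})
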