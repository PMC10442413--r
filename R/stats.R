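# cache of Monte-Carlo null distributions for the Lilliefors statistic,
# keyed by "n:B" (the null law depends only on the sample size)
.lillie_cache <- new.env(parent = emptyenv())

lillie_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  max(pmax(seq_len(n) / n - p, p - (seq_len(n) - 1) / n))
}

#' Lilliefors-type normality screen
#'
#' One-sample Kolmogorov-Smirnov distance against a normal with the sample
#' mean and SD. Because the parameters are estimated, the classical KS null
#' law does not apply; the p-value is obtained by Monte Carlo under the
#' normal null with a fixed internal seed (seed 1234, so results are
#' reproducible), with the null table cached per sample size.
#'
#' @param x Numeric vector (n >= 5, non-constant).
#' @param B Number of Monte-Carlo null replicates.
#' @return List with `statistic` (in \[0, 1\]) and `p`.
#' @export
ks_normality <- function(x, B = 1000) {
  n <- length(x)
  if (n < 5L) stop("need at least 5 observations")
  if (stats::sd(x) == 0) stop("constant vector")
  d <- lillie_stat(x)
  key <- paste(n, B, sep = ":")
  if (is.null(.lillie_cache[[key]])) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(1234)
    .lillie_cache[[key]] <- vapply(seq_len(B), function(i) {
      lillie_stat(stats::rnorm(n))
    }, numeric(1))
  }
  null_d <- .lillie_cache[[key]]
  list(statistic = d, p = (1 + sum(null_d >= d)) / (B + 1))
}

#' Repeated-measures matrix for one feature
#'
#' Pivots a long feature table into a complete-case subjects x conditions
#' matrix (subjects with any missing condition are dropped, mirroring the
#' exclusion of incomplete subjects from repeated-measures analyses).
#'
#' @param features Long table with `subject_id`, `label` and the feature.
#' @param feature Name of the feature column.
#' @param labels Optional condition ordering.
#' @return Numeric matrix, rownames subjects, colnames conditions.
#' @export
rm_matrix <- function(features, feature, labels = NULL) {
  if (is.null(labels)) labels <- unique(features$label)
  subj <- unique(features$subject_id)
  m <- matrix(NA_real_, length(subj), length(labels),
              dimnames = list(subj, labels))
  for (i in seq_len(nrow(features))) {
    m[features$subject_id[i], features$label[i]] <- features[[feature]][i]
  }
  m[stats::complete.cases(m), , drop = FALSE]
}

# tie-corrected Friedman statistic from a subjects x conditions matrix
friedman_statistic <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  r <- t(apply(m, 1, rank))
  Q <- 12 / (n * k * (k + 1)) * sum(colSums(r)^2) - 3 * n * (k + 1)
  ties <- sum(apply(m, 1, function(row) {
    tab <- table(row)
    sum(tab^3 - tab)
  }))
  corr <- 1 - ties / (n * k * (k^2 - 1))
  if (corr > 0) Q <- Q / corr
  Q
}

all_perms <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(k - 1L)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                            sub[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE]))
  }
  out
}

#' Friedman rank test for repeated measures
#'
#' Within-subject mid-ranks with the usual tie correction;
#' `Q = 12/(n k (k+1)) * sum(Rj^2) - 3 n (k+1)` before correction. For
#' small tables (`(k!)^n` enumerable) the p-value is the exact permutation
#' tail probability over all within-subject orderings; otherwise the
#' chi-square approximation with `k - 1` degrees of freedom is used.
#' All-tied data give `Q = 0`, `p = 1`.
#'
#' @param m Subjects x conditions matrix (complete cases).
#' @param p_method `"auto"`, `"chisq"` or `"exact"`.
#' @param exact_limit Largest `(k!)^n` enumerated under `"auto"`.
#' @return A `stat_report` list: `test`, `statistic`, `df`, `p`, `method`.
#' @export
friedman_rm <- function(m, p_method = c("auto", "chisq", "exact"),
                        exact_limit = 2000) {
  p_method <- match.arg(p_method)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 conditions")
  Q <- friedman_statistic(m)
  n_perm <- factorial(k)^n
  use_exact <- p_method == "exact" ||
    (p_method == "auto" && n_perm <= exact_limit)
  if (use_exact) {
    if (n_perm > 5e6) stop("exact enumeration infeasible for this table size")
    # Q is monotone in S = sum(colSums(ranks)^2) and the tie correction is
    # invariant under within-row permutation, so enumerate S directly.
    r <- t(apply(m, 1, rank))
    s_obs <- sum(colSums(r)^2)
    perms <- all_perms(k)
    idx <- rep(1L, n)
    total <- 0L
    hits <- 0L
    repeat {
      cs <- numeric(k)
      for (s in seq_len(n)) cs <- cs + r[s, perms[idx[s], ]]
      if (sum(cs^2) >= s_obs - 1e-9) hits <- hits + 1L
      total <- total + 1L
      j <- 1L
      while (j <= n) {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= nrow(perms)) break
        idx[j] <- 1L
        j <- j + 1L
      }
      if (j > n) break
    }
    p <- hits / total
    method <- "exact permutation"
  } else {
    p <- stats::pchisq(Q, df = k - 1, lower.tail = FALSE)
    method <- "chi-square approximation"
  }
  structure(list(test = "friedman", statistic = Q, df = k - 1, p = p,
                 method = method, n = n, k = k),
            class = "stat_report")
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Standard one-way within-subject F statistic; sphericity is compensated
#' by the Greenhouse-Geisser epsilon computed from the double-centered
#' sample covariance of the condition scores, `eps = tr(C)^2 / ((k-1)
#' sum(C^2))`, bounded in `[1/(k-1), 1]` (exactly 1 at k = 2). The p-value
#' uses the corrected degrees of freedom `eps (k-1)` and `eps (k-1)(n-1)`.
#'
#' @param m Subjects x conditions matrix (complete cases).
#' @return A `stat_report` list: `statistic` (F), `df` (corrected pair),
#'   `df_uncorrected`, `epsilon`, `p`.
#' @export
rm_anova_gg <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  if (k < 2L) stop("need >= 2 conditions")
  if (n < 3L) stop("need >= 3 subjects")
  grand <- mean(m)
  cond_means <- colMeans(m)
  subj_means <- rowMeans(m)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_err <- sum((m - outer(subj_means, cond_means, `+`) + grand)^2)
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  if (ss_err <= 0) stop("zero within-subject error; F undefined")
  Fstat <- (ss_cond / df1) / (ss_err / df2)

  C <- stats::cov(m)
  Cc <- C - outer(rowMeans(C), colMeans(C), `+`) + mean(C)
  denom <- (k - 1) * sum(Cc^2)
  if (denom <= 0) {
    stop(paste("singular condition covariance (n too small relative to k);",
               "epsilon is only bounded below by 1/(k-1)"))
  }
  eps <- sum(diag(Cc))^2 / denom
  eps <- min(1, max(1 / (k - 1), eps))
  p <- stats::pf(Fstat, eps * df1, eps * df2, lower.tail = FALSE)
  structure(list(test = "rm_anova_gg", statistic = Fstat,
                 df = c(eps * df1, eps * df2), df_uncorrected = c(df1, df2),
                 epsilon = eps, p = p, n = n, k = k),
            class = "stat_report")
}

#' @export
print.stat_report <- function(x, ...) {
  if (x$test == "friedman") {
    cat(sprintf("Friedman: Chi2(%d) = %.2f, p = %.4g (%s), n = %d\n",
                x$df, x$statistic, x$p, x$method, x$n))
  } else {
    cat(sprintf("RM-ANOVA: F(%.2f; %.2f) = %.2f, p = %.4g, GG epsilon = %.3f, n = %d\n",
                x$df[1], x$df[2], x$statistic, x$p, x$epsilon, x$n))
  }
  invisible(x)
}

#' Bonferroni-corrected pairwise post hoc t-tests
#'
#' Paired t-test for every condition pair; raw p-values are multiplied by
#' the number of pairs `m = k (k-1) / 2` and capped at 1. A zero-variance
#' difference vector gives p = 0 when the mean difference is nonzero and
#' p = 1 when it is zero, with a warning.
#'
#' @param m Subjects x conditions matrix (complete cases).
#' @return Symmetric k x k matrix of adjusted p-values, unit diagonal.
#' @export
posthoc_t_bonferroni <- function(m) {
  k <- ncol(m)
  if (k < 2L) stop("need >= 2 conditions")
  n_comp <- k * (k - 1) / 2
  out <- matrix(1, k, k, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- m[, i] - m[, j]
      if (stats::sd(d) == 0) {
        warning(sprintf("zero-variance difference for pair %s-%s",
                        colnames(m)[i], colnames(m)[j]))
        p_raw <- if (mean(d) == 0) 1 else 0
      } else {
        p_raw <- stats::t.test(m[, i], m[, j], paired = TRUE)$p.value
      }
      out[i, j] <- out[j, i] <- min(1, n_comp * p_raw)
    }
  }
  out
}

#' Cohen's d for two independent groups
#'
#' `(mean(a) - mean(b)) / s_pooled`, with the pooled SD using `n - 1`
#' weights.
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @return Effect size d.
#' @export
cohens_d <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs n >= 2")
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
  if (sp == 0) stop("zero pooled SD")
  (mean(a) - mean(b)) / sp
}

#' Mixed model with a moderating group variable
#'
#' Linear mixed model with random intercept per subject and fixed effects
#' for the condition value (e.g. walking speed), the moderator (e.g. the
#' fast/slow grouping or the desire to overtake) and their interaction:
#' `response ~ value * moderator + (1 | subject)`. Degrees of freedom and
#' p-values use the Satterthwaite approximation; a singular random-effects
#' fit falls back to a fixed-effects model with a warning. The response is
#' expected to be baseline z-standardized.
#'
#' @param data Long data frame.
#' @param response,value,moderator,subject Column names.
#' @return Data frame with one row per term: `term`, `beta`, `se`, `t`,
#'   `df`, `p`.
#' @export
mixed_mediation <- function(data, response, value, moderator,
                            subject = "subject_id") {
  if (length(unique(data[[moderator]])) < 2L) {
    stop("moderator is constant; interaction model is rank deficient")
  }
  f <- stats::as.formula(sprintf("%s ~ %s * %s + (1 | %s)",
                                 response, value, moderator, subject))
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(f, data = data,
                                    control = lme4::lmerControl(
                                      check.conv.singular = "ignore"))),
    error = function(e) NULL)
  if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
    co <- stats::coef(summary(fit))
    return(data.frame(term = rownames(co), beta = co[, "Estimate"],
                      se = co[, "Std. Error"], t = co[, "t value"],
                      df = co[, "df"], p = co[, "Pr(>|t|)"],
                      row.names = NULL))
  }
  warning("singular random-effects fit; falling back to fixed-effects model")
  ff <- stats::as.formula(sprintf("%s ~ %s * %s", response, value, moderator))
  co <- stats::coef(summary(stats::lm(ff, data = data)))
  data.frame(term = rownames(co), beta = co[, "Estimate"],
             se = co[, "Std. Error"], t = co[, "t value"],
             df = stats::df.residual(stats::lm(ff, data = data)),
             p = co[, "Pr(>|t|)"], row.names = NULL)
}

#' Study-level analysis of a feature table
#'
#' For each feature: screen every condition cell for normality
#' ([ks_normality()] at `alpha_normal`); if any cell rejects, compare
#' conditions with the Friedman rank test, otherwise with the
#' Greenhouse-Geisser corrected repeated-measures ANOVA; always follow up
#' with Bonferroni-corrected pairwise paired t-tests.
#'
#' @param features Long feature table (`subject_id`, `label`, features).
#' @param feature_cols Features to analyse.
#' @param labels Condition ordering (default: order of appearance).
#' @param alpha_normal Normality screening level.
#' @return Named list per feature: `omnibus` (`stat_report`), `posthoc`
#'   (adjusted-p matrix), `normality` (per-cell p), `test_used`.
#' @export
analyze_study <- function(features, feature_cols = c("mean_scl", "nsscr_count",
                                                     "mean_amplitude", "edasymp"),
                          labels = NULL, alpha_normal = 0.05) {
  if (is.null(labels)) labels <- unique(features$label)
  if (length(labels) < 2L) stop("need at least 2 conditions")
  out <- list()
  for (fc in feature_cols) {
    m <- rm_matrix(features, fc, labels = labels)
    if (nrow(m) >= 5L) {
      norm_p <- apply(m, 2, function(col) ks_normality(col)$p)
      nonnormal <- any(norm_p < alpha_normal)
    } else {
      # too few subjects to screen normality: stay nonparametric
      norm_p <- rep(NA_real_, ncol(m))
      nonnormal <- TRUE
    }
    omnibus <- if (nonnormal) friedman_rm(m, p_method = "chisq")
               else rm_anova_gg(m)
    out[[fc]] <- list(omnibus = omnibus,
                      posthoc = posthoc_t_bonferroni(m),
                      normality = norm_p,
                      test_used = if (nonnormal) "friedman" else "rm_anova_gg")
  }
  out
}
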