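test_that("accuracy coding inverts the familiarity key for ungrammatical items", {
  man <- toy_manifest()
  all_fam <- code_accuracy(toy_responses(c(1, 1, 1, 1)), man)
  expect_equal(all_fam$gram_all, 1)
  expect_equal(all_fam$ungram_all, 0)
  expect_equal(all_fam$overall, 0.5)
  none_fam <- code_accuracy(toy_responses(c(0, 0, 0, 0)), man)
  expect_equal(none_fam$gram_all, 0)
  expect_equal(none_fam$ungram_all, 1)
  expect_equal(none_fam$overall, 0.5)
  perfect <- code_accuracy(toy_responses(c(1, 1, 0, 0)), man)
  expect_equal(perfect$overall, 1)
  expect_equal(perfect$et1, 1)
  expect_error(code_accuracy(data.frame(participant = "p", stimulus = "zz",
                                        familiar = 1), man), "unknown stimulus")
})

test_that("outlier screening excludes only >k SD deviations, computed once", {
  acc <- data.frame(participant = sprintf("p%02d", 1:31),
                    overall = c(rep(0.6, 25), 0.55, 0.65, 0.58, 0.62,
                                0.95, 0.97))
  scr <- exclude_outliers(acc)
  expect_equal(nrow(scr$kept), 29L)
  expect_setequal(scr$excluded$participant, c("p30", "p31"))
  homog <- data.frame(participant = 1:10, overall = seq(0.5, 0.6, length.out = 10))
  expect_equal(nrow(exclude_outliers(homog)$excluded), 0L)
  # k = 0 excludes everything off the mean
  expect_equal(nrow(exclude_outliers(homog, k = 0)$kept), 0L)
  expect_error(exclude_outliers(acc[1:2, ]), "at least 3")
})

test_that("one-sample t matches the closed form and handles degenerate input", {
  set.seed(4)
  x <- rnorm(20, 0.6, 0.1)
  tt <- one_sample_t(x, mu = 0.5)
  expect_equal(tt$statistic, (mean(x) - 0.5) / (sd(x) / sqrt(20)))
  expect_equal(tt$df, 19)
  expect_equal(tt$p, 2 * pt(-abs(tt$statistic), 19))
  same <- one_sample_t(c(0.4, 0.5, 0.6), mu = 0.5)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(one_sample_t(rep(0.5, 5), mu = 0.5), "zero variance")
  ts <- t_from_summary(0.62, 0.1, 25, mu = 0.5)
  expect_equal(ts$statistic, 0.12 / (0.1 / 5))
})

test_that("Holm step-down matches worked examples and the p.adjust cross-check", {
  expect_equal(as.logical(holm_adjust(c(0.01, 0.02, 0.04), 0.05)),
               c(TRUE, TRUE, TRUE))
  expect_equal(as.logical(holm_adjust(c(0.03, 0.04, 0.05), 0.05)),
               c(FALSE, FALSE, FALSE))
  expect_true(as.logical(holm_adjust(0.04, 0.05)))
  set.seed(8)
  for (i in 1:30) {
    p <- runif(sample(2:10, 1))^sample(1:3, 1)
    dec <- as.logical(holm_adjust(p, 0.05))
    expect_identical(dec, p.adjust(p, "holm") <= 0.05)   # independent route
    bonf <- p <= 0.05 / length(p)
    unc <- p <= 0.05
    expect_true(all(dec[bonf]))      # no less powerful than Bonferroni
    expect_true(all(unc[dec]))       # no more powerful than uncorrected
  }
})

test_that("mixed ANOVA equals the brute-force split-plot oracle on balanced toys", {
  set.seed(21)
  for (rep in 1:3) {
    n_per <- 4
    wide <- expand.grid(group = c("g1", "g2"), musician = c(0, 1),
                        unit = seq_len(n_per))
    k <- nrow(wide)
    wide$w1 <- rnorm(k, 0.6, 0.1) + 0.08 * (wide$group == "g2")
    wide$w2 <- wide$w1 + rnorm(k, 0.05, 0.05)
    wide$w3 <- wide$w1 + rnorm(k, -0.03, 0.05) + 0.05 * wide$musician
    tab <- mixed_anova(wide, c("group", "musician"), c("w1", "w2", "w3"),
                       within_name = "cat")
    orc <- split_plot_oracle(wide, "group", "musician", c("w1", "w2", "w3"))
    pick <- function(eff) tab[tab$effect == eff, ]
    expect_equal(pick("group")$F, orc$A$F, tolerance = 1e-8)
    expect_equal(pick("musician")$F, orc$B$F, tolerance = 1e-8)
    expect_equal(pick("group:musician")$F, orc$AB$F, tolerance = 1e-8)
    expect_equal(pick("cat")$F, orc$C$F, tolerance = 1e-8)
    expect_equal(pick("group:cat")$F, orc$AC$F, tolerance = 1e-8)
    expect_equal(pick("musician:cat")$F, orc$BC$F, tolerance = 1e-8)
    expect_equal(pick("group:musician:cat")$F, orc$ABC$F, tolerance = 1e-8)
    expect_equal(pick("group")$pes, orc$A$pes, tolerance = 1e-8)
    expect_equal(pick("cat")$pes, orc$C$pes, tolerance = 1e-8)
    expect_equal(pick("group")$df_num, orc$A$df1)
    expect_equal(pick("cat")$df_den, orc$C$df2)
  }
})

test_that("degenerate ANOVA inputs give zero F, not NaN", {
  wide <- data.frame(group = rep(c("a", "b"), each = 4),
                     musician = rep(c(0, 1), 4),
                     w1 = rnorm(8), stringsAsFactors = FALSE)
  wide$w2 <- wide$w1           # within factor constant per participant
  wide$w3 <- wide$w1
  tab <- mixed_anova(wide, c("group", "musician"), c("w1", "w2", "w3"))
  expect_equal(tab$F[tab$effect == "level"], 0)
  expect_equal(tab$p[tab$effect == "level"], 1)

  # identical values duplicated across groups: no between-group variance
  base <- data.frame(musician = rep(c(0, 1), 3), w1 = rnorm(6), w2 = rnorm(6))
  dup <- rbind(cbind(base, group = "a"), cbind(base, group = "b"))
  tab2 <- mixed_anova(dup, c("group", "musician"), c("w1", "w2"))
  expect_equal(tab2$F[tab2$effect == "group"], 0)
})

test_that("within-subject contrasts reduce to squared one-sample t statistics", {
  set.seed(5)
  n <- 12
  d <- rnorm(n, 0.1, 0.2)
  wide <- data.frame(l1 = rnorm(n, 0.6, 0.1))
  wide$l2 <- wide$l1 - d
  ct <- within_contrasts(wide, c("l1", "l2"), kind = "simple")
  tstat <- mean(d) / (sd(d) / sqrt(n))
  expect_equal(ct$F, tstat^2, tolerance = 1e-10)
  expect_equal(ct$df_den, n - 1)
  expect_equal(ct$estimate, mean(d))

  wide$l2 <- wide$l1
  same <- within_contrasts(wide, c("l1", "l2"), kind = "simple")
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  wide5 <- as.data.frame(matrix(rnorm(12 * 5), 12))
  rep5 <- within_contrasts(wide5, paste0("V", 1:5), kind = "repeated")
  expect_equal(nrow(rep5), 4L)
  expect_equal(rep5$contrast[1], "V1 vs V2")
})

test_that("chunk strength matches exhaustive counting in both views", {
  corpus <- list(c(1, 2, 1, 2), c(1, 2, 3))
  expect_equal(chunk_strength(c(1, 2, 3), corpus, 2), 2)   # (3 + 1) / 2
  expect_equal(chunk_strength(c(1, 2, 3), list(c(1, 2, 3)), 3), 1)
  expect_equal(chunk_strength(c(9, 9), corpus, 2), 0)      # absent n-gram
  expect_error(chunk_strength(c(1, 2), corpus, 3), "no pitch 3-grams")
  # interval view operates on successive differences
  expect_equal(chunk_strength(c(60, 62, 64), list(c(10, 12, 14, 16)), 2,
                              view = "interval"), 2)
  set.seed(14)
  for (i in 1:20) {
    corpus <- lapply(1:4, function(j) sample(1:4, sample(4:9, 1), replace = TRUE))
    stimulus <- sample(1:4, 6, replace = TRUE)
    n <- sample(1:3, 1)
    for (v in c("pitch", "interval"))
      expect_equal(chunk_strength(stimulus, corpus, n, view = v),
                   brute_chunk_strength(stimulus, corpus, n, view = v))
    # invariance under corpus reordering
    expect_equal(chunk_strength(stimulus, rev(corpus), n),
                 chunk_strength(stimulus, corpus, n))
  }
})

test_that("ridge logistic matches glm on clean data and survives separation", {
  set.seed(3)
  n <- 400
  X <- cbind(intercept = 1, x1 = rnorm(n), x2 = rnorm(n))
  y <- rbinom(n, 1, plogis(0.5 + 0.8 * X[, "x1"] - 0.4 * X[, "x2"]))
  fit <- fit_participant_logistic(X, y)
  ref <- glm(y ~ X[, "x1"] + X[, "x2"], family = binomial)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-4)

  # complete separation: finite coefficients, no convergence to ML
  Xs <- cbind(intercept = 1, x = c(-2, -1, 1, 2))
  ys <- c(0, 0, 1, 1)
  sep <- fit_participant_logistic(Xs, ys)
  expect_true(all(is.finite(sep$coefficients)))

  # constant predictor dropped with warning, reported as NA
  Xc <- cbind(intercept = 1, x1 = rnorm(20), flat = 1)
  expect_warning(fitc <- fit_participant_logistic(Xc, rbinom(20, 1, 0.5)),
                 "constant predictor")
  expect_true(is.na(fitc$coefficients["flat"]))
  expect_equal(fitc$dropped, "flat")
})

test_that("null responses yield near-zero slopes and group tests match per-column t", {
  set.seed(6)
  n <- 2000
  X <- cbind(intercept = 1, x1 = rnorm(n))
  y <- rbinom(n, 1, 0.5)
  fit <- fit_participant_logistic(X, y)
  expect_lt(abs(fit$coefficients["x1"]), 0.15)

  betas <- data.frame(participant = 1:10,
                      intercept = rnorm(10, 1), acs2 = rnorm(10, -0.3),
                      converged = 1)
  gt <- group_beta_tests(betas)
  expect_setequal(gt$predictor, c("intercept", "acs2"))
  manual <- one_sample_t(betas$acs2, 0)
  row <- gt[gt$predictor == "acs2", ]
  expect_equal(row$t, manual$statistic)
  expect_equal(row$p, manual$p)
})

test_that("Type-2 d-prime follows signal-detection with extreme-cell correction", {
  # hit = fa = 0.5: no metaknowledge
  correct <- rep(c(TRUE, FALSE), each = 20)
  confident <- rep(c(TRUE, FALSE), 20)
  expect_equal(type2_dprime(correct, confident), 0)
  # hit .8, fa .2
  correct <- rep(c(TRUE, FALSE), each = 10)
  confident <- c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 2), rep(FALSE, 8))
  expect_equal(type2_dprime(correct, confident), 2 * qnorm(0.8))
  # perfect confidence among correct trials is clamped to 1 - 1/(2N)
  correct <- c(rep(TRUE, 33), rep(FALSE, 10))
  confident <- c(rep(TRUE, 33), rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(type2_dprime(correct, confident),
               qnorm(1 - 1 / 66) - qnorm(0.5))
  # antisymmetry under confidence-label swap
  set.seed(12)
  correct <- rbinom(60, 1, 0.6)
  confident <- rbinom(60, 1, 0.5)
  expect_equal(type2_dprime(correct, confident),
               -type2_dprime(correct, 1 - confident))
  # missing cell flagged
  expect_true(is.na(type2_dprime(rep(TRUE, 5), rbinom(5, 1, 0.5))))
})

test_that("exposure correlation recovers perfect, inverse and null relations", {
  expect_equal(exposure_correlation(1:10, 1:10)$r, 1)
  expect_equal(exposure_correlation(1:10, 10:1)$r, -1)
  set.seed(19)
  nullr <- exposure_correlation(rnorm(500), rnorm(500))
  expect_lt(abs(nullr$r), 0.12)
  expect_error(exposure_correlation(rep(1, 5), rnorm(5)), "zero variance")
})
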