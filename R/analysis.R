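#' Code familiarity responses for accuracy
#'
#' A grammatical stimulus (old or new) is correct when endorsed as familiar;
#' an ungrammatical stimulus is correct when rejected. With equally many
#' grammatical and ungrammatical test items, chance performance is 0.5 by
#' construction.
#'
#' @param responses data.frame with columns `participant`, `stimulus`,
#'   `familiar` (0/1) and optionally `group`, `musician`, `confidence`,
#'   `repetitions`.
#' @param manifest Stimulus manifest data.frame (see [stimulus_manifest]).
#' @return data.frame, one row per participant: identity columns plus
#'   accuracies `overall`, `gram_all`, `old_gram`, `new_gram`, `ungram_all`
#'   and `et1`..`et5`, each in [0, 1].
#' @export
code_accuracy <- function(responses, manifest) {
  idx <- match(responses$stimulus, manifest$id)
  if (anyNA(idx))
    stop("response references unknown stimulus id(s): ",
         paste(unique(responses$stimulus[is.na(idx)]), collapse = ", "))
  cat_ <- manifest$category[idx]
  et <- manifest$error_type[idx]
  correct <- ifelse(cat_ == "ungram", responses$familiar == 0,
                    responses$familiar == 1)
  ids <- unique(responses$participant)
  pid <- factor(responses$participant, levels = ids)
  masks <- list(overall = rep(TRUE, length(correct)),
                gram_all = cat_ != "ungram",
                old_gram = cat_ == "old_gram",
                new_gram = cat_ == "new_gram",
                ungram_all = cat_ == "ungram",
                et1 = !is.na(et) & et == 1, et2 = !is.na(et) & et == 2,
                et3 = !is.na(et) & et == 3, et4 = !is.na(et) & et == 4,
                et5 = !is.na(et) & et == 5)
  acc <- data.frame(participant = ids, stringsAsFactors = FALSE)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    v <- tapply(correct[m], pid[m], mean)
    acc[[nm]] <- as.numeric(v[match(ids, names(v))])
  }
  for (extra in c("group", "musician", "repetitions")) {
    if (extra %in% names(responses))
      acc[[extra]] <- responses[[extra]][match(acc$participant,
                                               responses$participant)]
  }
  acc
}

#' Exclude performance outliers
#'
#' Flags participants whose overall accuracy differs from the group mean by
#' more than `k` standard deviations. Mean and SD are computed once on the
#' full group (no iterative re-screening).
#'
#' @param acc Accuracy table from [code_accuracy].
#' @param k Exclusion threshold in standard deviations (default 2).
#' @return List with data.frames `kept` and `excluded`.
#' @export
exclude_outliers <- function(acc, k = 2) {
  if (nrow(acc) < 3L) stop("outlier screening needs at least 3 participants")
  m <- mean(acc$overall)
  s <- stats::sd(acc$overall)
  out <- abs(acc$overall - m) > k * s
  list(kept = acc[!out, , drop = FALSE], excluded = acc[out, , drop = FALSE])
}

#' One-sample t test
#'
#' Two-tailed one-sample t test (sample SD, df = n - 1).
#'
#' @param values Numeric vector, n >= 2, non-zero variance.
#' @param mu Null-hypothesis mean.
#' @return List of class `agl_test`: `statistic`, `df`, `p`, `mean`, `sd`, `n`.
#' @export
one_sample_t <- function(values, mu = 0) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("one-sample t needs n >= 2")
  if (stats::sd(values) == 0) stop("one-sample t is undefined for zero variance")
  tt <- stats::t.test(values, mu = mu)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean = mean(values), sd = stats::sd(values),
                 n = length(values)),
            class = "agl_test")
}

#' @export
print.agl_test <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g (mean %.3f, sd %.3f, n %d)\n",
              x$df, x$statistic, x$p, x$mean, x$sd, x$n))
  invisible(x)
}

#' One-sample t from summary statistics
#'
#' Recomputes t = (mean - mu) / (sd / sqrt(n)) from printed summary values,
#' e.g. to check published accuracy tables.
#'
#' @param mean,sd,n Summary statistics.
#' @param mu Null mean (default 0.5, chance in a balanced familiarity design).
#' @return List of class `agl_test`.
#' @export
t_from_summary <- function(mean, sd, n, mu = 0.5) {
  t <- (mean - mu) / (sd / sqrt(n))
  structure(list(statistic = t, df = n - 1,
                 p = 2 * stats::pt(-abs(t), n - 1),
                 mean = mean, sd = sd, n = n),
            class = "agl_test")
}

#' Holm sequential-Bonferroni decisions
#'
#' Step-down procedure: the i-th smallest p-value is compared with
#' alpha / (m - i + 1); testing stops at the first failure and all later
#' hypotheses are retained. Controls the familywise error rate at alpha.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @param alpha Familywise error level.
#' @return Logical rejection vector in the original order, with attribute
#'   `adjusted` (Holm-adjusted p-values).
#' @export
holm_adjust <- function(pvals, alpha = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  ord <- order(pvals)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (pvals[ord[i]] <= alpha / (m - i + 1)) reject[ord[i]] <- TRUE
    else break
  }
  structure(reject, adjusted = stats::p.adjust(pvals, method = "holm"))
}

#' Mixed-design ANOVA (between x within), Type III
#'
#' Classical univariate split-plot decomposition for a design with up to two
#' between-subject factors and one within-subject factor, computed from a
#' multivariate linear model with sum-to-zero contrasts and Type III sums of
#' squares (so unbalanced between groups are handled). Reports F, degrees of
#' freedom, p and partial eta squared (SS_effect / (SS_effect + SS_error))
#' for every between effect, the within effect and all interactions. No
#' sphericity correction is applied to the within factor.
#'
#' @param data data.frame in wide form: one row per participant.
#' @param between Character vector of between-factor column names (factors
#'   with a single observed level are dropped).
#' @param within_cols Column names holding the within-factor levels.
#' @param within_name Name for the within factor in the output.
#' @return data.frame of class `agl_anova`: effect, df_num, df_den, ss,
#'   ss_error, F, p, pes.
#' @export
mixed_anova <- function(data, between, within_cols, within_name = "level") {
  Y <- as.matrix(data[within_cols])
  if (anyNA(Y)) stop("within-subject cells must be complete")
  for (b in between) data[[b]] <- factor(data[[b]])
  between <- between[vapply(between, function(b)
    nlevels(droplevels(data[[b]])) >= 2L, logical(1))]
  for (b in between) data[[b]] <- droplevels(data[[b]])
  if (length(between) &&
      any(table(do.call(interaction, data[between])) == 0L))
    stop("empty between-subject cell")
  rhs <- if (length(between)) paste(between, collapse = " * ") else "1"
  contr <- stats::setNames(as.list(rep("contr.sum", length(between))), between)
  data$.Y <- Y
  mlm <- if (length(between))
    stats::lm(stats::as.formula(paste(".Y ~", rhs)), data = data,
              contrasts = contr)
  else stats::lm(.Y ~ 1, data = data)
  idata <- stats::setNames(
    data.frame(factor(within_cols, levels = within_cols)), within_name)
  av <- car::Anova(mlm, idata = idata,
                   idesign = stats::as.formula(paste0("~", within_name)),
                   type = 3)
  # sphericity corrections are not reported (and are unavailable for
  # zero-variance toys); silence only that advisory
  s <- withCallingHandlers(
    summary(av, multivariate = FALSE),
    warning = function(w) {
      if (grepl("non-sphericity|HF eps", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  u <- s$univariate.tests
  u <- u[rownames(u) != "(Intercept)", , drop = FALSE]
  ss <- u[, "Sum Sq"]; sse <- u[, "Error SS"]
  Fv <- ifelse(ss == 0, 0, u[, "F value"])
  pv <- ifelse(ss == 0, 1, u[, "Pr(>F)"])
  res <- data.frame(effect = rownames(u), df_num = u[, "num Df"],
                    df_den = u[, "den Df"], ss = ss, ss_error = sse,
                    F = Fv, p = pv,
                    pes = ifelse(ss + sse == 0, 0, ss / (ss + sse)),
                    row.names = NULL)
  class(res) <- c("agl_anova", "data.frame")
  res
}

#' Within-subject contrasts
#'
#' Simple contrasts compare each within level against the reference level;
#' repeated contrasts compare adjacent levels. Each contrast is evaluated as
#' a one-sample t on the participant-level difference scores and reported as
#' F = t^2 on (1, n - 1) degrees of freedom.
#'
#' @param data Wide data.frame, one row per participant.
#' @param within_cols Column names of the within-factor levels, in order.
#' @param kind `"simple"` or `"repeated"`.
#' @param reference Index of the reference level for simple contrasts.
#' @return data.frame: contrast, estimate (mean difference), F, df_num,
#'   df_den, p, pes.
#' @export
within_contrasts <- function(data, within_cols, kind = c("simple", "repeated"),
                             reference = 1L) {
  kind <- match.arg(kind)
  if (length(within_cols) < 2L) stop("contrasts need at least 2 within levels")
  pairs <- if (kind == "simple") {
    lapply(setdiff(seq_along(within_cols), reference),
           function(j) c(reference, j))
  } else {
    lapply(seq_len(length(within_cols) - 1L), function(j) c(j, j + 1L))
  }
  do.call(rbind, lapply(pairs, function(pr) {
    d <- data[[within_cols[pr[1]]]] - data[[within_cols[pr[2]]]]
    n <- length(d)
    if (stats::sd(d) == 0) {
      Fv <- if (mean(d) == 0) 0 else Inf
      pv <- if (mean(d) == 0) 1 else 0
      dfree <- n - 1L
    } else {
      tt <- stats::t.test(d, mu = 0)
      Fv <- unname(tt$statistic)^2
      pv <- tt$p.value
      dfree <- unname(tt$parameter)
    }
    data.frame(contrast = paste(within_cols[pr[1]], "vs", within_cols[pr[2]]),
               estimate = mean(d), F = Fv, df_num = 1L, df_den = dfree,
               p = pv, pes = if (is.infinite(Fv)) 1 else Fv / (Fv + dfree),
               stringsAsFactors = FALSE)
  }))
}

#' Average chunk strength of a stimulus
#'
#' Chunk strength of an n-gram is the number of times it occurs (with
#' overlaps) across the training corpus; the average chunk strength (ACS) of
#' a stimulus is the mean chunk strength over the stimulus's own n-grams. The
#' pitch view operates on the pitch sequence, the interval view on the
#' sequence of successive semitone intervals (one element shorter).
#'
#' @param stimulus Numeric pitch vector.
#' @param corpus List of pitch vectors (the training melodies, each counted
#'   once).
#' @param n Chunk size (>= 1).
#' @param view `"pitch"` or `"interval"`.
#' @return Mean occurrence count (numeric scalar).
#' @export
chunk_strength <- function(stimulus, corpus, n, view = c("pitch", "interval")) {
  view <- match.arg(view)
  tf <- function(x) if (view == "interval") diff(as.numeric(x)) else as.numeric(x)
  s <- tf(stimulus)
  if (length(s) < n)
    stop(sprintf("stimulus has no %s %d-grams", view, n))
  sg <- .ngrams(as.character(s), n)
  cg <- unlist(lapply(corpus, function(x) .ngrams(as.character(tf(x)), n)))
  mean(vapply(sg, function(g) sum(cg == g), numeric(1)))
}

#' Chunk-strength feature matrix for a stimulus set
#'
#' Builds the per-stimulus predictors used by the response model: average
#' chunk strength for chunk sizes `n_range` in the requested view, plus the
#' grammaticality indicator (1 grammatical, 0 ungrammatical). A stimulus too
#' short to contain any n-gram of a given size contributes an ACS of 0 for
#' that size (it has no such chunks).
#'
#' @param manifest Stimulus manifest data.frame.
#' @param corpus List of training pitch vectors (default: the old-grammatical
#'   melodies of the manifest, each counted once).
#' @param n_range Chunk sizes (default 1:8).
#' @param view `"pitch"` or `"interval"`.
#' @return Numeric matrix, rows in manifest order; columns `acs1`.. and
#'   `grammaticality`; rownames are stimulus ids.
#' @export
stimulus_features <- function(manifest, corpus = NULL, n_range = 1:8,
                              view = c("pitch", "interval")) {
  view <- match.arg(view)
  pitches <- lapply(strsplit(manifest$pitch_csv, ",", fixed = TRUE), as.integer)
  if (is.null(corpus)) corpus <- pitches[manifest$category == "old_gram"]
  acs <- vapply(n_range, function(n) vapply(pitches, function(p) {
    tf_len <- if (view == "interval") length(p) - 1L else length(p)
    if (tf_len < n) 0 else chunk_strength(p, corpus, n, view)
  }, numeric(1)), numeric(length(pitches)))
  X <- cbind(acs, as.numeric(manifest$category != "ungram"))
  dimnames(X) <- list(manifest$id,
                      c(paste0("acs", n_range), "grammaticality"))
  X
}

#' Ridge-stabilized logistic regression for one participant
#'
#' Maximum-likelihood logistic regression with a tiny quadratic (ridge)
#' penalty on all coefficients, fitted by Newton-Raphson on the unscaled
#' predictors. The penalty (default 1e-6) leaves well-conditioned fits
#' numerically indistinguishable from plain maximum likelihood but keeps
#' coefficients finite under complete separation. Constant predictors are
#' dropped with a warning and reported as NA.
#'
#' @param X Design matrix including an intercept column.
#' @param y Binary response vector (0/1).
#' @param ridge Penalty weight.
#' @param max_iter,tol Newton iteration controls.
#' @return List: `coefficients` (named, NA for dropped columns), `converged`
#'   (logical), `dropped` (character).
#' @export
fit_participant_logistic <- function(X, y, ridge = 1e-6, max_iter = 200L,
                                     tol = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y dimensions disagree")
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0 | seq_len(ncol(X)) == 1L   # column 1 is the intercept
  dropped <- colnames(X)[!keep]
  if (length(dropped))
    warning("constant predictor(s) dropped: ", paste(dropped, collapse = ", "))
  Xk <- X[, keep, drop = FALSE]
  beta <- rep(0, ncol(Xk))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Xk %*% beta)
    p <- stats::plogis(eta)
    grad <- drop(crossprod(Xk, y - p)) - 2 * ridge * beta
    w <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(Xk, Xk * w) + diag(2 * ridge, ncol(Xk))
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
  }
  coefs <- stats::setNames(rep(NA_real_, ncol(X)), colnames(X))
  coefs[keep] <- beta
  list(coefficients = coefs, converged = converged, dropped = dropped)
}

#' Per-participant chunk-strength regressions
#'
#' Fits, for every participant, a logistic regression of the familiarity
#' response on intercept + ACS for chunk sizes 1-8 + grammaticality, in the
#' requested view.
#'
#' @param responses Response data.frame (see [code_accuracy]).
#' @param manifest Stimulus manifest.
#' @param view `"pitch"` or `"interval"`.
#' @param corpus Optional training corpus override.
#' @param ridge Ridge penalty passed to [fit_participant_logistic].
#' @return data.frame, one row per participant: `participant`, coefficients
#'   `intercept`, `acs1`..`acs8`, `grammaticality`, and `converged`.
#' @export
participant_beta_table <- function(responses, manifest,
                                   view = c("pitch", "interval"),
                                   corpus = NULL, ridge = 1e-6) {
  view <- match.arg(view)
  feats <- stimulus_features(manifest, corpus = corpus, view = view)
  ids <- unique(responses$participant)
  rows <- lapply(ids, function(pid) {
    r <- responses[responses$participant == pid, ]
    X <- cbind(intercept = 1, feats[match(r$stimulus, rownames(feats)), ,
                                    drop = FALSE])
    fit <- suppressWarnings(fit_participant_logistic(X, r$familiar,
                                                     ridge = ridge))
    c(fit$coefficients, converged = as.numeric(fit$converged))
  })
  out <- data.frame(participant = ids, do.call(rbind, rows),
                    stringsAsFactors = FALSE)
  attr(out, "view") <- view
  out
}

#' Group-level tests of regression coefficients
#'
#' One-sample t tests of each predictor's per-participant coefficients
#' against zero (the published Table-2-style analysis).
#'
#' @param betas Beta table from [participant_beta_table].
#' @return data.frame: predictor, mean, sd, n, t, df, p.
#' @export
group_beta_tests <- function(betas) {
  preds <- setdiff(names(betas), c("participant", "converged"))
  do.call(rbind, lapply(preds, function(pr) {
    v <- betas[[pr]]
    tt <- one_sample_t(v[!is.na(v)], mu = 0)
    data.frame(predictor = pr, mean = tt$mean, sd = tt$sd, n = tt$n,
               t = tt$statistic, df = tt$df, p = tt$p,
               stringsAsFactors = FALSE)
  }))
}

#' Type-2 d-prime (metacognitive sensitivity)
#'
#' Signal-detection sensitivity of the confidence judgment to the accuracy of
#' one's own familiarity response: hit rate = P(high confidence | correct),
#' false-alarm rate = P(high confidence | incorrect), d' = qnorm(hit) -
#' qnorm(fa). Extreme proportions are replaced by 1/(2N) and 1 - 1/(2N),
#' where N is the trial count in that cell's denominator.
#'
#' @param correct Logical/0-1 vector: response accuracy per trial.
#' @param confident Logical/0-1 vector: high confidence per trial.
#' @return d' value; `NA` with attribute `reason` when the participant has no
#'   correct or no incorrect trials.
#' @export
type2_dprime <- function(correct, confident) {
  correct <- as.logical(correct)
  confident <- as.logical(confident)
  n_c <- sum(correct); n_i <- sum(!correct)
  if (n_c == 0L || n_i == 0L)
    return(structure(NA_real_, reason = "missing correct or incorrect cell"))
  clamp <- function(p, n) min(max(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  hit <- clamp(mean(confident[correct]), n_c)
  fa <- clamp(mean(confident[!correct]), n_i)
  stats::qnorm(hit) - stats::qnorm(fa)
}

#' Exposure-performance correlation
#'
#' Pearson correlation with two-tailed p, used to check that learning-phase
#' exposure (stimulus repetitions) does not predict performance or confidence.
#'
#' @param repetitions,values Paired numeric vectors (n >= 3).
#' @return List: `r`, `p`, `n`.
#' @export
exposure_correlation <- function(repetitions, values) {
  ok <- stats::complete.cases(repetitions, values)
  if (sum(ok) < 3L) stop("correlation needs at least 3 pairs")
  if (stats::sd(repetitions[ok]) == 0 || stats::sd(values[ok]) == 0)
    stop("correlation undefined for zero variance")
  ct <- stats::cor.test(repetitions[ok], values[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Full behavioral analysis pipeline
#'
#' Runs the complete analysis on a response dataset: accuracy coding,
#' per-group outlier exclusion (2 SD on overall accuracy), planned one-sample
#' t tests against chance with Holm correction for each group, the
#' grammaticality mixed ANOVA (old/new/ungrammatical within; group and
#' musicianship between) with simple contrasts, the error-type mixed ANOVA
#' with repeated contrasts, per-participant chunk-strength logistic
#' regressions with group-level coefficient tests (pitch and interval views),
#' Type-2 d' per participant with a group test, and exposure correlations.
#'
#' @param responses Response data.frame: `participant`, `group`, `musician`,
#'   `stimulus`, `familiar`, `confidence`, optionally `repetitions`.
#' @param manifest Stimulus manifest data.frame.
#' @param alpha Familywise error level for the planned-test family.
#' @param focus_group Group whose planned tests, regressions and d' are
#'   tabulated (default: first group level in the data).
#' @return Object of class `agl_analysis` (a list of result tables).
#' @export
agl_analyze <- function(responses, manifest, alpha = 0.05,
                        focus_group = NULL) {
  if (!"group" %in% names(responses)) responses$group <- "experimental"
  if (!"musician" %in% names(responses)) responses$musician <- 0L
  acc <- code_accuracy(responses, manifest)
  groups <- unique(acc$group)
  if (is.null(focus_group)) focus_group <- groups[1]

  screened <- lapply(groups, function(gr) {
    sub <- acc[acc$group == gr, , drop = FALSE]
    if (nrow(sub) >= 3L) exclude_outliers(sub)
    else list(kept = sub, excluded = sub[0, , drop = FALSE])
  })
  kept <- do.call(rbind, lapply(screened, `[[`, "kept"))
  excluded <- do.call(rbind, lapply(screened, `[[`, "excluded"))
  keep_resp <- responses[responses$participant %in% kept$participant, ]

  # planned one-sample t tests vs chance, Holm-corrected, for the focus group
  fg <- kept[kept$group == focus_group, , drop = FALSE]
  cats <- c("old_gram", "new_gram", "et1", "et2", "et3", "et4", "et5")
  planned <- do.call(rbind, lapply(cats, function(cn) {
    tt <- one_sample_t(fg[[cn]], mu = 0.5)
    data.frame(category = cn, mean = tt$mean, sd = tt$sd, n = tt$n,
               t = tt$statistic, df = tt$df, p = tt$p,
               stringsAsFactors = FALSE)
  }))
  planned$reject_holm <- as.logical(holm_adjust(planned$p, alpha))

  between <- c("group", "musician")
  anova_gram <- mixed_anova(kept, between,
                            c("old_gram", "new_gram", "ungram_all"),
                            within_name = "grammaticality")
  contr_gram <- within_contrasts(kept, c("old_gram", "new_gram", "ungram_all"),
                                 kind = "simple")
  anova_et <- mixed_anova(kept, between, paste0("et", 1:5),
                          within_name = "error_type")
  contr_et <- within_contrasts(kept, paste0("et", 1:5), kind = "repeated")

  fresp <- keep_resp[keep_resp$group == focus_group, ]
  betas <- lapply(c(pitch = "pitch", interval = "interval"), function(v)
    participant_beta_table(fresp, manifest, view = v))
  beta_tests <- lapply(betas, group_beta_tests)

  # Type-2 d' per focus-group participant
  idx <- match(fresp$stimulus, manifest$id)
  corr <- ifelse(manifest$category[idx] == "ungram",
                 fresp$familiar == 0, fresp$familiar == 1)
  dp <- vapply(unique(fresp$participant), function(pid) {
    s <- fresp$participant == pid
    as.numeric(type2_dprime(corr[s], fresp$confidence[s]))
  }, numeric(1))
  dp <- dp[!is.na(dp)]
  dprime_test <- if (length(dp) >= 2L && stats::sd(dp) > 0)
    one_sample_t(dp, mu = 0) else NULL

  exposure <- NULL
  if ("repetitions" %in% names(fg) && nrow(fg) >= 3L &&
      stats::sd(fg$repetitions) > 0)
    exposure <- exposure_correlation(fg$repetitions, fg$overall)

  structure(list(accuracy = kept, excluded = excluded, planned = planned,
                 anova_grammaticality = anova_gram,
                 contrasts_grammaticality = contr_gram,
                 anova_error_type = anova_et, contrasts_error_type = contr_et,
                 betas = betas, beta_tests = beta_tests,
                 dprime = dp, dprime_test = dprime_test,
                 exposure = exposure, alpha = alpha,
                 focus_group = focus_group),
            class = "agl_analysis")
}

#' @export
print.agl_analysis <- function(x, ...) {
  cat("AGL behavioral analysis (focus group:", x$focus_group, ")\n")
  cat(sprintf("  participants kept: %d (excluded: %d)\n",
              nrow(x$accuracy), nrow(x$excluded)))
  fg <- x$accuracy[x$accuracy$group == x$focus_group, ]
  cat(sprintf("  overall accuracy: %.3f (sd %.3f)\n",
              mean(fg$overall), stats::sd(fg$overall)))
  cat("  planned t tests vs chance (Holm at alpha =", x$alpha, "):\n")
  print(format(x$planned, digits = 3), row.names = FALSE)
  cat("  grammaticality ANOVA:\n")
  print(format(x$anova_grammaticality, digits = 3), row.names = FALSE)
  if (!is.null(x$dprime_test)) {
    cat("  Type-2 d': mean", format(mean(x$dprime), digits = 3), "- ")
    print(x$dprime_test)
  }
  invisible(x)
}

#' Write / read a response table
#'
#' @param responses Response data.frame.
#' @param path TSV path.
#' @return `read_responses` returns the data.frame.
#' @export
write_responses <- function(responses, path) {
  utils::write.table(responses, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
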