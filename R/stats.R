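#' Discard invalid trials
#'
#' Removes trials marked invalid (undefined response or response-time limit
#' exceeded) and reports exclusion counts per subject and condition.
#'
#' @param trials a trial-log data frame with at least `subject_id`,
#'   `stim_condition`, `valid`.
#' @return a list with `trials` (valid rows only) and `exclusions` (data
#'   frame of per-subject x condition counts). Errors if any subject x
#'   condition cell would be left without valid trials.
#' @export
clean_trials <- function(trials) {
  stopifnot(all(c("subject_id", "stim_condition", "valid") %in% names(trials)))
  agg <- stats::aggregate(valid ~ subject_id + stim_condition, data = trials,
                          FUN = function(v) c(n = length(v), excluded = sum(!v)))
  excl <- data.frame(subject_id = agg$subject_id,
                     stim_condition = agg$stim_condition,
                     n_trials = agg$valid[, "n"],
                     n_excluded = agg$valid[, "excluded"])
  empty <- excl$n_trials == excl$n_excluded
  if (any(empty)) {
    cell <- excl[which(empty)[1], ]
    stop("no valid trials left for subject ", cell$subject_id,
         " in condition ", cell$stim_condition)
  }
  list(trials = trials[trials$valid, , drop = FALSE], exclusions = excl)
}

#' Per-cell summary table for the 2x2 within-subject design
#'
#' Aggregates valid trials into one value per subject x stimulation
#' condition x opponent class: the cooperation percentage (default), the
#' mean response time, or the total points.
#'
#' @param trials valid trials (see [clean_trials()]).
#' @param measure `"cooperation"` (percent of cooperations among valid
#'   trials in the cell), `"rt"` (mean subject RT in seconds), or
#'   `"points"` (summed points).
#' @return data frame with `subject_id`, `stim_condition`,
#'   `opponent_class`, `value`, `n_valid_trials`.
#' @export
cooperation_table <- function(trials, measure = c("cooperation", "rt", "points")) {
  measure <- match.arg(measure)
  stopifnot(all(c("subject_id", "stim_condition", "opponent_class") %in% names(trials)))
  val <- switch(measure,
    cooperation = as.numeric(trials$subject_choice == "cooperate") * 100,
    rt = trials$subject_rt_s,
    points = trials$points_subject)
  f <- switch(measure, points = sum, mean)
  agg <- stats::aggregate(
    list(value = val),
    by = list(subject_id = trials$subject_id,
              stim_condition = trials$stim_condition,
              opponent_class = trials$opponent_class),
    FUN = f)
  n <- stats::aggregate(
    list(n_valid_trials = rep(1L, nrow(trials))),
    by = list(subject_id = trials$subject_id,
              stim_condition = trials$stim_condition,
              opponent_class = trials$opponent_class),
    FUN = sum)
  out <- merge(agg, n)
  out[order(out$subject_id, out$stim_condition, out$opponent_class), ]
}

#' Two-by-two repeated-measures ANOVA
#'
#' Standard within-subject decomposition (each effect tested against its
#' subject-by-effect interaction stratum) for a complete 2x2 design, via
#' `stats::aov` with an `Error(subject/(A*B))` term, plus paired Cohen's d
#' for each effect (d computed on the per-subject marginal means; the
#' interaction d on the difference of differences).
#'
#' @param tab a table in the layout of [cooperation_table()]: columns
#'   `subject_id`, `stim_condition`, `opponent_class`, `value`.
#' @return data frame of class `"pd_anova"`: one row per effect
#'   (`stimulation`, `opponent`, `interaction`) with `F`, `df1`, `df2`,
#'   `p`, `cohens_d`.
#' @export
rm_anova_2x2 <- function(tab) {
  need <- c("subject_id", "stim_condition", "opponent_class", "value")
  stopifnot(all(need %in% names(tab)))
  tab <- tab[stats::complete.cases(tab[, need]), need]
  counts <- table(tab$subject_id, tab$stim_condition, tab$opponent_class)
  if (any(counts != 1)) stop("each subject must contribute exactly one value per cell")
  if (length(unique(tab$subject_id)) < 3) stop("at least 3 subjects required")
  d <- data.frame(subject = factor(tab$subject_id),
                  A = factor(tab$stim_condition),
                  B = factor(tab$opponent_class),
                  y = tab$value)
  fit <- stats::aov(y ~ A * B + Error(subject / (A * B)), data = d)
  sm <- summary(fit)
  ss_scale <- sum((d$y - mean(d$y))^2)
  pick <- function(stratum, term) {
    t <- sm[[stratum]][[1]]
    i <- grep(term, trimws(rownames(t)))
    # a stratum whose entire SS is rounding noise (conditions identical):
    # the effect is exactly null, not a ratio of noise terms
    if (sum(t[, "Sum Sq"]) <= 1e-12 * max(ss_scale, 1))
      return(c(F = 0, df1 = t[i, "Df"], df2 = t[nrow(t), "Df"], p = 1))
    c(F = t[i, "F value"], df1 = t[i, "Df"],
      df2 = t[nrow(t), "Df"], p = t[i, "Pr(>F)"])
  }
  eff <- rbind(stimulation = pick("Error: subject:A", "^A$"),
               opponent = pick("Error: subject:B", "^B$"),
               interaction = pick("Error: subject:A:B", "A:B"))
  # paired effect sizes on per-subject marginals
  m <- function(lA = NULL, lB = NULL) {
    sel <- rep(TRUE, nrow(d))
    if (!is.null(lA)) sel <- sel & d$A == lA
    if (!is.null(lB)) sel <- sel & d$B == lB
    tapply(d$y[sel], d$subject[sel], mean)
  }
  lA <- levels(d$A); lB <- levels(d$B)
  d_stim <- cohens_d_paired(m(lA = lA[2]), m(lA = lA[1]))$d
  d_opp <- cohens_d_paired(m(lB = lB[2]), m(lB = lB[1]))$d
  dd <- (m(lA[2], lB[2]) - m(lA[2], lB[1])) - (m(lA[1], lB[2]) - m(lA[1], lB[1]))
  d_int <- if (stats::sd(dd) > 0) mean(dd) / stats::sd(dd) else 0
  out <- data.frame(effect = rownames(eff), eff,
                    cohens_d = c(d_stim, d_opp, d_int), row.names = NULL)
  class(out) <- c("pd_anova", "data.frame")
  out
}

#' Paired Cohen's d
#'
#' The d(z) convention: mean of the paired differences divided by the
#' standard deviation of the differences.
#'
#' @param x,y equal-length paired vectors (`n >= 2`).
#' @return list with `d` and `degenerate` (`TRUE` when the differences have
#'   zero spread but a nonzero mean, in which case `d` is signed infinity).
#' @export
cohens_d_paired <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  diffs <- x - y
  s <- stats::sd(diffs)
  if (s == 0) {
    m <- mean(diffs)
    if (m == 0) return(list(d = 0, degenerate = FALSE))
    return(list(d = sign(m) * Inf, degenerate = TRUE))
  }
  list(d = mean(diffs) / s, degenerate = FALSE)
}

#' Collinearity screen for regression predictors
#'
#' Iteratively removes predictors until no pair has squared Pearson
#' correlation above the threshold (strictly greater). Within a violating
#' pair, the predictor with the larger mean absolute correlation to all
#' other predictors is dropped; ties are broken by column order (the later
#' column is dropped).
#'
#' @param X numeric data frame or matrix of candidate predictors (>= 2
#'   columns).
#' @param r2_threshold squared-correlation threshold (default 0.7).
#' @return list with `retained` and `dropped` column names and a `report`
#'   data frame of the decisions (pair, r-squared, which was dropped).
#' @export
select_features <- function(X, r2_threshold = 0.7) {
  X <- as.data.frame(X)
  stopifnot(ncol(X) >= 2, all(vapply(X, is.numeric, TRUE)))
  keep <- names(X)
  report <- list()
  repeat {
    if (length(keep) < 2) break
    cc <- suppressWarnings(stats::cor(X[keep]))
    cc[is.na(cc)] <- 0
    r2 <- cc^2; diag(r2) <- 0
    if (max(r2) <= r2_threshold) break
    ij <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
    pair <- keep[ij]
    mean_abs <- rowMeans(abs(cc))[pair]
    drop <- if (mean_abs[1] > mean_abs[2]) pair[1]
            else if (mean_abs[2] > mean_abs[1]) pair[2]
            else pair[2]  # tie: drop the later column
    report[[length(report) + 1]] <- data.frame(
      predictor_1 = pair[1], predictor_2 = pair[2],
      r_squared = max(r2), dropped = drop, stringsAsFactors = FALSE)
    keep <- setdiff(keep, drop)
  }
  list(retained = keep, dropped = setdiff(names(X), keep),
       report = if (length(report)) do.call(rbind, report) else
         data.frame(predictor_1 = character(), predictor_2 = character(),
                    r_squared = numeric(), dropped = character()))
}

#' Mixed-effects logistic regression of trial-level cooperation
#'
#' Models each valid trial's cooperate/deceive decision with a subject
#' random intercept and fixed effects of opponent characteristics
#' (likability rating, opponent policy with the cooperative style as
#' reference, the opponent's last decision against this subject coded
#' +1 cooperate / 0 first encounter / -1 deceive), subject characteristics
#' (sex, age, the five personality scores, belief in live opponents) and
#' standardized trial index ("time"), plus interactions between stimulation
#' and every fixed effect. Numeric predictors are z-scored and screened for
#' collinearity with [select_features()] before entering. Coefficient
#' p-values use a t approximation on the residual degrees of freedom
#' (observations minus fixed effects).
#'
#' @param trials valid trials (see [clean_trials()]).
#' @param profiles subject profile table (see [generate_profiles()]).
#' @param likability likability-rating table (`subject_id`,
#'   `session_index`, `opponent_id`, `sam_likability`).
#' @param r2_threshold collinearity screen threshold.
#' @param nAGQ passed to [lme4::glmer()] (0 = fast Laplace-free fit,
#'   default; 1 = Laplace).
#' @return an object of class `"pd_mixed"`: list with the coefficient table
#'   (`term`, `estimate`, `se`, `t`, `p`), the random-intercept variance,
#'   the screen report, counts, and the fitted `glmer` model.
#' @export
mixed_logit_cooperation <- function(trials, profiles, likability,
                                    r2_threshold = 0.7, nAGQ = 0) {
  d <- trials[trials$valid & !is.na(trials$subject_choice), , drop = FALSE]
  d$cooperate <- as.integer(d$subject_choice == "cooperate")
  d$stim <- as.integer(d$stim_condition == "tvns")
  # opponent's last decision toward this subject in this session
  key <- paste(d$subject_id, d$session_index, d$opponent_id)
  d <- d[order(key, d$trial_index), ]
  key <- key[order(key, d$trial_index)]
  prev <- c(NA, d$opponent_choice[-nrow(d)])
  prev[c(TRUE, key[-1] != key[-length(key)])] <- NA
  d$last_opponent <- ifelse(is.na(prev), 0, ifelse(prev == "cooperate", 1, -1))
  lk <- likability
  d$likability <- lk$sam_likability[match(
    paste(d$subject_id, d$session_index, d$opponent_id),
    paste(lk$subject_id, lk$session_index, lk$opponent_id))]
  pr <- profiles[match(d$subject_id, profiles$subject_id), ]
  d$sex_female <- as.integer(pr$sex == "female")
  d$age <- pr$age
  for (tr in c("neuroticism", "extraversion", "openness", "agreeableness",
               "conscientiousness"))
    d[[tr]] <- pr[[paste0("neo_", tr)]]
  d$believed_live <- as.integer(pr$believed_live)
  d$time <- d$trial_index

  num_preds <- c("likability", "last_opponent", "age", "neuroticism",
                 "extraversion", "openness", "agreeableness",
                 "conscientiousness", "time")
  for (p in num_preds) {
    s <- stats::sd(d[[p]])
    d[[p]] <- if (s > 0) (d[[p]] - mean(d[[p]])) / s else 0
  }
  screen <- select_features(d[, num_preds], r2_threshold)
  preds <- c(screen$retained, "sex_female", "believed_live", "opponent_policy")
  d$opponent_policy <- stats::relevel(factor(d$opponent_policy), ref = "cooperative")
  form <- stats::as.formula(paste(
    "cooperate ~ stim * (", paste(preds, collapse = " + "), ") + (1 | subject_id)"))
  model <- tryCatch(
    lme4::glmer(form, data = d, family = stats::binomial(), nAGQ = nAGQ,
                control = lme4::glmerControl(calc.derivs = FALSE)),
    error = function(e) {
      if (grepl("Downdated|unidentifiable|failed", conditionMessage(e)))
        stop("mixed model could not be fitted (possible complete separation); ",
             "consider penalized estimation or fewer predictors: ",
             conditionMessage(e))
      stop(e)
    })
  cc <- summary(model)$coefficients
  n_fixed <- nrow(cc)
  df_resid <- nrow(d) - n_fixed
  tab <- data.frame(term = rownames(cc), estimate = cc[, "Estimate"],
                    se = cc[, "Std. Error"],
                    t = cc[, "Estimate"] / cc[, "Std. Error"],
                    stringsAsFactors = FALSE, row.names = NULL)
  tab$p <- 2 * stats::pt(-abs(tab$t), df_resid)
  vc <- as.data.frame(lme4::VarCorr(model))
  msgs <- unlist(model@optinfo$conv$lme4$messages)
  structure(list(coefficients = tab, df = df_resid,
                 subject_variance = vc$vcov[vc$grp == "subject_id"][1],
                 screen = screen, n_trials = nrow(d),
                 converged = length(msgs) == 0, messages = msgs,
                 model = model),
            class = "pd_mixed")
}

#' @export
print.pd_mixed <- function(x, digits = 3, ...) {
  cat("Mixed-effects logistic regression of trial-level cooperation\n")
  cat("Trials:", x$n_trials, " residual df:", x$df,
      " subject variance:", format(x$subject_variance, digits = digits), "\n")
  if (!x$converged) cat("NOTE: optimizer messages:", paste(x$messages, collapse = "; "), "\n")
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Per-subject stimulation effect on cooperation
#'
#' The tVNS-minus-sham difference of each subject's mean cell value from a
#' [cooperation_table()] (cells averaged within condition first).
#'
#' @param tab a [cooperation_table()].
#' @return data frame with `subject_id` and `effect` (percentage points).
#' @export
stimulation_effect <- function(tab) {
  m <- stats::aggregate(value ~ subject_id + stim_condition, data = tab, FUN = mean)
  w <- stats::reshape(m, idvar = "subject_id", timevar = "stim_condition",
                      direction = "wide")
  if (!all(c("value.tvns", "value.sham") %in% names(w)))
    stop("table must contain both 'tvns' and 'sham' conditions")
  data.frame(subject_id = w$subject_id, effect = w$value.tvns - w$value.sham)
}

#' Correlation with test
#'
#' Pearson or Spearman correlation with a two-sided test; Spearman uses
#' average ranks for ties. Errors on zero-variance input rather than
#' returning an undefined coefficient.
#'
#' @param x,y paired numeric vectors (`n >= 3`).
#' @param method `"pearson"` or `"spearman"`.
#' @return data frame with `method`, `coefficient`, `p`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("correlation needs at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: one of the vectors has zero variance")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  data.frame(method = method, coefficient = unname(ct$estimate),
             p = ct$p.value, n = length(x))
}

#' Minimum sample size for a paired comparison
#'
#' Smallest `n` such that a two-sided paired t-test at level `alpha` reaches
#' the requested power for the pilot effect size `mean_diff / sd_diff`
#' (exact noncentral-t power curve via [stats::power.t.test()]).
#'
#' @param pilot_mean_diff pilot mean of the paired differences.
#' @param pilot_sd pilot standard deviation of the paired differences
#'   (> 0).
#' @param alpha two-sided significance level.
#' @param power requested power.
#' @return list with `n` (minimum subjects), `power_at_n`,
#'   `power_at_n_minus_1`, and the input specification.
#' @export
sample_size_cooperation <- function(pilot_mean_diff, pilot_sd,
                                    alpha = 0.05, power = 0.95) {
  stopifnot(pilot_sd > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  if (pilot_mean_diff == 0)
    stop("effect size is zero: no finite sample size attains the requested power")
  delta <- abs(pilot_mean_diff)
  pw <- function(n) stats::power.t.test(n = n, delta = delta, sd = pilot_sd,
                                        sig.level = alpha, type = "paired")$power
  n <- max(2L, ceiling(stats::power.t.test(delta = delta, sd = pilot_sd,
                                           sig.level = alpha, power = power,
                                           type = "paired")$n))
  while (n > 2L && pw(n - 1L) >= power) n <- n - 1L
  while (pw(n) < power) n <- n + 1L
  list(n = n, power_at_n = pw(n),
       power_at_n_minus_1 = if (n > 2L) pw(n - 1L) else NA_real_,
       alpha = alpha, power = power,
       pilot_mean_diff = pilot_mean_diff, pilot_sd = pilot_sd)
}

# one-sample t on x against mu, degenerate-safe: zero spread at mu gives
# t = 0 / p = 1 instead of the error stats::t.test throws
safe_t_test <- function(x, mu = 0) {
  n <- length(x)
  s <- stats::sd(x)
  if (s == 0) {
    if (mean(x) == mu) return(list(t = 0, df = n - 1, p = 1))
    return(list(t = sign(mean(x) - mu) * Inf, df = n - 1, p = 0))
  }
  tt <- stats::t.test(x, mu = mu)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Paired t-tests on the affect scores
#'
#' Tests the tVNS-vs-sham difference in the per-session positive and
#' negative affect scores.
#'
#' @param profiles subject profile table with columns
#'   `panas_positive_tvns`, `panas_positive_sham`, `panas_negative_tvns`,
#'   `panas_negative_sham`.
#' @return data frame with one row per scale: `t`, `df`, `p`, means.
#' @export
affect_ttests <- function(profiles) {
  need <- c("panas_positive_tvns", "panas_positive_sham",
            "panas_negative_tvns", "panas_negative_sham")
  if (!all(need %in% names(profiles)))
    stop("profiles must contain both sessions' affect scores: ",
         paste(setdiff(need, names(profiles)), collapse = ", "))
  if (any(is.na(profiles[, need]))) stop("missing affect scores for some subjects")
  one <- function(scale) {
    x <- profiles[[paste0("panas_", scale, "_tvns")]]
    y <- profiles[[paste0("panas_", scale, "_sham")]]
    tt <- safe_t_test(x - y, mu = 0)
    data.frame(scale = scale, mean_tvns = mean(x), mean_sham = mean(y),
               t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
  }
  rbind(one("positive"), one("negative"))
}
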