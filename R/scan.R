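#' Chi-square difference test between nested diffusion models
#'
#' Compares a fully fixed model (all parameters shared across group levels)
#' to a model in which exactly one parameter is free per level. The statistic
#' is the deviance difference, floored at 0 against optimizer noise, referred
#' to a chi-square distribution with degrees of freedom equal to the number
#' of extra free parameters (levels minus one for one freed parameter).
#'
#' @param fit_fixed a [fit_ddm()] object with `free = "none"`.
#' @param fit_free a [fit_ddm()] object whose specification nests
#'   `fit_fixed`: same data, same group levels, same active variability
#'   parameters, one freed parameter.
#' @return an object of class `"ddm_comparison"`: a list with
#'   `free_parameter`, `statistic`, `df`, `p_value`, and both deviances.
#' @export
ddm_compare <- function(fit_fixed, fit_free) {
  stopifnot(inherits(fit_fixed, "ddmfit"), inherits(fit_free, "ddmfit"))
  if (fit_fixed$free != "none")
    stop("fit_fixed must be the fully fixed model (free = 'none')")
  if (fit_free$free == "none")
    stop("fit_free must have exactly one free parameter")
  if (!identical(fit_fixed$levels, fit_free$levels))
    stop("the two fits use different group levels; models are not nested")
  if (!identical(sort(fit_fixed$include), sort(fit_free$include)))
    stop("the two fits activate different variability parameters; models are not nested")
  if (sum(fit_fixed$nobs) != sum(fit_free$nobs))
    stop("the two fits use different data; models are not nested")
  df <- fit_free$npar - fit_fixed$npar
  if (df < 1) stop("free model has no extra parameters; models are not nested")
  stat <- max(0, fit_fixed$deviance - fit_free$deviance)
  structure(list(free_parameter = fit_free$free, statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 deviance_fixed = fit_fixed$deviance,
                 deviance_free = fit_free$deviance),
            class = "ddm_comparison")
}

#' @export
print.ddm_comparison <- function(x, ...) {
  cat(sprintf("Chi-square difference test, freed parameter '%s':\n", x$free_parameter))
  cat(sprintf("  chi2 = %.4f, df = %d, p = %.4g\n", x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Seven-nested-model scan for one dataset
#'
#' Fits, for each of the seven classic diffusion parameters, a model in which
#' only that parameter may differ across group levels, and compares each to
#' the fully fixed baseline by a chi-square difference test. Variability
#' parameters (`eta`, `sz`, `st`) are activated only in the comparison that
#' frees them: there the baseline estimates them shared across levels, so
#' every test has `levels - 1` degrees of freedom per freed parameter.
#' Free-model fits are warm-started from the corresponding fixed-model
#' optimum, which also enforces the nested deviance ordering numerically.
#'
#' @inheritParams fit_ddm
#' @param params which parameters to scan (default all seven).
#' @return a data frame of class `"ddm_scan"` with one row per freed
#'   parameter: `chi2`, `df`, `p`, both deviances, and convergence flags.
#' @export
ddm_scan <- function(rt, choice, group,
                     params = c("a", "t0", "eta", "z", "sz", "st", "v"),
                     control = fit_control()) {
  params <- match.arg(params, several.ok = TRUE)
  base_fixed <- fit_ddm(rt, choice, group, free = "none", control = control)
  rows <- lapply(params, function(p) {
    fixed <- if (p %in% .var3) {
      fit_ddm(rt, choice, group, free = "none", include = p, control = control)
    } else base_fixed
    warm <- control
    warm$start <- as.list(fixed$coefficients[1, c("a", "v", "t0")])
    warm$start$w <- fixed$coefficients$b[1]
    if (p %in% .var3) warm$start[[p]] <- fixed$coefficients[[p]][1]
    fr <- fit_ddm(rt, choice, group, free = p,
                  include = intersect(fixed$include, .var3), control = warm)
    cmp <- ddm_compare(fixed, fr)
    data.frame(free_parameter = p, chi2 = cmp$statistic, df = cmp$df,
               p = cmp$p_value, deviance_fixed = cmp$deviance_fixed,
               deviance_free = cmp$deviance_free,
               converged = fixed$converged && fr$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ddm_scan", "data.frame")
  out
}

#' Cohort-level nested-model comparison
#'
#' Runs [ddm_scan()] per subject and aggregates: the cohort chi-square
#' statistic for each freed parameter is the sum of the per-subject deviance
#' differences with summed degrees of freedom (per-subject fitting; subjects
#' are independent, so the summed statistic is chi-square under the null).
#'
#' @param trials a trial-log data frame (see [generate_study()]); only valid
#'   trials are used.
#' @param params parameters to scan.
#' @param group_col name of the condition column (default
#'   `"stim_condition"`).
#' @param subject_col name of the subject column.
#' @param control a [fit_control()] list.
#' @return a data frame with one row per freed parameter: summed `chi2`,
#'   summed `df`, `p`, and the number of subjects entering.
#' @export
ddm_scan_cohort <- function(trials, params = c("a", "t0", "eta", "z", "sz", "st", "v"),
                            group_col = "stim_condition",
                            subject_col = "subject_id",
                            control = fit_control()) {
  trials <- trials[trials$valid & !is.na(trials$subject_choice), , drop = FALSE]
  per_subj <- lapply(split(trials, trials[[subject_col]]), function(d) {
    ddm_scan(d$subject_rt_s, d$subject_choice, d[[group_col]],
             params = params, control = control)
  })
  out <- do.call(rbind, lapply(params, function(p) {
    rows <- do.call(rbind, lapply(per_subj, function(s) s[s$free_parameter == p, ]))
    chi2 <- sum(rows$chi2); df <- sum(rows$df)
    data.frame(free_parameter = p, chi2 = chi2, df = df,
               p = stats::pchisq(chi2, df, lower.tail = FALSE),
               n_subjects = nrow(rows), stringsAsFactors = FALSE)
  }))
  attr(out, "per_subject") <- per_subj
  class(out) <- c("ddm_scan", "data.frame")
  out
}

#' Per-subject, per-condition diffusion parameters
#'
#' For each subject, estimates the normalized starting bias per condition
#' (from the starting-point-free model) and the drift rate per condition
#' (from the drift-free model), with boundary separation and non-decision
#' time shared across conditions within subject.
#'
#' @inheritParams ddm_scan_cohort
#' @return data frame with one row per subject x condition: `b`, `v`, the
#'   shared `a` and `t0`, deviances and convergence flags.
#' @export
ddm_subject_params <- function(trials, group_col = "stim_condition",
                               subject_col = "subject_id",
                               control = fit_control()) {
  trials <- trials[trials$valid & !is.na(trials$subject_choice), , drop = FALSE]
  out <- lapply(split(trials, trials[[subject_col]]), function(d) {
    fz <- fit_ddm(d$subject_rt_s, d$subject_choice, d[[group_col]],
                  free = "z", control = control)
    fv <- fit_ddm(d$subject_rt_s, d$subject_choice, d[[group_col]],
                  free = "v", control = control)
    data.frame(subject_id = d[[subject_col]][1],
               condition = fz$coefficients$level,
               b = fz$coefficients$b,
               v = fv$coefficients$v,
               a = fz$coefficients$a,
               t0 = fz$coefficients$t0,
               deviance_z = fz$deviance, deviance_v = fv$deviance,
               converged = fz$converged && fv$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Group-level tests on fitted diffusion parameters
#'
#' Per condition, one-sample t-tests of the starting bias against 0.5 and of
#' the drift rate against 0; across conditions, paired t-tests with paired
#' Cohen's d. One-sample p-values are Bonferroni-adjusted within their
#' family of four simultaneous tests (2 parameters x 2 conditions); paired
#' p-values within their family of two.
#'
#' @param subject_params output of [ddm_subject_params()] (needs >= 3
#'   subjects with both conditions).
#' @return data frame with one row per test: `test`, `parameter`,
#'   `condition`, `estimate`, `t`, `df`, `p`, `p_adj`, `cohens_d` (paired
#'   rows only).
#' @export
ddm_group_tests <- function(subject_params) {
  sp <- subject_params
  conds <- sort(unique(sp$condition))
  wide_b <- stats::reshape(sp[, c("subject_id", "condition", "b")],
                           idvar = "subject_id", timevar = "condition",
                           direction = "wide")
  wide_v <- stats::reshape(sp[, c("subject_id", "condition", "v")],
                           idvar = "subject_id", timevar = "condition",
                           direction = "wide")
  if (nrow(wide_b) < 3) stop("group tests need at least 3 subjects with converged fits")
  one <- list(); paired <- list()
  for (cond in conds) {
    b <- sp$b[sp$condition == cond]; v <- sp$v[sp$condition == cond]
    tb <- safe_t_test(b, 0.5)
    tv <- safe_t_test(v, 0)
    one[[paste0("b.", cond)]] <- data.frame(
      test = "one_sample", parameter = "bias", condition = cond,
      estimate = mean(b), t = tb$t, df = tb$df, p = tb$p,
      stringsAsFactors = FALSE)
    one[[paste0("v.", cond)]] <- data.frame(
      test = "one_sample", parameter = "drift", condition = cond,
      estimate = mean(v), t = tv$t, df = tv$df, p = tv$p,
      stringsAsFactors = FALSE)
  }
  if (length(conds) == 2) {
    for (par in c("bias", "drift")) {
      wd <- if (par == "bias") wide_b else wide_v
      x <- wd[[2]]; y <- wd[[3]]
      tt <- safe_t_test(x - y, 0)
      paired[[par]] <- data.frame(
        test = "paired", parameter = par,
        condition = paste(sub("^[bv]\\.", "", names(wd)[2]), "-",
                          sub("^[bv]\\.", "", names(wd)[3])),
        estimate = mean(x - y), t = tt$t, df = tt$df, p = tt$p,
        stringsAsFactors = FALSE)
    }
  }
  one_df <- do.call(rbind, one)
  one_df$p_adj <- pmin(1, nrow(one_df) * one_df$p)
  one_df$cohens_d <- NA_real_
  out <- one_df
  if (length(paired)) {
    paired_df <- do.call(rbind, paired)
    paired_df$p_adj <- pmin(1, nrow(paired_df) * paired_df$p)
    paired_df$cohens_d <- c(
      bias = cohens_d_paired(wide_b[[2]], wide_b[[3]])$d,
      drift = cohens_d_paired(wide_v[[2]], wide_v[[3]])$d)
    out <- rbind(out, paired_df)
  }
  rownames(out) <- NULL
  out
}
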