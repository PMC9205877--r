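test_that("trial cleaning removes invalid rows and reports counts", {
  st <- small_study()
  tr <- st$trials
  cl <- clean_trials(tr)
  expect_equal(nrow(cl$trials), sum(tr$valid))
  expect_true(all(cl$trials$valid))
  expect_equal(sum(cl$exclusions$n_excluded), sum(!tr$valid))
  # a session with one injected timeout keeps 119 trials
  one <- tr[tr$subject_id == tr$subject_id[1] & tr$session_index == 1, ]
  one$valid[5] <- FALSE
  cl1 <- clean_trials(one)
  expect_equal(nrow(cl1$trials), 119L)
  # no invalid rows: output identical to input
  allv <- tr[tr$valid, ]
  expect_identical(clean_trials(allv)$trials, allv)
  # a cell with no valid trials is an error naming the cell
  bad <- tr
  bad$valid[bad$subject_id == "S02" & bad$stim_condition == "sham"] <- FALSE
  expect_error(clean_trials(bad), "S02.*sham")
})

test_that("cooperation table: saturation, arithmetic, independent recount", {
  st <- small_study()
  cl <- clean_trials(st$trials)
  # all-cooperate subject scores 100 in every cell
  mono <- cl$trials[cl$trials$subject_id == "S01", ]
  mono$subject_choice <- "cooperate"
  tab <- cooperation_table(mono)
  expect_true(all(tab$value == 100))
  # alternating choices over an even count give 50%
  alt <- mono[mono$stim_condition == mono$stim_condition[1], ][1:30, ]
  alt$opponent_class <- "human"
  alt$subject_choice <- rep(c("cooperate", "deceive"), 15)
  expect_equal(cooperation_table(alt)$value, 50)
  # independent group-by recount on a 30-trial fixture
  fix <- cl$trials[1:30, ]
  tabf <- cooperation_table(fix)
  for (i in seq_len(nrow(tabf))) {
    sel <- fix$subject_id == tabf$subject_id[i] &
      fix$stim_condition == tabf$stim_condition[i] &
      fix$opponent_class == tabf$opponent_class[i]
    expect_equal(tabf$value[i], 100 * mean(fix$subject_choice[sel] == "cooperate"))
    expect_equal(tabf$n_valid_trials[i], sum(sel))
  }
  # RT analogue
  rt_tab <- cooperation_table(fix, "rt")
  sel <- fix$subject_id == rt_tab$subject_id[1] &
    fix$stim_condition == rt_tab$stim_condition[1] &
    fix$opponent_class == rt_tab$opponent_class[1]
  expect_equal(rt_tab$value[1], mean(fix$subject_rt_s[sel]))
})

test_that("repeated-measures ANOVA matches a brute-force SS oracle", {
  set.seed(14)
  tab <- expand.grid(subject_id = sprintf("S%d", 1:5),
                     stim_condition = c("sham", "tvns"),
                     opponent_class = c("computer", "human"),
                     stringsAsFactors = FALSE)
  tab$value <- 40 + 3 * (tab$stim_condition == "tvns") +
    6 * (tab$opponent_class == "human") + rnorm(20, 0, 5)
  an <- rm_anova_2x2(tab)
  oracle <- anova_bruteforce(tab)
  expect_equal(an$F, unname(oracle[an$effect]), tolerance = 1e-10)
  expect_true(all(an$df1 == 1 & an$df2 == 4))
  # permuting subject labels leaves F unchanged
  perm <- tab
  relab <- setNames(sample(sprintf("S%d", 1:5)), sprintf("S%d", 1:5))
  perm$subject_id <- relab[perm$subject_id]
  expect_equal(rm_anova_2x2(perm)$F, an$F)
  # identical conditions per subject: stimulation effect exactly null
  null_tab <- tab
  sham <- tab[tab$stim_condition == "sham", ]
  null_tab$value <- sham$value[match(
    paste(null_tab$subject_id, null_tab$opponent_class),
    paste(sham$subject_id, sham$opponent_class))]
  an0 <- rm_anova_2x2(null_tab)
  expect_lt(an0$F[an0$effect == "stimulation"], 1e-10)
  expect_gt(an0$p[an0$effect == "stimulation"], 0.999)
  # incomplete design errors
  expect_error(rm_anova_2x2(tab[-1, ]), "exactly one value")
})

test_that("shuffling condition labels within subjects destroys a planted effect", {
  st <- small_study()
  tab <- cooperation_table(clean_trials(st$trials)$trials)
  f_obs <- rm_anova_2x2(tab)$F[1]
  set.seed(50)
  f_perm <- replicate(20, {
    flip <- sample(c(TRUE, FALSE), 6, replace = TRUE)
    pt <- tab
    for (i in which(flip)) {
      sel <- pt$subject_id == unique(pt$subject_id)[i]
      pt$stim_condition[sel] <- ifelse(pt$stim_condition[sel] == "tvns", "sham", "tvns")
    }
    rm_anova_2x2(pt)$F[1]
  })
  expect_lt(mean(f_perm), max(f_obs, 3))
  expect_gt(mean(f_perm), 0)
})

test_that("paired Cohen's d follows the dz convention", {
  x <- c(10, 12, 9, 14); y <- c(8, 11, 9, 10)
  d <- cohens_d_paired(x, y)
  diffs <- x - y
  expect_equal(d$d, mean(diffs) / sd(diffs))  # hand-checked: 1.75/sd(2,1,0,4)
  expect_false(d$degenerate)
  expect_equal(cohens_d_paired(x, x)$d, 0)
  deg <- cohens_d_paired(x + 2, x)
  expect_true(deg$degenerate)
  expect_equal(deg$d, Inf)
  expect_error(cohens_d_paired(1, numeric(0)))
})

test_that("feature screen drops exactly the collinear predictors", {
  set.seed(15)
  X <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  expect_equal(select_features(X)$retained, c("a", "b", "c"))
  # duplicated column: exactly one of the pair dropped
  X2 <- X; X2$d <- X2$a
  sel <- select_features(X2)
  expect_length(sel$dropped, 1)
  expect_true(sel$dropped %in% c("a", "d"))
  expect_equal(sel$report$r_squared, 1)
  # R^2 = 0.65 is below the strict threshold: both retained
  n <- 10000
  z <- rnorm(n)
  y <- sqrt(0.65) * scale(z)[, 1] + sqrt(0.35) * scale(rnorm(n))[, 1]
  X3 <- data.frame(z = z, y = y, w = rnorm(n))
  r2 <- cor(X3$z, X3$y)^2
  expect_lt(abs(r2 - 0.65), 0.03)
  expect_length(select_features(X3)$dropped, 0)
})

test_that("correlations: monotone, tie handling vs rank oracle, degenerate input", {
  x <- c(1, 2, 3, 4, 5); y <- exp(x)
  expect_equal(correlate(x, y, "spearman")$coefficient, 1)
  # ties: average-rank Spearman equals rank-then-Pearson
  xt <- c(1, 2, 2, 3, 5, 5, 7); yt <- c(2, 1, 4, 4, 6, 8, 8)
  sp <- correlate(xt, yt, "spearman")
  expect_equal(sp$coefficient, cor(rank(xt), rank(yt)))
  expect_error(correlate(x, rep(3, 5)), "zero variance")
  expect_error(correlate(1:2, 2:3), "at least 3")
  pe <- correlate(x, y, "pearson")
  expect_equal(pe$coefficient, cor(x, y))
})

test_that("per-subject stimulation effect equals the recomputed difference", {
  st <- small_study()
  tab <- cooperation_table(clean_trials(st$trials)$trials)
  eff <- stimulation_effect(tab)
  expect_equal(nrow(eff), 6L)
  for (i in seq_len(nrow(eff))) {
    s <- tab[tab$subject_id == eff$subject_id[i], ]
    expect_equal(eff$effect[i],
                 mean(s$value[s$stim_condition == "tvns"]) -
                   mean(s$value[s$stim_condition == "sham"]))
  }
  tab0 <- tab
  tab0$value <- ave(tab0$value, tab0$subject_id, tab0$opponent_class)
  expect_true(all(stimulation_effect(tab0)$effect == 0))
})

test_that("paired sample-size computation is minimal, monotone, and matches simulation", {
  ss <- sample_size_cooperation(9.2, 10, alpha = 0.05, power = 0.95)
  expect_gte(ss$power_at_n, 0.95)
  expect_lt(ss$power_at_n_minus_1, 0.95)
  # doubling the effect never increases n
  expect_lte(sample_size_cooperation(18.4, 10)$n, ss$n)
  expect_error(sample_size_cooperation(0, 10), "zero")
  # Monte-Carlo paired-t power at the returned n (vectorized, 1e5 replicates)
  set.seed(16)
  n <- ss$n; d <- 9.2 / 10
  z <- matrix(rnorm(n * 1e5, d, 1), nrow = n)
  tstat <- colMeans(z) / (apply(z, 2, sd) / sqrt(n))
  mc <- mean(abs(tstat) > qt(0.975, n - 1))
  expect_lt(abs(mc - ss$power_at_n), 0.01)
})

test_that("affect t-tests: null, antisymmetry, hand-computed fixture", {
  pr <- data.frame(panas_positive_tvns = c(17, 19, 16, 20),
                   panas_positive_sham = c(16, 18, 17, 19),
                   panas_negative_tvns = c(18, 18, 19, 17),
                   panas_negative_sham = c(18, 18, 19, 17))
  at <- affect_ttests(pr)
  # identical sessions: p = 1 for the negative scale
  expect_equal(at$p[at$scale == "negative"], 1)
  expect_equal(at$t[at$scale == "negative"], 0)
  # hand-computed paired t for the positive scale: diffs 1,1,-1,1
  diffs <- c(1, 1, -1, 1)
  t_hand <- mean(diffs) / (sd(diffs) / 2)
  expect_equal(at$t[at$scale == "positive"], t_hand)
  # swapping sessions flips the sign
  sw <- pr
  sw[, c(1, 2)] <- pr[, c(2, 1)]
  expect_equal(affect_ttests(sw)$t[1], -at$t[1])
  expect_error(affect_ttests(pr[, -2]), "panas_positive_sham")
})

test_that("mixed-effects logistic model runs and reports sane structure", {
  st <- small_study()
  cl <- clean_trials(st$trials)
  m <- mixed_logit_cooperation(cl$trials, st$profiles, st$likability)
  expect_s3_class(m, "pd_mixed")
  tb <- m$coefficients
  expect_true(all(c("(Intercept)", "stim", "stim:neuroticism") %in% tb$term))
  expect_true(all(is.finite(tb$t)))
  expect_true(all(tb$p >= 0 & tb$p <= 1))
  expect_gte(m$subject_variance, 0)
  expect_equal(m$df, m$n_trials - nrow(tb))
  # reciprocity generator: cooperation drops after being deceived
  cfg_r <- study_config(list(cohort = list(effects = list(reciprocity = 0.6))))
  str_ <- generate_study(n_subjects = 6, cfg = cfg_r, seed = 91)
  mr <- mixed_logit_cooperation(clean_trials(str_$trials)$trials,
                                str_$profiles, str_$likability)
  co <- mr$coefficients
  # last_opponent is coded +1 cooperate / -1 deceive, so the planted
  # after-deception drop appears as a positive coefficient
  expect_gt(co$estimate[co$term == "last_opponent"], 0)
  expect_lt(co$p[co$term == "last_opponent"], 0.05)
})
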