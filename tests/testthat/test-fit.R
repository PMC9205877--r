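test_that("parameters are recovered from simulated data", {
  true <- list(a = 1.6, v = 1.0, w = 0.55, t0 = 0.35)
  ok_b <- ok_rel <- logical(6)
  for (s in seq_len(6)) {
    set.seed(100 + s)
    d <- rwiener_fp(1000, true$a, true$v, true$w, true$t0, bridge = TRUE)
    f <- fit_ddm(d$rt, d$choice, control = fit_control(restarts = 2))
    cf <- f$coefficients
    ok_b[s] <- abs(cf$b - true$w) <= 0.05
    ok_rel[s] <- abs(cf$a - true$a) / true$a <= 0.15 &&
      abs(cf$v - true$v) / abs(true$v) <= 0.15 &&
      abs(cf$t0 - true$t0) <= 0.03
  }
  expect_true(all(ok_b))
  expect_gte(sum(ok_rel), 5)
})

test_that("bias is recovered at the study's trial count", {
  # 120 trials per condition, planted bias difference; error <= 0.08 in
  # at least 80% of seeds
  ok <- logical(15)
  for (s in seq_len(15)) {
    set.seed(300 + s)
    d <- rwiener_fp(120, 1.6, -0.33, 0.58, 0.35)
    f <- fit_ddm(d$rt, d$choice, control = fit_control(restarts = 1))
    ok[s] <- abs(f$coefficients$b - 0.58) <= 0.08
  }
  expect_gte(mean(ok), 0.8)
})

test_that("freeing a parameter never worsens the fit, refits are stable", {
  set.seed(21)
  g <- rep(c("sham", "tvns"), each = 150)
  d <- rbind(rwiener_fp(150, 1.6, -0.3, 0.5, 0.35),
             rwiener_fp(150, 1.6, -0.3, 0.58, 0.35))
  ctrl <- fit_control(restarts = 1)
  ffix <- fit_ddm(d$rt, d$choice, g, free = "none", control = ctrl)
  warm <- ctrl
  warm$start <- list(a = ffix$coefficients$a[1], w = ffix$coefficients$b[1],
                     v = ffix$coefficients$v[1], t0 = ffix$coefficients$t0[1])
  for (p in c("z", "v", "a", "t0")) {
    fr <- fit_ddm(d$rt, d$choice, g, free = p, control = warm)
    expect_lte(fr$deviance, ffix$deviance + 1e-6)
    expect_equal(fr$npar, 5L)
  }
  # fixed point: restarting from the optimum does not improve beyond tolerance
  warm2 <- ctrl
  warm2$restarts <- 0L
  warm2$start <- list(a = ffix$coefficients$a[1], w = ffix$coefficients$b[1],
                      v = ffix$coefficients$v[1], t0 = ffix$coefficients$t0[1])
  refit <- fit_ddm(d$rt, d$choice, g, free = "none", control = warm2)
  expect_lt(abs(refit$deviance - ffix$deviance), 0.01)
})

test_that("ddmfit methods behave", {
  set.seed(31)
  d <- rwiener_fp(300, 1.6, -0.3, 0.5, 0.35)
  f <- fit_ddm(d$rt, d$choice, control = fit_control(restarts = 1))
  expect_s3_class(f, "ddmfit")
  expect_named(coef(f), c("level", "a", "v", "b", "t0", "eta", "sz", "st"))
  expect_equal(as.numeric(logLik(f)), -deviance(f) / 2)
  expect_equal(unname(starting_bias(f)), coef(f)$b)
  sm <- summary(f)
  expect_lt(abs(sm$coefficients$p_cooperate_fit - sm$coefficients$p_cooperate_obs), 0.1)
  sim <- simulate(f, seed = 1)
  expect_equal(nrow(sim), 300L)
  pr <- predict(f)
  expect_true(pr$p_cooperate > 0 && pr$p_cooperate < 1)
  qs <- predict(f, type = "quantiles")
  expect_equal(nrow(qs), 10L)  # 5 quantiles x 2 boundaries
  expect_true(all(diff(qs$rt[qs$choice == "cooperate"]) > 0))
  expect_output(print(f), "Drift-diffusion")
  # trials under the RT floor are excluded and counted
  f2 <- fit_ddm(c(0.05, d$rt), c("cooperate", d$choice),
                control = fit_control(restarts = 0))
  expect_equal(f2$n_excluded, 1L)
})

test_that("nested comparison: statistic, df, p, and nesting guards", {
  mk <- function(free, npar, dev, levels = c("sham", "tvns"), include = character())
    structure(list(free = free, npar = npar, deviance = dev, levels = levels,
                   include = include, nobs = c(sham = 100, tvns = 100)),
              class = "ddmfit")
  # identical deviances: statistic 0, p 1
  cmp <- ddm_compare(mk("none", 4, 500), mk("z", 5, 500))
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$df, 1L)
  # deviance difference refers to chi-square df 1
  cmp2 <- ddm_compare(mk("none", 4, 510), mk("z", 5, 503.8))
  expect_equal(cmp2$statistic, 6.2)
  expect_equal(cmp2$p_value, pchisq(6.2, 1, lower.tail = FALSE))
  # optimizer noise cannot produce a negative statistic
  cmp3 <- ddm_compare(mk("none", 4, 500), mk("z", 5, 500.001))
  expect_equal(cmp3$statistic, 0)
  expect_error(ddm_compare(mk("z", 5, 500), mk("z", 5, 500)), "fixed")
  expect_error(ddm_compare(mk("none", 4, 500), mk("none", 4, 500)), "free")
  expect_error(ddm_compare(mk("none", 4, 500),
                           mk("eta", 6, 499, include = "eta")), "not nested")
  bad_levels <- mk("z", 5, 499, levels = c("x", "y"))
  expect_error(ddm_compare(mk("none", 4, 500), bad_levels), "levels")
})

test_that("the seven-model scan runs and orders models sanely", {
  set.seed(41)
  g <- rep(c("sham", "tvns"), each = 130)
  d <- rbind(rwiener_fp(130, 1.6, -0.33, 0.5, 0.35),
             rwiener_fp(130, 1.6, -0.33, 0.62, 0.35))
  sc <- ddm_scan(d$rt, d$choice, g, params = c("z", "v", "a"),
                 control = fit_control(restarts = 1, reltol = 1e-6))
  expect_equal(sc$free_parameter, c("z", "v", "a"))
  expect_true(all(sc$chi2 >= 0))
  expect_true(all(sc$df == 1L))
  expect_true(all(sc$deviance_free <= sc$deviance_fixed + 1e-6))
  # the planted bias difference is the best-supported freed parameter
  expect_equal(sc$free_parameter[which.max(sc$chi2)], "z")
})

test_that("group-level parameter tests: nulls, Bonferroni arithmetic, planted shift", {
  # all biases exactly 0.5: t = 0, adjusted p = 1
  sp <- data.frame(subject_id = rep(sprintf("S%02d", 1:6), each = 2),
                   condition = rep(c("sham", "tvns"), 6),
                   b = 0.5, v = rep(c(-0.2, -0.1), 6))
  gt <- ddm_group_tests(sp)
  b_rows <- gt[gt$parameter == "bias" & gt$test == "one_sample", ]
  expect_true(all(b_rows$t == 0))
  expect_true(all(b_rows$p_adj == 1))
  # Bonferroni: one-sample family has m = 4
  v_rows <- gt[gt$parameter == "drift" & gt$test == "one_sample", ]
  expect_equal(v_rows$p_adj, pmin(1, 4 * v_rows$p))
  # paired drift difference is constant -0.1: degenerate-safe, significant
  d_row <- gt[gt$parameter == "drift" & gt$test == "paired", ]
  expect_equal(d_row$p, 0)
  # planted bias shift across subjects is detected with the right sign
  set.seed(5)
  sp2 <- data.frame(subject_id = rep(sprintf("S%02d", 1:12), each = 2),
                    condition = rep(c("sham", "tvns"), 12),
                    b = 0.5 + rep(c(0, 0.05), 12) + rnorm(24, 0, 0.01),
                    v = rnorm(24, -0.3, 0.05))
  gt2 <- ddm_group_tests(sp2)
  pb <- gt2[gt2$parameter == "bias" & gt2$test == "paired", ]
  expect_lt(pb$p, 0.05)
  expect_lt(pb$estimate, 0)  # sham minus tvns
  expect_lt(pb$cohens_d, 0)
})
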