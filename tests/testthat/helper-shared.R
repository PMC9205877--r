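# Shared fixtures and memoised heavy simulations, so expensive Monte-Carlo
# runs are computed once and reused across test files.

.shared <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.shared[[key]])) .shared[[key]] <- force(expr)
  .shared[[key]]
}

# small planted-effect study reused by several stats tests
small_study <- function() memo("small_study", {
  generate_study(n_subjects = 6, seed = 420)
})

# p-values of the starting-point chi-square difference test under the null
# (both conditions generated from identical diffusion parameters,
# 120 trials per condition)
null_chisq_pvalues <- function(n_rep = 150L) {
  key <- paste0("null_chisq_", n_rep)
  memo(key, {
    ctrl <- fit_control(restarts = 0, reltol = 1e-6, maxit = 400)
    vapply(seq_len(n_rep), function(s) {
      set.seed(7000 + s)
      d <- rwiener_fp(240, a = 1.6, v = -0.33, w = 0.5, t0 = 0.35)
      g <- rep(c("sham", "tvns"), each = 120)
      ffix <- fit_ddm(d$rt, d$choice, g, free = "none", control = ctrl)
      warm <- ctrl
      warm$start <- list(a = ffix$coefficients$a[1], w = ffix$coefficients$b[1],
                         v = ffix$coefficients$v[1], t0 = ffix$coefficients$t0[1])
      ffree <- fit_ddm(d$rt, d$choice, g, free = "z", control = warm)
      ddm_compare(ffix, ffree)$p_value
    }, 0)
  })
}

# hand-rolled 2x2 within-subject sums-of-squares decomposition (oracle,
# independent of stats::aov)
anova_bruteforce <- function(tab) {
  s <- factor(tab$subject_id); A <- factor(tab$stim_condition)
  B <- factor(tab$opponent_class); y <- tab$value
  gm <- mean(y)
  ms <- tapply(y, s, mean); mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mAB <- tapply(y, list(A, B), mean)
  msA <- tapply(y, list(s, A), mean); msB <- tapply(y, list(s, B), mean)
  nS <- nlevels(s); nA <- nlevels(A); nB <- nlevels(B)
  ssA <- nS * nB * sum((mA - gm)^2)
  ssB <- nS * nA * sum((mB - gm)^2)
  ssAB <- nS * sum((mAB - outer(mA - gm, mB - gm, "+") - gm)^2)
  sssA <- nB * sum((msA - outer(ms - gm, mA - gm, "+") - gm)^2)
  sssB <- nA * sum((msB - outer(ms - gm, mB - gm, "+") - gm)^2)
  pred <- outer(ms - gm, rep(0, nA * nB), "+") + gm
  cell <- matrix(y[order(s, A, B)], nrow = nS, byrow = TRUE)
  # residual stratum: total within-subject SS minus all modelled strata
  ssWithin <- sum((cell - rowMeans(cell))^2)
  sssAB <- ssWithin - ssA - ssB - ssAB - sssA - sssB
  F_A <- (ssA / (nA - 1)) / (sssA / ((nS - 1) * (nA - 1)))
  F_B <- (ssB / (nB - 1)) / (sssB / ((nS - 1) * (nB - 1)))
  F_AB <- (ssAB / ((nA - 1) * (nB - 1))) / (sssAB / ((nS - 1) * (nA - 1) * (nB - 1)))
  c(stimulation = F_A, opponent = F_B, interaction = F_AB)
}
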