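## Synthetic cohort: subject profiles, condition assignment, and diffusion-
## generated sessions with planted stimulation effects.

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

#' Generate synthetic subject profiles
#'
#' Draws demographic, personality, belief, affect and clinical covariates
#' from the configured distributions. The trait and clinical distributions
#' are generator plumbing (the source cohort's per-subject distributions are
#' not public); demographics match the study description (age ~ truncated
#' Normal(45, 12), 13/19 female). A latent between-subject drift offset
#' (`latent_drift_offset`) is drawn here so that a subject's generative
#' parameters are a deterministic function of their profile.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param cfg a [study_config()] configuration.
#' @return data frame with one row per subject.
#' @export
generate_profiles <- function(n_subjects, cfg = study_config()) {
  if (!is.numeric(n_subjects) || n_subjects < 2)
    stop("n_subjects must be at least 2")
  n <- as.integer(n_subjects)
  co <- cfg$cohort
  if (co$age_sd <= 0) stop("invalid trait configuration: age_sd must be positive")
  pr <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    age = round(rtruncnorm1(n, co$age_mean, co$age_sd, co$age_min, co$age_max)),
    sex = ifelse(stats::runif(n) < co$female_p, "female", "male"),
    stringsAsFactors = FALSE)
  for (tr in names(co$trait_mean)) {
    pr[[paste0("neo_", tr)]] <- round(rtruncnorm1(
      n, co$trait_mean[[tr]], co$trait_sd[[tr]], co$trait_min, co$trait_max))
  }
  pr$believed_live <- stats::runif(n) < co$believed_live_p
  pr$panas_positive_tvns <- round(rtruncnorm1(n, co$panas_positive_mean, co$panas_positive_sd, 10, 50))
  pr$panas_positive_sham <- round(rtruncnorm1(n, co$panas_positive_mean, co$panas_positive_sd, 10, 50))
  pr$panas_negative_tvns <- round(rtruncnorm1(n, co$panas_negative_mean, co$panas_negative_sd, 10, 50))
  pr$panas_negative_sham <- round(rtruncnorm1(n, co$panas_negative_mean, co$panas_negative_sd, 10, 50))
  pr$disease_duration <- round(rtruncnorm1(n, co$disease_duration_mean, co$disease_duration_sd, 1, 60), 1)
  pr$time_since_last_seizure <- round(rtruncnorm1(n, co$seizure_free_mean, co$seizure_free_sd, 1, 40), 1)
  pr$affected_hemisphere <- sample(c("left", "right"), n, replace = TRUE)
  pr$medicated <- stats::runif(n) < co$medicated_p
  pr$latent_drift_offset <- stats::rnorm(n, 0, co$effects$subject_v_sd)
  pr
}

#' Generative diffusion parameters for one subject and condition
#'
#' Deterministic mapping from a subject profile and stimulation condition to
#' that subject's diffusion parameters. Under sham the starting bias is 0.5
#' (no initial preference). Under tVNS the bias is shifted towards
#' cooperation by `bias_shift_tvns`, scaled by
#' `1 + neuroticism_modulation * z_N + extraversion_modulation * z_E`
#' (traits standardized against the configured population mean/SD, so the
#' stimulation effect shrinks with neuroticism and grows with extraversion),
#' and the drift is shifted towards cooperation by `drift_shift_tvns`. The
#' resulting bias is clipped to (0.05, 0.95). The subject's latent drift
#' offset applies in both conditions.
#'
#' @param profile one row of [generate_profiles()] output.
#' @param stim_condition `"tvns"` or `"sham"`.
#' @param cfg a [study_config()] configuration.
#' @return list with `a`, `v`, `w`, `t0`.
#' @export
agent_params <- function(profile, stim_condition = c("sham", "tvns"),
                         cfg = study_config()) {
  stim_condition <- match.arg(stim_condition)
  ef <- cfg$cohort$effects
  co <- cfg$cohort
  v <- ef$base_v + profile$latent_drift_offset
  w <- ef$base_w
  if (stim_condition == "tvns") {
    z_n <- (profile$neo_neuroticism - co$trait_mean$neuroticism) / co$trait_sd$neuroticism
    z_e <- (profile$neo_extraversion - co$trait_mean$extraversion) / co$trait_sd$extraversion
    shift <- ef$bias_shift_tvns *
      (1 + ef$neuroticism_modulation * z_n + ef$extraversion_modulation * z_e)
    w <- min(max(w + shift, 0.05), 0.95)
    v <- v + ef$drift_shift_tvns
  }
  list(a = ef$base_a, v = v, w = w, t0 = ef$base_t0)
}

#' Simulate choices and response times from a diffusion process
#'
#' Thin wrapper around [rwiener_fp()] taking a parameter list: the upper
#' boundary codes cooperation, and the response time is the first-passage
#' time plus the non-decision time.
#'
#' @param n number of trials.
#' @param params list with `a`, `v`, `w`, `t0`.
#' @param dt Euler step (s).
#' @param bridge apply the exact-bridge crossing correction.
#' @param max_t maximum decision time (s).
#' @return data frame with `choice` and `rt`.
#' @export
simulate_choice_rt <- function(n, params, dt = 1e-3, bridge = FALSE, max_t = 20) {
  stopifnot(params$a > 0, params$w > 0, params$w < 1, params$t0 >= 0)
  rwiener_fp(n, params$a, params$v, params$w, params$t0,
             dt = dt, bridge = bridge, max_t = max_t)
}

# deterministic per-(subject, session) seed stream below 2^31
session_seed <- function(root_seed, subject_idx, session_idx) {
  (root_seed + 1000003 * subject_idx + 7919 * session_idx) %% 2147483647L
}

#' Generate a full synthetic crossover study
#'
#' Builds the complete dataset of a sham-controlled crossover study:
#' subject profiles, counterbalanced condition order (split differing by at
#' most one subject), two sessions of 8 opponents x `trials_per_opponent`
#' trials each with diffusion-generated choices and RTs, a configurable
#' fraction of trials marked invalid (undefined key / timeout), and
#' per-session likability ratings with a planted human > computer offset.
#' Each (subject, session) runs on a deterministically derived seed stream,
#' so any single session is reproducible in isolation.
#'
#' @param n_subjects number of subjects (default from config).
#' @param cfg a [study_config()] configuration.
#' @param seed root seed (integer). Required for reproducibility of the
#'   whole study.
#' @return an object of class `"pd_study"`: list with `trials`, `profiles`,
#'   `likability`, `condition_order`, `config`, `seed`.
#' @export
generate_study <- function(n_subjects = NULL, cfg = study_config(), seed = 1L) {
  n <- as.integer(n_subjects %||% cfg$cohort$n_subjects)
  if (n < 2) stop("n_subjects must be at least 2")
  set.seed(seed)
  profiles <- generate_profiles(n, cfg)
  orders <- sample(rep(c("tvns_first", "sham_first"), length.out = n))
  payoff <- config_payoff(cfg)
  opponents <- config_opponents(cfg)
  ef <- cfg$cohort$effects
  sim <- cfg$cohort$sim

  trials <- vector("list", 2L * n)
  lik <- vector("list", 2L * n)
  for (si in seq_len(n)) {
    for (sess in 1:2) {
      cond <- if (orders[si] == "tvns_first") c("tvns", "sham")[sess] else c("sham", "tvns")[sess]
      set.seed(session_seed(seed, si, sess))
      pars <- agent_params(profiles[si, ], cond, cfg)
      pars$v <- pars$v + stats::rnorm(1, 0, ef$session_v_sd)
      agent <- agent_ddm(a = pars$a, v = pars$v, w = pars$w, t0 = pars$t0,
                         human_v_bonus = ef$human_v_bonus,
                         reciprocity = ef$reciprocity,
                         dt = sim$dt, bridge = sim$bridge, max_t = sim$max_t_s)
      sched <- schedule_session(opponents, cfg$task$trials_per_opponent)
      tl <- play_session(agent, opponents, sched, payoff,
                         time_limit = cfg$task$time_limit_s,
                         opp_rt_range = c(cfg$task$opponent_rt_min_s,
                                          cfg$task$opponent_rt_max_s))
      # invalid-trial injection: undefined key presses / timeouts
      inv <- which(stats::runif(nrow(tl)) < cfg$cohort$invalid_rate)
      if (length(inv)) {
        tl$subject_choice[inv] <- NA
        tl$subject_rt_s[inv] <- NA
        tl$valid[inv] <- FALSE
        tl$points_subject[inv] <- 0
        tl$cumulative_points <- cumsum(tl$points_subject)
      }
      tl <- cbind(data.frame(subject_id = profiles$subject_id[si],
                             session_index = sess, stim_condition = cond,
                             stringsAsFactors = FALSE), tl)
      trials[[(si - 1) * 2 + sess]] <- tl
      mu <- ifelse(opponents$opponent_class == "human",
                   cfg$cohort$sam_human_mean, cfg$cohort$sam_computer_mean)
      lik[[(si - 1) * 2 + sess]] <- data.frame(
        subject_id = profiles$subject_id[si], session_index = sess,
        opponent_id = opponents$opponent_id,
        opponent_class = opponents$opponent_class,
        sam_likability = pmin(pmax(round(stats::rnorm(
          nrow(opponents), mu, cfg$cohort$sam_sd)), 1), 9),
        stringsAsFactors = FALSE)
    }
  }
  trials <- do.call(rbind, trials)
  rownames(trials) <- NULL
  trials <- trials[, .trial_cols]
  structure(list(trials = trials,
                 profiles = profiles,
                 likability = do.call(rbind, lik),
                 condition_order = data.frame(subject_id = profiles$subject_id,
                                              order = orders,
                                              stringsAsFactors = FALSE),
                 config = cfg, seed = seed),
            class = "pd_study")
}

#' @export
print.pd_study <- function(x, ...) {
  tr <- x$trials
  cat("Synthetic crossover study: ", nrow(x$profiles), " subjects, ",
      nrow(tr), " trials (seed ", x$seed, ")\n", sep = "")
  pct <- function(cond) {
    v <- tr[tr$valid & tr$stim_condition == cond, ]
    100 * mean(v$subject_choice == "cooperate")
  }
  cat(sprintf("Cooperation: tVNS %.1f%%, sham %.1f%%; invalid trials: %d\n",
              pct("tvns"), pct("sham"), sum(!tr$valid)))
  invisible(x)
}
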