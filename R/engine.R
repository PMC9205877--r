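#' Fixed-choice player agent
#'
#' @param choice `"cooperate"` or `"deceive"`.
#' @param rt response time returned on every trial (seconds).
#' @return a player agent: a function of a trial context returning
#'   `list(choice, rt)`, usable with [play_session()].
#' @export
agent_fixed <- function(choice = c("deceive", "cooperate"), rt = 1) {
  choice <- match.arg(choice)
  force(rt)
  function(ctx) list(choice = choice, rt = rt)
}

#' Bernoulli player agent
#'
#' Cooperates with a fixed probability on every trial, with a log-normal
#' response time. Used for smoke tests and Monte-Carlo cross-checks.
#'
#' @param coop_p cooperation probability.
#' @param rt_meanlog,rt_sdlog log-normal RT parameters (seconds).
#' @return a player agent function for [play_session()].
#' @export
agent_random <- function(coop_p = 0.5, rt_meanlog = 0, rt_sdlog = 0.3) {
  function(ctx) {
    list(choice = if (stats::runif(1) < coop_p) "cooperate" else "deceive",
         rt = stats::rlnorm(1, rt_meanlog, rt_sdlog))
  }
}

#' Diffusion-model player agent
#'
#' Generates each trial's choice and response time from a Wiener diffusion
#' process between a "deceive" (lower) and a "cooperate" (upper) boundary.
#' Optional terms make the drift depend on the opponent: a bonus towards
#' cooperation for human-labelled opponents and a reciprocity penalty after
#' having been deceived by this opponent in the previous encounter.
#'
#' @param a boundary separation (evidence units; diffusion coefficient 1).
#' @param v drift rate (evidence units per second).
#' @param w starting bias in (0, 1); 0.5 is unbiased.
#' @param t0 non-decision time (seconds).
#' @param human_v_bonus drift increment applied against human-labelled
#'   opponents (default 0).
#' @param reciprocity drift decrement applied when this opponent deceived the
#'   subject on their previous encounter (default 0, i.e. no conditioning on
#'   opponent behaviour).
#' @param dt Euler step of the first-passage simulation (seconds).
#' @param bridge logical; apply the exact-bridge crossing correction between
#'   Euler steps (default `FALSE`).
#' @param max_t give up after this decision time (seconds); such trials get an
#'   RT beyond any sensible time limit and are marked invalid downstream.
#' @return a player agent function for [play_session()].
#' @export
agent_ddm <- function(a = 1.6, v = -0.33, w = 0.5, t0 = 0.35,
                      human_v_bonus = 0, reciprocity = 0,
                      dt = 1e-3, bridge = FALSE, max_t = 20) {
  function(ctx) {
    v_trial <- v
    if (human_v_bonus != 0 && identical(ctx$opponent_class, "human"))
      v_trial <- v_trial + human_v_bonus
    if (reciprocity != 0 && length(ctx$opponent_history) > 0L &&
        ctx$opponent_history[length(ctx$opponent_history)] == "deceive")
      v_trial <- v_trial - reciprocity
    sim <- rwiener_fp(1L, a = a, v = v_trial, w = w, t0 = t0,
                      dt = dt, bridge = bridge, max_t = max_t)
    list(choice = sim$choice, rt = sim$rt)
  }
}

#' Play one session of the iterated prisoner's dilemma
#'
#' Runs the player agent through a session schedule against the configured
#' opponents, keeping per-opponent histories (for tit-for-tat and reciprocal
#' agents), drawing simulated opponent response times uniformly from
#' `opp_rt_range`, and accounting points by the payoff matrix. Trials whose
#' response time exceeds `time_limit` are marked invalid and score no points.
#'
#' @param agent a player agent: function of a context list with elements
#'   `trial_index`, `opponent_id`, `opponent_class`, `opponent_policy`,
#'   `subject_history`, `opponent_history` (choices in prior encounters with
#'   this opponent), returning `list(choice, rt)` with `rt > 0` in seconds.
#' @param opponents output of [build_opponents()].
#' @param schedule output of [schedule_session()].
#' @param payoff a [payoff_matrix()].
#' @param time_limit response-time limit in seconds (default 10).
#' @param opp_rt_range range of the simulated opponent response times.
#' @return a data frame, one row per trial, with the trial-log schema
#'   (choices, RTs, decision order, points, cumulative points, validity).
#' @export
play_session <- function(agent, opponents, schedule, payoff,
                         time_limit = 10, opp_rt_range = c(1, 3)) {
  stopifnot(is.function(agent), inherits(payoff, "payoff_matrix"))
  n <- nrow(schedule)
  opp <- split(opponents, opponents$opponent_id)
  sub_hist <- stats::setNames(vector("list", nrow(opponents)), opponents$opponent_id)
  opp_hist <- sub_hist
  subject_choice <- character(n); opponent_choice <- character(n)
  subject_rt <- numeric(n); opponent_rt <- numeric(n)
  points <- numeric(n); valid <- logical(n)
  for (i in seq_len(n)) {
    oid <- schedule$opponent_id[i]
    spec <- opp[[oid]]
    ctx <- list(trial_index = schedule$trial_index[i], opponent_id = oid,
                opponent_class = spec$opponent_class,
                opponent_policy = spec$opponent_policy,
                subject_history = sub_hist[[oid]],
                opponent_history = opp_hist[[oid]])
    resp <- agent(ctx)
    if (!is.numeric(resp$rt) || !is.finite(resp$rt) || resp$rt <= 0)
      stop("agent returned a non-positive response time on trial ", i)
    oc <- opponent_decide(spec, history = sub_hist[[oid]] %||% character(),
                          current_choice = resp$choice)
    subject_choice[i] <- resp$choice
    opponent_choice[i] <- oc
    subject_rt[i] <- resp$rt
    opponent_rt[i] <- stats::runif(1, opp_rt_range[1], opp_rt_range[2])
    valid[i] <- !is.na(resp$choice) && resp$rt <= time_limit
    points[i] <- if (valid[i]) payoff_points(payoff, resp$choice, oc) else 0
    sub_hist[[oid]] <- c(sub_hist[[oid]], resp$choice)
    opp_hist[[oid]] <- c(opp_hist[[oid]], oc)
  }
  out <- data.frame(
    trial_index = schedule$trial_index,
    opponent_id = schedule$opponent_id,
    decision_order = schedule$decision_order,
    stringsAsFactors = FALSE
  )
  out$opponent_class <- opponents$opponent_class[match(out$opponent_id, opponents$opponent_id)]
  out$opponent_policy <- opponents$opponent_policy[match(out$opponent_id, opponents$opponent_id)]
  out$subject_choice <- subject_choice
  out$opponent_choice <- opponent_choice
  out$subject_rt_s <- subject_rt
  out$opponent_rt_s <- opponent_rt
  out$points_subject <- points
  out$cumulative_points <- cumsum(points)
  out$valid <- valid
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Closed-form expected session points for a fixed player policy
#'
#' Computes the exact expectation of total points over one session (all
#' opponents times `trials_per_opponent` trials) for a player who follows a
#' fixed policy on every trial. Stochastic opponents contribute their
#' cooperation probability; tit-for-tat's response to a constant player is
#' fully determined once the first-move convention is fixed. Under the
#' `"mirror"` convention tit-for-tat simply plays the player's own policy,
#' which is the accounting consistent with the task's printed reference
#' totals.
#'
#' `policy = "best_constant"` scores, for each opponent, the better of the two
#' constant policies and sums the maxima — the "maximal possible points"
#' yardstick shown to participants (cooperation beats deception only against
#' tit-for-tat).
#'
#' @param policy `"cooperate"`, `"deceive"`, or `"best_constant"`.
#' @param opponents output of [build_opponents()] (its `tft_first` column
#'   fixes the tit-for-tat convention).
#' @param payoff a [payoff_matrix()].
#' @param trials_per_opponent trials per opponent (default 15).
#' @return expected total points (numeric scalar).
#' @export
expected_session_points <- function(policy = c("cooperate", "deceive", "best_constant"),
                                    opponents = build_opponents(),
                                    payoff = payoff_matrix(),
                                    trials_per_opponent = 15L) {
  policy <- match.arg(policy)
  m <- trials_per_opponent
  per_trial <- function(player, p_coop) {
    if (player == "cooperate")
      p_coop * payoff$cells[["cc"]] + (1 - p_coop) * payoff$cells[["cd"]]
    else
      p_coop * payoff$cells[["dc"]] + (1 - p_coop) * payoff$cells[["dd"]]
  }
  opp_points <- function(spec, player) {
    pol <- spec$opponent_policy
    if (pol %in% c("cooperative", "deceitful", "random"))
      return(m * per_trial(player, spec$coop_p))
    if (pol == "titfortat") {
      # expected number of opponent cooperations against a constant player
      first <- spec$tft_first
      n_coop <- if (first == "mirror") {
        if (player == "cooperate") m else 0
      } else {
        later <- if (player == "cooperate") m - 1 else 0
        later + (first == "cooperate")
      }
      p <- n_coop / m
      return(m * per_trial(player, p))
    }
    stop("unsupported opponent policy for closed-form expectation: ", pol)
  }
  total <- 0
  for (i in seq_len(nrow(opponents))) {
    spec <- opponents[i, ]
    total <- total + switch(policy,
      cooperate = opp_points(spec, "cooperate"),
      deceive = opp_points(spec, "deceive"),
      best_constant = max(opp_points(spec, "cooperate"), opp_points(spec, "deceive"))
    )
  }
  unname(total)
}
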