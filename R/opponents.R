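#' Build the eight session opponents
#'
#' Each session pits the subject against eight opponents: four presented as
#' humans and four as computers, with the same four decision policies assigned
#' to each class: a cooperative style (cooperating with probability
#' `cooperative_p`), a deceitful style (cooperating with probability
#' `deceitful_p`), tit-for-tat (replicating the subject's previous choice
#' against that opponent), and random (uniform).
#'
#' @param cooperative_p cooperation probability of the cooperative style
#'   (default 0.7).
#' @param deceitful_p cooperation probability of the deceitful style (default
#'   0.3, i.e. 70% deception).
#' @param tft_first first-move convention for tit-for-tat when the subject has
#'   no history against that opponent: `"mirror"` (copy the subject's choice
#'   in the same trial; the convention consistent with the task's published
#'   point totals), `"cooperate"`, or `"deceive"`.
#' @return a data frame with one row per opponent: `opponent_id`,
#'   `opponent_class` (`"human"`/`"computer"`), `opponent_policy`, `coop_p`,
#'   `tft_first`.
#' @export
build_opponents <- function(cooperative_p = 0.7, deceitful_p = 0.3,
                            tft_first = c("mirror", "cooperate", "deceive")) {
  tft_first <- match.arg(tft_first)
  for (p in c(cooperative = cooperative_p, deceitful = deceitful_p)) {
    if (!is.finite(p) || p < 0 || p > 1)
      stop("cooperation probability must lie in [0, 1], got ", p)
  }
  policies <- c("cooperative", "deceitful", "titfortat", "random")
  coop_p <- c(cooperative = cooperative_p, deceitful = deceitful_p,
              titfortat = NA_real_, random = 0.5)
  cls <- rep(c("human", "computer"), each = 4L)
  data.frame(
    opponent_id = paste(substr(cls, 1, 3), rep(policies, 2L), sep = "_"),
    opponent_class = cls,
    opponent_policy = rep(policies, 2L),
    coop_p = unname(coop_p[rep(policies, 2L)]),
    tft_first = tft_first,
    stringsAsFactors = FALSE
  )
}

#' One opponent decision
#'
#' @param spec a single-row slice of [build_opponents()] output (or a list
#'   with `opponent_policy`, `coop_p`, `tft_first`).
#' @param history character vector of the subject's previous choices against
#'   this opponent in this session, in trial order (may be empty).
#' @param current_choice the subject's choice in the current trial; required
#'   only by tit-for-tat under the `"mirror"` first-move convention when
#'   `history` is empty.
#' @return `"cooperate"` or `"deceive"`. Stochastic policies consume one
#'   `runif()` draw from the current RNG stream.
#' @export
opponent_decide <- function(spec, history = character(), current_choice = NULL) {
  policy <- spec$opponent_policy
  if (policy %in% c("cooperative", "deceitful", "random")) {
    p <- spec$coop_p
    return(if (stats::runif(1) < p) "cooperate" else "deceive")
  }
  if (policy == "titfortat") {
    if (length(history) > 0L) return(history[length(history)])
    first <- spec$tft_first
    if (first == "mirror") {
      if (is.null(current_choice))
        stop("tit-for-tat with tft_first='mirror' needs the subject's current choice on the first encounter")
      return(current_choice)
    }
    return(first)
  }
  stop("unknown opponent policy: ", policy)
}

#' Randomized session schedule
#'
#' Draws the trial order of a single session: every opponent appears exactly
#' `trials_per_opponent` times, trials are shuffled uniformly, and for each
#' trial the order in which the two decisions are requested is assigned
#' pseudo-randomly.
#'
#' @param opponents output of [build_opponents()].
#' @param trials_per_opponent trials per opponent (default 15, giving 120
#'   trials per session).
#' @return a data frame with `trial_index`, `opponent_id`, `decision_order`
#'   (`"subject_first"`/`"opponent_first"`).
#' @export
schedule_session <- function(opponents, trials_per_opponent = 15L) {
  stopifnot(is.data.frame(opponents), nrow(opponents) >= 1L,
            trials_per_opponent >= 1L)
  ids <- rep(opponents$opponent_id, each = trials_per_opponent)
  ids <- sample(ids)
  n <- length(ids)
  data.frame(
    trial_index = seq_len(n),
    opponent_id = ids,
    decision_order = sample(c("subject_first", "opponent_first"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}
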