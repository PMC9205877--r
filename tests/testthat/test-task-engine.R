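test_that("payoff matrix validates dominance and looks up points", {
  pm <- payoff_matrix(20, 0, 30, 5)
  expect_equal(payoff_points(pm, "cooperate", "cooperate"), 20)
  expect_equal(payoff_points(pm, "deceive", "cooperate"), 30)
  expect_equal(payoff_points(pm, c("deceive", "cooperate"), "deceive"), c(5, 0))
  expect_true(is.na(payoff_points(pm, NA, "cooperate")))
  expect_error(payoff_matrix(30, 0, 20, 5), "dominance")
  # dominance check can be waived for non-dilemma matrices
  expect_s3_class(payoff_matrix(30, 0, 20, 5, enforce_dominance = FALSE),
                  "payoff_matrix")
  expect_error(payoff_points(pm, "defect", "cooperate"), "cooperate")
})

test_that("eight opponents: same four policies in each class, probabilities checked", {
  opp <- build_opponents()
  expect_equal(nrow(opp), 8L)
  expect_equal(sum(opp$opponent_class == "human"), 4L)
  expect_equal(sum(opp$opponent_class == "computer"), 4L)
  for (cls in c("human", "computer"))
    expect_setequal(opp$opponent_policy[opp$opponent_class == cls],
                    c("cooperative", "deceitful", "titfortat", "random"))
  expect_error(build_opponents(cooperative_p = 1.2), "\\[0, 1\\]")
  expect_identical(build_opponents(), build_opponents())
})

test_that("session schedule: 120 trials, 15 per opponent, seeded permutation", {
  opp <- build_opponents()
  set.seed(1); s1 <- schedule_session(opp)
  expect_equal(nrow(s1), 120L)
  expect_true(all(table(s1$opponent_id) == 15L))
  expect_setequal(unique(s1$decision_order), c("subject_first", "opponent_first"))
  set.seed(1); s1b <- schedule_session(opp)
  expect_identical(s1, s1b)
  set.seed(2); s2 <- schedule_session(opp)
  expect_false(identical(s1$opponent_id, s2$opponent_id))
  expect_identical(sort(s1$opponent_id), sort(s2$opponent_id))
})

test_that("opponent policies behave as specified", {
  opp <- build_opponents()
  tft <- opp[opp$opponent_id == "hum_titfortat", ]
  expect_identical(opponent_decide(tft, history = c("deceive", "cooperate")),
                   "cooperate")
  expect_identical(opponent_decide(tft, history = "deceive"), "deceive")
  # first encounter: mirror copies the subject's current choice
  expect_identical(opponent_decide(tft, current_choice = "deceive"), "deceive")
  expect_error(opponent_decide(tft), "current choice")
  tft_c <- build_opponents(tft_first = "cooperate")
  tft_c <- tft_c[tft_c$opponent_policy == "titfortat", ][1, ]
  expect_identical(opponent_decide(tft_c), "cooperate")
  # stochastic policies draw at their configured rates
  set.seed(99)
  co <- opp[opp$opponent_id == "hum_cooperative", ]
  draws <- replicate(20000, opponent_decide(co))
  p <- mean(draws == "cooperate")
  expect_lt(abs(p - 0.7), 3 * sqrt(0.7 * 0.3 / 20000))
  de <- opp[opp$opponent_id == "hum_deceitful", ]
  draws <- replicate(20000, opponent_decide(de))
  expect_lt(abs(mean(draws == "cooperate") - 0.3), 3 * sqrt(0.3 * 0.7 / 20000))
})

test_that("tit-for-tat sequence is fully determined by the subject's choices", {
  opp <- build_opponents(tft_first = "cooperate")
  pm <- payoff_matrix()
  sched <- data.frame(trial_index = 1:6,
                      opponent_id = "hum_titfortat",
                      decision_order = "subject_first")
  seqs <- c("deceive", "cooperate", "cooperate", "deceive", "deceive", "cooperate")
  i <- 0
  agent <- function(ctx) { i <<- i + 1; list(choice = seqs[i], rt = 1) }
  tl <- play_session(agent, opp, sched, pm)
  expect_identical(tl$opponent_choice, c("cooperate", head(seqs, -1)))
})

test_that("play_session accounts points, samples opponent RTs, rejects bad agents", {
  opp <- build_opponents(); pm <- payoff_matrix()
  set.seed(3)
  sched <- schedule_session(opp)
  tl <- play_session(agent_random(0.5), opp, sched, pm)
  expect_equal(nrow(tl), 120L)
  expect_true(all(tl$opponent_rt_s >= 1 & tl$opponent_rt_s <= 3))
  expect_equal(sum(tl$points_subject), tl$cumulative_points[120])
  expect_equal(tl$points_subject[tl$valid],
               payoff_points(pm, tl$subject_choice[tl$valid],
                             tl$opponent_choice[tl$valid]))
  bad <- function(ctx) list(choice = "cooperate", rt = 0)
  expect_error(play_session(bad, opp, sched, pm), "non-positive")
  # timeouts are invalid and score nothing
  slow <- function(ctx) list(choice = "cooperate", rt = 11)
  tl2 <- play_session(slow, opp, sched, pm, time_limit = 10)
  expect_false(any(tl2$valid))
  expect_equal(sum(tl2$points_subject), 0)
})

test_that("closed-form session expectations reproduce the task's reference totals", {
  opp <- build_opponents()  # mirror tit-for-tat convention
  pm <- payoff_matrix()
  expect_equal(expected_session_points("deceive", opp, pm), 1725)
  expect_equal(expected_session_points("cooperate", opp, pm), 1500)
  expect_equal(expected_session_points("best_constant", opp, pm), 2175)
  expect_gt(expected_session_points("deceive", opp, pm),
            expected_session_points("cooperate", opp, pm))
  # degenerate matrix: constant payoff k in every cell gives 120k regardless
  pk <- payoff_matrix(7, 7, 7, 7, enforce_dominance = FALSE)
  expect_equal(expected_session_points("cooperate", opp, pk), 120 * 7)
  expect_equal(expected_session_points("deceive", opp, pk), 120 * 7)
  # fixed first-move conventions shift only the tit-for-tat block
  opp_c <- build_opponents(tft_first = "cooperate")
  expect_equal(expected_session_points("deceive", opp_c, pm),
               1725 + 2 * (30 - 5))  # one cooperation per tit-for-tat opponent
  opp_d <- build_opponents(tft_first = "deceive")
  expect_equal(expected_session_points("cooperate", opp_d, pm),
               1500 - 2 * 20)        # one lost mutual cooperation each
})

test_that("simulated sessions agree with the closed-form expectation", {
  opp <- build_opponents(); pm <- payoff_matrix()
  set.seed(8)
  totals <- replicate(300, {
    sched <- schedule_session(opp)
    sum(play_session(agent_fixed("deceive"), opp, sched, pm)$points_subject)
  })
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - 1725), 3 * se)
})
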