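#' Payoff matrix for the iterated prisoner's dilemma task
#'
#' Points awarded to the player for each combination of the player's and the
#' opponent's choice. The default cells are read from the shipped study
#' configuration (see [study_config()]); they satisfy the classic prisoner's
#' dilemma ordering (temptation > reward > punishment > sucker) and make
#' deception the dominant single-trial action.
#'
#' @param cooperate_cooperate points to the player when both cooperate.
#' @param cooperate_deceive points to the player when the player cooperates
#'   and the opponent deceives.
#' @param deceive_cooperate points to the player when the player deceives and
#'   the opponent cooperates.
#' @param deceive_deceive points to the player when both deceive.
#' @param enforce_dominance if `TRUE` (default), require that for each
#'   opponent choice the player's deceive payoff strictly exceeds the
#'   cooperate payoff, so that deception is the dominant single-trial action.
#' @return an object of class `"payoff_matrix"`.
#' @examples
#' pm <- payoff_matrix(20, 0, 30, 5)
#' payoff_points(pm, "deceive", "cooperate")
#' @export
payoff_matrix <- function(cooperate_cooperate = 20, cooperate_deceive = 0,
                          deceive_cooperate = 30, deceive_deceive = 5,
                          enforce_dominance = TRUE) {
  cells <- c(cc = cooperate_cooperate, cd = cooperate_deceive,
             dc = deceive_cooperate, dd = deceive_deceive)
  if (any(!is.finite(cells))) stop("all four payoff cells must be finite numbers")
  if (enforce_dominance) {
    if (!(cells["dc"] > cells["cc"]))
      stop("deception dominance violated: deceive-vs-cooperate payoff (",
           cells["dc"], ") must exceed cooperate-vs-cooperate payoff (", cells["cc"], ")")
    if (!(cells["dd"] > cells["cd"]))
      stop("deception dominance violated: deceive-vs-deceive payoff (",
           cells["dd"], ") must exceed cooperate-vs-deceive payoff (", cells["cd"], ")")
  }
  structure(list(cells = cells, enforce_dominance = enforce_dominance),
            class = "payoff_matrix")
}

#' Look up points awarded to the player
#'
#' @param pm a [payoff_matrix()].
#' @param player,opponent character vectors with values `"cooperate"` or
#'   `"deceive"` (recycled to a common length). `NA` entries yield `NA` points.
#' @return integer-valued numeric vector of points to the player.
#' @export
payoff_points <- function(pm, player, opponent) {
  stopifnot(inherits(pm, "payoff_matrix"))
  n <- max(length(player), length(opponent))
  player <- rep_len(as.character(player), n)
  opponent <- rep_len(as.character(opponent), n)
  ok <- function(x) is.na(x) | x %in% c("cooperate", "deceive")
  if (!all(ok(player)) || !all(ok(opponent)))
    stop("choices must be 'cooperate' or 'deceive' (or NA)")
  key <- paste0(substr(player, 1, 1), substr(opponent, 1, 1))
  out <- unname(pm$cells[key])
  out[is.na(player) | is.na(opponent)] <- NA_real_
  out
}

#' @export
print.payoff_matrix <- function(x, ...) {
  m <- matrix(x$cells[c("cc", "cd", "dc", "dd")], 2, 2, byrow = TRUE,
              dimnames = list(player = c("cooperate", "deceive"),
                              opponent = c("cooperate", "deceive")))
  cat("Prisoner's dilemma payoff matrix (points to the player)\n")
  print(m)
  invisible(x)
}
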