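#' Exploration rate after k actions
#'
#' Exponentially decaying epsilon-greedy schedule:
#' `eps(k) = epsilon_initial * exp(-k / epsilon_decay_actions)`, clamped to
#' `epsilon_final` once the value falls below `1e-3`. The counter `k` is the
#' number of actions taken so far by agents of the network's type.
#'
#' @param actions_taken Non-negative action count (vectorised).
#' @param config A [train_config()].
#'
#' @return Exploration rate(s) in `[0, 1]`, non-increasing in
#'   `actions_taken`.
#' @export
epsilon_at <- function(actions_taken, config) {
  stopifnot(all(actions_taken >= 0))
  e <- config$epsilon_initial * exp(-actions_taken / config$epsilon_decay_actions)
  ifelse(e < 1e-3, config$epsilon_final, e)
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon` a uniformly random action; otherwise the action
#' with the highest value (first index on ties).
#'
#' @param q_values Numeric vector of action values.
#' @param epsilon Exploration rate in `[0, 1]`.
#'
#' @return An action index in `1:length(q_values)`.
#' @export
select_action <- function(q_values, epsilon) {
  if (any(!is.finite(q_values))) {
    stop("non-finite action values passed to select_action", call. = FALSE)
  }
  stopifnot(epsilon >= 0, epsilon <= 1)
  if (epsilon > 0 && stats::runif(1) < epsilon) {
    sample.int(length(q_values), 1L)
  } else {
    which.max(q_values)
  }
}
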