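#' Segregation reward
#'
#' `SR = s - alpha * d`: the count of same-kind agents in the observation
#' window minus the intolerance-weighted count of different-kind agents. With
#' `alpha = 0` agents are indifferent to the other population; with
#' `alpha = 1` every different-kind neighbour cancels a same-kind one.
#'
#' @param s Number of same-kind agents in the window (excluding self).
#' @param d Number of different-kind agents in the window.
#' @param alpha Intolerance weight in `[0, 1]`.
#'
#' @return The scalar reward `s - alpha * d` (vectorised).
#' @export
segregation_reward <- function(s, d, alpha) {
  stopifnot(all(s >= 0), all(d >= 0), alpha >= 0, alpha <= 1)
  s - alpha * d
}

#' Total reward and its decomposition
#'
#' Evaluates all six reward components for one step outcome and returns them
#' together with their sum. Components are mutually constrained: the
#' vigilance reward and the death penalty never co-occur (an agent is either
#' alive or dead at the end of the step), and the interdependence reward is
#' only paid on a won interaction. Death outcomes (`lost_interaction_death`,
#' `natural_death`) carry `s = d = 0` and no action, so only the death
#' penalty applies to them.
#'
#' @param outcome A `step_outcome` from [apply_action()] or an equivalent list
#'   with fields `event`, `action`, `s`, `d`.
#' @param config A [reward_config()].
#'
#' @return A list of class `reward_breakdown` with components `SR`, `IR`,
#'   `VR`, `DR`, `OR`, `TR` and their exact sum `total`.
#' @export
total_reward <- function(outcome, config) {
  stopifnot(inherits(config, "reward_config"))
  dead <- outcome$event %in% c("lost_interaction_death", "natural_death")
  sr <- segregation_reward(outcome$s, outcome$d, config$alpha)
  ir <- if (identical(outcome$event, "won_interaction")) config$interdependence else 0
  vr <- if (!dead) config$vigilance else 0
  dr <- if (dead) config$death_penalty else 0
  or <- if (identical(outcome$event, "blocked_same_kind")) config$occlusion_penalty else 0
  tr <- if (identical(outcome$action, "stay")) config$stillness_penalty else 0
  structure(list(SR = sr, IR = ir, VR = vr, DR = dr, OR = or, TR = tr,
                 total = sr + ir + vr + dr + or + tr),
            class = "reward_breakdown")
}

#' @export
print.reward_breakdown <- function(x, ...) {
  cat(sprintf("<reward_breakdown> SR=%g IR=%g VR=%g DR=%g OR=%g TR=%g | total=%g\n",
              x$SR, x$IR, x$VR, x$DR, x$OR, x$TR, x$total))
  invisible(x)
}
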