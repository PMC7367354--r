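#' Simulation configuration
#'
#' Parameters of the grid world: lattice size, the agents' field of view,
#' lifespans, initial density and episode length. The observation window is a
#' square of side `2 * view_radius + 1` centred on the agent (11 x 11 with the
#' default radius of 5).
#'
#' @param grid_side Side of the square lattice, in cells.
#' @param view_radius Radius `r` of the field of view; the observation window
#'   has side `n = 2 * r + 1`.
#' @param base_lifespan Minimum number of iterations a newborn agent lives.
#' @param density_per_type Fraction of lattice cells initially occupied by
#'   *each* of the two types. Twice this value must stay below 1 so that the
#'   world keeps empty cells for movement.
#' @param n_iterations Number of iterations in one episode.
#' @param seed Optional integer seed consumed by [grid_reset()].
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(grid_side = 25, view_radius = 3, n_iterations = 500)
#' @export
sim_config <- function(grid_side = 50L, view_radius = 5L, base_lifespan = 100L,
                       density_per_type = 0.05, n_iterations = 5000L,
                       seed = NULL) {
  grid_side <- as.integer(grid_side)
  view_radius <- as.integer(view_radius)
  base_lifespan <- as.integer(base_lifespan)
  n_iterations <- as.integer(n_iterations)
  if (grid_side < 2L * view_radius + 1L) {
    stop("grid_side must be at least 2 * view_radius + 1", call. = FALSE)
  }
  if (view_radius < 1L) stop("view_radius must be >= 1", call. = FALSE)
  if (base_lifespan < 1L) stop("base_lifespan must be >= 1", call. = FALSE)
  if (!is.null(seed) && (length(seed) != 1L || is.na(seed))) seed <- NULL
  if (density_per_type < 0 || 2 * density_per_type >= 1) {
    stop("2 * density_per_type must lie in [0, 1): the world needs empty cells",
         call. = FALSE)
  }
  structure(list(grid_side = grid_side, view_radius = view_radius,
                 base_lifespan = base_lifespan,
                 density_per_type = density_per_type,
                 n_iterations = n_iterations, seed = seed),
            class = "sim_config")
}

#' Reward configuration
#'
#' The six scalar rewards an agent can collect in one step. The total reward is
#' always the plain sum `SR + IR + VR + DR + OR + TR` where
#' `SR = s - alpha * d` is the segregation reward computed from the counts of
#' same-kind (`s`) and different-kind (`d`) agents in the post-action
#' observation window.
#'
#' @param alpha Intolerance weight in `[0, 1]` applied to different-kind
#'   neighbours in the segregation reward.
#' @param interdependence Reward `IR` in `[0, 100]` granted to the winner of a
#'   cross-type interaction.
#' @param vigilance Per-step survival reward `VR`.
#' @param death_penalty Reward `DR` on any death (natural or lost interaction).
#' @param occlusion_penalty Reward `OR` for attempting to move onto a cell
#'   occupied by a same-kind agent.
#' @param stillness_penalty Reward `TR` for choosing the `stay` action.
#'
#' @return A list of class `reward_config`.
#' @export
reward_config <- function(alpha = 1, interdependence = 0, vigilance = 0.1,
                          death_penalty = -1, occlusion_penalty = -1,
                          stillness_penalty = -1) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]", call. = FALSE)
  if (interdependence < 0 || interdependence > 100) {
    stop("interdependence must lie in [0, 100]", call. = FALSE)
  }
  structure(list(alpha = alpha, interdependence = interdependence,
                 vigilance = vigilance, death_penalty = death_penalty,
                 occlusion_penalty = occlusion_penalty,
                 stillness_penalty = stillness_penalty),
            class = "reward_config")
}

#' Training configuration for the Deep Q-Networks
#'
#' Hyper-parameters of the learner: discount, Adam settings, replay buffer,
#' soft target updates and the exponentially decaying epsilon-greedy
#' exploration schedule. Defaults reproduce the full-scale training setup;
#' [scaled_experiment_spec()] provides a reduced profile for quick runs.
#'
#' @param gamma Discount factor in `(0, 1)`.
#' @param learning_rate Adam step size.
#' @param second_moment_decay Adam `beta2` (decay of the squared-gradient
#'   moving average).
#' @param batch_size Transitions per gradient step.
#' @param replay_capacity Ring-buffer capacity of the experience replay.
#' @param tau Soft target-network blending factor in `(0, 1]`.
#' @param epsilon_initial,epsilon_final,epsilon_decay_actions Exploration
#'   schedule: `eps(k) = epsilon_initial * exp(-k / epsilon_decay_actions)`
#'   over per-type action counts `k`, clamped to `epsilon_final` once it falls
#'   below `1e-3`.
#' @param total_training_steps Gradient steps per network over the whole
#'   episode; spread evenly across iterations.
#' @param n_iterations Episode length the cadence refers to.
#'
#' @return A list of class `train_config`.
#' @export
train_config <- function(gamma = 0.98, learning_rate = 0.001,
                         second_moment_decay = 0.999, batch_size = 256L,
                         replay_capacity = 1000000L, tau = 0.05,
                         epsilon_initial = 0.999, epsilon_final = 0,
                         epsilon_decay_actions = 100000,
                         total_training_steps = 60000L,
                         n_iterations = 5000L) {
  if (gamma <= 0 || gamma >= 1) stop("gamma must lie in (0, 1)", call. = FALSE)
  if (tau <= 0 || tau > 1) stop("tau must lie in (0, 1]", call. = FALSE)
  batch_size <- as.integer(batch_size)
  if (batch_size > replay_capacity) {
    stop("batch_size cannot exceed replay_capacity", call. = FALSE)
  }
  structure(list(gamma = gamma, learning_rate = learning_rate,
                 second_moment_decay = second_moment_decay,
                 batch_size = batch_size,
                 replay_capacity = as.integer(replay_capacity), tau = tau,
                 epsilon_initial = epsilon_initial,
                 epsilon_final = epsilon_final,
                 epsilon_decay_actions = epsilon_decay_actions,
                 total_training_steps = as.integer(total_training_steps),
                 n_iterations = as.integer(n_iterations)),
            class = "train_config")
}
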