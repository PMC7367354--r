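# Lattice encoding: type A = -1L, type B = +1L, empty = 0L.
# Agent positions are 0-based (row, col), row 0 at the top, "up" = row - 1.

#' Action vocabulary
#'
#' The five actions available to every agent, in canonical order. Action
#' indices used throughout the package refer to positions in this vector.
#'
#' @return Character vector `c("stay", "left", "right", "up", "down")`.
#' @export
actions <- function() c("stay", "left", "right", "up", "down")

.ACTION_DROW <- c(0L, 0L, 0L, -1L, 1L)
.ACTION_DCOL <- c(0L, -1L, 1L, 0L, 0L)

.action_index <- function(action) {
  if (is.character(action)) {
    i <- match(action, actions())
    if (is.na(i)) stop("unknown action: ", action, call. = FALSE)
    return(i)
  }
  i <- as.integer(action)
  if (i < 1L || i > 5L) stop("action index out of range", call. = FALSE)
  i
}

#' Toroidal coordinate wrap
#'
#' Moves a 0-based coordinate by `delta` on a ring of length `grid_side`;
#' agents that leave one side of the lattice re-enter on the other.
#'
#' @param coordinate 0-based coordinate (vectorised).
#' @param delta Signed displacement.
#' @param grid_side Ring length (positive).
#'
#' @return `(coordinate + delta) mod grid_side`, in `[0, grid_side)`.
#' @examples
#' wrap_coord(49, 1, 50) # 0
#' wrap_coord(0, -1, 50) # 49
#' @export
wrap_coord <- function(coordinate, delta, grid_side) {
  stopifnot(grid_side > 0)
  (coordinate + delta) %% grid_side
}

#' Number of distinct observation windows
#'
#' An observation window of radius `r` has `n = 2r + 1` cells per side; with
#' the centre pinned to the observing agent, each of the remaining `n^2 - 1`
#' cells takes one of three values, giving `3^(n^2 - 1)` distinct spatial
#' states. The count overflows doubles already at radius 3, so it is computed
#' exactly in decimal arithmetic and returned as a digit string.
#'
#' @param r Field-of-view radius, a non-negative integer.
#'
#' @return The exact count as a decimal character string.
#' @examples
#' state_space_size(0) # "1"
#' state_space_size(1) # "6561"
#' nchar(state_space_size(5)) # 58 digits: more than 10^57 states
#' @export
state_space_size <- function(r) {
  r <- as.integer(r)
  if (length(r) != 1L || is.na(r) || r < 0L) {
    stop("r must be a single non-negative integer", call. = FALSE)
  }
  e <- (2L * r + 1L)^2 - 1L
  digits <- 1L # little-endian base-10
  for (i in seq_len(e)) {
    digits <- digits * 3L
    j <- 1L
    while (j <= length(digits)) {
      if (digits[j] >= 10L) {
        carry <- digits[j] %/% 10L
        digits[j] <- digits[j] %% 10L
        if (j == length(digits)) digits <- c(digits, 0L)
        digits[j + 1L] <- digits[j + 1L] + carry
      }
      j <- j + 1L
    }
  }
  paste(rev(digits), collapse = "")
}

#' Initialise a grid world
#'
#' Places `round(density_per_type * grid_side^2)` agents of each type
#' uniformly at random on distinct cells. Initial remaining lifetimes are
#' drawn uniformly from `1:base_lifespan` to desynchronise death waves;
#' agents born later always start with the full `base_lifespan`.
#'
#' The returned object has reference semantics (it is an environment):
#' [apply_action()] and [run_iteration()] mutate it in place.
#'
#' @param config A [sim_config()]. If `config$seed` is set, the global RNG is
#'   seeded before placement, making the reset reproducible.
#'
#' @return An object of class `grid_state` with fields `lattice` (integer
#'   matrix in `{-1, 0, 1}`), per-slot agent vectors (`id`, `type`, `row`,
#'   `col`, `age`, `remaining`), a `slot_at` reverse-lookup matrix and an
#'   `iteration` counter.
#' @export
grid_reset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  side <- config$grid_side
  n_per_type <- as.integer(round(config$density_per_type * side^2))
  n <- 2L * n_per_type
  if (n > side^2) stop("requested agent count exceeds available cells",
                       call. = FALSE)
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$lattice <- matrix(0L, side, side)
  st$slot_at <- matrix(0L, side, side)
  cells <- if (n > 0L) sample.int(side^2, n) else integer()
  st$type <- rep(c(-1L, 1L), each = n_per_type)
  st$id <- seq_len(n)
  st$next_id <- n + 1L
  st$row <- (cells - 1L) %% side
  st$col <- (cells - 1L) %/% side
  st$age <- rep(0L, n)
  st$remaining <- if (n > 0L) {
    sample.int(config$base_lifespan, n, replace = TRUE)
  } else integer()
  st$iteration <- 0L
  st$lattice[cells] <- st$type
  st$slot_at[cells] <- seq_len(n)
  class(st) <- "grid_state"
  st
}

#' @export
print.grid_state <- function(x, ...) {
  cat(sprintf("<grid_state> %dx%d lattice, %d agents (%d A / %d B), iteration %d\n",
              x$config$grid_side, x$config$grid_side, length(x$id),
              sum(x$type == -1L), sum(x$type == 1L), x$iteration))
  invisible(x)
}

.slot_of <- function(state, agent_id) {
  slot <- match(agent_id, state$id)
  if (is.na(slot)) {
    stop("unknown agent id ", agent_id, " (registry corruption?)",
         call. = FALSE)
  }
  slot
}

# Fast internal observation by slot index; returns list(spatial, normalized_age).
.observe_slot <- function(state, slot) {
  r <- state$config$view_radius
  side <- state$config$grid_side
  rows <- (state$row[slot] + (-r:r)) %% side + 1L
  cols <- (state$col[slot] + (-r:r)) %% side + 1L
  spatial <- state$lattice[rows, cols, drop = FALSE] * state$type[slot]
  list(spatial = spatial,
       normalized_age = state$remaining[slot] / state$config$base_lifespan)
}

#' Observe the world from one agent's position
#'
#' Reads the `(2r+1) x (2r+1)` lattice patch centred on the agent with
#' toroidal wrapping and normalises it by the agent's own type so that
#' same-kind agents read `+1`, different-kind agents `-1` and empty cells `0`.
#' The centre cell is always `+1` (the agent itself). The attached
#' `normalized_age` is `remaining_lifetime / base_lifespan`; it is passed
#' through unclipped and can exceed 1 after lifespan extensions.
#'
#' @param state A `grid_state`.
#' @param agent_id Id of a living agent.
#'
#' @return A list with elements `spatial` (integer matrix) and
#'   `normalized_age` (scalar).
#' @export
observe <- function(state, agent_id) {
  .observe_slot(state, .slot_of(state, agent_id))
}

# Count same/different agents in the post-action window, excluding self.
.window_counts_slot <- function(state, slot) {
  obs <- .observe_slot(state, slot)
  c(s = sum(obs$spatial == 1L) - 1L, d = sum(obs$spatial == -1L))
}

# Respawn a fresh agent of `type` into slot `slot` at a random empty cell.
.respawn_slot <- function(state, slot, type) {
  empty <- which(state$lattice == 0L)
  if (length(empty) == 0L) stop("no empty cell available for respawn",
                                call. = FALSE)
  cell <- if (length(empty) == 1L) empty else empty[sample.int(length(empty), 1L)]
  side <- state$config$grid_side
  state$id[slot] <- state$next_id
  state$next_id <- state$next_id + 1L
  state$type[slot] <- type
  state$row[slot] <- (cell - 1L) %% side
  state$col[slot] <- (cell - 1L) %/% side
  state$age[slot] <- 0L
  state$remaining[slot] <- state$config$base_lifespan
  state$lattice[cell] <- type
  state$slot_at[cell] <- slot
  invisible(state)
}

.cell_index <- function(state, row, col) {
  row + col * state$config$grid_side + 1L
}

# Core action resolution by slot. Mutates `state`; returns a step_outcome.
# `counts = FALSE` skips the post-action window count (s = d = NA) for
# callers that read the post-action window themselves.
.apply_action_slot <- function(state, slot, action, counts = TRUE) {
  a <- .action_index(action)
  side <- state$config$grid_side
  agent_id <- state$id[slot]
  type <- state$type[slot]
  loser_id <- NA_integer_
  loser_slot <- NA_integer_
  if (a == 1L) {
    event <- "stayed"
  } else {
    nr <- (state$row[slot] + .ACTION_DROW[a]) %% side
    nc <- (state$col[slot] + .ACTION_DCOL[a]) %% side
    to <- .cell_index(state, nr, nc)
    occ <- state$lattice[to]
    if (occ == 0L) {
      from <- .cell_index(state, state$row[slot], state$col[slot])
      state$lattice[from] <- 0L
      state$slot_at[from] <- 0L
      state$lattice[to] <- type
      state$slot_at[to] <- slot
      state$row[slot] <- nr
      state$col[slot] <- nc
      event <- "moved"
    } else if (occ == type) {
      event <- "blocked_same_kind"
    } else {
      # Hostile interaction: the mover wins the cell and one extra iteration
      # of life; the occupant dies and is respawned elsewhere as a newborn of
      # the same type.
      loser_slot <- state$slot_at[to]
      loser_id <- state$id[loser_slot]
      from <- .cell_index(state, state$row[slot], state$col[slot])
      state$lattice[from] <- 0L
      state$slot_at[from] <- 0L
      state$lattice[to] <- type
      state$slot_at[to] <- slot
      state$row[slot] <- nr
      state$col[slot] <- nc
      state$remaining[slot] <- state$remaining[slot] + 1L
      .respawn_slot(state, loser_slot, -type)
      event <- "won_interaction"
    }
  }
  sd <- if (counts) .window_counts_slot(state, slot) else
    c(s = NA_integer_, d = NA_integer_)
  structure(list(agent_id = agent_id, action = actions()[a], event = event,
                 s = unname(sd["s"]), d = unname(sd["d"]),
                 loser_id = loser_id, loser_slot = loser_slot),
            class = "step_outcome")
}

#' Apply one agent action
#'
#' Resolves a single action on the evolving grid. Moves onto empty cells
#' succeed; moves onto same-kind cells are blocked (the agent keeps its
#' position; this is *not* the `stay` action, so the stillness penalty does
#' not apply but the occlusion penalty does); moves onto different-kind cells
#' trigger a hostile interaction in which the mover wins the cell and one
#' extra iteration of lifespan while the occupant dies and is respawned at a
#' random empty cell as a newborn of its own type, keeping per-type
#' populations constant.
#'
#' @param state A `grid_state`, mutated in place.
#' @param agent_id Id of the acting agent.
#' @param action One of `actions()` or its index in 1..5.
#'
#' @return A `step_outcome` with the event, the post-action window counts `s`
#'   (same kind, excluding self) and `d` (different kind), and the loser's id
#'   when an interaction occurred.
#' @export
apply_action <- function(state, agent_id, action) {
  .apply_action_slot(state, .slot_of(state, agent_id), action)
}

# End-of-iteration bookkeeping: age, lifetime decrement, natural deaths and
# respawns. Returns a list of death records (slot, id, type).
.end_iteration <- function(state) {
  n <- length(state$id)
  deaths <- list()
  if (n > 0L) {
    state$age <- state$age + 1L
    state$remaining <- state$remaining - 1L
    dead <- which(state$remaining <= 0L)
    for (slot in dead) {
      deaths[[length(deaths) + 1L]] <- list(slot = slot, id = state$id[slot],
                                            type = state$type[slot])
      cell <- .cell_index(state, state$row[slot], state$col[slot])
      state$lattice[cell] <- 0L
      state$slot_at[cell] <- 0L
      .respawn_slot(state, slot, state$type[slot])
    }
  }
  state$iteration <- state$iteration + 1L
  deaths
}

#' Advance the world by one iteration
#'
#' A uniformly random permutation of the agents alive at the start of the
#' iteration act once each, in sequence, on the evolving grid. Agents killed
#' mid-iteration by an interaction do not act afterwards and their respawned
#' replacements wait until the next iteration. Afterwards every survivor ages
#' by one iteration and loses one unit of remaining lifetime; agents reaching
#' zero die naturally and are respawned.
#'
#' @param state A `grid_state`, mutated in place.
#' @param policy_A,policy_B Functions mapping an observation (as returned by
#'   [observe()]) to an action; used for type A (`-1`) and type B (`+1`)
#'   agents respectively.
#'
#' @return Invisibly, a list with `steps` (one record per acting agent:
#'   `id`, `type`, `age`, `observation`, `action`, `outcome`) and
#'   `natural_deaths` (ids that died of old age at the end of the iteration).
#' @export
run_iteration <- function(state, policy_A, policy_B) {
  n <- length(state$id)
  ids_at_start <- state$id
  order <- if (n > 0L) sample.int(n) else integer()
  steps <- vector("list", n)
  kept <- 0L
  for (slot in order) {
    if (state$id[slot] != ids_at_start[slot]) next # killed and replaced
    obs <- .observe_slot(state, slot)
    policy <- if (state$type[slot] == -1L) policy_A else policy_B
    action <- policy(obs)
    age <- state$age[slot]
    outcome <- .apply_action_slot(state, slot, action)
    kept <- kept + 1L
    steps[[kept]] <- list(id = outcome$agent_id, type = state$type[slot],
                          age = age, observation = obs,
                          action = outcome$action, outcome = outcome)
  }
  deaths <- .end_iteration(state)
  invisible(list(steps = steps[seq_len(kept)],
                 natural_deaths = vapply(deaths, `[[`, integer(1), "id")))
}
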