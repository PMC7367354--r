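# The episode-level training loop. One Q-network per agent type; each agent
# action stores a transition in its type's replay buffer. Rewards that depend
# on surviving the iteration (vigilance, death) are folded into the pending
# transition before it is pushed, so a transition is finalised either when
# its agent acts again (alive, non-terminal) or when it dies (terminal, with
# the death penalty attached). This delivers the death signal to the learner
# even when an agent is eliminated before acting in the current iteration.

#' Train the two type-networks over one episode
#'
#' Runs `state$config$n_iterations` iterations of the grid world. Each agent
#' follows an epsilon-greedy policy on its type's online network (a per-type
#' global action counter drives the decay); every action produces a replay
#' transition; each network performs `total_training_steps / n_iterations`
#' gradient steps per iteration once its buffer holds at least one batch.
#' Both networks start from the same parameter draw.
#'
#' @param state A freshly [grid_reset()] `grid_state`; mutated in place.
#' @param reward_cfg A [reward_config()].
#' @param train_cfg A [train_config()].
#' @param record_from First iteration (1-based) from which per-agent records
#'   (age, window counts, action) are collected; `Inf` disables collection.
#' @param snapshot_from First iteration from which every lattice snapshot is
#'   stored.
#' @param snapshot_every_before Cadence (in iterations) of snapshots before
#'   `snapshot_from`; `0` disables them.
#' @param seg_window_sizes Window sides for the per-iteration segregation
#'   value logged during training; defaults to `c(6, 12, 25)` truncated to
#'   the grid side.
#' @param channels Channel widths of the Q-networks (see [qnet_new()]).
#' @param verbose Print a progress line every 100 iterations.
#'
#' @return A list with the trained networks (`net_A`, `net_B`, online and
#'   target), the per-iteration `log` (epsilon, mean loss, mean reward per
#'   type, segregation), `snapshots` (list of lattices named by iteration),
#'   `records` (data frame of per-agent samples) and the final `state`.
#' @export
training_loop <- function(state, reward_cfg = reward_config(),
                          train_cfg = train_config(),
                          record_from = Inf, snapshot_from = Inf,
                          snapshot_every_before = 0L,
                          seg_window_sizes = NULL, channels = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(state, "grid_state"))
  cfg <- state$config
  n_iter <- cfg$n_iterations
  n2 <- (2L * cfg$view_radius + 1L)^2
  if (is.null(seg_window_sizes)) {
    seg_window_sizes <- c(6L, 12L, 25L)
    seg_window_sizes <- seg_window_sizes[seg_window_sizes <= cfg$grid_side]
    if (length(seg_window_sizes) == 0L) seg_window_sizes <- cfg$grid_side
  }
  steps_per_iter <- as.integer(round(train_cfg$total_training_steps / n_iter))

  online_A <- qnet_new(cfg$view_radius, channels = channels)
  online_B <- online_A # same initial parameter draw
  target_A <- online_A
  target_B <- online_B
  buf_A <- replay_new(train_cfg$replay_capacity, n2)
  buf_B <- replay_new(train_cfg$replay_capacity, n2)
  k_A <- 0
  k_B <- 0

  n_slots <- length(state$id)
  pending <- vector("list", n_slots)

  # finalised transitions are collected here and block-pushed once per
  # iteration (the replay sampler is order-free)
  outbox <- list()
  n_out <- 0L
  push_pending <- function(p, terminal) {
    n_out <<- n_out + 1L
    p$terminal <- terminal
    outbox[[n_out]] <<- p
  }
  flush_outbox <- function() {
    if (n_out == 0L) return(invisible())
    tr <- outbox[seq_len(n_out)]
    types <- vapply(tr, `[[`, integer(1), "type")
    for (ty in c(-1L, 1L)) {
      sel <- tr[types == ty]
      if (length(sel) == 0L) next
      buf <- if (ty == -1L) buf_A else buf_B
      .replay_push_block(
        buf,
        obs = matrix(unlist(lapply(sel, `[[`, "obs")), length(sel), n2,
                     byrow = TRUE),
        age = vapply(sel, `[[`, numeric(1), "age"),
        action = vapply(sel, `[[`, integer(1), "action"),
        reward = vapply(sel, `[[`, numeric(1), "reward"),
        next_obs = matrix(unlist(lapply(sel, `[[`, "next_obs")), length(sel),
                          n2, byrow = TRUE),
        next_age = vapply(sel, `[[`, numeric(1), "next_age"),
        terminal = vapply(sel, `[[`, logical(1), "terminal"))
    }
    outbox <<- list()
    n_out <<- 0L
    invisible()
  }

  log_iter <- integer(n_iter)
  log_eps_A <- log_eps_B <- numeric(n_iter)
  log_loss_A <- log_loss_B <- rep(NA_real_, n_iter)
  log_rew_A <- log_rew_B <- rep(NA_real_, n_iter)
  log_seg <- numeric(n_iter)
  snapshots <- list()
  recs <- list()

  for (it in seq_len(n_iter)) {
    ids_at_start <- state$id
    order <- sample.int(n_slots)
    rew_sum <- c(`-1` = 0, `1` = 0)
    rew_n <- c(`-1` = 0L, `1` = 0L)
    collect <- it >= record_from
    if (collect) {
      r_id <- integer(n_slots); r_type <- integer(n_slots)
      r_age <- integer(n_slots); r_act <- integer(n_slots)
      r_s <- integer(n_slots); r_d <- integer(n_slots)
      r_k <- 0L
    }

    for (slot in order) {
      if (state$id[slot] != ids_at_start[slot]) next
      obs <- .observe_slot(state, slot)
      obs_flat <- as.numeric(obs$spatial)
      type <- state$type[slot]
      if (type == -1L) {
        eps <- epsilon_at(k_A, train_cfg); k_A <- k_A + 1
        net <- online_A
      } else {
        eps <- epsilon_at(k_B, train_cfg); k_B <- k_B + 1
        net <- online_B
      }
      a <- if (stats::runif(1) < eps) {
        sample.int(5L, 1L)
      } else {
        which.max(.qnet_forward1(net, obs_flat, obs$normalized_age))
      }
      age_now <- state$age[slot]
      outcome <- .apply_action_slot(state, slot, a, counts = FALSE)
      nxt <- .observe_slot(state, slot)
      s_cnt <- sum(nxt$spatial == 1L) - 1L
      d_cnt <- sum(nxt$spatial == -1L)
      outcome$s <- s_cnt
      outcome$d <- d_cnt
      base <- (s_cnt - reward_cfg$alpha * d_cnt) +
        (if (outcome$event == "won_interaction") reward_cfg$interdependence else 0) +
        (if (outcome$event == "blocked_same_kind") reward_cfg$occlusion_penalty else 0) +
        (if (a == 1L) reward_cfg$stillness_penalty else 0)
      ti <- as.character(type)
      rew_sum[ti] <- rew_sum[ti] + base
      rew_n[ti] <- rew_n[ti] + 1L

      if (!is.null(pending[[slot]])) push_pending(pending[[slot]], FALSE)
      pending[[slot]] <- list(obs = obs_flat, age = obs$normalized_age,
                              action = a, reward = base,
                              next_obs = as.numeric(nxt$spatial),
                              next_age = nxt$normalized_age,
                              type = type, vr_added = FALSE)
      if (!is.na(outcome$loser_slot)) {
        lp <- pending[[outcome$loser_slot]]
        if (!is.null(lp)) {
          lp$reward <- lp$reward + reward_cfg$death_penalty
          push_pending(lp, TRUE)
        }
        pending[outcome$loser_slot] <- list(NULL)
      }
      if (collect) {
        r_k <- r_k + 1L
        r_id[r_k] <- outcome$agent_id; r_type[r_k] <- type
        r_age[r_k] <- age_now; r_act[r_k] <- a
        r_s[r_k] <- outcome$s; r_d[r_k] <- outcome$d
      }
    }

    deaths <- .end_iteration(state)
    dead_slots <- vapply(deaths, `[[`, integer(1), "slot")
    for (slot in dead_slots) {
      p <- pending[[slot]]
      if (!is.null(p)) {
        p$reward <- p$reward + reward_cfg$death_penalty
        push_pending(p, TRUE)
      }
      pending[slot] <- list(NULL)
    }
    for (slot in seq_len(n_slots)) {
      p <- pending[[slot]]
      if (!is.null(p) && !p$vr_added) {
        p$reward <- p$reward + reward_cfg$vigilance
        p$vr_added <- TRUE
        pending[[slot]] <- p
      }
    }

    flush_outbox()

    if (steps_per_iter > 0L && replay_size(buf_A) >= train_cfg$batch_size) {
      batches <- lapply(seq_len(steps_per_iter), function(j) {
        replay_sample(buf_A, train_cfg$batch_size)
      })
      res <- .train_epoch(online_A, target_A, batches, train_cfg)
      online_A <- res$online; target_A <- res$target
      log_loss_A[it] <- mean(res$loss)
    }
    if (steps_per_iter > 0L && replay_size(buf_B) >= train_cfg$batch_size) {
      batches <- lapply(seq_len(steps_per_iter), function(j) {
        replay_sample(buf_B, train_cfg$batch_size)
      })
      res <- .train_epoch(online_B, target_B, batches, train_cfg)
      online_B <- res$online; target_B <- res$target
      log_loss_B[it] <- mean(res$loss)
    }

    log_iter[it] <- it
    log_eps_A[it] <- epsilon_at(k_A, train_cfg)
    log_eps_B[it] <- epsilon_at(k_B, train_cfg)
    log_rew_A[it] <- if (rew_n["-1"] > 0L) rew_sum["-1"] / rew_n["-1"] else NA_real_
    log_rew_B[it] <- if (rew_n["1"] > 0L) rew_sum["1"] / rew_n["1"] else NA_real_
    log_seg[it] <- multiscale_segregation(state$lattice,
                                          window_sizes = seg_window_sizes)
    if (it >= snapshot_from ||
        (snapshot_every_before > 0L && it %% snapshot_every_before == 0L)) {
      snapshots[[as.character(it)]] <- state$lattice
    }
    if (collect && r_k > 0L) {
      keep <- seq_len(r_k)
      recs[[length(recs) + 1L]] <- data.frame(
        iteration = it, id = r_id[keep], type = r_type[keep],
        age = r_age[keep], action = actions()[r_act[keep]],
        s = r_s[keep], d = r_d[keep], stringsAsFactors = FALSE)
    }
    if (verbose && it %% 100L == 0L) {
      message(sprintf("iter %d | eps %.3f | seg %.3f | rew A %.2f B %.2f",
                      it, log_eps_A[it], log_seg[it],
                      log_rew_A[it], log_rew_B[it]))
    }
  }

  records <- if (length(recs) > 0L) do.call(rbind, recs) else
    data.frame(iteration = integer(), id = integer(), type = integer(),
               age = integer(), action = character(), s = integer(),
               d = integer(), stringsAsFactors = FALSE)
  list(net_A = list(online = online_A, target = target_A),
       net_B = list(online = online_B, target = target_B),
       log = data.frame(iteration = log_iter, epsilon_A = log_eps_A,
                        epsilon_B = log_eps_B, loss_A = log_loss_A,
                        loss_B = log_loss_B, reward_A = log_rew_A,
                        reward_B = log_rew_B, segregation = log_seg),
       snapshots = snapshots, records = records, state = state)
}
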