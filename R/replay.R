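# Experience replay: a ring buffer over flat transition rows, preallocated in
# geometrically growing chunks up to `capacity`.

#' Create an experience replay buffer
#'
#' @param capacity Maximum number of stored transitions; once full, new
#'   transitions overwrite the oldest ones.
#' @param obs_dim Length of a flattened spatial observation.
#'
#' @return A `replay_buffer` (environment with reference semantics).
#' @export
replay_new <- function(capacity, obs_dim) {
  capacity <- as.integer(capacity)
  stopifnot(capacity >= 1L, obs_dim >= 1L)
  buf <- new.env(parent = emptyenv())
  buf$capacity <- capacity
  buf$obs_dim <- as.integer(obs_dim)
  buf$alloc <- 0L
  buf$size <- 0L
  buf$pos <- 0L # last written index
  class(buf) <- "replay_buffer"
  buf
}

.replay_grow <- function(buf, need) {
  new_alloc <- min(buf$capacity, max(1024L, buf$alloc * 2L, need))
  grow_mat <- function(m) {
    out <- matrix(0, new_alloc, buf$obs_dim)
    if (buf$alloc > 0L) out[seq_len(buf$alloc), ] <- m
    out
  }
  grow_vec <- function(v, proto) {
    out <- vector(typeof(proto), new_alloc)
    if (buf$alloc > 0L) out[seq_len(buf$alloc)] <- v
    out
  }
  buf$obs <- grow_mat(buf$obs)
  buf$next_obs <- grow_mat(buf$next_obs)
  buf$age <- grow_vec(buf$age, numeric(1))
  buf$next_age <- grow_vec(buf$next_age, numeric(1))
  buf$action <- grow_vec(buf$action, integer(1))
  buf$reward <- grow_vec(buf$reward, numeric(1))
  buf$terminal <- grow_vec(buf$terminal, logical(1))
  buf$alloc <- new_alloc
}

#' Store one transition
#'
#' @param buf A [replay_new()] buffer.
#' @param obs,next_obs Flattened spatial observations (numeric vectors).
#' @param age,next_age Normalised ages at the two ends of the transition.
#' @param action Action index in 1..5.
#' @param reward Scalar total reward.
#' @param terminal Whether the transition ended the agent's life (no
#'   bootstrap from `next_obs`).
#'
#' @return The buffer, invisibly.
#' @export
replay_push <- function(buf, obs, age, action, reward, next_obs, next_age,
                        terminal) {
  pos <- buf$pos %% buf$capacity + 1L
  if (pos > buf$alloc) .replay_grow(buf, pos)
  buf$obs[pos, ] <- obs
  buf$next_obs[pos, ] <- next_obs
  buf$age[pos] <- age
  buf$next_age[pos] <- next_age
  buf$action[pos] <- as.integer(action)
  buf$reward[pos] <- reward
  buf$terminal[pos] <- terminal
  buf$pos <- pos
  buf$size <- min(buf$size + 1L, buf$capacity)
  invisible(buf)
}

# Push a block of transitions at once (rows of `obs`/`next_obs`), wrapping
# around the ring boundary as needed.
.replay_push_block <- function(buf, obs, age, action, reward, next_obs,
                               next_age, terminal) {
  m <- nrow(obs)
  if (m == 0L) return(invisible(buf))
  pos <- (buf$pos + seq_len(m) - 1L) %% buf$capacity + 1L
  need <- max(pos)
  if (need > buf$alloc) .replay_grow(buf, min(buf$capacity, buf$pos + m))
  # in-place writes: the storage is owned by the buffer, and going through
  # the compiled writer avoids copy-on-write of the whole allocation
  .cpp_write_rows(buf$obs, pos, as.matrix(obs))
  .cpp_write_rows(buf$next_obs, pos, as.matrix(next_obs))
  .cpp_write_num(buf$age, pos, as.numeric(age))
  .cpp_write_num(buf$next_age, pos, as.numeric(next_age))
  .cpp_write_int(buf$action, pos, as.integer(action))
  .cpp_write_num(buf$reward, pos, as.numeric(reward))
  .cpp_write_lgl(buf$terminal, pos, as.logical(terminal))
  buf$pos <- pos[m]
  buf$size <- min(buf$size + m, buf$capacity)
  invisible(buf)
}

#' Number of stored transitions
#' @param buf A replay buffer.
#' @return Integer count, at most the buffer capacity.
#' @export
replay_size <- function(buf) buf$size

#' Sample a training batch
#'
#' Uniform sampling with replacement from the stored transitions.
#'
#' @param buf A replay buffer.
#' @param batch_size Number of transitions to draw.
#'
#' @return A list with matrix `obs`/`next_obs` and vectors `age`, `next_age`,
#'   `action`, `reward`, `terminal`.
#' @export
replay_sample <- function(buf, batch_size) {
  if (buf$size < batch_size) {
    stop("replay buffer holds fewer transitions than the requested batch",
         call. = FALSE)
  }
  idx <- sample.int(buf$size, batch_size, replace = TRUE)
  list(obs = buf$obs[idx, , drop = FALSE],
       next_obs = buf$next_obs[idx, , drop = FALSE],
       age = buf$age[idx], next_age = buf$next_age[idx],
       action = buf$action[idx], reward = buf$reward[idx],
       terminal = buf$terminal[idx])
}
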