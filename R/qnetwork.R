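# A small convolutional Q-network written directly on top of R's BLAS.
# Layout: `r` valid 3x3 convolutions with rectifier nonlinearities shrink the
# (2r+1) x (2r+1) observation window to a single spatial cell; the resulting
# channel vector is concatenated with the agent's normalised remaining
# lifetime and mapped by one fully connected layer to the 5 action values.
# Activations for a batch of B samples are stored as an (S*B) x C matrix with
# sample-major rows (S spatial cells in column-major order), which lets every
# convolution run as one im2col row gather plus one matrix product. Weight
# rows are laid out channel-major -- row (c-1)*9 + k holds the kernel entry
# for input channel c at patch offset k -- so that the gathered (9*P*B) x C
# block reshapes into the patch matrix without any interleaving work.

.default_channels <- function(r) {
  base <- c(16L, 32L, 32L, 64L, 64L)
  if (r <= 5L) base[seq_len(r)] else c(base, rep(64L, r - 5L))
}

# Precompute, per layer, the within-sample input indices of each 3x3 patch.
.conv_maps <- function(n, n_layers) {
  maps <- vector("list", n_layers)
  H <- n
  for (l in seq_len(n_layers)) {
    Ho <- H - 2L
    P <- Ho * Ho
    oi <- rep(seq_len(Ho), times = Ho)
    oj <- rep(seq_len(Ho), each = Ho)
    nbr <- matrix(0L, P, 9L)
    k <- 0L
    for (dj in 0:2) {
      for (di in 0:2) {
        k <- k + 1L
        nbr[, k] <- (oi + di) + (oj + dj - 1L) * H
      }
    }
    maps[[l]] <- list(H = H, Ho = Ho, P = P, S = H * H, nbr = nbr,
                      idx_cache = new.env(parent = emptyenv()))
    H <- Ho
  }
  maps
}

# Batch-size-dependent gather indices, memoised per layer. The cache lives in
# an environment so functional copies of the network share it.
.layer_idx <- function(mp, B) {
  key <- as.character(B)
  hit <- mp$idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  bb <- rep((seq_len(B) - 1L) * mp$S, each = mp$P)
  rows <- as.vector(mp$nbr[rep(seq_len(mp$P), times = B), , drop = FALSE]) +
    rep(bb, times = 9L)
  out <- list(bb = bb, rows = rows)
  mp$idx_cache[[key]] <- out
  out
}

#' Create a Q-network
#'
#' Initialises a convolutional Q-network for observation windows of radius
#' `view_radius`. Weights are drawn from the current RNG stream (He-scaled
#' normals), so two networks meant to start from the same parameter draw
#' should be created once and copied.
#'
#' @param view_radius Field-of-view radius `r`; the input window has side
#'   `2r + 1` and the body uses `r` valid 3x3 convolution steps.
#' @param channels Integer vector of channel widths, one per convolution
#'   step (length `r`). Defaults to `16, 32, 32, 64, 64` truncated or
#'   extended to `r` layers.
#' @param n_actions Output dimension (one value per action).
#'
#' @return An object of class `qnet`.
#' @export
qnet_new <- function(view_radius, channels = NULL, n_actions = 5L) {
  r <- as.integer(view_radius)
  stopifnot(r >= 1L)
  n <- 2L * r + 1L
  if (is.null(channels)) channels <- .default_channels(r)
  channels <- as.integer(channels)
  stopifnot(length(channels) == r, all(channels >= 1L))
  layers <- vector("list", r)
  cin <- 1L
  for (l in seq_len(r)) {
    cout <- channels[l]
    fan_in <- 9L * cin
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout),
      b = numeric(cout))
    cin <- cout
  }
  fc <- list(
    W = matrix(stats::rnorm((cin + 1L) * n_actions, sd = sqrt(1 / (cin + 1))),
               cin + 1L, n_actions),
    b = numeric(n_actions))
  structure(list(n = n, r = r, channels = channels,
                 n_actions = as.integer(n_actions),
                 maps = .conv_maps(n, r), layers = layers, fc = fc,
                 opt = NULL),
            class = "qnet")
}

#' @export
print.qnet <- function(x, ...) {
  cat(sprintf("<qnet> %dx%d input, %d conv steps (%s channels) + age -> %d actions\n",
              x$n, x$n, x$r, paste(x$channels, collapse = ","), x$n_actions))
  invisible(x)
}

# Coerce an observation (or list of them) to flat-matrix form.
.obs_matrix <- function(obs) {
  if (is.list(obs) && !is.null(obs$spatial)) {
    return(list(X = matrix(as.numeric(obs$spatial), nrow = 1L),
                age = obs$normalized_age))
  }
  NULL
}

#' Forward pass of a Q-network
#'
#' @param net A [qnet_new()] network.
#' @param obs Either a single observation (list with `spatial` and
#'   `normalized_age`) or a `B x n^2` matrix of flattened (column-major)
#'   spatial windows.
#' @param age Vector of normalised ages, one per row of `obs`; ignored when a
#'   single observation is given.
#' @param cache Keep intermediate activations for the backward pass.
#'
#' @return If `cache = FALSE`, a `B x n_actions` matrix of action values;
#'   otherwise a list with elements `Q` and `cache`.
#' @export
qnet_forward <- function(net, obs, age = NULL, cache = FALSE) {
  single <- .obs_matrix(obs)
  if (!is.null(single)) {
    obs <- single$X
    age <- single$age
  }
  stopifnot(is.matrix(obs), ncol(obs) == net$n^2, length(age) == nrow(obs))
  B <- nrow(obs)
  A <- matrix(as.numeric(t(obs)), ncol = 1L)
  caches <- if (cache) vector("list", net$r)
  for (l in seq_len(net$r)) {
    mp <- net$maps[[l]]
    ly <- net$layers[[l]]
    idx <- .layer_idx(mp, B)
    Pm <- A[idx$rows, , drop = FALSE]
    dim(Pm) <- c(mp$P * B, 9L * ncol(A))
    Z <- Pm %*% ly$W
    Z <- Z + rep(ly$b, each = nrow(Z))
    if (cache) caches[[l]] <- list(Pm = Pm, mask = Z > 0)
    Z[Z < 0] <- 0
    A <- Z
  }
  # final spatial extent is 1x1, so A is already B x C_last, sample-major
  Ffeat <- cbind(A, as.numeric(age))
  Q <- Ffeat %*% net$fc$W + rep(net$fc$b, each = B)
  if (!cache) return(Q)
  list(Q = Q, cache = list(layers = caches, F = Ffeat, B = B))
}

# Lean forward pass for a single flattened observation (numeric vector).
# Same computation as qnet_forward with B = 1, minus the per-call packaging.
.qnet_forward1 <- function(net, obs_vec, age) {
  A <- obs_vec
  for (l in seq_len(net$r)) {
    mp <- net$maps[[l]]
    ly <- net$layers[[l]]
    if (l == 1L) {
      Pm <- A[mp$nbr]
      dim(Pm) <- c(mp$P, 9L)
    } else {
      Pm <- A[.layer_idx(mp, 1L)$rows, , drop = FALSE]
      dim(Pm) <- c(mp$P, 9L * ncol(A))
    }
    Z <- Pm %*% ly$W
    Z <- Z + rep(ly$b, each = mp$P)
    Z[Z < 0] <- 0
    A <- Z
  }
  C <- length(A)
  drop(A %*% net$fc$W[seq_len(C), , drop = FALSE]) +
    age * net$fc$W[C + 1L, ] + net$fc$b
}

# Backpropagate dQ (B x n_actions) through the cached forward pass.
# Returns gradients with the same shapes as the parameters.
qnet_backward <- function(net, cache, dQ) {
  grads <- list(layers = vector("list", net$r),
                fc = list(W = crossprod(cache$F, dQ), b = colSums(dQ)))
  dF <- dQ %*% t(net$fc$W)
  dA <- dF[, -ncol(dF), drop = FALSE]
  for (l in rev(seq_len(net$r))) {
    mp <- net$maps[[l]]
    ch <- cache$layers[[l]]
    cin <- if (l == 1L) 1L else net$channels[l - 1L]
    dZ <- dA * ch$mask
    grads$layers[[l]] <- list(W = crossprod(ch$Pm, dZ), b = colSums(dZ))
    if (l > 1L) {
      dPm <- dZ %*% t(net$layers[[l]]$W)
      bb <- .layer_idx(mp, cache$B)$bb
      dAprev <- matrix(0, mp$S * cache$B, cin)
      for (k in 1:9) {
        idx <- bb + mp$nbr[, k]
        dAprev[idx, ] <- dAprev[idx, ] +
          dPm[, seq.int(k, 9L * cin, by = 9L), drop = FALSE]
      }
      dA <- dAprev
    }
  }
  grads
}

.zeros_like_params <- function(net) {
  list(layers = lapply(net$layers, function(l) {
    list(W = matrix(0, nrow(l$W), ncol(l$W)), b = numeric(length(l$b)))
  }),
  fc = list(W = matrix(0, nrow(net$fc$W), ncol(net$fc$W)),
            b = numeric(length(net$fc$b))))
}

# One Adam step over all parameters; optimiser state lives in net$opt.
qnet_adam_step <- function(net, grads, lr, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8) {
  if (is.null(net$opt)) {
    net$opt <- list(t = 0L, m = .zeros_like_params(net),
                    v = .zeros_like_params(net))
  }
  net$opt$t <- net$opt$t + 1L
  bc1 <- 1 - beta1^net$opt$t
  bc2 <- 1 - beta2^net$opt$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  for (l in seq_len(net$r)) {
    for (nm in c("W", "b")) {
      u <- upd(net$layers[[l]][[nm]], grads$layers[[l]][[nm]],
               net$opt$m$layers[[l]][[nm]], net$opt$v$layers[[l]][[nm]])
      net$layers[[l]][[nm]] <- u$p
      net$opt$m$layers[[l]][[nm]] <- u$m
      net$opt$v$layers[[l]][[nm]] <- u$v
    }
  }
  for (nm in c("W", "b")) {
    u <- upd(net$fc[[nm]], grads$fc[[nm]], net$opt$m$fc[[nm]],
             net$opt$v$fc[[nm]])
    net$fc[[nm]] <- u$p
    net$opt$m$fc[[nm]] <- u$m
    net$opt$v$fc[[nm]] <- u$v
  }
  net
}

#' Soft target-network update
#'
#' Blends every online parameter into the target network:
#' `target <- tau * online + (1 - tau) * target`. With `tau = 1` this is a
#' hard copy; with small `tau` the target trails the online network
#' geometrically, stabilising the bootstrap.
#'
#' @param online,target Two [qnet_new()] networks of identical architecture.
#' @param tau Blending factor in `(0, 1]`.
#'
#' @return The updated target network.
#' @export
soft_update <- function(online, target, tau) {
  stopifnot(tau > 0, tau <= 1)
  if (!identical(online$channels, target$channels) || online$n != target$n) {
    stop("architecture mismatch between online and target networks",
         call. = FALSE)
  }
  for (l in seq_len(online$r)) {
    target$layers[[l]]$W <- tau * online$layers[[l]]$W +
      (1 - tau) * target$layers[[l]]$W
    target$layers[[l]]$b <- tau * online$layers[[l]]$b +
      (1 - tau) * target$layers[[l]]$b
  }
  target$fc$W <- tau * online$fc$W + (1 - tau) * target$fc$W
  target$fc$b <- tau * online$fc$b + (1 - tau) * target$fc$b
  target
}

#' Double Q-learning bootstrap targets
#'
#' For each transition, `y = reward` if the transition is terminal; otherwise
#' `y = reward + gamma * Q_target(next_obs, argmax_a Q_online(next_obs, a))`:
#' the next action is *selected* by the online network but *evaluated* by the
#' target network, which curbs value overestimation.
#'
#' @param batch A transition batch as returned by [replay_sample()].
#' @param online,target The online and target networks.
#' @param gamma Discount factor.
#'
#' @return Numeric vector of targets, one per transition.
#' @export
double_q_target <- function(batch, online, target, gamma) {
  B <- nrow(batch$obs)
  qn <- qnet_forward(online, batch$next_obs, batch$next_age)
  qt <- qnet_forward(target, batch$next_obs, batch$next_age)
  a_star <- max.col(qn, ties.method = "first")
  boot <- qt[cbind(seq_len(B), a_star)]
  batch$reward + gamma * boot * as.numeric(!batch$terminal)
}

.huber <- function(err) ifelse(abs(err) <= 1, 0.5 * err^2, abs(err) - 0.5)
.dhuber <- function(err) pmax(pmin(err, 1), -1)

#' One gradient step on a transition batch
#'
#' Minimises the Huber loss between `Q_online(obs, action)` and the double
#' Q-learning target, applies one Adam update to the online network, then
#' soft-updates the target network.
#'
#' @param online,target The online and target networks.
#' @param batch A batch from [replay_sample()].
#' @param config A [train_config()].
#'
#' @return A list with the updated `online` and `target` networks and the
#'   pre-step mean Huber `loss`.
#' @export
train_step <- function(online, target, batch, config) {
  if (is.null(online$opt)) {
    online$opt <- list(t = 0L, m = .zeros_like_params(online),
                       v = .zeros_like_params(online))
  }
  out <- .train_epoch(online, target, list(batch), config)
  out$loss <- out$loss[1L]
  out
}

# Run several gradient steps in one compiled call (one parameter round-trip);
# `batches` is a list of replay_sample() batches. Returns the updated
# networks and the per-step loss vector.
.train_epoch <- function(online, target, batches, config) {
  if (is.null(online$opt)) {
    online$opt <- list(t = 0L, m = .zeros_like_params(online),
                       v = .zeros_like_params(online))
  }
  geom <- list(H = vapply(online$maps, `[[`, integer(1), "H"))
  out <- .cpp_train_epoch(online, target, batches, geom, config$gamma,
                          config$learning_rate, config$second_moment_decay,
                          config$tau)
  out$online <- structure(out$online, class = "qnet")
  out$target <- structure(out$target, class = "qnet")
  out
}

# Pure-R reference implementation of train_step; kept as the independent
# check of the compiled path.
.r_train_step <- function(online, target, batch, config) {
  B <- nrow(batch$obs)
  y <- double_q_target(batch, online, target, config$gamma)
  fw <- qnet_forward(online, batch$obs, batch$age, cache = TRUE)
  idx <- cbind(seq_len(B), batch$action)
  err <- fw$Q[idx] - y
  loss <- mean(.huber(err))
  if (!is.finite(loss)) {
    stop(sprintf("non-finite training loss (max |err| = %g); aborting",
                 max(abs(err))), call. = FALSE)
  }
  dQ <- matrix(0, B, online$n_actions)
  dQ[idx] <- .dhuber(err) / B
  grads <- qnet_backward(online, fw$cache, dQ)
  online <- qnet_adam_step(online, grads, lr = config$learning_rate,
                           beta2 = config$second_moment_decay)
  target <- soft_update(online, target, config$tau)
  list(online = online, target = target, loss = loss)
}

#' Greedy policy from a trained network
#'
#' @param net A trained [qnet_new()] network.
#' @param epsilon Optional exploration rate; with probability `epsilon` a
#'   uniformly random action is taken instead of the greedy one.
#'
#' @return A function mapping an observation to an action index in 1..5.
#' @export
qnet_policy <- function(net, epsilon = 0) {
  force(net)
  force(epsilon)
  function(obs) {
    if (epsilon > 0 && stats::runif(1) < epsilon) {
      return(sample.int(net$n_actions, 1L))
    }
    which.max(.qnet_forward1(net, as.numeric(obs$spatial), obs$normalized_age))
  }
}
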