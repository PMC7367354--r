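# Deterministic toy lattices and scripted (non-learning) policies. They make
# every statistic in the package testable without any training run.

#' Half-and-half segregated lattice
#'
#' Populates the left half of the lattice with type A and the right half with
#' type B, each cell occupied independently at the given density. The extreme
#' segregated fixture for the entropy metric.
#'
#' @param side Even lattice side.
#' @param density Occupation probability per cell within each half, in
#'   `(0, 1]`.
#' @param seed Optional seed for the cell draw.
#'
#' @return Integer lattice matrix in `{-1, 0, 1}`.
#' @export
make_split_lattice <- function(side, density = 1, seed = NULL) {
  side <- as.integer(side)
  if (side %% 2L != 0L) stop("side must be even", call. = FALSE)
  if (density <= 0 || density > 1) stop("density must lie in (0, 1]",
                                        call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  half_cells <- side * (side %/% 2L)
  n_per_half <- as.integer(round(density * half_cells))
  lat <- matrix(0L, side, side)
  # column-major: indices 1..half_cells are exactly the left-half columns
  lat[sample.int(half_cells, n_per_half)] <- -1L
  lat[half_cells + sample.int(half_cells, n_per_half)] <- 1L
  lat
}

#' Checkerboard lattice
#'
#' Alternating A/B agents on every cell: the extreme mixed fixture, with the
#' two types exactly balanced in every even-sized window.
#'
#' @param side Even lattice side.
#'
#' @return Integer lattice matrix with values `-1` and `1` only.
#' @export
make_checkerboard <- function(side) {
  side <- as.integer(side)
  if (side %% 2L != 0L) stop("side must be even", call. = FALSE)
  outer(seq_len(side), seq_len(side),
        function(i, j) as.integer(((i + j) %% 2L) * 2L - 1L))
}

#' Scripted policies
#'
#' Non-learning policies for testing and baselines:
#' \describe{
#'   \item{always_stay}{always returns `stay`.}
#'   \item{uniform_random}{a seeded uniform draw over the five actions.}
#'   \item{approach_nearest_foe}{the action minimising the Chebyshev distance
#'     from the agent's post-move position to the nearest different-kind cell
#'     in the window (`stay` when no foe is visible).}
#'   \item{flee_foes}{the action maximising that nearest-foe distance.}
#' }
#'
#' @param rule One of `"always_stay"`, `"uniform_random"`,
#'   `"approach_nearest_foe"`, `"flee_foes"`.
#' @param seed Optional seed for the random policy's private stream.
#'
#' @return An object of class `scripted_policy`; call it through
#'   [scripted_policy_action()] or directly as a function of an observation.
#' @export
scripted_policy <- function(rule = c("always_stay", "uniform_random",
                                     "approach_nearest_foe", "flee_foes"),
                            seed = NULL) {
  rule <- match.arg(rule)
  rng <- NULL
  if (rule == "uniform_random") {
    rng <- new.env(parent = emptyenv())
    rng$state <- if (is.null(seed)) sample.int(.Machine$integer.max, 1L) else
      as.integer(seed)
  }
  f <- function(observation) {
    switch(rule,
      always_stay = 1L,
      uniform_random = {
        # private deterministic stream, independent of the global RNG
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
          rm(".Random.seed", envir = globalenv()))
        set.seed(rng$state)
        a <- sample.int(5L, 1L)
        rng$state <- (rng$state * 69069 + 1) %% .Machine$integer.max
        a
      },
      approach_nearest_foe = .chase_action(observation, toward = TRUE),
      flee_foes = .chase_action(observation, toward = FALSE))
  }
  structure(f, class = c("scripted_policy", "function"), rule = rule)
}

# Pick the action optimising Chebyshev distance to the nearest foe cell.
.chase_action <- function(observation, toward = TRUE) {
  sp <- observation$spatial
  n <- nrow(sp)
  c0 <- (n + 1L) %/% 2L
  foes <- which(sp == -1L, arr.ind = TRUE)
  if (nrow(foes) == 0L) return(1L)
  di <- .ACTION_DROW
  dj <- .ACTION_DCOL
  score <- vapply(seq_along(di), function(a) {
    min(pmax(abs(foes[, 1L] - c0 - di[a]), abs(foes[, 2L] - c0 - dj[a])))
  }, numeric(1))
  if (toward) which.min(score) else which.max(score)
}

#' Apply a scripted policy to an observation
#'
#' @param policy A [scripted_policy()].
#' @param observation An observation as returned by [observe()].
#'
#' @return An action index in 1..5 (see [actions()]).
#' @export
scripted_policy_action <- function(policy, observation) {
  stopifnot(inherits(policy, "scripted_policy"))
  policy(observation)
}
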