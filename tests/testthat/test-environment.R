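test_that("toroidal wrap behaves as modular arithmetic", {
  expect_equal(wrap_coord(49, 1, 50), 0)
  expect_equal(wrap_coord(0, -1, 50), 49)
  expect_equal(wrap_coord(17, 0, 50), 17)
  # inverse property over many random cases
  set.seed(1)
  x <- sample(0:49, 200, replace = TRUE)
  d <- sample(-120:120, 200, replace = TRUE)
  expect_true(all(wrap_coord(wrap_coord(x, d, 50), -d, 50) == x))
  expect_true(all(wrap_coord(x, d, 50) >= 0 & wrap_coord(x, d, 50) < 50))
})

test_that("state-space count is exact and matches the analytic form", {
  expect_identical(state_space_size(0), "1")
  expect_identical(state_space_size(1), "6561") # 3^8
  # 3^24 for r = 2, checkable in doubles
  expect_identical(state_space_size(2), format(3^24, scientific = FALSE))
  # digit count agrees with floor(e * log10(3)) + 1 for several radii
  for (r in c(3, 4, 5, 7)) {
    e <- (2 * r + 1)^2 - 1
    expect_equal(nchar(state_space_size(r)), floor(e * log10(3)) + 1)
  }
  expect_error(state_space_size(-1))
})

test_that("reset places the configured number of agents consistently", {
  cfg <- sim_config(grid_side = 50, view_radius = 5, density_per_type = 0.05,
                    seed = 42)
  st <- grid_reset(cfg)
  expect_equal(sum(st$type == -1L), 125)
  expect_equal(sum(st$type == 1L), 125)
  expect_equal(sum(st$lattice != 0L), 250)
  # lattice/registry bijection
  expect_true(all(st$lattice[cbind(st$row + 1L, st$col + 1L)] == st$type))
  expect_true(all(st$slot_at[cbind(st$row + 1L, st$col + 1L)] == seq_along(st$id)))
  # initial lifetimes within [1, base_lifespan]
  expect_true(all(st$remaining >= 1L & st$remaining <= cfg$base_lifespan))

  # determinism
  st2 <- grid_reset(cfg)
  expect_identical(st$lattice, st2$lattice)
  expect_identical(st$remaining, st2$remaining)

  # degenerate density
  st0 <- grid_reset(sim_config(grid_side = 20, view_radius = 3,
                               density_per_type = 0))
  expect_equal(length(st0$id), 0)
  expect_true(all(st0$lattice == 0L))

  expect_error(sim_config(grid_side = 20, view_radius = 3,
                          density_per_type = 0.6))
  expect_error(sim_config(grid_side = 5, view_radius = 5))
})

test_that("observation is type-normalised and toroidally wrapped", {
  # lone agent: all zeros except +1 at centre
  st <- make_manual_state(20, 5, cbind(10, 10), -1L)
  obs <- observe(st, 1L)
  expect_equal(dim(obs$spatial), c(11, 11))
  expect_equal(obs$spatial[6, 6], 1)
  expect_equal(sum(obs$spatial != 0), 1)
  expect_equal(obs$normalized_age, 1)

  # a foe reads -1 regardless of which type observes
  st_ab <- make_manual_state(20, 5, rbind(c(10, 10), c(10, 11)), c(-1L, 1L))
  expect_equal(observe(st_ab, 1L)$spatial[6, 7], -1)
  expect_equal(observe(st_ab, 2L)$spatial[6, 5], -1)

  # antisymmetry: same patch seen by opposite types is negated
  set.seed(3)
  st_r <- make_manual_state(20, 3, rbind(c(5, 5), c(5, 5 + 7), c(6, 6), c(4, 4)),
                            c(-1L, 1L, 1L, -1L))
  oa <- observe(st_r, 1L)$spatial
  # re-type the observing agent in place and re-observe the same patch;
  # surroundings negate while both observers read themselves as +1
  st_r$type[1] <- 1L
  st_r$lattice[5 + 1, 5 + 1] <- 1L
  ob <- observe(st_r, 1L)$spatial
  c0 <- 4L
  expect_equal(oa[c0, c0], 1)
  expect_equal(ob[c0, c0], 1)
  oa[c0, c0] <- 0
  ob[c0, c0] <- 0
  expect_equal(oa, -ob)

  # corner agent sees across the boundary: brute-force wrapped enumeration
  st_c <- make_manual_state(50, 5, rbind(c(0, 0), c(49, 49), c(47, 2)),
                            c(-1L, -1L, 1L))
  obs_c <- observe(st_c, 1L)$spatial
  expected <- matrix(0, 11, 11)
  for (i in -5:5) for (j in -5:5) {
    v <- st_c$lattice[(0 + i) %% 50 + 1, (0 + j) %% 50 + 1]
    expected[i + 6, j + 6] <- v * -1L
  }
  expect_equal(obs_c, expected)

  expect_error(observe(st, 999L), "unknown agent")
})

test_that("actions move, block and resolve interactions correctly", {
  # move to empty cell, with wrapping
  st <- make_manual_state(10, 2, cbind(0, 0), -1L)
  out <- apply_action(st, 1L, "up")
  expect_equal(out$event, "moved")
  expect_equal(st$row[1], 9)
  expect_equal(st$lattice[10, 1], -1L)
  expect_equal(st$lattice[1, 1], 0L)

  # stay
  out <- apply_action(st, 1L, "stay")
  expect_equal(out$event, "stayed")
  expect_equal(out$s, 0)
  expect_equal(out$d, 0)

  # blocked by same kind: position unchanged, not a stay
  st2 <- make_manual_state(10, 2, rbind(c(5, 5), c(5, 6)), c(-1L, -1L))
  out2 <- apply_action(st2, 1L, "right")
  expect_equal(out2$event, "blocked_same_kind")
  expect_equal(st2$col[1], 5)
  expect_equal(out2$s, 1)

  # interaction: mover wins cell and +1 lifespan, loser respawns same type
  set.seed(9)
  st3 <- make_manual_state(10, 2, rbind(c(5, 5), c(5, 6)), c(-1L, 1L),
                           remaining = c(50L, 50L))
  out3 <- apply_action(st3, 1L, "right")
  expect_equal(out3$event, "won_interaction")
  expect_equal(out3$loser_id, 2L)
  expect_equal(st3$col[1], 6)
  expect_equal(st3$remaining[1], 51L)
  # populations conserved, loser slot holds a fresh agent of the same type
  expect_equal(sum(st3$type == -1L), 1)
  expect_equal(sum(st3$type == 1L), 1)
  expect_equal(st3$age[2], 0L)
  expect_equal(st3$remaining[2], 100L)
  expect_gt(st3$id[2], 2L)
  expect_equal(sum(st3$lattice != 0), 2)
})

test_that("a full iteration preserves populations and ages agents", {
  cfg <- sim_config(grid_side = 20, view_radius = 3, density_per_type = 0.1,
                    n_iterations = 50, seed = 5)
  st <- grid_reset(cfg)
  ages0 <- st$age
  stay <- scripted_policy("always_stay")
  res <- run_iteration(st, stay, stay)
  expect_equal(length(res$steps), 80)
  expect_true(all(st$age == ages0 + 1L | st$age == 0L)) # 0 for respawns
  expect_equal(st$iteration, 1L)

  # conservation + bijection over many random iterations
  rnd <- scripted_policy("uniform_random", seed = 7)
  for (i in 1:30) run_iteration(st, rnd, rnd)
  expect_equal(sum(st$type == -1L), 40)
  expect_equal(sum(st$type == 1L), 40)
  expect_equal(sum(st$lattice != 0L), 80)
  expect_true(all(st$lattice[cbind(st$row + 1L, st$col + 1L)] == st$type))
  occupied <- which(st$slot_at != 0L)
  expect_equal(sort(st$slot_at[occupied]), seq_along(st$id))

  # s + d equals occupied non-centre cells of the window (brute force)
  for (slot in sample(seq_along(st$id), 10)) {
    out <- apply_action(st, st$id[slot], "stay")
    obs <- observe(st, st$id[slot])
    expect_equal(out$s + out$d, sum(obs$spatial != 0) - 1L)
  }
})

test_that("mid-iteration victims do not act and collisions resolve one at a time", {
  # two adjacent foes, both scripted to move onto each other: whoever acts
  # first wins; exactly one interaction resolves
  for (seed in 1:6) {
    set.seed(seed)
    st <- make_manual_state(12, 2, rbind(c(5, 5), c(5, 6)), c(-1L, 1L))
    chaser_A <- function(obs) 3L # right (B is to the right of A)
    chaser_B <- function(obs) 2L # left
    res <- run_iteration(st, chaser_A, chaser_B)
    acted <- vapply(res$steps, `[[`, integer(1), "id")
    events <- vapply(res$steps, function(s) s$outcome$event, character(1))
    expect_equal(length(acted), 1L) # only the first mover acts
    expect_equal(events, "won_interaction")
    expect_equal(sum(st$type == -1L), 1)
    expect_equal(sum(st$type == 1L), 1)
  }
})

test_that("identical seeds give identical trajectories under scripted policies", {
  run_once <- function(seed) {
    cfg <- sim_config(grid_side = 15, view_radius = 3, density_per_type = 0.1,
                      n_iterations = 20, seed = seed)
    st <- grid_reset(cfg)
    set.seed(seed + 1000)
    rnd <- scripted_policy("uniform_random", seed = 99)
    for (i in 1:20) run_iteration(st, rnd, rnd)
    list(lat = st$lattice, id = st$id, rem = st$remaining)
  }
  expect_identical(run_once(4), run_once(4))
  expect_false(identical(run_once(4)$lat, run_once(5)$lat))
})
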