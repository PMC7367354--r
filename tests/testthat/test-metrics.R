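test_that("window entropy is the binary entropy of the type mix", {
  expect_equal(window_entropy(5, 5), 1)
  expect_equal(window_entropy(7, 0), 0)
  expect_equal(window_entropy(0, 3), 0)
  expect_equal(window_entropy(3, 1), 0.811278, tolerance = 1e-6)
  # symmetry and maximisation at equality
  set.seed(1)
  a <- sample(1:50, 40, replace = TRUE)
  b <- sample(1:50, 40, replace = TRUE)
  expect_equal(window_entropy(a, b), window_entropy(b, a))
  expect_true(all(window_entropy(a, b) <= 1))
  expect_error(window_entropy(0, 0))
})

test_that("multiscale segregation agrees exactly with brute-force enumeration", {
  set.seed(12)
  # random sparse lattices at several sizes, including wrap-critical scales
  for (side in c(12, 20, 26, 30)) {
    lat <- random_lattice(side)
    sizes <- c(5, 9, min(13, side))
    expect_equal(multiscale_segregation(lat, sizes),
                 brute_force_segregation(lat, sizes), tolerance = 1e-12)
  }
  # non-wrapped variant
  lat <- random_lattice(18)
  expect_equal(multiscale_segregation(lat, c(4, 6), wrap = FALSE),
               brute_force_segregation(lat, c(4, 6), wrap = FALSE),
               tolerance = 1e-12)
  # the two extreme fixtures
  expect_equal(multiscale_segregation(matrix(1L, 25, 25)), 1)
  expect_lt(multiscale_segregation(make_checkerboard(30)), 0.01)
  split <- make_split_lattice(20, density = 1, seed = 1)
  expect_equal(multiscale_segregation(split, c(5, 10)),
               brute_force_segregation(split, c(5, 10)), tolerance = 1e-12)
  expect_error(multiscale_segregation(matrix(0L, 10, 10), c(4)))
  expect_error(multiscale_segregation(matrix(1L, 10, 10), c(12)))
})

test_that("segregation is invariant under type swap and toroidal translation", {
  set.seed(13)
  lat <- random_lattice(24)
  sizes <- c(5, 8)
  base <- multiscale_segregation(lat, sizes)
  expect_equal(multiscale_segregation(-lat, sizes), base, tolerance = 1e-12)
  for (shift in list(c(3, 0), c(0, 7), c(11, 5))) {
    rolled <- lat[(seq_len(24) + shift[1] - 1) %% 24 + 1,
                  (seq_len(24) + shift[2] - 1) %% 24 + 1]
    expect_equal(multiscale_segregation(rolled, sizes), base,
                 tolerance = 1e-12)
  }
})

test_that("occupancy heatmaps average type indicators over snapshots", {
  lat <- random_lattice(10)
  hm <- occupancy_heatmaps(list(lat))
  expect_equal(hm$A, (lat == -1L) * 1)
  expect_equal(hm$B, (lat == 1L) * 1)

  # agent fixed in place over many snapshots reads 1.0
  hm2 <- occupancy_heatmaps(rep(list(lat), 100))
  expect_equal(hm2$A, (lat == -1L) * 1)

  # uniform random relocation: all cells close to the density
  set.seed(14)
  snaps <- lapply(1:400, function(i) {
    m <- matrix(0L, 10, 10)
    m[sample(100, 20)] <- -1L
    m
  })
  hm3 <- occupancy_heatmaps(snaps)
  expect_true(all(abs(hm3$A - 0.2) < 4 * sqrt(0.2 * 0.8 / 400)))
  expect_equal(sum(hm3$B), 0)
  expect_error(occupancy_heatmaps(list(matrix(0L, 3, 3), matrix(0L, 4, 4))))
})

test_that("smoothing is a length-preserving moving mean", {
  x <- rnorm(200)
  sm <- smooth_series(x, 50)
  expect_equal(length(sm), 200)
  expect_equal(smooth_series(rep(0.7, 100), 50), rep(0.7, 100))
  expect_equal(sm[100], mean(x[76:125]), tolerance = 1e-12)
})

test_that("age x segregation matrix reproduces a hand-computed example", {
  # 30 records, 3 distinct ages x 2 occupied segregation levels
  records <- data.frame(
    age = rep(c(1L, 5L, 9L), each = 10),
    s = c(rep(0L, 8), rep(4L, 2),   # young: mostly fully mixed? s=0,d=4 -> seg 0
          rep(0L, 5), rep(4L, 5),   # middle: half and half
          rep(4L, 9), rep(0L, 1)),  # old: mostly pure
    d = c(rep(4L, 8), rep(0L, 2),
          rep(4L, 5), rep(0L, 5),
          rep(0L, 9), rep(4L, 1)))
  m <- age_segregation_matrix(records, n_age_groups = 3L, n_seg_bins = 5L)
  # manual two-stage normalisation
  counts <- matrix(0, 5, 3)
  counts[1, ] <- c(8, 5, 1) # seg = 0 -> bin 1
  counts[5, ] <- c(2, 5, 9) # seg = 1 -> bin 5
  colnorm <- sweep(counts, 2, colSums(counts), "/")
  rs <- rowSums(colnorm); rs[rs == 0] <- 1
  manual <- sweep(colnorm, 1, rs, "/")
  expect_equal(unname(unclass(m)[, ]), manual, tolerance = 1e-12)
  expect_equal(rowSums(m)[rowSums(attr(m, "counts")) > 0],
               c(1, 1), ignore_attr = TRUE)

  # uniform records give 1/n_groups everywhere
  uni <- expand.grid(age = 1:10, bin = 1:5)
  uni <- data.frame(age = rep(uni$age, 4),
                    s = rep(uni$bin - 1L, 4), d = rep(5L - uni$bin, 4))
  mu <- age_segregation_matrix(uni, n_age_groups = 10L, n_seg_bins = 5L)
  expect_true(all(abs(mu - 0.1) < 1e-12))

  # separable extreme: old fully segregated, young fully mixed
  sep <- data.frame(age = rep(c(1L, 99L), each = 50),
                    s = c(rep(0L, 50), rep(6L, 50)),
                    d = c(rep(6L, 50), rep(0L, 50)))
  ms <- age_segregation_matrix(sep, n_age_groups = 2L, n_seg_bins = 5L)
  expect_equal(ms[1, 1], 1)
  expect_equal(ms[5, 2], 1)
  expect_equal(sum(ms), 2)

  # neighbourless records are excluded and reported
  withna <- rbind(records, data.frame(age = 3L, s = 0L, d = 0L))
  m2 <- age_segregation_matrix(withna, n_age_groups = 3L, n_seg_bins = 5L)
  expect_equal(attr(m2, "n_excluded"), 1L)
  expect_error(age_segregation_matrix(data.frame(age = 1L, s = 0L, d = 0L)))
})

test_that("action x age matrix reproduces a hand-computed example", {
  records <- data.frame(
    age = rep(c(2L, 8L), each = 15),
    action = c(rep("stay", 10), rep("left", 5),
               rep("stay", 3), rep("right", 12)))
  m <- action_age_matrix(records, n_age_groups = 2L)
  counts <- matrix(0, 5, 2)
  counts[1, ] <- c(10, 3)  # stay
  counts[2, ] <- c(5, 0)   # left
  counts[3, ] <- c(0, 12)  # right
  colnorm <- sweep(counts, 2, colSums(counts), "/")
  rs <- rowSums(colnorm); rs[rs == 0] <- 1
  manual <- sweep(colnorm, 1, rs, "/")
  expect_equal(unname(unclass(m)[, ]), manual, tolerance = 1e-12)

  # oldest stayers concentrate the stay row on the old column
  sep <- data.frame(age = rep(c(1L, 99L), each = 40),
                    action = c(rep("left", 40), rep("stay", 40)))
  ms <- action_age_matrix(sep, n_age_groups = 2L)
  expect_equal(ms["stay", 2], 1)
  expect_equal(ms["stay", 1], 0)

  # integer action codes are accepted
  m_int <- action_age_matrix(data.frame(age = records$age,
                                        action = match(records$action, actions())),
                             n_age_groups = 2L)
  expect_equal(m_int, m)
})
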