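# Independent brute-force oracles and small builders shared across tests.

# Enumerates every wrapped window of every scale explicitly; deliberately
# naive and structurally different from the package implementation.
brute_force_segregation <- function(lattice, sizes = c(6, 12, 25),
                                    wrap = TRUE) {
  s <- nrow(lattice)
  ent <- c()
  for (w in sizes) {
    starts <- if (wrap) 1:s else 1:(s - w + 1)
    for (i in starts) {
      for (j in starts) {
        rows <- ((i - 1):(i + w - 2)) %% s + 1
        cols <- ((j - 1):(j + w - 2)) %% s + 1
        win <- lattice[rows, cols]
        na <- sum(win == -1)
        nb <- sum(win == 1)
        if (na + nb > 0) {
          p <- na / (na + nb)
          f <- function(x) if (x > 0) x * log2(x) else 0
          ent <- c(ent, -f(p) - f(1 - p))
        }
      }
    }
  }
  1 - mean(ent)
}

# Random sparse lattice with both types present.
random_lattice <- function(side, p_occupied = 0.3) {
  m <- matrix(sample(c(-1L, 0L, 1L), side * side, replace = TRUE,
                     prob = c(p_occupied / 2, 1 - p_occupied, p_occupied / 2)),
              side, side)
  if (!any(m == -1L)) m[1, 1] <- -1L
  if (!any(m == 1L)) m[side, side] <- 1L
  m
}

# A tiny world with agents at fixed positions (0-based), for scripted tests.
make_manual_state <- function(side, r, positions, types, base_lifespan = 100L,
                              remaining = NULL) {
  cfg <- sim_config(grid_side = side, view_radius = r,
                    base_lifespan = base_lifespan, density_per_type = 0,
                    n_iterations = 10L)
  st <- grid_reset(cfg)
  n <- nrow(positions)
  st$id <- seq_len(n)
  st$next_id <- n + 1L
  st$type <- as.integer(types)
  st$row <- as.integer(positions[, 1])
  st$col <- as.integer(positions[, 2])
  st$age <- rep(0L, n)
  st$remaining <- if (is.null(remaining)) rep(base_lifespan, n) else
    as.integer(remaining)
  cells <- st$row + st$col * side + 1L
  st$lattice[cells] <- st$type
  st$slot_at[cells] <- seq_len(n)
  st
}

# Shared cache for expensive acceptance computations (built once per file).
acceptance_cache <- new.env(parent = emptyenv())

scaled_runs <- function(alpha, ir, seeds = c(1, 2, 3)) {
  key <- sprintf("a%s_ir%s_%s", alpha, ir, paste(seeds, collapse = "-"))
  if (!is.null(acceptance_cache[[key]])) return(acceptance_cache[[key]])
  out <- lapply(seeds, function(s) {
    run_experiment(scaled_experiment_spec(alpha = alpha, ir = ir), seed = s)
  })
  acceptance_cache[[key]] <- out
  out
}
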