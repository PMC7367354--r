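# Experiment orchestration: a spec bundles the three configuration objects
# with sweep grids and analysis settings; run_experiment() executes one
# (config, seed) point end to end and computes every statistic; run_sweep()
# covers the intolerance x interdependence grid.

#' Experiment specification
#'
#' @param simulation A [sim_config()].
#' @param rewards A [reward_config()].
#' @param training A [train_config()].
#' @param alpha_values,ir_values Sweep grids for the intolerance weight and
#'   the interdependence reward.
#' @param replicates Number of independently seeded repetitions per sweep
#'   cell.
#' @param analysis_window Number of final iterations over which snapshots,
#'   per-agent records and the reported segregation are collected.
#' @param snapshot_every_before Snapshot cadence before the analysis window.
#' @param seg_window_sizes Window sides of the segregation metric; `NULL`
#'   picks `c(6, 12, 25)` truncated to the grid side.
#' @param channels Q-network channel widths (`NULL` for the defaults of
#'   [qnet_new()]).
#'
#' @return A list of class `experiment_spec`.
#' @export
experiment_spec <- function(simulation = sim_config(),
                            rewards = reward_config(),
                            training = train_config(),
                            alpha_values = c(0, 0.25, 0.5, 0.75, 1),
                            ir_values = c(0, 25, 50, 75, 100),
                            replicates = 10L,
                            analysis_window = 1000L,
                            snapshot_every_before = 10L,
                            seg_window_sizes = NULL,
                            channels = NULL) {
  stopifnot(inherits(simulation, "sim_config"),
            inherits(rewards, "reward_config"),
            inherits(training, "train_config"))
  replicates <- as.integer(replicates)
  analysis_window <- as.integer(analysis_window)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  if (analysis_window > simulation$n_iterations) {
    stop("analysis_window cannot exceed n_iterations", call. = FALSE)
  }
  if (length(alpha_values) == 0L || length(ir_values) == 0L) {
    stop("sweep grids must be non-empty", call. = FALSE)
  }
  structure(list(simulation = simulation, rewards = rewards,
                 training = training, alpha_values = alpha_values,
                 ir_values = ir_values, replicates = replicates,
                 analysis_window = analysis_window,
                 snapshot_every_before = as.integer(snapshot_every_before),
                 seg_window_sizes = seg_window_sizes, channels = channels),
            class = "experiment_spec")
}

#' Reduced experiment profile
#'
#' A scaled-down study that keeps the model's geometry intact — the full
#' 11 x 11 field of view (radius 5) and the 6/12/25 segregation windows —
#' while shrinking the lattice to 25 x 25, the episode to 1,000 iterations
#' and the networks/training cadence to match, so one run takes about a
#' minute and a half on one CPU core. The exploration decay is shortened in
#' proportion to the smaller per-type action budget. See the methods
#' vignette for the sizing rationale.
#'
#' @param alpha,ir Reward parameters of the profile.
#' @param n_iterations Episode length.
#' @param replicates Repetitions per condition.
#'
#' @return An `experiment_spec`.
#' @export
scaled_experiment_spec <- function(alpha = 1, ir = 0, n_iterations = 1000L,
                                   replicates = 3L) {
  n_iterations <- as.integer(n_iterations)
  experiment_spec(
    simulation = sim_config(grid_side = 25L, view_radius = 5L,
                            base_lifespan = 100L, density_per_type = 0.05,
                            n_iterations = n_iterations),
    rewards = reward_config(alpha = alpha, interdependence = ir),
    training = train_config(batch_size = 64L, replay_capacity = 20000L,
                            epsilon_decay_actions = 10000,
                            total_training_steps = 12L * n_iterations,
                            n_iterations = n_iterations),
    alpha_values = c(0, 1), ir_values = c(0, 50, 100),
    replicates = replicates,
    analysis_window = max(1L, min(250L, n_iterations)),
    seg_window_sizes = c(6L, 12L, 25L),
    channels = c(4L, 4L, 4L, 8L, 8L))
}

#' Run one experiment end to end
#'
#' Builds the environment, trains both networks over one episode, collects
#' lattice snapshots and per-agent records over the analysis window, and
#' computes all statistics. Fully deterministic given `(spec, seed)`.
#'
#' @param spec An [experiment_spec()]; its `rewards` component defines the
#'   single `(alpha, IR)` point that is run.
#' @param seed Integer master seed.
#' @param keep_snapshots Keep the raw lattice snapshots in the result.
#' @param verbose Progress output from [training_loop()].
#'
#' @return An object of class `experiment_result` with the per-iteration
#'   segregation `series` (raw and smoothed), `final_segregation` (mean over
#'   the analysis window), occupancy `heatmaps`, the two conditional
#'   probability matrices, per-agent `records`, the training `log` and the
#'   echoed configuration.
#' @export
run_experiment <- function(spec, seed, keep_snapshots = FALSE,
                           verbose = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  set.seed(as.integer(seed))
  sim <- spec$simulation
  sim$seed <- NULL # the master seed above governs the whole run
  state <- grid_reset(sim)
  from <- sim$n_iterations - spec$analysis_window + 1L
  fit <- training_loop(state, spec$rewards, spec$training,
                       record_from = from, snapshot_from = from,
                       snapshot_every_before = spec$snapshot_every_before,
                       seg_window_sizes = spec$seg_window_sizes,
                       channels = spec$channels, verbose = verbose)
  in_window <- fit$log$iteration >= from
  series <- data.frame(iteration = fit$log$iteration,
                       segregation = fit$log$segregation,
                       smoothed = smooth_series(fit$log$segregation))
  window_snaps <- fit$snapshots[as.integer(names(fit$snapshots)) >= from]
  result <- list(
    version = 1L,
    spec = spec,
    seed = as.integer(seed),
    series = series,
    final_segregation = mean(fit$log$segregation[in_window]),
    heatmaps = occupancy_heatmaps(window_snaps),
    age_segregation = age_segregation_matrix(fit$records),
    action_age = action_age_matrix(fit$records),
    records = fit$records,
    log = fit$log,
    nets = list(A = fit$net_A, B = fit$net_B))
  if (keep_snapshots) result$snapshots <- window_snaps
  structure(result, class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(paste0("<experiment_result> alpha=%g IR=%g seed=%d | final ",
                     "segregation %.3f over last %d iterations\n"),
              x$spec$rewards$alpha, x$spec$rewards$interdependence, x$seed,
              x$final_segregation, x$spec$analysis_window))
  invisible(x)
}

#' Intolerance x interdependence sweep
#'
#' Runs every `(alpha, IR, replicate)` cell of the spec's grids and
#' assembles the mean final-segregation surface. Each replicate gets an
#' independent seed derived from the master seed; per-cell failures are
#' isolated and reported as `NA` in the surface.
#'
#' @param spec An [experiment_spec()].
#' @param seed Integer master seed.
#' @param verbose Print one line per completed cell.
#'
#' @return A list of class `sweep_result` with `surface` (matrix
#'   `alpha x IR` of mean final segregation), `final` (per-run data frame)
#'   and `results` (list of `experiment_result`, one per run).
#' @export
run_sweep <- function(spec, seed, verbose = FALSE) {
  stopifnot(inherits(spec, "experiment_spec"))
  set.seed(as.integer(seed))
  n_alpha <- length(spec$alpha_values)
  n_ir <- length(spec$ir_values)
  seeds <- array(sample.int(2^31 - 1, n_alpha * n_ir * spec$replicates),
                 dim = c(n_alpha, n_ir, spec$replicates))
  surface <- matrix(NA_real_, n_alpha, n_ir,
                    dimnames = list(alpha = spec$alpha_values,
                                    ir = spec$ir_values))
  results <- list()
  rows <- list()
  for (i in seq_len(n_alpha)) {
    for (j in seq_len(n_ir)) {
      vals <- rep(NA_real_, spec$replicates)
      for (k in seq_len(spec$replicates)) {
        cell_spec <- spec
        cell_spec$rewards$alpha <- spec$alpha_values[i]
        cell_spec$rewards$interdependence <- spec$ir_values[j]
        res <- tryCatch(run_experiment(cell_spec, seeds[i, j, k]),
                        error = function(e) e)
        key <- sprintf("alpha%g_ir%g_rep%d", spec$alpha_values[i],
                       spec$ir_values[j], k)
        if (inherits(res, "error")) {
          warning(sprintf("sweep cell %s failed: %s", key,
                          conditionMessage(res)), call. = FALSE)
        } else {
          vals[k] <- res$final_segregation
          results[[key]] <- res
        }
        rows[[length(rows) + 1L]] <- data.frame(
          alpha = spec$alpha_values[i], ir = spec$ir_values[j],
          replicate = k, seed = seeds[i, j, k],
          final_segregation = vals[k])
        if (verbose) {
          message(sprintf("%s -> %.3f", key, vals[k]))
        }
      }
      surface[i, j] <- mean(vals, na.rm = TRUE)
    }
  }
  structure(list(surface = surface, final = do.call(rbind, rows),
                 results = results, seed = as.integer(seed), spec = spec),
            class = "sweep_result")
}

# --- serialisation ---------------------------------------------------------

.mat_to_list <- function(m) list(dim = dim(m), data = as.numeric(m),
                                 dimnames = dimnames(m))
.list_to_mat <- function(l) {
  m <- matrix(l$data, l$dim[1L], l$dim[2L])
  if (!is.null(l$dimnames)) dimnames(m) <- l$dimnames
  m
}

#' Export an experiment result to disk
#'
#' Writes the complete numerical content of the result as JSON at full
#' double precision (plus tabular CSV copies of the series and records for
#' convenience), so that [load_results()] round-trips it exactly.
#'
#' @param result An `experiment_result`.
#' @param path Output directory (created if missing).
#'
#' @return `path`, invisibly.
#' @export
export_results <- function(result, path) {
  stopifnot(inherits(result, "experiment_result"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  spec <- result$spec
  payload <- list(
    version = result$version,
    seed = result$seed,
    config = list(simulation = unclass(spec$simulation),
                  rewards = unclass(spec$rewards),
                  training = unclass(spec$training),
                  analysis_window = spec$analysis_window,
                  snapshot_every_before = spec$snapshot_every_before,
                  seg_window_sizes = spec$seg_window_sizes,
                  channels = spec$channels),
    final_segregation = result$final_segregation,
    series = as.list(result$series),
    heatmap_A = .mat_to_list(result$heatmaps$A),
    heatmap_B = .mat_to_list(result$heatmaps$B),
    age_segregation = .mat_to_list(result$age_segregation),
    action_age = .mat_to_list(result$action_age),
    records = as.list(result$records))
  # I(17) = 17 significant digits: lossless double round-trip
  jsonlite::write_json(payload, file.path(path, "result.json"),
                       digits = I(17), auto_unbox = TRUE, null = "null")
  utils::write.csv(result$series, file.path(path, "segregation_series.csv"),
                   row.names = FALSE)
  utils::write.csv(result$records, file.path(path, "agent_records.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Load an exported experiment result
#'
#' @param path Directory written by [export_results()].
#'
#' @return An `experiment_result` with all numerical fields restored
#'   exactly (networks and raw snapshots are not serialised).
#' @export
load_results <- function(path) {
  file <- file.path(path, "result.json")
  if (!file.exists(file)) {
    stop("no exported result found at ", path, call. = FALSE)
  }
  p <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (is.null(p$version) || p$version != 1L) {
    stop("unsupported result-file version: ", p$version, call. = FALSE)
  }
  cfg <- p$config
  spec <- experiment_spec(
    simulation = do.call(sim_config, cfg$simulation),
    rewards = do.call(reward_config, cfg$rewards),
    training = do.call(train_config, cfg$training),
    replicates = 1L,
    analysis_window = cfg$analysis_window,
    snapshot_every_before = cfg$snapshot_every_before,
    seg_window_sizes = cfg$seg_window_sizes,
    channels = cfg$channels)
  structure(list(
    version = 1L, spec = spec, seed = p$seed,
    series = as.data.frame(p$series),
    final_segregation = p$final_segregation,
    heatmaps = list(A = .list_to_mat(p$heatmap_A),
                    B = .list_to_mat(p$heatmap_B)),
    age_segregation = .list_to_mat(p$age_segregation),
    action_age = .list_to_mat(p$action_age),
    records = as.data.frame(p$records),
    log = NULL, nets = NULL), class = "experiment_result")
}

#' Read an experiment spec from a YAML configuration file
#'
#' The file may contain `simulation`, `rewards`, `training` and `sweep`
#' sections whose keys match the arguments of [sim_config()],
#' [reward_config()], [train_config()] and [experiment_spec()]; missing keys
#' fall back to the defaults.
#'
#' @param path Path to a YAML file.
#'
#' @return An [experiment_spec()].
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list(
    simulation = do.call(sim_config, as.list(cfg$simulation)),
    rewards = do.call(reward_config, as.list(cfg$rewards)),
    training = do.call(train_config, as.list(cfg$training)))
  do.call(experiment_spec, c(args, as.list(cfg$sweep), as.list(cfg$analysis)))
}
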