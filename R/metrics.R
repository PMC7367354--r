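#' Binary entropy of a window's type composition
#'
#' Normalises the two type counts to probabilities and returns the base-2
#' entropy, so a perfectly mixed window scores 1 and a pure window scores 0.
#' `0 * log2(0)` is taken as 0. Empty windows are not evaluable and must be
#' excluded by the caller.
#'
#' @param n_same,n_other Non-negative type counts (vectorised); each pair
#'   must sum to a positive total.
#'
#' @return Entropy values in `[0, 1]`.
#' @examples
#' window_entropy(5, 5) # 1
#' window_entropy(7, 0) # 0
#' @export
window_entropy <- function(n_same, n_other) {
  tot <- n_same + n_other
  if (any(tot <= 0)) {
    stop("window_entropy is undefined on empty windows", call. = FALSE)
  }
  p <- n_same / tot
  plogp <- function(x) ifelse(x > 0, x * log2(x), 0)
  -plogp(p) - plogp(1 - p)
}

# All w x w window sums of `ind` at the given stride, via a summed-area
# table. With wrap = TRUE the lattice is extended periodically so every
# position contributes a window.
.window_sums <- function(ind, w, stride = 1L, wrap = TRUE) {
  s <- nrow(ind)
  if (wrap) {
    ext <- ind[c(seq_len(s), seq_len(w - 1L)), c(seq_len(s), seq_len(w - 1L)),
               drop = FALSE]
    starts <- seq.int(1L, s, by = stride)
  } else {
    ext <- ind
    starts <- seq.int(1L, s - w + 1L, by = stride)
  }
  sat <- apply(ext, 2, cumsum)
  sat <- t(apply(sat, 1, cumsum))
  sat <- rbind(0, cbind(0, sat)) # zero-padded: sat[i+1, j+1] = sum up to (i, j)
  i0 <- starts; i1 <- starts + w - 1L
  sat[i1 + 1L, i1 + 1L, drop = FALSE] - sat[i0, i1 + 1L, drop = FALSE] -
    sat[i1 + 1L, i0, drop = FALSE] + sat[i0, i0, drop = FALSE]
}

#' Multiscale-entropy segregation of a lattice
#'
#' Slides windows of several sizes over the lattice (toroidally by default),
#' computes the binary entropy of the type composition of every window that
#' contains at least one agent, averages the entropies over all windows of
#' all scales pooled together (`<e>`), and returns `1 - <e>`. The value is 1
#' for a fully segregated lattice and approaches 0 for a fully mixed one.
#'
#' @param lattice Integer matrix in `{-1, 0, 1}` with at least one agent.
#' @param window_sizes Window sides; all must fit in the lattice.
#' @param stride Window placement step, in cells.
#' @param wrap Slide windows across the periodic boundary so that every
#'   lattice position anchors a window.
#'
#' @return Segregation value in `[0, 1]`.
#' @export
multiscale_segregation <- function(lattice, window_sizes = c(6, 12, 25),
                                   stride = 1L, wrap = TRUE) {
  stopifnot(is.matrix(lattice), nrow(lattice) == ncol(lattice))
  if (any(window_sizes > nrow(lattice))) {
    stop("all window sizes must fit within the lattice", call. = FALSE)
  }
  if (!any(lattice != 0L)) {
    stop("segregation is undefined on an empty lattice", call. = FALSE)
  }
  ind_a <- lattice == -1L
  ind_b <- lattice == 1L
  ent <- numeric(0)
  for (w in window_sizes) {
    na <- as.vector(.window_sums(ind_a, w, stride, wrap))
    nb <- as.vector(.window_sums(ind_b, w, stride, wrap))
    keep <- (na + nb) > 0
    if (any(keep)) ent <- c(ent, window_entropy(na[keep], nb[keep]))
  }
  if (length(ent) == 0L) {
    stop("no window contains an agent; segregation undefined", call. = FALSE)
  }
  1 - mean(ent)
}

#' Segregation time series over lattice snapshots
#'
#' @param snapshots List of lattices (e.g. from [training_loop()]).
#' @param ... Passed to [multiscale_segregation()].
#'
#' @return Numeric vector, one segregation value per snapshot.
#' @export
segregation_series <- function(snapshots, ...) {
  vapply(snapshots, multiscale_segregation, numeric(1), ...)
}

#' Length-preserving moving mean
#'
#' Centred rolling mean with partial windows at the edges, used to smooth
#' per-iteration segregation series; a constant series is returned unchanged.
#'
#' @param x Numeric vector.
#' @param width Window width in samples.
#'
#' @return Smoothed vector of the same length as `x`.
#' @export
smooth_series <- function(x, width = 50L) {
  if (length(x) == 0L) return(x)
  zoo::rollapply(zoo::zoo(x), width = width, FUN = mean, partial = TRUE,
                 align = "center") |> as.numeric()
}

#' Time-averaged occupancy heatmaps
#'
#' Per-cell mean indicator of occupation by each type across a sequence of
#' lattice snapshots: the probability of finding a type A (or B) agent at
#' each location over the analysed window.
#'
#' @param snapshots Non-empty list of equally sized lattices.
#'
#' @return A list with matrices `A` and `B`, values in `[0, 1]`.
#' @export
occupancy_heatmaps <- function(snapshots) {
  stopifnot(length(snapshots) >= 1L)
  dims <- dim(snapshots[[1L]])
  if (!all(vapply(snapshots, function(m) identical(dim(m), dims), logical(1)))) {
    stop("all snapshots must have identical dimensions", call. = FALSE)
  }
  acc_a <- matrix(0, dims[1L], dims[2L])
  acc_b <- matrix(0, dims[1L], dims[2L])
  for (m in snapshots) {
    acc_a <- acc_a + (m == -1L)
    acc_b <- acc_b + (m == 1L)
  }
  list(A = acc_a / length(snapshots), B = acc_b / length(snapshots))
}

# Split ages into `n_groups` equal-count groups (ties broken by rank order).
.age_groups <- function(age, n_groups) {
  n <- length(age)
  ceiling(rank(age, ties.method = "first") * n_groups / n)
}

# Two-stage normalisation of a count matrix: columns (age groups) first,
# then rows, so each row sums to 1.
.double_normalize <- function(counts) {
  cs <- colSums(counts)
  cs[cs == 0] <- 1
  m <- sweep(counts, 2, cs, "/")
  rs <- rowSums(m)
  rs[rs == 0] <- 1
  sweep(m, 1, rs, "/")
}

#' Age-group probabilities conditional on window segregation
#'
#' Each record's window segregation is `s / (s + d)`; records without
#' neighbours (`s + d = 0`) are excluded. Ages are split into `n_age_groups`
#' equal-count groups and segregation into `n_seg_bins` equal-width bins on
#' `[0, 1]`. Counts are normalised first within each age group (column) and
#' then within each segregation bin (row), so rows sum to 1 and imbalanced
#' group sizes do not distort the picture.
#'
#' @param records Data frame with columns `age`, `s`, `d` (e.g. the
#'   `records` element of [training_loop()]).
#' @param n_age_groups Number of age groups (columns).
#' @param n_seg_bins Number of segregation bins (rows).
#'
#' @return A `n_seg_bins x n_age_groups` probability matrix with attributes
#'   `counts` (raw count matrix) and `n_excluded` (neighbourless records).
#' @export
age_segregation_matrix <- function(records, n_age_groups = 10L,
                                   n_seg_bins = 5L) {
  stopifnot(nrow(records) > 0L)
  keep <- (records$s + records$d) > 0
  n_excluded <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0L) {
    stop("all records have empty windows; matrix undefined", call. = FALSE)
  }
  seg <- records$s / (records$s + records$d)
  bin <- pmin(floor(seg * n_seg_bins) + 1L, n_seg_bins)
  grp <- .age_groups(records$age, n_age_groups)
  counts <- table(factor(bin, levels = seq_len(n_seg_bins)),
                  factor(grp, levels = seq_len(n_age_groups)))
  counts <- matrix(as.numeric(counts), n_seg_bins, n_age_groups,
                   dimnames = list(
                     segregation = sprintf("[%.1f,%.1f%s", (seq_len(n_seg_bins) - 1) / n_seg_bins,
                                           seq_len(n_seg_bins) / n_seg_bins,
                                           c(rep(")", n_seg_bins - 1L), "]")),
                     age_group = paste0("G", seq_len(n_age_groups))))
  out <- .double_normalize(counts)
  attr(out, "counts") <- counts
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Age-group probabilities conditional on the action taken
#'
#' Same double normalisation as [age_segregation_matrix()], with one row per
#' action instead of segregation bins.
#'
#' @param records Data frame with columns `age` and `action` (action names
#'   from [actions()] or indices in 1..5).
#' @param n_age_groups Number of age groups (columns).
#'
#' @return A `5 x n_age_groups` probability matrix with attribute `counts`.
#' @export
action_age_matrix <- function(records, n_age_groups = 10L) {
  stopifnot(nrow(records) > 0L)
  act <- records$action
  if (!is.character(act)) act <- actions()[as.integer(act)]
  grp <- .age_groups(records$age, n_age_groups)
  counts <- table(factor(act, levels = actions()),
                  factor(grp, levels = seq_len(n_age_groups)))
  counts <- matrix(as.numeric(counts), length(actions()), n_age_groups,
                   dimnames = list(action = actions(),
                                   age_group = paste0("G", seq_len(n_age_groups))))
  out <- .double_normalize(counts)
  attr(out, "counts") <- counts
  out
}
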