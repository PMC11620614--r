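#' Configure a simulated sequence space
#'
#' Specifies one site-percolation trial over the space of all `A^L`
#' sequences of length `L` on an `A`-letter alphabet. Each sequence receives
#' a deterministic uniform deviate from a counter-based hash of
#' `(seed, sequence)`; it is functional when the deviate falls below `p_fs`.
#' Nothing is materialised: spaces of hundreds of millions of sequences are
#' explored lazily.
#'
#' Under the `"full"` transition rule any letter can mutate into any of the
#' other `A - 1` letters, so every sequence has `L * (A - 1)` neighbours.
#' Under `"restricted"` each letter may reach only `A_t < A - 1` letters,
#' implemented as symmetric cyclic offsets (`c -> c +/- 1 ... +/- A_t/2`
#' modulo `A`; odd `A_t` additionally uses the half-turn offset `A/2` and
#' therefore requires even `A`). The rule is symmetric and every sequence
#' has exactly `L * A_t` neighbours.
#'
#' @param L sequence length (at least 2).
#' @param A alphabet size (at least 2).
#' @param p_fs probability that a sequence is functional, in \[0, 1\].
#' @param seed non-negative integer seed; together with a sequence it fully
#'   determines that sequence's functionality.
#' @param transition `"full"` or `"restricted"`.
#' @param A_t transitions per letter, required for `"restricted"`
#'   (`1 <= A_t < A - 1`); for `"full"` it is `A - 1`.
#' @param force_start_functional treat the start sequence as functional by
#'   construction (default `TRUE`); with `FALSE`, a start whose deviate
#'   exceeds `p_fs` yields an empty cluster.
#' @return An object of class `"space_config"`.
#' @examples
#' cfg <- space_config(L = 10, A = 7, p_fs = 0.019, seed = 1)
#' cluster_from_start(cfg)
#' @export
space_config <- function(L, A, p_fs, seed,
                         transition = c("full", "restricted"), A_t = NULL,
                         force_start_functional = TRUE) {
  transition <- match.arg(transition)
  stopifnot(length(L) == 1, length(A) == 1, length(p_fs) == 1,
            length(seed) == 1)
  if (A < 2 || A != floor(A)) stop("`A` must be an integer >= 2")
  if (L < 2 || L != floor(L)) stop("`L` must be an integer >= 2")
  if (p_fs < 0 || p_fs > 1) stop("`p_fs` must lie in [0, 1]")
  if (seed < 0 || seed != floor(seed)) stop("`seed` must be a non-negative integer")
  if (L * log2(A) > 62)
    stop("space too large to index: need A^L < 2^62")
  if (transition == "full") {
    if (!is.null(A_t) && A_t != A - 1)
      stop("`A_t` is A - 1 under the full transition rule")
    A_t <- A - 1
    offsets <- integer(0)
  } else {
    if (is.null(A_t)) stop("`A_t` is required for restricted transitions")
    if (A_t < 1 || A_t >= A - 1 || A_t != floor(A_t))
      stop("restricted `A_t` must be an integer in [1, A - 2]")
    half <- A_t %/% 2
    offsets <- if (half > 0) c(seq_len(half), -seq_len(half)) else integer(0)
    if (A_t %% 2 == 1) {
      if (A %% 2 == 1)
        stop("odd `A_t` with odd `A` admits no symmetric cyclic ",
             "transition rule; choose even `A_t` or even `A`")
      offsets <- c(offsets, A %/% 2)
    }
  }
  structure(list(L = as.integer(L), A = as.integer(A),
                 transition = transition, A_t = as.integer(A_t),
                 offsets = as.integer(offsets),
                 p_fs = p_fs, seed = as.numeric(seed),
                 force_start_functional = isTRUE(force_start_functional)),
            class = "space_config")
}

#' @export
print.space_config <- function(x, ...) {
  cat(sprintf(
    "Sequence space: L = %d, A = %d (%s transitions, A_t = %d), %s sequences\n",
    x$L, x$A, x$transition, x$A_t,
    format(x$A^x$L, big.mark = ",", scientific = FALSE)))
  cat(sprintf("P_fs = %g, seed = %.0f, neighbours per sequence = %d\n",
              x$p_fs, x$seed, x$L * x$A_t))
  invisible(x)
}

check_seq <- function(config, codes) {
  if (!is.numeric(codes) || length(codes) != config$L ||
      any(codes < 1) || any(codes > config$A) || any(codes != floor(codes)))
    stop("sequence must be ", config$L, " integer codes in [1, ", config$A, "]")
  as.integer(codes)
}

#' Start and target sequences of a trial
#'
#' The start is the sequence of all first letters; the target the sequence
#' of all second letters (Hamming distance `L` apart). Codes are 1-based.
#'
#' @param config a [space_config()].
#' @return An integer vector of length `L`.
#' @export
start_sequence <- function(config) rep(1L, config$L)

#' @rdname start_sequence
#' @export
target_sequence <- function(config) rep(2L, config$L)

seq_index <- function(config, codes) {
  codes <- check_seq(config, codes) - 1L
  sum(codes * config$A^(seq_along(codes) - 1))
}

#' Uniform deviate and functionality of sequences
#'
#' `seq_uniform()` returns the deterministic uniform deviate assigned to
#' each sequence (rows of `codes`); `functional()` compares it against
#' `p_fs` (the start sequence is functional by construction when
#' `force_start_functional` is set).
#'
#' @param config a [space_config()].
#' @param codes an integer vector of length `L` (1-based letter codes), or a
#'   matrix with `L` columns, one sequence per row.
#' @return Numeric deviates in \[0, 1\), or logical functionality flags.
#' @export
seq_uniform <- function(config, codes) {
  .cpp_site_uniforms(config$seed, codes_to_index(config, codes))
}

codes_to_index <- function(config, codes) {
  if (!is.matrix(codes)) codes <- matrix(codes, nrow = 1)
  if (ncol(codes) != config$L ||
      any(codes < 1) || any(codes > config$A) || any(codes != floor(codes)))
    stop("sequences must be ", config$L, " integer codes in [1, ", config$A,
         "] per row")
  as.numeric((codes - 1) %*% config$A^(seq_len(config$L) - 1))
}

#' @rdname seq_uniform
#' @export
functional <- function(config, codes) {
  idx <- codes_to_index(config, codes)
  ans <- .cpp_site_uniforms(config$seed, idx) < config$p_fs
  if (config$force_start_functional)
    ans[idx == codes_to_index(config, start_sequence(config))] <- TRUE
  ans
}

#' Single-substitution neighbours of a sequence
#'
#' All sequences differing from `codes` at exactly one position and
#' reachable under the configured transition rule. The relation is
#' symmetric and every sequence has exactly `L * A_t` neighbours
#' (substitution spaces have no boundary).
#'
#' @param config a [space_config()].
#' @param codes an integer vector of length `L` (1-based codes).
#' @return An integer matrix with `L * A_t` rows, one neighbour per row.
#' @export
neighbors <- function(config, codes) {
  codes <- check_seq(config, codes)
  out <- matrix(rep(codes, each = config$L * config$A_t),
                nrow = config$L * config$A_t)
  row <- 1L
  for (pos in seq_len(config$L)) {
    c0 <- codes[pos] - 1L
    targets <- if (config$transition == "full") {
      setdiff(0:(config$A - 1L), c0)
    } else {
      (c0 + config$offsets) %% config$A
    }
    for (a in targets) {
      out[row, pos] <- a + 1L
      row <- row + 1L
    }
  }
  out
}

run_bfs <- function(config, start, cap, target = NULL, tol = -1L,
                    collect = FALSE) {
  start0 <- check_seq(config, start) - 1L
  target0 <- if (is.null(target)) integer(config$L)
             else check_seq(config, target) - 1L
  rule <- if (config$transition == "full") 0L else 1L
  .cpp_bfs(config$L, config$A, rule, config$offsets,
           config$p_fs, config$seed, start0,
           as.numeric(cap), config$force_start_functional,
           target0, as.integer(tol), isTRUE(collect))
}

#' Functional cluster containing the start sequence
#'
#' Iterative breadth-first traversal of the functional sequences connected
#' to `start` by single-substitution steps. Each sequence is visited at most
#' once; the search stops once `cap` functional members have been found, in
#' which case the outcome is flagged `capped` and `is_large` (clusters above
#' the cap extend throughout sequence space).
#'
#' @param config a [space_config()].
#' @param start starting sequence (default [start_sequence()]).
#' @param cap cluster-size cap (default 20000).
#' @param collect also return the member sequences (only sensible for small
#'   spaces).
#' @return An object of class `"cluster_outcome"`: `size` (capped at `cap`),
#'   `capped`, `is_large`, and optionally `members` (matrix of 1-based
#'   codes).
#' @export
cluster_from_start <- function(config, start = start_sequence(config),
                               cap = 20000, collect = FALSE) {
  if (cap < 1) stop("`cap` must be at least 1")
  res <- run_bfs(config, start, cap, collect = collect)
  out <- list(size = res$size, capped = res$capped, is_large = res$capped)
  if (collect) {
    idx <- res$members
    out$members <- index_to_codes(config, idx)
  }
  structure(out, class = "cluster_outcome")
}

#' @export
print.cluster_outcome <- function(x, ...) {
  cat(sprintf("Cluster size %s%s\n",
              format(x$size, big.mark = ","),
              if (x$capped) " (capped; extends throughout sequence space)"
              else ""))
  invisible(x)
}

index_to_codes <- function(config, idx) {
  L <- config$L; A <- config$A
  out <- matrix(0L, nrow = length(idx), ncol = L)
  for (i in seq_len(L)) {
    out[, i] <- as.integer(idx %% A) + 1L
    idx <- idx %/% A
  }
  out
}

#' Does a continuous functional path reach a target?
#'
#' `TRUE` when the functional cluster of `start` contains a sequence within
#' Hamming distance `tol` of `target` (early exit on the first hit). Every
#' cluster member is functional, so the hit itself terminates a continuous
#' functional path.
#'
#' @param config a [space_config()].
#' @param start,target sequences (defaults: all-first-letter start,
#'   all-second-letter target).
#' @param tol Hamming tolerance around the target, in `[0, L]`.
#' @param search_cap abandon the search after this many functional sequences
#'   (default unlimited within the space); an abandoned search returns
#'   `FALSE`.
#' @return Logical.
#' @export
connect_to_target <- function(config, start = start_sequence(config),
                              target = target_sequence(config), tol,
                              search_cap = Inf) {
  stopifnot(length(tol) == 1)
  if (tol < 0 || tol > config$L) stop("`tol` must lie in [0, L]")
  cap <- if (is.finite(search_cap)) search_cap else config$A^config$L + 1
  res <- run_bfs(config, start, cap, target = target, tol = as.integer(tol))
  isTRUE(res$found)
}

#' Attempts until a connecting path appears
#'
#' Regenerates the space with fresh seeds (drawn from R's RNG stream) until
#' [connect_to_target()] succeeds, mirroring repeated random trials at fixed
#' `p_fs`.
#'
#' @inheritParams connect_to_target
#' @param max_attempts give up after this many spaces.
#' @return A list of class `"connectivity_outcome"`: `attempts`, `success`,
#'   `tol`.
#' @export
attempts_until_connected <- function(config, start = start_sequence(config),
                                     target = target_sequence(config), tol,
                                     max_attempts = 1000,
                                     search_cap = Inf) {
  if (max_attempts < 1) stop("`max_attempts` must be at least 1")
  for (att in seq_len(max_attempts)) {
    cfg <- config
    cfg$seed <- as.numeric(sample.int(.Machine$integer.max, 1))
    if (connect_to_target(cfg, start, target, tol, search_cap))
      return(structure(list(attempts = att, success = TRUE, tol = tol),
                       class = "connectivity_outcome"))
  }
  structure(list(attempts = as.integer(max_attempts), success = FALSE, tol = tol),
            class = "connectivity_outcome")
}

#' @export
print.connectivity_outcome <- function(x, ...) {
  cat(sprintf("%s after %d attempt(s) (tol = %d)\n",
              if (x$success) "Connected" else "Not connected",
              x$attempts, x$tol))
  invisible(x)
}

replicate_seeds <- function(config, reps) {
  # deterministic distinct streams per replicate; the hash decorrelates them
  config$seed + 1e6 * seq_len(reps)
}

#' Fraction of replicate spaces with a large start cluster
#'
#' Generates `reps` independent spaces (derived seeds) at the configured
#' `p_fs` and reports the fraction whose start cluster reaches the cap.
#'
#' @param config a [space_config()]; its seed anchors the replicate seeds.
#' @param reps number of replicate spaces.
#' @param cap large-cluster cap (default 20000).
#' @return Proportion in \[0, 1\].
#' @export
large_cluster_fraction <- function(config, reps, cap = 20000) {
  if (reps < 1) stop("`reps` must be at least 1")
  seeds <- replicate_seeds(config, reps)
  large <- vapply(seeds, function(s) {
    cfg <- config; cfg$seed <- s
    cluster_from_start(cfg, cap = cap)$is_large
  }, logical(1))
  mean(large)
}

#' Sweep the occupation probability through the phase transition
#'
#' For each `p_fs` on an ascending grid, measures the large-cluster fraction
#' and mean (capped) cluster size over `reps` replicate spaces. Replicates
#' share their underlying uniform deviates across grid points (monotone
#' coupling): the functional set at a lower `p_fs` is a subset of the set at
#' any higher `p_fs`, so per-seed cluster size is non-decreasing and a
#' replicate that is large at one grid point is large at all later ones.
#' The critical point is the smallest grid `p_fs` whose large-cluster
#' fraction reaches `detect_fraction`.
#'
#' @param config a [space_config()] providing `L`, `A`, the transition rule
#'   and the anchor seed (its own `p_fs` is ignored).
#' @param p_fs_grid ascending occupation probabilities.
#' @param reps replicates per grid point (at least 10).
#' @param cap large-cluster cap (default 20000).
#' @param detect_fraction detection level for the critical point (default
#'   0.05).
#' @return An object of class `"sweep_result"`: `grid` (a data frame with
#'   `p_fs`, `large_fraction`, `mean_size`), `critical_p_fs` (`NA` when the
#'   transition is not reached), `reps`, `cap`.
#' @examples
#' \donttest{
#' cfg <- space_config(10, 7, p_fs = 0, seed = 1)
#' sw <- sweep_transition(cfg, seq(0.016, 0.024, by = 0.001), reps = 50)
#' sw$critical_p_fs
#' }
#' @export
sweep_transition <- function(config, p_fs_grid, reps, cap = 20000,
                             detect_fraction = 0.05) {
  if (is.unsorted(p_fs_grid, strictly = TRUE))
    stop("`p_fs_grid` must be strictly ascending")
  if (reps < 10) stop("`reps` must be at least 10")
  if (detect_fraction <= 0 || detect_fraction >= 1)
    stop("`detect_fraction` must be in (0, 1)")
  seeds <- replicate_seeds(config, reps)
  k <- length(p_fs_grid)
  large <- matrix(FALSE, nrow = reps, ncol = k)
  sizes <- matrix(NA_real_, nrow = reps, ncol = k)
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- seeds[r]
    for (j in seq_len(k)) {
      if (j > 1 && large[r, j - 1]) {
        # coupling guarantees the cluster stays large at higher p_fs
        large[r, j] <- TRUE
        sizes[r, j] <- cap
        next
      }
      cfg$p_fs <- p_fs_grid[j]
      out <- cluster_from_start(cfg, cap = cap)
      large[r, j] <- out$is_large
      sizes[r, j] <- out$size
    }
  }
  frac <- colMeans(large)
  crit_idx <- which(frac >= detect_fraction)[1]
  structure(list(
    grid = data.frame(p_fs = p_fs_grid, large_fraction = frac,
                      mean_size = colMeans(sizes)),
    critical_p_fs = if (is.na(crit_idx)) NA_real_ else p_fs_grid[crit_idx],
    reps = reps, cap = cap,
    large = large, sizes = sizes
  ), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Percolation sweep (", x$reps, " replicates/point, cap ",
      format(x$cap, big.mark = ","), ")\n", sep = "")
  print(x$grid, row.names = FALSE)
  cat("Critical p_fs:",
      if (is.na(x$critical_p_fs)) "not reached" else x$critical_p_fs, "\n")
  invisible(x)
}

#' Cluster sizes over replicate spaces
#'
#' @param config a [space_config()].
#' @param reps number of replicate spaces (at least 1).
#' @param cap cluster-size cap; capped sizes are flagged and should be
#'   excluded from power-law fitting.
#' @return A data frame with columns `size` and `capped`.
#' @export
cluster_size_distribution <- function(config, reps, cap = 20000) {
  if (reps < 1) stop("`reps` must be at least 1")
  seeds <- replicate_seeds(config, reps)
  rows <- lapply(seeds, function(s) {
    cfg <- config; cfg$seed <- s
    out <- cluster_from_start(cfg, cap = cap)
    data.frame(size = out$size, capped = out$capped)
  })
  do.call(rbind, rows)
}

#' Power-law exponent of a cluster-size distribution
#'
#' Fits `N(s) ~ s^-tau` by linear regression of log density against log size
#' over logarithmically binned sizes at or above `s_min`. Bin edges grow by
#' a constant factor; counts are divided by bin width and regressed against
#' the geometric mid-point.
#'
#' Sparsely occupied bins in the far tail (fewer than `min_count` sizes)
#' carry mostly Poisson noise and flatten the apparent slope, so they are
#' excluded, as is usual for binned power-law estimates.
#'
#' @param sizes positive cluster sizes (capped sizes must be removed by the
#'   caller).
#' @param s_min smallest size entering the fit.
#' @param bin_factor multiplicative bin-edge growth (default 2).
#' @param min_count smallest bin occupancy entering the regression
#'   (default 5).
#' @return A list of class `"power_law_fit"`: `tau` (slope magnitude), `se`
#'   (its standard error), `n_used`, `bins`.
#' @export
fit_power_law_tau <- function(sizes, s_min = 1, bin_factor = 2,
                              min_count = 5) {
  stopifnot(is.numeric(sizes))
  sizes <- sizes[sizes >= s_min]
  if (length(sizes) < 20)
    stop("need at least 20 sizes >= s_min to fit (got ", length(sizes), ")")
  if (length(unique(sizes)) < 3)
    stop("degenerate size histogram: too few distinct sizes")
  edges <- s_min * bin_factor^(0:ceiling(log(max(sizes) / s_min,
                                             bin_factor) + 1))
  counts <- graphics::hist(sizes, breaks = edges, plot = FALSE,
                           right = FALSE)$counts
  width <- diff(edges)
  mid <- sqrt(edges[-length(edges)] * edges[-1])
  keep <- counts >= min_count
  if (sum(keep) < 3)
    stop("fewer than 3 occupied log bins; cannot fit a power law")
  fit <- stats::lm(log(counts[keep] / width[keep]) ~ log(mid[keep]))
  sm <- summary(fit)
  structure(list(tau = -unname(coef(fit)[2]),
                 se = sm$coefficients[2, 2],
                 n_used = length(sizes),
                 bins = data.frame(mid = mid[keep],
                                   density = counts[keep] / width[keep])),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Cluster-size power law: tau = %.3f (se %.3f, %d sizes)\n",
              x$tau, x$se, x$n_used))
  invisible(x)
}
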