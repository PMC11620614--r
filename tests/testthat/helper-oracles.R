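# Independent oracles used across the suite.

# Explicit-graph oracle for small spaces: enumerate every sequence, take the
# same per-sequence deviates the simulator uses, build the functional
# subgraph explicitly and solve it with igraph's connected components.
oracle_space <- function(config) {
  N <- config$A^config$L
  stopifnot(N <= 1e4)
  idx <- 0:(N - 1)
  u <- seq_uniform(config, index_codes(config, idx))
  func <- u < config$p_fs
  start_idx <- 0L
  if (config$force_start_functional) func[1] <- TRUE
  fidx <- idx[func]
  pow <- config$A^(0:(config$L - 1))
  from <- numeric(0); to <- numeric(0)
  for (pos in seq_len(config$L)) {
    c0 <- (fidx %/% pow[pos]) %% config$A
    deltas <- if (config$transition == "full") seq_len(config$A - 1)
              else config$offsets
    for (d in deltas) {
      nb <- fidx + pow[pos] * ((c0 + d) %% config$A - c0)
      keep <- func[nb + 1]
      from <- c(from, fidx[keep]); to <- c(to, nb[keep])
    }
  }
  g <- igraph::make_empty_graph(length(fidx), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(match(from, fidx), match(to, fidx)))
  comp <- igraph::components(g)
  list(functional = func, fidx = fidx, membership = comp$membership,
       csize = comp$csize)
}

oracle_cluster_members <- function(config) {
  sp <- oracle_space(config)
  if (!sp$functional[1]) return(numeric(0))
  m <- sp$membership[match(0, sp$fidx)]
  sort(sp$fidx[sp$membership == m])
}

oracle_connect <- function(config, tol) {
  sp <- oracle_space(config)
  if (!sp$functional[1]) return(FALSE)
  members <- oracle_cluster_members(config)
  codes <- index_codes(config, members)
  any(rowSums(codes != 2L) <= tol)
}

index_codes <- function(config, idx) {
  out <- matrix(0L, nrow = length(idx), ncol = config$L)
  for (i in seq_len(config$L)) {
    out[, i] <- as.integer(idx %% config$A) + 1L
    idx <- idx %/% config$A
  }
  out
}

# Approximately discrete power-law sizes via inverse-CDF sampling of a
# continuous Pareto tail, floored.
sample_power_law <- function(n, tau, s_min) {
  floor(s_min * (1 - stats::runif(n))^(-1 / (tau - 1)))
}

table2_fixture <- function() load_fixtures()$table2
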