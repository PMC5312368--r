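# Independent brute-force oracles, deliberately naive: they never share code
# with the implementation they check.

# All-pairs shortest path lengths by Floyd-Warshall on an adjacency matrix.
oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Enumerate every shortest path between two nodes by exhaustive DFS bounded
# by the known shortest distance.
oracle_all_shortest_paths <- function(adj, from, to) {
  d <- oracle_floyd_warshall(adj)
  if (!is.finite(d[from, to])) return(list())
  lim <- d[from, to]
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == to && length(path) - 1 == lim) {
      paths[[length(paths) + 1L]] <<- path
      return()
    }
    if (length(path) - 1 >= lim) return()
    for (u in which(adj[v, ] > 0)) if (!u %in% path) walk(c(path, u))
  }
  walk(from)
  paths
}

# Unordered-pair betweenness by exhaustive shortest-path enumeration.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in seq.int(s + 1, n)) {
    paths <- oracle_all_shortest_paths(adj, s, t)
    if (!length(paths)) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      thru <- sum(vapply(paths, function(p) v %in% p, TRUE))
      btw[v] <- btw[v] + thru / length(paths)
    }
  }
  btw
}

# Random connected-ish undirected graph as an adjacency matrix.
oracle_random_graph <- function(n, p_edge, seed) {
  set.seed(seed)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(stats::runif(n * (n - 1) / 2) < p_edge)
  adj + t(adj)
}

# A small two-group spectral data set with known planted structure, used by
# several modules' tests.
make_small_truth <- function(seed = 1, n_per_group = 20, noise_sd = 0,
                             jitter_sd = 0, n_met = 4,
                             factors = list(), effects = NULL,
                             background_frac = 0) {
  lib <- make_metabolite_library(n_met, seed = seed)
  d <- simulation_design(
    group_sizes = c(CON = n_per_group, GC = n_per_group),
    effect_matrix = effects, latent_factors = factors,
    base_log_sd = 0.1, noise_sd = noise_sd, jitter_sd = jitter_sd,
    background = list(frac = background_frac, n = 10, halfwidth = 0.05,
                      cv = 0.05),
    seed = seed)
  truth <- simulate_concentrations(d, lib)
  list(lib = lib, design = d, truth = truth)
}
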