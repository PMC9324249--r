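# Independent brute-force oracles for graph metrics, kept deliberately
# separate from the package's BFS/Brandes implementation: distances by
# Floyd-Warshall, betweenness by exhaustive enumeration of all shortest
# paths.  Only usable at small n.

fw_distances <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  d[A != 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
  d
}

# all shortest s -> t paths as a list of node index vectors
enum_shortest_paths <- function(A, d, s, t) {
  if (!is.finite(d[s, t])) return(list())
  if (s == t) return(list(s))
  preds <- which(A[, t] != 0 & d[s, ] == d[s, t] - 1)
  out <- list()
  for (u in preds) {
    for (p in enum_shortest_paths(A, d, s, u)) {
      out[[length(out) + 1L]] <- c(p, t)
    }
  }
  out
}

enum_betweenness <- function(A) {
  n <- nrow(A)
  d <- fw_distances(A)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- enum_shortest_paths(A, d, s, t)
      if (length(paths) == 0) next
      through <- numeric(n)
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        through[interior] <- through[interior] + 1
      }
      bc <- bc + through / length(paths)
    }
  }
  if (n > 2) bc / ((n - 1) * (n - 2) / 2) else bc
}

# all seven nodal metrics by direct definition
oracle_metrics <- function(A) {
  n <- nrow(A)
  d <- fw_distances(A)
  deg <- rowSums(A != 0)
  geff <- pl <- leff <- clust <- numeric(n)
  for (i in seq_len(n)) {
    di <- d[i, -i]
    geff[i] <- sum(1 / di[is.finite(di)]) / (n - 1)
    reach <- di[is.finite(di) & di > 0]
    pl[i] <- if (length(reach)) mean(reach) else 0
    nb <- which(A[i, ] != 0)
    if (deg[i] >= 2) {
      sub <- A[nb, nb, drop = FALSE]
      clust[i] <- sum(sub != 0) / (deg[i] * (deg[i] - 1))
      ds <- fw_distances(sub)
      off <- ds[row(ds) != col(ds)]
      leff[i] <- sum(1 / off[is.finite(off)]) / (deg[i] * (deg[i] - 1))
    }
  }
  data.frame(degree = deg, cost = deg / (n - 1),
             global_efficiency = geff, local_efficiency = leff,
             betweenness = enum_betweenness(A), path_length = pl,
             clustering = clust)
}

rand_adjacency <- function(n, p) {
  A <- matrix(runif(n * n) < p, n, n)
  A[lower.tri(A, diag = TRUE)] <- FALSE
  (A + t(A)) * 1
}

# ring lattice: each node joined to its k nearest neighbours per side
lattice_adjacency <- function(n, k) {
  A <- matrix(0, n, n)
  for (i in seq_len(n))
    for (s in seq_len(k)) {
      j <- (i - 1 + s) %% n + 1
      A[i, j] <- A[j, i] <- 1
    }
  A
}

# small run configuration for fast cohort-level tests
tiny_config <- function(seed, n_roi = 12L, n_hc = 10L, n_lgg = 10L,
                        n_hgg = 10L, n_volumes = 60L, ...) {
  cfg <- gliomaconn::default_run_config(master_seed = seed)
  cfg$n_roi <- n_roi
  cfg$n_hc <- n_hc; cfg$n_lgg <- n_lgg; cfg$n_hgg <- n_hgg
  cfg$n_volumes <- n_volumes
  extra <- list(...)
  for (nm in names(extra)) cfg[[nm]] <- extra[[nm]]
  cfg
}

# null configuration: every group carries the HC (zero-delta) structure
null_config <- function(seed, ...) {
  tiny_config(seed, lgg_delta_left_global = 0, lgg_delta_local = 0,
              hgg_delta_right = 0, ...)
}
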