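#' Edge-thresholding rule
#'
#' The adjacency rule applied to Fisher-z connectivity: a pair (i, j)
#' becomes an edge when its standardized Fisher statistic
#' `z_stat = z[i, j] * sqrt(T_effective - 3)` exceeds
#' `z_stat_threshold` *and* the corresponding one-sided normal p-value
#' falls below `p_threshold`.  With the defaults (`z > 2`, `p < 0.05`)
#' and `T_effective >= 8` the p-condition is implied by the
#' z-condition, so edges depend on the z-statistic alone.
#'
#' @param z_stat_threshold positive threshold on the standardized
#'   Fisher statistic (default 2).
#' @param p_threshold p-value threshold in (0, 1) (default 0.05).
#' @param positive_only if `TRUE` (default) only positive correlations
#'   can create edges; if `FALSE` the rule is applied to `|z_stat|`
#'   with a two-sided p.
#' @return object of class `threshold_spec`.
#' @export
threshold_spec <- function(z_stat_threshold = 2, p_threshold = 0.05,
                           positive_only = TRUE) {
  stopifnot(z_stat_threshold > 0, p_threshold > 0, p_threshold < 1)
  structure(list(z_stat_threshold = z_stat_threshold,
                 p_threshold = p_threshold,
                 positive_only = positive_only),
            class = "threshold_spec")
}

#' Construct an undirected binary graph
#'
#' @param adjacency symmetric logical/0-1 matrix with zero diagonal.
#' @param node_ids 0-based ROI ids of the nodes (defaults to
#'   `0:(N-1)`).
#' @return object of class `binary_graph` with elements `n_nodes`,
#'   `adjacency` (logical matrix), `node_ids`.
#' @export
binary_graph <- function(adjacency, node_ids = NULL) {
  A <- adjacency != 0
  if (!isSymmetric(A * 1)) stop("adjacency must be symmetric", call. = FALSE)
  if (any(diag(A))) stop("self-loops are not allowed", call. = FALSE)
  node_ids <- node_ids %||% (seq_len(nrow(A)) - 1L)
  stopifnot(length(node_ids) == nrow(A))
  structure(list(n_nodes = nrow(A), adjacency = A,
                 node_ids = as.integer(node_ids)),
            class = "binary_graph")
}

#' Threshold a connectivity matrix into a binary graph
#'
#' @param conn `conn_matrix` from [correlation_matrix()].
#' @param spec [threshold_spec()].
#' @param node_ids optional 0-based ROI ids.
#' @return `binary_graph`.
#' @export
threshold_graph <- function(conn, spec = threshold_spec(),
                            node_ids = NULL) {
  stopifnot(inherits(conn, "conn_matrix"), inherits(spec, "threshold_spec"))
  if (conn$T_effective <= 3) {
    stop("T_effective must exceed 3 to standardize Fisher z", call. = FALSE)
  }
  zs <- conn$z * sqrt(conn$T_effective - 3)
  if (spec$positive_only) {
    p <- pnorm(zs, lower.tail = FALSE)
    A <- zs > spec$z_stat_threshold & p < spec$p_threshold
  } else {
    p <- 2 * pnorm(abs(zs), lower.tail = FALSE)
    A <- abs(zs) > spec$z_stat_threshold & p < spec$p_threshold
  }
  diag(A) <- FALSE
  binary_graph(A, node_ids)
}

#' Induced subgraph on a set of ROIs
#'
#' @param graph `binary_graph`.
#' @param node_ids 0-based ROI ids to keep (order preserved as in the
#'   graph).
#' @return `binary_graph` on the selected nodes.
#' @export
graph_subgraph <- function(graph, node_ids) {
  stopifnot(inherits(graph, "binary_graph"))
  keep <- which(graph$node_ids %in% node_ids)
  if (length(keep) == 0) stop("empty node subset", call. = FALSE)
  binary_graph(graph$adjacency[keep, keep, drop = FALSE],
               graph$node_ids[keep])
}

#' @noRd
adj_int <- function(graph) {
  A <- graph$adjacency * 1L
  storage.mode(A) <- "integer"
  A
}

#' All-pairs geodesic distances
#'
#' Breadth-first-search shortest-path lengths (edge counts) between all
#' node pairs; unreachable pairs are `Inf`.
#'
#' @param graph `binary_graph`.
#' @return N x N numeric matrix of distances.
#' @export
shortest_paths <- function(graph) {
  stopifnot(inherits(graph, "binary_graph"))
  d <- graph_distances_cpp(adj_int(graph))
  d[d < 0] <- Inf
  storage.mode(d) <- "double"
  d
}

METRIC_NAMES <- c("degree", "cost", "global_efficiency",
                  "local_efficiency", "betweenness", "path_length",
                  "clustering")

#' Seven nodal graph-theoretical metrics
#'
#' For every node: degree (neighbour count), cost (degree divided by
#' `n - 1`), global efficiency (mean inverse geodesic distance to all
#' other nodes, unreachable pairs contributing 0), local efficiency
#' (mean pairwise inverse distance inside the subgraph induced by the
#' node's neighbours; 0 when degree < 2), betweenness centrality
#' (Brandes' accumulation normalized by `(n-1)(n-2)/2`), average path
#' length (mean distance over reachable nodes; 0 for isolated nodes)
#' and clustering coefficient (fraction of neighbour pairs that are
#' connected; 0 when degree < 2).
#'
#' @param graph `binary_graph` with at least 2 nodes.
#' @return data.frame with `roi_id` and the seven metric columns.
#' @export
nodal_metrics <- function(graph) {
  stopifnot(inherits(graph, "binary_graph"))
  if (graph$n_nodes < 2) stop("need at least 2 nodes", call. = FALSE)
  m <- nodal_metrics_cpp(adj_int(graph))
  colnames(m) <- METRIC_NAMES
  # structural identity, asserted on every construction
  stopifnot(all(abs(m[, "cost"] - m[, "degree"] / (graph$n_nodes - 1)) <
                  1e-12))
  data.frame(roi_id = graph$node_ids, m)
}

#' Betweenness centrality alone
#'
#' @param graph `binary_graph`.
#' @param normalized divide by `(n-1)(n-2)/2` (default `TRUE`).
#' @return numeric vector, one value per node.
#' @export
betweenness_centrality <- function(graph, normalized = TRUE) {
  stopifnot(inherits(graph, "binary_graph"))
  b <- betweenness_raw_cpp(adj_int(graph))
  n <- graph$n_nodes
  if (normalized && n > 2) b <- b / ((n - 1) * (n - 2) / 2)
  b
}

#' Network-level summary of nodal metrics
#'
#' Unweighted mean of every metric over a node subset (a whole-brain,
#' hemispheric or lobar network).
#'
#' @param metrics data.frame from [nodal_metrics()].
#' @param node_subset 0-based ROI ids to average over; must be a
#'   non-empty subset of `metrics$roi_id`.
#' @param scope_label label carried into the output.
#' @return one-row data.frame: `scope`, `n_nodes`, then the seven
#'   metric means.
#' @export
network_summary <- function(metrics, node_subset = metrics$roi_id,
                            scope_label = "whole_brain") {
  if (length(node_subset) == 0) stop("empty node subset", call. = FALSE)
  if (!all(node_subset %in% metrics$roi_id)) {
    stop("node subset outside the metric table", call. = FALSE)
  }
  sub <- metrics[metrics$roi_id %in% node_subset, METRIC_NAMES]
  out <- as.data.frame(as.list(colMeans(sub)))
  cbind(data.frame(scope = scope_label, n_nodes = nrow(sub)), out)
}

#' Write / read a binary graph's adjacency as TSV
#'
#' @param graph `binary_graph`.
#' @param path file path.
#' @return `read_graph` returns a `binary_graph`.
#' @export
write_graph_tsv <- function(graph, path) {
  stopifnot(inherits(graph, "binary_graph"))
  df <- data.frame(roi_id = graph$node_ids, graph$adjacency * 1L,
                   check.names = FALSE)
  names(df) <- c("roi_id", graph$node_ids)
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_graph_tsv
#' @export
read_graph_tsv <- function(path) {
  df <- read_tsv(path)
  ids <- as.integer(df$roi_id)
  A <- as.matrix(df[, -1]) != 0
  dimnames(A) <- NULL
  binary_graph(A, ids)
}
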