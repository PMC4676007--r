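#' Percentile used throughout for graph construction and filtering
#'
#' Percentiles are computed by linear interpolation between order statistics
#' with plotting positions p(k) = k/(n+1) (R's `quantile` type 6), the
#' convention under which the 75th percentile of {0.1, ..., 0.6} is 0.525.
#'
#' @param x numeric vector.
#' @param p percentile in \[0, 100\].
#' @return the interpolated percentile.
#' @keywords internal
pctile <- function(x, p) quantile(x, p / 100, type = 6, names = FALSE)

#' Threshold a PLV matrix into a binary functional graph
#'
#' The threshold is the given percentile (default 75th) of the matrix's own
#' upper-triangle weight distribution; an edge is kept iff its weight is
#' strictly greater than the threshold, so degenerate all-equal matrices
#' yield an explicitly flagged empty graph rather than an arbitrary edge
#' subset. The diagonal is never an edge.
#'
#' @param plv_mat symmetric weight matrix (PLV in \[0, 1\]).
#' @param percentile default 75.
#' @param labels optional node labels (default matrix dimnames or 1..n).
#' @param window optional `c(start, end)` of the source window, seconds.
#' @return object of class `functional_graph`: list with `n_nodes`,
#'   `adjacency` (logical), `edges` (2-column matrix), `labels`,
#'   `threshold_used`, `degenerate`, `window`.
#' @export
threshold_graph <- function(plv_mat, percentile = 75, labels = NULL,
                            window = NULL) {
  plv_mat <- as.matrix(plv_mat)
  n <- nrow(plv_mat)
  if (n < 2) stop_plvnet("need at least 2 nodes", "plvnet_bad_graph")
  w <- plv_mat[upper.tri(plv_mat)]
  # percentile 0 is the keep-everything limit: every positive-weight pair
  thr <- if (percentile == 0) 0 else pctile(w, percentile)
  A <- plv_mat > thr
  A[lower.tri(A, diag = TRUE)] <- FALSE
  A <- A | t(A)
  degenerate <- all(w == w[1])
  labels <- labels %||% (rownames(plv_mat) %||% as.character(seq_len(n)))
  edges <- which(A & upper.tri(A), arr.ind = TRUE)
  dimnames(edges) <- NULL
  structure(list(n_nodes = n, adjacency = A, edges = edges, labels = labels,
                 threshold_used = thr, degenerate = degenerate,
                 window = window),
            class = "functional_graph")
}

#' Build a functional_graph directly from an adjacency matrix
#' @param A logical/0-1 symmetric adjacency matrix, zero diagonal.
#' @param labels optional node labels.
#' @return a `functional_graph`.
#' @export
graph_from_adjacency <- function(A, labels = NULL) {
  A <- as.matrix(A) != 0
  if (any(A != t(A)) || any(diag(A)))
    stop_plvnet("adjacency must be symmetric with empty diagonal",
                "plvnet_bad_graph")
  edges <- which(A & upper.tri(A), arr.ind = TRUE)
  dimnames(edges) <- NULL
  structure(list(n_nodes = nrow(A), adjacency = A, edges = edges,
                 labels = labels %||% as.character(seq_len(nrow(A))),
                 threshold_used = NA_real_, degenerate = FALSE,
                 window = NULL),
            class = "functional_graph")
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
}

#' @export
print.functional_graph <- function(x, ...) {
  cat(sprintf("<functional_graph> %d nodes, %d edges%s\n", x$n_nodes,
              nrow(x$edges), if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

n_edges <- function(g) nrow(g$edges)

graph_density <- function(g) {
  n <- g$n_nodes
  if (n < 2) return(0)
  n_edges(g) / (n * (n - 1) / 2)
}

#' Connectivity admissibility of a functional graph
#'
#' A graph is admissible when its largest connected component contains at
#' least 99% of the nodes (by ceiling, so for n <= 100 every node must be
#' connected).
#'
#' @param g a `functional_graph`.
#' @return logical flag.
#' @export
is_admissible_connectivity <- function(g) {
  comp <- igraph::components(as_igraph(g))
  max(comp$csize) >= ceiling(0.99 * g$n_nodes)
}

#' Remove ensemble outlier graphs
#'
#' Discards graphs lying outside the \[5th, 95th\] percentile of any of the
#' node-count, edge-count or density distributions computed over the
#' ensemble. Ensembles smaller than 20 are returned unchanged with a
#' warning. Removal counts per criterion are attached as attribute
#' `removed_counts`.
#'
#' @param ensemble list of `functional_graph` objects.
#' @return the filtered list (attributes `removed_counts`, `n_removed`).
#' @export
filter_outlier_graphs <- function(ensemble) {
  if (length(ensemble) < 20) {
    warning("ensemble smaller than 20 graphs: outlier filter skipped",
            call. = FALSE)
    attr(ensemble, "removed_counts") <- c(nodes = 0L, edges = 0L,
                                          density = 0L)
    attr(ensemble, "n_removed") <- 0L
    return(ensemble)
  }
  nodes <- vapply(ensemble, function(g) g$n_nodes, numeric(1))
  edges <- vapply(ensemble, n_edges, numeric(1))
  dens <- vapply(ensemble, graph_density, numeric(1))
  inside <- function(x) {
    lo <- pctile(x, 5); hi <- pctile(x, 95)
    x >= lo & x <= hi
  }
  ok_n <- inside(nodes); ok_e <- inside(edges); ok_d <- inside(dens)
  keep <- ok_n & ok_e & ok_d
  out <- ensemble[keep]
  attr(out, "removed_counts") <- c(nodes = sum(!ok_n), edges = sum(!ok_e),
                                   density = sum(!ok_d))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Clustering coefficient (binary undirected)
#'
#' `C_i = 2 t_i / (k_i (k_i - 1))` with `t_i` the number of triangles
#' through node i and `k_i` its degree; nodes with degree < 2 contribute 0,
#' and the network value is the mean over all nodes (the binary-undirected
#' toolbox convention).
#'
#' @param g a `functional_graph`.
#' @return list with `per_node` and `mean`.
#' @export
clustering_coefficient <- function(g) {
  per <- igraph::transitivity(as_igraph(g), type = "local",
                              isolates = "zero")
  list(per_node = per, mean = mean(per))
}

#' Characteristic path length (hops)
#'
#' Mean shortest-path length over all ordered pairs of distinct nodes,
#' excluding unreachable (infinite-distance) pairs from the mean; the count
#' of excluded pairs is reported. An edgeless graph has no defined L.
#'
#' @param g a `functional_graph`.
#' @return list with `L` (NA when undefined), `n_unreachable_pairs`
#'   (unordered pairs).
#' @export
characteristic_path_length <- function(g) {
  if (n_edges(g) == 0)
    return(list(L = NA_real_, n_unreachable_pairs = choose(g$n_nodes, 2)))
  d <- igraph::distances(as_igraph(g))
  d <- d[upper.tri(d)]
  list(L = mean(d[is.finite(d)]), n_unreachable_pairs = sum(!is.finite(d)))
}

#' Normalized betweenness centrality
#'
#' Brandes accumulation over shortest paths (via igraph), normalized by
#' `(n-1)(n-2)/2` so values lie in \[0, 1\].
#'
#' @param g a `functional_graph`.
#' @return numeric per-node vector.
#' @export
betweenness_centrality <- function(g) {
  as.numeric(igraph::betweenness(as_igraph(g), normalized = TRUE))
}

#' Per-graph statistics for a filtered ensemble
#'
#' Emits the per-window C and L samples consumed by the statistical layer,
#' plus bookkeeping columns. The ensemble is expected to have passed the
#' admissibility and outlier filters.
#'
#' @param ensemble non-empty list of `functional_graph` objects.
#' @return data.frame with columns `window_start`, `n_nodes`, `n_edges`,
#'   `density`, `C`, `L`, `admissible`.
#' @export
ensemble_stats <- function(ensemble) {
  if (length(ensemble) == 0)
    stop_plvnet("empty ensemble after filtering", "plvnet_empty_ensemble")
  do.call(rbind, lapply(ensemble, function(g) {
    data.frame(
      window_start = if (is.null(g$window)) NA_real_ else g$window[1],
      n_nodes = g$n_nodes, n_edges = n_edges(g), density = graph_density(g),
      C = clustering_coefficient(g)$mean,
      L = characteristic_path_length(g)$L,
      admissible = is_admissible_connectivity(g))
  }))
}
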