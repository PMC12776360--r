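#' Pairwise Euclidean distance matrix
#'
#' Distances between the rows of an embedding matrix; the basis of the
#' modality-internal similarity graphs.
#'
#' @param emb a [dti_embeddings] object or numeric matrix.
#' @return symmetric matrix with zero diagonal.
#' @export
pairwise_distances <- function(emb) {
  x <- if (inherits(emb, "dti_embeddings")) emb$values else as.matrix(emb)
  S <- as.matrix(stats::dist(x, method = "euclidean"))
  dimnames(S) <- NULL
  diag(S) <- 0
  S
}

#' Build a similarity graph by thresholded Euclidean distance
#'
#' Nodes are the entities of one modality; an (undirected) edge joins two
#' distinct entities whose embedding distance is at or below the threshold
#' tau. The threshold may be given as an absolute distance or as a percentile
#' of the off-diagonal distance distribution (percentile thresholds adapt to
#' the scale of the embedding provenance). Isolated nodes are retained.
#'
#' @param emb a [dti_embeddings] object or numeric matrix (>= 1 row).
#' @param threshold_spec either `list(absolute = tau)` or
#'   `list(percentile = pct)` with `pct` in (0, 100].
#' @return An object of class `similarity_graph`: list with `node_ids`,
#'   `edges` (2-column integer matrix, i < k), `distance_matrix`, `threshold`
#'   (resolved absolute value) and `threshold_spec`.
#' @export
build_graph <- function(emb, threshold_spec = list(percentile = 10)) {
  ids <- if (inherits(emb, "dti_embeddings")) emb$ids
         else as.character(seq_len(nrow(as.matrix(emb))))
  S <- pairwise_distances(emb)
  n <- nrow(S)
  off <- S[upper.tri(S)]
  if (!is.null(threshold_spec$absolute)) {
    tau <- threshold_spec$absolute
    stop_if(!is.finite(tau) || tau < 0, "absolute threshold must be >= 0")
  } else if (!is.null(threshold_spec$percentile)) {
    # target edge density: keep the k smallest pairwise distances as edges,
    # k = floor(pct% of all unordered pairs); pct -> 0 gives the empty graph,
    # pct = 100 the complete graph
    pct <- threshold_spec$percentile
    stop_if(!is.finite(pct) || pct <= 0 || pct > 100,
            "percentile must be in (0, 100]")
    k <- floor(pct / 100 * length(off))
    tau <- if (k >= 1L) sort(off, partial = k)[k] else -1
  } else {
    stop("threshold_spec must contain 'absolute' or 'percentile'", call. = FALSE)
  }
  edges <- which(upper.tri(S) & S <= tau, arr.ind = TRUE)
  edges <- matrix(as.integer(edges), ncol = 2L,
                  dimnames = list(NULL, c("i", "k")))
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  structure(list(node_ids = ids, edges = edges, distance_matrix = S,
                 threshold = tau, threshold_spec = threshold_spec),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  s <- graph_stats(x)
  cat(sprintf(
    "<similarity_graph> %d nodes, %d edges (tau = %.4g), mean degree %.2f, %d isolated\n",
    s$n_nodes, s$n_edges, x$threshold, s$mean_degree, s$n_isolated))
  invisible(x)
}

#' Summary statistics of a similarity graph
#'
#' @param g a `similarity_graph`.
#' @return list with `n_nodes`, `n_edges`, `mean_degree`, `n_isolated`.
#' @export
graph_stats <- function(g) {
  stopifnot(inherits(g, "similarity_graph"))
  n <- length(g$node_ids)
  deg <- tabulate(c(g$edges[, 1L], g$edges[, 2L]), nbins = n)
  list(n_nodes = n, n_edges = nrow(g$edges),
       mean_degree = if (n) mean(deg) else 0,
       n_isolated = sum(deg == 0L))
}

#' Export a graph's edge list as text
#'
#' Writes `i<TAB>k<TAB>distance` rows (1-based node indices) for inspection.
#'
#' @param g a `similarity_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  d <- g$distance_matrix[g$edges]
  utils::write.table(data.frame(i = g$edges[, 1L], k = g$edges[, 2L],
                                distance = d),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# dense symmetric {0,1} adjacency (no self loops)
graph_adjacency <- function(g) {
  n <- length(g$node_ids)
  A <- matrix(0, n, n)
  if (nrow(g$edges)) {
    A[g$edges] <- 1
    A[g$edges[, c(2L, 1L), drop = FALSE]] <- 1
  }
  A
}

# symmetric-normalised adjacency with self loops, for the GCN-based
# cross-neighborhood selection networks
gcn_adjacency <- function(g) {
  A <- graph_adjacency(g)
  diag(A) <- 1
  dg <- 1 / sqrt(rowSums(A))
  A * outer(dg, dg)
}
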