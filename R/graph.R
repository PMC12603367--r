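# Ordered residue contact graphs: epsilon-neighborhood over CA-CA
# distances, optional radial-basis distance edge features, perturbation
# modes, and single-node relabelling for variant scoring.

#' Contact-graph construction parameters
#'
#' @param threshold Distance threshold in Angstrom; residues at most this
#'   far apart are connected.  Default 8.0, the range within which most
#'   local inter-residue interactions occur.
#' @param edge_features If `TRUE`, each edge carries a Gaussian
#'   radial-basis expansion of its distance.
#' @param rbf_centers Number of radial-basis centers (feature dimension).
#' @param rbf_min,rbf_max Range over which centers are evenly spaced;
#'   default `[0, threshold]`.  Width equals the center spacing.
#' @return A `graph_config` list.
#' @export
graph_config <- function(threshold = 8.0, edge_features = FALSE,
                         rbf_centers = 16L, rbf_min = 0, rbf_max = threshold) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  rbf_centers <- as.integer(rbf_centers)
  if (rbf_centers < 1L) stop("rbf_centers must be >= 1", call. = FALSE)
  structure(list(threshold = threshold, edge_features = isTRUE(edge_features),
                 rbf_centers = rbf_centers, rbf_min = rbf_min, rbf_max = rbf_max),
            class = "graph_config")
}

rbf_expand <- function(d, config) {
  k <- config$rbf_centers
  centers <- seq(config$rbf_min, config$rbf_max, length.out = k)
  width <- if (k > 1L) centers[2L] - centers[1L] else max(config$rbf_max - config$rbf_min, 1)
  out <- exp(-((outer(d, centers, "-"))^2) / (2 * width^2))
  dimnames(out) <- NULL
  out
}

new_protein_graph <- function(n_nodes, node_labels, edges, edge_dist,
                              edge_feats, config, protein_id) {
  structure(list(n_nodes = as.integer(n_nodes), node_labels = node_labels,
                 edges = edges, edge_dist = edge_dist, edge_feats = edge_feats,
                 config = config, protein_id = protein_id),
            class = "protein_graph")
}

#' @export
print.protein_graph <- function(x, ...) {
  cat(sprintf("<protein_graph> %s: %d nodes, %d edges (threshold %.1f A)\n",
              x$protein_id %||% "?", x$n_nodes, nrow(x$edges), x$config$threshold))
  invisible(x)
}

#' Build the ordered residue contact graph of a structure
#'
#' Connects residues `i != j` whose representative-atom (CA) Euclidean
#' distance is at most `config$threshold`.  Node order encodes sequence
#' order and nodes carry amino-acid labels; edges are unordered pairs
#' stored with `i < j` (1-based).  With `config$edge_features = TRUE` each
#' edge carries the radial-basis expansion of its distance.
#'
#' @param structure A [protein_structure()].
#' @param config A [graph_config()].
#' @return A `protein_graph`.
#' @export
#' @examples
#' g <- build_graph(make_chain("helix", 12, seed = 1))
#' g$config$threshold
build_graph <- function(structure, config = graph_config()) {
  stopifnot(inherits(structure, "protein_structure"),
            inherits(config, "graph_config"))
  n <- nrow(structure$coords)
  D <- as.matrix(dist(structure$coords))
  keep <- which(upper.tri(D) & D <= config$threshold, arr.ind = TRUE)
  edges <- keep[order(keep[, 1L], keep[, 2L]), , drop = FALSE]
  dimnames(edges) <- list(NULL, c("i", "j"))
  edge_dist <- D[edges]
  edge_feats <- if (config$edge_features && nrow(edges) > 0L) {
    rbf_expand(edge_dist, config)
  } else if (config$edge_features) {
    matrix(0, 0L, config$rbf_centers)
  } else NULL
  new_protein_graph(n, structure$sequence, edges, edge_dist, edge_feats,
                    config, structure$id)
}

all_pairs <- function(n) {
  if (n < 2L) return(matrix(integer(), 0L, 2L, dimnames = list(NULL, c("i", "j"))))
  p <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p <- p[order(p[, 1L], p[, 2L]), , drop = FALSE]
  dimnames(p) <- list(NULL, c("i", "j"))
  p
}

#' Perturb a contact graph to destroy structural information
#'
#' Ablation modes that keep the node set (and hence parameter count) while
#' eliminating secondary/tertiary structure: `sequential_only` keeps
#' exactly the chain edges `(i, i+1)`; `fully_connected` returns all
#' `n(n-1)/2` pairs; `rewired` samples, under `seed`, a uniform simple
#' graph with the same edge count as the input (no self-loops, no
#' duplicates).  Distance edge features are dropped: the perturbed
#' topology no longer corresponds to the geometry.
#'
#' @param graph A `protein_graph`.
#' @param mode One of `"sequential_only"`, `"rewired"`, `"fully_connected"`.
#' @param seed Integer seed (used by `rewired`).
#' @return A `protein_graph` with the perturbed edge set.
#' @export
perturb_graph <- function(graph, mode = c("sequential_only", "rewired", "fully_connected"),
                          seed = 1L) {
  stopifnot(inherits(graph, "protein_graph"))
  mode <- match.arg(mode)
  n <- graph$n_nodes
  edges <- switch(mode,
    sequential_only = {
      if (n < 2L) all_pairs(n) else
        matrix(c(seq_len(n - 1L), seq.int(2L, n)), ncol = 2L,
               dimnames = list(NULL, c("i", "j")))
    },
    fully_connected = all_pairs(n),
    rewired = {
      pool <- all_pairs(n)
      m <- nrow(graph$edges)
      if (m > nrow(pool)) stop("edge count exceeds n(n-1)/2", call. = FALSE)
      pick <- withr::with_seed(seed, sort(sample.int(nrow(pool), m)))
      pool[pick, , drop = FALSE]
    })
  out <- new_protein_graph(n, graph$node_labels, edges, edge_dist = NULL,
                           edge_feats = NULL, config = graph$config,
                           protein_id = graph$protein_id)
  out$perturbation <- mode
  out
}

#' Relabel one node of a contact graph (point mutation)
#'
#' Swaps the amino-acid identity at a mutated position in the graph while
#' leaving edges, distances and features untouched (the mutant keeps the
#' wild-type geometry).
#'
#' @param graph A `protein_graph`.
#' @param position 1-based residue position.
#' @param wt Expected wild-type one-letter code at `position`.
#' @param mut Replacement one-letter code.
#' @return A copy of `graph` with the single node relabelled.
#' @export
mutate_node <- function(graph, position, wt, mut) {
  stopifnot(inherits(graph, "protein_graph"))
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > graph$n_nodes) {
    stop(sprintf("position %d out of range [1, %d]", position, graph$n_nodes),
         call. = FALSE)
  }
  if (graph$node_labels[position] != wt) {
    stop(sprintf("wildtype mismatch at position %d: graph has '%s', variant states '%s'",
                 position, graph$node_labels[position], wt), call. = FALSE)
  }
  graph$node_labels[position] <- mut
  graph
}

#' Write a graph as a documented JSON archive
#'
#' Stores the node-label array, the edge index expanded to both directions
#' (2 x 2m), the optional edge-feature matrix (rows duplicated to match),
#' and a metadata block recording threshold and conventions.
#'
#' @param graph A `protein_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graph_archive <- function(graph, path) {
  m <- nrow(graph$edges)
  edge_index <- if (m > 0L) {
    rbind(c(graph$edges[, 1L], graph$edges[, 2L]),
          c(graph$edges[, 2L], graph$edges[, 1L]))
  } else matrix(integer(), 2L, 0L)
  feats <- if (!is.null(graph$edge_feats) && m > 0L) {
    rbind(graph$edge_feats, graph$edge_feats)
  } else NULL
  jsonlite::write_json(list(
    metadata = list(format = "pst-graph", version = 1L,
                    protein_id = graph$protein_id,
                    n_nodes = graph$n_nodes,
                    threshold = graph$config$threshold,
                    representative_atom = "CA",
                    indexing = "1-based",
                    perturbation = graph$perturbation %||% "none"),
    node_labels = graph$node_labels,
    edge_index = edge_index,
    edge_features = feats
  ), path, digits = I(17), auto_unbox = TRUE, null = "null", matrix = "rowmajor")
  invisible(path)
}
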