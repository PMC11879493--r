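#' Load and filter a STRING-style PPI edge list
#'
#' Reads a TSV with two node columns and a combined-score column. Scores on
#' the 0-1000 export scale are autodetected (any score > 1) and rescaled to
#' 0-1 with a message. Edges below `min_score` are dropped (the >= rule),
#' self-loops are removed (counted), and duplicate undirected edges are
#' collapsed keeping the maximum score.
#'
#' @param path TSV file; first two columns are node ids, the score column
#'   is named `combined_score` or `score` (else the third column is used).
#' @param min_score Minimum retained interaction score (default 0.18).
#' @return Object of class `edge_list`: data frame `node_a`, `node_b`,
#'   `score`; attributes `n_self_loops`, `n_below_threshold`, `rescaled`.
#' @export
load_edges <- function(path, min_score = 0.18) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop_config("edge list needs two node columns + score")
  score_col <- intersect(c("combined_score", "score"), names(tab))
  score_col <- if (length(score_col)) score_col[1] else names(tab)[3]
  edges <- data.frame(node_a = as.character(tab[[1]]),
                      node_b = as.character(tab[[2]]),
                      score = as.numeric(tab[[score_col]]),
                      stringsAsFactors = FALSE)
  filter_edges(edges, min_score)
}

# shared by load_edges() and in-memory edge frames
filter_edges <- function(edges, min_score = 0.18) {
  if (anyNA(edges$score) || any(edges$score < 0))
    stop_config("scores must be numeric and >= 0")
  rescaled <- FALSE
  if (any(edges$score > 1)) {
    if (any(edges$score > 1000)) stop_config("scores outside [0, 1000]")
    edges$score <- edges$score / 1000
    rescaled <- TRUE
    message("edge scores look like the 0-1000 export scale; rescaled to 0-1")
  }
  self <- edges$node_a == edges$node_b
  n_self <- sum(self)
  edges <- edges[!self, , drop = FALSE]
  below <- edges$score < min_score
  n_below <- sum(below)
  edges <- edges[!below, , drop = FALSE]
  # canonical undirected order, dedup keeping max score
  a <- pmin(edges$node_a, edges$node_b)
  b <- pmax(edges$node_a, edges$node_b)
  key <- paste(a, b, sep = "\r")
  ord <- order(key, -edges$score)
  keep <- !duplicated(key[ord])
  out <- data.frame(node_a = a[ord][keep], node_b = b[ord][keep],
                    score = edges$score[ord][keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_self_loops") <- n_self
  attr(out, "n_below_threshold") <- n_below
  attr(out, "rescaled") <- rescaled
  class(out) <- c("edge_list", class(out))
  out
}

#' Build an undirected simple PPI graph from a filtered edge list
#'
#' @param edges An [load_edges()] `edge_list` (or compatible data frame).
#' @param nodes Optional full candidate node set; ids absent from the edge
#'   list become isolated vertices.
#' @return An igraph undirected simple graph.
#' @export
build_ppi_graph <- function(edges, nodes = NULL) {
  g <- igraph::graph_from_data_frame(
    edges[, c("node_a", "node_b")], directed = FALSE,
    vertices = if (is.null(nodes)) NULL else unique(as.character(nodes))
  )
  igraph::simplify(g)
}

#' Connected components of a PPI graph
#'
#' @param graph An igraph graph from [build_ppi_graph()].
#' @return List with `membership` (named component id per node), `sizes`
#'   (descending), `n_components`, `n_isolated` (degree-0 nodes).
#' @export
ppi_components <- function(graph) {
  comp <- igraph::components(graph)
  sizes <- sort(comp$csize, decreasing = TRUE)
  list(membership = comp$membership,
       sizes = sizes,
       n_components = comp$no,
       n_isolated = sum(igraph::degree(graph) == 0))
}

#' Degree and key-hub classification
#'
#' A node is a key hub when it interacts with more than `hub_threshold`
#' other nodes (strict inequality: degree > 10 means >= 11 links).
#'
#' @param graph An igraph graph.
#' @param hub_threshold Degree above which a node is a key hub (default 10).
#' @return Data frame `node`, `degree`, `is_key_hub`, sorted by descending
#'   degree then node id.
#' @export
hubs <- function(graph, hub_threshold = 10) {
  deg <- igraph::degree(graph)
  out <- data.frame(node = names(deg), degree = as.integer(deg),
                    is_key_hub = deg > hub_threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node), ]
  rownames(out) <- NULL
  out
}

#' Random even chunking of a node set under a size cap
#'
#' Splits n nodes into k = ceiling(n / max_size) groups whose sizes differ
#' by at most one, with random (seeded) assignment — the workflow used when
#' an external PPI service caps the query size.
#'
#' @param nodes Character vector of node ids.
#' @param max_size Maximum group size (default 2000).
#' @param seed Integer seed, or `NULL`.
#' @return Named integer vector: group id (1..k) per node.
#' @examples
#' table(chunk_nodes(sprintf("g%04d", 1:7837), 2000, seed = 1))
#' @export
chunk_nodes <- function(nodes, max_size = 2000, seed = NULL) {
  check_number(max_size, "max_size", min = 1, integer = TRUE)
  n <- length(nodes)
  k <- ceiling(n / max_size)
  base <- n %/% k
  sizes <- rep(base, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- base + 1
  with_seed(seed, {
    perm <- sample.int(n)
    grp <- rep(seq_len(k), times = sizes)
    setNames(grp[order(perm)], nodes)
  })
}

#' Top-k hubs per group and their meta-network
#'
#' From each group's degree table, selects the `k` highest-degree nodes
#' including every node tied with the k-th (so a tie at the boundary can
#' yield more than k per group), then builds the induced subgraph among all
#' selected hubs from the full edge list.
#'
#' @param group_hubs List of per-group [hubs()] data frames.
#' @param edges The full `edge_list` (all groups).
#' @param k Hubs per group before tie inclusion (default 5).
#' @return List with `hubs` (data frame `node`, `degree`, `group`),
#'   `meta_graph` (igraph induced subgraph), `n_meta_edges`.
#' @export
top_hubs_meta <- function(group_hubs, edges, k = 5) {
  check_number(k, "k", min = 1, integer = TRUE)
  sel <- lapply(seq_along(group_hubs), function(gi) {
    h <- group_hubs[[gi]]
    h <- h[order(-h$degree, h$node), , drop = FALSE]
    if (nrow(h) <= k) {
      warning(sprintf("group %d has only %d nodes (<= k)", gi, nrow(h)))
      take <- nrow(h)
    } else {
      kth <- h$degree[k]
      take <- sum(h$degree >= kth) # include ties at the k-th rank
    }
    cbind(h[seq_len(take), c("node", "degree")], group = gi)
  })
  hub_tab <- do.call(rbind, sel)
  rownames(hub_tab) <- NULL
  sub <- edges[edges$node_a %in% hub_tab$node &
                 edges$node_b %in% hub_tab$node, , drop = FALSE]
  meta <- build_ppi_graph(sub, nodes = hub_tab$node)
  list(hubs = hub_tab, meta_graph = meta,
       n_meta_edges = igraph::ecount(meta))
}
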