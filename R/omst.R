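#' Construct a weighted graph from a connectivity matrix
#'
#' Weights are coherence-like (larger = stronger); the edge distance
#' convention throughout is `d = 1/w` for `w > 0`, with zero-weight
#' pairs treated as absent edges.
#'
#' @param weights Symmetric nonnegative matrix with zero diagonal, or a
#'   `connectivity_matrix`.
#' @param labels Node labels (defaults to dimnames or V1..Vn).
#' @return A `weighted_graph` with elements `weights`, `labels`.
#' @export
weighted_graph <- function(weights, labels = NULL) {
  if (inherits(weights, "connectivity_matrix")) {
    labels <- weights$labels
    weights <- weights$weights
  }
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(weights))) rownames(weights)
              else paste0("V", seq_len(n))
  }
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 1e-8))) {
    stop("`weights` must be symmetric", call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights < 0)) {
    stop("`weights` must be finite and nonnegative", call. = FALSE)
  }
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, labels = labels), class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("<weighted_graph> %d nodes, %d edges\n",
              length(x$labels), sum(x$weights[upper.tri(x$weights)] > 0)))
  invisible(x)
}

as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# edge table sorted for deterministic Kruskal: by distance (1/w), then
# lexicographically by label pair
sorted_edge_table <- function(graph) {
  w <- graph$weights
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (nrow(ut) == 0L) {
    return(tibble::tibble(i = integer(), j = integer(), weight = numeric()))
  }
  lab_i <- graph$labels[ut[, 1L]]
  lab_j <- graph$labels[ut[, 2L]]
  swap <- lab_j < lab_i
  a <- ifelse(swap, lab_j, lab_i); b <- ifelse(swap, lab_i, lab_j)
  ord <- order(-w[ut], a, b, method = "radix")
  tibble::tibble(i = ut[ord, 1L], j = ut[ord, 2L], weight = w[ut][ord])
}

# union-find
uf_find <- function(parent, x) {
  while (parent[x] != x) x <- parent[x]
  x
}

kruskal_mst <- function(n, edges) {
  parent <- seq_len(n)
  picked <- integer(0)
  for (r in seq_len(nrow(edges))) {
    ri <- uf_find(parent, edges$i[r]); rj <- uf_find(parent, edges$j[r])
    if (ri != rj) {
      parent[ri] <- rj
      picked <- c(picked, r)
      if (length(picked) == n - 1L) break
    }
  }
  picked
}

#' Maximum-weight (minimum-distance) spanning tree
#'
#' Kruskal's algorithm on edge distances `1/w` — equivalently, keep the
#' strongest edges that span all nodes without cycles. Equal-weight
#' edges are broken lexicographically by label pair so results are
#' reproducible across platforms.
#'
#' @param graph A [weighted_graph()] connected under nonzero weights.
#' @return Tibble of tree edges: `from`, `to`, `weight`; exactly
#'   `n - 1` rows.
#' @export
max_weight_mst <- function(graph) {
  stopifnot(inherits(graph, "weighted_graph"))
  n <- length(graph$labels)
  comp <- igraph::components(as_igraph(graph))
  if (comp$no > 1L) {
    sizes <- table(comp$membership)
    stop("graph is disconnected (", comp$no, " components of sizes ",
         paste(sizes, collapse = ", "), ")", call. = FALSE)
  }
  edges <- sorted_edge_table(graph)
  picked <- kruskal_mst(n, edges)
  tibble::tibble(from = graph$labels[edges$i[picked]],
                 to = graph$labels[edges$j[picked]],
                 weight = edges$weight[picked])
}

# remove an edge set (tibble from/to) from a graph
drop_edges <- function(graph, edge_tbl) {
  w <- graph$weights
  ii <- match(edge_tbl$from, graph$labels)
  jj <- match(edge_tbl$to, graph$labels)
  w[cbind(ii, jj)] <- 0
  w[cbind(jj, ii)] <- 0
  weighted_graph(w, graph$labels)
}

#' Successive edge-disjoint ("orthogonal") spanning trees
#'
#' Round `r` computes an MST on the graph with the edges of rounds
#' `1..r-1` removed; returns up to `m` pairwise edge-disjoint trees,
#' stopping early when the residual graph no longer spans all nodes.
#'
#' @param graph A connected [weighted_graph()].
#' @param m Maximum number of rounds (>= 1).
#' @return List of edge tibbles (each a spanning tree).
#' @export
orthogonal_msts <- function(graph, m) {
  stopifnot(inherits(graph, "weighted_graph"))
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  trees <- list()
  residual <- graph
  for (r in seq_len(m)) {
    ig <- as_igraph(residual)
    if (igraph::components(ig)$no > 1L) break
    trees[[r]] <- max_weight_mst(residual)
    residual <- drop_edges(residual, trees[[r]])
  }
  trees
}

#' Global cost efficiency of an edge selection
#'
#' Cost is the selected fraction of total connection weight. Global
#' efficiency of a weighted graph is the mean over ordered node pairs
#' of `1/d_ij` (shortest paths on `1/w` edge lengths; unreachable pairs
#' contribute 0); `ge` is reported relative to the full graph —
#' `GE(selection) / GE(original)` — so that selecting every edge gives
#' `ge = 1` at `cost = 1`, and `J = ge - cost` is the quantity the OMST
#' selection maximises.
#'
#' @param edges Edge tibble (`from`, `to`) selected from `original`.
#' @param original The full [weighted_graph()] the selection came from.
#' @return A one-row tibble: `cost`, `ge`, `J`.
#' @export
global_cost_efficiency <- function(edges, original) {
  stopifnot(inherits(original, "weighted_graph"))
  w_all <- sum(original$weights[upper.tri(original$weights)])
  n <- length(original$labels)
  if (nrow(edges) == 0L) {
    return(tibble::tibble(cost = 0, ge = 0, J = 0))
  }
  ii <- match(edges$from, original$labels)
  jj <- match(edges$to, original$labels)
  wsel <- original$weights[cbind(ii, jj)]
  cost <- sum(wsel) / w_all
  sel <- matrix(0, n, n, dimnames = list(original$labels, original$labels))
  sel[cbind(ii, jj)] <- wsel
  sel[cbind(jj, ii)] <- wsel
  ge_full <- raw_global_efficiency(original$weights)
  ge <- raw_global_efficiency(sel) / ge_full
  tibble::tibble(cost = cost, ge = ge, J = ge - cost)
}

# mean over ordered node pairs of 1/d_ij on a weight matrix
raw_global_efficiency <- function(w) {
  n <- nrow(w)
  ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  if (igraph::ecount(ig) == 0L) return(0)
  d <- igraph::distances(ig, weights = 1 / igraph::E(ig)$weight)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' OMST thresholding: keep the tree union maximising global cost efficiency
#'
#' Computes cumulative unions of edge-disjoint spanning trees and, after
#' each round, the global cost efficiency `J = GE - Cost`; the selection
#' is the cumulative union at the maximum `J` (ties broken toward fewer
#' rounds). By default rounds are capped at `floor((n-1)/2)` and the
#' scan stops early after 3 consecutive decreases of `J`; set
#' `exhaustive = TRUE` to evaluate every feasible round.
#'
#' @param graph A connected [weighted_graph()].
#' @param max_rounds Cap on rounds (default `floor((n-1)/2)`).
#' @param exhaustive Evaluate all feasible rounds (no cap, no early
#'   stop).
#' @return An `omst_selection`: `mst_rounds` (list of edge tibbles),
#'   `m_star`, `gce_curve` (tibble m/cost/ge/J), `thresholded`
#'   (a [weighted_graph()] with exactly the selected edges at original
#'   weights).
#' @export
select_omst <- function(graph, max_rounds = NULL, exhaustive = FALSE) {
  stopifnot(inherits(graph, "weighted_graph"))
  n <- length(graph$labels)
  comp <- igraph::components(as_igraph(graph))
  if (comp$no > 1L) stop("graph is disconnected; OMST needs a connected graph",
                         call. = FALSE)
  cap <- if (exhaustive) .Machine$integer.max
         else if (!is.null(max_rounds)) max_rounds
         else max(1L, floor((n - 1) / 2))
  trees <- list()
  residual <- graph
  curve <- list()
  cum_edges <- tibble::tibble(from = character(), to = character(),
                              weight = numeric())
  best_J <- -Inf; m_star <- 0L
  decreases <- 0L; last_J <- -Inf
  r <- 0L
  while (r < cap) {
    ig <- as_igraph(residual)
    if (igraph::components(ig)$no > 1L) break
    r <- r + 1L
    trees[[r]] <- max_weight_mst(residual)
    residual <- drop_edges(residual, trees[[r]])
    cum_edges <- dplyr::bind_rows(cum_edges, trees[[r]])
    gce <- global_cost_efficiency(cum_edges, graph)
    curve[[r]] <- dplyr::mutate(gce, m = r, .before = 1L)
    if (gce$J > best_J) { best_J <- gce$J; m_star <- r }
    if (gce$J < last_J) decreases <- decreases + 1L else decreases <- 0L
    last_J <- gce$J
    if (!exhaustive && decreases >= 3L) break
  }
  if (m_star == 0L) stop("no spanning tree round could be computed", call. = FALSE)
  sel_edges <- dplyr::bind_rows(trees[seq_len(m_star)])
  ii <- match(sel_edges$from, graph$labels)
  jj <- match(sel_edges$to, graph$labels)
  w <- matrix(0, n, n, dimnames = list(graph$labels, graph$labels))
  w[cbind(ii, jj)] <- sel_edges$weight
  w[cbind(jj, ii)] <- sel_edges$weight
  structure(
    list(mst_rounds = trees, m_star = m_star,
         gce_curve = dplyr::bind_rows(curve),
         thresholded = weighted_graph(w, graph$labels)),
    class = "omst_selection"
  )
}

#' @export
print.omst_selection <- function(x, ...) {
  cat(sprintf("<omst_selection> m* = %d of %d rounds, J = %.4f (cost %.3f, GE %.3f)\n",
              x$m_star, nrow(x$gce_curve),
              x$gce_curve$J[x$m_star], x$gce_curve$cost[x$m_star],
              x$gce_curve$ge[x$m_star]))
  invisible(x)
}

#' Write an OMST selection: thresholded matrix CSV + GCE-curve TSV
#'
#' @param selection An `omst_selection`.
#' @param path Output CSV path for the thresholded matrix; the curve is
#'   written next to it with suffix `_gce.tsv`.
#' @return `path`, invisibly.
#' @export
write_omst <- function(selection, path) {
  stopifnot(inherits(selection, "omst_selection"))
  g <- selection$thresholded
  utils::write.csv(cbind(channel = g$labels, as.data.frame(g$weights)),
                   path, row.names = FALSE)
  utils::write.table(selection$gce_curve,
                     sub("\\.csv$", "_gce.tsv", path),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
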