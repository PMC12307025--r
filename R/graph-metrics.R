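#' Rescale graph weights to [0, 1]
#'
#' Divides every weight by the maximum weight so the strongest edge is
#' exactly 1 and zeros are preserved. All downstream segregation and
#' integration indices are computed on normalised weights, which makes
#' them invariant to any positive rescaling of the raw connectivity.
#'
#' @param graph A [weighted_graph()] with at least one positive weight.
#' @return A [weighted_graph()] with max weight 1.
#' @export
normalize_weights <- function(graph) {
  stopifnot(inherits(graph, "weighted_graph"))
  mx <- max(graph$weights)
  if (mx <= 0) stop("all weights are zero; nothing to normalise", call. = FALSE)
  weighted_graph(graph$weights / mx, graph$labels)
}

#' Weighted clustering coefficient (Onnela form)
#'
#' Per node, the geometric mean of triangle weights:
#' `C_i = (1 / (k_i (k_i - 1))) * sum_{j,h} (w_ij w_ih w_jh)^{1/3}`
#' with binary degree `k_i`. Nodes with degree < 2 cannot close a
#' triangle and are excluded from the mean (undefined, not 0). The mean
#' is missing (`NA`) only when no node has degree >= 2; a tree, where
#' every defined node has `C_i = 0`, yields 0, not missing.
#'
#' @param graph A normalised [weighted_graph()].
#' @return List: `per_node` (named vector, `NA` for degree < 2 nodes),
#'   `mean` (scalar or `NA`).
#' @export
clustering_coefficient <- function(graph) {
  stopifnot(inherits(graph, "weighted_graph"))
  w <- graph$weights
  k <- rowSums(w > 0)
  w3 <- w^(1 / 3)
  tri <- diag(w3 %*% w3 %*% w3)        # sum over j,h of (w_ij w_jh w_hi)^(1/3)
  per_node <- ifelse(k >= 2, tri / (k * (k - 1)), NA_real_)
  names(per_node) <- graph$labels
  defined <- !is.na(per_node)
  list(per_node = per_node,
       mean = if (any(defined)) mean(per_node[defined]) else NA_real_)
}

# all set partitions of 1..n (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  grow <- function(assign, maxc) {
    i <- length(assign) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- assign; return(invisible()) }
    for (c in seq_len(maxc + 1L)) grow(c(assign, c), max(maxc, c))
  }
  grow(integer(0), 0L)
  out
}

newman_q <- function(w, membership) {
  m2 <- sum(w)                       # 2m for an undirected weight matrix
  s <- rowSums(w)
  same <- outer(membership, membership, "==")
  sum((w - outer(s, s) / m2) * same) / m2
}

#' Weighted modularity via community detection
#'
#' Maximises the weighted Newman modularity
#' `Q = (1/2m) sum_ij (w_ij - s_i s_j / 2m) delta(c_i, c_j)`.
#' For graphs of up to `exact_max_n` nodes the optimum is found by
#' exhaustive search over all partitions (exact); larger graphs use
#' Louvain with `restarts` random vertex-order restarts, keeping the
#' best Q. Deterministic for a fixed seed.
#'
#' @param graph A [weighted_graph()] with positive total weight.
#' @param restarts Louvain restarts.
#' @param seed Integer seed for the restart permutations.
#' @param exact_max_n Largest node count solved exactly.
#' @return List: `Q`, `partition` (named membership vector), `method`.
#' @export
modularity <- function(graph, restarts = 20, seed = 1, exact_max_n = 8) {
  stopifnot(inherits(graph, "weighted_graph"))
  w <- graph$weights
  if (sum(w) <= 0) stop("all weights are zero; modularity undefined", call. = FALSE)
  n <- length(graph$labels)
  if (n <= exact_max_n) {
    parts <- all_partitions(n)
    qs <- vapply(parts, function(p) newman_q(w, p), numeric(1))
    best <- which.max(qs)
    memb <- stats::setNames(parts[[best]], graph$labels)
    return(list(Q = qs[best], partition = memb, method = "exact"))
  }
  ig <- as_igraph(graph)
  best_q <- -Inf; best_memb <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      perm <- sample.int(n)
      igp <- igraph::permute(ig, perm)
      cl <- igraph::cluster_louvain(igp, weights = igraph::E(igp)$weight)
      memb <- igraph::membership(cl)[perm]     # back to original order
      q <- newman_q(w, as.integer(memb))
      if (q > best_q) { best_q <- q; best_memb <- as.integer(memb) }
    }
  })
  list(Q = best_q, partition = stats::setNames(best_memb, graph$labels),
       method = "louvain")
}

#' Weighted global efficiency
#'
#' Mean over ordered node pairs of `1/d_ij`, with `d_ij` the weighted
#' shortest-path distance on `1/w` edge lengths; unreachable pairs
#' contribute 0.
#'
#' @param graph A [weighted_graph()].
#' @return A scalar in `[0, max(w)]`.
#' @export
global_efficiency <- function(graph) {
  stopifnot(inherits(graph, "weighted_graph"))
  raw_global_efficiency(graph$weights)
}

#' Weighted characteristic path length
#'
#' Mean over ordered node pairs of the weighted shortest-path distance
#' with edge length `1/w`. Missing (`NA`) when the graph is
#' disconnected — the estimand is not silently switched to an
#' efficiency-style substitute.
#'
#' @param graph A normalised [weighted_graph()].
#' @return Scalar, or `NA` for disconnected graphs.
#' @export
characteristic_path_length <- function(graph) {
  stopifnot(inherits(graph, "weighted_graph"))
  ig <- as_igraph(graph)
  if (igraph::components(ig)$no > 1L) return(NA_real_)
  d <- igraph::distances(ig, weights = 1 / igraph::E(ig)$weight)
  mean(d[upper.tri(d) | lower.tri(d)])
}

# one degree-preserving surrogate: rewire the binary topology keeping
# the degree sequence, then shuffle the original weights among edges
rewired_surrogate <- function(graph) {
  ig <- as_igraph(graph)
  ne <- igraph::ecount(ig)
  rw <- igraph::rewire(ig, igraph::keeping_degseq(niter = 10 * ne))
  el <- igraph::as_edgelist(rw, names = FALSE)
  wts <- sample(igraph::E(ig)$weight)
  n <- length(graph$labels)
  w <- matrix(0, n, n, dimnames = list(graph$labels, graph$labels))
  w[el] <- wts
  w[el[, c(2L, 1L), drop = FALSE]] <- wts
  weighted_graph(w, graph$labels)
}

#' Small-world index
#'
#' `sigma = (C / C_null) / (L / L_null)`, where `C_null` and `L_null`
#' are the mean clustering coefficient and characteristic path length
#' over `n_null` degree-preserving rewired surrogates with weights
#' shuffled among edges. Values above 1 indicate small-world
#' organisation. Missing (`NA`) when the graph's own C or L is missing
#' or zero — e.g. on trees, whose clustering is 0 — or when any
#' surrogate statistic is missing or zero.
#'
#' @param graph A normalised [weighted_graph()].
#' @param n_null Number of surrogates (>= 1).
#' @param seed Integer seed.
#' @return List: `sigma` (scalar or `NA`), `C`, `L`, `C_null`, `L_null`,
#'   `null_sd_sigma` (SD of per-surrogate sigma-style ratios), `n_null`.
#' @export
small_world_index <- function(graph, n_null = 50, seed = 1) {
  stopifnot(inherits(graph, "weighted_graph"))
  if (n_null < 1) stop("`n_null` must be >= 1", call. = FALSE)
  C <- clustering_coefficient(graph)$mean
  L <- characteristic_path_length(graph)
  out <- list(sigma = NA_real_, C = C, L = L, C_null = NA_real_,
              L_null = NA_real_, null_sd_sigma = NA_real_, n_null = n_null)
  if (is.na(C) || is.na(L) || C == 0 || L == 0) return(out)
  cn <- numeric(n_null); ln <- numeric(n_null)
  with_seed(seed, {
    for (s in seq_len(n_null)) {
      sg <- rewired_surrogate(graph)
      cn[s] <- clustering_coefficient(sg)$mean
      ln[s] <- characteristic_path_length(sg)
    }
  })
  if (anyNA(cn) || anyNA(ln) || any(cn == 0) || any(ln == 0)) return(out)
  out$C_null <- mean(cn); out$L_null <- mean(ln)
  out$sigma <- (C / out$C_null) / (L / out$L_null)
  ratios <- (C / cn) / (L / ln)
  out$null_sd_sigma <- stats::sd(ratios)
  out
}

#' Compute all graph metrics for one thresholded matrix
#'
#' Normalises weights, then computes the dwPLI mean (from the original
#' connectivity matrix when given), Onnela clustering, modularity,
#' characteristic path length and the small-world index, with explicit
#' missingness: sparse graphs can have missing clustering and
#' small-world values; path length is missing only for disconnected
#' graphs. Nothing is imputed.
#'
#' @param graph A [weighted_graph()] (e.g. the OMST-thresholded graph).
#' @param connectivity Optional `connectivity_matrix` whose full-network
#'   mean is reported as `dwpli_mean` (defaults to the graph's own mean
#'   off-diagonal weight).
#' @param subject_id,band Identifiers carried into the record.
#' @param n_null,restarts,seed Passed to [small_world_index()] and
#'   [modularity()].
#' @return One-row tibble: `subject_id`, `band`, `dwpli_mean`,
#'   `clustering`, `modularity`, `path_length`, `small_world`, `n_null`.
#' @export
graph_metric_record <- function(graph, connectivity = NULL,
                                subject_id = NA_character_,
                                band = NA_character_,
                                n_null = 50, restarts = 20, seed = 1) {
  g <- normalize_weights(graph)
  dw <- if (!is.null(connectivity)) summarize_dwpli(connectivity)
        else summarize_dwpli(graph$weights)
  sw <- small_world_index(g, n_null = n_null, seed = seed)
  tibble::tibble(
    subject_id = subject_id, band = band,
    dwpli_mean = dw,
    clustering = clustering_coefficient(g)$mean,
    modularity = modularity(g, restarts = restarts, seed = seed)$Q,
    path_length = characteristic_path_length(g),
    small_world = sw$sigma,
    n_null = n_null
  )
}

#' Pivot a wide metrics table to the long on-disk layout
#'
#' @param metrics Wide tibble from [graph_metric_record()] rows.
#' @return Long tibble: `subject_id`, `band`, `measure`, `value`,
#'   `missing_flag`.
#' @export
metrics_long <- function(metrics) {
  tidyr::pivot_longer(
    metrics[, c("subject_id", "band", "dwpli_mean", "clustering",
                "modularity", "path_length", "small_world")],
    cols = -c("subject_id", "band"),
    names_to = "measure", values_to = "value"
  ) |>
    dplyr::mutate(missing_flag = is.na(.data$value))
}
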