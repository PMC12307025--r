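# Independent brute-force oracles used across the suite. These are
# deliberately naive (loops, enumeration) and share no code with the
# package implementation.

# random symmetric weight matrix; density = probability an edge exists
random_weight_matrix <- function(n, density = 0.7, wmin = 0.05, wmax = 1) {
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  present <- stats::runif(nrow(ut)) < density
  vals <- stats::runif(nrow(ut), wmin, wmax) * present
  w[ut] <- vals
  w <- w + t(w)
  w
}

# Floyd-Warshall all-pairs shortest paths on 1/w edge lengths
brute_distances <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && w[i, j] > 0) d[i, j] <- 1 / w[i, j]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

brute_path_length <- function(w) {
  d <- brute_distances(w)
  off <- d[row(d) != col(d)]
  if (any(is.infinite(off))) return(NA_real_)
  mean(off)
}

brute_global_efficiency <- function(w) {
  d <- brute_distances(w)
  inv <- ifelse(is.infinite(d), 0, 1 / d)
  diag(inv) <- 0
  n <- nrow(w)
  sum(inv) / (n * (n - 1))
}

# Onnela clustering by explicit triangle loops
brute_clustering <- function(w) {
  n <- nrow(w)
  per <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    acc <- 0
    for (j in nb) for (h in nb) {
      if (j != h) acc <- acc + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
    }
    per[i] <- acc / (k * (k - 1))
  }
  list(per_node = per,
       mean = if (all(is.na(per))) NA_real_ else mean(per, na.rm = TRUE))
}

# all set partitions of n items as membership vectors
brute_partitions <- function(n) {
  out <- list()
  recur <- function(memb, mx) {
    i <- length(memb) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- memb; return(invisible()) }
    for (c in seq_len(mx + 1L)) recur(c(memb, c), max(mx, c))
  }
  recur(integer(0), 0L)
  out
}

brute_newman_q <- function(w, memb) {
  two_m <- sum(w)
  s <- rowSums(w)
  q <- 0
  n <- nrow(w)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (memb[i] == memb[j]) q <- q + w[i, j] - s[i] * s[j] / two_m
  }
  q / two_m
}

brute_max_modularity <- function(w, partitions = NULL) {
  if (is.null(partitions)) partitions <- brute_partitions(nrow(w))
  qs <- vapply(partitions, function(p) brute_newman_q(w, p), numeric(1))
  list(Q = max(qs), partition = partitions[[which.max(qs)]])
}

# sequential edge-disjoint MSTs via igraph (independent of the
# package's Kruskal), returning the union edge matrix after m rounds
oracle_sequential_mst_union <- function(w, m) {
  n <- nrow(w)
  union <- matrix(FALSE, n, n)
  for (r in seq_len(m)) {
    ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
    if (igraph::ecount(ig) == 0 || igraph::components(ig)$no > 1) break
    mst <- igraph::mst(ig, weights = 1 / igraph::E(ig)$weight)
    el <- igraph::as_edgelist(mst, names = FALSE)
    union[el] <- TRUE
    union[el[, c(2, 1), drop = FALSE]] <- TRUE
    w[el] <- 0
    w[el[, c(2, 1), drop = FALSE]] <- 0
  }
  union
}

# J = GE(selection)/GE(full) - cost, all parts recomputed by brute force
oracle_J <- function(w_full, selected_mask) {
  wsel <- w_full * selected_mask
  cost <- sum(wsel) / sum(w_full)
  ge <- brute_global_efficiency(wsel) / brute_global_efficiency(w_full)
  ge - cost
}

# weighted ring lattice with a fraction of edges rewired (small-world
# regime when p is small), weights U(0.5, 1)
ws_regime_graph <- function(n = 30, k = 4, p = 0.1) {
  g <- igraph::sample_smallworld(1, n, k / 2, p)
  w <- igraph::as_adjacency_matrix(g, sparse = FALSE) * 1
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  vals <- stats::runif(nrow(ut), 0.5, 1)
  w[ut] <- vals
  w[cbind(ut[, 2], ut[, 1])] <- vals
  weighted_graph(w)
}

# two-channel synthetic recording -> alpha-band dwPLI weight
pair_alpha_dwpli <- function(strength, seed, duration = 300,
                             zero_lag_mix = 0, phase_lag = pi / 2) {
  sub <- synthetic_subject(
    "pair", "younger", "female", iapf_true = 10,
    couplings = list(coupling_spec("Fp1", "Fpz", "alpha", phase_lag, strength)),
    n_channels = 2, duration = duration, zero_lag_mix = zero_lag_mix
  )
  eeg <- lowpass_filter(generate_subject_signals(sub, seed))
  csd <- compute_csd(segment_epochs(eeg))
  bands <- derive_bands(estimate_iapf(csd), fallback = TRUE)
  band_dwpli(csd, bands[bands$band == "alpha", ])$weights[1, 2]
}

# hand-built csd object with prescribed imaginary cross-spectra:
# channel 1 has coefficient 1, channel 2 has -1i * I_e, so that
# Im(c1 * Conj(c2)) = I_e at the single frequency bin
csd_from_imag <- function(I, freq = 10) {
  coef <- array(complex(real = 0), dim = c(length(I), 2L, 1L))
  coef[, 1L, 1L] <- 1 + 0i
  coef[, 2L, 1L] <- complex(real = 0, imaginary = -I)
  structure(
    list(freqs = freq, coef = coef, channel_labels = c("A", "B"),
         n_epochs = length(I), epoch_length = 12, sampling_rate = 250),
    class = "csd"
  )
}
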