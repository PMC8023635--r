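# Graph metrics on density-thresholded weighted connectivity networks.
#
# For each connection density between 90% and 10% (10% steps), the
# strongest-weighted channel pairs are retained (negative debiased dwPLI
# values clipped to zero first), communities are detected with seeded
# Louvain restarts, and four summaries are computed: Newman weighted
# modularity Q, the mean Onnela weighted clustering coefficient, the
# population standard deviation of the participation coefficients, and the
# modular span (weight-weighted mean intra-module electrode distance in
# head-radius units). Each summary is then averaged over the nine densities.

#' Threshold a connectivity matrix by connection density
#'
#' Negative entries are clipped to 0; the `round(density * n(n-1)/2)`
#' largest-weight pairs are retained with their weights, all others zeroed.
#' Ties are broken by lexicographic pair order (stable).
#'
#' @param cm a `connectivity_matrix`.
#' @param density fraction of channel pairs to retain, in (0, 1].
#' @return Object of class `thresholded_graph`: list with non-negative
#'   symmetric `weights` (zero diagonal), `density`, `node_labels`,
#'   `n_edges`.
#' @export
threshold_by_density <- function(cm, density) {
  if (density <= 0 || density > 1)
    stop_eegprog("density must be in (0, 1]", class = "eegprog_invalid")
  w <- pmax(cm$values, 0)
  n <- nrow(w)
  pairs <- upper_pairs(n)
  k <- round(density * nrow(pairs))
  if (k < 1)
    stop_eegprog("density %g retains no edges for %d nodes", density, n,
                 class = "eegprog_invalid")
  pw <- w[pairs]
  ord <- order(-pw, pairs[, 1], pairs[, 2])   # stable lexicographic ties
  keep <- pairs[ord[seq_len(k)], , drop = FALSE]
  out <- matrix(0, n, n, dimnames = dimnames(w))
  out[keep] <- w[keep]
  out[keep[, c(2, 1), drop = FALSE]] <- w[keep]
  structure(list(weights = out, density = density,
                 node_labels = cm$channel_labels, n_edges = k),
            class = "thresholded_graph")
}

#' Community detection with seeded Louvain restarts
#'
#' Runs weighted Louvain (`igraph::cluster_louvain`) `n_runs` times from
#' seeded random node orders and returns the partition with the highest
#' Newman modularity. Deterministic given `seed`.
#'
#' @param g a `thresholded_graph` with at least one edge.
#' @param seed integer RNG seed.
#' @param n_runs restarts (default 100).
#' @return list of class `graph_partition` with `assignment` (integer module
#'   id per node, contiguous from 1, named by node label) and `q`.
#' @export
detect_communities <- function(g, seed, n_runs = 100) {
  if (sum(g$weights) <= 0)
    stop_eegprog("graph has no edges", class = "eegprog_invalid")
  n <- nrow(g$weights)
  base <- igraph::graph_from_adjacency_matrix(g$weights, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
  with_seed(seed, {
    best_q <- -Inf
    best <- NULL
    for (r in seq_len(n_runs)) {
      perm <- sample.int(n)
      gr <- igraph::permute(base, perm)   # vertex i -> position perm[i]
      cl <- igraph::cluster_louvain(gr, weights = igraph::E(gr)$weight)
      mem <- igraph::membership(cl)[perm]
      q <- modularity_q(g, list(assignment = mem))
      if (q > best_q) {
        best_q <- q
        best <- mem
      }
    }
    best <- match(best, unique(best))  # contiguous ids in first-appearance order
    names(best) <- g$node_labels
    structure(list(assignment = best, q = best_q), class = "graph_partition")
  })
}

#' Newman weighted modularity of a partition
#'
#' `Q = (1/2m) * sum_ij (w_ij - s_i s_j / 2m) * [c_i == c_j]` with node
#' strengths `s` and total weight `m`.
#'
#' @param g a `thresholded_graph`.
#' @param p a partition (list with integer `assignment`).
#' @return scalar Q in `[-0.5, 1]`.
#' @export
modularity_q <- function(g, p) {
  w <- g$weights
  two_m <- sum(w)
  if (two_m <= 0)
    stop_eegprog("graph has no edges", class = "eegprog_invalid")
  s <- rowSums(w)
  same <- outer(p$assignment, p$assignment, `==`)
  sum((w - outer(s, s) / two_m) * same) / two_m
}

#' Participation coefficients
#'
#' `P_i = 1 - sum_m (k_im / k_i)^2`, where `k_im` is node `i`'s strength
#' into module `m` and `k_i` its total strength; isolated nodes get 0. The
#' scalar feature is the population standard deviation over nodes.
#'
#' @param g a `thresholded_graph`.
#' @param p a partition covering all nodes.
#' @return list with `per_node` (named numeric in `[0, 1)`) and `sd`
#'   (population SD over nodes).
#' @export
participation_coefficients <- function(g, p) {
  w <- g$weights
  n <- nrow(w)
  mods <- sort(unique(p$assignment))
  k <- rowSums(w)
  km <- vapply(mods, function(m)
    rowSums(w[, p$assignment == m, drop = FALSE]), numeric(n))
  pc <- ifelse(k > 0, 1 - rowSums((km / pmax(k, .Machine$double.eps))^2), 0)
  pc[k == 0] <- 0
  names(pc) <- g$node_labels
  list(per_node = pc, sd = sqrt(mean((pc - mean(pc))^2)))
}

#' Onnela weighted clustering coefficients
#'
#' With weights normalized by the network maximum, `C_i` is the geometric-
#' mean triangle intensity around node `i`:
#' `C_i = (1/(k_i (k_i - 1))) * sum_{j,h} (w'_ij w'_ih w'_jh)^(1/3)`.
#' Nodes with degree < 2 get 0. The scalar feature is the mean over nodes.
#'
#' @param g a `thresholded_graph`.
#' @return list with `per_node` (named numeric in `[0, 1]`) and `mean`.
#' @export
clustering_coefficients <- function(g) {
  w <- g$weights
  mx <- max(w)
  n <- nrow(w)
  if (mx <= 0) {
    cc <- stats::setNames(numeric(n), g$node_labels)
    return(list(per_node = cc, mean = 0))
  }
  wn <- (w / mx)^(1 / 3)
  deg <- rowSums(w > 0)
  cyc <- diag(wn %*% wn %*% wn)
  cc <- ifelse(deg >= 2, cyc / (deg * (deg - 1)), 0)
  names(cc) <- g$node_labels
  list(per_node = cc, mean = mean(cc))
}

#' Modular span
#'
#' For every module with at least one internal edge, the weight-weighted
#' mean Euclidean distance between its connected electrodes:
#' `span_m = sum(w_ij d_ij) / sum(w_ij)` over within-module edges. The
#' feature is the mean span over such modules (0 if none); distances are in
#' head-radius units since montage coordinates sit on the unit sphere.
#'
#' @param g a `thresholded_graph`.
#' @param p a partition.
#' @param m an `eeg_montage` providing coordinates for all nodes.
#' @return scalar span >= 0.
#' @export
modular_span <- function(g, p, m) {
  idx <- match(g$node_labels, m$labels)
  if (anyNA(idx))
    stop_eegprog("montage '%s' lacks coordinates for: %s", m$name,
                 paste(g$node_labels[is.na(idx)], collapse = ", "),
                 class = "eegprog_missing_channel")
  coords <- m$coordinates[idx, , drop = FALSE]
  d <- as.matrix(stats::dist(coords))
  spans <- c()
  for (mod in unique(p$assignment)) {
    nodes <- which(p$assignment == mod)
    if (length(nodes) < 2) next
    wm <- g$weights[nodes, nodes, drop = FALSE]
    tot <- sum(wm[upper.tri(wm)])
    if (tot <= 0) next
    dm <- d[nodes, nodes, drop = FALSE]
    spans <- c(spans, sum((wm * dm)[upper.tri(wm)]) / tot)
  }
  if (!length(spans)) 0 else mean(spans)
}

#' Graph metrics averaged over connection densities
#'
#' Per density: threshold, detect communities, compute Q, mean clustering,
#' participation SD and modular span; the reported metrics are arithmetic
#' means over the density grid.
#'
#' @param cm a `connectivity_matrix`.
#' @param m an `eeg_montage`.
#' @param densities density grid (default 0.9 down to 0.1 in 0.1 steps).
#' @param seed integer seed for community detection.
#' @param n_runs Louvain restarts per density.
#' @return list of class `graph_metrics` with `per_density` (data frame) and
#'   `averaged` (named numeric: `q`, `clustering_mean`, `participation_sd`,
#'   `modular_span`).
#' @export
density_averaged_metrics <- function(cm, m, densities = seq(0.9, 0.1, by = -0.1),
                                     seed = 1L, n_runs = 100) {
  seeds <- derive_seeds(seed, length(densities))
  rows <- lapply(seq_along(densities), function(k) {
    g <- threshold_by_density(cm, densities[k])
    p <- detect_communities(g, seed = seeds[k], n_runs = n_runs)
    data.frame(density = densities[k],
               q = modularity_q(g, p),
               clustering_mean = clustering_coefficients(g)$mean,
               participation_sd = participation_coefficients(g, p)$sd,
               modular_span = modular_span(g, p, m),
               n_modules = length(unique(p$assignment)))
  })
  per_density <- do.call(rbind, rows)
  averaged <- colMeans(per_density[, c("q", "clustering_mean",
                                       "participation_sd", "modular_span")])
  structure(list(per_density = per_density, averaged = averaged),
            class = "graph_metrics")
}

#' Names of the eight extracted EEG features
#' @return character vector of feature keys.
#' @export
feature_names <- function() {
  c("alpha_rel_power", "alpha_median_dwpli", "alpha_modular_span",
    "alpha_participation_sd", "delta_rel_power", "delta_median_dwpli",
    "delta_clustering_mean", "delta_modularity")
}

#' Extract the eight EEG features of one preprocessed recording
#'
#' Alpha band: mean relative power, median dwPLI, density-averaged modular
#' span and participation-coefficient SD. Delta band: mean relative power,
#' median dwPLI, density-averaged mean clustering coefficient and
#' modularity. Channels are put in canonical (sorted-label) order first so
#' the features — including the seeded community detection — are invariant
#' to the input channel order.
#'
#' @param ep a preprocessed `eeg_epochs` object.
#' @param m an `eeg_montage` covering the channels.
#' @param seed integer seed for community detection.
#' @param n_runs Louvain restarts per density (default 100).
#' @param spectral_only if `TRUE`, return only the two relative-power
#'   features (fast path for power-only analyses).
#' @return named numeric vector with keys [feature_names()].
#' @export
extract_features <- function(ep, m, seed = 1L, n_runs = 100,
                             spectral_only = FALSE) {
  ord <- order(ep$channel_labels)
  ep$channel_labels <- ep$channel_labels[ord]
  ep$epochs <- ep$epochs[, ord, , drop = FALSE]

  spec <- compute_psd(ep)
  bands <- default_bands()
  out <- c(alpha_rel_power = mean_relative_power(relative_band_power(spec, bands$alpha)),
           delta_rel_power = mean_relative_power(relative_band_power(spec, bands$delta)))
  if (spectral_only) return(out)

  seeds <- derive_seeds(seed, 2)
  cm_a <- dwpli(epoch_cross_spectra(ep, bands$alpha))
  cm_d <- dwpli(epoch_cross_spectra(ep, bands$delta))
  gm_a <- density_averaged_metrics(cm_a, m, seed = seeds[1], n_runs = n_runs)
  gm_d <- density_averaged_metrics(cm_d, m, seed = seeds[2], n_runs = n_runs)
  res <- c(alpha_rel_power = unname(out["alpha_rel_power"]),
           alpha_median_dwpli = median_connectivity(cm_a),
           alpha_modular_span = unname(gm_a$averaged["modular_span"]),
           alpha_participation_sd = unname(gm_a$averaged["participation_sd"]),
           delta_rel_power = unname(out["delta_rel_power"]),
           delta_median_dwpli = median_connectivity(cm_d),
           delta_clustering_mean = unname(gm_d$averaged["clustering_mean"]),
           delta_modularity = unname(gm_d$averaged["q"]))
  res[feature_names()]
}
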