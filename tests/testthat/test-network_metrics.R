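test_that("density thresholding keeps exactly the strongest pairs", {
  cm <- random_connectivity(4, seed = 1, negative = FALSE)
  g <- threshold_by_density(cm, 0.5)
  expect_equal(g$n_edges, 3L)
  expect_equal(sum(g$weights[upper.tri(g$weights)] > 0), 3L)
  kept <- sort(g$weights[upper.tri(g$weights)], decreasing = TRUE)[1:3]
  all_w <- sort(cm$values[upper.tri(cm$values)], decreasing = TRUE)[1:3]
  expect_equal(kept, all_w)

  full <- threshold_by_density(cm, 1)
  expect_equal(full$weights, pmax(cm$values, 0))
  expect_error(threshold_by_density(cm, 0), class = "eegprog_invalid")
})

test_that("thresholded edge sets equal brute-force sort-and-cut", {
  for (s in 1:10) {
    cm <- random_connectivity(8, seed = 200 + s)
    for (dens in c(0.2, 0.5, 0.9)) {
      g <- threshold_by_density(cm, dens)
      got <- which(g$weights > 0 & upper.tri(g$weights), arr.ind = TRUE)
      got <- sort(paste(got[, 1], got[, 2], sep = "-"))
      want <- oracle_threshold_edges(cm$values, dens)
      # brute force includes zero-weight ties; compare retained positive sets
      expect_true(all(got %in% want))
      expect_equal(g$n_edges, length(want))
    }
  }
})

test_that("community detection recovers planted structure deterministically", {
  # two disconnected 5-cliques
  w <- matrix(0, 10, 10)
  w[1:5, 1:5] <- 1; w[6:10, 6:10] <- 1; diag(w) <- 0
  labels <- paste0("n", 1:10)
  dimnames(w) <- list(labels, labels)
  cm <- structure(list(values = w, band = default_bands()$alpha,
                       channel_labels = labels, n_observations = 5),
                  class = "connectivity_matrix")
  g <- threshold_by_density(cm, 1)
  p <- detect_communities(g, seed = 1, n_runs = 20)
  expect_equal(length(unique(p$assignment)), 2)
  expect_equal(length(unique(p$assignment[1:5])), 1)
  expect_equal(length(unique(p$assignment[6:10])), 1)
  expect_equal(modularity_q(g, p), 0.5, tolerance = 1e-12)

  p2 <- detect_communities(g, seed = 1, n_runs = 20)
  expect_identical(p, p2)
})

test_that("graph metrics match brute force on random small graphs", {
  for (s in 1:50) {
    n <- sample(4:8, 1)
    cm <- random_connectivity(n, seed = 300 + s)
    g <- threshold_by_density(cm, runif(1, 0.3, 1))
    mem <- sample(1:3, n, replace = TRUE)
    p <- list(assignment = mem)
    if (sum(g$weights) == 0) next

    expect_equal(modularity_q(g, p), oracle_modularity(g$weights, mem),
                 tolerance = 1e-12)
    pc <- participation_coefficients(g, p)
    expect_equal(unname(pc$per_node), oracle_participation(g$weights, mem),
                 tolerance = 1e-12)
    expect_equal(pc$sd, sqrt(mean((pc$per_node - mean(pc$per_node))^2)),
                 tolerance = 1e-12)
    cc <- clustering_coefficients(g)
    expect_equal(unname(cc$per_node), oracle_clustering(g$weights),
                 tolerance = 1e-12)
    m <- toy_montage(n, seed = 300 + s)
    expect_equal(modular_span(g, p, m),
                 oracle_span(g$weights, mem, m$coordinates), tolerance = 1e-12)

    # range invariants
    expect_true(modularity_q(g, p) >= -0.5 - 1e-12 && modularity_q(g, p) <= 1)
    expect_true(all(pc$per_node >= 0 & pc$per_node < 1))
    expect_true(all(cc$per_node >= 0 & cc$per_node <= 1 + 1e-12))
    expect_gte(modular_span(g, p, m), 0)
  }
})

test_that("modularity agrees with igraph's weighted implementation", {
  for (s in 1:5) {
    cm <- random_connectivity(8, seed = 400 + s, negative = FALSE)
    g <- threshold_by_density(cm, 0.7)
    mem <- sample(1:2, 8, replace = TRUE)
    gr <- igraph::graph_from_adjacency_matrix(g$weights, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
    expect_equal(modularity_q(g, list(assignment = mem)),
                 igraph::modularity(gr, mem, weights = igraph::E(gr)$weight),
                 tolerance = 1e-12)
  }
})

test_that("hand-computable metric cases hold", {
  # single-module partition: all participation 0
  cm <- random_connectivity(5, seed = 7, negative = FALSE)
  g <- threshold_by_density(cm, 1)
  pc <- participation_coefficients(g, list(assignment = rep(1, 5)))
  expect_equal(unname(pc$per_node), rep(0, 5))
  expect_equal(pc$sd, 0)

  # node with strength split equally between two modules -> P = 0.5
  w <- matrix(0, 3, 3); w[1, 2] <- w[2, 1] <- 1; w[1, 3] <- w[3, 1] <- 1
  dimnames(w) <- list(paste0("n", 1:3), paste0("n", 1:3))
  g2 <- list(weights = w, node_labels = paste0("n", 1:3))
  pc2 <- participation_coefficients(g2, list(assignment = c(1, 1, 2)))
  expect_equal(unname(pc2$per_node[1]), 0.5)

  # all nodes in one module -> q = 0
  expect_equal(modularity_q(g, list(assignment = rep(1, 5))), 0, tolerance = 1e-12)

  # unweighted triangle: clustering 1 everywhere; path: middle node 0
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  g3 <- list(weights = tri, node_labels = paste0("n", 1:3))
  expect_equal(unname(clustering_coefficients(g3)$per_node), rep(1, 3))
  path <- matrix(0, 3, 3); path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  g4 <- list(weights = path, node_labels = paste0("n", 1:3))
  expect_equal(unname(clustering_coefficients(g4)$per_node[2]), 0)

  # two nodes at distance 1 with one edge -> span 1
  m <- toy_montage(2)
  m$coordinates <- rbind(c(1, 0, 0), c(0, 1, 0)) / sqrt(1)
  m$coordinates <- m$coordinates / sqrt(rowSums(m$coordinates^2))
  d <- sqrt(sum((m$coordinates[1, ] - m$coordinates[2, ])^2))
  e <- matrix(0, 2, 2); e[1, 2] <- e[2, 1] <- 0.8
  g5 <- list(weights = e, node_labels = paste0("n", 1:2))
  expect_equal(modular_span(g5, list(assignment = c(1, 1)), m), d)

  # coincident electrodes -> span 0
  m0 <- toy_montage(2)
  m0$coordinates <- rbind(c(1, 0, 0), c(1, 0, 0))
  rownames(m0$coordinates) <- m0$labels
  expect_equal(modular_span(g5, list(assignment = c(1, 1)), m0), 0)
})

test_that("metrics are invariant under consistent node relabeling", {
  cm <- random_connectivity(7, seed = 11)
  m <- toy_montage(7, seed = 11)
  g <- threshold_by_density(cm, 0.6)
  mem <- c(1, 2, 1, 2, 3, 1, 2)
  perm <- sample(7)
  g2 <- list(weights = g$weights[perm, perm], node_labels = g$node_labels[perm],
             density = g$density)
  m2 <- m
  m2$labels <- m$labels[perm]
  m2$coordinates <- m$coordinates[perm, ]
  expect_equal(modularity_q(g2, list(assignment = mem[perm])),
               modularity_q(g, list(assignment = mem)), tolerance = 1e-12)
  expect_equal(clustering_coefficients(g2)$mean, clustering_coefficients(g)$mean,
               tolerance = 1e-12)
  expect_equal(participation_coefficients(g2, list(assignment = mem[perm]))$sd,
               participation_coefficients(g, list(assignment = mem))$sd,
               tolerance = 1e-12)
  expect_equal(modular_span(g2, list(assignment = mem[perm]), m2),
               modular_span(g, list(assignment = mem), m), tolerance = 1e-12)
})

test_that("density averaging is the arithmetic mean of per-density values", {
  cm <- random_connectivity(12, seed = 21, negative = FALSE)
  m <- toy_montage(12, seed = 21)
  gm <- density_averaged_metrics(cm, m, seed = 5, n_runs = 10)
  expect_equal(nrow(gm$per_density), 9)
  expect_equal(unname(gm$averaged["q"]), mean(gm$per_density$q))
  expect_equal(unname(gm$averaged["modular_span"]), mean(gm$per_density$modular_span))
})

test_that("extract_features returns the eight finite features, order-invariantly", {
  rec <- quick_recording(seed = 31, duration_s = 60,
                         module_assignment = two_module_assignment(),
                         coupling = 0.8)
  ep <- preprocess(rec)
  m <- load_montage("ld1020")
  f <- extract_features(ep, m, seed = 9, n_runs = 25)
  expect_named(f, feature_names())
  expect_true(all(is.finite(f)))
  expect_gt(f["alpha_rel_power"], f["delta_rel_power"])

  perm <- sample(length(ep$channel_labels))
  ep2 <- ep
  ep2$channel_labels <- ep$channel_labels[perm]
  ep2$epochs <- ep$epochs[, perm, , drop = FALSE]
  f2 <- extract_features(ep2, m, seed = 9, n_runs = 25)
  expect_equal(f, f2, tolerance = 1e-9)
})

test_that("participation spread separates planted modular structure from a single phase ring", {
  # A cleanly segregated two-module alpha network gives uniformly low
  # participation (small SD); a single module whose channels form one long
  # phase ring produces heterogeneous hub structure (larger SD). The
  # pipeline must separate the two consistently.
  sd2 <- sd1 <- numeric(5)
  for (s in 1:5) {
    ma2 <- two_module_assignment()
    rec2 <- quick_recording(seed = 500 + s, duration_s = 60,
                            module_assignment = ma2, coupling = 0.9)
    ma1 <- ma2; ma1[] <- 1
    rec1 <- quick_recording(seed = 500 + s, duration_s = 60,
                            module_assignment = ma1, coupling = 0.9)
    m <- load_montage("ld1020")
    f2 <- extract_features(preprocess(rec2), m, seed = 1, n_runs = 25)
    f1 <- extract_features(preprocess(rec1), m, seed = 1, n_runs = 25)
    sd2[s] <- f2["alpha_participation_sd"]
    sd1[s] <- f1["alpha_participation_sd"]
  }
  expect_true(all(sd2 < sd1))
})
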