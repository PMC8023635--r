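# Independent brute-force reference implementations used as oracles.
# These deliberately use plain loops and no shared code with the package.

oracle_dwpli_pair <- function(I) {
  # I: observations x bins matrix of Im(cross-spectrum) for one pair
  ests <- numeric(ncol(I))
  for (b in seq_len(ncol(I))) {
    s1 <- 0; s2 <- 0; s3 <- 0
    for (k in seq_len(nrow(I))) {
      s1 <- s1 + I[k, b]
      s2 <- s2 + I[k, b]^2
      s3 <- s3 + abs(I[k, b])
    }
    den <- s3^2 - s2
    ests[b] <- if (den == 0) 0 else (s1^2 - s2) / den
  }
  mean(ests)
}

oracle_modularity <- function(w, mem) {
  two_m <- sum(w)
  s <- rowSums(w)
  q <- 0
  for (i in seq_len(nrow(w)))
    for (j in seq_len(ncol(w)))
      if (mem[i] == mem[j])
        q <- q + w[i, j] - s[i] * s[j] / two_m
  unname(q / two_m)
}

oracle_participation <- function(w, mem) {
  n <- nrow(w)
  p <- numeric(n)
  for (i in seq_len(n)) {
    k_i <- sum(w[i, ])
    if (k_i == 0) { p[i] <- 0; next }
    acc <- 0
    for (m in unique(mem)) {
      k_im <- sum(w[i, mem == m])
      acc <- acc + (k_im / k_i)^2
    }
    p[i] <- 1 - acc
  }
  p
}

oracle_clustering <- function(w) {
  n <- nrow(w)
  wn <- w / max(w)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n))
      if (j != i && h != i && j != h)
        acc <- acc + (wn[i, j] * wn[i, h] * wn[j, h])^(1 / 3)
    cc[i] <- acc / (k * (k - 1))
  }
  cc
}

oracle_span <- function(w, mem, coords) {
  spans <- c()
  for (m in unique(mem)) {
    nodes <- which(mem == m)
    num <- 0; den <- 0
    if (length(nodes) >= 2)
      for (a in seq_along(nodes)) for (b in seq_along(nodes))
        if (a < b && w[nodes[a], nodes[b]] > 0) {
          d <- sqrt(sum((coords[nodes[a], ] - coords[nodes[b], ])^2))
          num <- num + w[nodes[a], nodes[b]] * d
          den <- den + w[nodes[a], nodes[b]]
        }
    if (den > 0) spans <- c(spans, num / den)
  }
  if (length(spans)) mean(spans) else 0
}

oracle_threshold_edges <- function(w, density) {
  # returns the retained pair set as a sorted "i-j" character vector
  w <- pmax(w, 0)
  n <- nrow(w)
  pairs <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    pairs <- rbind(pairs, c(i, j, w[i, j]))
  k <- round(density * nrow(pairs))
  ord <- order(-pairs[, 3], pairs[, 1], pairs[, 2])
  kept <- pairs[ord[seq_len(k)], , drop = FALSE]
  sort(paste(kept[, 1], kept[, 2], sep = "-"))
}

random_connectivity <- function(n, seed, negative = TRUE) {
  set.seed(seed)
  w <- matrix(stats::runif(n * n), n)
  if (negative) w <- w - 0.2
  w <- (w + t(w)) / 2
  diag(w) <- 0
  labels <- paste0("n", seq_len(n))
  dimnames(w) <- list(labels, labels)
  structure(list(values = w, band = default_bands()$alpha,
                 channel_labels = labels, n_observations = 10),
            class = "connectivity_matrix")
}

# tiny montage with the labels n1..n (points on the unit sphere)
toy_montage <- function(n, seed = 99) {
  set.seed(seed)
  x <- matrix(stats::rnorm(3 * n), n)
  x <- x / sqrt(rowSums(x^2))
  labels <- paste0("n", seq_len(n))
  rownames(x) <- labels
  structure(list(name = "toy", labels = labels, coordinates = x),
            class = "eeg_montage")
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  expected <- si * sj / comb2(sum(tab))
  (sij - expected) / ((si + sj) / 2 - expected)
}

# independent greedy stepwise reimplementation using anova partial F tests
oracle_stepwise <- function(y, X, entry_p = 0.05, removal_p = 0.10) {
  current <- character(0)
  dat <- cbind(data.frame(y = y), X)
  repeat {
    changed <- FALSE
    pool <- setdiff(names(X), current)
    if (length(pool)) {
      ps <- sapply(pool, function(v) {
        f0 <- lm(reformulate(if (length(current)) current else "1", "y"), dat)
        f1 <- lm(reformulate(c(current, v), "y"), dat)
        stats::anova(f0, f1)[2, "Pr(>F)"]
      })
      if (min(ps) <= entry_p) {
        current <- c(current, pool[which.min(ps)])
        changed <- TRUE
      }
    }
    repeat {
      if (!length(current)) break
      ps <- sapply(current, function(v) {
        f0 <- lm(reformulate(if (length(current) > 1) setdiff(current, v) else "1", "y"), dat)
        f1 <- lm(reformulate(current, "y"), dat)
        stats::anova(f0, f1)[2, "Pr(>F)"]
      })
      if (max(ps) >= removal_p) {
        current <- setdiff(current, names(which.max(ps)))
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  sort(current)
}

trapz_test <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

upper_pairs_test <- function(n) {
  out <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) out <- rbind(out, c(i = i, j = j))
  colnames(out) <- c("i", "j")
  out
}

derive_seeds_test <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
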