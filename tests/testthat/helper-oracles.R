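# Independent brute-force oracles used across the suite. These deliberately
# avoid igraph, hclust and the package's own internals: geodesics are
# enumerated from scratch, ward.D2 is the Lance-Williams recurrence applied
# naively, and phi is checked against cor() on explicit indicator vectors.

# All-pairs shortest-path distances and geodesic counts for a small graph.
# W: symmetric edge-length matrix, Inf where no edge, diagonal 0.
oracle_geodesics <- function(W) {
  n <- nrow(W)
  D <- W
  diag(D) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  sigma <- matrix(0, n, n)
  for (s in 1:n) {
    sigma[s, s] <- 1
    for (t in setdiff(order(D[s, ]), s)) {
      if (!is.finite(D[s, t])) next
      preds <- which(is.finite(W[, t]) &
                       abs(D[s, ] + W[, t] - D[s, t]) < 1e-9)
      preds <- setdiff(preds, t)
      sigma[s, t] <- sum(sigma[s, preds])
    }
  }
  list(D = D, sigma = sigma)
}

# Freeman betweenness: sum over unordered pairs s<t of the geodesic share
# through v.
oracle_betweenness <- function(W) {
  n <- nrow(W)
  g <- oracle_geodesics(W)
  b <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(g$D[s, t]) || g$sigma[s, t] == 0) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      on_path <- is.finite(g$D[s, v]) && is.finite(g$D[v, t]) &&
        abs(g$D[s, v] + g$D[v, t] - g$D[s, t]) < 1e-9
      if (on_path) b[v] <- b[v] + g$sigma[s, v] * g$sigma[v, t] / g$sigma[s, t]
    }
  }
  b
}

# Closeness: reciprocal of summed distances to reachable nodes; isolated -> 0.
oracle_closeness <- function(W) {
  D <- oracle_geodesics(W)$D
  vapply(seq_len(nrow(W)), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0L) 0 else 1 / sum(d)
  }, numeric(1))
}

# Naive O(n^3) agglomeration with the ward.D2 Lance-Williams update,
# returning the cophenetic distance matrix (which pins down heights and
# topology together).
oracle_ward_d2_cophenetic <- function(D) {
  n <- nrow(D)
  cur <- as.matrix(D)
  diag(cur) <- Inf
  size <- rep(1, n)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  cop <- matrix(0, n, n)
  for (step in seq_len(n - 1)) {
    cur[!active, ] <- Inf
    cur[, !active] <- Inf
    m <- which(cur == min(cur), arr.ind = TRUE)[1, ]
    i <- min(m); j <- max(m)
    h <- cur[i, j]
    cop[members[[i]], members[[j]]] <- h
    cop[members[[j]], members[[i]]] <- h
    for (k in which(active)) {
      if (k == i || k == j) next
      d2 <- ((size[i] + size[k]) * cur[k, i]^2 +
               (size[j] + size[k]) * cur[k, j]^2 -
               size[k] * cur[i, j]^2) /
        (size[i] + size[j] + size[k])
      cur[k, i] <- cur[i, k] <- sqrt(max(d2, 0))
    }
    size[i] <- size[i] + size[j]
    members[[i]] <- c(members[[i]], members[[j]])
    active[j] <- FALSE
    cur[i, i] <- Inf
  }
  cop
}

# Brute-force co-prescription counts: double loop over patients' drug sets.
oracle_cooccurrence <- function(sets) {
  codes <- sort(unique(unlist(sets)))
  k <- length(codes)
  P <- stats::setNames(integer(k), codes)
  C <- matrix(0L, k, k, dimnames = list(codes, codes))
  for (s in sets) {
    s <- unique(s)
    idx <- match(s, codes)
    P[idx] <- P[idx] + 1L
    if (length(idx) >= 2L) {
      for (a in 1:(length(idx) - 1)) for (b in (a + 1):length(idx)) {
        C[idx[a], idx[b]] <- C[idx[a], idx[b]] + 1L
        C[idx[b], idx[a]] <- C[idx[b], idx[a]] + 1L
      }
    }
  }
  list(P = P, C = C)
}
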