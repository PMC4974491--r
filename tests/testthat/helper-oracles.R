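## Independent brute-force oracles used to validate the fast implementations.

## TOM by explicit triple loop
naive_tom <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { out[i, j] <- 1; next }
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
      out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  out
}

## hypergeometric tails by direct pmf summation (exact for N <= 60)
enum_hyper_tail <- function(k, N, K, n, upper = TRUE) {
  kk <- max(0, n + K - N):min(K, n)
  pmf <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  if (upper) sum(pmf[kk >= k]) else sum(pmf[kk <= k])
}

## Benjamini-Hochberg by literal step-up definition
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * p[ord[i]] / i)
    adj[ord[i]] <- running
  }
  pmin(adj, 1)
}

## betweenness by all-pairs BFS path counting:
## sigma_st(v) = sigma_sv * sigma_vt when d(s,v) + d(v,t) = d(s,t)
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n); sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0; sigma[s, s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] > 0)) {
          if (is.infinite(dist[s, w])) {
            dist[s, w] <- dist[s, v] + 1
            nxt <- c(nxt, w)
          }
          if (dist[s, w] == dist[s, v] + 1) {
            sigma[s, w] <- sigma[s, w] + sigma[s, v]
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  bt <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s >= t || s == v || t == v) next
        if (is.finite(dist[s, t]) &&
            dist[s, v] + dist[v, t] == dist[s, t]) {
          bt[v] <- bt[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  bt
}

## adjusted Rand index (mclust is the reference; fall back if unavailable)
ari_of <- function(a, b) mclust::adjustedRandIndex(a, b)

## random symmetric "TOM-like" matrix with unit diagonal
random_sym <- function(n, seed) {
  withr::with_seed(seed, {
    m <- matrix(stats::runif(n * n), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    dimnames(m) <- list(sprintf("P%04d", 1:n), sprintf("P%04d", 1:n))
    m
  })
}

## sample-annotation helper for hand-built matrices
two_group_cols <- function(a = "ifn_alpha", b = "none", tp = 6, donors = 3) {
  c(sprintf("%s_t%03d_d%d", a, tp, seq_len(donors)),
    sprintf("%s_t%03d_d%d", b, tp, seq_len(donors)))
}

## truth restricted to the modules active in one condition
active_truth <- function(sim, condition) {
  cfg <- sim$config
  active <- cfg$modules$name[vapply(cfg$modules$conditions,
                                    function(cc) condition %in% cc, TRUE)]
  ifelse(sim$truth$module %in% active, sim$truth$module, "background")
}
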