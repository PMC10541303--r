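# Independent oracles used across the suite. None of these call igraph or
# the package's own centrality/enrichment code paths.

# Adjacency-list BFS distances from source s (1-based), Inf if unreachable.
oracle_bfs_dist <- function(adj, s) {
  n <- length(adj)
  d <- rep(Inf, n)
  d[s] <- 0
  queue <- s
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) {
      if (!is.finite(d[v])) {
        d[v] <- d[u] + 1
        queue <- c(queue, v)
      }
    }
  }
  d
}

# Enumerate every geodesic (shortest path) from s to t explicitly.
oracle_geodesics <- function(adj, dist_t, s, t) {
  if (!is.finite(dist_t[s])) return(list())
  if (s == t) return(list(s))
  paths <- list()
  for (v in adj[[s]]) {
    if (dist_t[v] == dist_t[s] - 1) {
      for (p in oracle_geodesics(adj, dist_t, v, t)) {
        paths[[length(paths) + 1L]] <- c(s, p)
      }
    }
  }
  paths
}

# Degree, pair-count-normalized betweenness, and Wasserman-Faust scaled
# closeness by exhaustive shortest-path enumeration.
oracle_centralities <- function(adj) {
  n <- length(adj)
  deg <- vapply(adj, length, integer(1))
  dists <- lapply(seq_len(n), function(s) oracle_bfs_dist(adj, s))
  btw <- rep(0, n)
  if (n > 2) {
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      if (!is.finite(dists[[t]][s])) next
      paths <- oracle_geodesics(adj, dists[[t]], s, t)
      if (!length(paths)) next
      through <- rep(0, n)
      for (p in paths) {
        inner <- setdiff(p, c(s, t))
        through[inner] <- through[inner] + 1
      }
      btw <- btw + through / length(paths)
    }
    btw <- btw / ((n - 1) * (n - 2) / 2)
  }
  clo <- vapply(seq_len(n), function(i) {
    d <- dists[[i]]
    reach <- which(is.finite(d) & seq_len(n) != i)
    nc <- length(reach) + 1
    if (nc <= 1 || n == 1) return(0)
    ((nc - 1) / sum(d[reach])) * ((nc - 1) / (n - 1))
  }, numeric(1))
  list(degree = deg, betweenness = btw, closeness = clo)
}

# Random undirected simple graph as (edge data.frame, adjacency list).
random_graph <- function(n, p = 0.35) {
  pairs <- if (n >= 2) t(combn(n, 2)) else matrix(numeric(0), ncol = 2)
  on <- runif(nrow(pairs)) < p
  e <- pairs[on, , drop = FALSE]
  adj <- lapply(seq_len(n), function(i) {
    sort(c(e[e[, 1] == i, 2], e[e[, 2] == i, 1]))
  })
  syms <- sprintf("N%02d", seq_len(n))
  edges <- data.frame(
    protein1 = syms[e[, 1]], protein2 = syms[e[, 2]],
    combined_score = rep(900L, nrow(e)), stringsAsFactors = FALSE
  )
  list(edges = edges, adj = adj, syms = syms)
}

# Exact upper-tail hypergeometric probability by combinatorial summation.
oracle_hyper_upper <- function(k, K, n, N) {
  js <- k:min(K, n)
  js <- js[js >= max(0, n - (N - K))]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Manual Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Tiny gene-set collection builder for enrichment tests.
make_collection <- function(members_list, categories = NULL) {
  ids <- sprintf("T%03d", seq_along(members_list))
  sets <- lapply(seq_along(members_list), function(i) {
    list(term_id = ids[i], term_name = paste("term", i),
         category = if (is.null(categories)) NA_character_ else categories[i],
         members = members_list[[i]])
  })
  names(sets) <- ids
  class(sets) <- "gene_set_collection"
  sets
}

# Minimal scored compound table for screening tests.
toy_library <- function() {
  data.frame(
    compound_id = c("c1", "c2", "c2", "c3", "c4"),
    name = c("alpha", "beta", "beta", "gamma", "delta"),
    herbs = c("h1", "h1", "h2", "h2", "h3"),
    mw = c(300, 350, 350, 420, 500), alogp = c(2, 3, 3, 1, 4),
    hba = c(4L, 5L, 5L, 3L, 6L), hbd = c(1L, 2L, 2L, 0L, 3L),
    psa = c(60, 80, 80, 40, 120), rotb = c(3L, 5L, 5L, 2L, 8L),
    arom = c(1L, 2L, 2L, 1L, 3L), alerts = c(0L, 0L, 0L, 1L, 2L),
    ob = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}
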