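# Independent brute-force oracles. Everything here works on plain adjacency
# lists built from a two-column character edge matrix -- no igraph, no calls
# into the package's own computational paths.

oracle_adj <- function(nodes, edges) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1L]; b <- edges[i, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

oracle_bfs_dist <- function(adj, s) {
  dist <- setNames(rep(Inf, length(adj)), names(adj))
  dist[s] <- 0
  queue <- s
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# All shortest paths between s and t, as lists of node sequences.
oracle_all_shortest_paths <- function(adj, dist_s, s, t) {
  if (is.infinite(dist_s[t])) return(list())
  if (s == t) return(list(s))
  paths <- list()
  walk <- function(v, acc) {
    if (v == s) {
      paths[[length(paths) + 1L]] <<- rev(acc)
      return(invisible())
    }
    for (u in adj[[v]]) {
      if (dist_s[u] == dist_s[v] - 1) walk(u, c(acc, u))
    }
  }
  walk(t, t)
  paths
}

# Node and edge betweenness by explicit shortest-path enumeration with
# fractional credit: each of the n_paths shortest s-t paths contributes
# 1/n_paths to its interior nodes and to its edges. Each unordered pair is
# counted once.
oracle_betweenness <- function(nodes, edges) {
  adj <- oracle_adj(nodes, edges)
  nb <- setNames(numeric(length(nodes)), nodes)
  ekeys <- if (nrow(edges)) {
    paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]), sep = "\t")
  } else character()
  eb <- setNames(numeric(length(ekeys)), ekeys)
  if (length(nodes) < 2L) return(list(node = nb, edge = eb))
  for (i in seq_len(length(nodes) - 1L)) {
    s <- nodes[i]
    dist_s <- oracle_bfs_dist(adj, s)
    for (j in (i + 1L):length(nodes)) {
      t <- nodes[j]
      paths <- oracle_all_shortest_paths(adj, dist_s, s, t)
      np <- length(paths)
      if (np == 0L) next
      for (p in paths) {
        if (length(p) > 2L) {
          inner <- p[-c(1L, length(p))]
          nb[inner] <- nb[inner] + 1 / np
        }
        a <- p[-length(p)]; b <- p[-1L]
        k <- paste(pmin(a, b), pmax(a, b), sep = "\t")
        eb[k] <- eb[k] + 1 / np
      }
    }
  }
  list(node = nb, edge = eb)
}

oracle_eccentricity <- function(nodes, edges) {
  adj <- oracle_adj(nodes, edges)
  vapply(nodes, function(s) {
    d <- oracle_bfs_dist(adj, s)
    max(d[is.finite(d)])
  }, 0)
}

oracle_clustering <- function(nodes, edges) {
  adj <- oracle_adj(nodes, edges)
  ek <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]),
              sep = "\t")
  vapply(nodes, function(v) {
    nb <- unique(adj[[v]])
    k <- length(nb)
    if (k < 2L) return(0)
    cnt <- 0L
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        key <- paste(min(nb[a], nb[b]), max(nb[a], nb[b]), sep = "\t")
        if (key %in% ek) cnt <- cnt + 1L
      }
    }
    2 * cnt / (k * (k - 1))
  }, 0)
}

# k-clique percolation by direct enumeration: all k-node cliques, adjacency
# iff sharing k-1 nodes, communities = components, nodes = union.
oracle_kclique_communities <- function(nodes, edges, k) {
  if (length(nodes) < k) return(list())
  ek <- paste(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]),
              sep = "\t")
  is_edge <- function(a, b) paste(min(a, b), max(a, b), sep = "\t") %in% ek
  subsets <- combn(sort(nodes), k, simplify = FALSE)
  cliques <- Filter(function(s) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) if (!is_edge(s[i], s[j])) return(FALSE)
    }
    TRUE
  }, subsets)
  if (length(cliques) == 0L) return(list())
  nc <- length(cliques)
  parent <- seq_len(nc)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(nc)) {
    for (j in seq_len(nc)) {
      if (i < j && length(intersect(cliques[[i]], cliques[[j]])) >= k - 1L) {
        parent[find(i)] <- find(j)
      }
    }
  }
  comp <- vapply(seq_len(nc), find, 1L)
  lapply(split(seq_len(nc), comp),
         function(idx) sort(unique(unlist(cliques[idx]))))
}

# Direct evaluation of M = sum_s [ l_s/L - (k_s/2L)^2 ] from an edge matrix
# and a list of disjoint node sets.
oracle_modularity <- function(edges, partition) {
  L <- nrow(edges)
  deg <- table(c(edges[, 1L], edges[, 2L]))
  total <- 0
  for (s in partition) {
    l_s <- sum(edges[, 1L] %in% s & edges[, 2L] %in% s)
    k_s <- sum(deg[names(deg) %in% s])
    total <- total + l_s / L - (k_s / (2 * L))^2
  }
  total
}

# All set partitions of 1..n via restricted growth strings.
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(rgs, mx) {
    if (length(rgs) == n) {
      out[[length(out) + 1L]] <<- split(seq_len(n), rgs)
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) rec(c(rgs, v), max(mx, v))
  }
  rec(1L, 1L)
  out
}

# One-sided over-representation Fisher p by explicit combinatorial tail sum.
oracle_fisher_over <- function(k, n, K, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

oracle_chi2 <- function(obs, expected) sum((obs - expected)^2 / expected)

# Mann-Whitney U by all-pairs rank comparison (counts pairs where x > y,
# half-credit for ties); equals wilcox.test's W for x vs y.
oracle_mwu <- function(x, y) {
  u <- 0
  for (xi in x) u <- u + sum(xi > y) + 0.5 * sum(xi == y)
  u
}

# Closed-form Welch two-sided p.
oracle_welch_p <- function(x, y) {
  m <- mean(x) - mean(y)
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- m / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(t), df)
}

# Erdos-Renyi-style fixture as a plain edge matrix (seeded).
er_edges <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(ids, 2L))
  pairs[runif(nrow(pairs)) < p, , drop = FALSE]
}

er_network <- function(n, p, seed, name = "er") {
  netstrat::ppi_network(er_edges(n, p, seed), name = name,
                        nodes = sprintf("n%02d", seq_len(n)))
}

# Two triangles joined by one bridge edge: a-b-c triangle, d-e-f triangle,
# bridge c-d. L = 7.
two_triangles_bridge <- function() {
  netstrat::ppi_network(rbind(
    c("a", "b"), c("b", "c"), c("a", "c"),
    c("d", "e"), c("e", "f"), c("d", "f"),
    c("c", "d")), name = "ttb")
}
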