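#' Construct a module set
#'
#' A collection of node sets extracted from one network by a clustering
#' algorithm. Modules are sorted deterministically (decreasing size, then
#' lexicographically by sorted membership) and given IDs \code{M001}, ...
#'
#' @param modules list of character vectors (non-empty node sets).
#' @param network source network name.
#' @param algorithm label of the producing algorithm.
#' @param params list of algorithm parameters.
#' @param overlapping logical; may modules share nodes?
#' @param modularity optional modularity score of the partition.
#' @return Object of class \code{module_set}.
#' @export
module_set <- function(modules, network = "network", algorithm = "manual",
                       params = list(), overlapping = FALSE, modularity = NULL) {
  modules <- lapply(modules, function(m) sort(unique(as.character(m))))
  if (any(vapply(modules, length, 1L) == 0L)) stop("empty module")
  key <- vapply(modules, paste, "", collapse = ",")
  ord <- order(-vapply(modules, length, 1L), key)
  modules <- modules[ord]
  names(modules) <- sprintf("M%03d", seq_along(modules))
  structure(list(network = network, algorithm = algorithm, params = params,
                 modules = modules, overlapping = overlapping,
                 modularity = modularity),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  sizes <- vapply(x$modules, length, 1L)
  cat(sprintf("<module_set> %s by %s: %d modules (sizes %s)%s\n",
              x$network, x$algorithm, length(x$modules),
              if (length(sizes)) paste(range(sizes), collapse = "-") else "-",
              if (x$overlapping) ", overlapping" else ""))
  if (!is.null(x$modularity)) cat(sprintf("  modularity M = %.4f\n", x$modularity))
  invisible(x)
}

n_modules <- function(ms) length(ms$modules)

#' k-clique percolation communities
#'
#' Communities are the connected components of the k-clique adjacency
#' structure: two k-cliques are adjacent when they share k-1 nodes, and each
#' community is the union of the nodes of its cliques. Computed over maximal
#' cliques of size >= k (two such cliques communicate exactly when they share
#' at least k-1 nodes). Communities may overlap.
#'
#' @param net a \code{\link{ppi_network}}.
#' @param k clique size, integer >= 3.
#' @return A \code{\link{module_set}} (empty when the graph has no k-clique).
#' @export
clique_percolation <- function(net, k = 3L) {
  stopifnot(inherits(net, "ppi_network"), k >= 3L)
  if (n_edges(net) == 0L) {
    return(module_set(list(), net$name, "cpm", list(k = k), overlapping = TRUE))
  }
  g <- as_igraph(net)
  mc <- igraph::max_cliques(g, min = k)
  if (length(mc) == 0L) {
    return(module_set(list(), net$name, "cpm", list(k = k), overlapping = TRUE))
  }
  cl <- lapply(mc, function(v) sort(as.integer(v)))
  nc <- length(cl)
  # candidate pairs: cliques sharing at least one node
  by_node <- list()
  for (i in seq_len(nc)) {
    for (v in cl[[i]]) {
      key <- as.character(v)
      by_node[[key]] <- c(by_node[[key]], i)
    }
  }
  parent <- seq_len(nc)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  unite <- function(x, y) { rx <- find(x); ry <- find(y); if (rx != ry) parent[rx] <<- ry }
  seen <- new.env(hash = TRUE)
  for (ids in by_node) {
    if (length(ids) < 2L) next
    ids <- sort(unique(ids))
    for (ii in seq_len(length(ids) - 1L)) {
      for (jj in (ii + 1L):length(ids)) {
        a <- ids[ii]; b <- ids[jj]
        pk <- paste0(a, "_", b)
        if (!is.null(seen[[pk]])) next
        seen[[pk]] <- TRUE
        if (length(intersect(cl[[a]], cl[[b]])) >= k - 1L) unite(a, b)
      }
    }
  }
  comp <- vapply(seq_len(nc), find, 1L)
  groups <- split(seq_len(nc), comp)
  vnames <- igraph::V(g)$name
  mods <- lapply(groups, function(idx) vnames[sort(unique(unlist(cl[idx])))])
  module_set(mods, net$name, "cpm", list(k = k), overlapping = TRUE)
}

partition_membership <- function(net, partition) {
  if (inherits(partition, "module_set")) partition <- partition$modules
  if (is.list(partition)) {
    mem <- stats::setNames(rep(NA_integer_, n_nodes(net)), net$nodes)
    for (i in seq_along(partition)) {
      ids <- as.character(partition[[i]])
      if (any(!ids %in% net$nodes)) stop("partition contains unknown nodes")
      if (any(!is.na(mem[ids]))) stop("partition modules overlap")
      mem[ids] <- i
    }
    if (any(is.na(mem))) stop("partition must cover all nodes")
    mem
  } else {
    if (!all(net$nodes %in% names(partition))) stop("partition must cover all nodes")
    m <- partition[net$nodes]
    stats::setNames(as.integer(factor(m)), net$nodes)
  }
}

#' Modularity M of a partition
#'
#' \deqn{M = \sum_s [ l_s/L - (k_s / 2L)^2 ]}
#' where \eqn{L} is the number of edges in the network, \eqn{l_s} the number
#' of edges within module \eqn{s}, and \eqn{k_s} the sum of degrees of the
#' module's nodes. The trivial one-module partition scores 0.
#'
#' @param net a \code{\link{ppi_network}} with at least one edge.
#' @param partition a \code{\link{module_set}}, a list of disjoint node sets
#'   covering all nodes, or a named membership vector.
#' @return Numeric modularity, or \code{NA} if the network has no edges.
#' @export
modularity_score <- function(net, partition) {
  stopifnot(inherits(net, "ppi_network"))
  L <- n_edges(net)
  if (L == 0L) return(NA_real_)
  mem <- partition_membership(net, partition)
  ma <- mem[net$edges[, 1L]]
  mb <- mem[net$edges[, 2L]]
  nmod <- max(mem)
  l_s <- vapply(seq_len(nmod), function(s) as.numeric(sum(ma == s & mb == s)), 0)
  deg <- table(factor(c(net$edges[, 1L], net$edges[, 2L]), levels = net$nodes))
  k_s <- vapply(seq_len(nmod), function(s) as.numeric(sum(deg[net$nodes[mem == s]])), 0)
  sum(l_s / L - (k_s / (2 * L))^2)
}

#' Modularity maximization by simulated annealing
#'
#' Optimizes the modularity score \code{M} over partitions by simulated
#' annealing: per temperature, \code{moves_factor * |V|^2} single-node
#' reassignment proposals (to an existing or a fresh module) plus \code{|V|}
#' collective proposals (merging two modules or randomly bisecting one),
#' accepted by the Metropolis rule. Starts from the singleton partition; the
#' best partition seen is returned, so the result never scores below the
#' starting point. Fully reproducible under \code{seed}. Temperatures are
#' expressed in units of the elementary modularity change \code{1/L} (one
#' edge moving in or out of a module), so the same schedule anneals properly
#' at any network size.
#'
#' @param net a \code{\link{ppi_network}} with at least one edge.
#' @param t0 initial temperature (default 1).
#' @param cooling geometric cooling factor in (0,1) (default 0.95).
#' @param moves_factor single-node proposals per temperature as a multiple of
#'   \code{|V|^2} (default 1).
#' @param t_min stopping temperature (default 1e-3).
#' @param seed integer seed.
#' @return A \code{\link{module_set}} with its \code{modularity} filled in.
#' @export
sa_modularity <- function(net, t0 = 1, cooling = 0.95, moves_factor = 1,
                          t_min = 1e-3, seed = 1L) {
  stopifnot(inherits(net, "ppi_network"), t0 > 0, cooling > 0, cooling < 1,
            t_min > 0, moves_factor > 0)
  L <- n_edges(net)
  if (L == 0L) stop("network has no edges")
  set.seed(seed)
  n <- n_nodes(net)
  idx <- stats::setNames(seq_len(n), net$nodes)
  em <- cbind(idx[net$edges[, 1L]], idx[net$edges[, 2L]]) - 1L
  storage.mode(em) <- "integer"
  # temperatures are in units of the elementary modularity change 1/L, so
  # the default schedule anneals through the scale of single-edge moves
  # regardless of network size
  res <- .sa_partition_cpp(n, em, t0 / L, cooling, moves_factor, t_min / L)
  mods <- split(net$nodes, res$membership)
  module_set(mods, net$name, "sa",
             list(t0 = t0, cooling = cooling, moves_factor = moves_factor,
                  t_min = t_min, seed = seed),
             overlapping = FALSE, modularity = res$modularity)
}

#' Edge-betweenness partitioning (fraction cutoff)
#'
#' Iteratively removes the edge with the highest edge betweenness
#' (recomputing betweenness after every removal; ties broken by the
#' lexicographically smallest canonical edge ID) until
#' \code{round(removal_fraction * L)} edges are gone. Modules are the
#' connected components of the residue; singleton components are dropped.
#'
#' @param net a \code{\link{ppi_network}}.
#' @param removal_fraction fraction of edges to remove, in \code{[0, 1)}.
#' @return A \code{\link{module_set}} (non-overlapping).
#' @export
girvan_newman <- function(net, removal_fraction = 0.4) {
  stopifnot(inherits(net, "ppi_network"),
            removal_fraction >= 0, removal_fraction < 1)
  g <- as_igraph(net)
  n_remove <- round(removal_fraction * n_edges(net))
  for (i in seq_len(n_remove)) {
    eb <- igraph::edge_betweenness(g, directed = FALSE)
    top <- which(eb >= max(eb) - 1e-9)
    if (length(top) > 1L) {
      ends <- igraph::ends(g, igraph::E(g)[top])
      keys <- edge_key(ends[, 1L], ends[, 2L])
      top <- top[order(keys)][1L]
    }
    g <- igraph::delete_edges(g, top)
  }
  comp <- igraph::components(g)
  groups <- split(igraph::V(g)$name, comp$membership)
  groups <- groups[vapply(groups, length, 1L) >= 2L]
  module_set(groups, net$name, "gn",
             list(removal_fraction = removal_fraction), overlapping = FALSE)
}

# Best admissible match of focal module `f` among `candidates`: the module
# maximizing shared-node count, admissible only when shared >= 50% of |f|.
# Ties: larger Jaccard with the focal module, then lexicographic module ID.
best_match <- function(f, candidates) {
  shared <- vapply(candidates, function(g) length(intersect(f, g)), 1L)
  mx <- max(shared)
  if (mx < 0.5 * length(f)) return(NULL)
  tied <- names(candidates)[shared == mx]
  if (length(tied) > 1L) {
    jac <- vapply(candidates[tied],
                  function(g) length(intersect(f, g)) / length(union(f, g)), 0)
    tied <- tied[jac == max(jac)]
    tied <- sort(tied)
  }
  tied[1L]
}

#' Modular compatibility score Cp between two module sets
#'
#' For each module of one set, its most compatible module in the other set is
#' the one sharing the most nodes, admissible only when the shared nodes are
#' at least 50\% of the focal module's size; the per-module agreement term is
#' \eqn{C / (T + P - C)} (shared over union of the matched pair), and
#' unmatched modules contribute 0. Each direction's terms are averaged over
#' its module count and the two directional means are averaged, giving
#' \eqn{Cp \in [0, 1]} with \eqn{Cp(S, S) = 1}; the score is symmetric in the
#' pair order.
#'
#' @param S1,S2 non-empty \code{\link{module_set}}s.
#' @return Object of class \code{cp_result}: list with \code{Cp},
#'   \code{matches} (per-module data frame: direction, module, matched module,
#'   T, P, C, term) and \code{threshold} (the 0.5 coverage rule).
#' @export
modular_compatibility <- function(S1, S2) {
  stopifnot(inherits(S1, "module_set"), inherits(S2, "module_set"))
  if (n_modules(S1) == 0L || n_modules(S2) == 0L) stop("empty module set")
  one_direction <- function(A, B, dir) {
    rows <- lapply(names(A$modules), function(id) {
      f <- A$modules[[id]]
      m <- best_match(f, B$modules)
      if (is.null(m)) {
        data.frame(direction = dir, module = id, match = NA_character_,
                   T = length(f), P = NA_integer_, C = NA_integer_, term = 0,
                   stringsAsFactors = FALSE)
      } else {
        g <- B$modules[[m]]
        C <- length(intersect(f, g))
        data.frame(direction = dir, module = id, match = m,
                   T = length(f), P = length(g), C = C,
                   term = C / (length(f) + length(g) - C),
                   stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, rows)
  }
  d1 <- one_direction(S1, S2, "1->2")
  d2 <- one_direction(S2, S1, "2->1")
  cp <- 0.5 * (mean(d1$term) + mean(d2$term))
  structure(list(pair = c(S1$network, S2$network), Cp = cp,
                 matches = rbind(d1, d2), threshold = 0.5,
                 normalization = "per-direction mean of module terms"),
            class = "cp_result")
}

#' @export
print.cp_result <- function(x, ...) {
  cat(sprintf("<cp_result> %s vs %s: Cp = %.4f\n", x$pair[1L], x$pair[2L], x$Cp))
  invisible(x)
}

run_clustering <- function(net, algorithm, param, sa_control = list()) {
  switch(algorithm,
    cpm = clique_percolation(net, k = as.integer(param)),
    gn = girvan_newman(net, removal_fraction = as.numeric(param)),
    sa = do.call(sa_modularity,
                 c(list(net = net, seed = as.integer(param)), sa_control)),
    stop("unknown algorithm"))
}

#' Modular compatibility comparison protocol
#'
#' Contrasts (i) Cp between total-network modules and each subnetwork's
#' modules at matched clustering parameters with (ii) Cp between module sets
#' of the same network across different parameter settings, and compares the
#' two groups with a two-sided Mann-Whitney U test. Low group-(i) relative to
#' group-(ii) values indicate that modules of the conglomerate/total network
#' do not carry over to context subnetworks.
#'
#' @param family a \code{\link{stratified_family}}.
#' @param algorithm \code{"cpm"} (param = k), \code{"gn"} (param = removal
#'   fraction) or \code{"sa"} (param = seed).
#' @param param_grid list/vector of at least two parameter settings.
#' @param contexts which subnetworks to compare against the total; defaults to
#'   the level-3 contexts.
#' @param sa_control extra arguments for \code{\link{sa_modularity}} (e.g. a
#'   shortened schedule).
#' @return Object of class \code{cp_report}: data frames \code{between}
#'   (total-vs-subnetwork Cp) and \code{within} (same-network Cp across
#'   parameters), group means/medians and the Mann-Whitney \code{statistic}
#'   and \code{p.value}.
#' @export
cp_comparison_protocol <- function(family, algorithm = c("cpm", "gn", "sa"),
                                   param_grid = NULL, contexts = NULL,
                                   sa_control = list()) {
  stopifnot(inherits(family, "stratified_family"))
  algorithm <- match.arg(algorithm)
  if (is.null(param_grid)) {
    param_grid <- switch(algorithm, cpm = list(3L, 4L, 5L),
                         gn = list(0.3, 0.4, 0.5), sa = list(1L, 2L, 3L))
  }
  if (length(param_grid) < 2L) stop("param_grid needs at least 2 settings")
  if (is.null(contexts)) contexts <- contexts_at_level(family, 3L)
  contexts <- setdiff(contexts, family$total)
  nets <- c(family$total, contexts)
  msets <- list()
  for (nm in nets) {
    for (pi in seq_along(param_grid)) {
      msets[[paste(nm, pi, sep = "@")]] <-
        run_clustering(family$networks[[nm]], algorithm, param_grid[[pi]],
                       sa_control)
    }
  }
  cp_or_na <- function(a, b) {
    if (n_modules(a) == 0L || n_modules(b) == 0L) return(NA_real_)
    modular_compatibility(a, b)$Cp
  }
  between <- do.call(rbind, lapply(contexts, function(ctx) {
    do.call(rbind, lapply(seq_along(param_grid), function(pi) {
      data.frame(context = ctx, param = pi,
                 Cp = cp_or_na(msets[[paste(family$total, pi, sep = "@")]],
                               msets[[paste(ctx, pi, sep = "@")]]),
                 stringsAsFactors = FALSE)
    }))
  }))
  pairs <- utils::combn(seq_along(param_grid), 2L)
  within <- do.call(rbind, lapply(nets, function(nm) {
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      data.frame(network = nm, param_a = pairs[1L, j], param_b = pairs[2L, j],
                 Cp = cp_or_na(msets[[paste(nm, pairs[1L, j], sep = "@")]],
                               msets[[paste(nm, pairs[2L, j], sep = "@")]]),
                 stringsAsFactors = FALSE)
    }))
  }))
  gi <- between$Cp[!is.na(between$Cp)]
  gii <- within$Cp[!is.na(within$Cp)]
  mw <- if (length(gi) && length(gii)) {
    if (stats::sd(c(gi, gii)) == 0) {
      list(statistic = length(gi) * length(gii) / 2, p.value = 1)
    } else {
      suppressWarnings(stats::wilcox.test(gi, gii, exact = FALSE))
    }
  } else NULL
  structure(list(algorithm = algorithm, param_grid = param_grid,
                 between = between, within = within,
                 mean_between = mean(gi), mean_within = mean(gii),
                 median_between = stats::median(gi),
                 median_within = stats::median(gii),
                 statistic = if (is.null(mw)) NA_real_ else unname(mw$statistic),
                 p.value = if (is.null(mw)) NA_real_ else mw$p.value),
            class = "cp_report")
}

#' @export
print.cp_report <- function(x, ...) {
  cat(sprintf("<cp_report> %s: mean Cp total-vs-subnetwork %.3f, within-network %.3f\n",
              x$algorithm, x$mean_between, x$mean_within))
  cat(sprintf("  Mann-Whitney U = %g, p = %.3g\n", x$statistic, x$p.value))
  invisible(x)
}
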