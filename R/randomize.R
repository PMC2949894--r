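#' Degree-constrained random node-sampling subnetwork
#'
#' Builds a randomized analogue of a real context subnetwork: a uniform node
#' sample overlaid on the total network (induced subnetwork), accepted only if
#' its total degree (twice the edge count) is within \code{tolerance} of the
#' reference subnetwork's. Because uniform samples of the exact list size
#' often cannot reach the reference density, rejected draws adapt the sample
#' size toward the degree target (\code{s <- s * sqrt(D_ref / D)}), mimicking
#' the "similar number of proteins" convention; every emitted replicate
#' satisfies the tolerance exactly at whatever size was accepted.
#'
#' @param total the total \code{\link{ppi_network}}.
#' @param n_proteins target node-sample size (the context list size).
#' @param reference the real subnetwork being mimicked (a
#'   \code{\link{ppi_network}}), or \code{NULL} to skip the degree constraint.
#' @param tolerance relative total-degree tolerance (default 0.10).
#' @param seed optional integer seed.
#' @param max_retries attempts before giving up (default 200).
#' @return A \code{\link{ppi_network}} with attributes \code{sample_size} and
#'   \code{retries}.
#' @export
random_subnetwork <- function(total, n_proteins, reference = NULL,
                              tolerance = 0.10, seed = NULL,
                              max_retries = 200L) {
  stopifnot(inherits(total, "ppi_network"), tolerance > 0)
  N <- n_nodes(total)
  if (n_proteins > N) stop("sample size exceeds total network size")
  if (!is.null(seed)) set.seed(seed)
  target <- if (is.null(reference)) NA_real_ else 2 * n_edges(reference)
  s <- as.integer(n_proteins)
  achieved <- c(Inf, -Inf)
  for (try in seq_len(max_retries)) {
    nodes <- sample(total$nodes, s)
    sub <- induce_subnetwork(total, nodes, name = "randomized")
    D <- 2 * n_edges(sub)
    if (is.null(reference) || abs(D - target) <= tolerance * target) {
      attr(sub, "sample_size") <- s
      attr(sub, "retries") <- try
      return(sub)
    }
    achieved <- c(min(achieved[1L], D), max(achieved[2L], D))
    if (D > 0) {
      s <- as.integer(round(s * sqrt(target / D)))
      s <- max(3L, min(N, s))
    } else {
      s <- min(N, s * 2L)
    }
  }
  stop(sprintf(
    "random_subnetwork: no draw within %.0f%% of target total degree %g after %d retries (achieved range %g-%g)",
    100 * tolerance, target, max_retries, achieved[1L], achieved[2L]))
}

#' Replace a fraction of interactions with random absent pairs
#'
#' Removes \code{round(fraction * L)} uniformly chosen edges and adds the same
#' number of uniformly chosen node pairs that are absent from the original
#' network (and from \code{universe} if given). Endpoints are drawn from the
#' network's existing node set; the node set and edge count are conserved
#' exactly. Models false-positive interactions in assembled networks.
#'
#' @param net a \code{\link{ppi_network}}.
#' @param fraction fraction of edges to replace, in \code{[0, 1)}.
#' @param seed optional integer seed.
#' @param universe optional \code{\link{ppi_network}} whose edges are also
#'   avoided when drawing new pairs.
#' @return A \code{\link{ppi_network}} with the same nodes and edge count.
#' @export
replace_interactions <- function(net, fraction, seed = NULL, universe = NULL) {
  stopifnot(inherits(net, "ppi_network"), fraction >= 0, fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  L <- n_edges(net)
  n_rep <- round(fraction * L)
  if (n_rep == 0L) {
    out <- net
    out$name <- paste0(net$name, ".replaced0")
    return(out)
  }
  nodes <- net$nodes
  n <- length(nodes)
  if (L >= n * (n - 1) / 2) stop("no absent pairs: network is complete")
  forbidden <- edge_keys(net)
  if (!is.null(universe)) forbidden <- union(forbidden, edge_keys(universe))
  drop_idx <- sample.int(L, n_rep)
  kept <- net$edges[-drop_idx, , drop = FALSE]
  new_keys <- character(0)
  guard <- 0L
  while (length(new_keys) < n_rep) {
    need <- n_rep - length(new_keys)
    a <- sample(nodes, 2L * need + 10L, replace = TRUE)
    b <- sample(nodes, 2L * need + 10L, replace = TRUE)
    ok <- a != b
    cand <- unique(edge_key(a[ok], b[ok]))
    cand <- setdiff(cand, c(forbidden, new_keys))
    new_keys <- c(new_keys, utils::head(cand, need))
    guard <- guard + 1L
    if (guard > 1000L) stop("could not draw enough absent pairs")
  }
  new_edges <- do.call(rbind, strsplit(new_keys, "\t", fixed = TRUE))
  out <- ppi_network(rbind(kept, new_edges),
                     name = paste0(net$name, ".replaced"), nodes = nodes)
  stopifnot(n_edges(out) == L)
  out
}

#' False-interaction robustness protocol
#'
#' For each replacement fraction and seed: replaces that fraction of the
#' conglomerate's interactions with random absent pairs, restratifies with
#' the same context hierarchy, recomputes hub/bottleneck status-change
#' percentages and summary network statistics, and reports the deltas against
#' the unperturbed run.
#'
#' @param conglomerate the assembled \code{\link{ppi_network}}.
#' @param hierarchy a \code{\link{context_hierarchy}}.
#' @param fractions replacement fractions (default \code{c(0.1, 0.2, 0.3,
#'   0.4)}).
#' @param seeds integer seeds, one perturbed run per seed per fraction.
#' @param pct hub/bottleneck percent cutoff (default 20).
#' @param contexts contexts compared against the total (default: level 3).
#' @param kinds role kinds to track (default degree and betweenness).
#' @return Object of class \code{robustness_report}: data frames
#'   \code{baseline} (unperturbed percentages) and \code{deltas} (per
#'   fraction/seed/context/kind changes in status-change percentages and in
#'   average degree and clustering coefficient).
#' @export
robustness_protocol <- function(conglomerate, hierarchy,
                                fractions = c(0.1, 0.2, 0.3, 0.4),
                                seeds = 1:3, pct = 20, contexts = NULL,
                                kinds = c("degree", "betweenness")) {
  run_once <- function(net) {
    fam <- stratify_all(net, hierarchy)
    ctxs <- if (is.null(contexts)) contexts_at_level(fam, 3L) else contexts
    ctxs <- setdiff(ctxs, fam$total)
    st_total <- node_stats(fam$networks[[fam$total]])
    rows <- list()
    for (kind in kinds) {
      ref <- identify_roles(st_total, kind, pct)
      for (ctx in ctxs) {
        st_c <- node_stats(fam$networks[[ctx]])
        sc <- status_change(ref, identify_roles(st_c, kind, pct))
        rows[[paste(kind, ctx)]] <- data.frame(
          kind = kind, context = ctx,
          pct_role_to_nonrole = sc$pct_role_to_nonrole,
          pct_nonrole_to_role = sc$pct_nonrole_to_role,
          avg_degree = mean(st_c$table$degree),
          avg_clustering = mean(st_c$table$clustering),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  base <- run_once(conglomerate)
  rownames(base) <- NULL
  deltas <- list()
  for (f in fractions) {
    for (s in seeds) {
      pert <- replace_interactions(conglomerate, f, seed = s)
      res <- run_once(pert)
      d <- merge(base, res, by = c("kind", "context"),
                 suffixes = c("_base", "_pert"))
      deltas[[paste(f, s)]] <- data.frame(
        fraction = f, seed = s, kind = d$kind, context = d$context,
        d_role_to_nonrole = d$pct_role_to_nonrole_pert - d$pct_role_to_nonrole_base,
        d_nonrole_to_role = d$pct_nonrole_to_role_pert - d$pct_nonrole_to_role_base,
        d_avg_degree = d$avg_degree_pert - d$avg_degree_base,
        d_avg_clustering = d$avg_clustering_pert - d$avg_clustering_base,
        stringsAsFactors = FALSE)
    }
  }
  deltas <- do.call(rbind, deltas)
  rownames(deltas) <- NULL
  structure(list(baseline = base, deltas = deltas, pct = pct,
                 fractions = fractions, seeds = seeds),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("<robustness_report>\n")
  agg <- stats::aggregate(
    cbind(d_role_to_nonrole, d_nonrole_to_role) ~ fraction + kind,
    data = x$deltas, FUN = function(v) mean(abs(v)))
  print(agg, row.names = FALSE)
  invisible(x)
}
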