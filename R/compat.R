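#' Jaccard index of two sets
#'
#' \eqn{|A \cap B| / |A \cup B|}. Vectors are treated as sets (duplicates
#' ignored). When both sets are empty the index is defined as 0, with a
#' warning, to avoid 0/0.
#'
#' @param a,b vectors.
#' @return Numeric in \code{[0, 1]}.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) {
    warning("Jaccard of two empty sets; returning 0")
    return(0)
  }
  length(intersect(a, b)) / u
}

#' Node and edge agreement between two networks
#'
#' Network compatibility measured by the Jaccard index over node sets
#' (\code{J_v}) and over canonical unordered edge pairs (\code{J_e}).
#' Symmetric in the pair order.
#'
#' @param A,B \code{\link{ppi_network}}s.
#' @return Object of class \code{compat_result}: list with \code{pair},
#'   \code{J_v}, \code{J_e}.
#' @export
network_compatibility <- function(A, B) {
  stopifnot(inherits(A, "ppi_network"), inherits(B, "ppi_network"))
  jv <- if (n_nodes(A) + n_nodes(B) == 0L) 0 else jaccard(A$nodes, B$nodes)
  je <- if (n_edges(A) + n_edges(B) == 0L) 0 else jaccard(edge_keys(A), edge_keys(B))
  structure(list(pair = c(A$name, B$name), J_v = jv, J_e = je),
            class = "compat_result")
}

#' @export
print.compat_result <- function(x, ...) {
  cat(sprintf("<compat_result> %s vs %s: J_v = %.4f, J_e = %.4f\n",
              x$pair[1L], x$pair[2L], x$J_v, x$J_e))
  invisible(x)
}

# Induced node/edge sets for a node sample, without building a full network.
induced_sets <- function(total, nodes) {
  sel <- total$edges[, 1L] %in% nodes & total$edges[, 2L] %in% nodes
  em <- total$edges[sel, , drop = FALSE]
  list(nodes = unique(c(em[, 1L], em[, 2L])),
       edges = if (nrow(em)) paste(em[, 1L], em[, 2L], sep = "\t") else character())
}

#' Randomized null for network compatibility
#'
#' Builds \code{n_rep} pairs of randomized networks by uniformly sampling
#' \code{sizeA} and \code{sizeB} nodes from the total network (independent
#' samples, paired replicate-wise) and inducing subnetworks, then computes the
#' node and edge Jaccard index for each pair. If observed values are supplied,
#' two-sided one-sample Student's t-tests compare each observed index against
#' the corresponding null replicate distribution.
#'
#' @param total the total \code{\link{ppi_network}} sampled from.
#' @param sizeA,sizeB node-sample sizes (each <= number of nodes in
#'   \code{total}).
#' @param n_rep number of replicate pairs; default 500.
#' @param seed optional integer seed for reproducibility.
#' @param observed optional \code{\link{network_compatibility}} result (or
#'   list with \code{J_v}, \code{J_e}) to test against the null.
#' @return List with \code{null_v}, \code{null_e} (replicate vectors), their
#'   means/sds, and \code{p_v}, \code{p_e} when \code{observed} is given.
#' @export
compatibility_null <- function(total, sizeA, sizeB, n_rep = 500, seed = NULL,
                               observed = NULL) {
  stopifnot(inherits(total, "ppi_network"))
  n <- n_nodes(total)
  if (sizeA > n || sizeB > n) stop("sample size exceeds total network size")
  if (!is.null(seed)) set.seed(seed)
  null_v <- numeric(n_rep); null_e <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    sa <- induced_sets(total, sample(total$nodes, sizeA))
    sb <- induced_sets(total, sample(total$nodes, sizeB))
    uv <- length(union(sa$nodes, sb$nodes))
    ue <- length(union(sa$edges, sb$edges))
    null_v[i] <- if (uv == 0L) 0 else length(intersect(sa$nodes, sb$nodes)) / uv
    null_e[i] <- if (ue == 0L) 0 else length(intersect(sa$edges, sb$edges)) / ue
  }
  out <- list(null_v = null_v, null_e = null_e,
              mean_v = mean(null_v), sd_v = stats::sd(null_v),
              mean_e = mean(null_e), sd_e = stats::sd(null_e),
              n_rep = n_rep,
              pairing = "replicate i of sample A vs replicate i of sample B",
              test = "one-sample two-sided Student's t of null replicates vs observed")
  if (!is.null(observed)) {
    one_sample_p <- function(nulls, obs) {
      if (stats::sd(nulls) == 0) return(if (isTRUE(all.equal(mean(nulls), obs))) 1 else 0)
      stats::t.test(nulls, mu = obs)$p.value
    }
    out$observed_v <- observed$J_v
    out$observed_e <- observed$J_e
    out$p_v <- one_sample_p(null_v, observed$J_v)
    out$p_e <- one_sample_p(null_e, observed$J_e)
  }
  out
}
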