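# Threshold value for "top pct% of nodes" on a statistic vector: the value at
# descending rank ceil(pct/100 * N). Ties at the threshold are inclusive, so
# the flagged set may exceed pct% of nodes.
top_pct_threshold <- function(values, pct) {
  n <- length(values)
  r <- max(1L, ceiling(pct / 100 * n))
  sort(values, decreasing = TRUE)[r]
}

#' Identify network hubs or bottlenecks
#'
#' Hubs are nodes in the top \code{pct}\% of degree values, bottlenecks the
#' top \code{pct}\% of betweenness values. The threshold is the statistic of
#' the node at descending rank \code{ceiling(pct/100 * N)}; every node with a
#' value greater than or equal to the threshold is flagged, so threshold ties
#' all become roles.
#'
#' @param stats a \code{\link{node_stats}} object.
#' @param kind \code{"degree"} (hubs) or \code{"betweenness"} (bottlenecks).
#' @param pct percent cutoff in (0, 100); default 20.
#' @return An object of class \code{role_assignment}: list with \code{network},
#'   \code{kind}, \code{pct}, \code{threshold} and \code{roles} (named logical
#'   over all nodes).
#' @export
identify_roles <- function(stats, kind = c("degree", "betweenness"), pct = 20) {
  kind <- match.arg(kind)
  stopifnot(pct > 0, pct < 100)
  v <- stat_vector(stats, kind)
  if (length(v) == 0L) stop("empty statistics table")
  thr <- unname(top_pct_threshold(v, pct))
  structure(list(network = stats$network, kind = kind, pct = pct,
                 threshold = thr, roles = v >= thr),
            class = "role_assignment")
}

#' @export
print.role_assignment <- function(x, ...) {
  cat(sprintf("<role_assignment> %s: top %g%% by %s, threshold %g, %d/%d flagged\n",
              x$network, x$pct, x$kind, x$threshold, sum(x$roles), length(x$roles)))
  invisible(x)
}

#' Role status change between two networks
#'
#' Counts, over the nodes present in both networks, how many reference-network
#' roles (hubs/bottlenecks) are demoted to non-roles in the comparison network
#' and how many non-roles are promoted to roles. Reference roles absent from
#' the comparison network are reported separately, not folded into demotions.
#' The promotion percentage divides by the comparison network's role count
#' (the convention used for reporting "non-hub to hub" rates); the demotion
#' percentage divides by the reference roles present in the comparison
#' network.
#'
#' @param ref,cmp \code{\link{identify_roles}} results of the same kind.
#' @return An object of class \code{status_change}: list of counts
#'   (\code{role_to_nonrole}, \code{role_to_role}, \code{nonrole_to_role},
#'   \code{role_absent}, \code{n_ref_roles}, \code{n_cmp_roles}) and
#'   percentages (\code{pct_role_to_nonrole}, \code{pct_nonrole_to_role}).
#' @export
status_change <- function(ref, cmp) {
  stopifnot(inherits(ref, "role_assignment"), inherits(cmp, "role_assignment"))
  if (ref$kind != cmp$kind) stop("role kinds differ")
  shared <- intersect(names(ref$roles), names(cmp$roles))
  r <- ref$roles[shared]; c_ <- cmp$roles[shared]
  role_to_nonrole <- sum(r & !c_)
  role_to_role <- sum(r & c_)
  nonrole_to_role <- sum(!r & c_)
  role_absent <- sum(ref$roles) - role_to_nonrole - role_to_role
  n_ref_shared <- role_to_nonrole + role_to_role
  structure(list(
    reference = ref$network, comparison = cmp$network, kind = ref$kind,
    role_to_nonrole = role_to_nonrole,
    role_to_role = role_to_role,
    nonrole_to_role = nonrole_to_role,
    role_absent = role_absent,
    n_ref_roles = sum(ref$roles),
    n_cmp_roles = sum(cmp$roles),
    pct_role_to_nonrole = if (n_ref_shared > 0) 100 * role_to_nonrole / n_ref_shared else NA_real_,
    pct_nonrole_to_role = if (sum(cmp$roles) > 0) 100 * nonrole_to_role / sum(cmp$roles) else NA_real_
  ), class = "status_change")
}

#' @export
print.status_change <- function(x, ...) {
  cat(sprintf("<status_change> %s vs %s (%s)\n", x$reference, x$comparison, x$kind))
  cat(sprintf("  role->nonrole %d (%.1f%%)  nonrole->role %d (%.1f%%)  role absent %d\n",
              x$role_to_nonrole, x$pct_role_to_nonrole,
              x$nonrole_to_role, x$pct_nonrole_to_role, x$role_absent))
  invisible(x)
}

#' Assign nodes to degree/betweenness classes
#'
#' Nodes are put into exclusive classes by percentile bands of a statistic:
#' with cutoffs \code{c(5, 10, 20, 50)}, class 1 is the top 5\%, class 2 the
#' next band up to the top-10\% threshold, and so on, with a final class for
#' the remainder. Band thresholds use the same inclusive top-percent rule as
#' \code{\link{identify_roles}}. Alternate schemes (e.g. \code{c(10, 20, 50)}
#' for four classes, or \code{c(5, 15, 25, 60)}) are accepted.
#'
#' @param stats a \code{\link{node_stats}} object.
#' @param kind \code{"degree"} or \code{"betweenness"}.
#' @param cutoffs strictly increasing percent cutoffs, all < 100.
#' @return An object of class \code{class_assignment}: list with
#'   \code{classes} (named integer, 1 = top band), \code{cutoffs},
#'   \code{thresholds}, \code{kind}, \code{network}.
#' @export
assign_classes <- function(stats, kind = c("degree", "betweenness"),
                           cutoffs = c(5, 10, 20, 50)) {
  kind <- match.arg(kind)
  if (any(diff(cutoffs) <= 0) || any(cutoffs >= 100) || any(cutoffs <= 0)) {
    stop("cutoffs must be strictly increasing and in (0, 100)")
  }
  v <- stat_vector(stats, kind)
  thr <- vapply(cutoffs, function(p) top_pct_threshold(v, p), 0)
  cls <- rep.int(length(cutoffs) + 1L, length(v))
  for (k in rev(seq_along(cutoffs))) cls[v >= thr[k]] <- k
  structure(list(network = stats$network, kind = kind, cutoffs = cutoffs,
                 thresholds = thr, classes = stats::setNames(cls, names(v))),
            class = "class_assignment")
}

#' Class changes and leap changes between two networks
#'
#' For nodes present in both class assignments, tabulates the class shift
#' (comparison minus reference; positive means demotion toward lower bands)
#' and flags leap changes, i.e. shifts of \code{leap} (default 2) or more
#' classes in either direction.
#'
#' @param a,b \code{\link{assign_classes}} results with identical kind and
#'   cutoff scheme.
#' @param leap minimum absolute shift that counts as a leap; default 2.
#' @return Data frame with columns \code{protein}, \code{class_a},
#'   \code{class_b}, \code{delta}, \code{leap}.
#' @export
class_changes <- function(a, b, leap = 2L) {
  stopifnot(inherits(a, "class_assignment"), inherits(b, "class_assignment"))
  if (a$kind != b$kind) stop("class kinds differ")
  if (!identical(a$cutoffs, b$cutoffs)) stop("cutoff schemes differ")
  shared <- intersect(names(a$classes), names(b$classes))
  ca <- a$classes[shared]; cb <- b$classes[shared]
  data.frame(protein = shared, class_a = as.integer(ca),
             class_b = as.integer(cb), delta = as.integer(cb - ca),
             leap = abs(cb - ca) >= leap,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare a statistic's distribution between two networks
#'
#' Two-sided test of a per-node statistic between two networks: Welch's t-test
#' (default), Student's t-test, or the Mann-Whitney U test.
#'
#' @param statsA,statsB \code{\link{node_stats}} objects.
#' @param statistic one of \code{"degree"}, \code{"betweenness"},
#'   \code{"clustering"}, \code{"eccentricity"}.
#' @param test \code{"welch"}, \code{"student"} or \code{"mannwhitney"}.
#' @return List with \code{statistic} (test statistic value), \code{p.value},
#'   \code{test} and \code{note} (non-\code{NA} when the test degenerates,
#'   e.g. zero variance in both samples).
#' @export
compare_stat_distributions <- function(statsA, statsB,
                                       statistic = "degree",
                                       test = c("welch", "student", "mannwhitney")) {
  test <- match.arg(test)
  x <- stat_vector(statsA, statistic)
  y <- stat_vector(statsB, statistic)
  if (length(x) < 2L || length(y) < 2L) stop("need at least 2 observations per side")
  res <- tryCatch({
    ht <- switch(test,
      welch = stats::t.test(x, y, var.equal = FALSE),
      student = stats::t.test(x, y, var.equal = TRUE),
      mannwhitney = suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    )
    list(statistic = unname(ht$statistic), p.value = ht$p.value,
         test = test, note = NA_character_)
  }, error = function(e) {
    list(statistic = NA_real_, p.value = NA_real_, test = test,
         note = conditionMessage(e))
  })
  res
}

#' Power-law slope of the degree distribution
#'
#' Descriptive scale-free check: least-squares slope of log degree frequency
#' against log degree over nonzero-frequency, nonzero-degree bins.
#'
#' @param stats a \code{\link{node_stats}} object.
#' @param min_distinct minimum number of distinct positive degree values
#'   required; fewer returns \code{NA} slope.
#' @return List with \code{slope}, \code{r.squared}, \code{n_bins}.
#' @export
powerlaw_slope <- function(stats, min_distinct = 5L) {
  deg <- stats$table$degree
  deg <- deg[deg > 0]
  tab <- table(deg)
  k <- as.numeric(names(tab))
  f <- as.numeric(tab)
  if (length(k) < min_distinct) {
    return(list(slope = NA_real_, r.squared = NA_real_, n_bins = length(k)))
  }
  fit <- stats::lm(log(f) ~ log(k))
  list(slope = unname(stats::coef(fit)[2L]),
       r.squared = suppressWarnings(summary(fit)$r.squared),
       n_bins = length(k))
}
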