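#' Read a protein annotation map
#'
#' TSV with columns \code{protein}, \code{category} (biological_process,
#' molecular_function or cellular_component), \code{term_id} and optional
#' \code{term_label}; \code{#} comment lines allowed. Terms are opaque,
#' already-mapped labels (e.g. GO slim); a protein may carry many terms.
#'
#' @param path file path.
#' @return Data frame of class \code{annotation_map}.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  annotation_map(df)
}

#' Build an annotation map from a data frame
#'
#' @param df data frame with columns \code{protein}, \code{category},
#'   \code{term_id} and optional \code{term_label}.
#' @return Data frame of class \code{annotation_map}, de-duplicated.
#' @export
annotation_map <- function(df) {
  need <- c("protein", "category", "term_id")
  if (!all(need %in% names(df))) {
    stop("annotation map needs columns protein, category, term_id")
  }
  if (is.null(df$term_label)) df$term_label <- df$term_id
  df <- df[!duplicated(df[, c("protein", "category", "term_id")]),
           c("protein", "category", "term_id", "term_label")]
  rownames(df) <- NULL
  class(df) <- c("annotation_map", "data.frame")
  df
}

annot_for_category <- function(annot, category) {
  a <- annot[annot$category == category, , drop = FALSE]
  if (nrow(a) == 0L) stop(sprintf("no annotations in category '%s'", category))
  a
}

# One-sided over-representation p from the 2x2 table (Fisher exact /
# hypergeometric upper tail): k of n foreground vs K of N universe.
fisher_over_p <- function(k, n, K, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Per-term functional enrichment of a protein set
#'
#' One-sided Fisher exact tests (over-representation) of each annotation term
#' in a foreground protein set against a background universe. The universe is
#' the annotated proteins of the background; unannotated proteins are excluded
#' from both margins, and the foreground is intersected with the universe.
#'
#' @param foreground character vector of protein IDs (or a
#'   \code{\link{ppi_network}}, whose nodes are used).
#' @param background character vector of protein IDs (or network) defining the
#'   universe.
#' @param annot an \code{\link{annotation_map}}.
#' @param category annotation category to test (default
#'   \code{"biological_process"}).
#' @param alpha significance cutoff for the \code{enriched} flag (default
#'   5e-4).
#' @param adjust if \code{TRUE}, also report Benjamini-Hochberg q-values
#'   (raw p-values are always used for the \code{enriched} flag).
#' @return Data frame of class \code{enrichment_table}: one row per term with
#'   foreground/background counts and totals, \code{p.value}, optional
#'   \code{q.value}, and \code{enriched}.
#' @export
protein_enrichment <- function(foreground, background, annot,
                               category = "biological_process",
                               alpha = 5e-4, adjust = FALSE) {
  if (inherits(foreground, "ppi_network")) foreground <- foreground$nodes
  if (inherits(background, "ppi_network")) background <- background$nodes
  a <- annot_for_category(annot, category)
  universe <- intersect(unique(background), unique(a$protein))
  fg <- intersect(unique(foreground), universe)
  if (length(fg) == 0L) stop("no annotated foreground proteins")
  a <- a[a$protein %in% universe, , drop = FALSE]
  terms <- sort(unique(a$term_id))
  N <- length(universe); n <- length(fg)
  rows <- lapply(terms, function(t) {
    carriers <- a$protein[a$term_id == t]
    K <- length(unique(carriers))
    k <- length(intersect(carriers, fg))
    data.frame(term_id = t,
               term_label = a$term_label[match(t, a$term_id)],
               fg_count = k, fg_total = n, bg_count = K, bg_total = N,
               p.value = fisher_over_p(k, n, K, N),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (adjust) tab$q.value <- stats::p.adjust(tab$p.value, method = "BH")
  tab$enriched <- tab$p.value < alpha
  tab <- tab[order(tab$p.value, tab$term_id), ]
  rownames(tab) <- NULL
  attr(tab, "alpha") <- alpha
  attr(tab, "category") <- category
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}

# Count, per term, the interacting pairs of `net` whose two partners share
# the term; a pair sharing several terms counts once per shared term.
pair_term_counts <- function(net, a) {
  if (n_edges(net) == 0L) return(list(counts = integer(), n_pairs = 0L))
  terms_by_protein <- split(a$term_id, a$protein)
  e1 <- net$edges[, 1L]; e2 <- net$edges[, 2L]
  annotated <- e1 %in% names(terms_by_protein) & e2 %in% names(terms_by_protein)
  n_pairs <- sum(annotated)
  shared <- unlist(lapply(which(annotated), function(i) {
    intersect(terms_by_protein[[e1[i]]], terms_by_protein[[e2[i]]])
  }))
  list(counts = table(shared), n_pairs = n_pairs)
}

#' Per-term enrichment of interacting pairs sharing a function
#'
#' The unit of counting is an interacting pair whose two partners share the
#' same annotation term (a pair sharing several terms counts once per shared
#' term). Each term's pair count in the focal network is tested against the
#' background network's pairs by a one-sided Fisher exact test; the margins
#' are the networks' annotated pairs (both endpoints annotated in the
#' category).
#'
#' @param net focal \code{\link{ppi_network}}.
#' @param background_net background \code{\link{ppi_network}} (typically the
#'   total network).
#' @param annot an \code{\link{annotation_map}}.
#' @param category annotation category (default \code{"biological_process"}).
#' @param alpha significance cutoff (default 5e-4).
#' @return Data frame of class \code{enrichment_table} (counts are pair
#'   counts).
#' @export
pair_enrichment <- function(net, background_net, annot,
                            category = "biological_process", alpha = 5e-4) {
  a <- annot_for_category(annot, category)
  fgc <- pair_term_counts(net, a)
  bgc <- pair_term_counts(background_net, a)
  if (bgc$n_pairs == 0L) stop("no annotated pairs in the background network")
  terms <- sort(unique(names(bgc$counts)))
  rows <- lapply(terms, function(t) {
    K <- as.integer(bgc$counts[t])
    k <- if (t %in% names(fgc$counts)) as.integer(fgc$counts[t]) else 0L
    data.frame(term_id = t,
               term_label = a$term_label[match(t, a$term_id)],
               fg_count = k, fg_total = fgc$n_pairs,
               bg_count = K, bg_total = bgc$n_pairs,
               p.value = fisher_over_p(k, fgc$n_pairs, K, bgc$n_pairs),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$enriched <- tab$p.value < alpha
  tab <- tab[order(tab$p.value, tab$term_id), ]
  rownames(tab) <- NULL
  attr(tab, "alpha") <- alpha
  attr(tab, "category") <- category
  class(tab) <- c("enrichment_table", "data.frame")
  tab
}

#' Chi-squared comparison of two count distributions
#'
#' Tests whether observed counts \code{countsA} follow the proportions of a
#' reference vector \code{countsB} over the same index (terms or networks).
#' Cells whose expected count is below 1 are pooled into an \code{"other"}
#' cell before the asymptotic test.
#'
#' @param countsA observed counts (named numeric/integer).
#' @param countsB reference counts on the same index.
#' @return List with \code{statistic} (chi-squared), \code{df},
#'   \code{p.value} and \code{pooled} (number of cells pooled).
#' @export
distribution_chi2 <- function(countsA, countsB) {
  if (length(countsA) != length(countsB)) {
    if (is.null(names(countsA)) || is.null(names(countsB))) {
      stop("count vectors differ in length and are unnamed")
    }
    idx <- union(names(countsA), names(countsB))
    countsA <- stats::setNames(ifelse(idx %in% names(countsA), countsA[idx], 0), idx)
    countsB <- stats::setNames(ifelse(idx %in% names(countsB), countsB[idx], 0), idx)
  } else if (!is.null(names(countsA)) && !is.null(names(countsB))) {
    countsB <- countsB[names(countsA)]
  }
  if (sum(countsA) == 0 || sum(countsB) == 0) stop("all-zero count vector")
  expected <- sum(countsA) * countsB / sum(countsB)
  pool <- expected < 1
  n_pooled <- sum(pool)
  if (any(pool)) {
    if (sum(!pool) < 1L) stop("all cells pooled; distributions too sparse")
    countsA <- c(countsA[!pool], other = sum(countsA[pool]))
    countsB <- c(countsB[!pool], other = sum(countsB[pool]))
  }
  ht <- suppressWarnings(
    stats::chisq.test(x = countsA, p = countsB / sum(countsB))
  )
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, pooled = n_pooled)
}

#' Module-level enrichment summary across networks
#'
#' Runs per-module protein enrichment for every network's module set (modules
#' below \code{min_size} skipped) against that network's background, then
#' summarizes: the fraction of modules per network with at least one enriched
#' term; terms enriched in at least one module of every network (universal);
#' terms enriched in exactly one network's modules (exclusive); and, among the
#' conglomerate/total network's exclusive terms, candidate artifact terms —
#' functions over-represented only in modules of the assembled network and in
#' no context subnetwork's modules.
#'
#' @param modsets named list: network name -> \code{\link{module_set}}.
#' @param annot an \code{\link{annotation_map}}.
#' @param backgrounds named list: network name -> background protein IDs or
#'   \code{\link{ppi_network}}.
#' @param category annotation category (default \code{"biological_process"}).
#' @param alpha significance cutoff (default 5e-4).
#' @param conglomerate name of the total/conglomerate network among
#'   \code{modsets} (default: first name).
#' @param min_size minimum module size tested (default 3).
#' @return Object of class \code{module_enrichment_summary}: per-network data
#'   frame \code{fractions}, list \code{enriched_terms} (per network),
#'   \code{universal}, \code{exclusive} (per network) and
#'   \code{conglomerate_only} (candidate artifact terms).
#' @export
module_enrichment_summary <- function(modsets, annot, backgrounds,
                                      category = "biological_process",
                                      alpha = 5e-4,
                                      conglomerate = names(modsets)[1L],
                                      min_size = 3L) {
  stopifnot(length(modsets) > 0L, !is.null(names(modsets)))
  per_net_terms <- list()
  fractions <- data.frame(network = character(), n_modules = integer(),
                          n_enriched = integer(), fraction = numeric(),
                          stringsAsFactors = FALSE)
  for (nm in names(modsets)) {
    ms <- modsets[[nm]]
    bg <- backgrounds[[nm]]
    if (inherits(bg, "ppi_network")) bg <- bg$nodes
    mods <- Filter(function(m) length(m) >= min_size, ms$modules)
    enriched_any <- 0L
    terms <- character()
    for (m in mods) {
      tab <- tryCatch(
        protein_enrichment(m, bg, annot, category = category, alpha = alpha),
        error = function(e) NULL)
      if (is.null(tab)) next
      hit <- tab$term_id[tab$enriched]
      if (length(hit)) enriched_any <- enriched_any + 1L
      terms <- c(terms, hit)
    }
    per_net_terms[[nm]] <- sort(unique(terms))
    fractions <- rbind(fractions, data.frame(
      network = nm, n_modules = length(mods), n_enriched = enriched_any,
      fraction = if (length(mods)) enriched_any / length(mods) else NA_real_,
      stringsAsFactors = FALSE))
  }
  universal <- Reduce(intersect, per_net_terms)
  exclusive <- lapply(names(per_net_terms), function(nm) {
    others <- unique(unlist(per_net_terms[setdiff(names(per_net_terms), nm)]))
    setdiff(per_net_terms[[nm]], others)
  })
  names(exclusive) <- names(per_net_terms)
  structure(list(fractions = fractions, enriched_terms = per_net_terms,
                 universal = universal, exclusive = exclusive,
                 conglomerate = conglomerate,
                 conglomerate_only = exclusive[[conglomerate]],
                 alpha = alpha, category = category, min_size = min_size),
            class = "module_enrichment_summary")
}

#' @export
print.module_enrichment_summary <- function(x, ...) {
  cat("<module_enrichment_summary>\n")
  print(x$fractions, row.names = FALSE)
  cat(sprintf("  universal terms: %d; conglomerate-only (candidate artifact) terms: %d\n",
              length(x$universal), length(x$conglomerate_only)))
  invisible(x)
}
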