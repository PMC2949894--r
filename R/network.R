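#' @importFrom stats setNames
NULL

# Canonical key for an unordered edge: "lo\thi". IDs are opaque strings that
# cannot contain tabs (TSV input), so the key is collision-free.
edge_key <- function(a, b) {
  lo <- ifelse(a <= b, a, b)
  hi <- ifelse(a <= b, b, a)
  paste(lo, hi, sep = "\t")
}

canonical_edges <- function(a, b) {
  lo <- ifelse(a <= b, a, b)
  hi <- ifelse(a <= b, b, a)
  m <- cbind(lo, hi, deparse.level = 0)
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

#' Construct an undirected protein-protein interaction network
#'
#' Networks are undirected simple graphs over opaque protein identifiers.
#' Edges are canonicalized as sorted ID pairs; self-loops are dropped and
#' duplicate pairs collapsed. An optional provenance map records which source
#' dataset(s) contributed each edge.
#'
#' @param edges two-column character matrix or data frame of interacting
#'   protein pairs (may be zero-row).
#' @param name label for the network.
#' @param nodes optional character vector of node IDs to retain in addition to
#'   edge endpoints (isolated nodes are kept only if listed here).
#' @param provenance optional named list mapping canonical edge keys to
#'   character vectors of source labels, or a single character label applied
#'   to every edge.
#' @return An object of class \code{ppi_network} with components \code{name},
#'   \code{nodes} (sorted character vector), \code{edges} (two-column sorted
#'   character matrix) and \code{provenance}.
#' @export
ppi_network <- function(edges, name = "network", nodes = NULL, provenance = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (ncol(edges) < 2L) stop("edges must have two columns")
  a <- as.character(edges[, 1L]); b <- as.character(edges[, 2L])
  if (any(!nzchar(a)) || any(!nzchar(b))) stop("empty protein ID in edge list")
  keep <- a != b                       # drop self-loops
  a <- a[keep]; b <- b[keep]
  m <- canonical_edges(a, b)
  keys <- paste(m[, 1L], m[, 2L], sep = "\t")
  dup <- duplicated(keys)
  m <- m[!dup, , drop = FALSE]
  keys <- keys[!dup]
  if (is.character(provenance) && length(provenance) == 1L && is.null(names(provenance))) {
    provenance <- setNames(rep(list(provenance), length(keys)), keys)
  }
  nds <- sort(unique(c(m[, 1L], m[, 2L], as.character(nodes))))
  structure(
    list(name = name, nodes = nds, edges = m, provenance = provenance),
    class = "ppi_network"
  )
}

n_nodes <- function(net) length(net$nodes)
n_edges <- function(net) nrow(net$edges)
edge_keys <- function(net) {
  if (nrow(net$edges) == 0L) return(character())
  paste(net$edges[, 1L], net$edges[, 2L], sep = "\t")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %s: %d nodes, %d edges\n",
              x$name, n_nodes(x), n_edges(x)))
  if (!is.null(x$provenance)) {
    src <- sort(unique(unlist(x$provenance)))
    cat("  sources:", paste(src, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.ppi_network <- function(object, ...) {
  st <- node_stats(object)
  print(object)
  print(st$summary)
  invisible(st)
}

# igraph view of a network; vertex order follows net$nodes (sorted).
as_igraph <- function(net) {
  df <- data.frame(from = net$edges[, 1L], to = net$edges[, 2L],
                   stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(df, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Assemble a conglomerate network from several interaction datasets
#'
#' Takes the union of all source edge lists: duplicate interactions across
#' sources are merged (with provenance union), self-loops are dropped, and
#' the node set is the union of all edge endpoints.
#'
#' @param edge_lists named list; each element a two-column matrix/data frame
#'   of protein pairs. Names are used as source-dataset labels.
#' @param name label for the assembled network.
#' @return A \code{\link{ppi_network}} whose \code{provenance} maps every edge
#'   to the set of source labels that reported it.
#' @export
assemble_conglomerate <- function(edge_lists, name = "conglomerate") {
  if (length(edge_lists) == 0L) stop("no datasets")
  labs <- names(edge_lists)
  if (is.null(labs) || any(!nzchar(labs))) {
    labs <- paste0("dataset", seq_along(edge_lists))
  }
  prov <- list()
  all_a <- character(); all_b <- character()
  for (i in seq_along(edge_lists)) {
    el <- edge_lists[[i]]
    if (is.data.frame(el)) el <- as.matrix(el)
    if (length(el) == 0L) next
    if (ncol(el) < 2L) stop(sprintf("dataset '%s': edge list needs two columns", labs[i]))
    a <- as.character(el[, 1L]); b <- as.character(el[, 2L])
    bad <- which(!nzchar(a) | !nzchar(b))
    if (length(bad)) {
      stop(sprintf("dataset '%s': malformed pair at row %d", labs[i], bad[1L]))
    }
    keep <- a != b
    k <- unique(edge_key(a[keep], b[keep]))
    for (key in k) prov[[key]] <- c(prov[[key]], labs[i])
    all_a <- c(all_a, a[keep]); all_b <- c(all_b, b[keep])
  }
  net <- ppi_network(cbind(all_a, all_b), name = name)
  net$provenance <- prov[edge_keys(net)]
  net
}

#' Induce a subnetwork on a protein set
#'
#' Returns the subnetwork of \code{net} whose edges have both endpoints in
#' \code{proteins}. Proteins absent from the network are silently ignored, and
#' listed proteins left without any surviving edge are dropped: subnetwork
#' membership requires at least one interaction.
#'
#' @param net a \code{\link{ppi_network}}.
#' @param proteins character vector of protein IDs.
#' @param name label for the induced network.
#' @return A \code{\link{ppi_network}} (possibly empty).
#' @export
induce_subnetwork <- function(net, proteins, name = paste0(net$name, ".sub")) {
  stopifnot(inherits(net, "ppi_network"))
  proteins <- unique(as.character(proteins))
  if (nrow(net$edges)) {
    sel <- net$edges[, 1L] %in% proteins & net$edges[, 2L] %in% proteins
    em <- net$edges[sel, , drop = FALSE]
  } else {
    em <- net$edges
  }
  out <- ppi_network(em, name = name)
  if (!is.null(net$provenance) && n_edges(out) > 0L) {
    out$provenance <- net$provenance[edge_keys(out)]
  }
  out
}

#' Per-node topological statistics
#'
#' Computes, for every node: degree; betweenness centrality (raw shortest-path
#' pair counts with fractional credit for ties, path endpoints excluded,
#' unnormalized); local clustering coefficient (0 by convention for nodes of
#' degree < 2); and eccentricity within the node's connected component.
#' Network-level averages and maxima are attached; the average eccentricity
#' averages per-component values over all nodes.
#'
#' @param net a non-empty \code{\link{ppi_network}}.
#' @return An object of class \code{node_stats}: list with \code{table} (data
#'   frame, one row per node) and \code{summary} (data frame of averages and
#'   maxima plus node and edge counts).
#' @export
node_stats <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  if (n_nodes(net) == 0L) stop("empty network")
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[is.na(cc)] <- 0
  ecc <- suppressWarnings(igraph::eccentricity(g, mode = "all"))
  tab <- data.frame(
    protein = igraph::V(g)$name,
    degree = as.numeric(deg),
    betweenness = as.numeric(btw),
    clustering = as.numeric(cc),
    eccentricity = as.numeric(ecc),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  smry <- data.frame(
    statistic = c("degree", "betweenness", "clustering", "eccentricity"),
    average = c(mean(tab$degree), mean(tab$betweenness),
                mean(tab$clustering), mean(tab$eccentricity)),
    maximum = c(max(tab$degree), max(tab$betweenness),
                max(tab$clustering), max(tab$eccentricity)),
    stringsAsFactors = FALSE
  )
  structure(list(network = net$name, table = tab, summary = smry,
                 n_nodes = n_nodes(net), n_edges = n_edges(net)),
            class = "node_stats")
}

#' @export
print.node_stats <- function(x, ...) {
  cat(sprintf("<node_stats> %s: %d nodes, %d edges\n", x$network,
              x$n_nodes, x$n_edges))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

stat_vector <- function(stats, statistic) {
  stopifnot(inherits(stats, "node_stats"))
  statistic <- match.arg(statistic,
                         c("degree", "betweenness", "clustering", "eccentricity"))
  setNames(stats$table[[statistic]], stats$table$protein)
}

#' Read an edge-list TSV as a network
#'
#' Expects two tab- or whitespace-separated ID columns with an optional third
#' provenance column; lines starting with \code{#} are comments. Duplicate
#' pairs (in either order) collapse to one edge.
#'
#' @param path file path.
#' @param name network label (defaults to the file name).
#' @return A \code{\link{ppi_network}}.
#' @export
read_network <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) return(ppi_network(NULL, name = name))
  parts <- strsplit(lines, "[\t ]+")
  nf <- vapply(parts, length, 1L)
  if (any(nf < 2L)) {
    stop(sprintf("line %d: fewer than two columns", which(nf < 2L)[1L]))
  }
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  src <- vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else NA_character_, "")
  net <- ppi_network(cbind(a, b), name = name)
  if (any(!is.na(src))) {
    keys <- edge_key(a, b)
    prov <- split(src[!is.na(src)], keys[!is.na(src)])
    prov <- lapply(prov, function(s) sort(unique(s)))
    net$provenance <- prov[edge_keys(net)]
  }
  net
}

#' Write a network as an edge-list TSV
#'
#' One canonical edge per line (\code{id_a<TAB>id_b[<TAB>source]}); a header
#' comment records the network name. Reading the file back with
#' \code{\link{read_network}} reproduces node and edge sets exactly (isolated
#' nodes are not representable in an edge list and are not written).
#'
#' @param net a \code{\link{ppi_network}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# network: %s", net$name), con)
  if (n_edges(net) > 0L) {
    if (!is.null(net$provenance)) {
      src <- vapply(edge_keys(net), function(k) {
        v <- net$provenance[[k]]
        if (is.null(v)) "" else paste(sort(unique(v)), collapse = ",")
      }, "")
      writeLines(paste(net$edges[, 1L], net$edges[, 2L], src, sep = "\t"), con)
    } else {
      writeLines(paste(net$edges[, 1L], net$edges[, 2L], sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a protein list (one ID per line)
#'
#' Blank lines and \code{#} comments are skipped; duplicates collapse.
#'
#' @param path file path.
#' @return Sorted character vector of unique protein IDs.
#' @export
read_protein_list <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  x <- trimws(readLines(path, warn = FALSE))
  sort(unique(x[nzchar(x) & !startsWith(x, "#")]))
}
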