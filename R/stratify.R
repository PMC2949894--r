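#' Define a leveled hierarchy of context protein lists
#'
#' A context hierarchy organizes named protein lists into levels 1..4: exactly
#' one level-1 context (the total list), and every deeper context names a
#' parent at a strictly lower level. Child lists are not forced to be subsets
#' of their parents; violations are reported as an attribute, not errors.
#'
#' @param contexts named list; each element a list with fields \code{level}
#'   (integer), \code{parent} (context name or \code{NA} for the root) and
#'   \code{proteins} (character vector).
#' @return An object of class \code{context_hierarchy} with a
#'   \code{subset_violations} attribute (data frame of parent/child pairs with
#'   the fraction of child proteins missing from the parent).
#' @export
context_hierarchy <- function(contexts) {
  stopifnot(is.list(contexts), length(contexts) > 0L, !is.null(names(contexts)))
  lv <- vapply(contexts, function(x) as.integer(x$level), 1L)
  if (sum(lv == 1L) != 1L) stop("exactly one level-1 (total) context required")
  for (nm in names(contexts)) {
    ctx <- contexts[[nm]]
    if (lv[[nm]] > 1L) {
      p <- ctx$parent
      if (is.null(p) || is.na(p) || !p %in% names(contexts)) {
        stop(sprintf("context '%s': unknown parent", nm))
      }
      if (lv[[p]] >= lv[[nm]]) {
        stop(sprintf("context '%s': parent '%s' not at a lower level", nm, p))
      }
    }
    contexts[[nm]]$proteins <- sort(unique(as.character(ctx$proteins)))
  }
  viol <- do.call(rbind, lapply(names(contexts), function(nm) {
    if (lv[[nm]] == 1L) return(NULL)
    p <- contexts[[nm]]$parent
    miss <- setdiff(contexts[[nm]]$proteins, contexts[[p]]$proteins)
    if (length(miss) == 0L) return(NULL)
    data.frame(context = nm, parent = p, n_missing = length(miss),
               frac_missing = length(miss) / length(contexts[[nm]]$proteins),
               stringsAsFactors = FALSE)
  }))
  structure(contexts, class = "context_hierarchy",
            subset_violations = viol)
}

hierarchy_levels <- function(hierarchy) {
  vapply(hierarchy, function(x) as.integer(x$level), 1L)
}

root_context <- function(hierarchy) {
  names(hierarchy)[hierarchy_levels(hierarchy) == 1L]
}

#' @export
print.context_hierarchy <- function(x, ...) {
  lv <- hierarchy_levels(x)
  cat(sprintf("<context_hierarchy> %d contexts, levels: %s\n", length(x),
              paste(sprintf("%d@L%d", tabulate(lv, max(lv)), seq_len(max(lv))),
                    collapse = " ")))
  viol <- attr(x, "subset_violations")
  if (!is.null(viol)) {
    cat(sprintf("  %d child list(s) not subsets of their parent\n", nrow(viol)))
  }
  invisible(x)
}

#' Read a context hierarchy from a YAML/JSON config
#'
#' The config holds a list \code{contexts} of records \code{{name, level,
#' parent, list_file}}; list files (one protein ID per line) are resolved
#' relative to \code{base_dir}.
#'
#' @param path config file (\code{.yaml}/\code{.yml} or \code{.json}).
#' @param base_dir directory against which relative \code{list_file} paths are
#'   resolved; defaults to the config's directory.
#' @return A \code{\link{context_hierarchy}}.
#' @export
read_hierarchy <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  entries <- cfg$contexts
  if (is.null(entries)) stop("config has no 'contexts' entry")
  ctx <- list()
  for (e in entries) {
    lf <- e$list_file
    if (!file.exists(lf)) lf <- file.path(base_dir, e$list_file)
    ctx[[e$name]] <- list(
      level = as.integer(e$level),
      parent = if (is.null(e$parent)) NA_character_ else e$parent,
      proteins = read_protein_list(lf)
    )
  }
  context_hierarchy(ctx)
}

#' Stratify a conglomerate network by a context hierarchy
#'
#' Overlays every context protein list on the conglomerate and keeps the
#' interactions whose two partners are both on the list (induced subnetwork).
#' The level-1 total network is itself induced from the total list, and every
#' other context is induced from the total network, so node and edge sets of
#' all stratified networks are subsets of the total network's. Coverage is the
#' fraction of each list's proteins that survive as interacting members.
#'
#' @param conglomerate the assembled \code{\link{ppi_network}}.
#' @param hierarchy a \code{\link{context_hierarchy}}.
#' @return An object of class \code{stratified_family}: list with
#'   \code{networks} (name -> \code{ppi_network}), \code{coverage} (named
#'   numeric), \code{hierarchy} and \code{total} (root context name).
#' @export
stratify_all <- function(conglomerate, hierarchy) {
  stopifnot(inherits(conglomerate, "ppi_network"),
            inherits(hierarchy, "context_hierarchy"))
  root <- root_context(hierarchy)
  total_net <- induce_subnetwork(conglomerate, hierarchy[[root]]$proteins,
                                 name = root)
  nets <- list()
  cov <- numeric()
  for (nm in names(hierarchy)) {
    lst <- hierarchy[[nm]]$proteins
    net <- if (nm == root) total_net else induce_subnetwork(total_net, lst, name = nm)
    if (n_nodes(net) == 0L) {
      warning(sprintf("context '%s': no overlap with the network", nm))
    }
    nets[[nm]] <- net
    cov[nm] <- if (length(lst)) n_nodes(net) / length(lst) else 0
  }
  structure(list(networks = nets, coverage = cov, hierarchy = hierarchy,
                 total = root),
            class = "stratified_family")
}

#' @export
print.stratified_family <- function(x, ...) {
  lv <- hierarchy_levels(x$hierarchy)
  cat(sprintf("<stratified_family> %d context networks (total: '%s')\n",
              length(x$networks), x$total))
  for (nm in names(x$networks)) {
    cat(sprintf("  L%d %-14s %5d nodes %6d edges  coverage %.3f\n",
                lv[[nm]], nm, n_nodes(x$networks[[nm]]),
                n_edges(x$networks[[nm]]), x$coverage[[nm]]))
  }
  invisible(x)
}

#' Names of the contexts at a hierarchy level
#'
#' @param family a \code{\link{stratified_family}}.
#' @param level hierarchy level (integer).
#' @return Character vector of context names (possibly empty).
#' @export
contexts_at_level <- function(family, level) {
  lv <- hierarchy_levels(family$hierarchy)
  names(lv)[lv == level]
}

#' Enumerate comparison pairs between two hierarchy levels
#'
#' Cross product of the networks at \code{levelA} with those at \code{levelB};
#' pairs involving the total network come first.
#'
#' @param family a \code{\link{stratified_family}}.
#' @param levelA,levelB hierarchy levels (integers).
#' @return List of two-element lists of \code{ppi_network}s, with a
#'   \code{pair_names} attribute (two-column character matrix).
#' @export
level_pairs <- function(family, levelA, levelB) {
  a <- contexts_at_level(family, levelA)
  b <- contexts_at_level(family, levelB)
  if (length(a) == 0L) stop(sprintf("no contexts at level %d", levelA))
  if (length(b) == 0L) stop(sprintf("no contexts at level %d", levelB))
  ord <- function(v) c(v[v == family$total], sort(v[v != family$total]))
  a <- ord(a); b <- ord(b)
  nm <- as.matrix(expand.grid(b = b, a = a, stringsAsFactors = FALSE))[, c("a", "b")]
  pairs <- lapply(seq_len(nrow(nm)), function(i) {
    list(family$networks[[nm[i, 1L]]], family$networks[[nm[i, 2L]]])
  })
  attr(pairs, "pair_names") <- nm
  pairs
}
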