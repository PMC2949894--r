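#' Configuration for the synthetic stratification study generator
#'
#' Defines the study conditions emulated by \code{\link{synth_ppi_study}}:
#' a universe of proteins, a 4-level context hierarchy (one total list, two
#' level-2 contexts, five level-3 tissue contexts, four level-4 refinements),
#' per-context scale-free interaction layers (preferential attachment),
#' planted dense context-exclusive modules, conglomerate-only artifact
#' structures, and annotations split into housekeeping and context-specific
#' terms with a noise rate.
#'
#' Tissue protein lists are a shared core plus context-specific samples from a
#' common pool, sized so that pairwise node-list Jaccard indices fall inside
#' \code{jaccard_band}; an error with the feasible range is raised when the
#' requested sizes cannot reach the band.
#'
#' @param n_proteins universe size (default 1000).
#' @param n_level3 number of level-3 tissue contexts (default 5).
#' @param n_level4 number of level-4 contexts (default 4).
#' @param core_frac fraction of the universe in the shared core (default 0.2).
#' @param specific_frac fraction sampled per tissue from the common pool
#'   (default 0.15).
#' @param jaccard_band admissible band for pairwise level-3 node-list Jaccard
#'   (default \code{c(0.39, 0.65)}).
#' @param modules_per_context planted dense modules per tissue (default 4).
#' @param module_size module size range (default \code{c(8, 12)}).
#' @param p_in planted-module internal edge density (default 0.8; protein complexes are near-cliques).
#' @param pa_m backbone preferential-attachment edges per new node
#'   (default 3).
#' @param context_pa_m context-layer preferential-attachment edges per new
#'   node (default 1; context-specific interactions are sparse relative to
#'   the database backbone).
#' @param module_out_edges interface edges connecting each planted module to
#'   its context's background (default 3).
#' @param wiring_frac fraction of each context list wired into its scale-free
#'   layer (default 0.85).
#' @param n_artifact number of artifact structures (default 2).
#' @param artifact_size artifact node-set size, split into two halves
#'   (default 14).
#' @param artifact_p_cross edge density on cross-half pairs (default 1.0:
#'   the two halves are fully cross-wired, like a complex whose subunits
#'   were each assayed against the other half under a different condition).
#' @param artifact_p_within edge density within each half (default 0: the
#'   structure is purely cross-wired, so a lone half carries no internal
#'   cohesion and dissolves into its context's background).
#' @param artifact_decoys number of scattered extra proteins carrying each
#'   artifact term (default 28); like real annotation terms, artifact terms
#'   are not private to the planted structure, so a term only becomes
#'   enriched where its carriers concentrate in one module.
#' @param density_thresholds audit thresholds \code{c(union, context)}: an
#'   artifact must exceed the first in the conglomerate and stay below the
#'   second in every single context subnetwork (default \code{c(0.5, 0.2)},
#'   bracketing the bipartite cross-wired union density of about 0.54 and
#'   the near-zero within-half density).
#' @param n_housekeeping housekeeping biological-process terms (default 10).
#' @param housekeeping_frac fraction of the total list carrying each
#'   housekeeping term (default 0.10).
#' @param n_mf_terms molecular-function terms (default 5).
#' @param annotation_noise fraction of proteins receiving one random extra
#'   term (default 0.05).
#' @param seed integer seed (default 1).
#' @return A list of class \code{synth_config}.
#' @export
synth_config <- function(n_proteins = 1000L, n_level3 = 5L, n_level4 = 4L,
                         core_frac = 0.2, specific_frac = 0.15,
                         jaccard_band = c(0.39, 0.65),
                         modules_per_context = 4L, module_size = c(8L, 12L),
                         p_in = 0.8, pa_m = 3L, context_pa_m = 1L,
                         module_out_edges = 3L,
                         wiring_frac = 0.85,
                         n_artifact = 2L, artifact_size = 14L,
                         artifact_p_cross = 1.0, artifact_p_within = 0,
                         artifact_decoys = 28L,
                         density_thresholds = c(0.5, 0.2),
                         n_housekeeping = 10L, housekeeping_frac = 0.10,
                         n_mf_terms = 5L, annotation_noise = 0.05,
                         seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins), n_level3 = as.integer(n_level3),
              n_level4 = as.integer(n_level4), core_frac = core_frac,
              specific_frac = specific_frac, jaccard_band = jaccard_band,
              modules_per_context = as.integer(modules_per_context),
              module_size = as.integer(module_size), p_in = p_in,
              pa_m = as.integer(pa_m),
              context_pa_m = as.integer(context_pa_m),
              module_out_edges = as.integer(module_out_edges),
              wiring_frac = wiring_frac,
              n_artifact = as.integer(n_artifact),
              artifact_size = as.integer(artifact_size),
              artifact_p_cross = artifact_p_cross,
              artifact_p_within = artifact_p_within,
              artifact_decoys = as.integer(artifact_decoys),
              density_thresholds = density_thresholds,
              n_housekeeping = as.integer(n_housekeeping),
              housekeeping_frac = housekeeping_frac,
              n_mf_terms = as.integer(n_mf_terms),
              annotation_noise = annotation_noise, seed = as.integer(seed))
  stopifnot(cfg$n_proteins > 0, cfg$n_level3 >= 2L,
            cfg$p_in >= 0, cfg$p_in <= 1,
            cfg$artifact_p_cross >= 0, cfg$artifact_p_cross <= 1,
            cfg$wiring_frac > 0, cfg$wiring_frac <= 1,
            cfg$annotation_noise >= 0, cfg$annotation_noise <= 1,
            length(cfg$module_size) == 2L, all(cfg$module_size > 0))
  # feasibility of the Jaccard band for the requested list sizes
  core_n <- round(cfg$core_frac * cfg$n_proteins)
  spec_n <- round(cfg$specific_frac * cfg$n_proteins)
  pool_n <- cfg$n_proteins - core_n - cfg$n_artifact * cfg$artifact_size
  if (pool_n < spec_n) stop("specific pool smaller than per-context sample")
  e_ov <- spec_n^2 / pool_n
  j_exp <- (core_n + e_ov) / (core_n + 2 * spec_n - e_ov)
  if (j_exp < cfg$jaccard_band[1L] || j_exp > cfg$jaccard_band[2L]) {
    j_min <- core_n / (core_n + 2 * spec_n)
    stop(sprintf(
      "expected pairwise list Jaccard %.3f outside band [%.3f, %.3f]; feasible range for these sizes is about [%.3f, 1]; adjust core_frac/specific_frac",
      j_exp, cfg$jaccard_band[1L], cfg$jaccard_band[2L], j_min))
  }
  cfg$expected_jaccard <- j_exp
  class(cfg) <- "synth_config"
  cfg
}

# Preferential-attachment layer over a node-ID vector; returns a 2-col
# character edge matrix.
pa_layer <- function(ids, m) {
  w <- length(ids)
  if (w < 2L) return(matrix(character(), ncol = 2L))
  g <- igraph::sample_pa(w, m = min(m, w - 1L), directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  cbind(ids[el[, 1L]], ids[el[, 2L]])
}

# Exactly round(p * n_pairs) distinct pairs among `nodes`.
dense_pairs <- function(nodes, p) {
  pairs <- t(utils::combn(nodes, 2L))
  k <- round(p * nrow(pairs))
  pairs[sample.int(nrow(pairs), k), , drop = FALSE]
}

# Exactly round(p * |a||b|) distinct cross pairs between node sets a and b.
cross_pairs <- function(a, b, p) {
  grid <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
  k <- round(p * nrow(grid))
  sel <- grid[sample.int(nrow(grid), k), , drop = FALSE]
  cbind(sel$a, sel$b)
}

#' Generate a synthetic stratification study
#'
#' Builds a conglomerate network as the union of per-context interaction
#' layers (scale-free background plus planted dense modules), a 4-level
#' context hierarchy of protein lists, annotations (housekeeping terms spread
#' over the total list, module terms concentrated in planted modules, plus
#' random noise), and the planted ground truth. Artifact structures are node
#' sets split across two contexts under different level-2 parents, densely
#' wired across the halves, so the full dense structure exists only in the
#' assembled union — never in any single context subnetwork. Deterministic
#' under the config seed.
#'
#' @param config a \code{\link{synth_config}}.
#' @param seed optional override of \code{config$seed}.
#' @return A list of class \code{synth_bundle} with components
#'   \code{conglomerate} (\code{\link{ppi_network}}), \code{hierarchy}
#'   (\code{\link{context_hierarchy}}), \code{annotations}
#'   (\code{\link{annotation_map}}) and \code{truth} (planted modules, module
#'   terms and artifact records).
#' @export
synth_ppi_study <- function(config = synth_config(), seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(if (is.null(seed)) config$seed else seed)
  n <- config$n_proteins
  proteins <- sprintf("P%05d", seq_len(n))
  avail <- proteins

  # reserve artifact halves (exclusive to their two contexts)
  half <- config$artifact_size %/% 2L
  artifacts <- list()
  for (i in seq_len(config$n_artifact)) {
    ha <- sample(avail, half); avail <- setdiff(avail, ha)
    hb <- sample(avail, config$artifact_size - half); avail <- setdiff(avail, hb)
    artifacts[[i]] <- list(half_a = sort(ha), half_b = sort(hb),
                           nodes = sort(c(ha, hb)),
                           term = sprintf("ART%02d", i))
  }

  core_n <- round(config$core_frac * n)
  spec_n <- round(config$specific_frac * n)
  core <- sample(avail, core_n); pool <- setdiff(avail, core)

  tissues <- sprintf("tissue%d", seq_len(config$n_level3))
  lists <- list(); specifics <- list()
  smin <- config$module_size[1L]; smax <- config$module_size[2L]
  truth_modules <- list()
  plant_modules <- function(ctx, donor, n_mod) {
    mods <- list()
    for (j in seq_len(n_mod)) {
      s <- sample(smin:smax, 1L)
      if (length(donor) < s) break
      m <- sample(donor, s)
      donor <- setdiff(donor, m)
      mods[[sprintf("MT_%s_%d", ctx, j)]] <- sort(m)
    }
    mods
  }
  # planted module nodes are context-exclusive: a tissue claims them from the
  # shared pool before the context-specific samples are drawn
  for (t in seq_along(tissues)) {
    truth_modules[[tissues[t]]] <-
      plant_modules(tissues[t], pool, config$modules_per_context)
    pool <- setdiff(pool,
                    unlist(truth_modules[[tissues[t]]], use.names = FALSE))
  }
  cc_pool <- pool
  truth_modules[["cell_culture"]] <-
    plant_modules("cell_culture", cc_pool,
                  max(1L, config$modules_per_context %/% 2L))
  pool <- setdiff(pool,
                  unlist(truth_modules[["cell_culture"]], use.names = FALSE))
  module_terms <- character()
  all_module_nodes <- unlist(truth_modules, use.names = FALSE)
  artifact_nodes <- unlist(lapply(artifacts, `[[`, "nodes"))

  # Shared scale-free backbone over core + pool (interaction databases are
  # context-agnostic). Housekeeping/core proteins are the oldest, most
  # connected part of the interactome: they enter the preferential-attachment
  # growth first and become the backbone hubs every context retains. Complex
  # members interact predominantly within their complex, so planted-module
  # and artifact nodes stay out of the background wiring.
  layers <- list()
  bb_pool <- c(core, pool)
  bb_wired <- sample(bb_pool, round(config$wiring_frac * length(bb_pool)))
  bb_order <- c(sample(intersect(bb_wired, core)),
                sample(setdiff(bb_wired, core)))
  layers[["backbone"]] <- pa_layer(bb_order, config$pa_m)
  bb_deg <- table(factor(as.vector(layers[["backbone"]]), levels = proteins))

  # Context lists: the shared core, the context's exclusive planted-module
  # nodes, and a pool sample grown by neighbourhood snowballing from
  # degree-biased seeds. Proteomics preferentially detects abundant,
  # well-connected proteins, and co-localized interaction partners are
  # co-detected, so real context lists retain hub neighbourhoods far better
  # than uniform node samples do.
  bb_adj <- split(c(layers[["backbone"]][, 2L], layers[["backbone"]][, 1L]),
                  c(layers[["backbone"]][, 1L], layers[["backbone"]][, 2L]))
  pick_specific <- function(pool_avail, size) {
    size <- min(size, length(pool_avail))
    if (size == 0L) return(character())
    w <- as.numeric(bb_deg[pool_avail]) + 0.5
    seeds <- sample(pool_avail, max(1L, size %/% 3L), prob = w)
    picked <- seeds
    while (length(picked) < size) {
      frontier <- unique(unlist(bb_adj[picked], use.names = FALSE))
      frontier <- setdiff(intersect(frontier, pool_avail), picked)
      if (length(frontier) == 0L) {
        picked <- c(picked, sample(setdiff(pool_avail, picked),
                                   size - length(picked)))
        break
      }
      take <- min(length(frontier), size - length(picked))
      picked <- c(picked, sample(frontier, take))
    }
    picked
  }
  for (t in seq_along(tissues)) {
    specifics[[tissues[t]]] <- pick_specific(pool, spec_n)
    lists[[tissues[t]]] <- sort(c(
      core, specifics[[tissues[t]]],
      unlist(truth_modules[[tissues[t]]], use.names = FALSE)))
  }
  # artifact half A goes to a tissue (cycling); half B to cell_culture
  for (i in seq_along(artifacts)) {
    t <- tissues[((i - 1L) %% length(tissues)) + 1L]
    artifacts[[i]]$context_a <- t
    artifacts[[i]]$context_b <- "cell_culture"
    lists[[t]] <- sort(c(lists[[t]], artifacts[[i]]$half_a))
  }
  cc_list <- c(sample(core, round(core_n / 2)), pick_specific(pool, spec_n),
               unlist(truth_modules[["cell_culture"]], use.names = FALSE),
               unlist(lapply(artifacts, `[[`, "half_b")))
  lists[["cell_culture"]] <- sort(unique(cc_list))

  # Per-context background layers: each non-core protein is wired into the
  # layer of the first context that detected it (its "home"), so degree does
  # not stack across contexts; the backbone carries the shared structure.
  total_list <- sort(unique(c(unlist(lists))))
  wired_sets <- list()
  claimed <- character()
  for (ctx in c(tissues, "cell_culture")) {
    own <- setdiff(lists[[ctx]],
                   c(core, all_module_nodes, artifact_nodes, claimed))
    claimed <- c(claimed, own)
    wired <- sample(own, round(config$wiring_frac * length(own)))
    wired_sets[[ctx]] <- wired
    edges <- pa_layer(sample(wired), config$context_pa_m)
    for (m in truth_modules[[ctx]]) {
      edges <- rbind(edges, dense_pairs(m, config$p_in))
      n_out <- min(config$module_out_edges, length(wired))
      if (n_out > 0L) {
        edges <- rbind(edges, cbind(sample(m, n_out, replace = TRUE),
                                    sample(wired, n_out)))
      }
    }
    layers[[ctx]] <- edges
  }
  # artifact halves: dense across-half wiring split between the two source
  # layers, loose within-half structure, and a few interface edges anchoring
  # each half in its own context's background
  for (art in artifacts) {
    cp <- cross_pairs(art$half_a, art$half_b, config$artifact_p_cross)
    split_at <- nrow(cp) %/% 2L
    anchor <- function(half, ctx) {
      n_out <- min(config$module_out_edges, length(wired_sets[[ctx]]))
      if (n_out == 0L) return(matrix(character(), ncol = 2L))
      cbind(sample(half, n_out, replace = TRUE),
            sample(wired_sets[[ctx]], n_out))
    }
    iface_a <- anchor(art$half_a, art$context_a)
    iface_b <- anchor(art$half_b, art$context_b)
    layers[[art$context_a]] <- rbind(layers[[art$context_a]],
                                     cp[seq_len(split_at), , drop = FALSE],
                                     dense_pairs(art$half_a, config$artifact_p_within),
                                     iface_a)
    layers[[art$context_b]] <- rbind(layers[[art$context_b]],
                                     cp[-seq_len(split_at), , drop = FALSE],
                                     dense_pairs(art$half_b, config$artifact_p_within),
                                     iface_b)
  }
  conglomerate <- assemble_conglomerate(layers, name = "conglomerate")

  organs <- sort(unique(unlist(lists[tissues])))
  total <- sort(unique(c(organs, lists[["cell_culture"]])))
  ctx <- list(total = list(level = 1L, parent = NA_character_, proteins = total),
              organs = list(level = 2L, parent = "total", proteins = organs),
              cell_culture = list(level = 2L, parent = "total",
                                  proteins = lists[["cell_culture"]]))
  for (t in tissues) {
    ctx[[t]] <- list(level = 3L, parent = "organs", proteins = lists[[t]])
  }
  for (j in seq_len(config$n_level4)) {
    parent <- tissues[((j - 1L) %% length(tissues)) + 1L]
    ctx[[sprintf("fine%d", j)]] <- list(
      level = 4L, parent = parent,
      proteins = sort(sample(lists[[parent]],
                             round(0.6 * length(lists[[parent]])))))
  }
  hierarchy <- context_hierarchy(ctx)

  # annotations
  ann <- list()
  hk_n <- max(1L, round(config$housekeeping_frac * length(total)))
  for (h in seq_len(config$n_housekeeping)) {
    term <- sprintf("HK%02d", h)
    ann[[term]] <- data.frame(protein = sample(total, hk_n),
                              category = "biological_process",
                              term_id = term,
                              term_label = sprintf("housekeeping process %d", h),
                              stringsAsFactors = FALSE)
  }
  for (ctx_nm in names(truth_modules)) {
    for (term in names(truth_modules[[ctx_nm]])) {
      ann[[term]] <- data.frame(protein = truth_modules[[ctx_nm]][[term]],
                                category = "biological_process",
                                term_id = term,
                                term_label = sprintf("%s-specific process", ctx_nm),
                                stringsAsFactors = FALSE)
      module_terms <- c(module_terms, term)
    }
  }
  for (art in artifacts) {
    decoys <- sample(setdiff(total, art$nodes),
                     min(config$artifact_decoys, length(total) - length(art$nodes)))
    ann[[art$term]] <- data.frame(protein = c(art$nodes, decoys),
                                  category = "biological_process",
                                  term_id = art$term,
                                  term_label = "artifact-structure process",
                                  stringsAsFactors = FALSE)
  }
  for (f in seq_len(config$n_mf_terms)) {
    term <- sprintf("MF%02d", f)
    ann[[term]] <- data.frame(protein = sample(total, hk_n),
                              category = "molecular_function",
                              term_id = term,
                              term_label = sprintf("molecular function %d", f),
                              stringsAsFactors = FALSE)
  }
  noise_n <- round(config$annotation_noise * length(total))
  if (noise_n > 0L) {
    bp_terms <- unique(unlist(lapply(ann, function(d) {
      d$term_id[d$category == "biological_process"]
    })))
    ann[["noise"]] <- data.frame(protein = sample(total, noise_n),
                                 category = "biological_process",
                                 term_id = sample(bp_terms, noise_n, replace = TRUE),
                                 term_label = "noise assignment",
                                 stringsAsFactors = FALSE)
  }
  annotations <- annotation_map(do.call(rbind, ann))

  structure(list(conglomerate = conglomerate, hierarchy = hierarchy,
                 annotations = annotations,
                 truth = list(modules = truth_modules,
                              module_terms = sort(module_terms),
                              artifacts = artifacts,
                              config = config)),
            class = "synth_bundle")
}

#' @export
print.synth_bundle <- function(x, ...) {
  cat("<synth_bundle>\n  ")
  print(x$conglomerate)
  print(x$hierarchy)
  cat(sprintf("  %d planted modules, %d artifact structures, %d annotations\n",
              sum(lengths(x$truth$modules)), length(x$truth$artifacts),
              nrow(x$annotations)))
  invisible(x)
}

#' Small fixed synthetic bundle for examples and integration tests
#'
#' A compact study (about 300 proteins, 5 level-3 contexts, 2 planted modules
#' per tissue, 1 artifact structure) generated deterministically from the
#' seed; suitable for documentation and fast end-to-end runs.
#'
#' @param seed integer seed (default 1).
#' @return A \code{synth_bundle} (see \code{\link{synth_ppi_study}}).
#' @export
paper_shaped_fixture <- function(seed = 1L) {
  cfg <- synth_config(n_proteins = 300L, modules_per_context = 2L,
                      module_size = c(8L, 12L), n_artifact = 1L,
                      seed = as.integer(seed))
  synth_ppi_study(cfg)
}

#' Write a synthetic bundle to a directory
#'
#' Emits the conglomerate edge-list TSV (with provenance), one protein-list
#' file per context, a YAML hierarchy config, the annotation TSV and the
#' planted truth as JSON.
#'
#' @param bundle a \code{synth_bundle}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_network(bundle$conglomerate, file.path(dir, "conglomerate.tsv"))
  ctxs <- lapply(names(bundle$hierarchy), function(nm) {
    lf <- sprintf("%s.list", nm)
    writeLines(bundle$hierarchy[[nm]]$proteins, file.path(dir, lf))
    list(name = nm, level = bundle$hierarchy[[nm]]$level,
         parent = if (is.na(bundle$hierarchy[[nm]]$parent)) NULL
                  else bundle$hierarchy[[nm]]$parent,
         list_file = lf)
  })
  yaml::write_yaml(list(contexts = ctxs), file.path(dir, "hierarchy.yaml"))
  utils::write.table(bundle$annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- bundle$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
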