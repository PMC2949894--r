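#' Configuration for a full stratification analysis run
#'
#' Collects every knob of the comparative pipeline: the input (either a
#' synthetic study configuration or file paths), role cutoffs, class scheme,
#' clustering algorithm and parameter grid, enrichment threshold, null
#' replicate counts, perturbation fractions and the master seed.
#'
#' @param synth a \code{\link{synth_config}} used to generate the study
#'   (ignored when \code{input} is given).
#' @param input optional list with paths \code{network}, \code{hierarchy},
#'   \code{annotations} to analyse real data files instead.
#' @param hub_pct percent cutoff for hubs/bottlenecks (default 20; 5 and 10
#'   are the usual alternates).
#' @param class_cutoffs percent cutoffs for degree/betweenness classes
#'   (default \code{c(5, 10, 20, 50)}).
#' @param algorithm clustering algorithm for the modular analysis
#'   (\code{"sa"}, \code{"cpm"} or \code{"gn"}).
#' @param sa_control list of \code{\link{sa_modularity}} schedule overrides
#'   used when \code{algorithm = "sa"} (default \code{list(moves_factor =
#'   0.2)}, a lighter schedule suited to repeated pipeline runs).
#' @param param_grid clustering parameter grid (default per algorithm, see
#'   \code{\link{cp_comparison_protocol}}).
#' @param alpha enrichment significance cutoff (default 5e-4).
#' @param n_null_compat compatibility null replicates (default 500).
#' @param n_null_roles node-sampling null replicates per context (default 20).
#' @param replace_fractions edge-replacement fractions for the robustness
#'   stage (default \code{c(0.1, 0.2)}).
#' @param seed master integer seed.
#' @param out_dir optional output directory for per-stage TSVs and the run
#'   manifest.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(synth = synth_config(), input = NULL, hub_pct = 20,
                       class_cutoffs = c(5, 10, 20, 50),
                       algorithm = c("sa", "cpm", "gn"), param_grid = NULL,
                       sa_control = list(moves_factor = 0.2),
                       alpha = 5e-4, n_null_compat = 500L, n_null_roles = 20L,
                       replace_fractions = c(0.1, 0.2), seed = 1L,
                       out_dir = NULL) {
  algorithm <- match.arg(algorithm)
  if (!is.null(input)) {
    for (f in unlist(input)) {
      if (!file.exists(f)) stop(sprintf("input file not found: %s", f))
    }
  }
  structure(list(synth = synth, input = input, hub_pct = hub_pct,
                 class_cutoffs = class_cutoffs, algorithm = algorithm,
                 param_grid = param_grid, sa_control = sa_control,
                 alpha = alpha,
                 n_null_compat = as.integer(n_null_compat),
                 n_null_roles = as.integer(n_null_roles),
                 replace_fractions = replace_fractions,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full comparative stratification analysis
#'
#' Executes the stages stratify, topology (hub/bottleneck status change,
#' class/leap assignment, distribution tests), compatibility (Jaccard with
#' randomized nulls), modules (clustering + modular compatibility protocol),
#' enrichment (per-context and module-level, with chi-squared distribution
#' comparisons) and randomization (node-sampling role nulls and
#' edge-replacement robustness), then derives a per-analysis transferability
#' verdict. With \code{out_dir} set, per-stage TSVs and a JSON manifest are
#' written; re-running the same config and seed reproduces them byte for
#' byte.
#'
#' @param config a \code{\link{run_config}}.
#' @return An object of class \code{netstrat_run}; see components
#'   \code{family}, \code{stats}, \code{topology}, \code{compat},
#'   \code{modules}, \code{enrichment}, \code{randomize}, \code{verdicts},
#'   \code{manifest}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- "inputs"
  result <- tryCatch({
    if (!is.null(config$input)) {
      conglomerate <- read_network(config$input$network, name = "conglomerate")
      hierarchy <- read_hierarchy(config$input$hierarchy)
      annotations <- read_annotations(config$input$annotations)
      truth <- NULL
    } else {
      bundle <- synth_ppi_study(config$synth, seed = config$seed)
      conglomerate <- bundle$conglomerate
      hierarchy <- bundle$hierarchy
      annotations <- bundle$annotations
      truth <- bundle$truth
    }

    stage <- "stratify"
    family <- stratify_all(conglomerate, hierarchy)
    total <- family$total
    l3 <- setdiff(contexts_at_level(family, 3L), total)

    stage <- "statistics"
    stats <- lapply(family$networks[c(total, l3)], node_stats)
    stat_tests <- do.call(rbind, lapply(l3, function(ctx) {
      do.call(rbind, lapply(c("degree", "betweenness", "clustering"), function(s) {
        ht <- compare_stat_distributions(stats[[total]], stats[[ctx]], s, "welch")
        data.frame(context = ctx, statistic = s, t = ht$statistic,
                   p.value = ht$p.value, stringsAsFactors = FALSE)
      }))
    }))

    stage <- "topology"
    roles <- list(); changes <- list()
    for (kind in c("degree", "betweenness")) {
      roles[[kind]] <- lapply(stats, identify_roles, kind = kind,
                              pct = config$hub_pct)
      changes[[kind]] <- do.call(rbind, lapply(l3, function(ctx) {
        sc <- status_change(roles[[kind]][[total]], roles[[kind]][[ctx]])
        data.frame(kind = kind, context = ctx,
                   role_to_nonrole = sc$role_to_nonrole,
                   nonrole_to_role = sc$nonrole_to_role,
                   role_absent = sc$role_absent,
                   pct_role_to_nonrole = sc$pct_role_to_nonrole,
                   pct_nonrole_to_role = sc$pct_nonrole_to_role,
                   stringsAsFactors = FALSE)
      }))
    }
    class_tabs <- do.call(rbind, lapply(c("degree", "betweenness"), function(kind) {
      ca_total <- assign_classes(stats[[total]], kind, config$class_cutoffs)
      do.call(rbind, lapply(l3, function(ctx) {
        cc <- class_changes(ca_total,
                            assign_classes(stats[[ctx]], kind, config$class_cutoffs))
        data.frame(kind = kind, context = ctx, n_shared = nrow(cc),
                   n_changed = sum(cc$delta != 0), n_leap = sum(cc$leap),
                   pct_changed = 100 * mean(cc$delta != 0),
                   pct_leap = 100 * mean(cc$leap), stringsAsFactors = FALSE)
      }))
    }))

    stage <- "compatibility"
    pairs <- utils::combn(l3, 2L)
    compat <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- family$networks[[pairs[1L, j]]]
      b <- family$networks[[pairs[2L, j]]]
      obs <- network_compatibility(a, b)
      nul <- compatibility_null(family$networks[[total]],
                                n_nodes(a), n_nodes(b),
                                n_rep = config$n_null_compat,
                                seed = config$seed + 1000L + j,
                                observed = obs)
      data.frame(a = pairs[1L, j], b = pairs[2L, j], J_v = obs$J_v,
                 J_e = obs$J_e, null_mean_v = nul$mean_v,
                 null_sd_v = nul$sd_v, p_v = nul$p_v,
                 null_mean_e = nul$mean_e, null_sd_e = nul$sd_e,
                 p_e = nul$p_e, stringsAsFactors = FALSE)
    }))

    stage <- "modules"
    cp <- cp_comparison_protocol(family, config$algorithm, config$param_grid,
                                 contexts = l3, sa_control = config$sa_control)

    stage <- "enrichment"
    enr <- lapply(l3, function(ctx) {
      protein_enrichment(family$networks[[ctx]], family$networks[[total]],
                         annotations, alpha = config$alpha)
    })
    names(enr) <- l3
    term_counts <- function(net) {
      a <- annotations[annotations$category == "biological_process" &
                         annotations$protein %in% net$nodes, ]
      tab <- table(a$term_id)
      stats::setNames(as.numeric(tab), names(tab))
    }
    chi2 <- do.call(rbind, lapply(l3, function(ctx) {
      ht <- distribution_chi2(term_counts(family$networks[[ctx]]),
                              term_counts(family$networks[[total]]))
      data.frame(context = ctx, chi2 = ht$statistic, df = ht$df,
                 p.value = ht$p.value, stringsAsFactors = FALSE)
    }))
    mid <- ceiling(length(cp$param_grid) / 2)
    modsets <- lapply(c(total, l3), function(nm) {
      run_clustering(family$networks[[nm]], config$algorithm,
                     cp$param_grid[[mid]], config$sa_control)
    })
    names(modsets) <- c(total, l3)
    mes <- module_enrichment_summary(
      modsets, annotations,
      backgrounds = lapply(family$networks[c(total, l3)], `[[`, "nodes"),
      alpha = config$alpha, conglomerate = total)

    stage <- "randomization"
    role_null <- do.call(rbind, lapply(seq_along(l3), function(i) {
      ctx <- l3[i]
      ref_net <- family$networks[[ctx]]
      lst <- family$hierarchy[[ctx]]$proteins
      do.call(rbind, lapply(seq_len(config$n_null_roles), function(r) {
        rnd <- random_subnetwork(family$networks[[total]], length(lst),
                                 reference = ref_net,
                                 seed = config$seed + 2000L + i * 100L + r)
        sc <- status_change(roles[["degree"]][[total]],
                            identify_roles(node_stats(rnd), "degree",
                                           config$hub_pct))
        data.frame(context = ctx, replicate = r,
                   pct_role_to_nonrole = sc$pct_role_to_nonrole,
                   pct_nonrole_to_role = sc$pct_nonrole_to_role,
                   stringsAsFactors = FALSE)
      }))
    }))
    null_t <- stats::t.test(changes[["degree"]]$pct_role_to_nonrole,
                            role_null$pct_role_to_nonrole, var.equal = TRUE)
    robust <- robustness_protocol(conglomerate, hierarchy,
                                  fractions = config$replace_fractions,
                                  seeds = config$seed + 0:2,
                                  pct = config$hub_pct, contexts = l3)

    stage <- "verdicts"
    vd <- function(analysis, verdict, evidence) {
      data.frame(analysis = analysis, verdict = verdict, evidence = evidence,
                 stringsAsFactors = FALSE)
    }
    hub_dem <- mean(changes[["degree"]]$pct_role_to_nonrole)
    bot_dem <- mean(changes[["betweenness"]]$pct_role_to_nonrole)
    # promotions judged as a share of the reference network's non-roles:
    # a promotion rate that is a trivial portion of total-network non-roles
    # leaves non-role identification transferable
    nonrole_share <- function(kind) {
      ref <- roles[[kind]][[total]]
      100 * mean(changes[[kind]]$nonrole_to_role) /
        (length(ref$roles) - sum(ref$roles))
    }
    hub_pro <- mean(changes[["degree"]]$pct_nonrole_to_role)
    bot_pro <- mean(changes[["betweenness"]]$pct_nonrole_to_role)
    hub_pro_share <- nonrole_share("degree")
    bot_pro_share <- nonrole_share("betweenness")
    verdicts <- rbind(
      vd("statistics",
         if (mean(stat_tests$p.value < 0.01, na.rm = TRUE) > 0.5)
           "not transferable" else "transferable",
         sprintf("%d/%d Welch tests p<0.01", sum(stat_tests$p.value < 0.01,
                                                 na.rm = TRUE), nrow(stat_tests))),
      vd("hubs", if (hub_dem > 50) "not transferable"
                 else if (hub_dem > 5) "to some degree" else "transferable",
         sprintf("mean role->nonrole %.1f%%", hub_dem)),
      vd("non-hubs", if (hub_pro_share < 10) "transferable" else "to some degree",
         sprintf("mean nonrole->role %.1f%% of subnetwork roles, %.1f%% of reference non-roles",
                 hub_pro, hub_pro_share)),
      vd("bottlenecks", if (bot_dem > 50) "not transferable"
                        else if (bot_dem > 5) "to some degree" else "transferable",
         sprintf("mean role->nonrole %.1f%%", bot_dem)),
      vd("non-bottlenecks", if (bot_pro_share < 10) "transferable" else "to some degree",
         sprintf("mean nonrole->role %.1f%% of subnetwork roles, %.1f%% of reference non-roles",
                 bot_pro, bot_pro_share)),
      vd("compatibility",
         if (all(compat$p_v < 0.01, na.rm = TRUE)) "not transferable"
         else "to some degree",
         sprintf("mean J_v %.3f vs null %.3f", mean(compat$J_v),
                 mean(compat$null_mean_v))),
      vd("enrichment",
         if (any(chi2$p.value < 0.01) ||
               any(lengths(mes$exclusive[l3]) > 0)) "not transferable"
         else "transferable",
         sprintf("%d/%d chi2 p<0.01; %d context-exclusive module terms",
                 sum(chi2$p.value < 0.01), nrow(chi2),
                 sum(lengths(mes$exclusive[l3])))),
      vd("modules",
         if (!is.na(cp$p.value) && cp$p.value < 0.05 &&
               cp$mean_between < cp$mean_within) "not transferable"
         else "to some degree",
         sprintf("Cp %.3f between vs %.3f within, MW p=%.2g",
                 cp$mean_between, cp$mean_within, cp$p.value))
    )

    list(config = config, family = family,
         stats = stats, stat_tests = stat_tests,
         topology = list(changes = changes, classes = class_tabs),
         compat = compat, modules = list(cp = cp, modsets = modsets),
         enrichment = list(per_context = enr, chi2 = chi2, modules = mes),
         randomize = list(role_null = role_null, null_t = null_t,
                          robustness = robust),
         truth = truth, verdicts = verdicts)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  manifest <- list(package = "netstrat",
                   version = as.character(utils::packageVersion("netstrat")),
                   seed = config$seed, algorithm = config$algorithm,
                   hub_pct = config$hub_pct, alpha = config$alpha,
                   n_null_compat = config$n_null_compat,
                   n_null_roles = config$n_null_roles, files = character())
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      write_tsv(result$stat_tests, file.path(config$out_dir, "stat_tests.tsv")),
      write_tsv(do.call(rbind, result$topology$changes),
                file.path(config$out_dir, "status_changes.tsv")),
      write_tsv(result$topology$classes,
                file.path(config$out_dir, "class_changes.tsv")),
      write_tsv(result$compat, file.path(config$out_dir, "compatibility.tsv")),
      write_tsv(rbind(
        data.frame(group = "between_total_and_subnetwork",
                   Cp = result$modules$cp$between$Cp),
        data.frame(group = "within_network",
                   Cp = result$modules$cp$within$Cp)),
        file.path(config$out_dir, "modular_compatibility.tsv")),
      write_tsv(result$enrichment$chi2, file.path(config$out_dir, "chi2.tsv")),
      write_tsv(result$enrichment$modules$fractions,
                file.path(config$out_dir, "module_enrichment.tsv")),
      write_tsv(result$randomize$role_null,
                file.path(config$out_dir, "role_null.tsv")),
      write_tsv(result$randomize$robustness$deltas,
                file.path(config$out_dir, "robustness.tsv")),
      write_tsv(result$verdicts, file.path(config$out_dir, "verdicts.tsv"))
    )
    manifest$files <- basename(files)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result$manifest <- manifest
  class(result) <- "netstrat_run"
  result
}

#' @export
print.netstrat_run <- function(x, ...) {
  cat("<netstrat_run> transferability of conglomerate-network analyses:\n")
  print(x$verdicts, row.names = FALSE)
  invisible(x)
}

#' @export
summary.netstrat_run <- function(object, ...) {
  print(object)
  cat("\nStatus changes (total vs level-3 contexts):\n")
  print(do.call(rbind, object$topology$changes), row.names = FALSE)
  cat("\nPairwise compatibility (level 3):\n")
  print(object$compat[, c("a", "b", "J_v", "J_e", "null_mean_v", "p_v")],
        row.names = FALSE)
  cat("\nModular compatibility:\n")
  print(object$modules$cp)
  invisible(object)
}
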