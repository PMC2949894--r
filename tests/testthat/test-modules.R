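two_triangles_shared_edge <- function() {
  # triangles a-b-c and b-c-d share edge b-c
  ppi_network(rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                    c("b", "d"), c("c", "d")), "tts")
}

test_that("clique percolation handles forced cases", {
  tri <- ppi_network(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  ms <- clique_percolation(tri, 3)
  expect_equal(length(ms$modules), 1L)
  expect_equal(ms$modules[[1]], c("a", "b", "c"))

  ms2 <- clique_percolation(two_triangles_shared_edge(), 3)
  expect_equal(length(ms2$modules), 1L)
  expect_equal(ms2$modules[[1]], c("a", "b", "c", "d"))

  path <- ppi_network(rbind(c("a", "b"), c("b", "c")))
  expect_equal(length(clique_percolation(path, 3)$modules), 0L)
  expect_equal(length(clique_percolation(tri, 4)$modules), 0L)
})

test_that("clique percolation matches direct k-clique enumeration", {
  for (seed in c(2, 13)) {
    net <- er_network(18, 0.3, seed)
    for (k in 3:4) {
      got <- clique_percolation(net, k)$modules
      want <- oracle_kclique_communities(net$nodes, net$edges, k)
      expect_setequal(unname(vapply(got, paste, "", collapse = ",")),
                      unname(vapply(want, paste, "", collapse = ",")))
      # every k-clique lies inside a community, and every community
      # contains at least one k-clique (clique-level uniqueness is implied
      # by the oracle equality above: communities partition the cliques)
      if (length(want)) {
        subsets <- combn(net$nodes, k, simplify = FALSE)
        ek <- netstrat:::edge_keys(net)
        for (s in subsets) {
          pp <- combn(s, 2)
          if (all(paste(pmin(pp[1, ], pp[2, ]), pmax(pp[1, ], pp[2, ]),
                        sep = "\t") %in% ek)) {
            expect_gte(sum(vapply(got, function(m) all(s %in% m), TRUE)), 1L)
          }
        }
        has_clique <- vapply(got, function(m) {
          any(vapply(subsets, function(s) {
            pp <- combn(s, 2)
            all(s %in% m) &&
              all(paste(pmin(pp[1, ], pp[2, ]), pmax(pp[1, ], pp[2, ]),
                        sep = "\t") %in% ek)
          }, TRUE))
        }, TRUE)
        expect_true(all(has_clique))
      }
    }
  }
})

test_that("modularity follows the formula exactly", {
  ttb <- two_triangles_bridge()
  expect_equal(modularity_score(ttb, list(ttb$nodes)), 0)
  part <- list(c("a", "b", "c"), c("d", "e", "f"))
  expect_equal(modularity_score(ttb, part), 2 * (3 / 7 - (7 / 14)^2),
               tolerance = 1e-12)
  expect_equal(modularity_score(ttb, part), 0.35714285714, tolerance = 1e-8)
  expect_true(is.na(modularity_score(ppi_network(NULL, nodes = "a"), list("a"))))
  expect_error(modularity_score(ttb, list(c("a", "b"))), "cover")
})

test_that("modularity agrees with independent oracles on random partitions", {
  for (seed in c(5, 21)) {
    net <- er_network(20, 0.2, seed)
    set.seed(seed)
    mem <- sample(1:4, length(net$nodes), replace = TRUE)
    part <- split(net$nodes, mem)
    m <- modularity_score(net, part)
    expect_equal(m, oracle_modularity(net$edges, part), tolerance = 1e-12)
    g <- netstrat:::as_igraph(net)
    memb <- mem[match(igraph::V(g)$name, net$nodes)]
    expect_equal(m, igraph::modularity(g, memb), tolerance = 1e-10)
  }
})

test_that("simulated annealing recovers forced optima", {
  two_tri <- ppi_network(rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                               c("d", "e"), c("e", "f"), c("d", "f")))
  ms <- sa_modularity(two_tri, seed = 3)
  expect_equal(ms$modularity, 0.5, tolerance = 1e-12)
  expect_setequal(vapply(ms$modules, paste, "", collapse = ","),
                  c("a,b,c", "d,e,f"))

  edge <- ppi_network(rbind(c("a", "b")))
  ms2 <- sa_modularity(edge, seed = 1)
  expect_equal(ms2$modularity, 0)
  expect_equal(length(ms2$modules), 1L)
})

test_that("simulated annealing is reproducible and beats its start", {
  net <- er_network(12, 0.25, seed = 8)
  a <- sa_modularity(net, seed = 5)
  b <- sa_modularity(net, seed = 5)
  expect_identical(a$modules, b$modules)
  # singleton start has negative M on any graph with edges
  singletons <- modularity_score(net, as.list(net$nodes))
  expect_gte(a$modularity, singletons)
  expect_equal(a$modularity, modularity_score(net, a$modules), tolerance = 1e-9)
})

test_that("edge-betweenness partitioning removes the brute-force top edge", {
  ttb <- two_triangles_bridge()
  # the bridge has the highest edge betweenness by enumeration
  orc <- oracle_betweenness(ttb$nodes, ttb$edges)
  expect_equal(names(which.max(orc$edge)), "c\td")
  ms <- girvan_newman(ttb, 1 / 7)
  expect_setequal(vapply(ms$modules, paste, "", collapse = ","),
                  c("a,b,c", "d,e,f"))

  # removal_fraction 0: connected components (no singletons)
  comps <- girvan_newman(ttb, 0)
  expect_equal(length(comps$modules), 1L)
  expect_equal(length(comps$modules[[1]]), 6L)
})

test_that("edge betweenness used for removal matches the oracle on fixtures", {
  for (seed in c(4, 17)) {
    net <- er_network(15, 0.2, seed)
    g <- netstrat:::as_igraph(net)
    eb <- igraph::edge_betweenness(g, directed = FALSE)
    ends <- igraph::ends(g, igraph::E(g))
    keys <- paste(pmin(ends[, 1], ends[, 2]), pmax(ends[, 1], ends[, 2]),
                  sep = "\t")
    orc <- oracle_betweenness(net$nodes, net$edges)$edge
    expect_equal(setNames(eb, keys)[names(orc)], orc, tolerance = 1e-10)
  }
})

test_that("modular compatibility matches hand-evaluated cases", {
  s1 <- module_set(list(c("a", "b", "c", "d")), "n1")
  s2 <- module_set(list(c("a", "b", "c"), c("d", "e", "f")), "n2")
  r <- modular_compatibility(s1, s2)
  expect_equal(r$Cp, 0.5625)
  expect_equal(modular_compatibility(s2, s1)$Cp, r$Cp)

  same <- modular_compatibility(s2, s2)
  expect_equal(same$Cp, 1)

  disj <- modular_compatibility(
    module_set(list(c("a", "b", "c"))),
    module_set(list(c("x", "y", "z"))))
  expect_equal(disj$Cp, 0)
  expect_error(modular_compatibility(module_set(list()), s1), "empty")
})

test_that("Cp is symmetric and bounded on random module sets", {
  set.seed(30)
  ids <- sprintf("p%02d", 1:40)
  for (i in 1:5) {
    s1 <- module_set(lapply(1:4, function(i) sample(ids, sample(3:8, 1))))
    s2 <- module_set(lapply(1:3, function(i) sample(ids, sample(3:8, 1))))
    a <- modular_compatibility(s1, s2)$Cp
    b <- modular_compatibility(s2, s1)$Cp
    expect_equal(a, b)
    expect_gte(a, 0); expect_lte(a, 1)
  }
})

test_that("Mann-Whitney U equals the brute-force pair count", {
  set.seed(31)
  x <- round(runif(12), 2); y <- round(runif(9), 2)
  w <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
  expect_equal(unname(w$statistic), oracle_mwu(x, y))
})

test_that("Cp protocol is flat when every subnetwork equals the total", {
  net <- er_network(30, 0.25, seed = 40)
  ctx <- list(total = list(level = 1L, parent = NA, proteins = net$nodes),
              mid = list(level = 2L, parent = "total", proteins = net$nodes))
  for (i in 1:2) ctx[[paste0("t", i)]] <-
    list(level = 3L, parent = "mid", proteins = net$nodes)
  fam <- stratify_all(net, context_hierarchy(ctx))
  rep <- cp_comparison_protocol(fam, "cpm", list(3L, 3L))
  expect_equal(rep$mean_between, rep$mean_within)
  expect_equal(rep$p.value, 1)
  expect_error(cp_comparison_protocol(fam, "cpm", list(3L)), "at least 2")
})

test_that("planted context-exclusive modules depress total-vs-subnetwork Cp", {
  bundle <- paper_shaped_fixture(seed = 6)
  fam <- stratify_all(bundle$conglomerate, bundle$hierarchy)
  rep <- cp_comparison_protocol(fam, "cpm", list(4L, 5L))
  expect_lt(rep$mean_between, rep$mean_within)
})

test_that("overlapping clique-percolation module sets score higher Cp", {
  # overlap-counting inflates agreement relative to hard partitions
  vals <- sapply(1:3, function(s) {
    b <- paper_shaped_fixture(seed = s)
    fam <- stratify_all(b$conglomerate, b$hierarchy)
    cpm <- mean(sapply(sprintf("tissue%d", 1:5), function(ctx) {
      a <- clique_percolation(fam$networks$total, 4)
      bb <- clique_percolation(fam$networks[[ctx]], 4)
      if (!length(a$modules) || !length(bb$modules)) return(NA)
      modular_compatibility(a, bb)$Cp
    }), na.rm = TRUE)
    sa <- mean(sapply(sprintf("tissue%d", 1:5), function(ctx) {
      modular_compatibility(
        sa_modularity(fam$networks$total, moves_factor = 0.3, seed = 1),
        sa_modularity(fam$networks[[ctx]], moves_factor = 0.3, seed = 1))$Cp
    }))
    c(cpm = cpm, sa = sa)
  })
  expect_gt(mean(vals["cpm", ]), mean(vals["sa", ]))
})

test_that("annealing does not lose modularity with a bigger move budget", {
  # monotone in expectation over a seed ensemble, not per seed
  net <- er_network(18, 0.22, seed = 44)
  m_small <- mean(vapply(1:8, function(s)
    sa_modularity(net, moves_factor = 0.1, seed = s)$modularity, 0))
  m_big <- mean(vapply(1:8, function(s)
    sa_modularity(net, moves_factor = 0.4, seed = s)$modularity, 0))
  expect_gte(m_big, m_small - 1e-6)
})
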