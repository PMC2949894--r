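test_that("conglomerate assembly merges sources with provenance union", {
  net <- assemble_conglomerate(list(
    d1 = rbind(c("a", "b"), c("b", "c")),
    d2 = rbind(c("b", "c"), c("c", "d"))))
  expect_equal(net$nodes, c("a", "b", "c", "d"))
  expect_equal(nrow(net$edges), 3L)
  expect_setequal(net$provenance[["b\tc"]], c("d1", "d2"))
  expect_equal(net$provenance[["a\tb"]], "d1")

  loop <- assemble_conglomerate(list(d1 = rbind(c("a", "a"), c("a", "b"))))
  expect_equal(loop$nodes, c("a", "b"))
  expect_equal(nrow(loop$edges), 1L)

  expect_error(assemble_conglomerate(list()), "no datasets")
  expect_error(assemble_conglomerate(list(d1 = rbind(c("", "b")))), "malformed")
})

test_that("assembly equals brute-force union of unordered pairs", {
  set.seed(42)
  ids <- sprintf("p%02d", 1:40)
  mk <- function(n) {
    a <- sample(ids, n, replace = TRUE); b <- sample(ids, n, replace = TRUE)
    cbind(a, b)
  }
  shared <- mk(10)
  lists <- list(s1 = rbind(mk(40), shared), s2 = rbind(mk(20), shared),
                s3 = rbind(mk(30), shared))
  net <- assemble_conglomerate(lists)
  all_pairs <- do.call(rbind, lists)
  keep <- all_pairs[, 1] != all_pairs[, 2]
  keys <- unique(paste(pmin(all_pairs[keep, 1], all_pairs[keep, 2]),
                       pmax(all_pairs[keep, 1], all_pairs[keep, 2])))
  expect_equal(nrow(net$edges), length(keys))
  expect_equal(length(net$nodes),
               length(unique(c(all_pairs[keep, 1], all_pairs[keep, 2]))))
})

test_that("induced subnetworks keep edges with both endpoints listed", {
  net <- ppi_network(rbind(c("a", "b"), c("b", "c"), c("c", "d")))
  sub <- induce_subnetwork(net, c("a", "b", "c"))
  expect_setequal(netstrat:::edge_keys(sub), c("a\tb", "b\tc"))
  empty <- induce_subnetwork(net, character())
  expect_equal(length(empty$nodes), 0L)
  expect_equal(nrow(empty$edges), 0L)

  # listed proteins without a surviving edge are dropped
  sub2 <- induce_subnetwork(net, c("a", "b", "d"))
  expect_setequal(sub2$nodes, c("a", "b"))
})

test_that("induction matches a brute-force edge filter and is monotone", {
  net <- er_network(200, 0.02, seed = 7)
  set.seed(8)
  p_small <- sample(net$nodes, 80)
  p_big <- unique(c(p_small, sample(net$nodes, 40)))
  sub_small <- induce_subnetwork(net, p_small)
  sub_big <- induce_subnetwork(net, p_big)

  brute <- apply(net$edges, 1L, function(e) all(e %in% p_small))
  expect_setequal(netstrat:::edge_keys(sub_small),
                  paste(net$edges[brute, 1], net$edges[brute, 2], sep = "\t"))
  expect_true(all(netstrat:::edge_keys(sub_small) %in%
                    netstrat:::edge_keys(sub_big)))
  expect_equal(netstrat:::edge_keys(induce_subnetwork(net, net$nodes)),
               netstrat:::edge_keys(net))
})

test_that("degree sum equals twice the edge count on varied networks", {
  for (seed in 1:5) {
    net <- er_network(30, 0.1, seed)
    st <- node_stats(net)
    expect_equal(sum(st$table$degree), 2 * nrow(net$edges))
  }
})

test_that("node statistics are exact on analytically forced graphs", {
  path <- ppi_network(rbind(c("a", "b"), c("b", "c")))
  st <- node_stats(path)
  tab <- st$table[order(st$table$protein), ]
  expect_equal(tab$degree, c(1, 2, 1))
  expect_equal(tab$betweenness, c(0, 1, 0))
  expect_equal(tab$eccentricity, c(2, 1, 2))

  tri <- ppi_network(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
  st2 <- node_stats(tri)
  expect_equal(st2$table$clustering, rep(1, 3))
  expect_equal(st2$table$betweenness, rep(0, 3))
  expect_error(node_stats(ppi_network(NULL)), "empty")
})

test_that("betweenness, eccentricity and clustering match brute-force oracles", {
  for (seed in c(3, 11)) {
    net <- er_network(30, 0.09, seed)
    st <- node_stats(net)
    orc <- oracle_betweenness(net$nodes, net$edges)
    expect_equal(setNames(st$table$betweenness, st$table$protein),
                 orc$node[st$table$protein], tolerance = 1e-10)
    expect_equal(setNames(st$table$eccentricity, st$table$protein),
                 oracle_eccentricity(net$nodes, net$edges)[st$table$protein])
    expect_equal(setNames(st$table$clustering, st$table$protein),
                 oracle_clustering(net$nodes, net$edges)[st$table$protein],
                 tolerance = 1e-10)
  }
})

test_that("network file round-trips preserve node and edge sets", {
  net <- assemble_conglomerate(list(src = rbind(c("a", "b"), c("b", "c"),
                                                c("c", "d"))))
  tmp <- tempfile(fileext = ".tsv")
  write_network(net, tmp)
  back <- read_network(tmp)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)
  expect_equal(back$provenance[["a\tb"]], "src")

  dup <- tempfile()
  writeLines(c("a\tb", "b\ta", "# comment", "b\tc"), dup)
  net2 <- read_network(dup)
  expect_equal(nrow(net2$edges), 2L)

  bad <- tempfile()
  writeLines(c("a\tb", "c"), bad)
  expect_error(read_network(bad), "two columns")
  expect_error(read_network(tempfile()), "not found")
})

test_that("parsed edge count matches an independent text scan on a big file", {
  set.seed(99)
  ids <- sprintf("g%03d", 1:120)
  a <- sample(ids, 500, replace = TRUE)
  b <- sample(ids, 500, replace = TRUE)
  tmp <- tempfile()
  writeLines(c("# header comment", paste(a, b, sep = "\t")), tmp)
  net <- read_network(tmp)
  # independent scan: canonical unordered non-loop pairs
  lines <- readLines(tmp)
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(lines, "\t")
  aa <- vapply(parts, `[[`, "", 1L); bb <- vapply(parts, `[[`, "", 2L)
  keep <- aa != bb
  expect_equal(nrow(net$edges),
               length(unique(paste(pmin(aa[keep], bb[keep]),
                                   pmax(aa[keep], bb[keep])))))
})

test_that("protein list files are read as sorted unique sets", {
  tmp <- tempfile()
  writeLines(c("b", "a", "# note", "", "a"), tmp)
  expect_equal(read_protein_list(tmp), c("a", "b"))
})
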