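# Minimal node_stats stand-in for tests that only need a statistic vector.
fake_stats <- function(values, statistic = "degree", network = "fake") {
  tab <- data.frame(protein = names(values), degree = 0, betweenness = 0,
                    clustering = 0, eccentricity = 0)
  tab[[statistic]] <- as.numeric(values)
  structure(list(network = network, table = tab,
                 n_nodes = nrow(tab), n_edges = 0L), class = "node_stats")
}

test_that("role thresholds use inclusive top-percent ranks", {
  st <- fake_stats(c(a = 4, b = 3, c = 2, d = 2, e = 1))
  ra <- identify_roles(st, "degree", 20)
  expect_equal(ra$threshold, 4)
  expect_equal(sum(ra$roles), 1L)
  expect_true(ra$roles[["a"]])

  # 5-cycle: all degrees tie at the threshold, so all are flagged
  cyc <- ppi_network(rbind(c("a","b"), c("b","c"), c("c","d"), c("d","e"),
                           c("e","a")))
  rc <- identify_roles(node_stats(cyc), "degree", 20)
  expect_equal(rc$threshold, 2)
  expect_equal(sum(rc$roles), 5L)
})

test_that("hub sets equal the brute-force sort/threshold oracle", {
  set.seed(10)
  ids <- sprintf("p%03d", 1:100)
  edges <- netstrat:::pa_layer(ids, 2L)
  net <- ppi_network(edges)
  st <- node_stats(net)
  ra <- identify_roles(st, "degree", 20)
  v <- setNames(st$table$degree, st$table$protein)
  thr <- sort(v, decreasing = TRUE)[ceiling(0.2 * length(v))]
  expect_setequal(names(ra$roles)[ra$roles], names(v)[v >= thr])
  # inclusive-threshold property
  expect_gte(min(v[ra$roles]), max(v[!ra$roles]))
  expect_gte(sum(ra$roles), ceiling(0.2 * length(v)))
})

test_that("status changes partition the reference roles", {
  ref <- identify_roles(fake_stats(c(a = 5, b = 4, c = 1, d = 1, e = 1)),
                        "degree", 40)
  # comparison network lacks b; a demoted
  cmpst <- fake_stats(c(a = 1, c = 5, d = 4, e = 1))
  cmp <- identify_roles(cmpst, "degree", 50)
  sc <- status_change(ref, cmp)
  expect_equal(sc$role_to_nonrole, 1L)
  expect_equal(sc$role_absent, 1L)
  expect_equal(sc$role_to_nonrole + sc$role_to_role + sc$role_absent,
               sc$n_ref_roles)
  expect_error(status_change(ref, identify_roles(cmpst, "betweenness", 50)),
               "kinds differ")

  same <- status_change(ref, ref)
  expect_equal(same$role_to_nonrole, 0L)
  expect_equal(same$nonrole_to_role, 0L)
  expect_equal(same$role_absent, 0L)
})

test_that("status-change counts match brute-force per-node comparison", {
  bundle <- paper_shaped_fixture(seed = 3)
  fam <- stratify_all(bundle$conglomerate, bundle$hierarchy)
  st_t <- node_stats(fam$networks[[fam$total]])
  st_c <- node_stats(fam$networks[["tissue2"]])
  ref <- identify_roles(st_t, "degree", 20)
  cmp <- identify_roles(st_c, "degree", 20)
  sc <- status_change(ref, cmp)
  shared <- intersect(names(ref$roles), names(cmp$roles))
  expect_equal(sc$role_to_nonrole,
               sum(ref$roles[shared] & !cmp$roles[shared]))
  expect_equal(sc$nonrole_to_role,
               sum(!ref$roles[shared] & cmp$roles[shared]))
  expect_equal(sc$role_absent, sum(ref$roles) - sum(ref$roles[shared]))
})

test_that("class bands follow rank arithmetic and partition all nodes", {
  v <- setNames(20:1, sprintf("p%02d", 1:20))
  ca <- assign_classes(fake_stats(v), "degree", c(5, 10, 20, 50))
  expect_equal(as.integer(table(ca$classes)), c(1L, 1L, 2L, 6L, 10L))
  expect_equal(sum(table(ca$classes)), 20L)
  # alternate schemes accepted
  ca4 <- assign_classes(fake_stats(v), "degree", c(10, 20, 50))
  expect_equal(length(unique(ca4$classes)), 4L)
  ca5 <- assign_classes(fake_stats(v), "degree", c(5, 15, 25, 60))
  expect_equal(max(ca5$classes), 5L)
  expect_error(assign_classes(fake_stats(v), "degree", c(10, 5)), "increasing")
})

test_that("class changes flag leaps and vanish on self-comparison", {
  v <- setNames(20:1, sprintf("p%02d", 1:20))
  ca <- assign_classes(fake_stats(v), "degree")
  self <- class_changes(ca, ca)
  expect_true(all(self$delta == 0))
  expect_false(any(self$leap))

  # planted drop: the top node falls to the bottom band
  v2 <- v; v2["p01"] <- 0
  cb <- assign_classes(fake_stats(v2), "degree")
  cc <- class_changes(ca, cb)
  expect_true(cc$leap[cc$protein == "p01"])
  expect_gte(cc$delta[cc$protein == "p01"], 2L)
})

test_that("distribution tests dispatch and match the closed-form Welch p", {
  same <- fake_stats(setNames(c(1, 2, 3, 4), letters[1:4]))
  r <- compare_stat_distributions(same, same, "degree", "welch")
  expect_equal(r$p.value, 1)

  lo <- fake_stats(setNames(c(0, 0, 0, 0) + c(1e-3, -1e-3, 2e-3, 0), letters[1:4]))
  hi <- fake_stats(setNames(c(5, 5, 5, 5) + c(1e-3, -1e-3, 2e-3, 0), letters[1:4]))
  expect_lt(compare_stat_distributions(lo, hi, "degree", "welch")$p.value, 0.01)

  set.seed(77)
  x <- rnorm(50, 0, 1); y <- rnorm(50, 1, 1)
  sx <- fake_stats(setNames(x, sprintf("a%02d", 1:50)))
  sy <- fake_stats(setNames(y, sprintf("b%02d", 1:50)))
  expect_equal(compare_stat_distributions(sx, sy, "degree", "welch")$p.value,
               oracle_welch_p(x, y), tolerance = 1e-10)
  # degenerate variance is reported, not crashed
  cst <- fake_stats(setNames(rep(2, 4), letters[1:4]))
  r2 <- compare_stat_distributions(cst, cst, "degree", "student")
  expect_true(is.na(r2$p.value))
  expect_false(is.na(r2$note))
})

test_that("power-law slope recovers an exact k^-2 histogram", {
  ks <- c(1, 2, 4, 8, 16, 32)
  freq <- 4096 / ks^2
  deg <- rep(ks, freq)
  st <- fake_stats(setNames(deg, sprintf("p%04d", seq_along(deg))))
  pl <- powerlaw_slope(st)
  expect_equal(pl$slope, -2, tolerance = 0.01)
  expect_gt(pl$r.squared, 0.999)

  uni <- fake_stats(setNames(rep(3, 30), sprintf("p%02d", 1:30)))
  expect_true(is.na(powerlaw_slope(uni)$slope))
})

test_that("preferential-attachment networks look scale-free", {
  set.seed(123)
  ids <- sprintf("p%04d", 1:2000)
  net <- ppi_network(netstrat:::pa_layer(ids, 2L))
  pl <- powerlaw_slope(node_stats(net))
  expect_lt(pl$slope, -1.5)
})

test_that("the Mann-Whitney dispatch returns a valid two-sided p", {
  sx <- fake_stats(setNames(1:10, letters[1:10]))
  sy <- fake_stats(setNames(4:13, LETTERS[1:10]))
  r <- compare_stat_distributions(sx, sy, "degree", "mannwhitney")
  expect_true(r$p.value > 0 && r$p.value <= 1)
  expect_equal(r$test, "mannwhitney")
})
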