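# 20 fully annotated proteins: t1 on p01..p05, t2 on p01..p10, and a broad
# base term on everyone so the annotated universe is all 20.
toy_annot <- function() {
  annotation_map(data.frame(
    protein = c(sprintf("p%02d", 1:5), sprintf("p%02d", 1:10),
                sprintf("p%02d", 1:20)),
    category = "biological_process",
    term_id = c(rep("t1", 5), rep("t2", 10), rep("t0", 20)),
    term_label = "x"))
}

test_that("Fisher enrichment p equals the exact hypergeometric value", {
  bg <- sprintf("p%02d", 1:20)
  tab <- protein_enrichment(sprintf("p%02d", 1:5), bg, toy_annot())
  p1 <- tab$p.value[tab$term_id == "t1"]
  # all 5 carriers of t1 in a 5-protein foreground from a 20-protein universe
  expect_equal(p1, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(p1, 6.4504e-5, tolerance = 1e-3)
  expect_true(tab$enriched[tab$term_id == "t1"])

  # foreground = background: nothing can be over-represented
  tab2 <- protein_enrichment(bg, bg, toy_annot())
  expect_true(all(tab2$p.value == 1))
  expect_error(protein_enrichment("zzz", bg, toy_annot()), "foreground")
})

test_that("enrichment p-values match brute-force tail sums on random tables", {
  set.seed(50)
  for (i in 1:20) {
    N <- sample(10:60, 1); K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    ks <- max(0, n + K - N):min(n, K)
    k <- if (length(ks) == 1L) ks else sample(ks, 1)
    expect_equal(netstrat:::fisher_over_p(k, n, K, N),
                 oracle_fisher_over(k, n, K, N), tolerance = 1e-10)
    # and against stats::fisher.test as an independent implementation
    ft <- fisher.test(matrix(c(k, K - k, n - k, N - K - n + k), 2),
                      alternative = "greater")
    expect_equal(netstrat:::fisher_over_p(k, n, K, N), ft$p.value,
                 tolerance = 1e-10)
  }
})

test_that("enrichment flags are anti-monotone in alpha", {
  bundle <- paper_shaped_fixture(seed = 7)
  fam <- stratify_all(bundle$conglomerate, bundle$hierarchy)
  t1 <- protein_enrichment(fam$networks$tissue1, fam$networks$total,
                           bundle$annotations, alpha = 5e-4)
  t2 <- protein_enrichment(fam$networks$tissue1, fam$networks$total,
                           bundle$annotations, alpha = 0.05)
  expect_true(all(t1$term_id[t1$enriched] %in% t2$term_id[t2$enriched]))
  # optional BH q-values are reported alongside raw p
  t3 <- protein_enrichment(fam$networks$tissue1, fam$networks$total,
                           bundle$annotations, adjust = TRUE)
  expect_true(all(t3$q.value >= t3$p.value - 1e-12))
})

test_that("pair counting credits an interacting pair once per shared term", {
  annot <- annotation_map(data.frame(
    protein = c("a", "b", "a", "b", "c"),
    category = "biological_process",
    term_id = c("t1", "t1", "t2", "t2", "t1"),
    term_label = "x"))
  net <- ppi_network(rbind(c("a", "b")))
  counts <- netstrat:::pair_term_counts(net, annot)
  expect_equal(as.integer(counts$counts[c("t1", "t2")]), c(1L, 1L))

  # an edge with no shared term contributes to no term
  net2 <- ppi_network(rbind(c("a", "c")))
  annot2 <- annotation_map(data.frame(
    protein = c("a", "c"), category = "biological_process",
    term_id = c("t1", "t2"), term_label = "x"))
  counts2 <- netstrat:::pair_term_counts(net2, annot2)
  expect_equal(length(counts2$counts), 0L)

  bundle <- paper_shaped_fixture(seed = 8)
  fam <- stratify_all(bundle$conglomerate, bundle$hierarchy)
  tab <- pair_enrichment(fam$networks$tissue1, fam$networks$total,
                         bundle$annotations)
  expect_true(all(tab$fg_count <= tab$bg_count))
  expect_true(all(tab$p.value > 0 & tab$p.value <= 1))
})

test_that("planted module terms are enriched for pairs in their own context", {
  bundle <- paper_shaped_fixture(seed = 9)
  fam <- stratify_all(bundle$conglomerate, bundle$hierarchy)
  tab <- pair_enrichment(fam$networks$tissue1, fam$networks$total,
                         bundle$annotations, alpha = 5e-4)
  own_terms <- names(bundle$truth$modules$tissue1)
  hit <- tab$term_id[tab$enriched]
  expect_true(any(own_terms %in% hit))
})

test_that("chi-squared comparison follows the hand formula and pools tiny cells", {
  r0 <- distribution_chi2(c(a = 2, b = 4, c = 6), c(a = 1, b = 2, c = 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)

  r1 <- distribution_chi2(c(x = 100, y = 0), c(x = 50, y = 50))
  expect_lt(r1$p.value, 1e-5)

  set.seed(60)
  for (i in 1:10) {
    a <- sample(5:40, 6); b <- sample(5:40, 6)
    names(a) <- names(b) <- letters[1:6]
    r <- distribution_chi2(a, b)
    expected <- sum(a) * b / sum(b)
    expect_equal(r$statistic, oracle_chi2(a, expected), tolerance = 1e-10)
    expect_equal(r$df, 5)
  }
  expect_error(distribution_chi2(c(a = 0), c(a = 0)), "all-zero")
  # cells with expected < 1 are pooled
  rp <- distribution_chi2(c(a = 50, b = 1, c = 1), c(a = 500, b = 1, c = 1))
  expect_equal(rp$pooled, 2)
})

test_that("module enrichment summary finds planted and shuffled truth", {
  # three modules, each fully annotated with a unique term -> fraction 1
  mods <- module_set(list(sprintf("a%d", 1:5), sprintf("b%d", 1:5),
                          sprintf("c%d", 1:5)), "net")
  universe <- c(sprintf("a%d", 1:5), sprintf("b%d", 1:5), sprintf("c%d", 1:5),
                sprintf("z%d", 1:35))
  annot <- annotation_map(data.frame(
    protein = c(universe, sprintf("a%d", 1:5), sprintf("b%d", 1:5),
                sprintf("c%d", 1:5)),
    category = "biological_process",
    term_id = c(rep("bgterm", 50), rep("ta", 5), rep("tb", 5), rep("tc", 5)),
    term_label = "x"))
  mes <- module_enrichment_summary(list(net = mods), annot,
                                   backgrounds = list(net = universe),
                                   alpha = 5e-4)
  expect_equal(mes$fractions$fraction, 1)

  # shuffling annotations destroys the signal
  set.seed(70)
  annot_shuf <- annot
  annot_shuf$protein <- sample(annot$protein)
  annot_shuf <- annotation_map(annot_shuf)
  mes2 <- module_enrichment_summary(list(net = mods), annot_shuf,
                                    backgrounds = list(net = universe),
                                    alpha = 5e-4)
  expect_lt(mes2$fractions$fraction, mes$fractions$fraction)
})

test_that("conglomerate-only artifact terms are flagged on the small fixture", {
  bundle <- paper_shaped_fixture(seed = 2)
  fam <- stratify_all(bundle$conglomerate, bundle$hierarchy)
  l3 <- sprintf("tissue%d", 1:5)
  modsets <- lapply(c("total", l3), function(nm)
    sa_modularity(fam$networks[[nm]], moves_factor = 0.3, seed = 2))
  names(modsets) <- c("total", l3)
  mes <- module_enrichment_summary(
    modsets, bundle$annotations,
    backgrounds = lapply(fam$networks[c("total", l3)], `[[`, "nodes"),
    conglomerate = "total")
  arts <- vapply(bundle$truth$artifacts, `[[`, "", "term")
  expect_true(all(arts %in% mes$conglomerate_only))
})

test_that("pair-level analysis sharpens p-values for planted module terms", {
  hits <- unlist(lapply(1:3, function(s) {
    b <- paper_shaped_fixture(seed = s)
    fam <- stratify_all(b$conglomerate, b$hierarchy)
    pt <- protein_enrichment(fam$networks$tissue1, fam$networks$total,
                             b$annotations)
    pr <- pair_enrichment(fam$networks$tissue1, fam$networks$total,
                          b$annotations)
    terms <- intersect(names(b$truth$modules$tissue1),
                       intersect(pt$term_id, pr$term_id))
    vapply(terms, function(t) {
      pr$p.value[pr$term_id == t] <= pt$p.value[pt$term_id == t]
    }, TRUE)
  }))
  expect_gt(mean(hits), 0.5)
})
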