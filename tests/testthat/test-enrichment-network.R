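test_that("dichotomize is a strict median split with ties to low", {
  expect_equal(dichotomize(c(1, 2, 3, 4)), c(0L, 0L, 1L, 1L))
  expect_equal(dichotomize(c(7, 7, 7)), c(0L, 0L, 0L))
  expect_equal(dichotomize(c(5, 1, 5, 1)), c(1L, 0L, 1L, 0L))
  expect_error(dichotomize(3), ">= 2")
})

test_that("odds_ratio applies the Haldane-Anscombe correction", {
  expect_equal(odds_ratio(2, 2, 2, 2), 1)
  expect_equal(odds_ratio(4, 1, 1, 4), 16)
  expect_equal(odds_ratio(5, 0, 0, 5), 121)  # (5.5*5.5)/(0.5*0.5)
  expect_error(odds_ratio(0, 0, 0, 0), "empty")
  expect_error(odds_ratio(-1, 1, 1, 1), "non-negative")
})

test_that("classify_enrichment assigns mutually exclusive categories", {
  r <- classify_enrichment(3)
  expect_equal(r$category, "enriched")
  expect_equal(r$da_score, log2(3))
  expect_true(r$associated)

  expect_equal(classify_enrichment(1.5)$category, "associated")
  b <- classify_enrichment(1)
  expect_equal(b$category, "other")
  expect_equal(b$da_score, 0)
  expect_false(b$associated)
  expect_equal(classify_enrichment(0.5)$category, "other")
  d <- classify_enrichment(0.25)
  expect_equal(d$category, "depleted")
  expect_equal(d$da_score, 2)
  expect_error(classify_enrichment(0), "positive")
})

test_that("label swap maps OR to 1/OR and mirrors the categories", {
  labels <- cohort_labels(6, 6)
  swapped <- setNames(ifelse(labels == "high", "low", "high"), names(labels))
  set.seed(17)
  tab <- matrix(rexp(12 * 20), nrow = 20,
                dimnames = list(sprintf("K%02d", 1:20), names(labels)))
  a <- metabotype_odds_ratios(tab, labels)
  b <- metabotype_odds_ratios(tab, swapped)
  expect_equal(a$odds_ratio, 1 / b$odds_ratio, tolerance = 1e-12)
  expect_equal(a$da_score, b$da_score, tolerance = 1e-12)
  # enriched <-> depleted mirror under the swap
  expect_equal(b$category[a$category == "enriched"],
               rep("depleted", sum(a$category == "enriched")))
  expect_equal(b$category[a$category == "depleted"],
               rep("enriched", sum(a$category == "depleted")))
})

test_that("build_network matches the definition and the blacklist rule", {
  ann <- data.frame(enzyme_id = c("A", "B"),
                    substrates = c("s", "x"),
                    products = c("x", "y"))
  g <- build_network(ann)
  expect_equal(igraph::as_edgelist(g), matrix(c("A", "B"), 1))
  g2 <- build_network(ann, blacklist = "x")
  expect_equal(igraph::ecount(g2), 0)
  expect_equal(igraph::vcount(g2), 2)   # isolated nodes retained

  # chain of 4 enzymes: 3 edges
  chain <- data.frame(enzyme_id = LETTERS[1:4],
                      substrates = c("c1", "c2", "c3", "c4"),
                      products = c("c2", "c3", "c4", "c5"))
  expect_equal(igraph::ecount(build_network(chain)), 3)

  # self-loops are dropped
  loop <- data.frame(enzyme_id = "A", substrates = "x", products = "x")
  expect_equal(igraph::ecount(build_network(loop)), 0)

  expect_error(build_network(rbind(ann, ann[1, ])), "unique")
})

test_that("build_network equals the brute-force pairwise oracle", {
  set.seed(23)
  for (i in 1:40) {
    ra <- random_annotation(n_enzymes = sample(3:8, 1),
                            n_compounds = sample(4:8, 1))
    blk <- if (i %% 3 == 0) sample(sprintf("C%02d", 1:8), 2) else character()
    g <- build_network(ra$df, blacklist = blk)
    got <- sort(apply(igraph::as_edgelist(g, names = FALSE), 1, paste,
                      collapse = " "))
    expect_identical(got, brute_network_edges(ra$subs, ra$prods, blk))
  }
})

test_that("betweenness matches hand cases and the enumeration oracle", {
  path3 <- data.frame(enzyme_id = c("a", "b", "c"),
                      substrates = c("1", "2", "3"),
                      products = c("2", "3", "4"))
  b <- betweenness_centrality(build_network(path3))
  expect_equal(unname(b[c("a", "b", "c")]), c(0, 0.5, 0))

  iso <- build_network(data.frame(enzyme_id = c("a", "b", "c", "z"),
                                  substrates = c("1", "2", "3", "q"),
                                  products = c("2", "3", "4", "r")))
  expect_equal(unname(betweenness_centrality(iso)["z"]), 0)

  set.seed(31)
  for (i in 1:40) {
    adj <- random_digraph(sample(3:8, 1), runif(1, 0.15, 0.5))
    got <- unname(betweenness_centrality(adj_to_igraph(adj)))
    expect_equal(got, brute_betweenness(adj), tolerance = 1e-12)
  }
})

test_that("betweenness conserves total interior visits (oracle cross-check)", {
  set.seed(37)
  for (i in 1:10) {
    adj <- random_digraph(6, 0.35)
    n <- 6
    raw_pkg <- sum(betweenness_centrality(adj_to_igraph(adj))) * (n - 1) * (n - 2)
    raw_oracle <- sum(brute_betweenness(adj)) * (n - 1) * (n - 2)
    expect_equal(raw_pkg, raw_oracle, tolerance = 1e-9)
  }
})

test_that("centrality_tiers is a deterministic tertile split", {
  t3 <- centrality_tiers(setNames(c(0, 0.1, 0.9), c("a", "b", "c")))
  expect_equal(t3$tier[match(c("a", "b", "c"), t3$enzyme_id)],
               c("peripheral", "intermediate", "central"))

  te <- centrality_tiers(setNames(rep(0, 7), letters[1:7]))
  expect_equal(as.vector(table(te$tier)[c("peripheral", "intermediate", "central")]),
               c(2L, 2L, 3L))   # remainder goes to the top tier
  # ties break lexically: a,b peripheral
  expect_equal(sort(te$enzyme_id[te$tier == "peripheral"]), c("a", "b"))
  # determinism
  expect_identical(te, centrality_tiers(setNames(rep(0, 7), letters[1:7])))

  set.seed(41)
  sc <- setNames(runif(9), paste0("k", 1:9))
  t9 <- centrality_tiers(sc)
  expect_equal(as.vector(table(t9$tier)), rep(3L, 3))
  # rank-consistent with a plain sort
  expect_equal(t9$enzyme_id[order(t9$rank)], names(sort(sc)))
  expect_error(centrality_tiers(c(1, 2)), ">= 3")
})

test_that("compare_centrality matches exact rank enumeration", {
  # associated {1,2} vs {10,11,12}: only 1 of C(5,2) assignments is as
  # extreme, two-sided doubles it
  r <- compare_centrality(c(1, 2, 10, 11, 12),
                          c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r$p, 2 / choose(5, 2), tolerance = 1e-12)
  expect_equal(r$W, 3)  # rank-sum of the associated group

  same <- compare_centrality(rep(4, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(same$p, 1)
  expect_error(compare_centrality(1:3, c(TRUE, TRUE, TRUE)), "non-empty")
})

test_that("tier_enrichment matches the combinatorial oracle", {
  tiers <- rep(c("central", "intermediate", "peripheral"), each = 5)
  assoc <- tiers == "peripheral"   # all 5 associated in one 5-node tier
  r <- tier_enrichment(tiers, assoc)
  expect_equal(r$p_over[r$tier == "peripheral"], 1 / choose(15, 5),
               tolerance = 1e-12)
  # a tier with zero associated has p = 1 for over-representation
  expect_equal(r$p_over[r$tier == "central"], 1)

  # proportional spread stays unremarkable
  assoc2 <- rep(c(TRUE, FALSE, FALSE, FALSE, FALSE), 3)
  r2 <- tier_enrichment(tiers, assoc2)
  expect_true(all(r2$p_over > 0.05))
})

test_that("score_topology_correlation is Spearman on midranks", {
  expect_equal(score_topology_correlation(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(score_topology_correlation(1:5, 5:1)$rho, -1)
  r <- score_topology_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$rho, 0.8, tolerance = 1e-12)
  expect_error(score_topology_correlation(c(1, 1, 1), 1:3), "zero rank")
  expect_error(score_topology_correlation(1:2, 1:2), "n >= 3")
})
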