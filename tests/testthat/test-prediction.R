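test_that("expected frequency implements tot_f * n(u) / tot_n", {
  expect_equal(expected_frequency(3, 4, 10), 1.2)
  expect_equal(expected_frequency(0, 5, 10), 0)
  expect_equal(expected_frequency(3, 0, 10), 0)
  expect_error(expected_frequency(3, 4, 0), "> 0")
  expect_error(expected_frequency(11, 4, 10), "tot_f")
})

test_that("Hishigaki score matches direct substitution and the enrichment guard", {
  expect_equal(hishigaki_score(1, 1), 0)
  expect_equal(hishigaki_score(2, 1.2), 0.8^2 / 1.2)
  # raw chi-square would score a seed-depleted neighborhood; guard suppresses it
  expect_equal(hishigaki_score(0, 2), 0)
  expect_equal(hishigaki_score(0, 2, overrepresented_only = FALSE), 2)
  expect_equal(hishigaki_score(3, 0), 0)
})

test_that("scoring a star of seeds reproduces the hand computation", {
  # u joined to 4 seeds in a 10-node network; extra nodes isolatedly chained
  a <- c("u", "u", "u", "u", "x1", "x2", "x3", "x4", "x5")
  b <- c("s1", "s2", "s3", "s4", "x2", "x3", "x4", "x5", "x1")
  g <- build_graph(make_edge_list(a, b, rep(500L, 9), dedup = TRUE))
  res <- score_all_candidates(g, c("s1", "s2", "s3", "s4"))
  u <- res[res$protein == "u", ]
  expect_equal(u$n_f_u, 4L)
  expect_equal(u$n_u, 4L)
  expect_equal(u$e_f, 1.6)
  expect_equal(u$score, 3.6)
  expect_equal(u$rank, 1L)
  # nodes with no seed neighbors score zero under the guard
  expect_true(all(res$score[res$protein %in% paste0("x", 1:5)] == 0))
})

test_that("ranking breaks score ties by protein ID and errors without seeds", {
  # b and a are symmetric neighbors of the same seed
  g <- build_graph(make_edge_list(c("s", "s"), c("b", "a"), c(500L, 500L),
                                  dedup = TRUE))
  res <- score_all_candidates(g, "s")
  expect_equal(res$protein, c("a", "b"))
  expect_equal(res$rank, 1:2)
  expect_equal(res$score[1], res$score[2])
  expect_error(score_all_candidates(g, "absent"), "no seed")
})

test_that("top-k selection never returns zero-score candidates and warns on truncation", {
  g <- build_graph(make_edge_list(c("s", "s", "x"), c("a", "b", "y"),
                                  rep(500L, 3), dedup = TRUE))
  res <- score_all_candidates(g, "s")
  expect_equal(sort(select_top_k(res, 2)), c("a", "b"))
  expect_warning(sel <- select_top_k(res, 10), "truncated")
  expect_equal(sort(sel), c("a", "b"))
  expect_error(select_top_k(res, 0), ">= 1")

  res0 <- score_all_candidates(g, c("x", "y"))
  expect_warning(sel0 <- select_top_k(res0[res0$score == 0, ], 5), "no candidate")
  expect_length(sel0, 0L)
})

test_that("module extraction assigns roles and keeps isolated members", {
  # "c" is in the network but has no edge to any module member
  g <- build_graph(make_edge_list(c("s1", "s2", "a", "c"),
                                  c("a", "b", "b", "x"),
                                  rep(500L, 4), dedup = TRUE))
  mod <- extract_module(g, c("s1", "s2"), c("a", "b", "c"))
  expect_s3_class(mod, "ppi_module")
  expect_equal(sort(names(mod$roles)), c("a", "b", "c", "s1", "s2"))
  expect_equal(unname(mod$roles[c("s1", "a")]), c("seed", "predicted"))
  expect_equal(unname(igraph::degree(mod$graph)["c"]), 0)
  expect_error(extract_module(g, "s1", c("s1", "a")), "disjoint")

  empty_cand <- extract_module(g, c("s1", "s2"), character())
  expect_equal(igraph::vcount(empty_cand$graph), 2L)
})

test_that("scores are invariant under protein relabeling", {
  set.seed(99)
  for (rep in 1:5) {
    g <- random_named_gnp(30, 0.15)
    seeds <- sample(igraph::V(g)$name, 5)
    res <- score_all_candidates(g, seeds)

    perm <- sample(igraph::V(g)$name)
    relabel <- stats::setNames(sprintf("Z%03d", seq_along(perm)), perm)
    g2 <- g
    igraph::V(g2)$name <- unname(relabel[igraph::V(g)$name])
    res2 <- score_all_candidates(g2, unname(relabel[seeds]))

    res$mapped <- unname(relabel[res$protein])
    merged <- merge(res, as.data.frame(res2), by.x = "mapped", by.y = "protein")
    expect_equal(merged$score.x, merged$score.y, tolerance = 1e-12)
    expect_equal(merged$n_f_u.x, merged$n_f_u.y)
  }
})

test_that("adding a seed neighbor never lowers the guarded score", {
  for (n_u in c(3, 8, 20)) {
    e_f <- expected_frequency(10, n_u, 100)
    scores <- hishigaki_score(0:n_u, rep(e_f, n_u + 1))
    expect_true(all(diff(scores) >= 0))
  }
})

test_that("seed retention reporting counts connected seeds per k", {
  # two seeds wired to candidates, one listed seed absent from the network;
  # the x-chain pads the network so candidate neighborhoods are seed-enriched
  g <- build_graph(make_edge_list(c("s1", "s2", "a", "x1", "x2"),
                                  c("a", "b", "b", "x2", "x3"),
                                  rep(500L, 5), dedup = TRUE))
  ss <- seed_set(c("s1", "s2", "s3"), igraph::V(g)$name)
  expect_equal(ss$missing_from_network, "s3")
  res <- score_all_candidates(g, ss)
  rep1 <- seed_retention_report(g, ss, res, c(1, 2))
  expect_equal(rep1$k, c(1L, 2L))
  expect_equal(rep1$present + rep1$absent, c(3L, 3L))
  expect_equal(rep1$present, c(1L, 2L))
  expect_error(seed_retention_report(g, ss, res, integer()), "non-empty")
  expect_error(seed_retention_report(g, ss, res, 0), ">= 1")
})
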