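test_that("parameter defaults are validated and frozen", {
  p <- mcode_params()
  expect_equal(p$degree_cutoff, 2L)
  expect_equal(p$node_score_cutoff, 0.6)
  expect_equal(p$kcore, 2L)
  expect_equal(p$max_depth, 100L)
  expect_true(p$haircut)
  expect_false(p$fluff)
  expect_error(mcode_params(node_score_cutoff = 1.5), "\\[0, 1\\]")
  expect_error(mcode_params(kcore = 0), ">= 1")
})

test_that("vertex weight matches hand computations on cliques and cutoffs", {
  # K4 plus a pendant: interior vertices see a K4 closed neighborhood
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- c("a", "b", "c", "d")
  g <- igraph::add_vertices(k4, 1, name = "p")
  g <- igraph::add_edges(g, c("a", "p"))
  expect_equal(vertex_weight(g, "b"), 3)     # highest core K4: k=3, density 1
  expect_equal(vertex_weight(g, "p"), 0)     # degree 1 < cutoff
  # with the cutoff lifted, p's closed neighborhood is a single edge: 1-core
  expect_equal(vertex_weight(g, "p", degree_cutoff = 0), 1)
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("x", "y", "z")
  expect_equal(vertex_weight(tri, "x"), 2)   # K3: k=2, density 1
  expect_error(vertex_weight(tri, "nope"), "unknown node")
})

test_that("vertex weights agree with brute-force k-core pruning on random graphs", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    g <- random_named_gnp(n, stats::runif(1, 0.08, 0.35))
    w <- mcode_vertex_weights(g)
    pick <- sample(igraph::V(g)$name, min(8, n))
    for (v in pick) {
      expect_equal(unname(w[v]), oracle_vertex_weight(g, v), tolerance = 1e-12)
    }
  }
})

test_that("find_complexes recovers cliques separated by a low-weight bridge node", {
  # two K4s joined through an articulation vertex: the bridge vertex weight
  # (2/3) falls below every clique seed's threshold, so the cliques stay
  # separate and the bridge stays unassigned
  g <- clique_union(c(4, 4))
  g <- igraph::add_vertices(g, 1, name = "bridge")
  g <- igraph::add_edges(g, c("C1_01", "bridge", "bridge", "C2_01"))
  cx <- find_complexes(g)
  expect_length(cx, 2L)
  members <- lapply(cx, `[[`, "members")
  expect_setequal(members[[1]], sprintf("C1_%02d", 1:4))
  expect_setequal(members[[2]], sprintf("C2_%02d", 1:4))

  # a direct bridge EDGE leaves all weights equal, so the growth rule
  # admits the far clique and the complexes merge (as in the original
  # algorithm)
  g2 <- clique_union(c(4, 4))
  g2 <- igraph::add_edges(g2, c("C1_01", "C2_01"))
  cx2 <- find_complexes(g2)
  expect_length(cx2, 1L)
  expect_length(cx2[[1]]$members, 8L)
})

test_that("degenerate graphs yield no complexes and a clique is one complex", {
  edgeless <- igraph::make_empty_graph(5, directed = FALSE)
  igraph::V(edgeless)$name <- letters[1:5]
  expect_length(find_complexes(edgeless), 0L)

  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  cx <- find_complexes(k5)
  expect_length(cx, 1L)
  expect_setequal(cx[[1]]$members, letters[1:5])
  expect_equal(cx[[1]]$score, 5)      # density 1 * size 5
  expect_equal(cx[[1]]$id, 1L)

  # trees have no 2-core and are fully discarded
  tree <- igraph::make_tree(7, 2, mode = "undirected")
  igraph::V(tree)$name <- letters[1:7]
  expect_length(find_complexes(tree), 0L)
})

test_that("a disjoint union of cliques is partitioned into exactly its cliques", {
  sizes <- c(6, 5, 4, 3)
  g <- clique_union(sizes)
  cx <- find_complexes(g)
  expect_length(cx, length(sizes))
  got <- lapply(cx, `[[`, "members")
  expect_setequal(unlist(got), igraph::V(g)$name)
  # ids follow score = density * size = size, descending
  expect_equal(lengths(got), sort(sizes, decreasing = TRUE))
  for (i in seq_along(cx)) {
    expect_equal(cx[[i]]$id, i)
    pref <- sub("_.*", "", got[[i]][1])
    expect_true(all(startsWith(got[[i]], pref)))
  }
})

test_that("every returned complex contains a 2-core (independent pruning)", {
  set.seed(21)
  for (rep in 1:10) {
    g <- random_named_gnp(35, 0.12)
    for (cx in find_complexes(g)) {
      A <- as.matrix(igraph::as_adjacency_matrix(
        igraph::induced_subgraph(g, cx$members)))
      expect_gt(nrow(oracle_kcore_prune(A, 2)), 0)
    }
  }
})

test_that("output is invariant to input edge ordering", {
  set.seed(5)
  g <- random_named_gnp(30, 0.18)
  df <- igraph::as_data_frame(g)
  shuf <- df[sample(nrow(df)), c(2, 1)]
  g2 <- igraph::graph_from_data_frame(shuf, directed = FALSE)
  cx1 <- find_complexes(g)
  cx2 <- find_complexes(g2)
  expect_equal(lapply(cx1, `[[`, "members"), lapply(cx2, `[[`, "members"))
  expect_equal(vapply(cx1, `[[`, numeric(1), "score"),
               vapply(cx2, `[[`, numeric(1), "score"))
})

test_that("sub-module assignment and one-pass satellite attachment follow the rule", {
  # complex A = triangle a1a2a3, complex B = triangle b1b2b3;
  # sat1 touches only A, amb touches both
  g <- clique_union(c(3, 3))
  g <- igraph::add_vertices(g, 2, name = c("sat1", "amb"))
  g <- igraph::add_edges(g, c("sat1", "C1_01", "amb", "C1_02", "amb", "C2_01"))
  cx <- find_complexes(g)
  expect_length(cx, 2L)
  module <- structure(list(graph = g,
                           roles = stats::setNames(rep("predicted",
                                                       igraph::vcount(g)),
                                                   igraph::V(g)$name),
                           k = 0L),
                      class = "ppi_module")
  base <- assign_submodules(module, cx, attach_satellites = FALSE)
  expect_true(is.na(base[["sat1"]]) && is.na(base[["amb"]]))

  att <- assign_submodules(module, cx, attach_satellites = TRUE)
  expect_false(is.na(att[["sat1"]]))
  expect_equal(att[["sat1"]], base[["C1_01"]])
  expect_true(is.na(att[["amb"]]))          # ambiguous between two sub-modules
  expect_equal(att[names(base)[!is.na(base)]], base[!is.na(base)])

  overlapping <- cx
  overlapping[[2]]$members <- c(overlapping[[2]]$members,
                                overlapping[[1]]$members[1])
  expect_error(assign_submodules(module, overlapping), "disjoint")
})
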