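# Reimplementation of the MCODE molecular-complex detection algorithm:
# vertex weighting by the core-clustering coefficient (density of the
# highest k-core of the closed neighborhood, scaled by its core number),
# greedy seeded complex growth with a weight threshold relative to the
# seed vertex, a k-core post-filter, and optional haircut/fluff
# post-processing. All choice points are tie-broken lexicographically by
# node ID so the output is invariant to input edge ordering.

#' MCODE parameters
#'
#' @param degree_cutoff Minimum degree for a vertex to receive a non-zero
#'   weight (default 2).
#' @param node_score_cutoff Fraction in `[0, 1]`; a neighbor joins a
#'   growing complex when its weight is at least
#'   `seed_weight * (1 - node_score_cutoff)` (default 0.6).
#' @param kcore A detected complex must contain a k-core of this order or
#'   it is discarded (default 2).
#' @param max_depth Maximum BFS depth from the seed vertex during growth
#'   (default 100).
#' @param haircut Iteratively strip members with fewer than 2 within-complex
#'   interactions (default `TRUE`).
#' @param fluff Add, after growth, unassigned neighbors whose closed-
#'   neighborhood density exceeds `fluff_density` (default `FALSE`).
#' @param fluff_density Density threshold for fluff (default 0.5).
#' @return A validated `mcode_params` list.
#' @export
mcode_params <- function(degree_cutoff = 2L, node_score_cutoff = 0.6,
                         kcore = 2L, max_depth = 100L,
                         haircut = TRUE, fluff = FALSE, fluff_density = 0.5) {
  assert_that(degree_cutoff >= 0, "`degree_cutoff` must be >= 0")
  assert_that(node_score_cutoff >= 0 && node_score_cutoff <= 1,
              "`node_score_cutoff` must be in [0, 1]")
  assert_that(kcore >= 1, "`kcore` must be >= 1")
  assert_that(max_depth >= 1, "`max_depth` must be >= 1")
  structure(list(degree_cutoff = as.integer(degree_cutoff),
                 node_score_cutoff = node_score_cutoff,
                 kcore = as.integer(kcore),
                 max_depth = as.integer(max_depth),
                 haircut = isTRUE(haircut),
                 fluff = isTRUE(fluff),
                 fluff_density = fluff_density),
            class = "mcode_params")
}

graph_density_simple <- function(n, e) {
  if (n < 2L) return(0)
  2 * e / (n * (n - 1))
}

#' MCODE vertex weight
#'
#' Weight of `v` is `k_max * density` computed on the highest k-core of the
#' subgraph induced on the closed neighborhood of `v` (density by the
#' loop-free formula `2e / (n (n - 1))`). Vertices with degree below
#' `degree_cutoff` weigh 0.
#'
#' @param network An `igraph` network.
#' @param v Node ID.
#' @param degree_cutoff Minimum degree (default 2).
#' @return Non-negative numeric weight.
#' @export
vertex_weight <- function(network, v, degree_cutoff = 2L) {
  assert_that(v %in% igraph::V(network)$name, sprintf("unknown node: %s", v))
  unname(mcode_vertex_weights(network, degree_cutoff)[v])
}

#' MCODE vertex weights for every node
#'
#' @inheritParams vertex_weight
#' @return Named numeric vector of weights over all vertices.
#' @export
mcode_vertex_weights <- function(network, degree_cutoff = 2L) {
  nodes <- igraph::V(network)$name
  deg <- igraph::degree(network)
  w <- stats::setNames(numeric(length(nodes)), nodes)
  eligible <- which(deg >= degree_cutoff)
  if (length(eligible) == 0L) return(w)
  closed_nb <- igraph::ego(network, order = 1L, nodes = eligible, mindist = 0L)
  for (i in seq_along(eligible)) {
    sub <- igraph::induced_subgraph(network, closed_nb[[i]])
    core <- igraph::coreness(sub)
    k_max <- max(core)
    if (k_max == 0L) next
    top <- igraph::induced_subgraph(sub, which(core == k_max))
    w[eligible[i]] <- k_max *
      graph_density_simple(igraph::vcount(top), igraph::ecount(top))
  }
  w
}

#' Detect dense complexes (sub-modules) with MCODE
#'
#' Greedy growth: the highest-weight unassigned vertex seeds a complex;
#' unassigned neighbors whose weight is at least
#' `seed_weight * (1 - node_score_cutoff)` are included breadth-first up to
#' `max_depth`. Grown complexes lacking a `kcore`-core are discarded;
#' haircut (if enabled) iteratively removes members with fewer than two
#' within-complex interactions. Complexes are scored by `density * size`,
#' sorted by score descending and numbered in that order.
#'
#' @param network An `igraph` network (typically a module graph).
#' @param params An [mcode_params()] list.
#' @return List of sub-modules (class `mcode_complexes`); each element has
#'   `id`, `members` (sorted IDs), `seed_vertex` and `score`.
#' @export
find_complexes <- function(network, params = mcode_params()) {
  stopifnot(inherits(params, "mcode_params"))
  nodes <- igraph::V(network)$name
  n <- length(nodes)
  if (n == 0L || igraph::ecount(network) == 0L) {
    return(structure(list(), class = "mcode_complexes"))
  }
  w <- mcode_vertex_weights(network, params$degree_cutoff)
  adj <- igraph::adjacent_vertices(network, igraph::V(network))
  adj <- lapply(adj, function(v) sort(igraph::V(network)$name[as.integer(v)]))
  names(adj) <- nodes

  seed_order <- nodes[order(-w, nodes)]
  assigned <- stats::setNames(rep(FALSE, n), nodes)
  raw <- list()

  for (s in seed_order) {
    if (assigned[[s]]) next
    threshold <- w[[s]] * (1 - params$node_score_cutoff)
    members <- s
    assigned[[s]] <- TRUE
    frontier <- s
    depth <- 0L
    while (length(frontier) > 0L && depth < params$max_depth) {
      nxt <- character()
      for (u in frontier) {
        for (v in adj[[u]]) {
          if (!assigned[[v]] && w[[v]] >= threshold) {
            assigned[[v]] <- TRUE
            members <- c(members, v)
            nxt <- c(nxt, v)
          }
        }
      }
      frontier <- sort(nxt)
      depth <- depth + 1L
    }
    raw[[length(raw) + 1L]] <- list(seed_vertex = s, members = sort(members))
  }

  complexes <- list()
  for (cx in raw) {
    sub <- igraph::induced_subgraph(network, cx$members)
    if (igraph::vcount(sub) == 0L) next
    if (max(igraph::coreness(sub)) < params$kcore) next
    if (params$haircut) {
      sub <- haircut_subgraph(sub)
      if (igraph::vcount(sub) == 0L) next
    }
    members <- sort(igraph::V(sub)$name)
    if (params$fluff) {
      cand <- unique(unlist(adj[members], use.names = FALSE))
      cand <- setdiff(cand, members)
      keep <- vapply(cand, function(v) {
        nb2 <- c(v, adj[[v]])
        s2 <- igraph::induced_subgraph(network, nb2)
        graph_density_simple(igraph::vcount(s2), igraph::ecount(s2)) >
          params$fluff_density
      }, logical(1L))
      members <- sort(c(members, cand[keep]))
      sub <- igraph::induced_subgraph(network, members)
    }
    score <- graph_density_simple(igraph::vcount(sub), igraph::ecount(sub)) *
      igraph::vcount(sub)
    complexes[[length(complexes) + 1L]] <-
      list(members = members, seed_vertex = cx$seed_vertex, score = score)
  }

  if (length(complexes) > 0L) {
    ord <- order(-vapply(complexes, `[[`, numeric(1L), "score"),
                 -lengths(lapply(complexes, `[[`, "members")),
                 vapply(complexes, function(cx) cx$members[[1L]], character(1L)))
    complexes <- complexes[ord]
    for (i in seq_along(complexes)) complexes[[i]]$id <- i
    complexes <- lapply(complexes, function(cx) cx[c("id", "members", "seed_vertex", "score")])
  }
  structure(complexes, class = "mcode_complexes")
}

# iteratively strip vertices with degree < 2 (tree-like fringes)
haircut_subgraph <- function(sub) {
  repeat {
    deg <- igraph::degree(sub)
    drop <- which(deg < 2L)
    if (length(drop) == 0L || igraph::vcount(sub) == 0L) break
    sub <- igraph::delete_vertices(sub, drop)
  }
  sub
}

#' @export
print.mcode_complexes <- function(x, ...) {
  cat(sprintf("MCODE: %d sub-module(s)\n", length(x)))
  for (cx in x) {
    cat(sprintf("  [%d] %d members, score %.3f (seed %s)\n",
                cx$id, length(cx$members), cx$score, cx$seed_vertex))
  }
  invisible(x)
}

#' Assign module nodes to sub-modules
#'
#' Complex members keep their complex id. With `attach_satellites`, one
#' deterministic pass assigns each remaining node that is adjacent to
#' members of exactly one sub-module to that sub-module (a documented,
#' reproducible replacement for manual cluster expansion on a network
#' drawing); nodes adjacent to several sub-modules stay unassigned.
#'
#' @param module A `ppi_module` (or an `igraph` graph).
#' @param complexes An `mcode_complexes` list with pairwise disjoint
#'   members.
#' @param attach_satellites Enable the one-pass attachment rule (default
#'   `FALSE`).
#' @return Named integer vector over module nodes; `NA` means unassigned.
#' @export
assign_submodules <- function(module, complexes, attach_satellites = FALSE) {
  g <- if (inherits(module, "ppi_module")) module$graph else module
  nodes <- igraph::V(g)$name
  members <- unlist(lapply(complexes, `[[`, "members"), use.names = FALSE)
  assert_that(!anyDuplicated(members), "complexes must be pairwise disjoint")
  assignment <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  for (cx in complexes) {
    assignment[intersect(cx$members, nodes)] <- cx$id
  }
  if (attach_satellites) {
    base <- assignment
    for (v in nodes[is.na(base)]) {
      nb <- igraph::neighbors(g, v)$name
      ids <- unique(base[nb])
      ids <- ids[!is.na(ids)]
      if (length(ids) == 1L) assignment[[v]] <- ids
    }
  }
  assignment
}

#' Sub-module membership table
#'
#' @param module A `ppi_module`.
#' @param assignment Output of [assign_submodules()].
#' @return Data frame `protein`, `submodule_id` (NA when unassigned),
#'   `role`.
#' @export
submodule_table <- function(module, assignment) {
  stopifnot(inherits(module, "ppi_module"))
  data.frame(protein = names(assignment),
             submodule_id = unname(assignment),
             role = unname(module$roles[names(assignment)]),
             stringsAsFactors = FALSE)
}
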