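# Hishigaki neighborhood chi-square scoring of candidate proteins against
# a seed set, ranking, top-k selection and phenotype-module extraction.
#
# For a candidate u with n(u) immediate neighbors of which n_f(u) are
# seed-annotated, the expected seed frequency is
#     e_f = tot_f * n(u) / tot_n
# (tot_f = seeds present in the network, tot_n = network size) and the
# prediction score is the chi-square-style statistic
#     score(u) = (n_f(u) - e_f)^2 / e_f .
# The raw statistic also rewards seed-*depleted* neighborhoods; since the
# ranking assumes enrichment, neighborhoods with n_f(u) <= e_f score 0 by
# default (`overrepresented_only`).

#' Expected seed frequency in a neighborhood
#'
#' @param tot_f Number of seed-annotated proteins in the network.
#' @param n_u Neighborhood size of the candidate.
#' @param tot_n Total number of proteins in the network (> 0).
#' @return `tot_f * n_u / tot_n`.
#' @export
expected_frequency <- function(tot_f, n_u, tot_n) {
  assert_that(all(tot_n > 0), "`tot_n` must be > 0")
  assert_that(all(tot_f >= 0) && all(tot_f <= tot_n),
              "`tot_f` must satisfy 0 <= tot_f <= tot_n")
  assert_that(all(n_u >= 0), "`n_u` must be >= 0")
  tot_f * n_u / tot_n
}

#' Hishigaki prediction score
#'
#' @param n_f_u Observed count of seed-annotated neighbors (vectorized).
#' @param e_f Expected seed frequency from [expected_frequency()].
#' @param overrepresented_only If `TRUE` (default), neighborhoods with
#'   `n_f_u <= e_f` score 0 so that seed-depleted neighborhoods are never
#'   ranked; set `FALSE` for the raw chi-square statistic.
#' @return Numeric score(s) `(n_f_u - e_f)^2 / e_f`, 0 whenever `e_f` is 0.
#' @export
hishigaki_score <- function(n_f_u, e_f, overrepresented_only = TRUE) {
  assert_that(all(n_f_u >= 0), "`n_f_u` must be >= 0")
  assert_that(all(e_f >= 0), "`e_f` must be >= 0")
  score <- ifelse(e_f == 0, 0, (n_f_u - e_f)^2 / e_f)
  if (overrepresented_only) {
    score[n_f_u <= e_f] <- 0
  }
  as.numeric(score)
}

#' Score every non-seed protein against the seed set
#'
#' Seeds define the function of interest and are never scored themselves.
#' `tot_f` counts only seeds present in the network (absent seeds cannot
#' contribute neighbors) and `tot_n` is the network node count.
#'
#' @param network An `igraph` PPI network.
#' @param seeds A `seed_set` or character vector of seed IDs; at least one
#'   must be present in the network.
#' @param radius Neighborhood radius (default 1, the immediate
#'   neighborhood).
#' @param overrepresented_only Passed to [hishigaki_score()].
#' @return A data frame (class `hishigaki_scores`) with one row per
#'   non-seed node: `protein`, `n_f_u`, `n_u`, `e_f`, `score`, `rank`;
#'   sorted by score descending with ties broken by protein ID. Attributes
#'   `tot_f`, `tot_n` and `radius` record the scoring context.
#' @export
score_all_candidates <- function(network, seeds, radius = 1L,
                                 overrepresented_only = TRUE) {
  ids <- if (inherits(seeds, "seed_set")) seeds$ids else unique(as.character(seeds))
  nodes <- igraph::V(network)$name
  seeds_in <- intersect(ids, nodes)
  assert_that(length(seeds_in) > 0L, "no seed protein is present in the network")

  tot_f <- length(seeds_in)
  tot_n <- length(nodes)
  candidates <- setdiff(nodes, seeds_in)
  if (length(candidates) == 0L) {
    res <- data.frame(protein = character(), n_f_u = integer(),
                      n_u = integer(), e_f = numeric(), score = numeric(),
                      rank = integer(), stringsAsFactors = FALSE)
  } else {
    nb <- igraph::ego(network, order = radius, nodes = candidates, mindist = 1L)
    n_u <- lengths(nb)
    is_seed <- nodes %in% seeds_in
    n_f_u <- vapply(nb, function(v) sum(is_seed[as.integer(v)]), integer(1L))
    e_f <- expected_frequency(tot_f, n_u, tot_n)
    score <- hishigaki_score(n_f_u, e_f, overrepresented_only)
    res <- data.frame(protein = candidates, n_f_u = n_f_u, n_u = n_u,
                      e_f = e_f, score = score, stringsAsFactors = FALSE)
    res <- res[order(-res$score, res$protein), , drop = FALSE]
    res$rank <- seq_len(nrow(res))
    rownames(res) <- NULL
  }
  structure(res, class = c("hishigaki_scores", "data.frame"),
            tot_f = tot_f, tot_n = tot_n, radius = radius)
}

#' Select the top-k ranked candidates
#'
#' Zero-score candidates are never selected even when fewer than `k`
#' positive scores exist.
#'
#' @param results Output of [score_all_candidates()].
#' @param k Number of candidates requested (>= 1).
#' @return Character vector of at most `k` candidate IDs, in rank order.
#' @export
select_top_k <- function(results, k) {
  assert_that(is.numeric(k) && length(k) == 1L && k >= 1, "`k` must be >= 1")
  pos <- results[results$score > 0, , drop = FALSE]
  if (nrow(pos) == 0L) {
    warning("no candidate has a positive score; empty selection", call. = FALSE)
    return(character())
  }
  if (nrow(pos) < k) {
    warning(sprintf("only %d candidate(s) with positive score; k = %d truncated",
                    nrow(pos), k), call. = FALSE)
  }
  utils::head(pos$protein, k)
}

#' Extract the phenotype module
#'
#' Induced subgraph on the in-network seeds plus the selected candidates,
#' with a role label for every member. Members without any within-module
#' edge are retained at degree 0.
#'
#' @param network An `igraph` PPI network.
#' @param seeds A `seed_set` or character vector of seed IDs.
#' @param candidates Character vector of candidate IDs (disjoint from the
#'   seeds).
#' @return A `ppi_module`: list with `graph` (induced `igraph` subgraph),
#'   `roles` (named character vector, `"seed"` or `"predicted"`) and `k`
#'   (number of candidates requested).
#' @export
extract_module <- function(network, seeds, candidates) {
  ids <- if (inherits(seeds, "seed_set")) seeds$ids else unique(as.character(seeds))
  candidates <- unique(as.character(candidates))
  assert_that(length(intersect(ids, candidates)) == 0L,
              "candidates must be disjoint from the seed set")
  nodes <- igraph::V(network)$name
  seeds_in <- intersect(ids, nodes)
  members <- union(seeds_in, intersect(candidates, nodes))
  g <- igraph::induced_subgraph(network, members)
  roles <- stats::setNames(
    ifelse(igraph::V(g)$name %in% seeds_in, "seed", "predicted"),
    igraph::V(g)$name
  )
  structure(list(graph = g, roles = roles, k = length(candidates)),
            class = "ppi_module")
}

#' @export
print.ppi_module <- function(x, ...) {
  cat(sprintf("PPI module: %d proteins (%d seed, %d predicted), %d interactions\n",
              igraph::vcount(x$graph), sum(x$roles == "seed"),
              sum(x$roles == "predicted"), igraph::ecount(x$graph)))
  invisible(x)
}

#' Module node table
#'
#' @param module A `ppi_module`.
#' @return Data frame with `protein`, `role` and within-module `degree`.
#' @export
module_node_table <- function(module) {
  stopifnot(inherits(module, "ppi_module"))
  g <- module$graph
  data.frame(protein = igraph::V(g)$name,
             role = unname(module$roles[igraph::V(g)$name]),
             degree = unname(igraph::degree(g)),
             stringsAsFactors = FALSE)
}

#' Seed retention across candidate-list sizes
#'
#' For each requested `k`, extracts the module for the top-k candidates and
#' counts how many of the *listed* seeds have at least one interaction
#' inside it ("present") versus the remainder ("absent": seeds missing from
#' the network or isolated in the module). Used to choose the candidate
#' cutoff that maximizes seed capture.
#'
#' @param network An `igraph` PPI network.
#' @param seeds A `seed_set` (its full `ids` list is the retention
#'   denominator).
#' @param results Output of [score_all_candidates()].
#' @param k_values Non-empty vector of candidate-list sizes (all >= 1).
#' @return Data frame with columns `k`, `present`, `absent`.
#' @export
seed_retention_report <- function(network, seeds, results, k_values) {
  assert_that(length(k_values) > 0L, "`k_values` must be non-empty")
  assert_that(all(k_values >= 1), "all `k_values` must be >= 1")
  ids <- if (inherits(seeds, "seed_set")) seeds$ids else unique(as.character(seeds))
  rows <- lapply(k_values, function(k) {
    cand <- suppressWarnings(select_top_k(results, k))
    mod <- extract_module(network, ids, cand)
    deg <- igraph::degree(mod$graph)
    present <- sum(names(deg) %in% ids & deg >= 1)
    data.frame(k = as.integer(k), present = present,
               absent = length(ids) - present)
  })
  do.call(rbind, rows)
}

#' Write a ranked candidate table as TSV
#'
#' @param results Output of [score_all_candidates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prediction_table <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
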