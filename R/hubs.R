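# Hub identification within an extracted phenotype module. Degrees are
# always module degrees (computed on the extracted subgraph, not the global
# network): hub status describes a protein's centrality *within* the
# phenotype neighborhood.

#' Intramodular hubs: top decile of module degree, ties included
#'
#' The cutoff is the degree of the `(floor(fraction * n) + 1)`-th node in
#' descending degree order -- the empirical `(1 - fraction)` quantile of the
#' module degree distribution -- and every node at or above the cutoff is a
#' hub, so ties at the boundary can push the list past `fraction * n`.
#'
#' @param module A `ppi_module`.
#' @param fraction Top fraction of the degree distribution to call hubs
#'   (default 0.10).
#' @return List (class `intramodular_hubs`) with `degree_cutoff` and
#'   `hubs`, a data frame (`protein`, `degree`, `role`) sorted by degree
#'   descending then ID.
#' @export
intramodular_hubs <- function(module, fraction = 0.10) {
  stopifnot(inherits(module, "ppi_module"))
  assert_that(fraction > 0 && fraction <= 1, "`fraction` must be in (0, 1]")
  g <- module$graph
  n <- igraph::vcount(g)
  assert_that(n > 0L, "module is empty")
  deg <- igraph::degree(g)
  m <- min(n, floor(fraction * n) + 1L)
  cutoff <- sort(deg, decreasing = TRUE)[m]
  hub_names <- names(deg)[deg >= cutoff]
  if (length(hub_names) == n && n > m) {
    warning("every module node ties at the hub cutoff; hub list saturated",
            call. = FALSE)
  }
  hubs <- data.frame(protein = hub_names,
                     degree = unname(deg[hub_names]),
                     role = unname(module$roles[hub_names]),
                     stringsAsFactors = FALSE)
  hubs <- hubs[order(-hubs$degree, hubs$protein), , drop = FALSE]
  rownames(hubs) <- NULL
  structure(list(degree_cutoff = unname(cutoff), hubs = hubs),
            class = "intramodular_hubs")
}

#' @export
print.intramodular_hubs <- function(x, ...) {
  cat(sprintf("Intramodular hubs: %d protein(s) at degree cutoff %d\n",
              nrow(x$hubs), x$degree_cutoff))
  invisible(x)
}

#' Intermodular hubs: proteins whose neighbors span several sub-modules
#'
#' For each module node the span is the number of distinct sub-module ids
#' among its neighbors (a node's own sub-module counts when it has a
#' same-sub-module neighbor; unassigned neighbors contribute nothing).
#' Nodes with span at least `min_span` are intermodular hubs,
#' interpreted as linking distinct biological pathways.
#'
#' @param module A `ppi_module`.
#' @param assignment Named integer vector from [assign_submodules()].
#' @param min_span Minimum number of spanned sub-modules (default 3).
#' @return Data frame (`protein`, `degree`, `role`, `spanned`, a
#'   comma-separated id list, and `span`) sorted by degree descending then
#'   ID.
#' @export
intermodular_hubs <- function(module, assignment, min_span = 3L) {
  stopifnot(inherits(module, "ppi_module"))
  assert_that(min_span >= 1, "`min_span` must be >= 1")
  g <- module$graph
  nodes <- igraph::V(g)$name
  assert_that(all(nodes %in% names(assignment)),
              "assignment must cover every module node")
  rows <- lapply(nodes, function(v) {
    nb <- igraph::neighbors(g, v)$name
    ids <- unique(assignment[nb])
    ids <- sort(ids[!is.na(ids)])
    data.frame(protein = v,
               degree = length(nb),
               role = unname(module$roles[v]),
               spanned = paste(ids, collapse = ","),
               span = length(ids),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$span >= min_span, , drop = FALSE]
  out <- out[order(-out$degree, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full hub report for a module
#'
#' @param module A `ppi_module`.
#' @param assignment Sub-module assignment from [assign_submodules()].
#' @param fraction Intramodular hub fraction (default 0.10).
#' @param min_span Intermodular hub span threshold (default 3).
#' @return A `hub_report` list with `degree_cutoff`, `intramodular` and
#'   `intermodular` tables.
#' @export
hub_report <- function(module, assignment, fraction = 0.10, min_span = 3L) {
  intra <- intramodular_hubs(module, fraction)
  inter <- intermodular_hubs(module, assignment, min_span)
  structure(list(degree_cutoff = intra$degree_cutoff,
                 intramodular = intra$hubs,
                 intermodular = inter),
            class = "hub_report")
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("Hub report: %d intramodular (degree >= %d), %d intermodular\n",
              nrow(x$intramodular), x$degree_cutoff, nrow(x$intermodular)))
  invisible(x)
}

#' Write a hub report (TSVs plus a JSON summary)
#'
#' @param report A `hub_report`.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_hub_report <- function(report, dir) {
  stopifnot(inherits(report, "hub_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "intramodular_hubs.tsv")
  p2 <- file.path(dir, "intermodular_hubs.tsv")
  p3 <- file.path(dir, "hub_summary.json")
  utils::write.table(report$intramodular, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$intermodular, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(degree_cutoff = report$degree_cutoff,
         n_intramodular = nrow(report$intramodular),
         n_intermodular = nrow(report$intermodular),
         intermodular = report$intermodular$protein),
    p3, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}
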