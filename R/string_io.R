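# Reading, filtering and deduplicating STRING-style scored edge lists,
# plus seed-list loading and tabular writers.

new_edge_list <- function(df, deduplicated = FALSE, provenance = list()) {
  stopifnot(is.data.frame(df))
  rownames(df) <- NULL
  structure(df,
            class = c("edge_list", "data.frame"),
            deduplicated = deduplicated,
            provenance = provenance)
}

#' Is an edge list deduplicated?
#'
#' @param edges An `edge_list`.
#' @return Logical flag set by [deduplicate()].
#' @export
is_deduplicated <- function(edges) {
  isTRUE(attr(edges, "deduplicated"))
}

#' Provenance log of an edge list
#'
#' Every parsing/filtering/deduplication step records counts here, so the
#' headline numbers of a preprocessing run (raw records, post-filter records,
#' post-dedup edges, self-loops dropped) can be reported for any input.
#'
#' @param edges An `edge_list`.
#' @return A named list of provenance fields.
#' @export
edge_provenance <- function(edges) {
  attr(edges, "provenance") %||% list()
}

#' Parse a STRING-style protein links file
#'
#' Reads a whitespace- or tab-delimited scored edge list with a header row
#' and at least three columns (`protein1`, `protein2`, `combined_score`).
#' Scores must be integers on the STRING 0--1000 confidence scale. The
#' result is *not* deduplicated: STRING distributes every interaction in
#' both orientations, and [deduplicate()] collapses them.
#'
#' @param path Path to the links file.
#' @param alias_table Optional identifier mapping applied to both endpoint
#'   columns: either a named character vector (`names` = source IDs) or a
#'   two-column data frame (source, preferred name). IDs without a mapping
#'   are kept verbatim and counted in the provenance log, so graph topology
#'   is never altered by an incomplete alias table.
#' @return An `edge_list` (a data frame with columns `protein_a`,
#'   `protein_b`, `combined_score` plus provenance attributes).
#' @export
parse_string_links <- function(path, alias_table = NULL) {
  assert_that(is.character(path) && length(path) == 1L, "`path` must be a single file path")
  assert_that(file.exists(path), sprintf("links file not found: %s", path))

  header <- readLines(path, n = 1L)
  assert_that(length(header) == 1L && nzchar(trimws(header)),
              sprintf("links file is empty: %s", path))
  header_fields <- strsplit(trimws(header), "[ \t]+")[[1]]
  assert_that(length(header_fields) >= 3L,
              sprintf("header row must have >= 3 columns, found %d in: %s",
                      length(header_fields), path))

  raw <- tryCatch(
    utils::read.table(path, header = FALSE, skip = 1L,
                      colClasses = "character", fill = TRUE,
                      comment.char = "", quote = "",
                      stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        stop(sprintf("no records after header in: %s", path), call. = FALSE)
      }
      stop(e)
    })
  assert_that(nrow(raw) > 0L, sprintf("no records after header in: %s", path))

  a <- raw[[1L]]
  b <- raw[[2L]]
  s <- raw[[3L]]
  # line numbers in the file: header is line 1
  line_no <- seq_len(nrow(raw)) + 1L

  malformed <- is.na(a) | is.na(b) | is.na(s) | a == "" | b == "" | s == ""
  if (any(malformed)) {
    stop(sprintf("malformed record(s) with fewer than 3 fields at line(s): %s",
                 paste(line_no[malformed], collapse = ", ")), call. = FALSE)
  }
  bad_int <- !grepl("^[0-9]+$", s)
  if (any(bad_int)) {
    stop(sprintf("non-integer combined_score at line(s): %s",
                 paste(line_no[bad_int], collapse = ", ")), call. = FALSE)
  }
  score <- as.integer(s)
  out_of_range <- score < 0L | score > 1000L
  if (any(out_of_range)) {
    stop(sprintf("combined_score outside [0, 1000] at line(s): %s",
                 paste(line_no[out_of_range], collapse = ", ")), call. = FALSE)
  }

  alias_unmapped <- 0L
  alias_mapped <- 0L
  if (!is.null(alias_table)) {
    map <- as_alias_map(alias_table)
    for (col in c("a", "b")) {
      v <- get(col)
      hit <- v %in% names(map)
      alias_mapped <- alias_mapped + sum(hit)
      alias_unmapped <- alias_unmapped + sum(!hit)
      v[hit] <- unname(map[v[hit]])
      assign(col, v)
    }
  }

  prov <- list(
    source = path,
    raw_records = nrow(raw),
    alias_applied = !is.null(alias_table),
    alias_mapped_endpoints = alias_mapped,
    alias_unmapped_endpoints = if (is.null(alias_table)) NA_integer_ else alias_unmapped
  )
  new_edge_list(
    data.frame(protein_a = a, protein_b = b, combined_score = score,
               stringsAsFactors = FALSE),
    deduplicated = FALSE, provenance = prov
  )
}

as_alias_map <- function(alias_table) {
  if (is.data.frame(alias_table)) {
    assert_that(ncol(alias_table) >= 2L, "alias table needs >= 2 columns (id, preferred name)")
    map <- as.character(alias_table[[2L]])
    names(map) <- as.character(alias_table[[1L]])
  } else if (is.character(alias_table) && !is.null(names(alias_table))) {
    map <- alias_table
  } else {
    stop("alias_table must be a named character vector or a two-column data frame",
         call. = FALSE)
  }
  map[!duplicated(names(map))]
}

#' Filter an edge list by combined score
#'
#' @param edges An `edge_list`.
#' @param cutoff Score threshold on the STRING 0--1000 scale. 400 is the
#'   conventional medium-confidence mark.
#' @param strict If `TRUE` (default) keep edges with score strictly greater
#'   than `cutoff`; if `FALSE` keep `>= cutoff` (the STRING convention that
#'   treats 400 itself as medium confidence).
#' @return The filtered `edge_list`; before/after counts are appended to the
#'   provenance log.
#' @export
filter_by_score <- function(edges, cutoff = 400L, strict = TRUE) {
  stopifnot(inherits(edges, "edge_list"))
  assert_that(is.numeric(cutoff) && length(cutoff) == 1L &&
                cutoff >= 0 && cutoff <= 1000,
              "`cutoff` must be a single value in [0, 1000]")
  keep <- if (strict) edges$combined_score > cutoff else edges$combined_score >= cutoff
  prov <- edge_provenance(edges)
  prov$score_filter <- list(cutoff = as.integer(cutoff),
                            comparator = if (strict) ">" else ">=",
                            records_before = nrow(edges),
                            records_after = sum(keep))
  new_edge_list(as.data.frame(edges)[keep, , drop = FALSE],
                deduplicated = is_deduplicated(edges), provenance = prov)
}

#' Collapse duplicate records and drop self-loops
#'
#' Each unordered protein pair is kept exactly once, stored in canonical
#' (lexicographically sorted) endpoint order. Records of the same pair with
#' unequal scores (possible when sources are concatenated) keep the maximum
#' score. Self-loops are removed and counted in the provenance log.
#'
#' @param edges An `edge_list`.
#' @return A deduplicated `edge_list`, rows sorted by endpoint pair.
#' @export
deduplicate <- function(edges) {
  stopifnot(inherits(edges, "edge_list"))
  df <- as.data.frame(edges)
  prov <- edge_provenance(edges)

  self <- df$protein_a == df$protein_b
  n_self <- sum(self)
  df <- df[!self, , drop = FALSE]

  if (nrow(df) > 0L) {
    lo <- pmin(df$protein_a, df$protein_b)
    hi <- pmax(df$protein_a, df$protein_b)
    key <- paste(lo, hi, sep = "\r")
    score <- vapply(split(df$combined_score, key), max, integer(1L))
    uk <- names(score)
    parts <- strsplit(uk, "\r", fixed = TRUE)
    out <- data.frame(protein_a = vapply(parts, `[[`, "", 1L),
                      protein_b = vapply(parts, `[[`, "", 2L),
                      combined_score = unname(score),
                      stringsAsFactors = FALSE)
    out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
  } else {
    out <- df
  }

  prov$deduplication <- list(records_before = nrow(edges),
                             self_loops_removed = n_self,
                             duplicates_removed = (nrow(edges) - n_self) - nrow(out),
                             edges_after = nrow(out))
  new_edge_list(out, deduplicated = TRUE, provenance = prov)
}

#' Load a seed-protein list
#'
#' One protein ID per line; blank lines and lines starting with `#` are
#' ignored; duplicated IDs are collapsed with a warning.
#'
#' @param path Path to the seed list.
#' @param network_nodes Character vector of node IDs of the preprocessed
#'   network, used to compute which seeds are missing from it.
#' @return A `seed_set`: list with `ids` (all listed seeds) and
#'   `missing_from_network` (subset absent from `network_nodes`).
#' @export
load_seed_list <- function(path, network_nodes = character()) {
  assert_that(file.exists(path), sprintf("seed file not found: %s", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  assert_that(length(lines) > 0L, sprintf("seed file has no IDs: %s", path))
  if (anyDuplicated(lines)) {
    warning(sprintf("%d duplicated seed ID(s) collapsed", sum(duplicated(lines))),
            call. = FALSE)
    lines <- unique(lines)
  }
  seed_set(lines, network_nodes)
}

#' Construct a seed set from IDs already in memory
#'
#' @param ids Character vector of seed protein IDs (non-empty).
#' @param network_nodes Node IDs of the preprocessed network.
#' @return A `seed_set` object.
#' @export
seed_set <- function(ids, network_nodes = character()) {
  ids <- unique(as.character(ids))
  assert_that(length(ids) > 0L, "seed set must be non-empty")
  structure(list(ids = ids,
                 missing_from_network = setdiff(ids, network_nodes)),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("Seed set: %d protein(s), %d missing from network\n",
              length(x$ids), length(x$missing_from_network)))
  invisible(x)
}

#' @export
as.data.frame.edge_list <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(protein_a = x$protein_a, protein_b = x$protein_b,
             combined_score = x$combined_score, stringsAsFactors = FALSE)
}

#' @export
print.edge_list <- function(x, ...) {
  cat(sprintf("Scored edge list: %d record(s)%s\n", nrow(x),
              if (is_deduplicated(x)) " (deduplicated)" else ""))
  NextMethod()
}

#' Write an edge list as TSV
#'
#' Columns `protein_a`, `protein_b`, `combined_score`, with a header row, so
#' the file round-trips through [parse_string_links()].
#'
#' @param edges An `edge_list`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  stopifnot(inherits(edges, "edge_list"))
  utils::write.table(as.data.frame(edges), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an edge list in SIF format
#'
#' Simple interaction format (`A pp B`), importable by Cytoscape.
#'
#' @param edges An `edge_list` or a two-column data frame of endpoints.
#' @param path Output path.
#' @param interaction Interaction type label (default `"pp"`).
#' @return `path`, invisibly.
#' @export
write_sif <- function(edges, path, interaction = "pp") {
  df <- as.data.frame(edges)
  writeLines(paste(df[[1L]], interaction, df[[2L]]), path)
  invisible(path)
}

#' Write the provenance log as JSON
#'
#' @param edges An `edge_list`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(edges, path) {
  jsonlite::write_json(edge_provenance(edges), path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
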