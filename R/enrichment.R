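# Over-representation analysis: hypergeometric upper-tail test of each
# annotation term in a query set against a background, with
# Benjamini-Hochberg adjusted p-values reported alongside the raw ones.
# Annotations are flat sets (no ontology-graph propagation).

#' Build an annotation map
#'
#' @param df Data frame with at least two columns: term id and protein id
#'   (one row per annotation).
#' @param term_names Optional named character vector mapping term ids to
#'   human-readable names.
#' @return An `annotation_map`: named list of protein-ID vectors with a
#'   `term_names` attribute.
#' @export
annotation_map <- function(df, term_names = NULL) {
  stopifnot(is.data.frame(df), ncol(df) >= 2L)
  terms <- split(as.character(df[[2L]]), as.character(df[[1L]]))
  terms <- lapply(terms, unique)
  assert_that(all(lengths(terms) > 0L), "annotated sets must be non-empty")
  nm <- stats::setNames(rep(NA_character_, length(terms)), names(terms))
  if (!is.null(term_names)) {
    hit <- intersect(names(nm), names(term_names))
    nm[hit] <- term_names[hit]
  }
  structure(terms, class = "annotation_map", term_names = nm)
}

#' Read a two-column term/protein annotation TSV
#'
#' Format: `term_id<TAB>protein_id`, one annotation per line, no header
#' required (a header line is detected and skipped when its first field is
#' `term_id`).
#'
#' @param path Path to the TSV.
#' @param term_names Optional term-name mapping, see [annotation_map()].
#' @return An `annotation_map`.
#' @export
read_annotation_table <- function(path, term_names = NULL) {
  assert_that(file.exists(path), sprintf("annotation file not found: %s", path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) > 0L && identical(tolower(df[1L, 1L]), "term_id")) {
    df <- df[-1L, , drop = FALSE]
  }
  annotation_map(df, term_names)
}

#' Read annotations in GMT format
#'
#' One term per line: `term_id<TAB>description<TAB>protein1<TAB>protein2...`
#'
#' @param path Path to the GMT file.
#' @return An `annotation_map` (descriptions become term names).
#' @export
read_gmt <- function(path) {
  assert_that(file.exists(path), sprintf("GMT file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  assert_that(length(lines) > 0L, sprintf("GMT file is empty: %s", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  assert_that(all(lengths(parts) >= 3L),
              "each GMT line needs term, description and >= 1 member")
  ids <- vapply(parts, `[[`, "", 1L)
  descs <- stats::setNames(vapply(parts, `[[`, "", 2L), ids)
  df <- do.call(rbind, lapply(parts, function(p) {
    data.frame(term_id = p[[1L]], protein = p[-(1:2)], stringsAsFactors = FALSE)
  }))
  annotation_map(df, descs)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`:
#' the chance of drawing at least `k` annotated proteins in a query of size
#' `n` from a background of `N` proteins of which `K` carry the term.
#'
#' @param k Observed annotated proteins in the query.
#' @param K Annotated proteins in the background.
#' @param n Query size.
#' @param N Background size.
#' @param ease If `TRUE`, compute the EASE-style conservative variant that
#'   discounts one query hit (`P(X >= k - 1)` is replaced by the tail at
#'   `k - 1` successes; `k = 0` still yields 1).
#' @return The p-value in `[0, 1]`.
#' @export
hypergeometric_pvalue <- function(k, K, n, N, ease = FALSE) {
  assert_that(all(c(k, K, n, N) >= 0), "counts must be non-negative")
  assert_that(K <= N && n <= N, "K and n must not exceed N")
  assert_that(k <= min(K, n), "k must not exceed min(K, n)")
  if (ease) k <- max(k - 1L, 0L)
  if (k == 0L) return(1)
  stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, order-preserving with the input.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  assert_that(all(p_values >= 0 & p_values <= 1, na.rm = FALSE),
              "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of a query set
#'
#' One test per annotation term with at least one query hit. The
#' significance flag uses the raw p-value against `alpha`; BH-adjusted
#' values are always reported so stricter control can be applied.
#'
#' @param query Non-empty set of protein IDs, a subset of `background`.
#' @param annotations An `annotation_map`.
#' @param background Background protein set (>= 2 proteins); by default the
#'   caller should pass all proteins of the preprocessed network.
#' @param alpha Raw-p significance level (default 0.05).
#' @param ease Use the EASE variant of the test (default `FALSE`).
#' @return Data frame sorted by p-value: `term_id`, `term_name`, `k`, `K`,
#'   `n`, `N`, `p_value`, `adjusted_p`, `significant`.
#' @export
enrich <- function(query, annotations, background, alpha = 0.05, ease = FALSE) {
  stopifnot(inherits(annotations, "annotation_map"))
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  assert_that(length(query) > 0L, "query set is empty")
  assert_that(length(background) >= 2L, "background must have >= 2 proteins")
  assert_that(all(query %in% background), "query must be a subset of background")

  N <- length(background)
  n <- length(query)
  term_names <- attr(annotations, "term_names")
  rows <- lapply(names(annotations), function(tid) {
    ann <- intersect(annotations[[tid]], background)
    K <- length(ann)
    k <- length(intersect(ann, query))
    if (k == 0L) return(NULL)
    data.frame(term_id = tid,
               term_name = unname(term_names[tid]),
               k = k, K = K, n = n, N = N,
               p_value = hypergeometric_pvalue(k, K, n, N, ease = ease),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) {
    warning("no annotation term overlaps the query; empty result", call. = FALSE)
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(),
                      adjusted_p = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$adjusted_p <- bh_adjust(out$p_value)
  out$significant <- out$p_value < alpha
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
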