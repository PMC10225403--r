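# Shared fixtures and independent oracles. The oracles deliberately avoid
# the package's own code paths: they work from dense adjacency matrices and
# exhaustive enumeration so they can certify the igraph-based
# implementations.

# build an edge_list from triples without touching the parser
make_edge_list <- function(a, b, s, dedup = FALSE) {
  f <- tempfile(fileext = ".txt")
  writeLines(c("protein1 protein2 combined_score", paste(a, b, s)), f)
  el <- parse_string_links(f)
  if (dedup) el <- deduplicate(el)
  el
}

# named Erdos-Renyi graph for property tests
random_named_gnp <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("N%03d", seq_len(n))
  g
}

# --- independent Hishigaki oracle (adjacency-matrix recount) -------------
oracle_hishigaki <- function(network, seed_ids, overrepresented_only = TRUE) {
  A <- as.matrix(igraph::as_adjacency_matrix(network))
  nodes <- rownames(A)
  seeds_in <- intersect(seed_ids, nodes)
  tot_f <- length(seeds_in)
  tot_n <- length(nodes)
  cand <- setdiff(nodes, seeds_in)
  res <- lapply(cand, function(u) {
    nbr <- nodes[A[u, ] > 0]
    n_u <- length(nbr)
    n_f_u <- sum(nbr %in% seeds_in)
    e_f <- tot_f * n_u / tot_n
    score <- if (e_f == 0) 0 else (n_f_u - e_f)^2 / e_f
    if (overrepresented_only && n_f_u <= e_f) score <- 0
    data.frame(protein = u, n_f_u = n_f_u, n_u = n_u, e_f = e_f,
               score = score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$protein), , drop = FALSE]
}

# --- independent k-core / MCODE vertex weight oracle ---------------------
# repeated pruning on a dense adjacency matrix
oracle_kcore_prune <- function(A, k) {
  repeat {
    deg <- rowSums(A)
    drop <- which(deg < k)
    if (length(drop) == 0L || nrow(A) == 0L) break
    A <- A[-drop, -drop, drop = FALSE]
  }
  A
}

oracle_vertex_weight <- function(network, v, degree_cutoff = 2) {
  A <- as.matrix(igraph::as_adjacency_matrix(network))
  nodes <- rownames(A)
  if (sum(A[v, ]) < degree_cutoff) return(0)
  nb <- c(v, nodes[A[v, ] > 0])
  B <- A[nb, nb, drop = FALSE]
  k_max <- 0
  best <- NULL
  for (k in seq_len(nrow(B))) {
    pruned <- oracle_kcore_prune(B, k)
    if (nrow(pruned) == 0L) break
    k_max <- k
    best <- pruned
  }
  if (k_max == 0) return(0)
  n <- nrow(best)
  e <- sum(best) / 2
  if (n < 2) return(0)
  k_max * (2 * e / (n * (n - 1)))
}

# --- exhaustive hypergeometric oracle ------------------------------------
oracle_hyper_upper <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2L, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# disjoint union of cliques with named vertices
clique_union <- function(sizes) {
  gs <- lapply(seq_along(sizes), function(i) {
    g <- igraph::make_full_graph(sizes[i])
    igraph::V(g)$name <- sprintf("C%d_%02d", i, seq_len(sizes[i]))
    g
  })
  Reduce(igraph::disjoint_union, gs)
}
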