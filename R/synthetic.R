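# Synthetic STRING-like network generator. Emulates the study inputs every
# pipeline stage needs: a sparse scored background (Erdos-Renyi), one or
# more planted dense communities, a combined-score distribution straddling
# the 400 confidence cutoff, symmetric duplicate records, and controlled
# seed dropout (seeds withheld from the raw file entirely, and seeds whose
# every record scores below the cutoff so preprocessing removes them).

#' Synthetic network configuration
#'
#' Defaults describe the package's reference study condition: a 600-protein
#' network with one planted 80-protein phenotype community (intra-community
#' edge probability 0.25 versus background 0.01), 51 listed seed proteins
#' drawn from that community of which 3 never appear in the raw edge file
#' and 3 participate only in sub-cutoff records -- so preprocessing retains
#' 45 seeds. Community edges score uniformly in 401--1000 (always above the
#' 400 cutoff); background edges score uniformly in 100--800, so roughly
#' 43% of them fall below the cutoff and filtering has bite.
#'
#' @param n_nodes Total number of proteins.
#' @param background_edge_prob Erdos-Renyi background edge probability.
#' @param communities List of `list(size =, intra_edge_prob =)` planted
#'   communities, occupying consecutive node blocks from node 1.
#' @param phenotype_community Index of the community the seeds come from.
#' @param seed_count Number of listed seed proteins (ignored when
#'   `seed_label_fraction` is given).
#' @param seed_label_fraction Optional fraction of the phenotype community
#'   to declare as seeds (overrides `seed_count`).
#' @param seeds_missing_from_raw Seeds withheld from the edge file.
#' @param seeds_below_cutoff Seeds whose every record is rescored below 400.
#' @param background_score_range Integer interval for background scores.
#' @param community_score_range Integer interval for community scores.
#' @param noise_seeds Seeds additionally planted outside the phenotype
#'   community (default 0), to stress guilt-by-association recovery.
#' @param emit_symmetric_duplicates Write every record in both orientations
#'   (the STRING distribution convention).
#' @param rng_seed Integer seed making the output byte-identical across
#'   runs.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_nodes = 600L,
                         background_edge_prob = 0.01,
                         communities = list(list(size = 80L, intra_edge_prob = 0.25)),
                         phenotype_community = 1L,
                         seed_count = 51L,
                         seed_label_fraction = NULL,
                         seeds_missing_from_raw = 3L,
                         seeds_below_cutoff = 3L,
                         background_score_range = c(100L, 800L),
                         community_score_range = c(401L, 1000L),
                         noise_seeds = 0L,
                         emit_symmetric_duplicates = TRUE,
                         rng_seed = 7L) {
  sizes <- vapply(communities, function(cm) as.integer(cm$size), integer(1L))
  probs <- vapply(communities, function(cm) cm$intra_edge_prob, numeric(1L))
  assert_that(sum(sizes) <= n_nodes, "community sizes must sum to <= n_nodes")
  assert_that(all(probs >= 0 & probs <= 1) &&
                background_edge_prob >= 0 && background_edge_prob <= 1,
              "edge probabilities must lie in [0, 1]")
  assert_that(phenotype_community >= 1L && phenotype_community <= length(communities),
              "`phenotype_community` must index a community")
  if (!is.null(seed_label_fraction)) {
    assert_that(seed_label_fraction > 0 && seed_label_fraction <= 1,
                "`seed_label_fraction` must be in (0, 1]")
    seed_count <- round(seed_label_fraction * sizes[phenotype_community])
  }
  assert_that(seed_count >= 1L, "`seed_count` must be >= 1")
  assert_that(seed_count + noise_seeds <= sizes[phenotype_community] + (n_nodes - sum(sizes)),
              "seed_count inconsistent with community sizes")
  assert_that(seed_count <= sizes[phenotype_community],
              "phenotype-community seeds cannot exceed the community size")
  assert_that(seeds_missing_from_raw + seeds_below_cutoff <= seed_count,
              "dropout counts cannot exceed seed_count")
  for (r in list(background_score_range, community_score_range)) {
    assert_that(length(r) == 2L && r[1L] <= r[2L] && r[1L] >= 0 && r[2L] <= 1000,
                "score ranges must be intervals within [0, 1000]")
  }
  structure(list(n_nodes = as.integer(n_nodes),
                 background_edge_prob = background_edge_prob,
                 communities = lapply(seq_along(sizes), function(i)
                   list(size = sizes[i], intra_edge_prob = probs[i])),
                 phenotype_community = as.integer(phenotype_community),
                 seed_count = as.integer(seed_count),
                 seeds_missing_from_raw = as.integer(seeds_missing_from_raw),
                 seeds_below_cutoff = as.integer(seeds_below_cutoff),
                 background_score_range = as.integer(background_score_range),
                 community_score_range = as.integer(community_score_range),
                 noise_seeds = as.integer(noise_seeds),
                 emit_symmetric_duplicates = isTRUE(emit_symmetric_duplicates),
                 rng_seed = as.integer(rng_seed)),
            class = "synth_config")
}

uniform_int <- function(k, lo, hi) {
  if (k == 0L) return(integer())
  lo + as.integer(floor(stats::runif(k) * (hi - lo + 1L)))
}

#' Generate a synthetic STRING-like dataset
#'
#' Writes four plain-text files into `dir`: the raw scored links file (in
#' the STRING `protein1 protein2 combined_score` dialect, with symmetric
#' duplicates when configured), the seed list (all listed seeds, including
#' the deliberately withheld ones), a GMT annotation file with one term per
#' planted community, and a ground-truth TSV with each node's community,
#' seed flag and dropout status. Fully reproducible from `rng_seed`.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return List with `paths` (links, seeds, annotations, truth), the
#'   `truth` data frame, `seed_ids`, and the `config`.
#' @export
generate_synthetic <- function(config, dir = tempfile("synthnet")) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_rng_seed(config$rng_seed, {
    n <- config$n_nodes
    width <- max(4L, nchar(as.character(n)))
    ids <- sprintf(paste0("P%0", width, "d"), seq_len(n))

    sizes <- vapply(config$communities, `[[`, integer(1L), "size")
    ends <- cumsum(sizes)
    starts <- ends - sizes + 1L
    community_of <- integer(n)
    for (i in seq_along(sizes)) community_of[starts[i]:ends[i]] <- i

    # background edges over all pairs
    pairs <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
    keep_bg <- stats::runif(nrow(pairs)) < config$background_edge_prob
    bg <- pairs[keep_bg, , drop = FALSE]

    # planted intra-community edges
    cm_list <- lapply(seq_along(sizes), function(i) {
      member <- starts[i]:ends[i]
      cp <- t(utils::combn(member, 2L))
      cp[stats::runif(nrow(cp)) < config$communities[[i]]$intra_edge_prob, ,
         drop = FALSE]
    })
    cm <- do.call(rbind, cm_list)

    key <- function(m) (m[, 1L] - 1L) * n + m[, 2L]
    bg <- bg[!(key(bg) %in% key(cm)), , drop = FALSE]

    edges <- data.frame(
      i = c(bg[, 1L], cm[, 1L]),
      j = c(bg[, 2L], cm[, 2L]),
      combined_score = c(
        uniform_int(nrow(bg), config$background_score_range[1L],
                    config$background_score_range[2L]),
        uniform_int(nrow(cm), config$community_score_range[1L],
                    config$community_score_range[2L]))
    )
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]

    # seed sampling: phenotype-community seeds plus optional noise seeds
    pheno <- which(community_of == config$phenotype_community)
    seed_idx <- sort(sample(pheno, config$seed_count))
    if (config$noise_seeds > 0L) {
      outside <- setdiff(seq_len(n), pheno)
      seed_idx <- c(seed_idx, sort(sample(outside, config$noise_seeds)))
    }
    n_miss <- config$seeds_missing_from_raw
    n_below <- config$seeds_below_cutoff
    missing_idx <- seed_idx[seq_len(n_miss)]
    below_idx <- seed_idx[n_miss + seq_len(n_below)]

    # controlled dropout: withhold, then down-score
    touches <- function(idx) edges$i %in% idx | edges$j %in% idx
    edges <- edges[!touches(missing_idx), , drop = FALSE]
    hit_below <- touches(below_idx)
    edges$combined_score[hit_below] <-
      uniform_int(sum(hit_below), 100L, 399L)

    out <- data.frame(protein1 = ids[edges$i], protein2 = ids[edges$j],
                      combined_score = edges$combined_score,
                      stringsAsFactors = FALSE)
    if (config$emit_symmetric_duplicates) {
      out <- rbind(out, data.frame(protein1 = out$protein2,
                                   protein2 = out$protein1,
                                   combined_score = out$combined_score,
                                   stringsAsFactors = FALSE))
    }

    seed_status <- rep("not_seed", n)
    seed_status[seed_idx] <- "retained"
    seed_status[missing_idx] <- "missing_from_raw"
    seed_status[below_idx] <- "below_cutoff"
    truth <- data.frame(node = ids,
                        community = community_of,
                        is_seed = seq_len(n) %in% seed_idx,
                        seed_status = seed_status,
                        stringsAsFactors = FALSE)

    paths <- list(links = file.path(dir, "links.txt"),
                  seeds = file.path(dir, "seeds.txt"),
                  annotations = file.path(dir, "annotations.gmt"),
                  truth = file.path(dir, "truth.tsv"))
    utils::write.table(out, paths$links, sep = " ", quote = FALSE,
                       row.names = FALSE)
    writeLines(ids[seed_idx], paths$seeds)
    gmt <- vapply(seq_along(sizes), function(i) {
      paste(c(sprintf("planted_community_%d", i),
              "synthetic planted community",
              ids[starts[i]:ends[i]]), collapse = "\t")
    }, character(1L))
    writeLines(gmt, paths$annotations)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    list(paths = paths, truth = truth, seed_ids = ids[seed_idx],
         config = config)
  })
}

#' Precision and recall of candidates against the planted community
#'
#' The positive class is the set of *unlabeled* planted-community members
#' (planted nodes not declared as seeds): the proteins a guilt-by-
#' association method should recover.
#'
#' @param candidates Character vector of predicted candidate IDs.
#' @param truth Ground-truth data frame from [generate_synthetic()].
#' @param community Planted community index (default 1).
#' @return List with `precision`, `recall` and `undefined_precision` (TRUE
#'   with precision reported as 0 when `candidates` is empty).
#' @export
ground_truth_metrics <- function(candidates, truth, community = 1L) {
  stopifnot(is.data.frame(truth),
            all(c("node", "community", "is_seed") %in% names(truth)))
  candidates <- unique(as.character(candidates))
  assert_that(all(candidates %in% truth$node), "truth must cover all candidates")
  planted <- truth$node[truth$community == community & !truth$is_seed]
  tp <- length(intersect(candidates, planted))
  if (length(candidates) == 0L) {
    return(list(precision = 0, recall = 0, undefined_precision = TRUE))
  }
  list(precision = tp / length(candidates),
       recall = if (length(planted) == 0L) 0 else tp / length(planted),
       undefined_precision = FALSE)
}
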