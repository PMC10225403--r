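# Bundled example data: the 20 reported intramodular hub degrees and the
# four characterized sub-module rosters of a 120-protein rice (Oryza
# sativa) root-development PPI module, plus builders that realize them as
# concrete graphs. These make the hub-calling rules demonstrable and
# testable on real published values without any network download. The
# graphs produced are synthetic realizations: only the printed degrees,
# rosters and the two intermodular neighbor lists are data; the remaining
# wiring is constructed deterministically.

#' Reported intramodular hub degrees of the rice root-development module
#'
#' The 20 proteins at the top decile of the 120-protein module's degree
#' distribution, with their module degrees and seed/predicted status.
#'
#' @return Data frame with `protein`, `degree`, `role`.
#' @export
example_hub_degrees <- function() {
  data.frame(
    protein = c("PIN2", "RHD3", "Osj_34384", "Os12T0604600-01", "LAX1",
                "GNP4", "Os04T0672900-01", "Osj_07614", "Osj_019622",
                "ARL1", "PIN1", "PIN3A", "IAA30", "Osj_14626", "FH1",
                "IAA13", "CKX4", "RR2", "RR1", "OSEIL1"),
    degree = c(22L, 19L, 17L, 17L, 13L, 12L, 11L, 11L, 10L, 10L, 10L, 9L,
               8L, 8L, 8L, 8L, 8L, 8L, 8L, 8L),
    role = c("seed", "seed", "seed", "seed", "predicted", "predicted",
             "predicted", "predicted", "predicted", "seed", "seed", "seed",
             "predicted", "predicted", "seed", "seed", "seed", "seed",
             "seed", "seed"),
    stringsAsFactors = FALSE
  )
}

#' Example 120-node module realizing the reported hub degrees
#'
#' Builds a deterministic 120-node module in which the 20 proteins of
#' [example_hub_degrees()] have exactly their reported degrees and the
#' remaining 100 filler nodes all have degree at most 3. Hub stubs are
#' wired round-robin to the fillers (a bipartite construction), so the
#' degree sequence is realized without parallel edges.
#'
#' @return A `ppi_module` (fillers carry role `"predicted"`).
#' @export
example_hub_module <- function() {
  hubs <- example_hub_degrees()
  fillers <- sprintf("F%03d", seq_len(100L))
  from <- character()
  to <- character()
  ptr <- 0L
  for (i in seq_len(nrow(hubs))) {
    d <- hubs$degree[i]
    sel <- ((ptr + seq_len(d) - 1L) %% length(fillers)) + 1L
    from <- c(from, rep(hubs$protein[i], d))
    to <- c(to, fillers[sel])
    ptr <- (ptr + d) %% length(fillers)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = c(hubs$protein, fillers),
                          stringsAsFactors = FALSE))
  roles <- stats::setNames(c(hubs$role, rep("predicted", length(fillers))),
                           c(hubs$protein, fillers))
  structure(list(graph = g, roles = roles[igraph::V(g)$name], k = 75L),
            class = "ppi_module")
}

#' Reported sub-module rosters of the rice root-development module
#'
#' Membership and seed/predicted status of the four functionally
#' characterized sub-modules (ER tubular network organization, auxin
#' signaling, cytokinin signaling, cell wall organization).
#'
#' @return Data frame with `protein`, `submodule`, `role`.
#' @export
example_submodule_rosters <- function() {
  sub1 <- c("RHD3", "Osj_34384", "Os12t0604600-01", "Os04t0672900-01",
            "Osj_07614", "Os08t0467500-02", "Os09t0450600-00", "Osj_24793",
            "Os01s0728150-00", "Os11t0498600-01", "P0425F05.2",
            "Os05t0146900-00", "Osj_09048", "Osj_32478", "Os07t0632600-01",
            "Os05t0145700-01", "Os05t0146100-01", "Os01t0844300-01",
            "Os01t0728200-01")
  sub1_seed <- c("RHD3", "Osj_34384", "Os12t0604600-01")
  sub2 <- c("ARL1", "PIN1", "PIN2", "PIN3A", "IAA13", "EL5.2", "EL5.1",
            "ARF25", "ARF12", "Osj_28507", "CCC1", "IAA14", "GLR3.1",
            "VLN2", "Osj_019622", "IAA30", "GNP4", "LAX1", "Osj_14626",
            "HOX10", "HOX9", "ARF19", "Os02t0190300-01", "Os02t0235900-01",
            "Os03t0253200-01", "Os06t0610100-00", "Os08t0423600-00",
            "Os08t0424100-00", "Os08t0564300-04", "Os11t0515500-01",
            "Osj_20964", "Osj_30022", "P0025H07.5", "PDR16")
  sub2_seed <- c("ARL1", "PIN1", "PIN2", "PIN3A", "IAA13", "EL5.2", "EL5.1",
                 "ARF25", "ARF12", "Osj_28507", "CCC1", "IAA14", "GLR3.1",
                 "VLN2")
  sub3 <- c("RR1", "RR2", "CKX4", "RR3", "RR6", "CKI1", "WOX11", "CR4",
            "HK4", "HK6", "ORR5", "Os11t0143300-02", "Os04t0445300-01",
            "Os07t0162600-02")
  sub3_seed <- c("RR1", "RR2", "CKX4", "RR3", "RR6", "CKI1", "WOX11")
  sub4 <- c("FH1", "DRO1", "GLU3", "GLU5", "ORC3", "EXPA8", "EXPA17", "C68",
            "EXPA31", "Os03t0303100-01", "Os04t0101800-01",
            "Os06t0697000-02", "Os11t0439600-01", "Os11t0672900-01",
            "Osj_06916", "Osj_22409", "PT2", "PT3")
  sub4_seed <- c("FH1", "DRO1", "GLU3", "GLU5", "ORC3", "EXPA8", "EXPA17")
  members <- list(sub1, sub2, sub3, sub4)
  seeds <- c(sub1_seed, sub2_seed, sub3_seed, sub4_seed)
  do.call(rbind, lapply(seq_along(members), function(i) {
    data.frame(protein = members[[i]], submodule = i,
               role = ifelse(members[[i]] %in% seeds, "seed", "predicted"),
               stringsAsFactors = FALSE)
  }))
}

#' Example intermodular-hub fixture
#'
#' Builds a deterministic module over the four reported sub-module rosters
#' in which DRO1 and FH1 carry exactly their reported neighbor lists
#' (spanning sub-modules 2/3/4 and 1/3/4 respectively) while every other
#' protein is wired along a path inside its own sub-module. Under the
#' span-at-least-3 rule, DRO1 and FH1 are the only intermodular hubs.
#'
#' @return List with `module` (a `ppi_module`) and `assignment` (named
#'   integer vector of sub-module ids).
#' @export
example_intermodular_fixture <- function() {
  rosters <- example_submodule_rosters()
  special <- c("DRO1", "FH1")
  from <- character()
  to <- character()
  for (i in unique(rosters$submodule)) {
    path_nodes <- rosters$protein[rosters$submodule == i]
    path_nodes <- setdiff(path_nodes, special)
    if (length(path_nodes) > 1L) {
      from <- c(from, path_nodes[-length(path_nodes)])
      to <- c(to, path_nodes[-1L])
    }
  }
  dro1_nb <- c("C68", "Os04t0101800-01", "ARL1", "WOX11")
  fh1_nb <- c("PT3", "PT2", "EXPA8", "EXPA17", "Osj_22409",
              "Os11t0439600-01", "RHD3", "WOX11")
  from <- c(from, rep("DRO1", length(dro1_nb)), rep("FH1", length(fh1_nb)))
  to <- c(to, dro1_nb, fh1_nb)
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = rosters$protein, stringsAsFactors = FALSE))
  roles <- stats::setNames(rosters$role, rosters$protein)
  module <- structure(list(graph = g, roles = roles[igraph::V(g)$name],
                           k = 75L),
                      class = "ppi_module")
  assignment <- stats::setNames(as.integer(rosters$submodule),
                                rosters$protein)
  list(module = module, assignment = assignment[igraph::V(g)$name])
}
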