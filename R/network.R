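# Cell subpopulation correlation networks and Cytoscape-style topology.
#
# Nodes are cell populations; an undirected edge joins two populations whose
# abundance vectors across the patients of one (group, region) stratum have
# Pearson correlation strictly above the threshold (signed, default 0.5).
# Topology metrics follow the Cytoscape NetworkAnalyzer conventions: nodes
# are counted only if they carry at least one edge (matching edge-list
# import), centralization is Freeman's degree centralization, and
# heterogeneity is the coefficient of variation of the degree distribution.

#' Build a cell-population correlation network
#'
#' @param abundance `abundance_profile` (or data.frame with one score column
#'   per cell type) restricted to the patients of one group/region stratum.
#' @param r_threshold Signed Pearson threshold; edge iff `r > r_threshold`
#'   (strictly). Default 0.5.
#' @param group,region Optional provenance tags stored on the network.
#' @return List of class `cell_network`: `nodes` (all cell types), `edges`
#'   (data.frame source, target, weight), `r_threshold`, `group`, `region`.
#' @export
build_network <- function(abundance, r_threshold = 0.5,
                          group = NA_character_, region = NA_character_) {
  m <- abundance_matrix(abundance)
  if (nrow(m) < 3L)
    stopf("need at least 3 patients to estimate correlations (got %d)", nrow(m))
  if (ncol(m) < 2L) stopf("need at least 2 cell types")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    warnf("constant-variance cell type(s) produce no edges: %s",
          paste(colnames(m)[sds == 0], collapse = ", "))
  ok <- sds > 0
  r <- suppressWarnings(stats::cor(m))
  r[!ok, ] <- NA; r[, !ok] <- NA
  idx <- which(upper.tri(r) & r > r_threshold, arr.ind = TRUE)
  edges <- data.frame(source = colnames(m)[idx[, 1]],
                      target = colnames(m)[idx[, 2]],
                      weight = r[idx], stringsAsFactors = FALSE)
  structure(list(nodes = colnames(m), edges = edges,
                 r_threshold = r_threshold, group = group, region = region),
            class = "cell_network")
}

#' @export
print.cell_network <- function(x, ...) {
  cat(sprintf("cell_network: %d candidate nodes, %d edges (r > %g)",
              length(x$nodes), nrow(x$edges), x$r_threshold))
  if (!is.na(x$group)) cat(sprintf(" [%s/%s]", x$group, x$region))
  cat("\n")
  invisible(x)
}

#' Write a network edge list as TSV
#' @param net `cell_network`.
#' @param path Output path (columns source, target, weight).
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Topology summary of a cell network
#'
#' Nine parameters: node number (nodes with degree >= 1), edge number,
#' density `2E / (n (n - 1))`, mean local clustering coefficient over nodes
#' with degree >= 2, diameter and characteristic path length over the
#' largest connected component, Freeman degree centralization
#' `n / (n - 2) * (max_deg / (n - 1) - density)`, degree heterogeneity
#' `sqrt(var(deg)) / mean(deg)` (population variance), and mean degree
#' `2E / n`. Degenerate networks (no edges, or n <= 2 for centralization)
#' return 0 for the affected metrics.
#'
#' @param net A `cell_network` (or any list with `nodes` and an `edges`
#'   data.frame).
#' @return Named list of the nine topology parameters.
#' @export
topology <- function(net) {
  e <- net$edges
  zero <- list(diameter = 0, n_edges = 0, n_nodes = 0, centralization = 0,
               heterogeneity = 0, density = 0, clustering = 0,
               char_path_length = 0, mean_degree = 0)
  if (is.null(e) || nrow(e) == 0L) return(zero)
  g <- igraph::graph_from_data_frame(e[, c("source", "target")],
                                     directed = FALSE)
  n <- igraph::vcount(g)          # nodes with >= 1 edge by construction
  m <- igraph::ecount(g)
  deg <- igraph::degree(g)
  density <- 2 * m / (n * (n - 1))
  mean_degree <- 2 * m / n
  loc <- igraph::transitivity(g, type = "local", isolates = "zero")
  eligible <- deg >= 2
  clustering <- if (any(eligible)) mean(loc[eligible]) else 0
  comp <- igraph::components(g)
  ## largest component; ties broken by edge count, then by the smallest
  ## node name, so disconnected networks are summarized deterministically
  stats_per_comp <- vapply(seq_len(comp$no), function(ci) {
    members <- which(comp$membership == ci)
    sg <- igraph::induced_subgraph(g, members)
    c(size = length(members), edges = igraph::ecount(sg))
  }, numeric(2))
  cand <- which(stats_per_comp["size", ] == max(stats_per_comp["size", ]))
  cand <- cand[stats_per_comp["edges", cand] ==
                 max(stats_per_comp["edges", cand])]
  if (length(cand) > 1) {
    first_name <- vapply(cand, function(ci)
      min(igraph::V(g)$name[comp$membership == ci]), character(1))
    cand <- cand[order(first_name)[1]]
  }
  sub <- igraph::induced_subgraph(g, which(comp$membership == cand[1]))
  dmat <- igraph::distances(sub)
  off <- dmat[upper.tri(dmat)]
  diameter <- if (length(off)) max(off) else 0
  cpl <- if (length(off)) mean(off) else 0
  centralization <- if (n > 2)
    (n / (n - 2)) * (max(deg) / (n - 1) - density) else 0
  heterogeneity <- sqrt(pop_var(deg)) / mean(deg)
  list(diameter = diameter, n_edges = m, n_nodes = n,
       centralization = centralization, heterogeneity = heterogeneity,
       density = density, clustering = clustering,
       char_path_length = cpl, mean_degree = mean_degree)
}

#' Topology comparison across (group, region) strata
#'
#' Builds one network per stratum of the abundance table and returns the
#' topology panel as one row per stratum.
#'
#' @param abundance `abundance_profile` with `group` and `region` columns.
#' @param r_threshold Pearson edge threshold.
#' @return data.frame: group, region, plus the nine topology columns.
#' @export
topology_by_stratum <- function(abundance, r_threshold = 0.5) {
  stopifnot(all(c("group", "region") %in% names(abundance)))
  strata <- unique(abundance[, c("group", "region")])
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    sub <- abundance[abundance$group == strata$group[i] &
                       abundance$region == strata$region[i], ]
    net <- build_network(sub, r_threshold,
                         group = strata$group[i], region = strata$region[i])
    cbind(strata[i, ], as.data.frame(topology(net)), row.names = NULL)
  })
  do.call(rbind, rows)
}
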