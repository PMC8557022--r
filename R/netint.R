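# Cross-source PPI integration: high-confidence edges joining nodes from
# different evidence sources (DEG / DMR / FEM), topology metrics, hub
# selection at the 95th percentile, and gene-set over-representation.

#' Normalise a PPI edge table
#'
#' Drops self-loops and deduplicates undirected pairs keeping the maximum
#' confidence.
#'
#' @param ppi Tibble `gene_a`, `gene_b`, `confidence`.
#' @return A normalised edge tibble.
#' @export
normalize_ppi <- function(ppi) {
  ppi |>
    filter(.data$gene_a != .data$gene_b) |>
    mutate(a = pmin(.data$gene_a, .data$gene_b),
           b = pmax(.data$gene_a, .data$gene_b)) |>
    group_by(.data$a, .data$b) |>
    summarise(confidence = max(.data$confidence), .groups = "drop") |>
    rename(gene_a = "a", gene_b = "b")
}

#' Build the cross-source integrated network
#'
#' Restricts the PPI graph to genes carrying at least one source label
#' (DEG, DMR, FEM) and edges with confidence at least `min_conf`, keeps an
#' edge only when its endpoints can be labelled with two *different*
#' sources, and returns the largest connected component (ties broken by
#' the lexicographically smallest node set).
#'
#' @param ppi PPI edge tibble (`gene_a`, `gene_b`, `confidence`).
#' @param deg_genes,dmr_genes,fem_genes Character vectors of source genes.
#' @param min_conf Minimum edge confidence (default 0.7).
#' @return An object of class `integrated_network` with elements `graph`
#'   (igraph), `nodes` (tibble `node`, `sources` list-column, `label`),
#'   `edges` (tibble).
#' @export
build_integrated_network <- function(ppi, deg_genes, dmr_genes, fem_genes,
                                     min_conf = 0.7) {
  sources <- list(DEG = unique(deg_genes), DMR = unique(dmr_genes),
                  FEM = unique(fem_genes))
  universe <- unique(unlist(sources))
  if (!length(universe)) abort("all source gene sets are empty",
                               class = "invalid_argument")
  src_of <- function(g) names(sources)[map_lgl(sources, function(s) g %in% s)]
  e <- normalize_ppi(ppi) |>
    filter(.data$confidence >= min_conf,
           .data$gene_a %in% universe, .data$gene_b %in% universe)
  src_a <- lapply(e$gene_a, src_of)
  src_b <- lapply(e$gene_b, src_of)
  cross <- mapply(function(a, b) length(unique(c(a, b))) >= 2, src_a, src_b)
  e <- e[as.logical(cross), , drop = FALSE]
  if (!nrow(e)) abort("no cross-source edges retained", class = "empty_network")
  g <- igraph::graph_from_data_frame(e, directed = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize
  biggest <- which(sizes == max(sizes))
  keys <- vapply(biggest, function(ci) {
    paste(sort(names(comp$membership)[comp$membership == ci]), collapse = ",")
  }, character(1))
  pick <- biggest[order(keys)[1]]
  keep <- names(comp$membership)[comp$membership == pick]
  g <- igraph::induced_subgraph(g, keep)
  nodes <- tibble(node = igraph::V(g)$name) |>
    mutate(sources = lapply(.data$node, src_of),
           label = map_chr(.data$sources, paste, collapse = "+"))
  edges <- igraph::as_data_frame(g, what = "edges") |>
    as_tibble() |>
    rename(gene_a = "from", gene_b = "to")
  structure(list(graph = g, nodes = nodes, edges = edges,
                 min_conf = min_conf),
            class = "integrated_network")
}

#' Seven node-topology metrics of the integrated network
#'
#' Degree (raw count), average neighbour degree, closeness
#' (`(n-1)/sum of distances`), eigenvector centrality (principal
#' eigenvector of the adjacency matrix, L2-normalised), Katz centrality
#' (`alpha = 0.9 / lambda_max`, `beta = 1`, L2-normalised), betweenness
#' (normalised by `2 / ((n-1)(n-2))`), and the local clustering
#' coefficient.
#'
#' @param net An `integrated_network` (or any connected igraph).
#' @return A tibble, one row per node, with the seven metric columns.
#' @export
compute_centralities <- function(net) {
  g <- if (inherits(net, "integrated_network")) net$graph else net
  n <- igraph::vcount(g)
  if (n < 2) abort("need at least 2 nodes", class = "invalid_input")
  if (!igraph::is_connected(g)) {
    abort("graph must be connected (pass the major component)",
          class = "invalid_input")
  }
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  ev <- eigen(A, symmetric = TRUE)
  lmax <- max(ev$values)
  evec <- abs(ev$vectors[, which.max(ev$values)])
  evec <- evec / sqrt(sum(evec^2))
  alpha <- 0.9 / lmax
  katz <- unname(solve(diag(n) - alpha * A, rep(1, n)))
  katz <- katz / sqrt(sum(katz^2))
  tibble(
    node = igraph::V(g)$name,
    degree = as.numeric(igraph::degree(g)),
    neighbor_degree = as.numeric(igraph::knn(g)$knn),
    closeness = as.numeric(igraph::closeness(g, normalized = TRUE)),
    eigenvector = evec,
    katz = katz,
    betweenness = as.numeric(igraph::betweenness(g, normalized = TRUE)),
    clustering_coeff = unname(igraph::transitivity(g, type = "local",
                                                   isolates = "zero"))
  )
}

#' Select hub nodes at a percentile threshold
#'
#' Per metric, the threshold is the empirical `percentile` quantile
#' (linear interpolation by default; `method = "nearest"` uses the
#' nearest-rank quantile) and a node is selected for that metric when its
#' value is at or above the threshold (ties included). The hub set is the
#' union over the seven metrics, with per-metric provenance.
#'
#' @param ct Output of [compute_centralities()].
#' @param percentile Percentile threshold (default 95).
#' @param method Quantile type: `"linear"` or `"nearest"`.
#' @return `ct` with added `selected` (logical) and `selected_by`
#'   (list-column of metric names).
#' @export
select_hubs <- function(ct, percentile = 95, method = c("linear", "nearest")) {
  method <- match.arg(method)
  qtype <- if (method == "linear") 7 else 1
  metrics <- c("degree", "neighbor_degree", "closeness", "eigenvector",
               "katz", "betweenness", "clustering_coeff")
  stopifnot(all(metrics %in% names(ct)), nrow(ct) > 0)
  hit <- vapply(metrics, function(mcol) {
    thr <- quantile(ct[[mcol]], percentile / 100, type = qtype, names = FALSE)
    ct[[mcol]] >= thr
  }, logical(nrow(ct)))
  if (is.null(dim(hit))) hit <- matrix(hit, nrow = 1, dimnames = list(NULL, metrics))
  ct$selected <- rowSums(hit) > 0
  ct$selected_by <- lapply(seq_len(nrow(ct)), function(i) metrics[hit[i, ]])
  ct
}

#' Hypergeometric gene-set over-representation
#'
#' One-sided upper-tail hypergeometric test of the overlap between the
#' query set and each gene set, after intersecting sets with the universe;
#' sets with effective size below `min_size` are excluded before testing,
#' and BH adjustment runs across the tested sets.
#'
#' @param query Character vector of query genes (subset of `universe`).
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector, the testing universe.
#' @param min_size Minimum effective set size (default 5).
#' @param fdr_cut FDR threshold for the `significant` flag (default 0.05).
#' @return A tibble `set_name`, `set_size`, `overlap`, `p`, `fdr`,
#'   `significant`, sorted by p.
#' @export
hypergeom_enrich <- function(query, sets, universe, min_size = 5,
                             fdr_cut = 0.05) {
  query <- unique(query); universe <- unique(universe)
  if (!all(query %in% universe)) {
    abort("query must be a subset of the universe", class = "invalid_argument")
  }
  eff <- lapply(sets, function(s) intersect(unique(s), universe))
  eff <- eff[lengths(eff) >= min_size]
  if (!length(eff)) {
    return(tibble(set_name = character(), set_size = integer(),
                  overlap = integer(), p = double(), fdr = double(),
                  significant = logical()))
  }
  N <- length(universe); nq <- length(query)
  out <- tibble(
    set_name = names(eff),
    set_size = unname(lengths(eff)),
    overlap = unname(vapply(eff, function(s) length(intersect(query, s)),
                            integer(1)))
  ) |>
    mutate(p = phyper(.data$overlap - 1, .data$set_size, N - .data$set_size,
                      nq, lower.tail = FALSE))
  out$fdr <- bh_adjust(out$p)
  out |>
    mutate(significant = .data$fdr < fdr_cut) |>
    arrange(.data$p)
}

#' @export
tidy.integrated_network <- function(x, ...) x$edges

#' @export
glance.integrated_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_multi_source = sum(lengths(x$nodes$sources) > 1),
         min_conf = x$min_conf)
}

#' @export
print.integrated_network <- function(x, ...) {
  cat("<integrated_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (confidence >= ", x$min_conf, ")\n", sep = "")
  invisible(x)
}
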