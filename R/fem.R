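# Detection of PPI subnetworks enriched for differential methylation
# (functional-epigenetic-module style), with permutation significance.

#' Aggregate per-CpG statistics to gene level
#'
#' Since multiple CpG sites may map to the same gene, per-probe |t|
#' statistics are aggregated per gene (mean or max), optionally restricted
#' to promoter probes; the signed mean delta-beta carries the direction.
#'
#' @param dms Output of [fit_dms()].
#' @param manifest Probe annotation with `gene` and `feature`.
#' @param aggregation `"mean"` or `"max"`.
#' @param feature_filter Optional feature class to keep (e.g. `"promoter"`).
#' @return A tibble `gene`, `stat`, `n_probes`, `signed_mean_delta_beta`.
#' @export
gene_stats <- function(dms, manifest, aggregation = c("mean", "max"),
                       feature_filter = NULL) {
  aggregation <- match.arg(aggregation)
  agg <- if (aggregation == "mean") mean else max
  ann <- manifest[, c("probe_id", "gene", "feature")]
  d <- dms |>
    left_join(ann, by = "probe_id") |>
    filter(!is.na(.data$gene))
  if (!is.null(feature_filter)) d <- filter(d, .data$feature %in% feature_filter)
  d |>
    group_by(.data$gene) |>
    summarise(stat = agg(abs(.data$t)), n_probes = n(),
              signed_mean_delta_beta = mean(.data$delta_beta),
              .groups = "drop")
}

#' Detect differential-methylation hotspot modules on a PPI graph
#'
#' Node weights are gene-level statistics (zero for graph genes without a
#' statistic); each edge is weighted by the mean of its endpoint weights.
#' Seeds are the highest-ranked local maxima of the node weight; each seed
#' module grows greedily by the neighbour that maximises the module score
#' (mean internal edge weight) for as long as the score does not decrease
#' and the module stays within `max_size`. Significance is assessed by
#' permuting node statistics over the graph `n_perm` times, re-running the
#' search, and comparing each observed module's centred, size-adjusted
#' statistic (`mass = (score - mean node weight) * sqrt(edge count)`, which
#' separates a coherent high-statistic neighbourhood from both a single
#' lucky heavy edge and a large mediocre subgraph) with the permutation
#' distribution of maximum module mass (add-one estimator, so `emp_p` is
#' never zero).
#'
#' @param stats Output of [gene_stats()].
#' @param ppi Edge tibble `gene_a`, `gene_b`, `confidence`.
#' @param max_modules Maximum number of seed modules.
#' @param max_size Maximum module size.
#' @param n_perm Number of node-statistic permutations.
#' @param grow_tol Relative tolerance of the growth stop rule: the best
#'   neighbour is accepted while its average incident edge weight is at
#'   least `(1 - grow_tol)` times the module score. At `grow_tol = 0` the
#'   mean-edge-weight score can never grow past its best single edge, so a
#'   small slack is what lets coherent high-statistic neighbourhoods
#'   assemble while still rejecting background nodes.
#' @param seed Integer RNG seed.
#' @return An object of class `epi_modules`: a tibble with `seed_gene`,
#'   `members` (list-column), `size`, `score`, `emp_p`, `frac_hyper`.
#' @export
detect_modules <- function(stats, ppi, max_modules = 10, max_size = 100,
                           n_perm = 1000, grow_tol = 0.2, seed = 1) {
  nodes <- sort(union(ppi$gene_a, ppi$gene_b))
  if (!length(intersect(stats$gene, nodes))) {
    abort("no overlap between statistic genes and PPI genes",
          class = "no_overlap")
  }
  w <- setNames(rep(0, length(nodes)), nodes)
  w[stats$gene[stats$gene %in% nodes]] <-
    stats$stat[stats$gene %in% nodes]
  adj <- build_adjacency(ppi, nodes)
  obs <- greedy_module_search(w, adj, max_modules, max_size, grow_tol)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      wp <- setNames(sample(w), nodes)
      mods <- greedy_module_search(wp, adj, max_modules, max_size, grow_tol)
      if (nrow(mods)) max(mods$mass) else -Inf
    }, numeric(1))
  })
  # mean node weight is permutation-invariant, so the centering in `mass`
  # cancels from the null comparison only through the edge-count weighting
  dirs <- setNames(rep(NA_real_, length(nodes)), nodes)
  hit <- stats$gene %in% nodes
  dirs[stats$gene[hit]] <- stats$signed_mean_delta_beta[hit]
  obs$emp_p <- vapply(obs$mass, function(s) {
    (1 + sum(null_max >= s)) / (1 + n_perm)
  }, numeric(1))
  obs$frac_hyper <- vapply(obs$members, function(m) {
    d <- dirs[m]; if (all(is.na(d))) NA_real_ else mean(d > 0, na.rm = TRUE)
  }, numeric(1))
  structure(obs, class = c("epi_modules", class(obs)),
            n_perm = n_perm, seed = seed)
}

build_adjacency <- function(ppi, nodes) {
  ia <- match(ppi$gene_a, nodes); ib <- match(ppi$gene_b, nodes)
  adj <- vector("list", length(nodes))
  for (k in seq_along(ia)) {
    adj[[ia[k]]] <- c(adj[[ia[k]]], ib[k])
    adj[[ib[k]]] <- c(adj[[ib[k]]], ia[k])
  }
  lapply(adj, unique)
}

# Greedy growth from local-maximum seeds. Score bookkeeping is incremental:
# S = sum over internal edges of mean endpoint weight, m = edge count;
# adding node v contributes cnt[v] edges and wsum[v] weight.
greedy_module_search <- function(w, adj, max_modules, max_size,
                                 grow_tol = 0.2) {
  n <- length(w)
  w_bar <- mean(w)
  is_local_max <- vapply(seq_len(n), function(i) {
    nb <- adj[[i]]
    length(nb) > 0 && all(w[i] >= w[nb])
  }, logical(1))
  seeds <- order(-w)[is_local_max[order(-w)]]
  taken <- logical(n)
  out <- list()
  for (s in seeds) {
    if (length(out) >= max_modules) break
    if (taken[s]) next
    members <- s
    in_mod <- logical(n); in_mod[s] <- TRUE
    # nodes already claimed by a better-scoring module are not regrown
    cnt <- numeric(n); wsum <- numeric(n)
    for (u in adj[[s]]) { cnt[u] <- 1; wsum[u] <- (w[u] + w[s]) / 2 }
    S <- 0; m <- 0
    score <- -Inf; peak <- -Inf
    repeat {
      if (length(members) >= max_size) break
      cand <- which(cnt > 0 & !in_mod & !taken)
      if (!length(cand)) break
      new_scores <- (S + wsum[cand]) / (m + cnt[cand])
      v <- cand[which.max(new_scores)]
      # accept while the candidate's average incident edge weight stays
      # within grow_tol of the best score seen; anchoring at the peak (not
      # the current score) stops the threshold from drifting down as the
      # module dilutes, which would otherwise let background nodes cascade
      if (m > 0 && wsum[v] / cnt[v] < (1 - grow_tol) * peak) break
      members <- c(members, v)
      in_mod[v] <- TRUE
      S <- S + wsum[v]; m <- m + cnt[v]
      score <- S / m
      peak <- max(peak, score)
      for (u in adj[[v]]) {
        if (!in_mod[u]) { cnt[u] <- cnt[u] + 1; wsum[u] <- wsum[u] + (w[u] + w[v]) / 2 }
      }
    }
    if (length(members) < 2) next
    taken[members] <- TRUE
    sz <- length(members)
    out[[length(out) + 1]] <- tibble(
      seed_gene = names(w)[s],
      members = list(names(w)[sort(members)]),
      size = sz, score = score,
      mass = (score - w_bar) * sqrt(m))
  }
  if (!length(out)) {
    return(tibble(seed_gene = character(), members = list(),
                  size = integer(), score = double(), mass = double()))
  }
  bind_rows(out) |> arrange(desc(.data$mass))
}

#' @export
tidy.epi_modules <- function(x, ...) {
  as_tibble(x) |>
    mutate(members = map_chr(.data$members, paste, collapse = ";")) |>
    select("seed_gene", "size", "score", "emp_p", "frac_hyper", "members")
}

#' @export
glance.epi_modules <- function(x, ...) {
  tibble(n_modules = nrow(x),
         n_significant = sum(x$emp_p < 0.05),
         best_score = if (nrow(x)) max(x$score) else NA_real_,
         n_perm = attr(x, "n_perm"))
}
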