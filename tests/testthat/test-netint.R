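# Cross-source network construction, centrality metrics, hub selection,
# and over-representation.

test_that("edge retention follows confidence and cross-source rules", {
  ppi <- tibble::tibble(gene_a = c("a1", "a1", "a1"),
                        gene_b = c("b1", "a2", "b2"),
                        confidence = c(0.9, 0.9, 0.69))
  net <- build_integrated_network(ppi, deg_genes = c("a1", "a2"),
                                  dmr_genes = c("b1", "b2"),
                                  fem_genes = character())
  expect_setequal(c(net$edges$gene_a, net$edges$gene_b), c("a1", "b1"))
  expect_equal(nrow(net$edges), 1)          # a1-a2 same-source, b2 low conf
  # every retained edge joins two distinct source labels
  lab <- setNames(net$nodes$sources, net$nodes$node)
  for (i in seq_len(nrow(net$edges))) {
    u <- lab[[net$edges$gene_a[i]]]; v <- lab[[net$edges$gene_b[i]]]
    expect_gte(length(unique(c(u, v))), 2)
  }
  expect_error(build_integrated_network(ppi, character(), character(),
                                        character()),
               class = "invalid_argument")
  expect_error(build_integrated_network(ppi, "a1", character(), character()),
               class = "empty_network")
})

test_that("the larger of two cross-source components is kept", {
  ppi <- tibble::tibble(
    gene_a = c("a1", "a2", "a3", "a4", "a4", "x1", "x2"),
    gene_b = c("b1", "b1", "b1", "b1", "b2", "y1", "y1"),
    confidence = 0.9)
  net <- build_integrated_network(
    ppi, deg_genes = c("a1", "a2", "a3", "a4", "x1", "x2"),
    dmr_genes = c("b1", "b2", "y1"), fem_genes = character())
  expect_equal(sort(net$nodes$node),
               c("a1", "a2", "a3", "a4", "b1", "b2"))
  expect_equal(glance(net)$n_nodes, 6)
})

test_that("centralities match hand values on canonical graphs", {
  tri <- tibble::tibble(gene_a = c("a", "a", "b"),
                        gene_b = c("b", "c", "c"), confidence = 1)
  g <- igraph::graph_from_data_frame(tri[, 1:2], directed = FALSE)
  ct <- compute_centralities(g)
  expect_equal(ct$degree, rep(2, 3))
  expect_equal(ct$clustering_coeff, rep(1, 3))
  expect_equal(ct$betweenness, rep(0, 3))
  expect_equal(ct$eigenvector, rep(1 / sqrt(3), 3), tolerance = 1e-10)

  path <- igraph::graph_from_data_frame(
    tibble::tibble(gene_a = c("A", "B"), gene_b = c("B", "C")),
    directed = FALSE)
  cp <- compute_centralities(path)
  expect_equal(cp$betweenness[cp$node == "B"], 1)
  expect_equal(cp$closeness[cp$node == "B"], 1)
  expect_equal(cp$closeness[cp$node == "A"], 2 / 3)

  star <- igraph::graph_from_data_frame(
    tibble::tibble(gene_a = "c", gene_b = paste0("l", 1:4)),
    directed = FALSE)
  cs <- compute_centralities(star)
  expect_equal(cs$degree[cs$node == "c"], 4)
  expect_equal(cs$neighbor_degree[cs$node == "l1"], 4)
  expect_equal(cs$clustering_coeff[cs$node == "c"], 0)

  disconnected <- igraph::graph_from_data_frame(
    tibble::tibble(gene_a = c("a", "x"), gene_b = c("b", "y")),
    directed = FALSE)
  expect_error(compute_centralities(disconnected), class = "invalid_input")
})

test_that("all seven metrics agree with the brute-force oracle", {
  set.seed(10)
  for (r in 1:50) {
    n <- sample(4:8, 1)
    A <- random_connected_graph(n)
    g <- igraph::graph_from_data_frame(graph_tbl_from_adj(A)[, 1:2],
                                       directed = FALSE)
    ct <- compute_centralities(g)
    ct <- ct[order(ct$node), ]
    oracle <- centrality_oracle(A)
    for (metric in names(oracle)) {
      expect_equal(ct[[metric]], unname(oracle[[metric]]),
                   tolerance = 1e-8,
                   label = paste(metric, "rep", r))
    }
  }
})

test_that("hub selection uses interpolated percentiles with tie inclusion", {
  base <- tibble::tibble(node = sprintf("n%03d", 1:100),
                         degree = as.numeric(1:100),
                         neighbor_degree = 1, closeness = 1,
                         eigenvector = 1, katz = 1, betweenness = 1,
                         clustering_coeff = 1)
  hubs <- select_hubs(base, percentile = 95)
  picked_by_degree <- hubs$node[vapply(hubs$selected_by,
                                       function(s) "degree" %in% s,
                                       logical(1))]
  expect_setequal(picked_by_degree, sprintf("n%03d", 96:100))
  # constant metrics select everyone (ties at the threshold included)
  expect_true(all(hubs$selected))
  # a node in the top 5% of exactly one metric carries that provenance
  two <- tibble::tibble(node = base$node,
                        degree = as.numeric(1:100),
                        neighbor_degree = as.numeric(100:1),
                        closeness = as.numeric(100:1),
                        eigenvector = as.numeric(100:1),
                        katz = as.numeric(100:1),
                        betweenness = as.numeric(100:1),
                        clustering_coeff = as.numeric(100:1))
  h2 <- select_hubs(two)
  expect_equal(h2$selected_by[[100]], "degree")
  expect_true(h2$selected[100])
  # union is monotone when the percentile relaxes
  h90 <- select_hubs(base, percentile = 90)
  expect_true(all(hubs$node[hubs$selected] %in% h90$node[h90$selected]))
})

test_that("hypergeometric enrichment matches combinatorial counts", {
  universe <- sprintf("u%02d", 1:20)
  sets <- list(hit = universe[1:5], small = universe[1:4])
  res <- hypergeom_enrich(universe[1:5], sets, universe, min_size = 5)
  expect_false("small" %in% res$set_name)    # effective size 4 excluded
  expect_equal(res$p[res$set_name == "hit"], 1 / choose(20, 5),
               tolerance = 1e-12)
  res0 <- hypergeom_enrich(universe[6:10], list(s = universe[11:15]),
                           universe)
  expect_equal(res0$p, 1)                    # zero overlap, upper tail
  expect_error(hypergeom_enrich(c("zz"), sets, universe),
               class = "invalid_argument")
  # enumeration oracle on small universes
  set.seed(4)
  for (r in 1:30) {
    N <- sample(8:15, 1)
    uni <- sprintf("x%02d", seq_len(N))
    K <- sample(5:N, 1)
    nq <- sample(1:N, 1)
    s <- sample(uni, K); q <- sample(uni, nq)
    res <- hypergeom_enrich(q, list(s = s), uni, min_size = 5)
    ov <- length(intersect(q, s))
    expect_equal(res$p, hyper_oracle(ov, K, N, nq), tolerance = 1e-12)
  }
})

test_that("gene sets round-trip through GMT", {
  sets <- list(alpha = c("A", "B", "C"), beta = c("B", "D"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)
})
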