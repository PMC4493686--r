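toy_net <- function(edges, ...) gene_network(edges, ...)

test_that("edge-weight standardization maps binary nets to the confidence constant", {
  bin <- toy_net(tibble::tibble(gene1 = c("a", "b", "c"),
                                gene2 = c("b", "c", "d"),
                                weight = c(1, 1, 1)), net_type = "physical")
  std <- standardize_edge_weights(bin)
  expect_equal(std$weight, c(2, 2, 2))
  std5 <- standardize_edge_weights(bin, binary_confidence = 5)
  expect_equal(std5$weight, c(5, 5, 5))

  cont <- toy_net(tibble::tibble(gene1 = c("a", "a", "b"),
                                 gene2 = c("b", "c", "c"),
                                 weight = c(1, 4, 10)))
  std2 <- standardize_edge_weights(cont)
  expect_lt(abs(mean(std2$weight)), 1e-9)
  expect_lt(abs(sd(std2$weight) - 1), 1e-9)
  # idempotent on already-standardized weights
  std3 <- standardize_edge_weights(std2)
  expect_equal(std3$weight, std2$weight, tolerance = 1e-9)
})

test_that("integration averages over the networks that score each pair", {
  A <- toy_net(tibble::tibble(gene1 = "g1", gene2 = "g2", weight = 1))
  B <- toy_net(tibble::tibble(gene1 = "g1", gene2 = "g2", weight = 3))
  C <- toy_net(tibble::tibble(gene1 = "h1", gene2 = "h2", weight = 7))

  one <- integrate_networks(list(A))
  expect_equal(one$weight, A$weight)
  self <- integrate_networks(list(A, A))
  expect_equal(self$weight, A$weight)

  # pair scored 1.0 and 3.0 where present, absent from C's universe -> mean 2
  comb <- integrate_networks(list(A, B, C))
  expect_equal(comb$weight[comb$gene1 == "g1" & comb$gene2 == "g2"], 2)
  expect_equal(comb$weight[comb$gene1 == "h1"], 7)
  expect_setequal(attr(comb, "universe"), c("g1", "g2", "h1", "h2"))
  expect_equal(attr(comb, "net_type"), "functional")

  expect_error(integrate_networks(list()), "at least one")
})

test_that("integration is permutation-invariant and bounded by per-net weights", {
  withr::with_seed(99, {
    nets <- lapply(1:3, function(i) {
      gen_interaction_network(n_genes = 30, n_clusters = 2, cluster_size = 8,
                              p_in = 0.8, p_out = 0.2, seed = 40 + i)$network
    })
    ab <- integrate_networks(nets)
    ba <- integrate_networks(rev(nets))
    expect_equal(as.data.frame(ab), as.data.frame(ba))

    per_edge <- dplyr::bind_rows(lapply(nets, tibble::as_tibble)) |>
      dplyr::group_by(gene1, gene2) |>
      dplyr::summarise(lo = min(weight), hi = max(weight), .groups = "drop")
    j <- dplyr::inner_join(tibble::as_tibble(ab), per_edge,
                           by = c("gene1", "gene2"))
    expect_true(all(j$weight >= j$lo - 1e-12 & j$weight <= j$hi + 1e-12))
  })
})

test_that("greedy extraction on a hand-built graph follows per-step argmax with lexicographic ties", {
  edges <- tibble::tibble(
    gene1 = c("q1", "q1", "q2", "a", "b", "q2"),
    gene2 = c("a",  "b",  "b",  "b", "c", "c"),
    weight = c(3,    1,    2,   1,   5,   0.5))
  net <- toy_net(edges, universe = c("q1", "q2", "a", "b", "c", "d"))
  sg <- extract_subgraph(net, c("q1", "q2"), k = 2)
  # step 1: a = 3, b = 1 + 2 = 3 -> tie, lexicographic pick "a"
  # step 2: b = 1 + 2 + 1 = 4, c = 0.5 -> "b"
  expect_equal(sg$added_nodes, c("a", "b"))
  expect_equal(sg$nodes$add_score[sg$nodes$node == "a"], 3)
  expect_equal(sg$nodes$add_score[sg$nodes$node == "b"], 4)
  expect_equal(nrow(sg$edges), 4)   # pairs among {q1, q2, a, b}

  # k = 0 returns only the seeds
  sg0 <- extract_subgraph(net, c("q1", "q2"), k = 0)
  expect_equal(sg0$nodes$node, c("q1", "q2"))

  # absent query genes: dropped with a warning, error when none remain
  expect_warning(extract_subgraph(net, c("q1", "zz"), k = 1), "zz")
  expect_error(suppressWarnings(extract_subgraph(net, "zz", k = 1)), "zz")
})

test_that("greedy additions match exhaustive per-step evaluation on random graphs", {
  withr::with_seed(202, {
    for (i in 1:25) {
      n <- sample(6:15, 1)
      genes <- sprintf("n%02d", seq_len(n))
      pairs <- t(combn(genes, 2))
      keep <- runif(nrow(pairs)) < 0.5
      # quarter-integer weights are binary-exact, so score ties are exact in
      # both the implementation and the oracle
      edges <- tibble::tibble(gene1 = pairs[keep, 1], gene2 = pairs[keep, 2],
                              weight = sample(seq(-8, 12) / 4, sum(keep),
                                              replace = TRUE))
      net <- gene_network(edges, universe = genes)
      seeds <- sample(genes, sample(1:3, 1))
      k <- sample(0:4, 1)
      sg <- extract_subgraph(net, seeds, k)
      expect_identical(sg$added_nodes,
                       brute_greedy(edges, genes, seeds, k))
    }
  })
})

test_that("subgraph size follows |Q| + min(k, |V| - |Q|) and scores recompute from induced edges", {
  withr::with_seed(77, {
    for (i in 1:10) {
      fix <- gen_interaction_network(n_genes = 40, n_clusters = 3,
                                     cluster_size = 8, seed = 300 + i)
      net <- fix$network
      uni <- attr(net, "universe")
      q <- sample(uni, sample(2:6, 1))
      k <- sample(c(0, 3, 10, 50), 1)
      sg <- extract_subgraph(net, q, k)
      expect_equal(nrow(sg$nodes),
                   length(q) + min(k, length(uni) - length(q)))

      # recorded add-time score = sum of induced-edge weights to prior nodes
      before <- sg$seed_nodes
      for (j in seq_along(sg$added_nodes)) {
        v <- sg$added_nodes[j]
        expected <- brute_score(sg$edges, before, v)
        expect_equal(sg$nodes$add_score[sg$nodes$node == v], expected,
                     tolerance = 1e-9)
        before <- c(before, v)
      }
    }
  })
})

test_that("networks round-trip through edge-list files with canonical pair order", {
  net <- gen_interaction_network(n_genes = 25, n_clusters = 2, cluster_size = 6,
                                 seed = 5)$network
  f <- file.path(withr::local_tempdir(), "net.tsv")
  write_network(net, f)
  back <- read_network(f, net_type = "functional")
  expect_equal(as.data.frame(back)[c("gene1", "gene2")],
               as.data.frame(net)[c("gene1", "gene2")])
  expect_equal(back$weight, net$weight, tolerance = 1e-9)
  expect_true(all(back$gene1 < back$gene2))

  # thresholded writer keeps only high-confidence edges
  f2 <- file.path(withr::local_tempdir(), "net2.tsv")
  write_network(net, f2, threshold = 2)
  high <- read_network(f2)
  expect_true(all(abs(high$weight) > 2))
})
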