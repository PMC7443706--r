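test_that("graph building counts compartment-filtered links", {
  labs <- list(
    a = setNames(c("dendrite", "axon", "axon"), 1:3),
    b = setNames(c("dendrite", "dendrite", "axon"), 1:3))
  conn <- as_connectors(data.frame(
    connector_id = "c1", pre_neuron = "a", pre_node = 2,
    post_neuron = "b", post_node = c(1, 2, 3), x = 0, y = 0, z = 0))
  g <- build_graph(conn, labs)                       # unfiltered
  expect_equal(igraph::E(g)$weight, 3)
  g_ad <- build_graph(conn, labs, "axon", "dendrite")
  expect_equal(igraph::E(g_ad)$weight, 2)            # links onto b's nodes 1,2
  g_aa <- build_graph(conn, labs, "axon", "axon")
  expect_equal(igraph::E(g_aa)$weight, 1)
  g_da <- build_graph(conn, labs, "dendrite", "axon")
  expect_equal(igraph::ecount(g_da), 0L)             # filter excludes all
  expect_error(build_graph(conn, labs, "axonal", "axon"), "compartment")
})

test_that("graphs built from a bundle equal the generator's ground truth", {
  cfg <- brain_config(seed = 11, n_glomeruli = 2, n_upn_per_glom = 2,
                      n_mpn = 2, n_dendrite_points = 50, n_axon_points = 50,
                      lambda_within = 6, n_communities = 2)
  b <- generate_network(cfg)
  g <- build_graph(b$conn_axo, b$truth_labels, "axon", "axon")
  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight",
                                             sparse = FALSE))
  ids <- rownames(b$truth_graph)
  expect_equal(W[ids, ids], b$truth_graph)
})

test_that("weighted reciprocity reproduces the two-node worked example", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("i", "j"), to = c("j", "i"), weight = c(5, 2)))
  r <- weighted_reciprocity(g)
  expect_equal(r, 2 / 7)
  expect_equal(floor(r * 1000) / 1000, 0.285)        # printed 3-decimal form

  sym <- matrix(c(0, 4, 4, 0), 2)                    # fully symmetric pair
  expect_equal(weighted_reciprocity(sym), 0.5)
  dag <- matrix(c(0, 0, 3, 0), 2)
  expect_equal(weighted_reciprocity(dag), 0)

  set.seed(149)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    W <- matrix(rpois(n * n, 1.2), n); diag(W) <- 0
    if (sum(W) == 0) next
    expect_equal(weighted_reciprocity(W), oracle_reciprocity(W))
  }
})

test_that("weighted out-degree equals adjacency row sums", {
  set.seed(151)
  W <- matrix(rpois(36, 2), 6); diag(W) <- 0
  rownames(W) <- colnames(W) <- letters[1:6]
  g <- igraph::graph_from_adjacency_matrix(W, weighted = TRUE)
  expect_equal(unname(weighted_out_degree(g)[letters[1:6]]),
               unname(rowSums(W)))
  sink <- matrix(c(0, 1, 0, 0), 2,
                 dimnames = list(c("a", "b"), c("a", "b")))
  gs <- igraph::graph_from_adjacency_matrix(sink, weighted = TRUE)
  expect_equal(unname(weighted_out_degree(gs)["a"]), 0)
})

test_that("local reaching centrality follows the weighted-path formula", {
  chain <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  chain["a", "b"] <- 1; chain["b", "c"] <- 1
  g <- igraph::graph_from_adjacency_matrix(chain, weighted = TRUE)
  lrc <- local_reaching_centrality(g)
  expect_equal(unname(lrc), c(1, 0.5, 0))            # hand evaluation

  comp <- igraph::make_full_graph(5, directed = TRUE)
  igraph::E(comp)$weight <- 1
  expect_equal(unname(local_reaching_centrality(comp)), rep(1, 5))

  iso <- igraph::make_empty_graph(3, directed = TRUE) |>
    igraph::add_edges(c(1, 2)) |> igraph::set_edge_attr("weight", value = 2)
  expect_equal(unname(local_reaching_centrality(iso))[3], 0)

  set.seed(157)
  for (rep in 1:20) {
    n <- sample(4:7, 1)
    W <- matrix(rpois(n * n, 1) * runif(n * n, 0.5, 2), n)
    W[sample(n * n, n * n %/% 2)] <- 0
    diag(W) <- 0
    if (sum(W) == 0) next
    rownames(W) <- colnames(W) <- paste0("v", seq_len(n))
    g <- igraph::graph_from_adjacency_matrix(W, weighted = TRUE)
    got <- local_reaching_centrality(g)[paste0("v", seq_len(n))]
    expect_equal(unname(got), oracle_lrc(W), tolerance = 1e-9)
  }
})

test_that("community detection recovers planted and forced structure", {
  # two disconnected cliques: exact recovery forced by structure
  W <- matrix(0, 6, 6, dimnames = rep(list(paste0("v", 1:6)), 2))
  W[1:3, 1:3] <- 5; W[4:6, 4:6] <- 5; diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, weighted = TRUE)
  cm <- detect_communities(g, seed = 1)
  expect_equal(cm$n_communities, 2L)
  expect_equal(length(unique(cm$membership[1:3])), 1L)
  expect_equal(length(unique(cm$membership[4:6])), 1L)

  # fully disconnected nodes stay unassigned
  g0 <- igraph::make_empty_graph(4, directed = TRUE)
  igraph::V(g0)$name <- paste0("v", 1:4)
  cm0 <- detect_communities(g0, seed = 1)
  expect_true(all(is.na(cm0$membership)))

  # planted 3-block synthetic graphs: adjusted agreement >= 0.9 over seeds
  adjusted_rand <- function(a, b) {
    tab <- table(a, b)
    sum_comb <- function(x) sum(choose(x, 2))
    sij <- sum_comb(tab); si <- sum_comb(rowSums(tab)); sj <- sum_comb(colSums(tab))
    expected <- si * sj / choose(sum(tab), 2)
    (sij - expected) / ((si + sj) / 2 - expected)
  }
  cfg <- brain_config(seed = 19, n_glomeruli = 3, n_upn_per_glom = 3,
                      n_mpn = 6, n_dendrite_points = 40, n_axon_points = 40,
                      lambda_within = 10, lambda_between = 0.3,
                      n_communities = 3)
  b <- generate_network(cfg)
  g <- build_graph(b$conn_axo, b$truth_labels, "axon", "axon")
  aris <- vapply(1:10, function(s) {
    cm <- detect_communities(g, seed = s)
    memb <- cm$membership[names(b$truth_partition)]
    adjusted_rand(memb, b$truth_partition)
  }, numeric(1))
  expect_true(all(aris >= 0.9))
})

test_that("the proximity null model scores symmetric and one-sided geometry", {
  # two interdigitated cables with presynapses on both: fully symmetric null
  a <- chain_skeleton(30, spacing = 1000, id = "a")
  b <- chain_skeleton(30, spacing = 1000, id = "b", y = 600)
  conn <- as_connectors(data.frame(
    connector_id = sprintf("c%d", 1:20),
    pre_neuron = rep(c("a", "b"), each = 10), pre_node = rep(2:11, 2),
    post_neuron = rep(c("b", "a"), each = 10), post_node = rep(2:11, 2),
    x = rep((1:10) * 1000, 2), y = rep(c(0, 600), each = 10), z = 0))
  null <- proximity_null_reciprocity(list(a = a, b = b), conn,
                                     prediction_params(delta = 2000))
  expect_equal(null$reciprocity, 0.5)                # symmetric convention max

  one_sided <- conn[conn$pre_neuron == "a", ]
  null1 <- proximity_null_reciprocity(list(a = a, b = b), one_sided,
                                      prediction_params(delta = 2000))
  expect_equal(null1$reciprocity, 0)
})

test_that("community fingerprints tally annotation fractions", {
  memb <- c(a = 1, b = 1, c = 2, d = 2, e = 2, f = NA)
  ann <- c(a = "food", b = "food", c = "food", d = "pheromonal",
           e = "pheromonal", f = "food")
  fp <- community_fingerprint(memb, ann)
  expect_equal(fp[["1"]][["food"]], 1)               # single-scene community
  expect_equal(unname(fp[["2"]]["food"]), 1 / 3)
  expect_true(all(abs(vapply(fp, sum, numeric(1)) - 1) < 1e-12))
  # uniform annotation gives uniform fractions
  fp2 <- community_fingerprint(c(x = 1, y = 1), c(x = "s1", y = "s2"))
  expect_equal(unname(fp2[["1"]]), c(0.5, 0.5))
})

test_that("input budgets split weak and strong partners at thresholds", {
  W <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "t")), 2))
  W["a", "t"] <- 10
  g <- igraph::graph_from_adjacency_matrix(W, weighted = TRUE)
  st <- input_budget_stats(g, "t")
  expect_equal(st$n_strong, 1L)
  expect_equal(st$n_weak, 0L)

  # 200 equal partners are all weak at the 1% threshold
  n <- 200
  W2 <- matrix(0, n + 1, n + 1,
               dimnames = rep(list(c(paste0("u", 1:n), "t")), 2))
  W2[1:n, n + 1] <- 4
  g2 <- igraph::graph_from_adjacency_matrix(W2, weighted = TRUE)
  st2 <- input_budget_stats(g2, "t", threshold = 0.01)
  expect_equal(st2$n_weak, n)
  expect_equal(st2$n_strong, 0L)

  set.seed(163)
  w <- rpois(30, 20) + 1
  W3 <- matrix(0, 31, 31, dimnames = rep(list(c(paste0("u", 1:30), "t")), 2))
  W3[1:30, 31] <- w
  g3 <- igraph::graph_from_adjacency_matrix(W3, weighted = TRUE)
  cls <- setNames(rep(c("uPN", "mPN", "LHLN"), 10), paste0("u", 1:30))
  for (thr in c(0.01, 0.015)) {
    st3 <- input_budget_stats(g3, "t", threshold = thr, classes = cls)
    frac <- w / sum(w)
    expect_equal(st3$n_weak, sum(frac < thr))
    expect_equal(st3$n_strong, sum(frac >= thr))
    expect_equal(sum(st3$composition), 1)
    expect_equal(unname(st3$composition["uPN"]),
                 sum(w[cls[paste0("u", 1:30)] == "uPN"]) / sum(w))
  }
  expect_error(input_budget_stats(g3, "nope"), "not in graph")
})
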