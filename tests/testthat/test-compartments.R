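test_that("flow centrality matches the exhaustive pair-counting oracle", {
  # backbone with 2 proximal inputs and 2 distal outputs
  bb <- chain_skeleton(6, spacing = 1000)
  fc <- flow_centrality(bb, presyn_nodes = c(5, 6), postsyn_nodes = c(1, 2))
  expect_equal(max(fc$scores), 4)
  expect_equal(unname(fc$split_node), 3)     # tie broken towards the root
  expect_true(all(c("5", "6") %in%
                    names(fc$labels)[fc$labels == "axon"]))
  expect_equal(unname(fc$scores),
               unname(oracle_flow_centrality(bb, c(5, 6), c(1, 2))[
                 as.character(bb$nodes$node_id)]))

  # all synapses on one node: unsplittable, scores all zero
  fc0 <- flow_centrality(bb, presyn_nodes = 4, postsyn_nodes = 4)
  expect_false(fc0$splittable)
  expect_true(all(fc0$scores == 0))

  set.seed(97)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    sk <- random_tree_skeleton(n)
    pre <- sample(sk$nodes$node_id, sample(1:5, 1), replace = TRUE)
    post <- sample(sk$nodes$node_id, sample(1:8, 1), replace = TRUE)
    fc <- flow_centrality(sk, pre, post)
    orc <- oracle_flow_centrality(sk, pre, post)
    expect_equal(unname(fc$scores),
                 unname(orc[as.character(sk$nodes$node_id)]))
  }
})

test_that("synthetic neurons are split into their ground-truth compartments", {
  set.seed(101)
  glom <- generate_glomeruli(brain_config(n_glomeruli = 2))
  pn <- generate_pn(glom, c(G01 = 0.7, G02 = 0.3), n_dendrite_points = 200,
                    n_axon_points = 120)
  truth <- pn$truth_labels
  dend_ids <- as.integer(names(truth)[truth == "dendrite"])
  axon_ids <- as.integer(names(truth)[truth == "axon"])
  pre <- sample(axon_ids, 40, replace = TRUE)          # outputs on the axon
  post <- sample(dend_ids, 80, replace = TRUE)         # inputs on the dendrite
  fc <- flow_centrality(pn, pre, post)
  both <- names(truth)[truth %in% c("axon", "dendrite")]
  agree <- mean(fc$labels[both] == truth[both])
  expect_gte(agree, 0.95)
  expect_equal(segregation_index(fc), 1)    # fully polarized by construction
})

test_that("segregation index hits its boundary semantics and is symmetric", {
  bb <- chain_skeleton(10, spacing = 1000)
  polarized <- flow_centrality(bb, presyn_nodes = c(8, 9, 10),
                               postsyn_nodes = c(1, 2, 3))
  expect_equal(segregation_index(polarized), 1)

  # identical input:output mix in both compartments -> 0; imposed split so
  # each half carries exactly one input and one output
  mixed <- flow_centrality(bb, presyn_nodes = c(2, 9),
                           postsyn_nodes = c(3, 8))
  mixed$labels[] <- rep(c("dendrite", "axon"), each = 5)
  cts <- synapse_densities(mixed)
  expect_true(all(cts$n_presyn == 1) && all(cts$n_postsyn == 1))
  expect_equal(segregation_index(mixed), 0)

  # invariance under swapping the axon/dendrite labels
  swapped <- mixed
  swapped$labels <- c(axon = "dendrite", dendrite = "axon",
                      linker = "linker", `soma-fiber` = "soma-fiber")[
                        mixed$labels]
  names(swapped$labels) <- names(mixed$labels)
  expect_equal(segregation_index(swapped), segregation_index(mixed))
})

test_that("synapse densities are counts per um and survive subdivision", {
  bb <- chain_skeleton(21, spacing = 1000)  # 20 um chain
  fc <- flow_centrality(bb, presyn_nodes = rep(c(12, 14, 16, 18, 20), 2),
                        postsyn_nodes = c(2, 4, 6))
  dens <- synapse_densities(fc)
  axon <- dens[dens$compartment == "axon", ]
  expect_equal(axon$presyn_density, axon$n_presyn / axon$cable_um)

  # 10 presynapses on a 10 um axon -> 1 per um
  sk10 <- chain_skeleton(12, spacing = 1000)
  fc10 <- flow_centrality(sk10, presyn_nodes = 3:12, postsyn_nodes = 1)
  d10 <- synapse_densities(fc10)
  expect_equal(d10$presyn_density[d10$compartment == "axon"],
               10 / d10$cable_um[d10$compartment == "axon"])

  # subdividing every edge with a degree-2 node (same geometry, node i of
  # the original chain becomes node 2i - 1) leaves densities unchanged
  sub <- chain_skeleton(41, spacing = 500)
  to_sub <- function(ids) 2 * ids - 1
  fc_sub <- flow_centrality(sub,
                            presyn_nodes = to_sub(rep(c(12, 14, 16, 18, 20), 2)),
                            postsyn_nodes = to_sub(c(2, 4, 6)))
  dens_sub <- synapse_densities(fc_sub)
  m <- match(dens$compartment, dens_sub$compartment)
  expect_equal(dens_sub$n_presyn[m], dens$n_presyn)
  expect_equal(dens_sub$n_postsyn[m], dens$n_postsyn)
  # the split tie run gains the new midpoint node, so the compartment
  # boundary can shift by half an edge: densities agree to that resolution
  expect_equal(dens_sub$presyn_density[m], dens$presyn_density,
               tolerance = 0.05)
  expect_equal(dens_sub$postsyn_density[m], dens$postsyn_density,
               tolerance = 0.05)
})

test_that("polyadicity statistics summarise links per presynapse", {
  conn <- as_connectors(data.frame(
    connector_id = c("a", "b", "b", "c", "c", "c"),
    pre_neuron = "n", pre_node = 1,
    post_neuron = "m", post_node = 1:6, x = 0, y = 0, z = 0))
  st <- polyadicity_stats(conn)
  expect_equal(st$mean, 2)                  # link counts 1, 2, 3
  expect_equal(st$n, 3L)

  single <- as_connectors(conn[1, ])
  st1 <- polyadicity_stats(single)
  expect_true(is.na(st1$sem))
  expect_error(polyadicity_stats(conn[integer(0), ]), "no connectors")
})

test_that("lifetime sparseness matches its closed form and is scale invariant", {
  expect_equal(lifetime_sparseness(c(1, 0, 0, 0)), 1)
  expect_equal(lifetime_sparseness(rep(0.3, 8)), 0)
  v <- c(2, 1, 1, 0); n <- 4
  direct <- (1 - (sum(v) / n)^2 / (sum(v^2) / n)) / (1 - 1 / n)
  expect_equal(lifetime_sparseness(v), direct)
  set.seed(103)
  r <- rexp(30)
  expect_equal(lifetime_sparseness(5.5 * r), lifetime_sparseness(r),
               tolerance = 1e-12)
  expect_error(lifetime_sparseness(rep(0, 4)), "zero")
  expect_error(lifetime_sparseness(c(-1, 2)), "non-negative")
})
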