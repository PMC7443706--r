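test_that("overlap score matches its analytic values and the brute force", {
  p0 <- matrix(c(0, 0, 0), 1)
  expect_equal(overlap_score(p0, p0), 1)               # exp(0)
  p1 <- matrix(c(1210, 0, 0), 1)
  expect_equal(overlap_score(p0, p1, prediction_params(delta = 1210)),
               exp(-0.5))
  set.seed(107)
  for (rep in 1:5) {
    S <- matrix(runif(3 * sample(20:100, 1), 0, 4000), ncol = 3)
    K <- matrix(runif(3 * sample(20:100, 1), 0, 4000), ncol = 3)
    pp <- prediction_params(delta = runif(1, 500, 3000))
    expect_equal(overlap_score(S, K, pp), oracle_overlap(S, K, pp$delta),
                 tolerance = 1e-9)
  }
  expect_warning(o <- overlap_score(matrix(numeric(0), 0, 3), p0), "empty")
  expect_equal(o, 0)
})

test_that("overlap score is monotonically non-decreasing in delta", {
  set.seed(109)
  S <- matrix(runif(90, 0, 5000), ncol = 3)
  K <- matrix(runif(90, 0, 5000), ncol = 3)
  scores <- vapply(c(200, 600, 1200, 2400, 10000), function(d)
    overlap_score(S, K, prediction_params(delta = d)), numeric(1))
  expect_true(all(diff(scores) >= 0))
})

test_that("delta calibration takes the quantile of link distances", {
  tgt <- chain_skeleton(50, spacing = 1000, id = "t")
  # presynapses all exactly 700 nm off the target line
  conn <- as_connectors(data.frame(
    connector_id = sprintf("c%d", 1:20), pre_neuron = "s", pre_node = 1,
    post_neuron = "t", post_node = 1:20,
    x = (1:20 - 1) * 1000, y = 700, z = 0))
  expect_equal(calibrate_delta(conn, list(t = tgt)), 700)

  # distances 1..100: quantile within one grid step of the 90th percentile
  tgt2 <- chain_skeleton(2, spacing = 1e6, id = "t2")
  conn2 <- as_connectors(data.frame(
    connector_id = sprintf("c%d", 1:100), pre_neuron = "s", pre_node = 1,
    post_neuron = "t2", post_node = 1,
    x = 0, y = 1:100, z = 0))
  expect_lt(abs(calibrate_delta(conn2, list(t2 = tgt2)) - 90), 1)
  expect_error(calibrate_delta(conn2[1:5, ], list(t2 = tgt2)), ">= 10")
})

test_that("potential contacts count merged crossing sites", {
  a <- chain_skeleton(21, spacing = 1000, id = "a")
  far <- chain_skeleton(21, spacing = 1000, id = "b", y = 1e6)
  expect_equal(potential_contacts(a, far)$sites, 0L)

  # two straight cables crossing once at < delta
  cross <- skeleton(data.frame(node_id = 1:2, parent_id = c(NA, 1),
                               x = c(10000, 10000), y = c(-10000, 10000),
                               z = 500, radius = 50), neuron_id = "x")
  pc <- potential_contacts(a, cross, prediction_params(delta = 1210))
  expect_equal(pc$sites, 1L)
  expect_gt(pc$points, 0L)

  set.seed(113)
  for (rep in 1:5) {
    S <- matrix(runif(3 * 60, 0, 8000), ncol = 3)
    K <- matrix(runif(3 * 60, 0, 8000), ncol = 3)
    pp <- prediction_params(delta = 800, resample_step = 1000)
    got <- potential_contacts(S, K, pp)
    expect_equal(got$sites, oracle_contacts(S, K, pp$delta, pp$resample_step))
  }
})

test_that("near synapses count presynapses within range with saturation", {
  tgt <- chain_skeleton(11, spacing = 1000, id = "t")
  at_node <- matrix(c(3000, 0, 0), 1)                  # exactly on a node
  expect_equal(near_synapses(at_node, tgt), 1L)
  far <- matrix(c(0, 1e6, 0), 1)
  expect_equal(near_synapses(far, tgt), 0L)
  set.seed(127)
  P <- matrix(runif(60, 0, 12000), ncol = 3)
  expect_equal(near_synapses(P, tgt, prediction_params(delta = 1e9)),
               nrow(P))                                # saturation
  tiny <- near_synapses(P, tgt, prediction_params(delta = 1e-6))
  expect_equal(tiny, 0L)
})

test_that("generated links are always recalled by the near-synapse model", {
  set.seed(131)
  src <- chain_skeleton(101, spacing = 1000, id = "s")
  tgt <- chain_skeleton(101, spacing = 1000, id = "t", y = 2000)
  gs <- generate_synapses(src, list(t = tgt), rate = 1, mean_polyadicity = 4,
                          link_delta = 4000)
  observed_conns <- length(unique(gs$connectors$connector_id))
  predicted <- near_synapses(gs$connectors, tgt,
                             prediction_params(delta = 4000))
  expect_gte(predicted, observed_conns)    # recall 1 by construction
})

test_that("cosine similarity behaves on identical, orthogonal and random data", {
  M <- matrix(rpois(40, 5), 8)
  expect_equal(unname(prediction_similarity(M, M)), 1)
  a <- rbind(c(1, 0), c(2, 0)); b <- rbind(c(0, 3), c(0, 1))
  expect_equal(unname(prediction_similarity(a, b)), 0)
  set.seed(137)
  P <- matrix(rexp(30), 5); O <- matrix(rexp(30), 5)
  direct <- sum(P * O) / sqrt(sum(P^2) * sum(O^2))
  expect_equal(unname(prediction_similarity(P, O)), direct)
  expect_warning(z <- prediction_similarity(matrix(0, 2, 2), matrix(1, 2, 2)))
  expect_true(is.na(z))
})

test_that("filling fractions recover planted fill rates and separate groups", {
  expect_equal(filling_fraction(c(5, 8), c(5, 8))$mean, 1)  # fully realized
  expect_equal(filling_fraction(c(5, 8), c(0, 0))$mean, 0)
  set.seed(139)
  n <- 120
  near <- rpois(2 * n, 60) + 1
  fill <- rep(c(0.8, 0.2), each = n)
  obs <- rbinom(2 * n, near, fill)
  grp <- rep(c("KC", "LHLN"), each = n)
  ff <- filling_fraction(near, obs, grp)
  expect_lt(abs(ff$mean[ff$group == "KC"] - 0.8), 0.05)
  expect_lt(abs(ff$mean[ff$group == "LHLN"] - 0.2), 0.05)
  i <- grp == "KC"
  wt <- weighted_t_test(obs[i] / near[i], near[i],
                        obs[!i] / near[!i], near[!i])
  expect_lt(wt$p_value, 1e-6)
  # zero-prediction pairs are excluded and reported
  ff2 <- filling_fraction(c(0, 10), c(0, 5))
  expect_equal(ff2$n_excluded, 1L)
})
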