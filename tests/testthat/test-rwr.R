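test_that("walk parameter validation enforces the probability constraints", {
  net <- toy_het_net()
  cfg <- rwr_config(net)
  expect_equal(cfg$r, 0.7)
  expect_equal(as.numeric(cfg$eta), c(0.5, 0.5))
  expect_equal(cfg$lam, matrix(0.5, 2, 2))
  expect_equal(as.numeric(cfg$delta), c(0.5, 0.5))
  expect_equal(cfg$tau$g, c(0.5, 0.5))
  expect_equal(cfg$tau$d, 1)
  expect_error(rwr_config(net, eta = c(0.5, 0.2)), "summing to 1")
  expect_error(rwr_config(net, lam = matrix(c(1, 0.5, 0, 0.2), 2, 2)),
               "rows summing to 1")
  expect_error(rwr_config(net, tau = list(c(0.7, 0.2), 1)), "summing to 1")
  expect_error(rwr_config(net, r = 0), "r must be")
  expect_error(rwr_config(net, r = 1.2), "r must be")
})

test_that("path graph operator is the hand-built 2x2 swap", {
  net <- path2_net()
  op <- build_transition_operator(net, rwr_config(net))
  expect_equal(as.matrix(op$M), matrix(c(0, 1, 1, 0), 2, 2),
               ignore_attr = TRUE)
  expect_equal(op$dangling, c(0, 0))
})

test_that("operator columns are stochastic and dangling mass is accounted", {
  for (seed in 1:5) {
    net <- random_small_net(seed)
    op <- build_transition_operator(net, rwr_config(net))
    expect_lt(max(abs(Matrix::colSums(op$M) + op$dangling - 1)), 1e-12)
    expect_true(all(op$M@x >= 0))
  }
})

test_that("a node isolated in every layer forwards all mass to restart", {
  lg <- layer_graph(data.frame(from = "a", to = "b"))
  m <- multiplex("m", list(lg), nodes = c("a", "b", "zzz"))
  net <- multilayer_network(list(m))
  op <- build_transition_operator(net, rwr_config(net))
  col <- which(net$nodes$local_id == "zzz")
  expect_equal(op$dangling[col], 1)
  expect_equal(Matrix::colSums(op$M)[col], 0, ignore_attr = TRUE)
  # with dangling routed to restart the materialized operator is stochastic
  s <- build_restart_vector(op, "m::a")
  expect_equal(colSums(transition_matrix(op, s)), rep(1, 3),
               ignore_attr = TRUE)
})

test_that("an all-empty network is rejected as degenerate", {
  m <- multiplex("m", list(layer_graph(data.frame(from = character(),
                                                  to = character()))),
                 nodes = c("a", "b"))
  net <- multilayer_network(list(m))
  expect_error(build_transition_operator(net, rwr_config(net)), "degenerate")
})

test_that("restart vector spreads seed mass over layers by tau", {
  g <- generate_planted_network(planted_spec(), seed = 2)
  op <- build_transition_operator(g$network, rwr_config(g$network))
  s <- build_restart_vector(op, "gene::gene_001")
  expect_equal(sum(s), 1)
  expect_equal(sort(unique(s[s > 0])), 1 / 3)   # 3 gene layers, tau uniform
  expect_equal(sum(s > 0), 3)
  s2 <- build_restart_vector(op, "disease::disease_002")
  expect_equal(s2[s2 > 0], c(0.5, 0.5), ignore_attr = TRUE)
  expect_error(build_restart_vector(op, "gene::nope"), "unknown seed")
  # monoplex: all mass on the single replica
  net1 <- path2_net()
  op1 <- build_transition_operator(net1, rwr_config(net1))
  expect_equal(build_restart_vector(op1, "m::b"), c(0, 1))
})

test_that("restart-only walk returns the restart distribution", {
  net <- toy_het_net()
  op <- build_transition_operator(net, rwr_config(net, r = 1))
  s <- build_restart_vector(op, "g::g1")
  expect_equal(rwr_stationary(op, s), s, ignore_attr = TRUE)
  S <- similarity_matrix(net, rwr_config(net, r = 1))
  expect_equal(unname(S), diag(n_nodes(net)))
})

test_that("path graph stationary distribution matches the closed form", {
  net <- path2_net()
  cfg <- rwr_config(net, r = 0.5)
  op <- build_transition_operator(net, cfg)
  x <- rwr_stationary(op, build_restart_vector(op, "m::a"))
  # solve (I - 0.5 [[0,1],[1,0]]) x = 0.5 e_a  ->  x = (2/3, 1/3)
  expect_l1_close(x, c(2 / 3, 1 / 3), 1e-7)
})

test_that("power iteration conserves mass at every step", {
  net <- random_small_net(11)
  op <- build_transition_operator(net, rwr_config(net))
  s <- build_restart_vector(op, net$nodes$id[1])
  x <- s
  for (i in 1:25) {
    x <- 0.3 * (as.numeric(op$M %*% x) + s * sum(op$dangling * x)) + 0.7 * s
    expect_lt(abs(sum(x) - 1), 1e-10)
  }
})

test_that("power iteration matches the direct linear solve", {
  for (seed in 1:6) {
    net <- random_small_net(seed + 100)
    cfg <- rwr_config(net, tol = 1e-12)
    op <- build_transition_operator(net, cfg)
    expect_lte(op$n_replicas, 60)
    s <- build_restart_vector(op, net$nodes$id[2])
    expect_l1_close(rwr_stationary(op, s), rwr_solve_oracle(op, s, cfg$r),
                    1e-6)
  }
})

test_that("monoplex walk reduces to personalized PageRank", {
  skip_if_not_installed("igraph")
  for (seed in 1:4) {
    set.seed(seed)
    n <- 12
    pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
    keep <- runif(nrow(pr)) < 0.3
    ids <- paste0("v", seq_len(n))
    lg <- layer_graph(data.frame(from = ids[pr[keep, 1]],
                                 to = ids[pr[keep, 2]]))
    net <- multilayer_network(list(multiplex("g", list(lg), nodes = ids)))
    cfg <- rwr_config(net, tol = 1e-14)
    op <- build_transition_operator(net, cfg)
    mine <- aggregate_to_nodes(op, rwr_stationary(op, build_restart_vector(op, "g::v3")))
    ig <- igraph::graph_from_data_frame(lg$edges[, 1:2], directed = FALSE,
                                        vertices = ids)
    ppr <- igraph::page_rank(ig, damping = 1 - cfg$r,
                             personalized = as.numeric(ids == "v3"),
                             weights = lg$edges$weight)$vector
    expect_l1_close(mine, ppr[sub("g::", "", names(mine))], 1e-8)
  }
})

test_that("replica aggregation sums a node's layer masses", {
  net <- toy_het_net()   # g has 2 layers over 4 nodes, d has 1 layer
  op <- build_transition_operator(net, rwr_config(net))
  x <- numeric(op$n_replicas)
  x[1] <- 0.1; x[5] <- 0.2    # g1 in layer 1 and layer 2
  x[9] <- 0.7                 # d1
  agg <- aggregate_to_nodes(op, x)
  expect_equal(agg[["g::g1"]], 0.3)
  expect_equal(agg[["d::d1"]], 0.7)
  expect_equal(sum(agg), 1)
})

test_that("similarity rows are distributions regardless of walk order", {
  net <- toy_het_net()
  S <- similarity_matrix(net)
  expect_lt(max(abs(rowSums(S) - 1)), 1e-8)
  expect_true(all(S >= 0))
  # row-wise recomputation in reverse order gives identical rows
  op <- build_transition_operator(net, rwr_config(net))
  for (v in rev(seq_len(n_nodes(net)))) {
    row <- aggregate_to_nodes(op, rwr_stationary(
      op, build_restart_vector(op, net$nodes$id[v])))
    expect_equal(row, S[v, ])
  }
})

test_that("non-convergence raises a warning carrying the residual", {
  net <- toy_het_net()
  cfg <- rwr_config(net, tol = 1e-15, max_iter = 3)
  op <- build_transition_operator(net, cfg)
  s <- build_restart_vector(op, "g::g1")
  expect_warning(x <- rwr_stationary(op, s), "not converged")
  expect_true(is.finite(attr(x, "residual")))
})
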