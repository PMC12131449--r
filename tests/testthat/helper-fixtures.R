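# In-code fixtures shared across test files.

# path a - b as a one-layer monoplex
path2_net <- function() {
  lg <- layer_graph(data.frame(from = "a", to = "b"))
  multilayer_network(list(multiplex("m", list(lg))))
}

# small two-multiplex network with a bipartite: 2-layer "g" over 4 nodes,
# 1-layer "d" over 3 nodes
toy_het_net <- function() {
  g1 <- layer_graph(data.frame(from = c("g1", "g2", "g3"),
                               to = c("g2", "g3", "g4")))
  g2 <- layer_graph(data.frame(from = c("g1", "g2"), to = c("g3", "g4")))
  d1 <- layer_graph(data.frame(from = c("d1", "d2"), to = c("d2", "d3")))
  bp <- bipartite("gd", "g", "d",
                  data.frame(from = c("g1", "g2", "g4"),
                             to = c("d1", "d2", "d3")))
  multilayer_network(list(multiplex("g", list(g1, g2)),
                          multiplex("d", list(d1))), list(bp))
}

# random multiplex-heterogeneous network with <= 60 replicas
random_small_net <- function(seed) {
  set.seed(seed)
  rand_layer <- function(ids, p = 0.45) {
    pr <- which(upper.tri(diag(length(ids))), arr.ind = TRUE)
    keep <- runif(nrow(pr)) < p
    if (!any(keep)) keep[sample.int(nrow(pr), 1)] <- TRUE
    layer_graph(data.frame(from = ids[pr[keep, 1]], to = ids[pr[keep, 2]]))
  }
  na <- sample(4:8, 1); nb <- sample(3:6, 1)
  aids <- paste0("a", seq_len(na)); bids <- paste0("b", seq_len(nb))
  A <- multiplex("A", lapply(1:2, function(i) rand_layer(aids)), nodes = aids)
  B <- multiplex("B", list(rand_layer(bids)), nodes = bids)
  nbp <- max(2, rbinom(1, na * nb, 0.3))
  pairs <- expand.grid(from = aids, to = bids, stringsAsFactors = FALSE)
  bp <- bipartite("ab", "A", "B", pairs[sample.int(nrow(pairs), nbp), ])
  multilayer_network(list(A, B), list(bp))
}

# dense-matrix fixed point oracle: solve (I - (1-r) M) x = r s with dangling
# mass routed to the restart vector
rwr_solve_oracle <- function(op, s, r) {
  M <- as.matrix(op$M) + outer(as.numeric(s), op$dangling)
  as.numeric(solve(diag(length(s)) - (1 - r) * M, r * s))
}

# small planted monoplex spec with two communities
two_community_spec <- function(n = 30L, p_in = 0.4, p_out = 0.02) {
  planted_spec(
    multiplexes = data.frame(name = "m", n = n, layers = 1L,
                             p_in = p_in, p_out = p_out),
    bipartites = data.frame(name = character(), left = character(),
                            right = character(), q_in = numeric(),
                            q_out = numeric()),
    C = 2L)
}

expect_l1_close <- function(x, y, tol) {
  expect_lt(sum(abs(as.numeric(x) - as.numeric(y))), tol)
}
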