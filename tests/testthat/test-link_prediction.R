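test_that("bipartite splits are exact partitions with the stated counts", {
  g <- generate_planted_network(planted_spec(), seed = 6)
  net <- g$network
  sp <- split_bipartite_edges(net, 0.3, seed = 1)
  for (b in names(net$bipartites)) {
    orig <- net$bipartites[[b]]$edges
    trn <- sp$train_network$bipartites[[b]]$edges
    tst <- sp$test_positives[[b]]
    expect_equal(nrow(tst), round(0.3 * nrow(orig)))
    key <- function(e) paste(e$from, e$to)
    expect_length(intersect(key(trn), key(tst)), 0)
    expect_setequal(c(key(trn), key(tst)), key(orig))
  }
  # multiplex layers untouched
  expect_identical(sp$train_network$multiplexes, net$multiplexes)

  sp0 <- split_bipartite_edges(net, 0, seed = 1)
  expect_true(all(vapply(sp0$test_positives, nrow, integer(1)) == 0))
  expect_error(split_bipartite_edges(net, 1), "fraction")
  expect_error(split_bipartite_edges(net, -0.1), "fraction")
})

test_that("edge operators compute the standard pair features", {
  E <- rbind(u = c(1, 2), v = c(3, 4), w = c(3, 0), x = c(1, 0), y = c(0, 1),
             z = c(0, 0))
  pr <- function(a, b) data.frame(from = a, to = b)
  expect_equal(as.numeric(edge_features(E, pr("u", "v"), "hadamard")), c(3, 8))
  expect_equal(as.numeric(edge_features(E, pr("u", "v"), "average")), c(2, 3))
  expect_equal(as.numeric(edge_features(E, pr("u", "w"), "weighted_l1")),
               c(2, 2))
  expect_equal(as.numeric(edge_features(E, pr("u", "w"), "weighted_l2")),
               c(4, 4))
  expect_equal(as.numeric(edge_features(E, pr("x", "y"), "cosine")), 0)
  expect_equal(as.numeric(edge_features(E, pr("x", "z"), "cosine")), 0)
  expect_error(edge_features(E, pr("u", "v"), "minkowski"), "unknown operator")
  expect_error(edge_features(E, pr("u", "nope"), "hadamard"), "not embedded")
})

test_that("edge operators are symmetric in their endpoints", {
  set.seed(4)
  E <- matrix(rnorm(20), 5, 4, dimnames = list(letters[1:5], NULL))
  pairs <- data.frame(from = c("a", "b", "c"), to = c("d", "e", "a"))
  rev <- data.frame(from = pairs$to, to = pairs$from)
  for (op in c("hadamard", "weighted_l1", "weighted_l2", "average", "cosine"))
    expect_equal(edge_features(E, pairs, op), edge_features(E, rev, op))
})

test_that("non-edge sampling avoids the full edge set exactly", {
  net <- toy_het_net()   # gd bipartite: 3 of 12 possible pairs are edges
  set.seed(2)
  ne <- sample_nonedges(net, "gd", 9)
  expect_equal(nrow(ne), 9)
  key <- paste(ne$from, ne$to)
  expect_equal(anyDuplicated(key), 0)
  ek <- paste(net$bipartites$gd$edges$from, net$bipartites$gd$edges$to)
  expect_length(intersect(key, ek), 0)
  expect_error(sample_nonedges(net, "gd", 10), "available")
  expect_error(sample_nonedges(net, "nope", 1), "unknown bipartite")
  # exclusion list is honoured
  ne2 <- sample_nonedges(net, "gd", 5, exclude = ne[1:4, ])
  expect_length(intersect(paste(ne2$from, ne2$to), key[1:4]), 0)
})

test_that("rank-statistic AUC matches pROC and its limits", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(roc_auc(c(3, 2, 1), c(0, 0, 1)), 0)
  expect_equal(roc_auc(c(1, 1, 1, 1), c(0, 1, 0, 1)), 0.5)  # all ties
  skip_if_not_installed("pROC")
  set.seed(9)
  sc <- rnorm(100); y <- rbinom(100, 1, 0.4)
  expect_equal(roc_auc(sc, y),
               as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))))
})

test_that("null AUC concentrates near one half", {
  set.seed(3)
  aucs <- replicate(20, roc_auc(rnorm(200), rbinom(200, 1, 0.5)))
  expect_true(all(aucs > 0.35 & aucs < 0.65))
  expect_gt(mean(aucs > 0.4 & aucs < 0.6), 0.8)
})

test_that("the evaluation protocol runs end-to-end and is reproducible", {
  spec <- planted_spec(
    multiplexes = data.frame(name = c("g", "d"), n = c(45L, 30L),
                             layers = c(2L, 1L), p_in = 0.3, p_out = 0.02),
    bipartites = data.frame(name = "gd", left = "g", right = "d",
                            q_in = 0.3, q_out = 0.005),
    C = 3L)
  net <- generate_planted_network(spec, seed = 10)$network
  p <- train_params(n_nodes(net), d = 8L)
  res <- evaluate_link_prediction(net, params = p, repetitions = 2L, seed = 3L)
  expect_s3_class(res, "link_prediction_result")
  expect_equal(nrow(res), 5)             # 1 bipartite x 5 operators
  expect_true(all(res$mean_auc >= 0 & res$mean_auc <= 1))
  expect_true(all(res$sd_auc >= 0))
  expect_equal(unique(res$repetitions), 2L)
  res2 <- evaluate_link_prediction(net, params = p, repetitions = 2L, seed = 3L)
  expect_equal(res$mean_auc, res2$mean_auc)
  # the planted signal is learnable above chance on the informative operators
  expect_gt(max(res$mean_auc), 0.6)
})

test_that("undersized bipartites are skipped with a warning", {
  g1 <- layer_graph(data.frame(from = c("a", "b"), to = c("b", "c")))
  d1 <- layer_graph(data.frame(from = c("x", "y"), to = c("y", "z")))
  bp <- bipartite("tiny", "g", "d", data.frame(from = c("a", "b"),
                                               to = c("x", "y")))
  net <- multilayer_network(list(multiplex("g", list(g1)),
                                 multiplex("d", list(d1))), list(bp))
  expect_error(expect_warning(
    evaluate_link_prediction(net, params = train_params(6L, d = 2L, s = 2L)),
    "fewer than 4"), "no usable bipartite")
})

test_that("held-out positives never reach the embedded training network", {
  g <- generate_planted_network(planted_spec(), seed = 13)
  sp <- split_bipartite_edges(g$network, 0.3, seed = 2)
  for (b in names(sp$test_positives)) {
    trn <- sp$train_network$bipartites[[b]]$edges
    tst <- sp$test_positives[[b]]
    expect_length(intersect(paste(trn$from, trn$to),
                            paste(tst$from, tst$to)), 0)
  }
})
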