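# Link-prediction evaluation over held-out bipartite edges: remove a
# fraction of every bipartite's edges, embed the training network, featurize
# node pairs with edge operators, and score a random-forest classifier by
# ROC-AUC on the held-out positives versus sampled non-edges.

EDGE_OPERATORS <- c("hadamard", "weighted_l1", "weighted_l2", "average",
                    "cosine")

#' Split bipartite edges into train and test sets
#'
#' Uniformly samples `round(fraction * m)` test edges per bipartite, without
#' replacement; multiplex layers are untouched. The returned training
#' network is the input with test edges removed from its bipartites.
#'
#' @param net a [multilayer_network()].
#' @param fraction fraction of edges held out per bipartite, in \[0, 1).
#' @param seed RNG seed.
#' @return list of class `split_result`: `train_network`, `test_positives`
#'   (per-bipartite data.frames of held-out edges), `fraction`, `seed`.
#' @export
split_bipartite_edges <- function(net, fraction = 0.3, seed = 1L) {
  if (!(fraction >= 0 && fraction < 1))
    stop("split_bipartite_edges: fraction must be in [0, 1)")
  set.seed(seed)
  test <- list()
  bps <- lapply(net$bipartites, function(b) {
    m <- nrow(b$edges)
    ntest <- round(fraction * m)
    idx <- sort(sample.int(m, ntest))
    test[[b$name]] <<- b$edges[idx, , drop = FALSE]
    bipartite(b$name, b$left, b$right, b$edges[setdiff(seq_len(m), idx), ,
                                               drop = FALSE])
  })
  structure(list(train_network = multilayer_network(net$multiplexes, bps),
                 test_positives = test, fraction = fraction, seed = seed),
            class = "split_result")
}

#' Edge features from node embeddings
#'
#' Combines the embeddings of the two endpoints of each pair: `hadamard`
#' (elementwise product), `weighted_l1` (`|w_u - w_v|`), `weighted_l2`
#' (`(w_u - w_v)^2`), `average` (elementwise mean) — each d-dimensional —
#' or `cosine` (scalar `w_u.w_v / (|w_u||w_v|)`, 0 if either norm is 0).
#'
#' @param E embedding matrix with node ids as rownames.
#' @param pairs data.frame with columns `from`, `to` of node ids.
#' @param op operator name, one of `r paste(EDGE_OPERATORS, collapse = ", ")`.
#' @return numeric feature matrix, one row per pair.
#' @export
edge_features <- function(E, pairs, op) {
  if (!op %in% EDGE_OPERATORS)
    stop("edge_features: unknown operator '", op, "'")
  miss <- setdiff(unique(c(pairs$from, pairs$to)), rownames(E))
  if (length(miss))
    stop("edge_features: pair endpoints not embedded: ",
         paste(head(miss, 5), collapse = ", "))
  U <- E[pairs$from, , drop = FALSE]
  V <- E[pairs$to, , drop = FALSE]
  rownames(U) <- rownames(V) <- NULL
  switch(op,
    hadamard = U * V,
    weighted_l1 = abs(U - V),
    weighted_l2 = (U - V)^2,
    average = (U + V) / 2,
    cosine = {
      nu <- sqrt(rowSums(U^2)); nv <- sqrt(rowSums(V^2))
      cs <- rowSums(U * V) / (nu * nv)
      cs[nu == 0 | nv == 0] <- 0
      matrix(cs, ncol = 1)
    })
}

# bipartite edges as namespaced global-id pairs
bip_pairs_global <- function(b, edges = b$edges) {
  data.frame(from = paste0(b$left, "::", edges$from),
             to = paste0(b$right, "::", edges$to),
             stringsAsFactors = FALSE)
}

#' Sample non-edges of a bipartite
#'
#' Uniform distinct (left, right) pairs absent from the bipartite's full
#' edge set, optionally also excluding previously drawn pairs.
#'
#' @param net a [multilayer_network()] (the full, pre-split network).
#' @param bipartite_name which bipartite.
#' @param count number of non-edges to draw.
#' @param exclude optional data.frame of additional local-id pairs to avoid.
#' @return data.frame of local-id pairs (`from` on the left side).
#' @export
sample_nonedges <- function(net, bipartite_name, count, exclude = NULL) {
  b <- net$bipartites[[bipartite_name]]
  if (is.null(b)) stop("sample_nonedges: unknown bipartite '", bipartite_name, "'")
  lids <- net$multiplexes[[b$left]]$nodes
  rids <- net$multiplexes[[b$right]]$nodes
  npairs <- length(lids) * length(rids)
  forbidden <- paste(b$edges$from, b$edges$to, sep = "\r")
  if (!is.null(exclude) && nrow(exclude))
    forbidden <- c(forbidden, paste(exclude$from, exclude$to, sep = "\r"))
  if (count > npairs - length(unique(forbidden)))
    stop("sample_nonedges: requested ", count, " non-edges but only ",
         npairs - length(unique(forbidden)), " available")
  got <- character(0)
  from <- character(0); to <- character(0)
  while (length(got) < count) {
    need <- count - length(got)
    li <- sample(lids, 2 * need + 10, replace = TRUE)
    ri <- sample(rids, 2 * need + 10, replace = TRUE)
    key <- paste(li, ri, sep = "\r")
    ok <- !(key %in% forbidden) & !(key %in% got) & !duplicated(key)
    take <- which(ok)[seq_len(min(need, sum(ok)))]
    got <- c(got, key[take])
    from <- c(from, li[take]); to <- c(to, ri[take])
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

#' ROC-AUC by the rank statistic
#'
#' Mann-Whitney form on predicted scores, ties averaged.
#'
#' @param scores numeric predictions; @param labels 0/1 truth.
#' @return scalar AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate link prediction on held-out bipartite edges
#'
#' Per repetition: split each bipartite, compute RWR similarity and train
#' embeddings on the training network only, then for every bipartite and
#' edge operator fit a random-forest classifier (100 trees) on training
#' edges versus an equal number of sampled non-edges, and compute ROC-AUC on
#' the held-out positives versus fresh non-edges (disjoint from the training
#' negatives). Results are aggregated as mean and standard deviation over
#' repetitions.
#'
#' @param net a [multilayer_network()] with at least one bipartite.
#' @param cfg an [rwr_config()]; defaults to `rwr_config(net)`.
#' @param params a [train_params()]; defaults to `train_params(n_nodes(net))`.
#' @param fraction held-out fraction per bipartite (default 0.3).
#' @param repetitions number of repetitions (default 10).
#' @param seed root seed; per-repetition seeds are derived from it.
#' @param operators subset of edge operators to evaluate.
#' @param num_trees random-forest size.
#' @return `link_prediction_result`: data.frame with one row per
#'   (bipartite, operator): `mean_auc`, `sd_auc`, `repetitions`; the per-
#'   repetition AUCs are kept in `attr(, "per_rep")`.
#' @export
evaluate_link_prediction <- function(net, cfg = rwr_config(net),
                                     params = train_params(n_nodes(net)),
                                     fraction = 0.3, repetitions = 10L,
                                     seed = 1L, operators = EDGE_OPERATORS,
                                     num_trees = 100L) {
  if (length(net$bipartites) == 0)
    stop("evaluate_link_prediction: network has no bipartites")
  use <- vapply(net$bipartites, function(b) nrow(b$edges) >= 4, logical(1))
  for (b in names(use)[!use])
    warning("evaluate_link_prediction: bipartite '", b,
            "' has fewer than 4 edges; skipped")
  bnames <- names(use)[use]
  if (length(bnames) == 0) stop("evaluate_link_prediction: no usable bipartite")
  aucs <- array(NA_real_, dim = c(repetitions, length(bnames), length(operators)),
                dimnames = list(NULL, bnames, operators))
  for (rep in seq_len(repetitions)) {
    rep_seed <- seed * 1000L + rep
    split <- split_bipartite_edges(net, fraction, seed = rep_seed)
    simG <- similarity_matrix(split$train_network, cfg)
    p <- params
    p$seed <- rep_seed
    E <- train_embedding(simG, p)$embedding
    set.seed(rep_seed + 500L)
    for (b in bnames) {
      bp <- net$bipartites[[b]]
      train_pos <- split$train_network$bipartites[[b]]$edges
      test_pos <- split$test_positives[[b]]
      train_neg <- sample_nonedges(net, b, nrow(train_pos))
      test_neg <- sample_nonedges(net, b, nrow(test_pos), exclude = train_neg)
      trn <- rbind(bip_pairs_global(bp, train_pos), bip_pairs_global(bp, train_neg))
      tst <- rbind(bip_pairs_global(bp, test_pos), bip_pairs_global(bp, test_neg))
      y_trn <- factor(rep(c(1, 0), c(nrow(train_pos), nrow(train_neg))))
      y_tst <- rep(c(1, 0), c(nrow(test_pos), nrow(test_neg)))
      for (op in operators) {
        Xtr <- as.data.frame(edge_features(E, trn, op))
        Xte <- as.data.frame(edge_features(E, tst, op))
        colnames(Xte) <- colnames(Xtr)
        fit <- ranger::ranger(x = Xtr, y = y_trn, num.trees = num_trees,
                              probability = TRUE, seed = rep_seed,
                              num.threads = 1)
        prob <- predict(fit, Xte, num.threads = 1)$predictions[, "1"]
        aucs[rep, b, op] <- roc_auc(prob, y_tst)
      }
    }
  }
  res <- expand.grid(bipartite = bnames, operator = operators,
                     stringsAsFactors = FALSE)
  res$mean_auc <- mapply(function(b, o) mean(aucs[, b, o]),
                         res$bipartite, res$operator)
  res$sd_auc <- mapply(function(b, o) sd(aucs[, b, o]),
                       res$bipartite, res$operator)
  res$repetitions <- repetitions
  structure(res, per_rep = aucs, class = c("link_prediction_result",
                                           "data.frame"))
}

#' @export
print.link_prediction_result <- function(x, ...) {
  cat(sprintf("link prediction: ROC-AUC over %d repetition(s)\n",
              x$repetitions[1]))
  wide <- tapply(sprintf("%.3f +/- %.3f", x$mean_auc, x$sd_auc),
                 list(x$operator, x$bipartite), identity)
  print(wide, quote = FALSE)
  invisible(x)
}
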