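# Embedding of the RWR similarity by noise-contrastive estimation.
#
# The target is the KL divergence between the graph similarity sim_G(v,.)
# and the softmax similarity of the embedding space,
#   sim_Emb(v,.) = exp(w_v . w) / sum_i exp(w_v . w_i),
# minimized sample-wise: NCE trains a logistic discriminator between pairs
# (u, v) with u ~ P (uniform) and v ~ sim_G(u,.) and s noise pairs with
# v ~ Q (uniform), using the unnormalized dot product as the score. A single
# shared embedding matrix is used; the softmax is only materialized for
# diagnostics.

#' Default embedding training parameters
#'
#' @param n_nodes number of nodes to be embedded (sets the default step
#'   count, 1400 samples per node).
#' @param d embedding dimension.
#' @param steps number of SGD samples.
#' @param lr,lr_min initial learning rate and its linear-decay floor.
#' @param s negative samples per positive.
#' @param seed RNG seed; all sampling is reproducible given the seed.
#' @param n_probe,n_checkpoints size of the fixed Monte-Carlo probe set used
#'   for the loss trajectory and number of checkpoints recorded.
#' @return list of class `train_params`.
#' @export
train_params <- function(n_nodes, d = 128L, steps = 1400L * n_nodes,
                         lr = 0.025, lr_min = 1e-4, s = 3L, seed = 42L,
                         n_probe = 200L, n_checkpoints = 11L) {
  stopifnot(d >= 2, steps >= 1, lr > 0, s >= 1, s < n_nodes)
  structure(list(d = as.integer(d), steps = as.integer(steps), lr = lr,
                 lr_min = lr_min, s = as.integer(s), seed = as.integer(seed),
                 n_probe = as.integer(n_probe),
                 n_checkpoints = as.integer(n_checkpoints)),
            class = "train_params")
}

#' Initialize an embedding matrix
#'
#' Entries i.i.d. uniform in `[-0.5/d, 0.5/d]` (the usual word2vec-style
#' scale), deterministic for a fixed seed.
#'
#' @param n number of nodes; @param d dimension; @param seed optional seed
#'   (when `NULL` the current RNG state is used).
#' @return `n x d` numeric matrix.
#' @export
init_embedding <- function(n, d, seed = NULL) {
  stopifnot(n >= 1, d >= 1)
  if (!is.null(seed)) set.seed(seed)
  matrix(runif(n * d, -0.5 / d, 0.5 / d), nrow = n, ncol = d)
}

#' Sample a node from one similarity row
#'
#' Inverse-CDF sampling on the row's cumulative sums; deterministic given the
#' RNG state. The row must be normalized.
#'
#' @param row nonnegative numeric vector summing to 1 (within 1e-6).
#' @return the sampled index (named if `row` is named).
#' @export
sample_positive <- function(row) {
  if (abs(sum(row) - 1) > 1e-6)
    stop("sample_positive: row is not normalized (sum = ", format(sum(row)), ")")
  cum <- cumsum(row)
  cum[length(cum)] <- 1
  idx <- sum(cum < runif(1)) + 1L
  if (!is.null(names(row))) names(idx) <- names(row)[idx]
  idx
}

log_sigmoid <- function(x) ifelse(x >= 0, -log1p(exp(-x)), x - log1p(exp(x)))

#' One NCE gradient step
#'
#' Given a source node `u`, a positive `v_pos` and negatives `v_negs`, takes
#' one gradient-ascent step on
#' `log sigma(w_u . w_pos) + sum log(1 - sigma(w_u . w_neg))`, updating both
#' endpoints of every pair simultaneously (all gradients evaluated at the
#' pre-update point), and returns the pre-update sampled loss (the negative
#' log-likelihood of that sample).
#'
#' @param E embedding matrix (rows = nodes).
#' @param u,v_pos row indices; @param v_negs integer vector of row indices.
#' @param lr learning rate.
#' @return list with the updated `embedding` and the scalar `loss`.
#' @export
nce_update <- function(E, u, v_pos, v_negs, lr) {
  sig <- function(x) 1 / (1 + exp(-x))
  dpos <- sum(E[u, ] * E[v_pos, ])
  gpos <- 1 - sig(dpos)
  dneg <- as.numeric(E[v_negs, , drop = FALSE] %*% E[u, ])
  gneg <- -sig(dneg)
  loss <- -log_sigmoid(dpos) - sum(log_sigmoid(-dneg))
  gu <- gpos * E[v_pos, ] +
    as.numeric(crossprod(E[v_negs, , drop = FALSE], gneg))
  old_u <- E[u, ]
  for (q in seq_along(v_negs))
    E[v_negs[q], ] <- E[v_negs[q], ] + lr * gneg[q] * old_u
  E[v_pos, ] <- E[v_pos, ] + lr * gpos * old_u
  E[u, ] <- E[u, ] + lr * gu
  list(embedding = E, loss = loss)
}

#' Train node embeddings against a similarity matrix
#'
#' Runs `steps` NCE samples: draw `u` uniformly, a positive from
#' `sim_G(u,.)`, `s` uniform negatives, and one [nce_update()] step, with the
#' learning rate decaying linearly from `lr` to `lr_min`. Deterministic for a
#' fixed seed. The returned report holds the NCE loss on a fixed probe set at
#' evenly spaced checkpoints.
#'
#' @param simmat similarity matrix (rows = seed nodes, each row a probability
#'   distribution; rownames are node ids).
#' @param params a [train_params()] list.
#' @param engine `"cpp"` (default) or `"reference"`, a pure-R loop drawing
#'   the identical sample sequence (for verification; slow).
#' @return list with `embedding` (matrix, rownames = node ids) and `report`
#'   (data.frame of checkpoint step and probe loss).
#' @export
train_embedding <- function(simmat, params = train_params(nrow(simmat)),
                            engine = c("cpp", "reference")) {
  engine <- match.arg(engine)
  stopifnot(is.matrix(simmat), nrow(simmat) == ncol(simmat))
  if (any(abs(rowSums(simmat) - 1) > 1e-6))
    stop("train_embedding: similarity rows must each sum to 1")
  n <- nrow(simmat)
  set.seed(params$seed)
  E0 <- init_embedding(n, params$d)
  cum <- t(apply(simmat, 1, cumsum))
  cum[, n] <- 1
  if (engine == "cpp") {
    fit <- nce_train_cpp(E0, t(cum), params$steps, params$s, params$lr,
                         params$lr_min, params$n_probe, params$n_checkpoints)
    E <- fit$embedding
    report <- data.frame(step = fit$checkpoint, loss = fit$loss)
  } else {
    draw_node <- function() min(as.integer(floor(n * runif(1))) + 1L, n)
    draw_pos <- function(u) {
      x <- runif(1)
      min(sum(cum[u, ] < x) + 1L, n)
    }
    np <- params$n_probe
    pu <- integer(np); pv <- integer(np)
    pneg <- matrix(0L, np, params$s)
    for (p in seq_len(np)) {
      pu[p] <- draw_node()
      pv[p] <- draw_pos(pu[p])
      for (q in seq_len(params$s)) pneg[p, q] <- draw_node()
    }
    probe_loss <- function(E) {
      tot <- 0
      for (p in seq_len(np)) {
        dpos <- sum(E[pu[p], ] * E[pv[p], ])
        dneg <- as.numeric(E[pneg[p, ], , drop = FALSE] %*% E[pu[p], ])
        tot <- tot - log_sigmoid(dpos) - sum(log_sigmoid(-dneg))
      }
      tot / np
    }
    nck <- max(2L, params$n_checkpoints)
    ck <- round(seq(0, params$steps, length.out = nck))
    E <- E0
    losses <- numeric(nck)
    losses[1] <- probe_loss(E)
    next_ck <- 2L
    for (t in seq_len(params$steps)) {
      lr <- if (params$steps > 1)
        params$lr + (params$lr_min - params$lr) * (t - 1) / (params$steps - 1)
      else params$lr
      u <- draw_node()
      v <- draw_pos(u)
      negs <- vapply(seq_len(params$s), function(q) draw_node(), integer(1))
      E <- nce_update(E, u, v, negs, lr)$embedding
      while (next_ck <= nck && t == ck[next_ck]) {
        losses[next_ck] <- probe_loss(E)
        next_ck <- next_ck + 1L
      }
    }
    while (next_ck <= nck) {
      losses[next_ck] <- probe_loss(E)
      next_ck <- next_ck + 1L
    }
    report <- data.frame(step = ck, loss = losses)
  }
  rownames(E) <- rownames(simmat)
  list(embedding = E, report = report)
}

#' Softmax similarity of an embedding
#'
#' Materializes `sim_Emb(v,.)` for every node: the row-wise softmax of the
#' dot-product matrix. Exhaustive (O(n^2 d)); diagnostic use only.
#'
#' @param E embedding matrix.
#' @return row-stochastic matrix of the same node order.
#' @export
embedding_softmax <- function(E) {
  D <- E %*% t(E)
  D <- D - apply(D, 1, max)
  P <- exp(D)
  P / rowSums(P)
}

#' Total KL divergence between graph and embedding similarities
#'
#' `sum_v KL(sim_G(v,.) || sim_Emb(v,.))`, the exhaustive objective the NCE
#' training approximates.
#'
#' @param simmat graph similarity matrix (row-stochastic).
#' @param E embedding matrix in the same node order.
#' @return scalar divergence (nats).
#' @export
embedding_kl <- function(simmat, E) {
  Q <- embedding_softmax(E)
  pos <- simmat > 0
  sum(simmat[pos] * (log(simmat[pos]) - log(Q[pos])))
}
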