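# Random walk with restart on multiplex-heterogeneous networks.
#
# State space: one replica per (multiplex, layer, node). The walk operator is
# a column-stochastic map on replica distributions; mass that would be lost
# (isolated layer-copies, missing bipartite neighbours) is redirected to the
# restart distribution, which keeps every column stochastic.

#' Random-walk-with-restart parameters
#'
#' Holds the walk parameters of the universal multilayer walk: the global
#' restart probability `r`, the restart allocation across multiplexes `eta`,
#' the inter-multiplex jump matrix `lam` (row `k` gives the probability of
#' jumping from multiplex `k` into each multiplex, diagonal = stay), the
#' within-multiplex layer-jump probability `delta`, and the restart
#' allocation across layers `tau` (one vector per multiplex). Defaults:
#' `r = 0.7`, uniform `eta`, uniform `lam` rows, `delta = 0.5` everywhere,
#' uniform `tau` within each multiplex.
#'
#' @param net the [multilayer_network()] the parameters are sized for.
#' @param r restart probability in (0, 1].
#' @param eta numeric vector over multiplexes, summing to 1.
#' @param lam square matrix over multiplexes; rows sum to 1, entries >= 0.
#' @param delta scalar or per-multiplex vector in \[0, 1\].
#' @param tau list of per-multiplex vectors over that multiplex's layers,
#'   each summing to 1.
#' @param tol L1 convergence threshold for the power iteration.
#' @param max_iter iteration cap.
#' @return An object of class `rwr_config`.
#' @export
rwr_config <- function(net, r = 0.7, eta = NULL, lam = NULL, delta = 0.5,
                       tau = NULL, tol = 1e-8, max_iter = 1000L) {
  stopifnot(inherits(net, "multilayer_network"))
  K <- length(net$multiplexes)
  mnames <- names(net$multiplexes)
  nlayers <- vapply(net$multiplexes, function(m) length(m$layers), integer(1))
  if (is.null(eta)) eta <- rep(1 / K, K)
  eta <- as.numeric(unlist(eta))
  if (length(eta) != K || abs(sum(eta) - 1) > 1e-8 || any(eta < 0))
    stop("rwr_config: eta must be a length-", K, " nonnegative vector summing to 1")
  if (is.null(lam)) lam <- matrix(1 / K, K, K)
  if (is.list(lam)) lam <- do.call(rbind, lapply(lam, as.numeric))
  lam <- as.matrix(lam)
  if (!all(dim(lam) == c(K, K)) || any(lam < 0) ||
      any(abs(rowSums(lam) - 1) > 1e-8))
    stop("rwr_config: lam must be a ", K, "x", K,
         " nonnegative matrix with rows summing to 1")
  delta <- as.numeric(unlist(delta))
  if (length(delta) == 1) delta <- rep(delta, K)
  if (length(delta) != K || any(delta < 0 | delta > 1))
    stop("rwr_config: delta must be in [0,1], one value (or one per multiplex)")
  if (is.null(tau)) tau <- lapply(nlayers, function(L) rep(1 / L, L))
  tau <- lapply(tau, as.numeric)
  if (length(tau) != K) stop("rwr_config: tau must have one vector per multiplex")
  for (k in seq_len(K)) {
    if (length(tau[[k]]) != nlayers[k] || any(tau[[k]] < 0) ||
        abs(sum(tau[[k]]) - 1) > 1e-8)
      stop("rwr_config: tau[[", k, "]] must have ", nlayers[k],
           " nonnegative entries summing to 1")
  }
  if (!(r > 0 && r <= 1)) stop("rwr_config: r must be in (0, 1]")
  if (tol <= 0 || max_iter < 1) stop("rwr_config: tol > 0 and max_iter >= 1 required")
  structure(list(r = r, eta = setNames(eta, mnames), lam = lam,
                 delta = setNames(delta, mnames),
                 tau = setNames(tau, mnames),
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "rwr_config")
}

# column-normalized sparse adjacency of one layer over the multiplex node set;
# directed layers use out-edges (column i = distribution over i's successors)
layer_transition <- function(layer, nodes) {
  n <- length(nodes)
  idx <- seq_len(n)
  names(idx) <- nodes
  e <- layer$edges
  if (nrow(e) == 0) {
    A <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(n, n))
  } else if (layer$directed) {
    A <- Matrix::sparseMatrix(i = idx[e$to], j = idx[e$from], x = e$weight,
                              dims = c(n, n))
  } else {
    A <- Matrix::sparseMatrix(i = c(idx[e$to], idx[e$from]),
                              j = c(idx[e$from], idx[e$to]),
                              x = c(e$weight, e$weight), dims = c(n, n))
  }
  cs <- Matrix::colSums(A)
  dangling <- cs == 0
  cs[dangling] <- 1
  list(P = A %*% Matrix::Diagonal(n, 1 / cs), dangling = dangling)
}

#' Build the multilayer transition operator
#'
#' One application of the operator is one step of the walk from each replica
#' `(multiplex k, layer a, node i)`: row `k` of `lam` allocates mass across
#' multiplexes — mass sent to multiplex `j != k` moves along bipartite edges
#' from `i` (proportional to bipartite edge weight), landing on `j`'s layers
#' according to `tau[j]`; if `i` has no bipartite neighbour in `j` that mass
#' joins the stay-in-`k` branch. The stay branch walks to a weight-random
#' neighbour in the current layer with probability `1 - delta_k`, and with
#' probability `delta_k` first hops to a uniformly chosen other layer of `k`
#' (single-layer multiplexes never hop). Mass that hits an isolated
#' layer-copy is redirected to the restart distribution, so every column of
#' the implied matrix sums to 1.
#'
#' @param net a [multilayer_network()].
#' @param cfg an [rwr_config()].
#' @return An object of class `transition_operator`: a sparse matrix over
#'   replicas plus a per-column dangling-mass vector (redirected to restart),
#'   replica bookkeeping, and the node-aggregation map.
#' @export
build_transition_operator <- function(net, cfg) {
  stopifnot(inherits(net, "multilayer_network"), inherits(cfg, "rwr_config"))
  K <- length(net$multiplexes)
  mnames <- names(net$multiplexes)
  nn <- vapply(net$multiplexes, function(m) length(m$nodes), integer(1))
  LL <- vapply(net$multiplexes, function(m) length(m$layers), integer(1))
  total_edges <- sum(vapply(net$multiplexes, function(m)
    sum(vapply(m$layers, function(l) nrow(l$edges), integer(1))), integer(1))) +
    sum(vapply(net$bipartites, function(b) nrow(b$edges), integer(1)), 0L)
  if (total_edges == 0)
    stop("build_transition_operator: network has no edges anywhere (degenerate operator)")

  # replica layout: multiplexes in order; within multiplex, layer-major blocks
  rep_off <- c(0, cumsum(nn * LL))[seq_len(K)]     # replica offset per multiplex
  node_off <- c(0, cumsum(nn))[seq_len(K)]         # global node offset
  n_rep <- sum(nn * LL)
  rep_index <- function(k, a, i) rep_off[k] + (a - 1L) * nn[k] + i
  node_of_replica <- integer(n_rep)
  for (k in seq_len(K)) for (a in seq_len(LL[k]))
    node_of_replica[rep_index(k, a, seq_len(nn[k]))] <- node_off[k] + seq_len(nn[k])

  # per-layer column-normalized transitions
  LT <- lapply(seq_len(K), function(k)
    lapply(net$multiplexes[[k]]$layers, function(l)
      layer_transition(l, net$multiplexes[[k]]$nodes)))

  # column-normalized bipartite transitions for each ordered multiplex pair,
  # merging all bipartites connecting the pair (weight-proportional; uniform
  # for the default unit weights)
  BT <- vector("list", K)
  for (k in seq_len(K)) BT[[k]] <- vector("list", K)
  midx <- setNames(seq_len(K), mnames)
  for (k in seq_len(K)) for (j in seq_len(K)) {
    if (j == k) next
    src <- net$multiplexes[[k]]$nodes
    dst <- net$multiplexes[[j]]$nodes
    si <- setNames(seq_along(src), src)
    di <- setNames(seq_along(dst), dst)
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    for (b in net$bipartites) {
      if (b$left == mnames[k] && b$right == mnames[j]) {
        ii <- c(ii, di[b$edges$to]); jj <- c(jj, si[b$edges$from])
        xx <- c(xx, b$edges$weight)
      } else if (b$left == mnames[j] && b$right == mnames[k]) {
        ii <- c(ii, di[b$edges$from]); jj <- c(jj, si[b$edges$to])
        xx <- c(xx, b$edges$weight)
      }
    }
    B <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                              dims = c(nn[j], nn[k]))
    cs <- Matrix::colSums(B)
    nonb <- cs == 0
    cs[nonb] <- 1
    BT[[k]][[j]] <- list(P = B %*% Matrix::Diagonal(nn[k], 1 / cs),
                         no_neighbor = nonb)
  }

  trip_i <- list(); trip_j <- list(); trip_x <- list(); tn <- 0L
  add_block <- function(P, scale_col, row0, col0) {
    # P sparse (rows local to row0 block), scaled per source column
    s <- Matrix::summary(methods::as(P, "TsparseMatrix"))
    if (nrow(s) == 0) return(invisible())
    x <- s$x * scale_col[s$j]
    keep <- x > 0
    if (!any(keep)) return(invisible())
    tn <<- tn + 1L
    trip_i[[tn]] <<- row0 + s$i[keep]
    trip_j[[tn]] <<- col0 + s$j[keep]
    trip_x[[tn]] <<- x[keep]
  }

  dangling <- numeric(n_rep)
  for (k in seq_len(K)) {
    nk <- nn[k]; Lk <- LL[k]
    # stay mass per source node: lam[k,k] plus reclaimed mass from multiplexes
    # the node has no bipartite neighbour in
    S <- rep(cfg$lam[k, k], nk)
    for (j in seq_len(K)) {
      if (j == k || cfg$lam[k, j] == 0) next
      S <- S + cfg$lam[k, j] * BT[[k]][[j]]$no_neighbor
    }
    deff <- if (Lk > 1) cfg$delta[k] else 0
    for (a in seq_len(Lk)) {
      col0 <- rep_off[k] + (a - 1L) * nk
      # bipartite jumps (independent of the source layer)
      for (j in seq_len(K)) {
        if (j == k || cfg$lam[k, j] == 0) next
        for (b in seq_len(LL[j])) {
          sc <- cfg$lam[k, j] * cfg$tau[[j]][b] *
            as.numeric(!BT[[k]][[j]]$no_neighbor)
          add_block(BT[[k]][[j]]$P, sc, rep_off[j] + (b - 1L) * nn[j], col0)
        }
      }
      # same-layer walk
      sc_same <- (1 - deff) * S
      add_block(LT[[k]][[a]]$P, sc_same * !LT[[k]][[a]]$dangling, col0, col0)
      dang_col <- sc_same * LT[[k]][[a]]$dangling
      # layer-hop walk
      if (Lk > 1) {
        for (b in seq_len(Lk)) {
          if (b == a) next
          sc_hop <- (deff / (Lk - 1)) * S
          add_block(LT[[k]][[b]]$P, sc_hop * !LT[[k]][[b]]$dangling,
                    rep_off[k] + (b - 1L) * nk, col0)
          dang_col <- dang_col + sc_hop * LT[[k]][[b]]$dangling
        }
      }
      dangling[col0 + seq_len(nk)] <- dangling[col0 + seq_len(nk)] + dang_col
    }
  }
  M <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                            x = unlist(trip_x), dims = c(n_rep, n_rep))
  structure(list(M = M, dangling = dangling, n_replicas = n_rep,
                 node_of_replica = node_of_replica,
                 rep_off = rep_off, node_off = node_off,
                 n_nodes_mx = nn, n_layers_mx = LL,
                 multiplex_names = mnames, nodes = net$nodes, cfg = cfg),
            class = "transition_operator")
}

#' Materialize the transition operator as a dense matrix
#'
#' Intended for small networks and verification: returns the replica-space
#' matrix whose columns sum to 1. Dangling mass is routed to `restart` when
#' supplied, otherwise reported separately would break stochasticity, so a
#' restart distribution is required whenever any column has dangling mass.
#'
#' @param op a `transition_operator`.
#' @param restart optional replica-space restart distribution (required if
#'   any dangling mass exists).
#' @return dense matrix, columns summing to 1.
#' @export
transition_matrix <- function(op, restart = NULL) {
  M <- as.matrix(op$M)
  if (any(op$dangling > 0)) {
    if (is.null(restart))
      stop("transition_matrix: restart distribution required (dangling mass present)")
    M <- M + outer(as.numeric(restart), op$dangling)
  }
  M
}

#' Build the restart distribution for one seed node
#'
#' With a single seed node all restart mass is placed on the seed's own
#' multiplex: mass `tau[k][l]` on replica `(k, l, seed)` where `k` is the
#' seed's multiplex (the cross-multiplex allocation `eta` only matters for
#' multi-seed walks, which renormalize onto the seeded multiplexes).
#'
#' @param op a `transition_operator`.
#' @param seed node id — namespaced (`"mx::id"`) or the bare local id if
#'   unambiguous.
#' @return numeric replica-space distribution summing to 1.
#' @export
build_restart_vector <- function(op, seed) {
  row <- which(op$nodes$id == seed)
  if (length(row) == 0) row <- which(op$nodes$local_id == seed)
  if (length(row) == 0) stop("build_restart_vector: unknown seed node '", seed, "'")
  if (length(row) > 1) stop("build_restart_vector: ambiguous seed '", seed,
                            "'; use the namespaced id")
  k <- match(op$nodes$multiplex[row], op$multiplex_names)
  i <- row - op$node_off[k]
  s <- numeric(op$n_replicas)
  for (a in seq_len(op$n_layers_mx[k]))
    s[op$rep_off[k] + (a - 1L) * op$n_nodes_mx[k] + i] <- op$cfg$tau[[k]][a]
  s
}

#' Stationary distribution of the restart walk
#'
#' Power iteration of `x <- (1 - r) * (M x + restart * dangling_mass(x)) +
#' r * restart` from `x0 = restart` until the L1 change drops below `tol`.
#'
#' @param op a `transition_operator`.
#' @param s replica-space restart distribution (sums to 1).
#' @param r restart probability; defaults to the operator's config.
#' @param tol,max_iter convergence controls; default from the config.
#' @return replica-space stationary distribution (nonnegative, sums to 1
#'   within `tol`), with attributes `iterations` and `residual`.
#' @export
rwr_stationary <- function(op, s, r = op$cfg$r, tol = op$cfg$tol,
                           max_iter = op$cfg$max_iter) {
  stopifnot(r > 0, r <= 1, abs(sum(s) - 1) < 1e-8)
  x <- s
  it <- 0L
  resid <- Inf
  while (it < max_iter) {
    it <- it + 1L
    xn <- (1 - r) * (as.numeric(op$M %*% x) + s * sum(op$dangling * x)) + r * s
    resid <- sum(abs(xn - x))
    x <- xn
    if (resid < tol) break
  }
  if (resid >= tol)
    warning(sprintf("rwr_stationary: not converged after %d iterations (L1 residual %.3e)",
                    it, resid))
  attr(x, "iterations") <- it
  attr(x, "residual") <- resid
  x
}

#' Aggregate a replica distribution to node scores
#'
#' The similarity score of a node is the sum of the walker's stationary mass
#' over all of that node's layer replicas; the result is a probability
#' distribution over the nodes of the full network.
#'
#' @param op a `transition_operator`.
#' @param x replica-space distribution.
#' @return named numeric vector over all nodes (namespaced ids), summing to
#'   the total mass of `x`.
#' @export
aggregate_to_nodes <- function(op, x) {
  out <- numeric(nrow(op$nodes))
  agg <- tapply(as.numeric(x), op$node_of_replica, sum)
  out[as.integer(names(agg))] <- agg
  names(out) <- op$nodes$id
  out
}

#' Full similarity matrix by one restart walk per node
#'
#' Runs [rwr_stationary()] from every node of the network and aggregates to
#' node scores: row `v` is `sim_G(v, .)`, a probability distribution over all
#' nodes. Rows are computed independently, so the result does not depend on
#' execution order.
#'
#' @param net a [multilayer_network()].
#' @param cfg an [rwr_config()]; defaults to `rwr_config(net)`.
#' @return dense numeric matrix, rows and columns named by namespaced node
#'   ids; every row sums to 1.
#' @export
similarity_matrix <- function(net, cfg = rwr_config(net)) {
  op <- build_transition_operator(net, cfg)
  n <- nrow(op$nodes)
  S <- matrix(0, n, n, dimnames = list(op$nodes$id, op$nodes$id))
  for (v in seq_len(n)) {
    s <- build_restart_vector(op, op$nodes$id[v])
    S[v, ] <- aggregate_to_nodes(op, rwr_stationary(op, s))
  }
  S
}
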