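# Module discovery: spherical k-means on the embedding (cosine similarity on
# unit-normalized vectors) and extraction of the induced mixed-type
# subnetwork of a cluster.

#' Spherical k-means over node embeddings
#'
#' Clusters unit-normalized embedding vectors by cosine similarity:
#' k-means++-style initialization on the normalized vectors, then alternate
#' assignment to the centroid of maximal cosine (ties broken toward the
#' lowest centroid index) and centroid recomputation as the normalized mean
#' direction of members, until assignments are stable or `max_iter` is
#' reached. Empty clusters are re-seeded from the point with the worst
#' similarity to its centroid. The objective (sum of member-centroid
#' cosines) is non-decreasing across iterations.
#'
#' @param E embedding matrix, rownames = node ids; all rows nonzero.
#' @param k number of clusters, `2 <= k <= nrow(E)` (k = 1 allowed).
#' @param seed RNG seed.
#' @param max_iter iteration cap.
#' @return list of class `cluster_assignment`: `k`, `labels` (named integer
#'   vector in 1..k), `centroids` (k x d, unit rows), `objective` (per-
#'   iteration trajectory), `seed`.
#' @export
spherical_kmeans <- function(E, k, seed = 1L, max_iter = 100L) {
  stopifnot(is.matrix(E), k >= 1)
  n <- nrow(E)
  if (k > n) stop("spherical_kmeans: k = ", k, " exceeds number of nodes ", n)
  nrm <- sqrt(rowSums(E^2))
  zero <- which(nrm == 0)
  if (length(zero))
    stop("spherical_kmeans: zero embedding vector for node ",
         rownames(E)[zero[1]])
  X <- E / nrm
  set.seed(seed)
  # k-means++ on cosine distance (1 - cos)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- pmax(0, 1 - as.numeric(X %*% X[centers[1], ]))
    for (c in 2:k) {
      if (sum(d2) == 0) centers[c] <- sample.int(n, 1)
      else centers[c] <- sample.int(n, 1, prob = d2)
      d2 <- pmin(d2, pmax(0, 1 - as.numeric(X %*% X[centers[c], ])))
    }
  }
  Cn <- X[centers, , drop = FALSE]
  dimnames(Cn) <- NULL
  labels <- integer(n)
  objective <- numeric(0)
  for (it in seq_len(max_iter)) {
    S <- X %*% t(Cn)
    new_labels <- max.col(S, ties.method = "first")
    sims <- S[cbind(seq_len(n), new_labels)]
    # re-seed empty clusters from the worst-fit point
    for (c in which(tabulate(new_labels, k) == 0)) {
      worst <- which.min(sims)
      new_labels[worst] <- c
      sims[worst] <- 1
    }
    objective <- c(objective, sum(S[cbind(seq_len(n), new_labels)]))
    stable <- identical(new_labels, labels)
    labels <- new_labels
    for (c in seq_len(k)) {
      mu <- colSums(X[labels == c, , drop = FALSE])
      nm <- sqrt(sum(mu^2))
      if (nm > 0) Cn[c, ] <- mu / nm
    }
    if (stable) break
  }
  names(labels) <- rownames(E)
  structure(list(k = k, labels = labels, centroids = Cn,
                 objective = objective, seed = seed),
            class = "cluster_assignment")
}

#' Extract the induced subnetwork of one cluster
#'
#' Returns every intra-layer edge of every multiplex layer and every
#' bipartite edge with both endpoints inside the cluster, each tagged with
#' its source network — the mixed gene/drug/disease module view.
#'
#' @param net a [multilayer_network()].
#' @param assignment a `cluster_assignment` over the network's (namespaced)
#'   node ids.
#' @param cluster_id which cluster to extract.
#' @return list with `nodes` (namespaced ids) and `edges` (data.frame with
#'   `from`, `to`, `weight`, `source_network`).
#' @export
extract_cluster_module <- function(net, assignment, cluster_id) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  if (!cluster_id %in% seq_len(assignment$k))
    stop("extract_cluster_module: invalid cluster id ", cluster_id)
  members <- names(assignment$labels)[assignment$labels == cluster_id]
  if (length(members) == 0)
    warning("extract_cluster_module: cluster ", cluster_id, " is empty")
  out <- list()
  for (m in net$multiplexes) {
    local <- sub(paste0("^", m$name, "::"), "",
                 grep(paste0("^", m$name, "::"), members, value = TRUE))
    for (l in seq_along(m$layers)) {
      e <- m$layers[[l]]$edges
      keep <- e$from %in% local & e$to %in% local
      if (any(keep))
        out[[length(out) + 1]] <- data.frame(
          from = paste0(m$name, "::", e$from[keep]),
          to = paste0(m$name, "::", e$to[keep]),
          weight = e$weight[keep],
          source_network = sprintf("%s_layer%d", m$name, l),
          stringsAsFactors = FALSE)
    }
  }
  for (b in net$bipartites) {
    g <- bip_pairs_global(b)
    keep <- g$from %in% members & g$to %in% members
    if (any(keep))
      out[[length(out) + 1]] <- data.frame(
        from = g$from[keep], to = g$to[keep],
        weight = b$edges$weight[keep], source_network = b$name,
        stringsAsFactors = FALSE)
  }
  edges <- if (length(out)) do.call(rbind, out)
  else data.frame(from = character(), to = character(), weight = numeric(),
                  source_network = character(), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  list(nodes = members, edges = edges)
}
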