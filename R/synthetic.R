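# Planted-partition generator for multiplex-heterogeneous benchmarks.
#
# Every multiplex shares one set of C community labels (balanced within each
# node type), so community c of one type lines up with community c of every
# other: bipartite edges are then denser between label-matched pairs, which
# is exactly the cross-type signal a multilayer embedding should recover.

#' Specification of a planted multiplex-heterogeneous network
#'
#' The default shape mirrors a drug-gene-disease knowledge network: a gene
#' multiplex with 3 layers (n = 200), a disease multiplex with 2 layers
#' (n = 100) and a drug multiplex with 4 layers (n = 150), joined by
#' gene-disease, drug-gene (target) and drug-disease bipartites, with C = 5
#' planted communities aligned across the three node types.
#'
#' @param multiplexes data.frame with columns `name`, `n`, `layers`, `p_in`,
#'   `p_out` (per-layer intra/inter-community edge probabilities).
#' @param bipartites data.frame with columns `name`, `left`, `right`, `q_in`,
#'   `q_out` (edge probabilities for label-matched / unmatched cross-type
#'   pairs).
#' @param C number of shared communities (>= 2; every `n` must be >= C).
#' @return list of class `planted_spec`.
#' @export
planted_spec <- function(
    multiplexes = data.frame(
      name = c("gene", "disease", "drug"),
      n = c(200L, 100L, 150L),
      layers = c(3L, 2L, 4L),
      p_in = 0.15, p_out = 0.01),
    bipartites = data.frame(
      name = c("gene_disease", "drug_gene", "drug_disease"),
      left = c("gene", "drug", "drug"),
      right = c("disease", "gene", "disease"),
      q_in = 0.10, q_out = 0.005),
    C = 5L) {
  stopifnot(C >= 2, all(multiplexes$n >= C),
            all(multiplexes$p_out >= 0), all(multiplexes$p_in <= 1),
            all(multiplexes$p_out < multiplexes$p_in),
            all(bipartites$q_out >= 0), all(bipartites$q_in <= 1),
            all(bipartites$q_out < bipartites$q_in),
            all(bipartites$left %in% multiplexes$name),
            all(bipartites$right %in% multiplexes$name))
  structure(list(multiplexes = multiplexes, bipartites = bipartites,
                 C = as.integer(C)),
            class = "planted_spec")
}

# balanced labels 1..C in round-robin over n nodes
balanced_labels <- function(n, C) rep_len(seq_len(C), n)

# Bernoulli edges over the upper triangle of n nodes with probability p_in
# for same-label pairs and p_out otherwise
sample_intra_edges <- function(ids, labels, p_in, p_out) {
  n <- length(ids)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  p <- ifelse(labels[pr[, 1]] == labels[pr[, 2]], p_in, p_out)
  keep <- runif(nrow(pr)) < p
  data.frame(from = ids[pr[keep, 1]], to = ids[pr[keep, 2]], weight = 1,
             stringsAsFactors = FALSE)
}

sample_bipartite_edges <- function(lids, llab, rids, rlab, q_in, q_out) {
  pr <- expand.grid(l = seq_along(lids), r = seq_along(rids))
  p <- ifelse(llab[pr$l] == rlab[pr$r], q_in, q_out)
  keep <- runif(nrow(pr)) < p
  data.frame(from = lids[pr$l[keep]], to = rids[pr$r[keep]], weight = 1,
             stringsAsFactors = FALSE)
}

#' Generate a planted multiplex-heterogeneous network
#'
#' Each layer is an independent undirected Bernoulli graph with edge
#' probability `p_in` within a community and `p_out` across; each bipartite
#' draws label-matched pairs with probability `q_in` and unmatched pairs
#' with `q_out`. Deterministic for a fixed seed.
#'
#' @param spec a [planted_spec()].
#' @param seed integer RNG seed.
#' @return list with `network` (a [multilayer_network()]) and `labels`
#'   (named integer vector of planted community labels over all namespaced
#'   node ids).
#' @export
generate_planted_network <- function(spec = planted_spec(), seed = 1L) {
  stopifnot(inherits(spec, "planted_spec"))
  set.seed(seed)
  ids <- list(); labs <- list()
  mxs <- vector("list", nrow(spec$multiplexes))
  for (i in seq_len(nrow(spec$multiplexes))) {
    m <- spec$multiplexes[i, ]
    ids[[m$name]] <- sprintf("%s_%03d", m$name, seq_len(m$n))
    labs[[m$name]] <- balanced_labels(m$n, spec$C)
    layers <- lapply(seq_len(m$layers), function(l)
      layer_graph(sample_intra_edges(ids[[m$name]], labs[[m$name]],
                                     m$p_in, m$p_out)))
    mxs[[i]] <- multiplex(m$name, layers, nodes = ids[[m$name]])
  }
  bps <- lapply(seq_len(nrow(spec$bipartites)), function(i) {
    b <- spec$bipartites[i, ]
    bipartite(b$name, b$left, b$right,
              sample_bipartite_edges(ids[[b$left]], labs[[b$left]],
                                     ids[[b$right]], labs[[b$right]],
                                     b$q_in, b$q_out))
  })
  net <- multilayer_network(mxs, bps)
  labels <- integer(0)
  for (m in spec$multiplexes$name)
    labels <- c(labels, setNames(labs[[m]], paste0(m, "::", ids[[m]])))
  labels <- labels[net$nodes$id]
  list(network = net, labels = labels)
}

#' Generate a structureless null network of the same shape
#'
#' Same multiplexes, layer counts and expected edge densities as the planted
#' model, but with a single edge probability everywhere — the mean of the
#' planted mixture — so there is no community signal for any downstream
#' method to find.
#'
#' @inheritParams generate_planted_network
#' @return a [multilayer_network()].
#' @export
generate_null_network <- function(spec = planted_spec(), seed = 1L) {
  stopifnot(inherits(spec, "planted_spec"))
  set.seed(seed)
  C <- spec$C
  mxs <- vector("list", nrow(spec$multiplexes))
  ids <- list()
  for (i in seq_len(nrow(spec$multiplexes))) {
    m <- spec$multiplexes[i, ]
    ids[[m$name]] <- sprintf("%s_%03d", m$name, seq_len(m$n))
    lab <- balanced_labels(m$n, C)
    npair <- m$n * (m$n - 1) / 2
    # exact intra-pair count for the round-robin balanced labels
    nintra <- sum(choose(table(lab), 2))
    pbar <- (nintra * m$p_in + (npair - nintra) * m$p_out) / npair
    layers <- lapply(seq_len(m$layers), function(l)
      layer_graph(sample_intra_edges(ids[[m$name]], rep(1L, m$n),
                                     pbar, 0)))
    mxs[[i]] <- multiplex(m$name, layers, nodes = ids[[m$name]])
  }
  bps <- lapply(seq_len(nrow(spec$bipartites)), function(i) {
    b <- spec$bipartites[i, ]
    nl <- spec$multiplexes$n[spec$multiplexes$name == b$left]
    nr <- spec$multiplexes$n[spec$multiplexes$name == b$right]
    nmatch <- sum(table(balanced_labels(nl, C))[balanced_labels(nr, C)])
    qbar <- (nmatch * b$q_in + (nl * nr - nmatch) * b$q_out) / (nl * nr)
    bipartite(b$name, b$left, b$right,
              sample_bipartite_edges(ids[[b$left]], rep(1L, nl),
                                     ids[[b$right]], rep(1L, nr), qbar, 0))
  })
  multilayer_network(mxs, bps)
}

#' Write a generated network to edge-list files plus a YAML config
#'
#' Writes one TSV per layer and per bipartite, a `config.yaml` loadable by
#' [load_multilayer_config()], and (for planted networks) a
#' `labels.tsv` ground-truth table.
#'
#' @param net a [multilayer_network()].
#' @param dir output directory (created if needed).
#' @param labels optional named community-label vector to write.
#' @return the config file path, invisibly.
#' @export
write_network_files <- function(net, dir, labels = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(multiplexes = list(), bipartites = list())
  for (m in net$multiplexes) {
    files <- character(length(m$layers))
    for (l in seq_along(m$layers)) {
      files[l] <- sprintf("%s_layer%d.tsv", m$name, l)
      e <- m$layers[[l]]$edges
      utils::write.table(e[, c("from", "to")], file.path(dir, files[l]),
                         sep = "\t", quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
    cfg$multiplexes[[m$name]] <- list(layers = as.list(files),
                                      nodes = as.list(m$nodes))
  }
  for (b in net$bipartites) {
    f <- sprintf("%s.tsv", b$name)
    utils::write.table(b$edges[, c("from", "to")], file.path(dir, f),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    cfg$bipartites[[b$name]] <- list(left = b$left, right = b$right, file = f)
  }
  if (!is.null(labels))
    utils::write.table(data.frame(node = names(labels), community = labels),
                       file.path(dir, "labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}
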