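#' @useDynLib mxembed, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rbinom sd setNames predict
#' @importFrom utils head
NULL

# ---- layer graphs -----------------------------------------------------------

#' Construct a single network layer from an edge table
#'
#' A layer is one interaction type over one node set: an edge list with
#' strictly positive weights. Self-loops are dropped and duplicate edges are
#' collapsed by summing their weights. Undirected layers store each edge once;
#' adjacency queries return both directions.
#'
#' @param edges data.frame with columns `from`, `to` and optionally `weight`
#'   (default 1). Node identifiers are character strings.
#' @param directed logical; undirected by default.
#' @return An object of class `layer_graph`.
#' @export
layer_graph <- function(edges, directed = FALSE) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    if (is.null(edges$weight)) edges$weight <- 1
    edges$weight <- as.numeric(edges$weight)
    if (any(!is.finite(edges$weight)) || any(edges$weight <= 0))
      stop("layer_graph: edge weights must be finite and strictly positive")
    loops <- edges$from == edges$to
    if (any(loops)) {
      message(sprintf("layer_graph: dropped %d self-loop(s)", sum(loops)))
      edges <- edges[!loops, , drop = FALSE]
    }
    # canonical orientation for undirected edges so duplicates collapse
    if (!directed && nrow(edges) > 0) {
      swap <- edges$from > edges$to
      tmp <- edges$from[swap]
      edges$from[swap] <- edges$to[swap]
      edges$to[swap] <- tmp
    }
    if (nrow(edges) > 0) {
      key <- paste(edges$from, edges$to, sep = "\r")
      if (anyDuplicated(key)) {
        ndup <- sum(duplicated(key))
        message(sprintf("layer_graph: collapsed %d duplicate edge(s) by summing weights", ndup))
        w <- tapply(edges$weight, key, sum)
        first <- !duplicated(key)
        edges <- edges[first, , drop = FALSE]
        edges$weight <- as.numeric(w[paste(edges$from, edges$to, sep = "\r")])
      }
    }
    rownames(edges) <- NULL
  }
  structure(list(edges = edges[, c("from", "to", "weight")],
                 directed = isTRUE(directed)),
            class = "layer_graph")
}

#' Read a 2- or 3-column edge list file into a layer
#'
#' Lines starting with `#` are comments; fields are separated by tabs or
#' spaces. Two fields per line for unweighted input, three (the last a
#' strictly positive weight) for weighted input.
#'
#' @param path file path.
#' @param directed logical.
#' @param weighted logical; when `FALSE` a third column is an error.
#' @return A [layer_graph()].
#' @export
read_edge_list <- function(path, directed = FALSE, weighted = FALSE) {
  if (!file.exists(path)) stop("read_edge_list: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  from <- character(length(keep)); to <- character(length(keep))
  weight <- rep(1, length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    fields <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    want <- if (weighted) 3L else 2L
    if (length(fields) != want)
      stop(sprintf("read_edge_list: line %d of %s has %d field(s), expected %d",
                   ln, path, length(fields), want))
    from[i] <- fields[1]; to[i] <- fields[2]
    if (weighted) {
      w <- suppressWarnings(as.numeric(fields[3]))
      if (is.na(w)) stop(sprintf("read_edge_list: line %d: weight '%s' is not numeric",
                                 ln, fields[3]))
      if (w <= 0) stop(sprintf("read_edge_list: line %d: weight must be positive", ln))
      weight[i] <- w
    }
  }
  layer_graph(data.frame(from = from, to = to, weight = weight,
                         stringsAsFactors = FALSE), directed = directed)
}

layer_nodes <- function(layer) unique(c(layer$edges$from, layer$edges$to))

# ---- multiplex --------------------------------------------------------------

#' Construct a multiplex network
#'
#' A multiplex is an ordered list of layers sharing one node set. The node
#' set is the union of all layer endpoints (plus any explicitly supplied
#' isolated nodes), ordered by first appearance.
#'
#' @param name multiplex name (unique within a multilayer network).
#' @param layers list of [layer_graph()] objects, at least one.
#' @param nodes optional character vector of node ids fixing the node order
#'   and adding isolated nodes.
#' @return An object of class `multiplex`.
#' @export
multiplex <- function(name, layers, nodes = NULL) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (inherits(layers, "layer_graph")) layers <- list(layers)
  if (length(layers) < 1) stop("multiplex: at least one layer is required")
  for (l in layers) if (!inherits(l, "layer_graph"))
    stop("multiplex: every layer must be a layer_graph")
  seen <- unique(c(as.character(nodes), unlist(lapply(layers, layer_nodes))))
  if (length(seen) == 0) stop("multiplex '", name, "' has no nodes")
  structure(list(name = name, nodes = seen, layers = layers),
            class = "multiplex")
}

# ---- bipartite --------------------------------------------------------------

#' Construct a bipartite network between two multiplexes
#'
#' @param name bipartite name.
#' @param left,right names of the two (distinct) multiplexes it connects.
#' @param edges data.frame with columns `from` (left-side id), `to`
#'   (right-side id) and optionally `weight`.
#' @return An object of class `bipartite`.
#' @export
bipartite <- function(name, left, right, edges) {
  if (identical(left, right))
    stop("bipartite '", name, "' must connect two distinct multiplexes")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (is.null(edges$weight)) edges$weight <- 1
  edges$weight <- as.numeric(edges$weight)
  if (any(edges$weight <= 0)) stop("bipartite: weights must be positive")
  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) {
    w <- tapply(edges$weight, key, sum)
    edges <- edges[!duplicated(key), , drop = FALSE]
    edges$weight <- as.numeric(w[paste(edges$from, edges$to, sep = "\r")])
  }
  rownames(edges) <- NULL
  structure(list(name = name, left = left, right = right,
                 edges = edges[, c("from", "to", "weight")]),
            class = "bipartite")
}

# ---- multilayer network -----------------------------------------------------

#' Assemble a multiplex-heterogeneous (universal multilayer) network
#'
#' Several multiplexes over disjoint node types, joined by bipartite
#' networks. Node ids are namespaced as `"multiplex::id"` on assembly so that
#' ids are globally unique; the original ids are retained for reporting.
#'
#' @param multiplexes list of [multiplex()] objects with unique names.
#' @param bipartites list of [bipartite()] objects; each must reference
#'   declared multiplexes and its edge endpoints must exist in them.
#' @return An object of class `multilayer_network` with a `nodes` table
#'   (global id, multiplex, local id, zero-based index).
#' @export
multilayer_network <- function(multiplexes, bipartites = list()) {
  if (inherits(multiplexes, "multiplex")) multiplexes <- list(multiplexes)
  nm <- vapply(multiplexes, function(m) m$name, character(1))
  if (anyDuplicated(nm)) stop("multilayer_network: multiplex names must be unique")
  names(multiplexes) <- nm
  for (b in bipartites) {
    if (!b$left %in% nm || !b$right %in% nm)
      stop("bipartite '", b$name, "' references unknown multiplex '",
           setdiff(c(b$left, b$right), nm)[1], "'")
    missL <- setdiff(unique(b$edges$from), multiplexes[[b$left]]$nodes)
    missR <- setdiff(unique(b$edges$to), multiplexes[[b$right]]$nodes)
    if (length(missL) || length(missR))
      stop("bipartite '", b$name, "' has endpoints absent from its multiplexes: ",
           paste(head(c(missL, missR), 5), collapse = ", "))
  }
  if (length(bipartites))
    names(bipartites) <- vapply(bipartites, function(b) b$name, character(1))
  nodes <- do.call(rbind, lapply(multiplexes, function(m)
    data.frame(id = paste0(m$name, "::", m$nodes), multiplex = m$name,
               local_id = m$nodes, stringsAsFactors = FALSE)))
  rownames(nodes) <- NULL
  nodes$index <- seq_len(nrow(nodes))
  if (nrow(nodes) == 0) stop("multilayer_network: empty node set")
  structure(list(multiplexes = multiplexes, bipartites = bipartites,
                 nodes = nodes),
            class = "multilayer_network")
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat(sprintf("multilayer_network: %d multiplex(es), %d bipartite(s), %d nodes\n",
              length(x$multiplexes), length(x$bipartites), nrow(x$nodes)))
  for (m in x$multiplexes) {
    ne <- vapply(m$layers, function(l) nrow(l$edges), integer(1))
    cat(sprintf("  %s: %d nodes, %d layer(s) with %s edges\n",
                m$name, length(m$nodes), length(m$layers),
                paste(ne, collapse = "/")))
  }
  for (b in x$bipartites)
    cat(sprintf("  %s: %s -- %s, %d edges\n", b$name, b$left, b$right,
                nrow(b$edges)))
  invisible(x)
}

#' Number of nodes in the full multilayer network
#' @param net a `multilayer_network`.
#' @return integer node count.
#' @export
n_nodes <- function(net) nrow(net$nodes)

# ---- config loading ---------------------------------------------------------

#' Load a multilayer network and walk parameters from a YAML config
#'
#' The config declares `multiplexes:` (each a name with a list of layer edge
#' list files, plus optional `directed`/`weighted` flags), `bipartites:`
#' (name, `left`, `right`, `file`), and optional `rwr:` and `embedding:`
#' blocks overriding defaults. Relative file paths are resolved against the
#' config file's directory.
#'
#' @param path path to the YAML config.
#' @return list with elements `network` (a [multilayer_network()]), `rwr`
#'   (an [rwr_config()]) and `embedding` (a list of training parameters).
#' @export
load_multilayer_config <- function(path) {
  if (!file.exists(path)) stop("load_multilayer_config: file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$multiplexes) || length(cfg$multiplexes) < 1)
    stop("config error: at least one multiplex must be declared")
  base <- dirname(normalizePath(path))
  resolve <- function(f) if (grepl("^(/|[A-Za-z]:)", f)) f else file.path(base, f)
  mxs <- lapply(names(cfg$multiplexes), function(nm) {
    blk <- cfg$multiplexes[[nm]]
    files <- blk$layers
    if (is.null(files) || length(files) < 1)
      stop("config error: multiplex '", nm, "' declares no layers")
    directed <- isTRUE(blk$directed)
    weighted <- isTRUE(blk$weighted)
    layers <- lapply(files, function(f)
      read_edge_list(resolve(f), directed = directed, weighted = weighted))
    multiplex(nm, layers, nodes = blk$nodes)
  })
  bps <- lapply(names(cfg$bipartites), function(nm) {
    blk <- cfg$bipartites[[nm]]
    if (is.null(blk$left) || is.null(blk$right) || is.null(blk$file))
      stop("config error: bipartite '", nm, "' needs left, right and file")
    lg <- read_edge_list(resolve(blk$file), directed = TRUE,
                         weighted = isTRUE(blk$weighted))
    bipartite(nm, blk$left, blk$right, lg$edges)
  })
  net <- multilayer_network(mxs, bps)
  rwr <- do.call(rwr_config, c(list(net = net), cfg$rwr))
  emb <- cfg$embedding
  if (is.null(emb)) emb <- list()
  list(network = net, rwr = rwr, embedding = emb)
}

# ---- embeddings I/O ---------------------------------------------------------

#' Write embeddings in word2vec text format
#'
#' Header line `n d`, then one line per node: the node id followed by `d`
#' reals at 12 significant digits (round-trips within 1e-9).
#'
#' @param E numeric matrix, one row per node, rownames = node ids.
#' @param path output file path.
#' @export
write_embeddings <- function(E, path) {
  stopifnot(is.matrix(E), !is.null(rownames(E)), all(is.finite(E)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(E), ncol(E)), con)
  for (i in seq_len(nrow(E)))
    writeLines(paste(c(rownames(E)[i],
                       formatC(E[i, ], format = "g", digits = 12)),
                     collapse = " "), con)
  invisible(path)
}

#' Read embeddings written by [write_embeddings()]
#' @param path input file path.
#' @return numeric matrix with node ids as rownames.
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) stop("read_embeddings: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  if (length(hdr) != 2) stop("read_embeddings: malformed header")
  n <- as.integer(hdr[1]); d <- as.integer(hdr[2])
  if (length(lines) - 1 != n)
    stop("read_embeddings: header declares ", n, " rows, found ", length(lines) - 1)
  E <- matrix(0, n, d)
  ids <- character(n)
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(lines[i + 1]), "[ \t]+")[[1]]
    if (length(fields) != d + 1)
      stop("read_embeddings: row ", i, " has ", length(fields) - 1,
           " values, expected ", d)
    ids[i] <- fields[1]
    E[i, ] <- as.numeric(fields[-1])
  }
  rownames(E) <- ids
  E
}
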