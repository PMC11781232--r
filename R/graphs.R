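#' Graph-construction configuration
#'
#' Two transcripts within one cell are connected when their Euclidean
#' separation is at most the radius `d` (in platform coordinate units).
#' Platform presets: 12 (CosMx SMI pixels, i.e. about 2.16 um at 0.18 um
#' per pixel), 2 (MERFISH, um), 3 (Xenium, um) — chosen so each transcript
#' is linked to an average of 10-30 neighbors. An optional mutual-k cap
#' bounds the neighbor count while keeping the adjacency symmetric.
#'
#' @param d Connection radius in platform units (> 0).
#' @param k_cap Optional maximum neighbors per node; an edge is kept only
#'   when each endpoint is among the other's `k_cap` nearest neighbors.
#' @param louvain_resolution Resolution parameter of the Louvain
#'   modularity objective.
#' @param seed Integer seed making the Louvain partition deterministic.
#' @return An object of class `graph_config`.
#' @export
graph_config <- function(d, k_cap = NULL, louvain_resolution = 1, seed = 0L) {
  stopifnot(d > 0, is.null(k_cap) || k_cap >= 1)
  structure(list(d = d, k_cap = if (is.null(k_cap)) NULL else as.integer(k_cap),
                 louvain_resolution = louvain_resolution,
                 seed = as.integer(seed)),
            class = "graph_config")
}

# Radius neighbor search on a uniform grid of bucket width d: candidates for
# a point can only live in its own or the 8 surrounding buckets. Returns an
# m x 2 integer matrix of index pairs (u < v) with distance <= d.
radius_pairs <- function(coords, d) {
  n <- nrow(coords)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  gx <- floor(coords[, 1] / d)
  gy <- floor(coords[, 2] / d)
  key <- paste(gx, gy, sep = ",")
  buckets <- split(seq_len(n), key)
  bucket_xy <- do.call(rbind, strsplit(names(buckets), ",", fixed = TRUE))
  bx <- as.numeric(bucket_xy[, 1]); by <- as.numeric(bucket_xy[, 2])
  us <- integer(0); vs <- integer(0)
  d2 <- d * d
  for (b in seq_along(buckets)) {
    pts <- buckets[[b]]
    # neighbor buckets with lexicographically >= (dx,dy) offsets, so each
    # bucket pair is visited once
    for (off in list(c(0, 0), c(1, 0), c(-1, 1), c(0, 1), c(1, 1))) {
      if (off[1] == 0 && off[2] == 0) {
        other <- pts
        same <- TRUE
      } else {
        k <- paste(bx[b] + off[1], by[b] + off[2], sep = ",")
        other <- buckets[[k]]
        if (is.null(other)) next
        same <- FALSE
      }
      if (same) {
        if (length(pts) < 2L) next
        cmb <- utils::combn(pts, 2L)
        a <- cmb[1, ]; bb <- cmb[2, ]
      } else {
        a <- rep(pts, each = length(other))
        bb <- rep(other, times = length(pts))
      }
      dx <- coords[a, 1] - coords[bb, 1]
      dy <- coords[a, 2] - coords[bb, 2]
      hit <- (dx * dx + dy * dy) <= d2
      if (any(hit)) {
        us <- c(us, pmin(a[hit], bb[hit]))
        vs <- c(vs, pmax(a[hit], bb[hit]))
      }
    }
  }
  if (length(us) == 0L) return(matrix(integer(0), ncol = 2L))
  edges <- cbind(us, vs, deparse.level = 0)
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

# Mutual-k cap: keep edge (u,v) only when v is among u's k nearest radius
# neighbors AND u among v's (ties broken by distance then node index).
apply_k_cap <- function(edges, coords, k_cap) {
  if (nrow(edges) == 0L) return(edges)
  u <- edges[, 1]; v <- edges[, 2]
  dist2 <- (coords[u, 1] - coords[v, 1])^2 + (coords[u, 2] - coords[v, 2])^2
  inc <- data.frame(node = c(u, v), other = c(v, u), d2 = c(dist2, dist2),
                    eid = c(seq_along(u), seq_along(u)))
  keep_by_node <- unlist(lapply(split(inc, inc$node), function(df) {
    df <- df[order(df$d2, df$other), , drop = FALSE]
    df$eid[seq_len(min(k_cap, nrow(df)))]
  }), use.names = FALSE)
  counts <- tabulate(keep_by_node, nbins = nrow(edges))
  edges[counts == 2L, , drop = FALSE]  # mutual: kept by both endpoints
}

#' Build one cell's gene neighborhood network
#'
#' Nodes are the cell's transcripts (carrying their gene index and
#' coordinates); an undirected edge joins two transcripts whose Euclidean
#' distance is at most `config$d`. Coincident transcripts (distance 0) are
#' connected; self-loops never occur. Distances are planar (x, y): any z
#' coordinate is carried through but ignored unless `use_z = TRUE`.
#'
#' @param cell_records `data.frame` of one cell's transcripts (columns
#'   `cell_id`, `gene`, `x`, `y`).
#' @param config A [graph_config()].
#' @param vocab A [build_vocabulary()] result; genes absent from the
#'   vocabulary are dropped with a warning.
#' @param use_z Use 3-D distances when a `z` column is present.
#' @return An object of class `cell_graph`: list with `cell_id`, `genes`
#'   (integer vocabulary indices), `coords` (n x 2 matrix), `edges`
#'   (m x 2 integer matrix, each row `u < v`), `n`, `d` (feature dimension)
#'   and `partition` (filled by [partition_louvain()]).
#' @export
build_radius_graph <- function(cell_records, config, vocab, use_z = FALSE) {
  stopifnot(nrow(cell_records) >= 1L)
  gidx <- unname(vocab$index[cell_records$gene])
  known <- !is.na(gidx)
  if (!all(known)) {
    warning(sum(!known), " transcript(s) with genes absent from the vocabulary dropped in cell ",
            cell_records$cell_id[1])
    cell_records <- cell_records[known, , drop = FALSE]
    gidx <- gidx[known]
  }
  n <- nrow(cell_records)
  if (n == 0L) stop("no transcripts with known genes in cell")
  coords <- cbind(cell_records$x, cell_records$y)
  if (use_z && !is.null(cell_records$z)) coords <- cbind(coords, cell_records$z)
  if (n == 1L) {
    warning("cell ", cell_records$cell_id[1], " has a single transcript; edgeless graph")
    edges <- matrix(integer(0), ncol = 2L)
  } else if (ncol(coords) == 3L) {
    # 3-D: brute force (opt-in, cells are small)
    dm <- as.matrix(stats::dist(coords))
    hit <- which(upper.tri(dm) & dm <= config$d, arr.ind = TRUE)
    edges <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    dimnames(edges) <- NULL
    storage.mode(edges) <- "integer"
  } else {
    edges <- radius_pairs(coords, config$d)
  }
  if (!is.null(config$k_cap)) edges <- apply_k_cap(edges, coords, config$k_cap)
  structure(list(cell_id = as.character(cell_records$cell_id[1]),
                 genes = as.integer(gidx),
                 coords = coords[, 1:2, drop = FALSE],
                 edges = edges, n = n, d = vocab$d,
                 partition = NULL),
            class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("cell_graph %s: %d transcripts, %d edges, %s communities\n",
              x$cell_id, x$n, nrow(x$edges),
              if (is.null(x$partition)) "un-partitioned" else max(x$partition)))
  invisible(x)
}

#' Mean node degree of a cell graph
#'
#' Returns `2|E|/n`; the construction target is an average of 10-30
#' neighbors per transcript, and the pipeline warns when a dataset falls
#' outside that band.
#'
#' @param graph A `cell_graph`.
#' @return Numeric scalar.
#' @export
mean_degree <- function(graph) {
  if (graph$n == 0L) stop("empty graph has no mean degree")
  2 * nrow(graph$edges) / graph$n
}

#' Partition a cell graph into RNA communities
#'
#' Runs Louvain modularity clustering on the gene neighborhood network,
#' giving the subcellular RNA communities used for subgraph-level
#' augmentation and scoring. Deterministic under `config$seed`; community
#' ids are relabelled canonically so community 1 contains the
#' lowest-indexed node. Isolated nodes become singleton communities.
#'
#' @param graph A `cell_graph`.
#' @param config A [graph_config()] (resolution and seed are used).
#' @return Integer vector: community id (1..k) per node.
#' @export
partition_louvain <- function(graph, config = graph_config(d = 1)) {
  stopifnot(graph$n >= 1L)
  if (nrow(graph$edges) == 0L) return(seq_len(graph$n))
  g <- igraph::graph_from_edgelist(graph$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, graph$n - igraph::vcount(g)))
  memb <- withr::with_seed(config$seed, {
    igraph::membership(igraph::cluster_louvain(
      g, resolution = config$louvain_resolution))
  })
  memb <- as.integer(memb)
  # canonical relabel: communities numbered by their minimum node index
  first <- vapply(split(seq_len(graph$n), memb), min, integer(1))
  relabel <- integer(length(first))
  relabel[order(first)] <- seq_along(first)
  relabel[memb]
}

#' Build (and partition) the gene neighborhood network of every cell
#'
#' @param table QC-filtered transcript `data.frame`.
#' @param config A [graph_config()].
#' @param vocab A `gene_vocabulary`.
#' @param labels Optional label `data.frame` (`cell_id`, `cell_type`);
#'   matching cells get a `label` field.
#' @param partition Compute the Louvain partition per graph (default TRUE).
#' @param verbose Report counts and the mean-degree band check.
#' @return Named list of `cell_graph` objects (names are cell ids).
#' @export
build_cell_graphs <- function(table, config, vocab, labels = NULL,
                              partition = TRUE, verbose = TRUE) {
  recs <- split(table, table$cell_id)
  graphs <- lapply(recs, build_radius_graph, config = config, vocab = vocab)
  if (partition) {
    for (i in seq_along(graphs)) {
      graphs[[i]]$partition <- partition_louvain(graphs[[i]], config)
    }
  }
  if (!is.null(labels)) {
    lab <- stats::setNames(labels$cell_type, labels$cell_id)
    for (i in seq_along(graphs)) {
      graphs[[i]]$label <- unname(lab[graphs[[i]]$cell_id])
    }
  }
  if (verbose) {
    md <- mean(vapply(graphs, mean_degree, numeric(1)))
    message(sprintf("built %d cell graphs; mean degree %.1f", length(graphs), md))
    if (md < 10 || md > 30) {
      warning(sprintf("mean degree %.1f outside the 10-30 target band; consider adjusting d", md))
    }
  }
  graphs
}

# Dense adjacency (0/1, zero diagonal) of a cell graph or augmented view.
adjacency_dense <- function(graph) {
  A <- matrix(0, graph$n, graph$n)
  if (nrow(graph$edges) > 0L) {
    A[graph$edges] <- 1
    A[graph$edges[, c(2, 1), drop = FALSE]] <- 1
  }
  A
}

# Symmetric-normalized adjacency with self-loops:
# Ahat = D^{-1/2} (A + I) D^{-1/2}
adjacency_normalized <- function(graph) {
  A <- adjacency_dense(graph) + diag(graph$n)
  dinv <- 1 / sqrt(rowSums(A))
  A * tcrossprod(dinv)
}

# One-hot n x d feature matrix from gene indices.
one_hot_features <- function(genes, d) {
  X <- matrix(0, length(genes), d)
  X[cbind(seq_along(genes), genes)] <- 1
  X
}

#' Export a cell graph for inspection
#'
#' `write_edge_list()` writes a two-column TSV of node-index pairs;
#' `write_graphml()` writes GraphML (via igraph) with gene symbols and
#' coordinates as node attributes; `write_partition()` writes a CSV of
#' `(node_index, community)`.
#'
#' @param graph A `cell_graph`.
#' @param path Output file.
#' @param vocab Vocabulary used to resolve gene symbols (GraphML only).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", row.names = FALSE,
                     col.names = c("u", "v"), quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(graph, path, vocab = NULL) {
  g <- igraph::make_empty_graph(n = graph$n, directed = FALSE)
  if (nrow(graph$edges) > 0L) g <- igraph::add_edges(g, t(graph$edges))
  igraph::V(g)$gene <- if (is.null(vocab)) as.character(graph$genes) else vocab$symbols[graph$genes]
  igraph::V(g)$x <- graph$coords[, 1]
  igraph::V(g)$y <- graph$coords[, 2]
  if (!is.null(graph$partition)) igraph::V(g)$community <- graph$partition
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_partition <- function(graph, path) {
  stopifnot(!is.null(graph$partition))
  utils::write.csv(data.frame(node_index = seq_len(graph$n),
                              community = graph$partition),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
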