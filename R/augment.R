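#' Compute per-node augmentation scores
#'
#' Each direct node-level augmentation (node dropping, node masking) has a
#' scoring head producing two logits per node ("augment" vs "keep") from
#' the GIN node embeddings. A Gumbel-Softmax sample over the two logits
#' gives the probability of augmenting the node; the node score for
#' augmentation `i` is `p_vi = 1 - GumbelSoftmax(MLP_i(H_v))`, so high
#' scores mark important nodes that should be retained. The aggregate node
#' importance is `p_v = sum_i p_vi` (in `[0, 2]` with the two direct
#' augmentations). In evaluation mode the Gumbel noise is disabled and the
#' scores reduce to a plain temperature-scaled softmax, making them
#' deterministic.
#'
#' @param H `n x hidden` node embeddings from [gin_encode()].
#' @param params Parameter list (uses `head_drop`, `head_mask`).
#' @param temperature Gumbel-Softmax temperature (> 0).
#' @param noise Draw Gumbel noise (training) or not (evaluation).
#' @return List of class `augmentation_scores`: `p_drop`, `p_mask`
#'   (per-node keep-probabilities in `[0,1]`), `p_v` (their sum), and a
#'   `cache` used for backpropagation.
#' @export
compute_node_scores <- function(H, params, temperature = 1, noise = TRUE) {
  stopifnot(temperature > 0)
  # heads read the direction of the GIN embedding: row-normalizing keeps the
  # score logits bounded (node degree drives |H_v| and would otherwise
  # saturate the sigmoid, freezing every score at 0 or 1)
  r <- sqrt(rowSums(H^2))
  r_safe <- ifelse(r == 0, 1, r)
  U <- H / r_safe
  one_head <- function(head) {
    logits <- U %*% head$W + matrix(head$b, nrow(H), 2L, byrow = TRUE)
    if (any(!is.finite(logits))) stop("non-finite scoring logits")
    g <- if (noise) {
      matrix(-log(-log(stats::runif(length(logits)))), nrow(logits))
    } else {
      matrix(0, nrow(logits), 2L)
    }
    a <- (logits + g) / temperature
    # row-wise 2-class softmax; column 1 = "augment", column 2 = "keep"
    m <- pmax(a[, 1], a[, 2])
    e1 <- exp(a[, 1] - m); e2 <- exp(a[, 2] - m)
    y_aug <- e1 / (e1 + e2)
    list(p = 1 - y_aug, y_aug = y_aug)
  }
  hd <- one_head(params$head_drop)
  hm <- one_head(params$head_mask)
  structure(list(p_drop = hd$p, p_mask = hm$p, p_v = hd$p + hm$p,
                 cache = list(y_drop = hd$y_aug, y_mask = hm$y_aug,
                              U = U, r = r_safe,
                              temperature = temperature)),
            class = "augmentation_scores")
}

#' Per-edge keep probabilities
#'
#' The probability of an edge being retained is the average of its two
#' endpoints' aggregate scores, rescaled from `[0, 2]` to `[0, 1]`.
#'
#' @param scores An `augmentation_scores` object (or a numeric `p_v`
#'   vector).
#' @param edges `m x 2` integer edge matrix.
#' @return Numeric vector of length `m` in `[0, 1]`.
#' @export
compute_edge_scores <- function(scores, edges) {
  p_v <- if (inherits(scores, "augmentation_scores")) scores$p_v else scores
  if (nrow(edges) == 0L) return(numeric(0))
  keep <- (p_v[edges[, 1]] + p_v[edges[, 2]]) / 2 / 2
  pmin(pmax(keep, 0), 1)
}

#' Per-community (subgraph) scores
#'
#' The score of an RNA community is the arithmetic mean of its members'
#' aggregate node scores `p_v`.
#'
#' @param scores An `augmentation_scores` object (or numeric `p_v`).
#' @param partition Integer community id per node (1..k).
#' @return Numeric vector of length k: `p_S` per community.
#' @export
compute_subgraph_scores <- function(scores, partition) {
  p_v <- if (inherits(scores, "augmentation_scores")) scores$p_v else scores
  as.numeric(tapply(p_v, factor(partition, levels = seq_len(max(partition))),
                    mean))
}

# An augmented view is a cell_graph plus bookkeeping:
#   node_ids  : original node indices of the surviving nodes
#   masked    : logical per surviving node (zeroed feature row)
#   provenance: list of operators that fired and their decisions
new_view <- function(graph) {
  structure(list(cell_id = graph$cell_id, genes = graph$genes,
                 coords = graph$coords, edges = graph$edges, n = graph$n,
                 d = graph$d, partition = graph$partition,
                 node_ids = seq_len(graph$n),
                 masked = rep(FALSE, graph$n),
                 provenance = list(), origin_cell = graph$cell_id),
            class = c("augmented_view", "cell_graph"))
}

#' Node dropping
#'
#' Each node is independently retained with probability equal to its
#' node-dropping keep-score `p_drop`; removed nodes take their incident
#' edges with them and the partition is restricted to survivors. If every
#' node would be dropped, the highest-scoring node is kept so the view is
#' never empty.
#'
#' @param view An `augmented_view` (from the internal view constructor).
#' @param scores An `augmentation_scores` object for the view's current
#'   nodes.
#' @return The modified view.
#' @export
apply_node_dropping <- function(view, scores) {
  keep <- stats::runif(view$n) < scores$p_drop
  if (!any(keep)) keep[which.max(scores$p_v)] <- TRUE
  idx <- which(keep)
  remap <- integer(view$n); remap[idx] <- seq_along(idx)
  e <- view$edges
  e <- e[keep[e[, 1]] & keep[e[, 2]], , drop = FALSE]
  e <- cbind(remap[e[, 1]], remap[e[, 2]], deparse.level = 0)
  part <- view$partition[idx]
  # keep community ids stable (they refer to the original partition)
  view$genes <- view$genes[idx]
  view$coords <- view$coords[idx, , drop = FALSE]
  view$edges <- e
  view$n <- length(idx)
  view$partition <- part
  view$node_ids <- view$node_ids[idx]
  view$masked <- view$masked[idx]
  view$provenance$node_dropping <- list(kept = idx)
  view
}

#' Node masking
#'
#' Conceals node attributes while preserving the graph structure: each node
#' is independently left unmasked with probability `p_mask`; masked nodes
#' get an all-zero feature row. Node and edge sets are unchanged.
#'
#' @inheritParams apply_node_dropping
#' @return The modified view.
#' @export
apply_node_masking <- function(view, scores) {
  masked <- stats::runif(view$n) >= scores$p_mask
  view$masked <- view$masked | masked
  view$provenance$node_masking <- list(masked = which(masked))
  view
}

#' Edge perturbation
#'
#' At the node level every edge is independently retained with the keep
#' probability from [compute_edge_scores()]. At the subgraph level only
#' edges crossing community boundaries are eligible for removal, with keep
#' probability given by the mean of the two communities' scores rescaled to
#' `[0, 1]`; intra-community edges are untouched. The node set never
#' changes.
#'
#' @inheritParams apply_node_dropping
#' @param level `"node"` or `"subgraph"`.
#' @return The modified view.
#' @export
apply_edge_perturbation <- function(view, scores, level = c("node", "subgraph")) {
  level <- match.arg(level)
  e <- view$edges
  if (nrow(e) == 0L) return(view)
  if (level == "node") {
    keep_p <- compute_edge_scores(scores, e)
    keep <- stats::runif(nrow(e)) < keep_p
  } else {
    p_S <- compute_subgraph_scores(scores, view$partition)
    cu <- view$partition[e[, 1]]; cv <- view$partition[e[, 2]]
    inter <- cu != cv
    keep <- rep(TRUE, nrow(e))
    if (any(inter)) {
      keep_p <- (p_S[cu[inter]] + p_S[cv[inter]]) / 2 / 2
      keep[inter] <- stats::runif(sum(inter)) < pmin(pmax(keep_p, 0), 1)
    }
  }
  view$edges <- e[keep, , drop = FALSE]
  view$provenance[[paste0("edge_perturbation_", level)]] <-
    list(kept_edges = which(keep))
  view
}

#' Subgraph swapping
#'
#' Exchanges the inter-community connectivity of two RNA communities.
#' Communities are sampled with probability inversely proportional to
#' their score `p_S` (low-importance communities are perturbed
#' preferentially). All edges crossing into either chosen community are
#' removed, then re-created with the external endpoint preserved and the
#' internal endpoint resampled uniformly from the *other* chosen community;
#' edges directly joining the two chosen communities are resampled between
#' them. Node count, intra-community edges and the community count are
#' unchanged; with fewer than two communities the operator is a no-op.
#'
#' @inheritParams apply_node_dropping
#' @return The modified view.
#' @export
apply_subgraph_swap <- function(view, scores) {
  k <- max(view$partition)
  present <- sort(unique(view$partition))
  if (length(present) < 2L) {
    warning("subgraph swap skipped: fewer than 2 communities")
    return(view)
  }
  p_S <- compute_subgraph_scores(scores, view$partition)
  w <- 1 / (p_S[present] + 0.01)
  chosen <- sample(present, 2L, prob = w / sum(w))
  a <- chosen[1]; b <- chosen[2]
  nodes_a <- which(view$partition == a)
  nodes_b <- which(view$partition == b)
  e <- view$edges
  cu <- view$partition[e[, 1]]; cv <- view$partition[e[, 2]]
  touches_a <- (cu == a) != (cv == a)  # exactly one endpoint in a
  touches_b <- (cu == b) != (cv == b)
  ab <- touches_a & touches_b          # direct a-b edges
  rem_a <- touches_a & !ab             # a <-> external
  rem_b <- touches_b & !ab             # b <-> external
  removed <- ab | rem_a | rem_b
  new_edges <- list(e[!removed, , drop = FALSE])
  reattach <- function(rows, into_nodes, chosen_comm) {
    if (!any(rows)) return(NULL)
    er <- e[rows, , drop = FALSE]
    ext <- ifelse(view$partition[er[, 1]] %in% chosen_comm, er[, 2], er[, 1])
    new_in <- into_nodes[sample.int(length(into_nodes), length(ext), replace = TRUE)]
    cbind(pmin(ext, new_in), pmax(ext, new_in), deparse.level = 0)
  }
  # a's former external neighbors now connect to b, and vice versa
  new_edges$a <- reattach(rem_a, nodes_b, a)
  new_edges$b <- reattach(rem_b, nodes_a, b)
  if (any(ab)) {
    na <- nodes_a[sample.int(length(nodes_a), sum(ab), replace = TRUE)]
    nb <- nodes_b[sample.int(length(nodes_b), sum(ab), replace = TRUE)]
    new_edges$ab <- cbind(pmin(na, nb), pmax(na, nb), deparse.level = 0)
  }
  e2 <- do.call(rbind, new_edges)
  e2 <- e2[e2[, 1] != e2[, 2], , drop = FALSE]       # no self-loops
  e2 <- unique(e2)                                    # set semantics
  view$edges <- e2[order(e2[, 1], e2[, 2]), , drop = FALSE]
  view$provenance$subgraph_swap <- list(communities = c(a, b))
  view
}

#' Augmentation policies
#'
#' A policy is the subset of operators applied when generating a view.
#' `"identical"` applies none (the control condition); `"all"` enables all
#' five. Operators fire in coarse-to-fine order: subgraph-level edge
#' perturbation, subgraph swapping, node dropping, node masking, node-level
#' edge perturbation.
#'
#' @param policy Character vector drawn from `"identical"`,
#'   `"node_dropping"`, `"node_masking"`, `"edge_perturbation_node"`,
#'   `"edge_perturbation_subgraph"`, `"subgraph_swap"`, or the shorthand
#'   `"all"`.
#' @return Normalized character vector of enabled operators.
#' @export
augment_policy <- function(policy = "all") {
  ops <- c("edge_perturbation_subgraph", "subgraph_swap", "node_dropping",
           "node_masking", "edge_perturbation_node")
  if (identical(policy, "all")) return(ops)
  if (identical(policy, "identical")) return(character(0))
  unknown <- setdiff(policy, c(ops, "identical"))
  if (length(unknown) > 0L) stop("unknown augmentation operator(s): ",
                                 paste(unknown, collapse = ", "))
  ops[ops %in% policy]
}

#' Generate one stochastic view of a cell graph
#'
#' Applies the enabled operators in coarse-to-fine order using the given
#' node scores. Two calls with independent RNG states yield the two views
#' forming a positive pair during contrastive training; the `"identical"`
#' policy returns the graph unchanged (used at inference and as the
#' ablation control).
#'
#' @param graph A partitioned `cell_graph`.
#' @param scores An `augmentation_scores` for the graph.
#' @param policy Operators to enable (see [augment_policy()]).
#' @return An `augmented_view`.
#' @export
generate_view <- function(graph, scores, policy = augment_policy("all")) {
  policy <- augment_policy(if (length(policy) == 1L &&
                               policy %in% c("all", "identical")) policy else policy)
  view <- new_view(graph)
  if (length(policy) == 0L) return(view)
  if ("edge_perturbation_subgraph" %in% policy) {
    view <- apply_edge_perturbation(view, scores, "subgraph")
  }
  if ("subgraph_swap" %in% policy && max(graph$partition) >= 2L) {
    view <- apply_subgraph_swap(view, scores)
  }
  sc <- scores
  if ("node_dropping" %in% policy) {
    view <- apply_node_dropping(view, sc)
    if (view$n < graph$n) {
      idx <- view$node_ids
      sc <- structure(list(p_drop = sc$p_drop[idx], p_mask = sc$p_mask[idx],
                           p_v = sc$p_v[idx], cache = sc$cache),
                      class = "augmentation_scores")
    }
  }
  if ("node_masking" %in% policy) view <- apply_node_masking(view, sc)
  if ("edge_perturbation_node" %in% policy) {
    view <- apply_edge_perturbation(view, sc, "node")
  }
  view
}
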