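#' Evaluation-mode node scores for a set of cells
#'
#' Runs the GIN scorer and the Gumbel-Softmax heads with noise disabled
#' (plain temperature-scaled softmax), giving a deterministic importance
#' score `p_v` in `[0, 2]` for every transcript node.
#'
#' @param model A `gcl_model`.
#' @param cells List of `cell_graph`s.
#' @return Named list (by cell id) of `augmentation_scores`.
#' @export
node_scores <- function(model, cells) {
  out <- lapply(cells, function(g) {
    H <- gin_encode(g, model$encoder, model$params)
    compute_node_scores(H, model$params, model$gumbel_temperature,
                        noise = FALSE)
  })
  stats::setNames(out, vapply(cells, `[[`, character(1), "cell_id"))
}

#' Per-gene importance table
#'
#' For each cell type, collects the evaluation-mode node score `p_v` of
#' every transcript in every cell of that type, averages by gene symbol
#' and ranks genes by descending mean score (ties broken lexicographically
#' by gene). Genes never observed in a type are absent, not zero-filled.
#'
#' @param model A `gcl_model`.
#' @param cells List of `cell_graph`s.
#' @param types Character vector: the cell type of each graph (true labels
#'   or predictions).
#' @return `data.frame` of class `gene_importance_table`: `cell_type`,
#'   `gene`, `mean_score`, `n_transcripts`, `rank` (1 = highest within the
#'   type).
#' @export
gene_importance <- function(model, cells, types) {
  stopifnot(length(cells) == length(types))
  sc <- node_scores(model, cells)
  per_node <- do.call(rbind, lapply(seq_along(cells), function(i) {
    g <- cells[[i]]
    data.frame(cell_type = types[i],
               gene = model$vocab$symbols[g$genes],
               score = sc[[i]]$p_v,
               stringsAsFactors = FALSE)
  }))
  agg <- stats::aggregate(score ~ cell_type + gene, data = per_node,
                          FUN = function(x) c(mean = mean(x), n = length(x)))
  out <- data.frame(cell_type = agg$cell_type, gene = agg$gene,
                    mean_score = agg$score[, "mean"],
                    n_transcripts = as.integer(agg$score[, "n"]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$cell_type, -out$mean_score, out$gene), , drop = FALSE]
  out$rank <- stats::ave(seq_len(nrow(out)), out$cell_type,
                         FUN = seq_along)
  rownames(out) <- NULL
  class(out) <- c("gene_importance_table", "data.frame")
  out
}

#' Export a GSEA-preranked .rnk file
#'
#' Writes the standard two-column tab-separated preranked dialect (gene,
#' score), one gene per line in descending score order (ties broken
#' lexicographically), ready for preranked gene set enrichment analysis.
#' Enrichment runs themselves are out of scope; conventional significance
#' filters for the downstream run are NOM p < 0.05, FDR q < 0.25 and
#' NES >= 1.
#'
#' @param table A [gene_importance()] table.
#' @param cell_type Which cell type's ranking to export.
#' @param path Output `.rnk` file.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(table, cell_type, path) {
  rows <- table[table$cell_type == cell_type, , drop = FALSE]
  if (nrow(rows) == 0L) stop("cell type not present in importance table: ", cell_type)
  rows <- rows[order(-rows$mean_score, rows$gene), , drop = FALSE]
  utils::write.table(rows[, c("gene", "mean_score")], path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-community subgraph score records
#'
#' Computes the evaluation-mode score `p_S` (mean member `p_v`) of every
#' RNA community of every cell, with the member gene symbols.
#'
#' @param model A `gcl_model`.
#' @param cells List of partitioned `cell_graph`s.
#' @param types Optional cell type per graph, carried into the records.
#' @return `data.frame`: `cell_id`, `cell_type`, `community_id`, `p_S`,
#'   `n_members`, `member_genes` (comma-separated symbols).
#' @export
subgraph_scores <- function(model, cells, types = NULL) {
  sc <- node_scores(model, cells)
  do.call(rbind, lapply(seq_along(cells), function(i) {
    g <- cells[[i]]
    stopifnot(!is.null(g$partition))
    p_S <- compute_subgraph_scores(sc[[i]], g$partition)
    comms <- sort(unique(g$partition))
    data.frame(
      cell_id = g$cell_id,
      cell_type = if (is.null(types)) NA_character_ else types[i],
      community_id = comms,
      p_S = p_S[comms],
      n_members = as.integer(table(factor(g$partition, levels = comms))),
      member_genes = vapply(comms, function(cm) {
        paste(sort(model$vocab$symbols[g$genes[g$partition == cm]]),
              collapse = ",")
      }, character(1)),
      stringsAsFactors = FALSE)
  }))
}

#' Highest- and lowest-scoring subgraphs of a cell type
#'
#' @param records A [subgraph_scores()] data frame.
#' @param cell_type Cell type to select.
#' @param top_n How many records per extreme.
#' @return List with `highest` and `lowest` data frames, sorted by `p_S`
#'   descending / ascending; ties broken by `(cell_id, community_id)`.
#' @export
extreme_subgraphs <- function(records, cell_type, top_n = 10L) {
  rows <- records[!is.na(records$cell_type) & records$cell_type == cell_type, ,
                  drop = FALSE]
  stopifnot(nrow(rows) >= 1L)
  hi <- rows[order(-rows$p_S, rows$cell_id, rows$community_id), , drop = FALSE]
  lo <- rows[order(rows$p_S, rows$cell_id, rows$community_id), , drop = FALSE]
  list(highest = utils::head(hi, top_n), lowest = utils::head(lo, top_n))
}

#' Gene co-occurrence network over selected subgraphs
#'
#' Builds a weighted gene-gene graph from the transcript-level edges lying
#' inside the selected communities: nodes are gene symbols and the weight
#' of edge (g1, g2) counts the transcript edges joining those two genes
#' across all selected subgraphs (self-pairs become self-loops). Edges
#' with co-occurrence weight strictly below `alpha` are removed
#' (default `alpha = 1`).
#'
#' @param cells Named list of `cell_graph`s (names or `cell_id`s matching
#'   the records).
#' @param records Selected [subgraph_scores()] rows (e.g. from
#'   [extreme_subgraphs()]).
#' @param vocab The model's `gene_vocabulary`.
#' @param alpha Minimum co-occurrence weight to keep an edge.
#' @return `data.frame`: `gene_a`, `gene_b` (lexicographic, `gene_a <=
#'   gene_b`), integer `weight`.
#' @export
cooccurrence_network <- function(cells, records, vocab, alpha = 1L) {
  by_id <- stats::setNames(cells, vapply(cells, `[[`, character(1), "cell_id"))
  pairs <- list()
  for (r in seq_len(nrow(records))) {
    g <- by_id[[records$cell_id[r]]]
    if (is.null(g)) stop("cell not found: ", records$cell_id[r])
    cm <- records$community_id[r]
    in_cm <- g$partition == cm
    e <- g$edges
    e <- e[in_cm[e[, 1]] & in_cm[e[, 2]], , drop = FALSE]
    if (nrow(e) == 0L) next
    ga <- vocab$symbols[g$genes[e[, 1]]]
    gb <- vocab$symbols[g$genes[e[, 2]]]
    pairs[[length(pairs) + 1L]] <- data.frame(
      gene_a = pmin(ga, gb), gene_b = pmax(ga, gb), stringsAsFactors = FALSE)
  }
  if (length(pairs) == 0L) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      weight = integer(0)))
  }
  all_pairs <- do.call(rbind, pairs)
  agg <- stats::aggregate(list(weight = rep(1L, nrow(all_pairs))),
                          by = all_pairs, FUN = sum)
  agg <- agg[agg$weight >= alpha, , drop = FALSE]
  agg <- agg[order(agg$gene_a, agg$gene_b), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Write a co-occurrence network
#'
#' Weighted edge list as TSV, or GraphML via igraph.
#'
#' @param network A [cooccurrence_network()] data frame.
#' @param path Output file; format chosen by extension (`.graphml` or TSV
#'   otherwise).
#' @return `path`, invisibly.
#' @export
write_cooccurrence <- function(network, path) {
  if (grepl("\\.graphml$", path)) {
    genes <- sort(unique(c(network$gene_a, network$gene_b)))
    g <- igraph::graph_from_data_frame(
      data.frame(from = network$gene_a, to = network$gene_b,
                 weight = network$weight),
      directed = FALSE,
      vertices = data.frame(name = genes))
    igraph::write_graph(g, path, format = "graphml")
  } else {
    utils::write.table(network, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
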