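# A small trained-enough model (2 epochs) over a toy dataset, shared by
# the interpretation tests.
make_toy_model <- function() {
  withr::with_seed(90, {
    tx <- data.frame(
      cell_id = rep(sprintf("c%02d", 1:10), each = 30),
      gene = paste0("g", sprintf("%02d", sample(1:6, 300, replace = TRUE))),
      x = rep(seq(0, 90, by = 10), each = 30) + rnorm(300, sd = 2),
      y = rnorm(300, sd = 2))
  })
  labels <- data.frame(cell_id = sprintf("c%02d", 1:5),
                       cell_type = rep(c("A", "B"), length.out = 5))
  vocab <- build_vocabulary(tx)
  gcfg <- graph_config(d = 2, seed = 1L)
  ref <- build_cell_graphs(tx[tx$cell_id %in% labels$cell_id, ], gcfg, vocab,
                           labels = labels, verbose = FALSE)
  qry <- build_cell_graphs(tx[!tx$cell_id %in% labels$cell_id, ], gcfg, vocab,
                           verbose = FALSE)
  m <- fit_gcl(ref, qry, vocab,
               encoder = encoder_config(hidden = 4L, n_classes = 2L),
               train = train_config(epochs = 2L, batch_size = 5L, seed = 2L),
               verbose = FALSE)
  list(model = m, query = qry)
}

toy <- make_toy_model()

test_that("gene importance equals a groupby-mean of node scores", {
  types <- rep(c("A", "B"), length.out = length(toy$query))
  imp <- gene_importance(toy$model, toy$query, types)
  sc <- node_scores(toy$model, toy$query)
  # oracle: flat per-transcript table, then mean by (type, gene)
  flat <- do.call(rbind, lapply(seq_along(toy$query), function(i) {
    data.frame(ct = types[i],
               gene = toy$model$vocab$symbols[toy$query[[i]]$genes],
               p = sc[[i]]$p_v)
  }))
  for (r in seq_len(nrow(imp))) {
    sel <- flat$ct == imp$cell_type[r] & flat$gene == imp$gene[r]
    expect_equal(imp$mean_score[r], mean(flat$p[sel]), tolerance = 1e-9)
    expect_equal(imp$n_transcripts[r], sum(sel))
  }
  # ranks are contiguous and descending in score within each type
  for (ct in unique(imp$cell_type)) {
    sub <- imp[imp$cell_type == ct, ]
    expect_equal(sort(sub$rank), seq_len(nrow(sub)))
    expect_true(all(diff(sub$mean_score[order(sub$rank)]) <= 1e-12))
  }
})

test_that("subgraph scores conserve the total node score within each cell", {
  recs <- subgraph_scores(toy$model, toy$query)
  sc <- node_scores(toy$model, toy$query)
  for (i in seq_along(toy$query)) {
    g <- toy$query[[i]]
    rows <- recs[recs$cell_id == g$cell_id, ]
    # sum over communities of |S| * p_S equals sum of p_v exactly
    expect_equal(sum(rows$n_members * rows$p_S), sum(sc[[i]]$p_v),
                 tolerance = 1e-9)
    expect_equal(sum(rows$n_members), g$n)
  }
})

test_that("extreme subgraphs are the sorted head and tail of the records", {
  types <- rep("A", length(toy$query))
  recs <- subgraph_scores(toy$model, toy$query, types)
  ex <- extreme_subgraphs(recs, "A", top_n = 3L)
  expect_lte(nrow(ex$highest), 3L)
  expect_equal(ex$highest$p_S, sort(recs$p_S, decreasing = TRUE)[1:nrow(ex$highest)])
  expect_equal(ex$lowest$p_S, sort(recs$p_S)[1:nrow(ex$lowest)])
})

test_that("rnk export is two-column, descending, and reads back", {
  types <- rep(c("A", "B"), length.out = length(toy$query))
  imp <- gene_importance(toy$model, toy$query, types)
  path <- withr::local_tempfile(fileext = ".rnk")
  write_rnk(imp, "A", path)
  back <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("gene", "score"))
  expect_equal(nrow(back), sum(imp$cell_type == "A"))
  expect_true(all(diff(back$score) <= 1e-12))
  expect_error(write_rnk(imp, "NoSuchType", withr::local_tempfile()),
               "not present")
})

test_that("co-occurrence network counts intra-community gene pair edges", {
  # hand-built graph: triangle of genes (1,1,2) in community 1 and an
  # isolated pair (2,3) in community 2
  g <- structure(list(
    cell_id = "cc", genes = c(1L, 1L, 2L, 2L, 3L), d = 3L,
    coords = cbind(1:5, 0),
    edges = rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L), c(4L, 5L)),
    n = 5L, partition = c(1L, 1L, 1L, 2L, 2L)), class = "cell_graph")
  vocab <- build_vocabulary(c("gA", "gB", "gC"))
  recs <- data.frame(cell_id = "cc", community_id = c(1L, 2L))
  net <- cooccurrence_network(list(cc = g), recs, vocab)
  # expected: gA-gA x1 (edge 1-2), gA-gB x2 (edges 1-3, 2-3), gB-gC x1
  expect_equal(net$weight[net$gene_a == "gA" & net$gene_b == "gA"], 1L)
  expect_equal(net$weight[net$gene_a == "gA" & net$gene_b == "gB"], 2L)
  expect_equal(net$weight[net$gene_a == "gB" & net$gene_b == "gC"], 1L)
  # alpha threshold prunes rare pairs
  net2 <- cooccurrence_network(list(cc = g), recs, vocab, alpha = 2L)
  expect_equal(nrow(net2), 1L)
  expect_equal(net2$gene_a, "gA")
  # TSV round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cooccurrence(net, path)
  back <- utils::read.table(path, sep = "\t", header = TRUE)
  expect_equal(back$weight, net$weight)
})
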