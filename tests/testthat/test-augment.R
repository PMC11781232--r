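make_scores <- function(g, params, cfg, noise = FALSE) {
  H <- gin_encode(g, cfg, params)
  compute_node_scores(H, params, temperature = 1, noise = noise)
}

test_that("node scores live in [0, 2] and are deterministic in eval mode", {
  g <- toy_graph(10L)
  cfg <- encoder_config(hidden = 8L, n_classes = 2L)
  params <- spatialGCL:::init_params(cfg, g$d, seed = 2L)
  s1 <- make_scores(g, params, cfg)
  s2 <- make_scores(g, params, cfg)
  expect_identical(s1$p_v, s2$p_v)
  expect_true(all(s1$p_v >= 0 & s1$p_v <= 2))
  # training mode adds Gumbel noise: still bounded, seeded-reproducible
  withr::with_seed(4, n1 <- make_scores(g, params, cfg, noise = TRUE))
  withr::with_seed(4, n2 <- make_scores(g, params, cfg, noise = TRUE))
  expect_identical(n1$p_v, n2$p_v)
  expect_true(all(n1$p_v >= 0 & n1$p_v <= 2))
})

test_that("edge keep probabilities average the endpoint scores", {
  p_v <- c(2, 1, 0.5, 0)
  edges <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(1L, 4L))
  expect_equal(compute_edge_scores(p_v, edges),
               c((2 + 1) / 4, (1 + 0.5) / 4, (0.5 + 0) / 4, (2 + 0) / 4))
  expect_equal(compute_edge_scores(p_v, edges[0, , drop = FALSE]), numeric(0))
})

test_that("subgraph scores match an explicit groupby-mean to 1e-9", {
  withr::with_seed(31, {
    for (i in 1:20) {
      n <- sample(5:60, 1)
      p_v <- runif(n, 0, 2)
      part <- sample(1:4, n, replace = TRUE)
      part[1:4] <- 1:4  # every community inhabited
      got <- compute_subgraph_scores(p_v, part)
      want <- as.numeric(by(p_v, part, mean))
      expect_equal(got, want, tolerance = 1e-9)
    }
  })
})

test_that("the identical policy returns the raw graph as a fixed point", {
  g <- toy_graph(9L)
  cfg <- encoder_config(hidden = 6L, n_classes = 2L)
  params <- spatialGCL:::init_params(cfg, g$d, seed = 5L)
  s <- make_scores(g, params, cfg)
  v <- generate_view(g, s, augment_policy("identical"))
  expect_identical(v$genes, g$genes)
  expect_identical(v$edges, g$edges)
  expect_identical(v$node_ids, seq_len(g$n))
  expect_false(any(v$masked))
  # eval-mode embeddings of the identity view equal the raw graph's
  # bit for bit
  expect_identical(resgcn_encode(v, cfg, params, training = FALSE),
                   resgcn_encode(g, cfg, params, training = FALSE))
})

test_that("node dropping keeps a subset, remaps edges and never empties", {
  g <- toy_graph(12L)
  cfg <- encoder_config(hidden = 6L, n_classes = 2L)
  params <- spatialGCL:::init_params(cfg, g$d, seed = 6L)
  withr::with_seed(8, {
    for (i in 1:20) {
      s <- make_scores(g, params, cfg, noise = TRUE)
      v <- apply_node_dropping(spatialGCL:::new_view(g), s)
      expect_gte(v$n, 1L)
      expect_true(all(v$node_ids %in% seq_len(g$n)))
      expect_identical(v$genes, g$genes[v$node_ids])
      if (nrow(v$edges) > 0) {
        # every surviving edge is an original edge between survivors
        orig <- paste(g$edges[, 1], g$edges[, 2])
        mapped <- paste(v$node_ids[v$edges[, 1]], v$node_ids[v$edges[, 2]])
        expect_true(all(mapped %in% orig))
      }
    }
  })
})

test_that("node masking zeroes feature rows without touching topology", {
  g <- toy_graph(10L)
  cfg <- encoder_config(hidden = 6L, n_classes = 2L)
  params <- spatialGCL:::init_params(cfg, g$d, seed = 7L)
  withr::with_seed(12, {
    s <- make_scores(g, params, cfg, noise = TRUE)
    v <- apply_node_masking(spatialGCL:::new_view(g), s)
    expect_identical(v$edges, g$edges)
    expect_identical(v$genes, g$genes)
    X <- spatialGCL:::view_features(v)
    if (any(v$masked)) expect_true(all(X[v$masked, ] == 0))
    expect_equal(unname(rowSums(X)), as.numeric(!v$masked))
  })
})

test_that("edge perturbation keeps edge subsets at node level and only
           touches inter-community edges at subgraph level", {
  g <- toy_graph(12L)
  cfg <- encoder_config(hidden = 6L, n_classes = 2L)
  params <- spatialGCL:::init_params(cfg, g$d, seed = 9L)
  withr::with_seed(15, {
    for (i in 1:10) {
      s <- make_scores(g, params, cfg, noise = TRUE)
      vn <- apply_edge_perturbation(spatialGCL:::new_view(g), s, "node")
      orig <- paste(g$edges[, 1], g$edges[, 2])
      expect_true(all(paste(vn$edges[, 1], vn$edges[, 2]) %in% orig))
      vs <- apply_edge_perturbation(spatialGCL:::new_view(g), s, "subgraph")
      intra <- g$partition[g$edges[, 1]] == g$partition[g$edges[, 2]]
      kept <- paste(vs$edges[, 1], vs$edges[, 2])
      expect_true(all(orig[intra] %in% kept))
    }
  })
})

test_that("subgraph swap preserves node count and produces valid edges", {
  # a graph with enough communities to swap
  withr::with_seed(44, {
    tx <- data.frame(
      cell_id = "sw",
      gene = paste0("g", sprintf("%02d", sample(1:5, 40, replace = TRUE))),
      x = c(rnorm(20, 0, 1), rnorm(20, 10, 1)),
      y = c(rnorm(20, 0, 1), rnorm(20, 10, 1)))
  })
  vocab <- build_vocabulary(tx)
  g <- build_cell_graphs(tx, graph_config(d = 3, seed = 1L), vocab,
                         verbose = FALSE)[[1]]
  expect_gte(max(g$partition), 2L)  # two separated blobs -> >= 2 communities
  cfg <- encoder_config(hidden = 6L, n_classes = 2L)
  params <- spatialGCL:::init_params(cfg, g$d, seed = 10L)
  withr::with_seed(16, {
    for (i in 1:10) {
      s <- make_scores(g, params, cfg, noise = TRUE)
      v <- apply_subgraph_swap(spatialGCL:::new_view(g), s)
      expect_equal(v$n, g$n)
      if (nrow(v$edges)) {
        expect_true(all(v$edges[, 1] < v$edges[, 2]))
        expect_true(all(v$edges >= 1 & v$edges <= v$n))
        expect_false(any(duplicated(paste(v$edges[, 1], v$edges[, 2]))))
      }
    }
  })
})

test_that("augmentation policies resolve and reject unknown operators", {
  expect_equal(length(augment_policy("identical")), 0L)
  expect_setequal(augment_policy("all"),
                  c("edge_perturbation_subgraph", "subgraph_swap",
                    "node_dropping", "node_masking",
                    "edge_perturbation_node"))
  expect_error(augment_policy("typo_operator"))
})
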