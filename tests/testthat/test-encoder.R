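test_that("gin_layer matches a per-node loop on random small graphs", {
  withr::with_seed(21, {
    for (i in 1:100) {
      n <- sample(1:10, 1)
      p <- sample(2:5, 1); q <- sample(2:5, 1)
      A <- matrix(0, n, n)
      if (n > 1) {
        up <- which(upper.tri(A))
        on <- up[runif(length(up)) < 0.4]
        A[on] <- 1
        A <- A + t(A)
      }
      H <- matrix(rnorm(n * p), n, p)
      W <- matrix(rnorm(p * q), p, q)
      eps <- rnorm(1)
      expect_equal(gin_layer(H, A, eps, W), oracle_gin_layer(H, A, eps, W),
                   tolerance = 1e-12)
    }
  })
})

test_that("sum-pooled embeddings are invariant to node relabeling", {
  g <- toy_graph(12L, d_vocab = 4L)
  cfg <- encoder_config(hidden = 8L, n_classes = 2L)
  params <- spatialGCL:::init_params(cfg, g$d, seed = 3L)
  hg <- sum_pool(resgcn_encode(g, cfg, params, training = FALSE))
  withr::with_seed(9, {
    for (i in 1:10) {
      perm <- sample(g$n)
      gp <- g
      gp$genes <- g$genes[perm]
      gp$coords <- g$coords[perm, , drop = FALSE]
      inv <- integer(g$n); inv[perm] <- seq_len(g$n)
      e <- cbind(inv[g$edges[, 1]], inv[g$edges[, 2]])
      swap <- e[, 1] > e[, 2]
      e[swap, ] <- e[swap, 2:1]
      gp$edges <- e[order(e[, 1], e[, 2]), , drop = FALSE]
      gp$partition <- g$partition[perm]
      hgp <- sum_pool(resgcn_encode(gp, cfg, params,
                                    training = FALSE))
      expect_equal(hgp, hg, tolerance = 1e-5)
      # GIN node embeddings are permutation-equivariant
      Hp <- gin_encode(gp, cfg, params)
      H <- gin_encode(g, cfg, params)
      expect_equal(Hp, H[perm, , drop = FALSE], tolerance = 1e-10,
                   ignore_attr = TRUE)
    }
  })
})

test_that("residual layers leave an all-zero input pathway stable", {
  # with ReLU(Z) + H residual form, layers >= 2 can only add to the
  # carried signal; a zero weight matrix must act as the identity
  g <- toy_graph(6L)
  cfg <- encoder_config(resgcn_layers = 3L, hidden = 5L, n_classes = 2L)
  params <- spatialGCL:::init_params(cfg, g$d, seed = 1L)
  params$enc_W[[2]][] <- 0
  params$enc_W[[3]][] <- 0
  one_layer <- encoder_config(resgcn_layers = 1L, hidden = 5L, n_classes = 2L)
  p1 <- params
  p1$enc_W <- params$enc_W[1]
  expect_equal(resgcn_encode(g, cfg, params),
               resgcn_encode(g, one_layer, p1))
})

test_that("classifier logits are invariant to embedding magnitude", {
  cfg <- encoder_config(hidden = 4L, n_classes = 3L)
  params <- spatialGCL:::init_params(cfg, 5L, seed = 2L)
  hg <- c(0.3, -1.2, 2.0, 0.5)
  expect_equal(classify(hg, params), classify(100 * hg, params),
               tolerance = 1e-12)
  expect_error(classify(numeric(4), params), "zero-norm")
})

test_that("softmax is stable under large logit offsets and sums to one", {
  x <- c(1000, 1001, 999)
  p <- softmax(x)
  expect_equal(sum(p), 1)
  expect_equal(p, softmax(x - 1000))
  expect_false(any(is.nan(p)))
})

test_that("model checkpoints round-trip through JSON to double precision", {
  cfg <- encoder_config(gin_layers = 2L, resgcn_layers = 2L, hidden = 6L,
                        n_classes = 2L)
  model <- structure(list(
    params = spatialGCL:::init_params(cfg, 4L, seed = 8L),
    encoder = cfg,
    train = train_config(epochs = 2L),
    classes = c("TypeA", "TypeB"),
    vocab = build_vocabulary(c("g1", "g2", "g3", "g4")),
    gumbel_temperature = 1,
    loss_history = data.frame(epoch = 1:2, L_cl = c(1, 0.5),
                              L_cls = c(0.7, 0.6), L_reg = c(0, 0),
                              L = c(1.7, 1.1))
  ), class = "gcl_model")
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  expect_equal(back$params, model$params, tolerance = 1e-14)
  expect_equal(back$classes, model$classes)
  expect_equal(back$vocab$index, model$vocab$index)
  expect_equal(unclass(back$encoder), unclass(model$encoder))
})

test_that("encoder gradients match finite differences through the losses", {
  # end-to-end check of resgcn_backward: d(combined loss)/d(enc_W) on a
  # tiny two-cell batch, against central differences
  g1 <- toy_graph(6L, seed = 4L)
  g2 <- toy_graph(7L, seed = 5L)
  cfg <- encoder_config(resgcn_layers = 2L, hidden = 4L, dropout = 0,
                        n_classes = 2L)
  params <- spatialGCL:::init_params(cfg, g1$d, seed = 6L)
  loss_of <- function(params) {
    Z <- rbind(
      spatialGCL:::resgcn_forward(spatialGCL:::view_features(g1), spatialGCL:::adjacency_normalized(g1),
                     cfg, params)$hg,
      spatialGCL:::resgcn_forward(spatialGCL:::view_features(g2), spatialGCL:::adjacency_normalized(g2),
                     cfg, params)$hg)
    as.numeric(ntxent_loss(Z, tau = 0.5))
  }
  fwd1 <- spatialGCL:::resgcn_forward(spatialGCL:::view_features(g1), spatialGCL:::adjacency_normalized(g1),
                         cfg, params)
  fwd2 <- spatialGCL:::resgcn_forward(spatialGCL:::view_features(g2), spatialGCL:::adjacency_normalized(g2),
                         cfg, params)
  l <- ntxent_loss(rbind(fwd1$hg, fwd2$hg), tau = 0.5, grad = TRUE)
  dZ <- attr(l, "gradient")
  grads <- list(enc_W = lapply(params$enc_W, function(w) w * 0))
  grads <- spatialGCL:::resgcn_backward(dZ[1, ], fwd1, spatialGCL:::view_features(g1),
                           spatialGCL:::adjacency_normalized(g1), params, grads)$grads
  grads <- spatialGCL:::resgcn_backward(dZ[2, ], fwd2, spatialGCL:::view_features(g2),
                           spatialGCL:::adjacency_normalized(g2), params, grads)$grads
  eps <- 1e-6
  for (l_i in 1:2) {
    idx <- cbind(c(1, 2), c(1, 3))
    for (r in seq_len(nrow(idx))) {
      pp <- params; pm <- params
      pp$enc_W[[l_i]][idx[r, 1], idx[r, 2]] <-
        pp$enc_W[[l_i]][idx[r, 1], idx[r, 2]] + eps
      pm$enc_W[[l_i]][idx[r, 1], idx[r, 2]] <-
        pm$enc_W[[l_i]][idx[r, 1], idx[r, 2]] - eps
      num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      expect_equal(grads$enc_W[[l_i]][idx[r, 1], idx[r, 2]], num,
                   tolerance = 1e-5)
    }
  }
})
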