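test_that("NT-Xent is exactly zero for a single positive pair", {
  withr::with_seed(51, {
    for (i in 1:10) {
      Z <- matrix(rnorm(2 * 7), 2, 7)
      expect_equal(as.numeric(ntxent_loss(Z, tau = runif(1, 0.1, 2))), 0,
                   tolerance = 1e-12)
    }
  })
})

test_that("NT-Xent reproduces the orthogonal two-cell closed form", {
  # two cells, views identical within a pair, pairs mutually orthogonal:
  # each anchor sees one positive at cos=1 and two negatives at cos=0, so
  # l = -log(e / (e + 2)) at tau = 1 for every one of the 4 directions
  Z <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  want <- -log(exp(1) / (exp(1) + 2))
  expect_equal(as.numeric(ntxent_loss(Z, tau = 1)), want, tolerance = 1e-6)
})

test_that("NT-Xent is invariant to per-row rescaling (cosine geometry)", {
  withr::with_seed(52, {
    Z <- matrix(rnorm(8 * 5), 8, 5)
    scales <- runif(8, 0.1, 10)
    expect_equal(as.numeric(ntxent_loss(Z * scales, tau = 0.5)),
                 as.numeric(ntxent_loss(Z, tau = 0.5)), tolerance = 1e-10)
  })
})

test_that("cross-entropy returns log C on uniform logits", {
  for (C in 2:6) {
    logits <- matrix(0, 5, C)
    y <- rep_len(seq_len(C), 5)
    expect_equal(as.numeric(cross_entropy_loss(logits, y)), log(C),
                 tolerance = 1e-12)
  }
})

test_that("combined loss is the lambda-weighted sum of its terms", {
  withr::with_seed(53, {
    for (i in 1:20) {
      a <- runif(1, 0, 5); b <- runif(1, 0, 5); lam <- runif(1, 0, 5)
      expect_equal(combined_loss(a, b, lam), a + lam * b, tolerance = 1e-6)
    }
  })
})

test_that("loss gradients match finite differences", {
  withr::with_seed(54, {
    Z <- matrix(rnorm(6 * 4), 6, 4)
    l <- ntxent_loss(Z, tau = 0.7, grad = TRUE)
    G <- attr(l, "gradient")
    eps <- 1e-6
    for (idx in sample(length(Z), 8)) {
      Zp <- Z; Zp[idx] <- Zp[idx] + eps
      Zm <- Z; Zm[idx] <- Zm[idx] - eps
      num <- (as.numeric(ntxent_loss(Zp, 0.7)) -
                as.numeric(ntxent_loss(Zm, 0.7))) / (2 * eps)
      expect_equal(G[idx], num, tolerance = 1e-5)
    }
    logits <- matrix(rnorm(5 * 3), 5, 3)
    y <- c(1L, 3L, 2L, 1L, 2L)
    lc <- cross_entropy_loss(logits, y, grad = TRUE)
    Gc <- attr(lc, "gradient")
    for (idx in sample(length(logits), 6)) {
      lp <- logits; lp[idx] <- lp[idx] + eps
      lm <- logits; lm[idx] <- lm[idx] - eps
      num <- (as.numeric(cross_entropy_loss(lp, y)) -
                as.numeric(cross_entropy_loss(lm, y))) / (2 * eps)
      expect_equal(Gc[idx], num, tolerance = 1e-5)
    }
  })
})

test_that("Adam takes a bias-corrected first step of size lr", {
  params <- list(w = matrix(c(1, -2), 1, 2), b = 0.5)
  grads <- list(w = matrix(c(0.3, -0.1), 1, 2), b = -2)
  state <- list(t = 0L, m = spatialGCL:::zeros_like(params),
                v = spatialGCL:::zeros_like(params))
  upd <- spatialGCL:::adam_step(params, grads, state, lr = 0.01)
  # after bias correction the first update is lr * sign(g) (up to eps)
  expect_equal(upd$params$w, params$w - 0.01 * sign(grads$w),
               tolerance = 1e-4)
  expect_equal(upd$params$b, params$b - 0.01 * sign(grads$b),
               tolerance = 1e-4)
  # zero gradient leaves a parameter untouched
  g0 <- list(w = matrix(0, 1, 2), b = 0)
  s0 <- list(t = 0L, m = spatialGCL:::zeros_like(params),
             v = spatialGCL:::zeros_like(params))
  expect_equal(spatialGCL:::adam_step(params, g0, s0, lr = 0.01)$params,
               params)
})

test_that("training is deterministic given a seed and reduces the loss", {
  withr::with_seed(60, {
    tx <- data.frame(
      cell_id = rep(sprintf("c%02d", 1:12), each = 25),
      gene = paste0("g", sprintf("%02d", sample(1:6, 300, replace = TRUE))),
      x = rep(rnorm(12, sd = 0.1), each = 25) + rnorm(300, sd = 2),
      y = rep(rnorm(12, sd = 0.1), each = 25) + rnorm(300, sd = 2))
  })
  labels <- data.frame(cell_id = sprintf("c%02d", 1:6),
                       cell_type = rep(c("A", "B"), 3))
  vocab <- build_vocabulary(tx)
  gcfg <- graph_config(d = 2, seed = 1L)
  ref <- build_cell_graphs(tx[tx$cell_id %in% labels$cell_id, ], gcfg, vocab,
                           labels = labels, verbose = FALSE)
  qry <- build_cell_graphs(tx[!tx$cell_id %in% labels$cell_id, ], gcfg, vocab,
                           verbose = FALSE)
  enc <- encoder_config(hidden = 4L, n_classes = 2L)
  tr <- train_config(epochs = 3L, batch_size = 6L, seed = 7L)
  m1 <- fit_gcl(ref, qry, vocab, encoder = enc, train = tr, verbose = FALSE)
  m2 <- fit_gcl(ref, qry, vocab, encoder = enc, train = tr, verbose = FALSE)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_equal(m1$classes, c("A", "B"))
  # annotation output is well-formed
  pred <- annotate_cells(m1, qry)
  expect_equal(nrow(pred), length(qry))
  expect_true(all(pred$predicted_type %in% m1$classes))
  probs <- as.matrix(pred[, grep("^prob_", names(pred))])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(pred)), tolerance = 1e-9)
})

test_that("the loss history decomposes as L = L_cl + lambda L_cls + L_reg", {
  withr::with_seed(61, {
    tx <- data.frame(
      cell_id = rep(sprintf("c%02d", 1:8), each = 20),
      gene = paste0("g", sprintf("%02d", sample(1:5, 160, replace = TRUE))),
      x = rnorm(160, sd = 2), y = rnorm(160, sd = 2))
  })
  labels <- data.frame(cell_id = sprintf("c%02d", 1:4),
                       cell_type = rep(c("A", "B"), 2))
  vocab <- build_vocabulary(tx)
  gcfg <- graph_config(d = 2, seed = 1L)
  ref <- build_cell_graphs(tx[tx$cell_id %in% labels$cell_id, ], gcfg, vocab,
                           labels = labels, verbose = FALSE)
  qry <- build_cell_graphs(tx[!tx$cell_id %in% labels$cell_id, ], gcfg, vocab,
                           verbose = FALSE)
  tr <- train_config(epochs = 2L, batch_size = 4L, lambda = 2.5,
                     keep_reg = 0.3, seed = 3L)
  m <- fit_gcl(ref, qry, vocab,
               encoder = encoder_config(hidden = 4L, n_classes = 2L),
               train = tr, verbose = FALSE)
  h <- m$loss_history
  expect_equal(h$L, h$L_cl + 2.5 * h$L_cls + h$L_reg, tolerance = 1e-9)
  expect_true(all(h$L_reg >= 0))
})
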