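#' Training configuration
#'
#' Defaults are the tuned operating point: temperature `tau = 0.5`, batch
#' size 32, learning rate 5e-4, and contrastive/supervised balance
#' `lambda = 1` (1 and 5 perform equivalently). Training runs a fixed
#' number of epochs with no early stopping.
#'
#' @param tau NT-Xent temperature (> 0).
#' @param lambda Weight of the supervised cross-entropy term in the
#'   combined loss `L = L_cl + lambda * L_cls`.
#' @param batch_size Cells per batch (N); the contrastive loss sees 2N
#'   views.
#' @param lr Adam learning rate.
#' @param epochs Number of passes over the data.
#' @param keep_reg Optional keep-rate regularizer on the learned node
#'   scores (default 0, off). When positive, it penalizes the mean sampled
#'   augmentation probability, biasing views toward mild perturbation.
#'   Anchoring the supervised loss on the identity view already prevents
#'   the drop-everything collapse, and a strong penalty is
#'   counterproductive: it saturates the keep probabilities where the
#'   sigmoid gradient vanishes, freezing the score ranking at early random
#'   drift. Reserve it for aggressive custom policies.
#' @param seed Root seed for parameter initialization, batching, Gumbel
#'   noise and augmentation sampling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(tau = 0.5, lambda = 1, batch_size = 32L, lr = 5e-4,
                         epochs = 50L, keep_reg = 0, seed = 0L) {
  stopifnot(tau > 0, lambda >= 0, batch_size >= 2, lr > 0, epochs >= 1,
            keep_reg >= 0)
  structure(list(tau = tau, lambda = lambda,
                 batch_size = as.integer(batch_size), lr = lr,
                 epochs = as.integer(epochs), keep_reg = keep_reg,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' NT-Xent contrastive loss
#'
#' Normalized temperature-scaled cross-entropy over 2N graph embeddings,
#' where rows (2k-1, 2k) are the two augmented views of cell k (the
#' positive pair) and all other views in the batch are negatives:
#' `l(i,j) = -log( exp(sim(i,j)/tau) / sum_{k != i} exp(sim(i,k)/tau) )`
#' with cosine similarity, averaged over both directions of every pair.
#' With a single cell (N = 1) the denominator holds only the positive term
#' and the loss is exactly 0.
#'
#' @param embeddings `2N x hidden` matrix of graph embeddings, paired rows.
#' @param tau Temperature (> 0).
#' @return Non-negative scalar loss (with gradient wrt the embeddings in
#'   attribute `gradient` when `grad = TRUE`).
#' @param grad Also return the gradient.
#' @export
ntxent_loss <- function(embeddings, tau = 0.5, grad = FALSE) {
  Z <- as.matrix(embeddings)
  n2 <- nrow(Z)
  stopifnot(n2 >= 2L, n2 %% 2L == 0L, tau > 0)
  r <- sqrt(rowSums(Z^2))
  if (any(r == 0)) stop("zero-norm embedding: cosine similarity undefined")
  U <- Z / r
  S <- tcrossprod(U)
  partner <- ifelse(seq_len(n2) %% 2L == 1L, seq_len(n2) + 1L, seq_len(n2) - 1L)
  L <- 0
  G <- matrix(0, n2, n2)
  for (i in seq_len(n2)) {
    s <- S[i, -i] / tau
    m <- max(s)
    lse <- m + log(sum(exp(s - m)))
    L <- L + (lse - S[i, partner[i]] / tau)
    if (grad) {
      p <- exp(s - lse)
      gi <- numeric(n2)
      gi[-i] <- p
      gi[partner[i]] <- gi[partner[i]] - 1
      G[i, ] <- gi / tau
    }
  }
  L <- L / n2
  if (!grad) return(L)
  G <- G / n2
  dU <- (G + t(G)) %*% U
  dZ <- (dU - U * rowSums(dU * U)) / r
  attr(L, "gradient") <- dZ
  L
}

#' Cross-entropy classification loss
#'
#' Mean over labeled views of the negative log softmax-probability of the
#' true cell type. An empty label set yields 0.
#'
#' @param logits `V x C` matrix of class logits (one row per labeled view).
#' @param labels Integer class indices in `1..C`.
#' @param grad Also return the gradient wrt the logits.
#' @return Scalar loss (gradient in attribute `gradient` when requested).
#' @export
cross_entropy_loss <- function(logits, labels, grad = FALSE) {
  if (length(labels) == 0L) {
    L <- 0
    if (grad) attr(L, "gradient") <- matrix(0, 0, ncol(logits))
    return(L)
  }
  logits <- matrix(logits, nrow = length(labels))
  if (any(labels < 1L | labels > ncol(logits))) stop("label outside class range")
  m <- apply(logits, 1, max)
  lse <- m + log(rowSums(exp(logits - m)))
  L <- mean(lse - logits[cbind(seq_along(labels), labels)])
  if (!grad) return(L)
  P <- exp(logits - lse)
  P[cbind(seq_along(labels), labels)] <- P[cbind(seq_along(labels), labels)] - 1
  attr(L, "gradient") <- P / length(labels)
  L
}

#' Combined semi-supervised loss
#'
#' `L = L_cl + lambda * L_cls`.
#'
#' @param l_cl Contrastive component.
#' @param l_cls Classification component.
#' @param lambda Balance weight.
#' @return Scalar total loss.
#' @export
combined_loss <- function(l_cl, l_cls, lambda = 1) {
  as.numeric(l_cl) + lambda * as.numeric(l_cls)
}

# --- parameter-tree utilities (params, gradients and Adam moments share
# the same nested-list shape) ---

ptree_map <- function(f, ...) {
  trees <- list(...)
  rec <- function(...) {
    xs <- list(...)
    if (is.numeric(xs[[1]])) return(do.call(f, xs))
    out <- xs[[1]]
    for (i in seq_along(out)) out[[i]] <- do.call(rec, lapply(xs, `[[`, i))
    out
  }
  do.call(rec, trees)
}

zeros_like <- function(params) ptree_map(function(x) x * 0, params)

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- ptree_map(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- ptree_map(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- ptree_map(function(p, m, v) p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
                      params, state$m, state$v)
  list(params = params, state = state)
}

# Backward pass through the ResGCN given d(loss)/d(hg). Returns gradient
# contributions for enc_W and d(loss)/dX' (the masked input features).
# With grads = NULL only dX is computed (used for the score-head gradient,
# which flows from the supervised loss alone).
resgcn_backward <- function(dhg, fwd, X, Ahat, params, grads) {
  t_layers <- length(params$enc_W)
  n <- nrow(X)
  dH <- matrix(dhg, n, length(dhg), byrow = TRUE)  # d colSums
  for (l in rev(seq_len(t_layers))) {
    cc <- fwd$cache[[l]]
    if (!is.null(cc$drop_mask)) dH <- dH * cc$drop_mask
    dZ <- dH * (cc$Z > 0)
    if (!is.null(grads)) {
      grads$enc_W[[l]] <- grads$enc_W[[l]] + crossprod(cc$M, dZ)
    }
    dM <- tcrossprod(dZ, params$enc_W[[l]])
    dH_prev <- Ahat %*% dM
    if (l > 1L) dH <- dH_prev + dH else dX <- dH_prev
  }
  list(grads = grads, dX = dX)
}

# Backward through one Gumbel-Softmax scoring head: dp (per original node,
# zeros where no gradient) -> gradients for the head and dU on the
# row-normalized GIN embeddings the heads read. y_aug is the sampled
# "augment" probability per node.
score_head_backward <- function(dp, y_aug, temperature, U, head, ghead) {
  # p = 1 - y_aug; dy_aug/da_aug = y(1-y), a = (logits+g)/T
  coef <- dp * y_aug * (1 - y_aug) / temperature
  dlogits <- cbind(-coef, coef)  # column 1 = augment, column 2 = keep
  ghead$W <- ghead$W + crossprod(U, dlogits)
  ghead$b <- ghead$b + colSums(dlogits)
  list(ghead = ghead, dU = tcrossprod(dlogits, head$W))
}

#' Fit the graph-contrastive cell type annotator
#'
#' Semi-supervised training over labeled reference cells and unlabeled
#' query cells. Each epoch shuffles all cells into mixed batches
#' (stratified so labeled cells spread across batches); for every batch,
#' the GIN scorer produces node scores, two stochastic augmented views per
#' cell are generated, the ResGCN encodes all views, and one Adam step
#' minimizes `L = L_cl + lambda * L_cls`, where the NT-Xent contrastive
#' term runs over all 2N views and the cross-entropy term over both views
#' of every labeled cell. Gradients reach the scoring heads through the
#' Gumbel-Softmax relaxation with a straight-through estimator on the hard
#' node keep/mask decisions; query cells contribute nothing to the
#' supervised term. Fully deterministic under `train$seed`.
#'
#' @param reference Named list of partitioned `cell_graph`s with a `label`
#'   field (see [build_cell_graphs()]).
#' @param query Optional list of unlabeled `cell_graph`s used
#'   contrastively.
#' @param vocab The `gene_vocabulary` the graphs were built with.
#' @param encoder An [encoder_config()]; `n_classes` is overridden by the
#'   number of reference cell types.
#' @param train A [train_config()].
#' @param policy Augmentation policy (see [augment_policy()]).
#' @param gumbel_temperature Temperature of the Gumbel-Softmax score
#'   sampling.
#' @param verbose Print the per-epoch loss.
#' @return An object of class `gcl_model`: trained `params`, the configs,
#'   `classes`, `vocab` and a per-epoch `loss_history` data frame with
#'   columns `epoch`, `L_cl`, `L_cls`, `L`.
#' @export
fit_gcl <- function(reference, query = list(), vocab,
                    encoder = encoder_config(), train = train_config(),
                    policy = "all", gumbel_temperature = 1, verbose = TRUE) {
  labels_chr <- vapply(reference, function(g) g$label %||% NA_character_, character(1))
  if (length(reference) == 0L || anyNA(labels_chr)) {
    stop("fit_gcl needs at least one labeled reference cell (all reference graphs must carry a label)")
  }
  classes <- sort(unique(labels_chr))
  if (length(classes) < 2L) warning("single-class reference labels: classifier is degenerate")
  encoder$n_classes <- length(classes)
  y_ref <- match(labels_chr, classes)
  graphs <- c(reference, query)
  y_all <- c(y_ref, rep(NA_integer_, length(query)))
  n_cells <- length(graphs)
  d <- vocab$d
  policy_ops <- augment_policy(policy)

  params <- init_params(encoder, d, seed = train$seed)
  astate <- list(t = 0L, m = zeros_like(params), v = zeros_like(params))
  history <- data.frame(epoch = integer(0), L_cl = numeric(0),
                        L_cls = numeric(0), L_reg = numeric(0),
                        L = numeric(0))

  withr::with_seed(train$seed + 1L, {
    for (epoch in seq_len(train$epochs)) {
      # stratified batching: labeled and unlabeled shuffled separately and
      # dealt round-robin so labels spread across batches
      n_batches <- max(1L, ceiling(n_cells / train$batch_size))
      lab_idx <- sample(which(!is.na(y_all)))
      qry_idx <- sample(which(is.na(y_all)))
      slots <- split(c(lab_idx, qry_idx),
                     rep_len(seq_len(n_batches), n_cells))
      ep_cl <- 0; ep_cls <- 0; ep_reg <- 0; n_lab_batches <- 0L
      for (batch in slots) {
        N <- length(batch)
        if (N < 2L) next
        res <- train_step(graphs[batch], y_all[batch], params, encoder,
                          train, policy_ops, gumbel_temperature)
        upd <- adam_step(params, res$grads, astate, train$lr)
        params <- upd$params; astate <- upd$state
        ep_cl <- ep_cl + res$l_cl
        ep_cls <- ep_cls + res$l_cls
        ep_reg <- ep_reg + res$l_reg
        n_lab_batches <- n_lab_batches + 1L
      }
      l_cl <- ep_cl / n_lab_batches
      l_cls <- ep_cls / n_lab_batches
      l_reg <- ep_reg / n_lab_batches
      history <- rbind(history, data.frame(
        epoch = epoch, L_cl = l_cl, L_cls = l_cls, L_reg = l_reg,
        L = combined_loss(l_cl, l_cls, train$lambda) + l_reg))
      if (verbose) {
        message(sprintf("epoch %3d  L_cl %.4f  L_cls %.4f  L_reg %.4f  L %.4f",
                        epoch, l_cl, l_cls, l_reg, history$L[epoch]))
      }
    }
  })
  structure(list(params = params, encoder = encoder, train = train,
                 classes = classes, vocab = vocab,
                 gumbel_temperature = gumbel_temperature,
                 loss_history = history),
            class = "gcl_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One batch: forward both views of every cell, combined loss, full backward.
train_step <- function(batch_graphs, batch_y, params, encoder, train,
                       policy_ops, gumbel_temperature) {
  N <- length(batch_graphs)
  h <- encoder$hidden
  grads <- zeros_like(params)
  Z <- matrix(0, 2L * N, h)
  cells <- vector("list", N)
  for (k in seq_len(N)) {
    g <- batch_graphs[[k]]
    H_gin <- gin_encode(g, encoder, params, cache = TRUE)
    X <- one_hot_features(g$genes, g$d)
    views <- vector("list", 2L)
    for (v in 1:2) {
      scores <- compute_node_scores(H_gin, params, gumbel_temperature,
                                    noise = TRUE)
      view <- generate_view(g, scores, policy_ops)
      if (all(view$masked)) {  # keep the graph embedding non-degenerate
        view$masked[which.max(scores$p_v[view$node_ids])] <- FALSE
      }
      Xv <- X[view$node_ids, , drop = FALSE]
      Xv[view$masked, ] <- 0
      Ahat <- adjacency_normalized(view)
      fwd <- resgcn_forward(Xv, Ahat, encoder, params, training = TRUE)
      Z[2L * (k - 1L) + v, ] <- fwd$hg
      views[[v]] <- list(view = view, scores = scores, X = Xv, Ahat = Ahat,
                         fwd = fwd)
    }
    cells[[k]] <- list(graph = g, H_gin = H_gin, views = views)
  }

  l_cl <- ntxent_loss(Z, tau = train$tau, grad = TRUE)
  dZ <- attr(l_cl, "gradient")

  # supervised term on both augmented views of every labeled cell, plus
  # its identity view (full graph, no dropout). The identity view is what
  # annotation encodes at inference; anchoring the classifier to it
  # removes the train/eval distribution shift that heavy augmentation
  # would otherwise induce.
  lab_k <- which(!is.na(batch_y))
  l_cls <- 0
  dZ_cls <- NULL
  if (length(lab_k) > 0L) {
    lab_rows <- as.vector(vapply(lab_k, function(k) 2L * (k - 1L) + 1:2,
                                 integer(2)))
    id_fwd <- vector("list", length(lab_k))
    Zi <- matrix(0, length(lab_k), h)
    for (j in seq_along(lab_k)) {
      g <- batch_graphs[[lab_k[j]]]
      Xi <- one_hot_features(g$genes, g$d)
      Ahat_i <- adjacency_normalized(g)
      fwd_i <- resgcn_forward(Xi, Ahat_i, encoder, params, training = FALSE)
      Zi[j, ] <- fwd_i$hg
      id_fwd[[j]] <- list(fwd = fwd_i, X = Xi, Ahat = Ahat_i)
    }
    Zl <- rbind(Z[lab_rows, , drop = FALSE], Zi)
    lab_y <- c(rep(batch_y[lab_k], each = 2L), batch_y[lab_k])
    rl <- sqrt(rowSums(Zl^2))
    if (any(rl == 0)) stop("zero-norm graph embedding")
    Ul <- Zl / rl  # classifier reads the L2-normalized embedding
    logits <- Ul %*% params$cls_W +
      matrix(params$cls_b, nrow(Zl), encoder$n_classes, byrow = TRUE)
    l_cls <- cross_entropy_loss(logits, lab_y, grad = TRUE)
    dlogits <- attr(l_cls, "gradient") * train$lambda
    grads$cls_W <- grads$cls_W + crossprod(Ul, dlogits)
    grads$cls_b <- grads$cls_b + colSums(dlogits)
    dUl <- tcrossprod(dlogits, params$cls_W)
    dZl <- (dUl - Ul * rowSums(dUl * Ul)) / rl
    n_aug <- length(lab_rows)
    dZ_cls <- matrix(0, 2L * N, h)
    dZ_cls[lab_rows, ] <- dZl[seq_len(n_aug), , drop = FALSE]
    dZ <- dZ + dZ_cls
    for (j in seq_along(lab_k)) {
      bk <- resgcn_backward(dZl[n_aug + j, ], id_fwd[[j]]$fwd,
                            id_fwd[[j]]$X, id_fwd[[j]]$Ahat, params, grads)
      grads <- bk$grads
    }
  }

  # backward per cell
  l_reg <- 0
  for (k in seq_len(N)) {
    cell <- cells[[k]]
    g <- cell$graph
    dU_gin <- matrix(0, g$n, h)
    for (v in 1:2) {
      vw <- cell$views[[v]]
      row <- 2L * (k - 1L) + v
      bk <- resgcn_backward(dZ[row, ], vw$fwd, vw$X, vw$Ahat, params, grads)
      grads <- bk$grads
      # Two signals reach the scoring heads. (a) Straight-through from the
      # supervised loss into the keep/mask probabilities: X' = X * w with
      # w the hard drop*mask decision; dw = rowSums(dX' * X_orig). This
      # gives the scores their intended meaning — how much each transcript
      # contributes to identifying the cell's type. The contrastive loss
      # deliberately does not drive the heads: its degenerate optimum is
      # to drop almost everything (near-empty views align trivially).
      # (b) The optional keep-rate regularizer (off by default), which
      # penalizes the mean sampled augmentation probability.
      l_reg <- l_reg +
        train$keep_reg * (1 - mean(vw$scores$p_v) / 2) / (2 * N)
      dp_reg <- rep(-train$keep_reg / (4 * N * g$n), g$n)
      dp_mask <- dp_reg
      dp_drop <- dp_reg
      if (!is.null(dZ_cls) && any(dZ_cls[row, ] != 0)) {
        bk_cls <- resgcn_backward(dZ_cls[row, ], vw$fwd, vw$X, vw$Ahat,
                                  params, NULL)
        X_orig <- one_hot_features(vw$view$genes, g$d)
        dw <- rowSums(bk_cls$dX * X_orig)
        ids <- vw$view$node_ids
        dp_mask[ids] <- dp_mask[ids] + dw
        dp_drop[ids] <- dp_drop[ids] + dw * !vw$view$masked
      }
      sbm <- score_head_backward(dp_mask, vw$scores$cache$y_mask,
                                 gumbel_temperature, vw$scores$cache$U,
                                 params$head_mask, grads$head_mask)
      grads$head_mask <- sbm$ghead
      sbd <- score_head_backward(dp_drop, vw$scores$cache$y_drop,
                                 gumbel_temperature, vw$scores$cache$U,
                                 params$head_drop, grads$head_drop)
      grads$head_drop <- sbd$ghead
      dU_gin <- dU_gin + sbm$dU + sbd$dU
    }
    # backward through the GIN scorer (shared by both views)
    if (!any(dU_gin != 0)) next
    # chain through the row normalization U = H / r (U, r identical across
    # the two views since both score the same raw graph):
    # dH = (dU - U * <dU, U>_row) / r
    sc <- cell$views[[1]]$scores$cache
    dH_gin <- (dU_gin - sc$U * rowSums(dU_gin * sc$U)) / sc$r
    cache <- attr(cell$H_gin, "cache")
    A <- cache$A
    dH <- dH_gin
    for (l in rev(seq_along(params$gin_W))) {
      cc <- cache$layers[[l]]
      dZl <- dH * (cc$Z > 0)
      grads$gin_W[[l]] <- grads$gin_W[[l]] + crossprod(cc$M, dZl)
      if (encoder$epsilon_learnable) {
        dM <- tcrossprod(dZl, params$gin_W[[l]])
        grads$gin_eps[l] <- grads$gin_eps[l] + sum(dM * cc$H_in)
        dH <- (1 + params$gin_eps[l]) * dM + A %*% dM
      } else {
        dM <- tcrossprod(dZl, params$gin_W[[l]])
        dH <- (1 + params$gin_eps[l]) * dM + A %*% dM
      }
    }
  }
  list(grads = grads, l_cl = as.numeric(l_cl), l_cls = as.numeric(l_cls),
       l_reg = l_reg)
}

#' Annotate cells with a trained model
#'
#' Runs the encoder on the identity (un-augmented) view of each cell in
#' evaluation mode and returns the argmax cell type with the full class
#' probability vector; ties break to the lowest class index. Transcripts
#' whose gene is absent from the training vocabulary were already dropped
#' at graph construction.
#'
#' @param model A `gcl_model` from [fit_gcl()].
#' @param cells List of `cell_graph`s built with the model's vocabulary.
#' @return An `annotation_result` data frame: `cell_id`, `predicted_type`,
#'   one `prob_<class>` column per cell type.
#' @export
annotate_cells <- function(model, cells) {
  C <- length(model$classes)
  probs <- matrix(numeric(0), 0L, C)
  ids <- character(0)
  for (g in cells) {
    H <- resgcn_encode(new_view(g), model$encoder, model$params,
                       training = FALSE)
    p <- softmax(classify(sum_pool(H), model$params))
    probs <- rbind(probs, p)
    ids <- c(ids, g$cell_id)
  }
  out <- data.frame(cell_id = ids,
                    predicted_type = if (length(ids)) model$classes[apply(probs, 1, which.max)] else character(0),
                    stringsAsFactors = FALSE)
  colnames(probs) <- paste0("prob_", model$classes)
  out <- cbind(out, as.data.frame(probs, row.names = NULL))
  rownames(out) <- NULL
  class(out) <- c("annotation_result", "data.frame")
  out
}

#' @export
predict.gcl_model <- function(object, cells, ...) {
  annotate_cells(object, cells)
}
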