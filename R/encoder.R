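#' Encoder configuration
#'
#' The model has three trainable parts: a GIN (Graph Isomorphism Network)
#' scorer whose node embeddings feed the augmentation scoring heads, a
#' residual GCN encoder applied to the augmented graphs, and a linear
#' classifier head on the sum-pooled graph embedding. Defaults follow the
#' tuned operating point (hidden 128, dropout 0.3); smaller hidden widths
#' (16/32/64) from the same search grid are appropriate for small panels
#' and desk-scale runs.
#'
#' @param gin_layers Number of GIN layers in the scorer (L >= 1).
#' @param resgcn_layers Number of ResGCN layers in the encoder (t >= 1).
#' @param hidden Hidden width of all layers.
#' @param dropout Dropout rate applied between ResGCN layers in training
#'   mode only.
#' @param n_classes Number of cell types (set by [fit_gcl()] from the
#'   reference labels).
#' @param epsilon_learnable Whether the GIN self-weight epsilon is a
#'   learnable per-layer parameter.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(gin_layers = 2L, resgcn_layers = 3L, hidden = 128L,
                           dropout = 0.3, n_classes = 2L,
                           epsilon_learnable = TRUE) {
  stopifnot(gin_layers >= 1, resgcn_layers >= 1, hidden >= 1,
            dropout >= 0, dropout < 1, n_classes >= 1)
  structure(list(gin_layers = as.integer(gin_layers),
                 resgcn_layers = as.integer(resgcn_layers),
                 hidden = as.integer(hidden), dropout = dropout,
                 n_classes = as.integer(n_classes),
                 epsilon_learnable = isTRUE(epsilon_learnable)),
            class = "encoder_config")
}

# Glorot-style initialization for a fan_in x fan_out weight matrix.
glorot <- function(fan_in, fan_out) {
  s <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -s, s), fan_in, fan_out)
}

# Initialize all trainable parameters. `d` is the one-hot feature dimension
# (vocabulary size). Layout:
#   gin_W[[l]]   : GIN scorer weights (d->h, then h->h)
#   gin_eps      : per-layer epsilon
#   head_drop/head_mask : list(W = h x 2, b = 2) Gumbel-Softmax scoring heads
#   enc_W[[l]]   : ResGCN weights (d->h, then h->h)
#   cls_W, cls_b : classifier head (h x C, C)
init_params <- function(config, d, seed = 0L) {
  withr::with_seed(seed, {
    h <- config$hidden
    gin_W <- vector("list", config$gin_layers)
    gin_W[[1]] <- glorot(d, h)
    if (config$gin_layers > 1L) {
      for (l in 2:config$gin_layers) gin_W[[l]] <- glorot(h, h)
    }
    enc_W <- vector("list", config$resgcn_layers)
    enc_W[[1]] <- glorot(d, h)
    if (config$resgcn_layers > 1L) {
      for (l in 2:config$resgcn_layers) enc_W[[l]] <- glorot(h, h)
    }
    # scoring-head bias starts the "augment" logit low so initial keep
    # probabilities sit near 0.9 (mild perturbation, the usual graph-
    # augmentation regime); training moves them per node from there
    list(gin_W = gin_W,
         gin_eps = rep(0, config$gin_layers),
         head_drop = list(W = glorot(h, 2L) * 0.1, b = c(-2.2, 0)),
         head_mask = list(W = glorot(h, 2L) * 0.1, b = c(-2.2, 0)),
         enc_W = enc_W,
         cls_W = glorot(h, config$n_classes),
         cls_b = rep(0, config$n_classes))
  })
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' One GIN layer
#'
#' Computes `H' = ReLU(((1 + eps) * H + A %*% H) %*% W)`: each node adds the
#' sum of its neighbors' embeddings to a weighted copy of its own, applies a
#' linear map and a ReLU.
#'
#' @param H `n x p` node embedding matrix.
#' @param A `n x n` binary symmetric adjacency (zero diagonal).
#' @param eps Scalar self-weight (learnable per layer during training).
#' @param W `p x q` weight matrix.
#' @return `n x q` updated node embeddings.
#' @export
gin_layer <- function(H, A, eps, W) {
  stopifnot(nrow(A) == nrow(H), ncol(A) == nrow(H), ncol(H) == nrow(W))
  relu(((1 + eps) * H + A %*% H) %*% W)
}

#' Encode a cell graph with the GIN scorer
#'
#' Stacks `config$gin_layers` GIN layers on the raw (un-augmented) graph,
#' starting from one-hot gene features. The final-layer node embeddings are
#' the input to the augmentation scoring heads.
#'
#' @param graph A `cell_graph`.
#' @param config An [encoder_config()].
#' @param params Parameter list from the trained model (or `init_params`).
#' @param cache Return intermediate layer inputs for backpropagation.
#' @return `n x hidden` node embedding matrix (with attribute `cache` when
#'   requested).
#' @export
gin_encode <- function(graph, config, params, cache = FALSE) {
  A <- adjacency_dense(graph)
  H <- one_hot_features(graph$genes, graph$d)
  caches <- vector("list", config$gin_layers)
  for (l in seq_len(config$gin_layers)) {
    M <- (1 + params$gin_eps[l]) * H + A %*% H
    Z <- M %*% params$gin_W[[l]]
    if (cache) caches[[l]] <- list(H_in = H, M = M, Z = Z)
    H <- relu(Z)
  }
  if (cache) attr(H, "cache") <- list(A = A, layers = caches)
  H
}

# ResGCN forward pass on (possibly augmented) node features X and normalized
# adjacency Ahat. Layer 1 projects to hidden width; layers >= 2 are residual:
#   H^{l+1} = ReLU(Ahat H^l W_l) + H^l
# Dropout (inverted, scale 1/(1-p)) is applied to the layer output in
# training mode. Returns list(H, hg, cache).
resgcn_forward <- function(X, Ahat, config, params, training = FALSE) {
  t_layers <- config$resgcn_layers
  caches <- vector("list", t_layers)
  H <- X
  for (l in seq_len(t_layers)) {
    M <- Ahat %*% H
    Z <- M %*% params$enc_W[[l]]
    H_out <- if (l == 1L) relu(Z) else relu(Z) + H
    drop_mask <- NULL
    if (training && config$dropout > 0 && l < t_layers) {
      drop_mask <- matrix(stats::rbinom(length(H_out), 1L, 1 - config$dropout),
                          nrow(H_out)) / (1 - config$dropout)
      H_out <- H_out * drop_mask
    }
    caches[[l]] <- list(M = M, Z = Z, drop_mask = drop_mask)
    H <- H_out
  }
  list(H = H, hg = colSums(H), cache = caches)
}

#' Encode an augmented graph view with the ResGCN encoder
#'
#' Runs `config$resgcn_layers` graph convolutions with symmetric
#' normalization `D^{-1/2}(A + I)D^{-1/2}` and additive residual
#' connections from layer 2 on, starting from the view's (possibly masked)
#' one-hot features. Deterministic in evaluation mode; dropout fires only
#' with `training = TRUE`.
#'
#' @param view An `augmented_view` (or a raw `cell_graph`, treated as the
#'   identity view).
#' @param config An [encoder_config()].
#' @param params Parameter list.
#' @param training Apply dropout between layers.
#' @return `n x hidden` node embedding matrix.
#' @export
resgcn_encode <- function(view, config, params, training = FALSE) {
  X <- view_features(view)
  Ahat <- adjacency_normalized(view)
  resgcn_forward(X, Ahat, config, params, training = training)$H
}

# One-hot features of a view; masked nodes have all-zero rows.
view_features <- function(view) {
  X <- one_hot_features(view$genes, view$d)
  if (!is.null(view$masked) && any(view$masked)) X[view$masked, ] <- 0
  X
}

#' Sum-pool node embeddings into a graph embedding
#'
#' The cell-level embedding is the elementwise sum of the final node
#' embeddings, hence invariant to node relabeling.
#'
#' @param H `n x hidden` node embedding matrix (`n >= 1`).
#' @return Numeric vector of length `hidden`.
#' @export
sum_pool <- function(H) {
  if (nrow(H) == 0L) stop("cannot pool an empty graph")
  colSums(H)
}

#' Classifier head
#'
#' Linear map from the L2-normalized graph embedding to per-cell-type
#' logits. Normalizing first puts the classifier in the same cosine
#' geometry that the contrastive loss organizes, and makes the logits
#' invariant to the embedding-magnitude difference between augmented
#' training views (fewer, partly masked nodes) and the identity view used
#' at inference.
#'
#' @param hg Graph embedding vector (non-zero).
#' @param params Parameter list (uses `cls_W`, `cls_b`).
#' @return Numeric vector of `n_classes` logits.
#' @export
classify <- function(hg, params) {
  r <- sqrt(sum(hg^2))
  if (r == 0) stop("zero-norm graph embedding")
  drop((hg / r) %*% params$cls_W) + params$cls_b
}

#' Numerically stable softmax
#'
#' @param x Numeric vector of logits.
#' @return Probability vector summing to 1.
#' @export
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Save / load a trained model checkpoint
#'
#' Parameters and configuration are serialized to a single JSON file;
#' `load_model(save_model(m, path))` reproduces the model to double
#' precision (decimal text round trip, differences at most 1 ulp).
#'
#' @param model A `gcl_model` from [fit_gcl()].
#' @param path Checkpoint file path.
#' @return `save_model()`: `path`, invisibly; `load_model()`: a `gcl_model`.
#' @export
save_model <- function(model, path) {
  ser <- list(
    encoder = unclass(model$encoder),
    train = unclass(model$train),
    classes = model$classes,
    vocabulary = model$vocab$symbols,
    gumbel_temperature = model$gumbel_temperature,
    params = rapply(model$params, function(m) {
      if (is.matrix(m)) list(dim = dim(m), data = as.vector(m)) else m
    }, classes = "matrix", how = "replace"),
    loss_history = as.list(model$loss_history)  # column-wise, stable to read
  )
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  rebuild <- function(x) {
    if (is.list(x) && identical(sort(names(x)), c("data", "dim"))) {
      matrix(x$data, x$dim[1], x$dim[2])
    } else if (is.list(x)) {
      lapply(x, rebuild)
    } else x
  }
  enc <- ser$encoder
  structure(list(
    params = rebuild(ser$params),
    encoder = encoder_config(enc$gin_layers, enc$resgcn_layers, enc$hidden,
                             enc$dropout, enc$n_classes, enc$epsilon_learnable),
    train = do.call(train_config, as.list(ser$train)),
    classes = ser$classes,
    vocab = build_vocabulary(ser$vocabulary),
    gumbel_temperature = ser$gumbel_temperature,
    loss_history = as.data.frame(lapply(ser$loss_history, unlist))
  ), class = "gcl_model")
}
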