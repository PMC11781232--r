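# Independent oracle implementations used across test files. These are
# deliberately naive (quadratic loops, direct formula transcription) so a
# disagreement points at the package code, not at a shared abstraction.

# Brute-force all-pairs radius graph: every unordered pair with Euclidean
# distance <= d, as a sorted two-column matrix (u < v).
oracle_radius_pairs <- function(x, y, d) {
  n <- length(x)
  out <- matrix(integer(0), 0L, 2L)
  if (n >= 2L) {
    for (u in seq_len(n - 1L)) {
      for (v in (u + 1L):n) {
        if ((x[u] - x[v])^2 + (y[u] - y[v])^2 <= d^2) {
          out <- rbind(out, c(u, v))
        }
      }
    }
  }
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# Per-node GIN layer: h'_v = relu(W^T ((1+eps) h_v + sum_{u ~ v} h_u)).
oracle_gin_layer <- function(H, A, eps, W) {
  n <- nrow(H)
  out <- matrix(0, n, ncol(W))
  for (v in seq_len(n)) {
    agg <- (1 + eps) * H[v, ]
    for (u in seq_len(n)) if (A[v, u] == 1) agg <- agg + H[u, ]
    out[v, ] <- pmax(drop(agg %*% W), 0)
  }
  out
}

# Direct confusion-matrix metrics over the union of observed labels.
oracle_metrics <- function(truth, predicted) {
  classes <- sort(unique(c(truth, predicted)))
  cm <- table(factor(truth, classes), factor(predicted, classes))
  acc <- sum(diag(cm)) / sum(cm)
  f1 <- vapply(sort(unique(truth)), function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  list(accuracy = acc, f1_macro = mean(f1))
}

# Random connected-ish point cloud for graph tests.
random_cloud <- function(n, span = 20) {
  data.frame(x = stats::runif(n, 0, span), y = stats::runif(n, 0, span))
}

# A tiny deterministic cell graph for encoder/augmentation tests: a cycle
# of `n` transcripts, alternating between two gene symbols.
toy_graph <- function(n = 8L, d_vocab = 4L, seed = 1L) {
  withr::with_seed(seed, {
    theta <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
    tx <- data.frame(
      cell_id = "toy",
      gene = paste0("g", sprintf("%02d", (seq_len(n) %% d_vocab) + 1L)),
      x = 3 * cos(theta), y = 3 * sin(theta))
    vocab <- build_vocabulary(paste0("g", sprintf("%02d", seq_len(d_vocab))))
    build_cell_graphs(tx, graph_config(d = 2.5, seed = seed), vocab,
                      verbose = FALSE)[[1]]
  })
}
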