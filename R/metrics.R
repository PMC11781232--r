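#' One-vs-rest confusion counts
#'
#' Per-class TP, FP, FN, TN over a pair of label vectors; the building
#' block of the accuracy and F1 evaluation metrics.
#'
#' @param truth Character (or factor) vector of true cell types.
#' @param predicted Vector of predicted cell types, same length.
#' @return `data.frame` with one row per class observed in either vector:
#'   `class`, `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted), length(truth) >= 1L)
  truth <- as.character(truth); predicted <- as.character(predicted)
  classes <- sort(unique(c(truth, predicted)))
  n <- length(truth)
  do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    data.frame(class = cl, TP = tp, FP = fp, FN = fn, TN = n - tp - fp - fn,
               stringsAsFactors = FALSE)
  }))
}

#' Annotation accuracy
#'
#' Fraction of cells whose predicted type matches the truth (for a single
#' class this equals `(TP + TN) / (TP + FP + TN + FN)` on the one-vs-rest
#' counts).
#'
#' @inheritParams confusion_counts
#' @return Numeric scalar in `[0, 1]`.
#' @export
annotation_accuracy <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stop("label vectors differ in length")
  stopifnot(length(truth) >= 1L)
  mean(as.character(truth) == as.character(predicted))
}

#' F1 score
#'
#' Per-class F1 is `2 TP / (2 TP + FP + FN)` on one-vs-rest counts; the
#' macro average is the unweighted mean over the classes present in the
#' true labels (the convention of the cell type annotation literature). A
#' class with `TP = FP = FN = 0` contributes 0.
#'
#' @inheritParams confusion_counts
#' @param average `"macro"` (default) or `"micro"`.
#' @return Numeric scalar in `[0, 1]`.
#' @export
f1_score <- function(truth, predicted, average = c("macro", "micro")) {
  average <- match.arg(average)
  cc <- confusion_counts(truth, predicted)
  cc <- cc[cc$class %in% unique(as.character(truth)), , drop = FALSE]
  if (average == "micro") {
    return(2 * sum(cc$TP) / (2 * sum(cc$TP) + sum(cc$FP) + sum(cc$FN)))
  }
  denom <- 2 * cc$TP + cc$FP + cc$FN
  f1 <- ifelse(denom == 0, 0, 2 * cc$TP / denom)
  mean(f1)
}

#' Full evaluation report
#'
#' @inheritParams confusion_counts
#' @return List with `accuracy`, `f1_macro` and a per-class `data.frame`
#'   (`class`, `TP`, `FP`, `FN`, `TN`, `f1`).
#' @export
evaluate_annotation <- function(truth, predicted) {
  cc <- confusion_counts(truth, predicted)
  denom <- 2 * cc$TP + cc$FP + cc$FN
  cc$f1 <- ifelse(denom == 0, 0, 2 * cc$TP / denom)
  list(accuracy = annotation_accuracy(truth, predicted),
       f1_macro = f1_score(truth, predicted, "macro"),
       per_class = cc)
}

#' Expression-only baseline classifier
#'
#' Multinomial logistic regression on per-cell gene count vectors,
#' ignoring all spatial information. Serves as the control showing when
#' cell types are separable by expression alone: on data where types
#' differ only in subcellular transcript placement, this baseline stays at
#' chance while the graph model does not.
#'
#' @param ref_table QC-filtered reference transcript `data.frame`.
#' @param ref_labels Reference label `data.frame` (`cell_id`, `cell_type`).
#' @param query_table Query transcript `data.frame`.
#' @param vocab A `gene_vocabulary` defining the count features.
#' @return `data.frame` with `cell_id` and `predicted_type` for every query
#'   cell.
#' @export
expression_baseline <- function(ref_table, ref_labels, query_table, vocab) {
  count_matrix <- function(table) {
    cells <- unique(table$cell_id)
    M <- matrix(0, length(cells), vocab$d,
                dimnames = list(cells, vocab$symbols))
    tab <- table(table$cell_id, factor(table$gene, levels = vocab$symbols))
    M[rownames(tab), ] <- as.matrix(tab)
    M
  }
  Xr <- count_matrix(ref_table)
  Xq <- count_matrix(query_table)
  y <- factor(stats::setNames(ref_labels$cell_type, ref_labels$cell_id)[rownames(Xr)])
  df <- data.frame(y = y, Xr, check.names = FALSE)
  fit <- nnet::multinom(y ~ ., data = df, trace = FALSE, maxit = 200)
  pred <- stats::predict(fit, newdata = data.frame(Xq, check.names = FALSE))
  data.frame(cell_id = rownames(Xq), predicted_type = as.character(pred),
             stringsAsFactors = FALSE)
}
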