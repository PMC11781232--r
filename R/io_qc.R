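#' Read a per-transcript table
#'
#' Parses a delimited text file of individual transcript detections as
#' produced by imaging-based spatial transcriptomics platforms (CosMx SMI,
#' MERFISH, Xenium). Each row is one detected RNA molecule with a cell
#' identifier, a gene symbol and spatial coordinates. Platform exports use
#' different column names; `columns` maps them onto the canonical names.
#'
#' Rows whose coordinates cannot be parsed as finite numbers, or with an
#' empty gene symbol, are rejected (not fatal); the number of rejected rows
#' is reported and stored in the `n_rejected` attribute.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param columns Named character vector mapping canonical names
#'   (`cell_id`, `gene`, `x`, `y`, and optionally `z`) to the file's column
#'   names.
#' @param sep Field separator; `NULL` (default) chooses `"\t"` for `.tsv`
#'   files and `","` otherwise.
#' @param unit_scale Micrometers per coordinate unit (e.g. `0.18` for CosMx
#'   pixel coordinates, `1` for MERFISH/Xenium micrometer coordinates).
#'   Carried as metadata; distances are always computed in platform units.
#' @return A `data.frame` with columns `cell_id` (character), `gene`
#'   (character), `x`, `y` (double) and `z` when mapped, in file order,
#'   with attributes `unit_scale` and `n_rejected`.
#' @export
read_transcripts <- function(path,
                             columns = c(cell_id = "cell_id", gene = "gene",
                                         x = "x", y = "y"),
                             sep = NULL,
                             unit_scale = 1) {
  stopifnot(file.exists(path))
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  required <- c("cell_id", "gene", "x", "y")
  stopifnot(all(required %in% names(columns)))
  missing_cols <- setdiff(unname(columns), names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing column(s) in ", path, ": ", paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    cell_id = raw[[columns[["cell_id"]]]],
    gene    = raw[[columns[["gene"]]]],
    x       = suppressWarnings(as.numeric(raw[[columns[["x"]]]])),
    y       = suppressWarnings(as.numeric(raw[[columns[["y"]]]])),
    stringsAsFactors = FALSE
  )
  if ("z" %in% names(columns) && columns[["z"]] %in% names(raw)) {
    out$z <- suppressWarnings(as.numeric(raw[[columns[["z"]]]]))
  }
  coord_ok <- is.finite(out$x) & is.finite(out$y)
  if (!is.null(out$z)) coord_ok <- coord_ok & is.finite(out$z)
  ok <- coord_ok & !is.na(out$gene) & nzchar(out$gene) &
    !is.na(out$cell_id) & nzchar(out$cell_id)
  n_rejected <- sum(!ok)
  if (n_rejected > 0L) {
    message(n_rejected, " malformed row(s) rejected while reading ", path)
  }
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unit_scale") <- unit_scale
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write a transcript table
#'
#' Writes the canonical columns to CSV with full coordinate precision, so
#' that a write/read round trip reproduces the records exactly.
#'
#' @param table A transcript `data.frame` as returned by
#'   [read_transcripts()] or [simulate_cells()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(table, path) {
  cols <- intersect(c("cell_id", "gene", "x", "y", "z"), names(table))
  out <- table[, cols, drop = FALSE]
  for (cc in intersect(c("x", "y", "z"), cols)) {
    out[[cc]] <- format(out[[cc]], digits = 17, trim = TRUE, scientific = FALSE)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cell label table
#'
#' @param path CSV file with one row per cell.
#' @param columns Named character vector mapping `cell_id` and `cell_type`
#'   to the file's column names.
#' @return `data.frame` with character columns `cell_id`, `cell_type`.
#' @export
read_labels <- function(path, columns = c(cell_id = "cell_id",
                                          cell_type = "cell_type")) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(unname(columns), names(raw))
  if (length(missing_cols) > 0L) {
    stop("missing column(s) in ", path, ": ", paste(missing_cols, collapse = ", "))
  }
  data.frame(cell_id = raw[[columns[["cell_id"]]]],
             cell_type = raw[[columns[["cell_type"]]]],
             stringsAsFactors = FALSE)
}

#' Quality-control configuration
#'
#' Two filters are applied to raw transcript tables: removal of
#' negative-control probes (probes targeting no real transcript, used to
#' gauge nonspecific hybridization) and removal of low-quality cells whose
#' transcript count falls below a platform-specific threshold `alpha`
#' (100 for MERFISH, 50 for CosMx SMI and Xenium).
#'
#' @param alpha Minimum transcripts per cell; cells with strictly fewer
#'   transcripts are removed.
#' @param negative_control_patterns Case-insensitive regular expressions;
#'   any matching gene symbol is treated as a negative-control probe.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(alpha = 50,
                      negative_control_patterns = c("^NegPrb", "^NegControl",
                                                    "^BLANK", "^Blank")) {
  stopifnot(alpha >= 0, length(negative_control_patterns) >= 1L)
  for (p in negative_control_patterns) {
    ok <- tryCatch({ grepl(p, "x"); TRUE }, error = function(e) FALSE)
    if (!ok) stop("invalid negative-control regex: ", p)
  }
  structure(list(alpha = as.integer(alpha),
                 negative_control_patterns = negative_control_patterns),
            class = "qc_config")
}

#' Remove negative-control probe records
#'
#' Drops every record whose gene symbol matches any of the configured
#' control patterns (case-insensitive); all other records are preserved in
#' order.
#'
#' @param table Transcript `data.frame`.
#' @param qc A [qc_config()].
#' @return Filtered transcript `data.frame` (attributes preserved).
#' @export
filter_negative_controls <- function(table, qc = qc_config()) {
  is_ctrl <- rep(FALSE, nrow(table))
  for (p in qc$negative_control_patterns) {
    is_ctrl <- is_ctrl | grepl(p, table$gene, ignore.case = TRUE)
  }
  out <- table[!is_ctrl, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unit_scale") <- attr(table, "unit_scale")
  out
}

#' Remove low-quality cells
#'
#' Removes every cell whose transcript count is strictly below
#' `qc$alpha`, together with all of its records.
#'
#' @inheritParams filter_negative_controls
#' @return Filtered transcript `data.frame`.
#' @export
filter_low_quality_cells <- function(table, qc = qc_config()) {
  counts <- table(table$cell_id)
  keep_cells <- names(counts)[counts >= qc$alpha]
  out <- table[table$cell_id %in% keep_cells, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unit_scale") <- attr(table, "unit_scale")
  out
}

#' Apply the full QC pipeline
#'
#' Negative-control probes are removed first, then the per-cell transcript
#' threshold `alpha` is applied, so that control counts never rescue a
#' low-quality cell. Stage-by-stage record and cell counts are reported.
#'
#' @inheritParams filter_negative_controls
#' @param verbose Report counts per stage.
#' @return Filtered transcript `data.frame` with attribute `qc_log`
#'   (a named list of record/cell counts at each stage).
#' @export
apply_qc <- function(table, qc = qc_config(), verbose = TRUE) {
  log <- list(input_records = nrow(table),
              input_cells = length(unique(table$cell_id)))
  t1 <- filter_negative_controls(table, qc)
  log$after_control_filter_records <- nrow(t1)
  t2 <- filter_low_quality_cells(t1, qc)
  log$after_alpha_filter_records <- nrow(t2)
  log$after_alpha_filter_cells <- length(unique(t2$cell_id))
  log$cells_removed <- log$input_cells - log$after_alpha_filter_cells
  if (verbose) {
    message(sprintf(
      "QC: %d records / %d cells in; %d control records removed; %d cells below alpha=%d removed; %d records / %d cells out",
      log$input_records, log$input_cells,
      log$input_records - log$after_control_filter_records,
      log$cells_removed, qc$alpha,
      log$after_alpha_filter_records, log$after_alpha_filter_cells))
  }
  attr(t2, "qc_log") <- log
  t2
}

#' Build the gene vocabulary
#'
#' Collects the distinct gene symbols of a transcript table in stable
#' lexicographic order; the vocabulary size `d` is the one-hot feature
#' dimension of every gene neighborhood network.
#'
#' @param table Transcript `data.frame` (must be non-empty).
#' @return An object of class `gene_vocabulary`: list with `symbols`
#'   (ordered character vector), `index` (named integer, 1-based) and `d`.
#' @export
build_vocabulary <- function(table) {
  if (is.data.frame(table)) {
    if (nrow(table) == 0L) stop("cannot build a vocabulary from an empty table")
    symbols <- table$gene
  } else {
    symbols <- table
    if (length(symbols) == 0L) stop("cannot build a vocabulary from an empty table")
  }
  symbols <- sort(unique(symbols), method = "radix")
  idx <- stats::setNames(seq_along(symbols), symbols)
  structure(list(symbols = symbols, index = idx, d = length(symbols)),
            class = "gene_vocabulary")
}

#' @export
print.gene_vocabulary <- function(x, ...) {
  cat("gene_vocabulary with", x$d, "symbols\n")
  invisible(x)
}

#' Write / read a gene vocabulary as one symbol per line
#'
#' @param vocab A `gene_vocabulary`.
#' @param path Text file path.
#' @return `write_vocabulary()`: `path`, invisibly; `read_vocabulary()`:
#'   a `gene_vocabulary`.
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(vocab$symbols, path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  build_vocabulary(readLines(path))
}
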