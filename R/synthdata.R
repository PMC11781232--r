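#' Subcellular niche specifications
#'
#' Where a gene's transcripts sit inside the (disk-shaped) model cell:
#' uniform over the cell, a ring between two radii (a small inner ring
#' models perinuclear localization, an outer ring a peripheral /
#' membrane-proximal shell), or a few Gaussian foci (RNA granules).
#' Radii are in the same units as `cell_radius` (micrometers by default).
#'
#' @param r_in,r_out Inner/outer ring radius (`r_in < r_out`).
#' @param n_foci Number of cluster foci per cell.
#' @param focus_sd Gaussian spread of transcripts around a focus.
#' @return A niche specification list.
#' @export
niche_uniform <- function() list(kind = "uniform")

#' @rdname niche_uniform
#' @export
niche_ring <- function(r_in, r_out) {
  if (r_in >= r_out) stop("infeasible niche: r_in >= r_out")
  list(kind = "ring", r_in = r_in, r_out = r_out)
}

#' @rdname niche_uniform
#' @export
niche_cluster <- function(n_foci = 2L, focus_sd = 0.5) {
  stopifnot(n_foci >= 1, focus_sd > 0)
  list(kind = "cluster", n_foci = as.integer(n_foci), focus_sd = focus_sd)
}

#' Simulation configuration
#'
#' Defines a synthetic imaging-based spatial transcriptomics experiment
#' with known ground truth. Each cell type has a gene-frequency program
#' and, per gene, a subcellular niche; cells are disks of radius
#' `cell_radius` with a notional nucleus at the center. Transcript counts
#' per cell are negative-binomial (emulating the 50-600 transcripts per
#' cell of real panels); a fraction of transcripts is placed uniformly as
#' background regardless of niche, and a fraction of negative-control
#' probes (`NegPrb###`) exercises the QC filters.
#'
#' @param cell_types Named list; each element is
#'   `list(gene_freqs = <named numeric summing to 1>, niches = <named list
#'   of niche specs>)`. Genes without an entry in `niches` place uniformly.
#' @param n_cells Cells per type (scalar, or named vector by type).
#' @param transcripts_per_cell `c(mean, size)` of the negative-binomial
#'   transcript count.
#' @param cell_radius Cell disk radius (coordinate units; um by default).
#' @param background_fraction Fraction of uniformly placed transcripts.
#' @param control_fraction Fraction of negative-control probe records
#'   added on top.
#' @param coordinate_jitter_sd Gaussian noise added to every coordinate.
#' @param seed Simulation seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(cell_types, n_cells = 100L,
                       transcripts_per_cell = c(mean = 150, size = 20),
                       cell_radius = 7,
                       background_fraction = 0.05,
                       control_fraction = 0.03,
                       coordinate_jitter_sd = 0.1,
                       seed = 0L) {
  stopifnot(length(cell_types) >= 1L, !is.null(names(cell_types)),
            cell_radius > 0,
            background_fraction >= 0, background_fraction <= 1,
            control_fraction >= 0, control_fraction <= 1,
            coordinate_jitter_sd >= 0)
  for (ct in cell_types) {
    stopifnot(abs(sum(ct$gene_freqs) - 1) < 1e-8)
    for (nm in names(ct$niches)) {
      sp <- ct$niches[[nm]]
      if (sp$kind == "ring" && sp$r_in >= sp$r_out) {
        stop("infeasible niche for gene ", nm, ": r_in >= r_out")
      }
    }
  }
  if (length(n_cells) == 1L) {
    n_cells <- stats::setNames(rep(as.integer(n_cells), length(cell_types)),
                               names(cell_types))
  }
  structure(list(cell_types = cell_types, n_cells = n_cells,
                 transcripts_per_cell = transcripts_per_cell,
                 cell_radius = cell_radius,
                 background_fraction = background_fraction,
                 control_fraction = control_fraction,
                 coordinate_jitter_sd = coordinate_jitter_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Sample n points at the given niche inside a disk of radius R (relative to
# the cell center).
sample_niche <- function(n, spec, R) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2L))
  switch(spec$kind,
    uniform = {
      r <- R * sqrt(stats::runif(n))
      th <- stats::runif(n, 0, 2 * pi)
      cbind(r * cos(th), r * sin(th))
    },
    ring = {
      r <- sqrt(stats::runif(n, spec$r_in^2, spec$r_out^2))
      th <- stats::runif(n, 0, 2 * pi)
      cbind(r * cos(th), r * sin(th))
    },
    cluster = {
      rf <- 0.7 * R * sqrt(stats::runif(spec$n_foci))
      tf <- stats::runif(spec$n_foci, 0, 2 * pi)
      foci <- cbind(rf * cos(tf), rf * sin(tf))
      which_focus <- sample.int(spec$n_foci, n, replace = TRUE)
      foci[which_focus, , drop = FALSE] +
        matrix(stats::rnorm(2L * n, 0, spec$focus_sd), ncol = 2L)
    },
    stop("unknown niche kind: ", spec$kind))
}

#' Simulate a synthetic transcript table with ground truth
#'
#' Draws, for every cell: a transcript count, gene symbols from the type's
#' frequency program, subcellular positions from the per-(type, gene)
#' niches inside a disk centered at the cell's (grid-spaced) tissue
#' position, plus uniform background transcripts, negative-control probes
#' and coordinate jitter. Fully reproducible under the config seed.
#'
#' @param config A [sim_config()].
#' @param seed Optional override of `config$seed`.
#' @return List: `transcripts` (a transcript `data.frame` ready for
#'   [apply_qc()]), `labels` (`cell_id`, `cell_type`) and `truth` (the
#'   generative config).
#' @export
simulate_cells <- function(config, seed = config$seed) {
  R <- config$cell_radius
  mean_t <- config$transcripts_per_cell[[1]]
  size_t <- config$transcripts_per_cell[[2]]
  n_total <- sum(config$n_cells)
  grid_n <- ceiling(sqrt(n_total))
  pitch <- 4 * R
  withr::with_seed(seed, {
    rows <- list(); labs <- list(); cell_i <- 0L
    for (type in names(config$cell_types)) {
      ct <- config$cell_types[[type]]
      genes_avail <- names(ct$gene_freqs)
      for (j in seq_len(config$n_cells[[type]])) {
        cell_i <- cell_i + 1L
        cid <- sprintf("cell_%04d", cell_i)
        cx <- ((cell_i - 1L) %% grid_n) * pitch + stats::runif(1, -R / 2, R / 2)
        cy <- ((cell_i - 1L) %/% grid_n) * pitch + stats::runif(1, -R / 2, R / 2)
        count <- max(1L, stats::rnbinom(1L, size = size_t, mu = mean_t))
        n_bg <- round(config$background_fraction * count)
        n_main <- count - n_bg
        g_main <- sample(genes_avail, n_main, replace = TRUE,
                         prob = ct$gene_freqs)
        pos <- matrix(0, n_main, 2L)
        for (gene in unique(g_main)) {
          sel <- which(g_main == gene)
          spec <- ct$niches[[gene]] %||% niche_uniform()
          pos[sel, ] <- sample_niche(length(sel), spec, R)
        }
        g_bg <- sample(genes_avail, n_bg, replace = TRUE, prob = ct$gene_freqs)
        pos_bg <- sample_niche(n_bg, niche_uniform(), R)
        n_ctrl <- round(config$control_fraction * count)
        g_ctrl <- sprintf("NegPrb%03d", sample.int(10L, n_ctrl, replace = TRUE))
        pos_ctrl <- sample_niche(n_ctrl, niche_uniform(), R)
        xy <- rbind(pos, pos_bg, pos_ctrl)
        xy <- xy + matrix(stats::rnorm(length(xy), 0, config$coordinate_jitter_sd),
                          ncol = 2L)
        rows[[cell_i]] <- data.frame(
          cell_id = cid, gene = c(g_main, g_bg, g_ctrl),
          x = cx + xy[, 1], y = cy + xy[, 2], stringsAsFactors = FALSE)
        labs[[cell_i]] <- data.frame(cell_id = cid, cell_type = type,
                                     stringsAsFactors = FALSE)
      }
    }
    transcripts <- do.call(rbind, rows)
    rownames(transcripts) <- NULL
    attr(transcripts, "unit_scale") <- 1
    list(transcripts = transcripts, labels = do.call(rbind, labs),
         truth = config)
  })
}

# 20-gene symbols used by the built-in presets.
preset_genes <- function() sprintf("g%02d", 1:20)

# Equal-frequency program with one marker gene taking `marker_frac`.
marker_freqs <- function(genes, marker, marker_frac = 0.25) {
  freqs <- stats::setNames(rep((1 - marker_frac) / (length(genes) - 1L), length(genes)),
                           genes)
  freqs[marker] <- marker_frac
  freqs
}

#' Built-in synthetic benchmarks
#'
#' Presets with known ground truth, each splitting cells into a labeled
#' reference and a held-out query:
#'
#' * `"spatial-only"` — two cell types with *identical* gene-frequency
#'   programs (so per-cell count vectors are exchangeable between types and
#'   an expression-only classifier is at chance); the marker gene `g01`
#'   sits in a perinuclear ring in `TypeA` and a peripheral shell in
#'   `TypeB`. 200 reference + 200 query cells, 20 genes, ~150 transcripts
#'   per cell. Only the gene neighborhood network distinguishes the types.
#' * `"expression-only"` — two types with different frequency programs and
#'   all-uniform niches (the degenerate spatial-blind control).
#' * `"mixed"` — three types differing in both expression and niches.
#' * `"reference-fraction-sweep"` — the mixed data plus nested,
#'   type-stratified reference subsets at 10/40/70/100% of the query size,
#'   for robustness-to-reference-downsampling experiments.
#'
#' All presets use cell radius 7 um, a 2 um connection radius
#' (`$graph_d`), and QC threshold alpha 50 (`$alpha`).
#'
#' @param preset One of `"spatial-only"`, `"expression-only"`, `"mixed"`,
#'   `"reference-fraction-sweep"`.
#' @param seed Simulation seed.
#' @return List with `reference` and `query` (each
#'   `list(transcripts, labels)`), `truth`, `graph_d`, `alpha`, and for the
#'   sweep preset `reference_subsets`: named list mapping fraction to the
#'   reference cell ids of that nested subset.
#' @export
make_benchmark <- function(preset = c("spatial-only", "expression-only",
                                      "mixed", "reference-fraction-sweep"),
                           seed = 0L) {
  preset <- match.arg(preset)
  genes <- preset_genes()
  cfg <- switch(preset,
    "spatial-only" = sim_config(
      cell_types = list(
        TypeA = list(gene_freqs = marker_freqs(genes, "g01"),
                     niches = list(g01 = niche_ring(0.3, 2.2))),
        TypeB = list(gene_freqs = marker_freqs(genes, "g01"),
                     niches = list(g01 = niche_ring(5.6, 7.0)))),
      n_cells = 200L, seed = seed),
    "expression-only" = sim_config(
      cell_types = list(
        TypeA = list(gene_freqs = marker_freqs(genes, "g01", 0.30),
                     niches = list()),
        TypeB = list(gene_freqs = marker_freqs(genes, "g20", 0.30),
                     niches = list())),
      n_cells = 100L, seed = seed),
    sim_config(  # mixed (also the sweep base)
      cell_types = list(
        TypeA = list(gene_freqs = marker_freqs(genes, "g01", 0.30),
                     niches = list(g01 = niche_ring(0.3, 2.2))),
        TypeB = list(gene_freqs = marker_freqs(genes, "g10", 0.30),
                     niches = list(g10 = niche_ring(5.6, 7.0))),
        TypeC = list(gene_freqs = marker_freqs(genes, "g20", 0.30),
                     niches = list(g20 = niche_cluster(2L, 0.6)))),
      n_cells = 80L, seed = seed))
  sim <- simulate_cells(cfg)
  # per-type split: first half reference, second half query
  by_type <- split(sim$labels$cell_id, sim$labels$cell_type)
  ref_ids <- unlist(lapply(by_type, function(ids) ids[seq_len(length(ids) %/% 2L)]),
                    use.names = FALSE)
  qry_ids <- setdiff(sim$labels$cell_id, ref_ids)
  subset_tbl <- function(ids) {
    tr <- sim$transcripts[sim$transcripts$cell_id %in% ids, , drop = FALSE]
    rownames(tr) <- NULL
    attr(tr, "unit_scale") <- 1
    list(transcripts = tr,
         labels = sim$labels[sim$labels$cell_id %in% ids, , drop = FALSE])
  }
  out <- list(reference = subset_tbl(ref_ids), query = subset_tbl(qry_ids),
              truth = cfg, graph_d = 2, alpha = 50L, preset = preset)
  if (preset == "reference-fraction-sweep") {
    fractions <- c(0.1, 0.4, 0.7, 1.0)
    n_query <- length(qry_ids)
    ref_by_type <- split(out$reference$labels$cell_id,
                         out$reference$labels$cell_type)
    out$reference_subsets <- stats::setNames(lapply(fractions, function(f) {
      per_type <- round(f * n_query / length(ref_by_type))
      unlist(lapply(ref_by_type, function(ids) {
        ids[seq_len(min(per_type, length(ids)))]
      }), use.names = FALSE)
    }), paste0(fractions * 100, "%"))
  }
  out
}

#' Write a simulated dataset to a directory
#'
#' Writes `transcripts.csv`, `labels.csv` and `truth.json` (the full
#' generative parameters).
#'
#' @param sim A [simulate_cells()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_transcripts(sim$transcripts, file.path(dir, "transcripts.csv"))
  utils::write.csv(sim$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(sim$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
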