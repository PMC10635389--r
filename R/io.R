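#' Read and write the cell, tract and truth tables
#'
#' Plain UTF-8 comma-delimited CSV with a header row; coordinates in
#' micrometres, image convention (origin top-left, y down). Column layouts
#' are documented in the data dictionary (`inst/extdata/data_dictionary.md`).
#'
#' @param x data.frame to write.
#' @param path file path.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_cells <- function(x, path) utils::write.csv(x, path, row.names = FALSE)

#' @rdname table_io
#' @export
read_cells <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' @rdname table_io
#' @export
write_tracts <- function(x, path) utils::write.csv(x, path, row.names = FALSE)

#' @rdname table_io
#' @export
read_tracts <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Scene geometry JSON round trip
#'
#' @param scene scene list (regions, midline, ventricle_edge, um_per_unit).
#' @param path file path.
#' @export
write_scene <- function(scene, path) {
  out <- list(
    regions = lapply(scene$regions, function(m) unname(as.matrix(m))),
    midline = unname(as.matrix(scene$midline)),
    ventricle_edge = unname(as.matrix(scene$ventricle_edge)),
    um_per_unit = scene$um_per_unit)
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(regions = lapply(raw$regions, function(m) matrix(unlist(m), ncol = 2,
         dimnames = list(NULL, c("x", "y")))),
       midline = matrix(unlist(raw$midline), ncol = 2),
       ventricle_edge = matrix(unlist(raw$ventricle_edge), ncol = 2),
       um_per_unit = raw$um_per_unit)
}

#' Write a count matrix as MatrixMarket triplets with sidecars
#'
#' Writes `counts.mtx` (1-based MatrixMarket coordinate format, cells in
#' rows), `cells.csv` (per-cell metadata) and `genes.csv` to a directory.
#'
#' @param es an [expr_set()].
#' @param dir output directory (created if absent).
#' @export
write_counts <- function(es, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(es$counts, sparse = TRUE),
                               "generalMatrix"), "TsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "counts.mtx"))
  utils::write.csv(es$meta, file.path(dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(data.frame(gene = colnames(es$counts)),
                   file.path(dir, "genes.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a count matrix (MTX directory or long CSV)
#'
#' Two dialects produce identical matrices: (1) a directory holding
#' `counts.mtx` + `cells.csv` + `genes.csv`; (2) a long CSV with columns
#' cell_id, gene, count and optional x, y, fov, region. Duplicate
#' (cell, gene) entries in the long form are summed with a warning;
#' non-integer counts are an error.
#'
#' @param path directory or CSV file path.
#' @return An [expr_set()].
#' @export
read_counts <- function(path) {
  if (dir.exists(path)) {
    m <- as.matrix(Matrix::readMM(file.path(path, "counts.mtx")))
    meta <- utils::read.csv(file.path(path, "cells.csv"),
                            stringsAsFactors = FALSE)
    genes <- utils::read.csv(file.path(path, "genes.csv"),
                             stringsAsFactors = FALSE)$gene
    if (any(m != round(m)) || any(m < 0)) stop("non-integer counts")
    dimnames(m) <- list(meta$cell_id, genes)
    return(expr_set(m, meta))
  }
  if (!file.exists(path) || file.size(path) == 0) stop("empty or missing file")
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(long) == 0) stop("empty count table")
  if (any(long$count != round(long$count)) || any(long$count < 0))
    stop("non-integer counts")
  key <- paste(long$cell_id, long$gene, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (cell, gene) entries summed")
    agg <- tapply(long$count, key, sum)
    first <- !duplicated(key)
    long <- long[first, ]
    long$count <- as.numeric(agg[key[first]])
  }
  cells <- unique(long$cell_id)
  genes <- sort(unique(long$gene))
  m <- matrix(0, length(cells), length(genes),
              dimnames = list(cells, genes))
  m[cbind(match(long$cell_id, cells), match(long$gene, genes))] <- long$count
  meta_cols <- intersect(c("x", "y", "fov", "region"), names(long))
  meta <- long[!duplicated(long$cell_id),
               c("cell_id", meta_cols), drop = FALSE]
  meta <- meta[match(cells, meta$cell_id), , drop = FALSE]
  for (col in setdiff(c("x", "y", "fov", "region"), meta_cols))
    meta[[col]] <- if (col %in% c("x", "y")) NA_real_ else NA_character_
  rownames(meta) <- NULL
  expr_set(m, meta)
}

#' Default full-pipeline configuration
#'
#' Every tunable default of the simulation, morphometric, clustering and
#' enrichment stages in one serializable list; unknown keys are rejected at
#' run time.
#'
#' @param seed integer seed propagated to every stage.
#' @return Named list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    scene = list(mice_per_group = 3L),
    counts = list(n_genes = 1000L),
    cluster = list(n_hvg = 200L, n_pcs = 20L, k = 15L,
                   resolution = 0.1, budget = 1000L),
    enrichment = list(gene = "Lgals3", k_min = 2L),
    qc = list(t_min = 20L),
    threshold = list(k = 2),
    reference_group = "YNG"
  ), class = "run_config")
}

validate_run_config <- function(config) {
  known <- c("seed", "scene", "counts", "cluster", "enrichment", "qc",
             "threshold", "reference_group")
  extra <- setdiff(names(config), known)
  if (length(extra) > 0) stop("unknown config keys: ",
                              paste(extra, collapse = ", "))
  if (config$cluster$resolution <= 0) stop("resolution must be > 0")
  if (config$qc$t_min < 0) stop("t_min must be >= 0")
  invisible(config)
}

#' Run the full synthetic-to-statistics pipeline
#'
#' Simulates sections and counts, runs morphometrics, stratification,
#' clustering, enrichment and differential expression, and writes every
#' stage output plus a manifest (config hash, seed, stage order, md5
#' checksum per file) to a run directory. Re-running with the same config
#' reproduces the checksums exactly.
#'
#' @param config a [default_config()]-style list.
#' @param out_dir run directory (created).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  # imaging arm
  sc <- stage("simulate-section", {
    cfg <- scene_config(seed = config$seed,
                        mice_per_group = config$scene$mice_per_group)
    simulate_section(cfg)
  })
  write_cells(sc$cells, file.path(out_dir, "cells.csv"))
  write_tracts(sc$tracts, file.path(out_dir, "tracts.csv"))
  write_scene(sc$scene, file.path(out_dir, "scene.json"))
  utils::write.csv(sc$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  morpho <- stage("morpho", compute_morphometrics(
    sc$cells, sc$tracts, reference_group = config$reference_group))
  utils::write.csv(morpho, file.path(out_dir, "morphometrics.csv"),
                   row.names = FALSE)
  stats_out <- stage("stratify", {
    yng <- morpho$group == config$reference_group
    thr <- derive_threshold(morpho$norm_GAL3[yng], k = config$threshold$k,
                            channel = "GAL3",
                            group = config$reference_group)
    gal3 <- marker_calls(morpho$norm_GAL3, thr$threshold)
    dens <- vapply(split(morpho, morpho$group), function(d)
      mean(tapply(d$cell_id, d$mouse, length)), numeric(1))
    ks <- ks_two_sample(morpho$angle_offset[morpho$group == "OLD" &
                                              morpho$region == "fimbria"],
                        morpho$angle_offset[morpho$group == "YNG" &
                                              morpho$region == "fimbria"])
    list(threshold = unclass(thr),
         gal3_positive_frac = tapply(gal3, morpho$group, mean),
         cells_per_mouse = dens,
         ks_angle_offset = unclass(ks))
  })
  jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                       digits = NA, auto_unbox = TRUE)
  # transcriptomics arm
  dam <- stage("cluster", {
    ccfg <- counts_config(seed = config$seed,
                          n_genes = config$counts$n_genes)
    simc <- simulate_counts(ccfg, sc$scene)
    es <- qc_filter(simc$expr, config$qc$t_min)
    es <- normalize_scale(es)
    hvg <- select_hvg(es, config$cluster$n_hvg)
    gr <- pca_knn(es, hvg, n_pcs = config$cluster$n_pcs,
                  k = config$cluster$k)
    lab <- leiden_cluster(gr, resolution = config$cluster$resolution,
                          budget = config$cluster$budget,
                          seed = config$seed)
    list(es = es, labels = lab, truth = simc$truth)
  })
  utils::write.csv(data.frame(cell_id = dam$es$meta$cell_id,
                              cluster = dam$labels),
                   file.path(out_dir, "clusters.csv"), row.names = FALSE)
  enr <- stage("enrich", classify_enriched(dam$es, config$enrichment$gene,
                                           config$enrichment$k_min))
  utils::write.csv(data.frame(cell_id = dam$es$meta$cell_id,
                              enriched = enr),
                   file.path(out_dir, "enrichment.csv"), row.names = FALSE)
  de <- stage("de", {
    if (sum(enr) >= 3 && sum(!enr) >= 3)
      de_wilcoxon(dam$es, enr, !enr)
    else data.frame(gene = character(0), log2fc = numeric(0),
                    p = numeric(0), padj = numeric(0),
                    direction = character(0))
  })
  utils::write.csv(de, file.path(out_dir, "de.csv"), row.names = FALSE)
  # manifest
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  cfg_json <- jsonlite::toJSON(unclass(config), digits = NA, auto_unbox = TRUE)
  manifest <- list(
    config = unclass(config),
    config_md5 = as.character(tools::md5sum(local({
      f <- tempfile(); writeLines(cfg_json, f); f
    }))),
    seed = config$seed,
    stages = c("simulate-section", "morpho", "stratify", "simulate-counts",
               "cluster", "enrich", "de"),
    checksums = as.list(tools::md5sum(file.path(out_dir, files)))
  )
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(manifest)
}
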