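#' Gate and macrophage-panel specification
#'
#' Marker panels used for microglia selection and macrophage exclusion:
#' nine validated microglia inclusion markers, a six-gene macrophage
#' up-panel and a two-gene down-panel (genes microglia express but
#' infiltrating macrophages largely lack).
#'
#' @param inclusion,macro_up,macro_down character vectors of gene names.
#' @param score_threshold gate-score threshold (scaled-z units).
#' @param min_markers minimum number of distinct inclusion markers detected.
#' @param macro_quantile quantile of the macrophage score above which gated
#'   cells are removed as macrophages.
#' @return Object of class `gate_spec`.
#' @export
gate_spec <- function(inclusion = c("Csf1r", "Ctss", "Cx3cr1", "Hexb", "Selplg",
                                    "Itgam", "P2ry12", "Tmem119", "Trem2"),
                      macro_up = c("Crip1", "Cd74", "Fxyd5", "H2-Aa",
                                   "H2-Ab1", "H3f3b"),
                      macro_down = c("Cd9", "Ctsd"),
                      score_threshold = 0,
                      min_markers = 2L,
                      macro_quantile = 0.95) {
  if (length(intersect(macro_up, macro_down)) > 0)
    stop("macrophage up- and down-panels must be disjoint")
  structure(list(inclusion = inclusion, macro_up = macro_up,
                 macro_down = macro_down, score_threshold = score_threshold,
                 min_markers = as.integer(min_markers),
                 macro_quantile = macro_quantile),
            class = "gate_spec")
}

# Signature gene sets for the simulated panel.
sim_gene_sets <- function() {
  list(
    gate = gate_spec()$inclusion,
    macro_up = gate_spec()$macro_up,
    macro_down = gate_spec()$macro_down,
    dam = c("Apoe", "Lgals3", "Itgax", "Spp1", "Cst7", "Clec7a", "Fth1",
            "Lyz1", "Lyz2", "Bcl2", "Cd63", "Msr1"),
    cdkn = c("Cdkn1a", "Cdkn1b", "Cdkn2a", "Cdkn2d"),
    oligo = c("Plp1", "Mobp", "Gpr37", "App", "Cpe"),
    astro = c("Gfap", "Aqp4", "Slc1a3")
  )
}

#' Counts configuration for the spatial transcriptomics simulator
#'
#' Stated world for the simulated in-situ panel: a ~1000-gene panel (a small
#' signature core embedded in filler genes, emulating a custom senescence
#' panel applied in tandem with a ~950-plex neuroscience panel) measured
#' over five cell types placed by region. Counts are negative binomial with
#' lognormal per-cell library-size scaling. DAM-type cells concentrate in
#' white matter (fimbria); the DAM signature carries planted log2
#' fold-changes of 2 versus homeostatic microglia and a high Lgals3 mean so
#' that transcript-count enrichment (>= 2 counts) tags DAM cells.
#'
#' @param seed RNG seed.
#' @param n_genes total panel size (signature genes plus filler).
#' @param dispersion negative binomial size parameter (larger = closer to
#'   Poisson).
#' @param libsize_sdlog lognormal SD of the per-cell library factor.
#' @param cells_per_region named list: region -> named integer vector of
#'   cells per type.
#' @param planted_lfc log2 fold-change planted on the DAM signature genes
#'   (DAM vs homeostatic).
#' @return Object of class `counts_config` with the per-type mean matrix in
#'   `$means` (types x genes) and planted truth in `$planted`.
#' @export
counts_config <- function(seed = 1L,
                          n_genes = 1000L,
                          dispersion = 3,
                          libsize_sdlog = 0.25,
                          cells_per_region = list(
                            fimbria = c(homeostatic = 300, dam = 150,
                                        macrophage = 30, oligodendrocyte = 150,
                                        astrocyte = 70),
                            hippocampus = c(homeostatic = 700, dam = 30,
                                            macrophage = 30,
                                            oligodendrocyte = 100,
                                            astrocyte = 150)),
                          planted_lfc = 2) {
  sets <- sim_gene_sets()
  sig <- unique(unlist(sets))
  if (n_genes < length(sig) + 10) stop("panel too small for signature genes")
  filler <- sprintf("Filler%04d", seq_len(n_genes - length(sig)))
  genes <- c(sig, filler)
  types <- c("homeostatic", "dam", "macrophage", "oligodendrocyte", "astrocyte")
  means <- matrix(0.05, nrow = length(types), ncol = length(genes),
                  dimnames = list(types, genes))
  # housekeeping floor so every cell clears the 20-transcript QC bar most
  # of the time: filler genes carry a small baseline in all types
  means[, filler] <- 0.05
  # homeostatic microglia: strong gate markers, moderate Cd9/Ctsd
  means["homeostatic", sets$gate] <- 4
  means["homeostatic", sets$macro_down] <- 3
  means["homeostatic", sets$dam] <- 0.5
  means["homeostatic", "Lgals3"] <- 0.1   # homeostatic cells: 1 or no counts
  means["homeostatic", sets$cdkn] <- 0.1
  # DAM: gate markers partially retained, DAM signature up by planted_lfc,
  # Lgals3 high enough that >=2 raw transcripts tags the cell reliably
  means["dam", sets$gate] <- 2.5
  means["dam", sets$macro_down] <- 3
  means["dam", sets$dam] <- 0.5 * 2^planted_lfc
  means["dam", "Lgals3"] <- 12
  means["dam", sets$cdkn] <- c(1.5, 0.8, 3, 0.8)
  # macrophages: pass the microglia gate partially (realistic contamination),
  # strong up-panel, depleted Cd9/Ctsd
  means["macrophage", sets$gate] <- 2
  means["macrophage", sets$macro_up] <- 6
  means["macrophage", sets$macro_down] <- 0.1
  means["macrophage", "Lyz1"] <- 3; means["macrophage", "Lyz2"] <- 3
  # oligodendrocytes / astrocytes: their own markers, near-zero gate genes
  means["oligodendrocyte", sets$oligo] <- 8
  means["astrocyte", sets$astro] <- 8
  structure(list(seed = as.integer(seed), genes = genes, types = types,
                 means = means, dispersion = dispersion,
                 libsize_sdlog = libsize_sdlog,
                 cells_per_region = cells_per_region,
                 planted_lfc = planted_lfc,
                 planted_genes = setdiff(sets$dam, "Lgals3"),
                 sets = sets),
            class = "counts_config")
}

#' Simulate a spatial single-cell count matrix over a section scene
#'
#' Draws per-cell negative binomial counts from the per-type mean vectors in
#' `config`, scaled by a lognormal library factor, and places cells
#' uniformly within their assigned region of `scene`. Returns the raw
#' expression container plus a ground-truth table (true type, true
#' enrichment class) consumed only by tests.
#'
#' @param config a [counts_config()].
#' @param scene scene geometry as returned by [simulate_section()] (list
#'   with `regions`), or the full simulate_section() result.
#' @return list with `expr` (an [expr_set()]) and `truth` (data.frame).
#' @export
simulate_counts <- function(config, scene) {
  stopifnot(inherits(config, "counts_config"))
  if (!is.null(scene$scene)) scene <- scene$scene
  set.seed(config$seed)
  regions <- names(config$cells_per_region)
  missing_r <- setdiff(regions, names(scene$regions))
  if (length(missing_r) > 0)
    stop("cell type placed in region absent from scene: ",
         paste(missing_r, collapse = ", "))
  blocks <- list(); meta <- list(); truth <- list()
  cid <- 0L
  for (rg in regions) {
    per_type <- config$cells_per_region[[rg]]
    for (ty in names(per_type)) {
      n <- per_type[[ty]]
      if (n == 0) next
      pos <- runif_in_polygon(n, scene$regions[[rg]])
      lib <- stats::rlnorm(n, 0, config$libsize_sdlog)
      mu <- outer(lib, config$means[ty, ])
      cnt <- matrix(stats::rnbinom(length(mu), size = config$dispersion,
                                   mu = mu),
                    nrow = n, dimnames = list(NULL, config$genes))
      ids <- sprintf("c%05d", cid + seq_len(n))
      rownames(cnt) <- ids
      blocks[[length(blocks) + 1L]] <- cnt
      meta[[length(meta) + 1L]] <- data.frame(
        cell_id = ids, x = pos[, 1], y = pos[, 2],
        fov = paste0("F_", rg), region = rg, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        cell_id = ids, type = ty, stringsAsFactors = FALSE)
      cid <- cid + n
    }
  }
  counts <- do.call(rbind, blocks)
  meta <- do.call(rbind, meta); rownames(meta) <- NULL
  truth <- do.call(rbind, truth); rownames(truth) <- NULL
  truth$high_lgals3 <- truth$type == "dam"
  list(expr = expr_set(counts, meta), truth = truth)
}
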