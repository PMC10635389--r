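#' Spatial expression container
#'
#' Lightweight container for an in-situ single-cell experiment: an integer
#' cells x genes count matrix with per-cell spatial metadata and optional
#' derived layers (`norm`, `scaled`) added by [normalize_scale()].
#'
#' @param counts integer matrix, cells in rows (rownames = cell ids), genes
#'   in columns (colnames = gene names).
#' @param meta data.frame with one row per cell: cell_id, x, y, fov, region.
#' @return Object of class `expr_set`.
#' @export
expr_set <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry cell and gene names")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (!identical(rownames(counts), meta$cell_id))
    stop("meta rows must match count matrix rows")
  structure(list(counts = counts, meta = meta, norm = NULL, scaled = NULL,
                 qc = NULL), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat("expr_set:", nrow(x$counts), "cells x", ncol(x$counts), "genes;",
      "layers:", paste(c("counts", if (!is.null(x$norm)) "norm",
                         if (!is.null(x$scaled)) "scaled"), collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-cell transcript-count QC filter
#'
#' Removes cells whose total transcript count is below `t_min`; the default
#' excludes cells with fewer than 20 total transcripts (a cell with exactly
#' 20 is kept).
#'
#' @param es an [expr_set()].
#' @param t_min minimum total transcripts per cell.
#' @return The filtered `expr_set` with a `$qc` report (cells kept/removed).
#' @export
qc_filter <- function(es, t_min = 20) {
  totals <- rowSums(es$counts)
  keep <- totals >= t_min
  if (!any(keep)) stop("empty after QC")
  out <- expr_set(es$counts[keep, , drop = FALSE],
                  es$meta[keep, , drop = FALSE])
  out$meta <- es$meta[keep, , drop = FALSE]
  rownames(out$meta) <- NULL
  out$qc <- list(t_min = t_min, n_in = length(totals), n_kept = sum(keep),
                 n_removed = sum(!keep),
                 removed = es$meta$cell_id[!keep])
  out
}

#' Library-size normalization and per-gene scaling
#'
#' Normalized layer: counts divided by the per-cell total and multiplied by
#' the median total, so every cell's normalized row sums to median(T).
#' Scaled layer: log1p of the normalized values, then per-gene z-score
#' (constant genes map to 0), clipped at +/- `clip`.
#'
#' @param es an [expr_set()] (after QC; zero-total cells are an error).
#' @param clip z-score clipping bound.
#' @return `expr_set` with `$norm` and `$scaled` layers.
#' @export
normalize_scale <- function(es, clip = 10) {
  totals <- rowSums(es$counts)
  if (any(totals == 0)) stop("zero-total cell; run qc_filter first")
  target <- stats::median(totals)
  es$norm <- es$counts / totals * target
  lg <- log1p(es$norm)
  mu <- colMeans(lg)
  sd <- apply(lg, 2, stats::sd)
  z <- sweep(lg, 2, mu)
  z <- sweep(z, 2, ifelse(sd > 0, sd, 1), "/")
  es$scaled <- pmin(pmax(z, -clip), clip)
  es
}

#' Highly variable gene selection by Pearson residual variance
#'
#' Genes are ranked by the variance of their Poisson-Pearson residuals
#' (observed count minus the expectation under a constant-proportion model,
#' scaled by per-cell totals, divided by the square root of the
#' expectation). A gene that tracks the constant-proportion null has
#' residual variance near 1; genes with real structure score higher. Ties
#' break by gene-name order.
#'
#' @param es an [expr_set()].
#' @param n number of genes to return.
#' @return Character vector of the top `n` gene names.
#' @export
select_hvg <- function(es, n = 200) {
  if (n > ncol(es$counts)) stop("n exceeds the gene count")
  totals <- rowSums(es$counts)
  p <- colSums(es$counts) / sum(totals)
  mu <- outer(totals, p)
  r <- (es$counts - mu) / sqrt(pmax(mu, .Machine$double.eps))
  v <- apply(r, 2, stats::var)
  ord <- order(-v, colnames(es$counts))
  colnames(es$counts)[ord][seq_len(n)]
}

#' PCA and kNN graph over the scaled HVG submatrix
#'
#' @param es an [expr_set()] with a scaled layer.
#' @param genes genes to use (typically [select_hvg()] output).
#' @param n_pcs number of principal components.
#' @param k neighbours per cell; the graph is undirected with duplicate
#'   edges removed.
#' @return list with `embedding` (cells x n_pcs), `edges` (2-column integer
#'   matrix), `n` cells, and `var_explained`.
#' @export
pca_knn <- function(es, genes = NULL, n_pcs = 20, k = 15) {
  if (is.null(es$scaled)) stop("scaled layer missing; run normalize_scale")
  if (is.null(genes)) genes <- colnames(es$scaled)
  x <- es$scaled[, genes, drop = FALSE]
  if (n_pcs >= min(dim(x))) stop("n_pcs must be < min(cells, genes)")
  if (k >= nrow(x)) stop("k must be < number of cells")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)
  emb <- pc$x
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  edges <- knn_edges(emb, k)
  list(embedding = emb, edges = edges, n = nrow(emb),
       var_explained = ve[seq_len(n_pcs)])
}

# Exact kNN by blocked all-pairs Euclidean distance; returns deduplicated
# undirected edges as a 2-column matrix of 1-based indices.
knn_edges <- function(emb, k) {
  n <- nrow(emb)
  sq <- rowSums(emb^2)
  block <- 512L
  from <- integer(0); to <- integer(0)
  for (s in seq(1, n, by = block)) {
    e <- min(s + block - 1L, n)
    d2 <- outer(sq[s:e], sq, "+") - 2 * emb[s:e, , drop = FALSE] %*% t(emb)
    for (i in seq_len(e - s + 1L)) {
      row <- d2[i, ]
      row[s + i - 1L] <- Inf
      nb <- order(row)[seq_len(k)]
      from <- c(from, rep(s + i - 1L, k)); to <- c(to, nb)
    }
  }
  a <- pmin(from, to); b <- pmax(from, to)
  unique(cbind(a, b))
}

#' Leiden clustering of a kNN graph
#'
#' Optimizes resolution-parameterized modularity with the Leiden algorithm
#' under a fixed seed and an iteration budget. Cluster ids are relabelled in
#' descending size order (cluster 1 is the largest).
#'
#' @param graph output of [pca_knn()] (list with `edges`, `n`), or an
#'   igraph object.
#' @param resolution resolution parameter gamma.
#' @param budget Leiden iteration budget.
#' @param seed RNG seed for the optimizer.
#' @return Integer vector of cluster labels (1 = largest).
#' @export
leiden_cluster <- function(graph, resolution = 0.1, budget = 1000, seed = 1) {
  if (resolution <= 0) stop("resolution must be > 0")
  g <- if (inherits(graph, "igraph")) graph else {
    if (is.null(graph$edges) || nrow(graph$edges) == 0) stop("empty graph")
    g0 <- igraph::graph_from_edgelist(graph$edges, directed = FALSE)
    if (igraph::vcount(g0) < graph$n)
      g0 <- igraph::add_vertices(g0, graph$n - igraph::vcount(g0))
    g0
  }
  if (igraph::vcount(g) == 0) stop("empty graph")
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution,
                               n_iterations = budget)
  relabel_by_size(igraph::membership(cl))
}

relabel_by_size <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  map <- stats::setNames(seq_along(tab), names(tab))
  as.integer(map[as.character(labels)])
}

#' Microglia gating by validated marker panel
#'
#' Per-cell gate score = mean scaled expression over the inclusion markers.
#' A cell is kept when its score exceeds `gate$score_threshold` (default 0,
#' i.e. above the experiment-wide mean) and at least `gate$min_markers`
#' distinct inclusion markers have nonzero raw counts.
#'
#' @param es an [expr_set()] with a scaled layer.
#' @param gate a [gate_spec()].
#' @return list with `keep` (logical), `score`, `report`.
#' @export
gate_microglia <- function(es, gate = gate_spec()) {
  missing_g <- setdiff(gate$inclusion, colnames(es$counts))
  if (length(missing_g) > 0)
    stop("gate gene absent from panel: ", paste(missing_g, collapse = ", "))
  if (is.null(es$scaled)) stop("scaled layer missing; run normalize_scale")
  score <- rowMeans(es$scaled[, gate$inclusion, drop = FALSE])
  detected <- rowSums(es$counts[, gate$inclusion, drop = FALSE] > 0)
  keep <- score > gate$score_threshold & detected >= gate$min_markers
  list(keep = keep, score = score,
       report = list(n_in = length(keep), n_kept = sum(keep),
                     kept_fraction = mean(keep)))
}

#' Macrophage exclusion from a gated microglia subset
#'
#' Macrophage score = mean scaled z over the up-panel minus mean scaled z
#' over the down-panel, computed within the gated subset. Cells above the
#' `gate$macro_quantile` quantile of the score are removed (contamination
#' assumed minor).
#'
#' @param es gated [expr_set()] with a scaled layer.
#' @param gate a [gate_spec()].
#' @return list with `keep` (logical), `score`, `removed` cell ids,
#'   `threshold`.
#' @export
exclude_macrophages <- function(es, gate = gate_spec()) {
  pan <- c(gate$macro_up, gate$macro_down)
  missing_g <- setdiff(pan, colnames(es$counts))
  if (length(missing_g) > 0)
    stop("macrophage panel gene absent: ", paste(missing_g, collapse = ", "))
  if (is.null(es$scaled)) stop("scaled layer missing; run normalize_scale")
  score <- rowMeans(es$scaled[, gate$macro_up, drop = FALSE]) -
    rowMeans(es$scaled[, gate$macro_down, drop = FALSE])
  thr <- stats::quantile(score, gate$macro_quantile, names = FALSE)
  keep <- score <= thr
  list(keep = keep, score = score, threshold = thr,
       removed = es$meta$cell_id[!keep])
}

#' Subset an expr_set by cells
#'
#' @param es an [expr_set()].
#' @param keep logical or cell-id vector.
#' @return Subsetted `expr_set` (derived layers subset along with counts).
#' @export
subset_cells <- function(es, keep) {
  if (!is.logical(keep)) keep <- es$meta$cell_id %in% keep
  out <- expr_set(es$counts[keep, , drop = FALSE],
                  es$meta[keep, , drop = FALSE])
  if (!is.null(es$norm)) out$norm <- es$norm[keep, , drop = FALSE]
  if (!is.null(es$scaled)) out$scaled <- es$scaled[keep, , drop = FALSE]
  out
}

#' Transcript-count enrichment classification
#'
#' A cell is enriched for a gene when its RAW transcript count is at least
#' `k_min` (default 2: cells with 2 or more counts versus cells with 1 or
#' none). With several genes the rule applies to the summed raw count across
#' the set (`mode = "set"`, the default) or requires every gene to meet
#' `k_min` individually (`mode = "each"`).
#'
#' Enrichment operates on raw counts by construction, so it is invariant to
#' any normalization choice.
#'
#' @param es an [expr_set()].
#' @param genes gene name(s).
#' @param k_min minimum transcript count.
#' @param mode "set" (summed counts) or "each".
#' @return Logical vector, one call per cell.
#' @export
classify_enriched <- function(es, genes, k_min = 2, mode = c("set", "each")) {
  mode <- match.arg(mode)
  missing_g <- setdiff(genes, colnames(es$counts))
  if (length(missing_g) > 0)
    stop("gene absent from panel: ", paste(missing_g, collapse = ", "))
  sub <- es$counts[, genes, drop = FALSE]
  if (mode == "set") rowSums(sub) >= k_min else rowSums(sub >= k_min) == length(genes)
}

#' Wilcoxon rank-sum differential expression
#'
#' Per-gene two-sided Wilcoxon rank-sum test on library-size-normalized
#' values between two disjoint cell sets, with tie correction; the exact
#' permutation null is enumerated when |A| + |B| <= `exact_max`. Fold-change
#' is log2((mean_A + eps) / (mean_B + eps)) on normalized values with
#' eps = 1e-9 x median per-cell total. P-values are Benjamini-Hochberg
#' adjusted across all tested genes.
#'
#' @param es an [expr_set()] with a normalized layer.
#' @param cells_a,cells_b disjoint cell-id (or logical) vectors, each >= 3.
#' @param genes genes to test (default all).
#' @param exact_max size bound for exact enumeration.
#' @return data.frame: gene, log2fc, p, padj, direction.
#' @export
de_wilcoxon <- function(es, cells_a, cells_b, genes = NULL, exact_max = 12) {
  if (is.null(es$norm)) stop("normalized layer missing; run normalize_scale")
  ids <- es$meta$cell_id
  if (is.logical(cells_a)) cells_a <- ids[cells_a]
  if (is.logical(cells_b)) cells_b <- ids[cells_b]
  if (length(intersect(cells_a, cells_b)) > 0) stop("cell sets overlap")
  if (length(cells_a) < 3 || length(cells_b) < 3)
    stop("each group needs at least 3 cells")
  if (is.null(genes)) genes <- colnames(es$norm)
  a <- es$norm[match(cells_a, ids), genes, drop = FALSE]
  b <- es$norm[match(cells_b, ids), genes, drop = FALSE]
  eps <- 1e-9 * stats::median(rowSums(es$counts))
  ma <- colMeans(a); mb <- colMeans(b)
  l2fc <- log2((ma + eps) / (mb + eps))
  p <- vapply(seq_along(genes), function(j) {
    wilcox_p(a[, j], b[, j], exact_max)
  }, numeric(1))
  data.frame(gene = genes, log2fc = l2fc, p = p,
             padj = stats::p.adjust(p, method = "BH"),
             direction = ifelse(l2fc >= 0, "up", "down"),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Two-sided rank-sum p-value: exact enumeration of all labelings for small
# samples (correct under ties), normal approximation with tie correction
# otherwise.
wilcox_p <- function(x, y, exact_max = 12) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  if (n <= exact_max) {
    combs <- utils::combn(n, nx)
    ws <- colSums(matrix(r[combs], nrow = nx))
    e <- nx * (n + 1) / 2
    return(mean(abs(ws - e) >= abs(w - e) - 1e-9))
  }
  e <- nx * (n + 1) / 2
  ties <- table(r)
  v <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (v == 0) return(1)
  z <- (abs(w - e) - 0.5) / sqrt(v)
  min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
}

#' Gini-coefficient cluster-marker scores
#'
#' For each gene, the Gini coefficient of its vector of per-cluster mean
#' normalized expression: near 0 for uniformly expressed genes, approaching
#' 1 - 1/n_clusters for genes confined to one cluster. The assigned cluster
#' is the argmax of the per-cluster means.
#'
#' @param es an [expr_set()] with a normalized layer.
#' @param labels cluster label per cell (>= 2 clusters).
#' @return data.frame: gene, gini, cluster, zero (all-zero flag).
#' @export
gini_markers <- function(es, labels) {
  if (is.null(es$norm)) stop("normalized layer missing")
  if (length(unique(labels)) < 2) stop("need at least 2 clusters")
  cl <- sort(unique(labels))
  means <- vapply(cl, function(k) colMeans(es$norm[labels == k, , drop = FALSE]),
                  numeric(ncol(es$norm)))
  g <- apply(means, 1, gini_coefficient)
  data.frame(gene = colnames(es$norm), gini = g,
             cluster = cl[apply(means, 1, which.max)],
             zero = rowSums(means) == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gini coefficient of a nonnegative vector
#'
#' @param x nonnegative numeric vector.
#' @return Gini coefficient in [0, 1 - 1/length(x)]; 0 for an all-zero
#'   vector.
#' @export
gini_coefficient <- function(x) {
  if (any(x < 0)) stop("Gini requires nonnegative values")
  if (sum(x) == 0) return(0)
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

#' Re-cluster a subset of clusters
#'
#' Re-runs HVG selection, PCA/kNN and Leiden clustering on the cells of the
#' selected parent clusters only; new labels are namespaced as
#' `<prefix>-1`, `<prefix>-2`, ... in descending size order.
#'
#' @param es an [expr_set()] with derived layers.
#' @param labels parent cluster labels per cell.
#' @param selected parent cluster ids to subcluster.
#' @param n_hvg,n_pcs,k,resolution,budget,seed pipeline parameters.
#' @param prefix label namespace prefix.
#' @return Character vector of subcluster labels for the subset cells, named
#'   by cell id.
#' @export
subcluster <- function(es, labels, selected, n_hvg = 200, n_pcs = 20, k = 15,
                       resolution = 0.1, budget = 1000, seed = 1,
                       prefix = NULL) {
  if (!all(selected %in% labels)) stop("selected cluster label not present")
  keep <- labels %in% selected
  if (sum(keep) < 2 * k) stop("subset too small for k neighbours")
  sub <- subset_cells(es, keep)
  sub <- normalize_scale(sub)
  hvg <- select_hvg(sub, min(n_hvg, ncol(sub$counts)))
  gr <- pca_knn(sub, hvg, n_pcs = min(n_pcs, min(dim(sub$scaled)) - 1), k = k)
  lab <- leiden_cluster(gr, resolution = resolution, budget = budget,
                        seed = seed)
  if (is.null(prefix)) prefix <- paste(selected, collapse = "")
  stats::setNames(paste0(prefix, "-", lab), sub$meta$cell_id)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; used
#' to compare recovered clusters with planted ground truth.
#'
#' @param a,b label vectors of equal length.
#' @return ARI in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must match")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n <- ch2(length(a))
  exp_idx <- si * sj / n
  max_idx <- (si + sj) / 2
  if (max_idx == exp_idx) return(1)
  (sij - exp_idx) / (max_idx - exp_idx)
}
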