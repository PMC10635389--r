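# Fixture builders shared across test files. All randomness is seeded by the
# caller; helpers are pure given the RNG state.

# Random simple (star-shaped) polygon around the origin.
random_polygon <- function(n_vertices = sample(4:12, 1), radius = 10) {
  ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
  r <- stats::runif(n_vertices, 0.3 * radius, radius)
  cbind(r * cos(ang), r * sin(ang))
}

# Independent brute-force feret oracle: double loop over vertex pairs.
feret_oracle <- function(poly) {
  best <- -1; bi <- bj <- 0
  n <- nrow(poly)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((poly[i, ] - poly[j, ])^2))
    if (d > best + 1e-15) { best <- d; bi <- i; bj <- j }
  }
  a <- atan2(poly[bj, 2] - poly[bi, 2], poly[bj, 1] - poly[bi, 1]) * 180 / pi
  list(length = best, angle = a %% 180)
}

# ECDF sup-difference oracle: explicit counting at every pooled point.
ks_d_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(vapply(pts, function(t) abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# O(n^2) kNN oracle returning the undirected deduplicated edge set as a
# sorted character vector "i-j".
knn_oracle_edges <- function(emb, k) {
  n <- nrow(emb)
  out <- character(0)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(emb) - emb[i, ])^2))
    d[i] <- Inf
    nb <- order(d)[seq_len(k)]
    out <- c(out, paste(pmin(i, nb), pmax(i, nb), sep = "-"))
  }
  sort(unique(out))
}

# Package kNN edges rendered in the oracle's "i-j" format.
knn_edges_for_test <- function(emb, k) {
  e <- senoglia:::knn_edges(emb, k)
  sort(unique(paste(e[, 1], e[, 2], sep = "-")))
}

# Tiny expr_set with named cells/genes from a dense matrix.
make_expr <- function(counts) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("c%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("g%03d", seq_len(ncol(counts)))
  meta <- data.frame(cell_id = rownames(counts),
                     x = seq_len(nrow(counts)), y = 0,
                     fov = "F1", region = "fimbria",
                     stringsAsFactors = FALSE)
  expr_set(counts, meta)
}

# Small two-type negative binomial mixture with gene panel from the
# simulator; returns a QCed+normalized expr_set and true types.
make_two_type_mix <- function(n_a = 150, n_b = 150, seed = 7,
                              type_a = "homeostatic", type_b = "oligodendrocyte") {
  cfg <- counts_config(seed = seed, n_genes = 120,
                       cells_per_region = stats::setNames(
                         list(stats::setNames(c(n_a, n_b), c(type_a, type_b))),
                         "fimbria"))
  sc <- list(regions = list(
    fimbria = matrix(c(0, 0, 500, 0, 500, 500, 0, 500), ncol = 2, byrow = TRUE)))
  sim <- simulate_counts(cfg, sc)
  es <- normalize_scale(qc_filter(sim$expr, 1))
  truth <- sim$truth[match(es$meta$cell_id, sim$truth$cell_id), ]
  list(es = es, truth = truth)
}

# Planted stochastic block model graph as a pca_knn-style edge list.
sbm_graph <- function(block_sizes, p_in, p_out) {
  n <- sum(block_sizes)
  lab <- rep(seq_along(block_sizes), block_sizes)
  from <- integer(0); to <- integer(0)
  for (i in 1:(n - 1)) {
    j <- (i + 1):n
    p <- ifelse(lab[j] == lab[i], p_in, p_out)
    hit <- j[stats::runif(length(j)) < p]
    from <- c(from, rep(i, length(hit))); to <- c(to, hit)
  }
  list(edges = cbind(from, to), n = n, labels = lab)
}
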