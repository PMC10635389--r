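#' Relative expression by the delta-delta-Ct method
#'
#' Normalizes each target gene to a housekeeper (Hprt by default) and
#' references the resulting delta-Ct to the mean delta-Ct of a reference
#' group: RE = 2^-ddCt. When a `sex` column is present the reference mean is
#' computed per sex, matching designs normalized within sex. Rows with a
#' missing Ct (target or housekeeper) are flagged and dropped with a log
#' entry in the `dropped` attribute.
#'
#' The geometric mean of RE over the reference group is exactly 1, and
#' adding a constant to every Ct leaves RE unchanged.
#'
#' @param ct long-format data.frame: sample, group, gene, Ct, optionally
#'   sex, tissue.
#' @param housekeeper housekeeper gene name.
#' @param reference reference group label.
#' @return data.frame with sample, group, (sex,) gene, d_ct, dd_ct,
#'   rel_expr; dropped rows recorded in `attr(, "dropped")`.
#' @export
ddct <- function(ct, housekeeper = "Hprt", reference = "YNG") {
  need <- c("sample", "group", "gene", "Ct")
  if (!all(need %in% names(ct))) stop("ct table needs columns: ",
                                      paste(need, collapse = ", "))
  has_sex <- "sex" %in% names(ct)
  hk <- ct[ct$gene == housekeeper, ]
  if (nrow(hk) == 0) stop("housekeeper not found: ", housekeeper)
  tg <- ct[ct$gene != housekeeper, ]
  tg$Ct_hk <- hk$Ct[match(tg$sample, hk$sample)]
  bad <- is.na(tg$Ct) | is.na(tg$Ct_hk)
  dropped <- tg[bad, c("sample", "gene")]
  tg <- tg[!bad, ]
  if (!any(tg$group == reference)) stop("reference group absent: ", reference)
  tg$d_ct <- tg$Ct - tg$Ct_hk
  strat <- if (has_sex) interaction(tg$gene, tg$sex, drop = TRUE) else tg$gene
  ref_mean <- tapply(tg$d_ct[tg$group == reference],
                     strat[tg$group == reference], mean)
  tg$dd_ct <- tg$d_ct - ref_mean[as.character(strat)]
  if (anyNA(tg$dd_ct)) stop("reference group missing for some gene/sex stratum")
  tg$rel_expr <- 2^(-tg$dd_ct)
  out <- tg[, c("sample", "group", if (has_sex) "sex",
                if ("tissue" %in% names(tg)) "tissue",
                "gene", "d_ct", "dd_ct", "rel_expr")]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Negative-probe limit of quantification and gene filter
#'
#' Per AOI, the LOQ is two geometric standard deviations above the geometric
#' mean of the negative-probe counts, computed in log2 space:
#' LOQ = 2^(mean(log2 neg) + 2 * sd(log2 neg)). A gene is kept when the
#' fraction of AOIs in which its count exceeds the LOQ is at least `f`
#' (default 0.15; the boundary is inclusive since genes below 15% are the
#' ones filtered out).
#'
#' @param counts genes x AOIs numeric matrix (rownames = genes).
#' @param neg_rows row names (or indices) of the negative-probe rows;
#'   at least 2 per AOI.
#' @param f minimum fraction of AOIs above LOQ.
#' @param k geometric-SD multiplier.
#' @param log_space compute GM/GSD in log2 space (default) or on the plain
#'   scale (mean + k*sd of raw counts) behind this flag.
#' @return list: `loq` (per-AOI), `kept` genes, `detect_frac` per gene,
#'   `counts` (kept gene submatrix, negative probes removed).
#' @export
loq_filter <- function(counts, neg_rows, f = 0.15, k = 2, log_space = TRUE) {
  counts <- as.matrix(counts)
  if (is.character(neg_rows)) neg_rows <- match(neg_rows, rownames(counts))
  if (anyNA(neg_rows) || length(neg_rows) < 2)
    stop("need at least 2 negative probes")
  neg <- counts[neg_rows, , drop = FALSE]
  if (any(neg <= 0)) neg <- neg + 0.5   # zero-count guard for the log scale
  loq <- if (log_space) {
    apply(neg, 2, function(v) 2^(mean(log2(v)) + k * stats::sd(log2(v))))
  } else {
    apply(neg, 2, function(v) mean(v) + k * stats::sd(v))
  }
  if (any(!is.finite(loq))) stop("single negative probe: SD undefined")
  gene_rows <- setdiff(seq_len(nrow(counts)), neg_rows)
  above <- sweep(counts[gene_rows, , drop = FALSE], 2, loq, ">")
  detect_frac <- rowMeans(above)
  kept <- rownames(counts)[gene_rows][detect_frac >= f]
  list(loq = loq, kept = kept, detect_frac = detect_frac,
       counts = counts[kept, , drop = FALSE])
}

#' Third-quartile normalization across AOIs
#'
#' Each AOI's counts are scaled so that its third quartile (over the kept
#' genes) equals the geometric mean of all AOIs' third quartiles; after
#' normalization every AOI has exactly the same Q3.
#'
#' @param counts genes x AOIs matrix of LOQ-filtered counts (>= 4 genes).
#' @return list: `normalized` matrix, `factors` per AOI, `target` common Q3.
#' @export
q3_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 4) stop("need >= 4 kept genes per AOI")
  q3 <- apply(counts, 2, stats::quantile, probs = 0.75, names = FALSE)
  if (any(q3 <= 0)) stop("zero third quartile in AOI(s): ",
                         paste(colnames(counts)[q3 <= 0], collapse = ", "))
  target <- exp(mean(log(q3)))
  normalized <- sweep(counts, 2, target / q3, "*")
  list(normalized = normalized, factors = target / q3, target = target)
}

#' Differential expression between AOI groups
#'
#' Delegates to the Wilcoxon rank-sum machinery used for the single-cell
#' data (the NB-GLM route of dedicated count-model packages is intentionally
#' out of scope; the claim here is the filter/normalization logic, and the
#' substitution is recorded in the result metadata).
#'
#' @param normalized genes x AOIs matrix from [q3_normalize()].
#' @param group_a,group_b disjoint AOI name vectors (each >= 3).
#' @return data.frame as [de_wilcoxon()]: gene, log2fc, p, padj, direction;
#'   `attr(, "method")` records the test used.
#' @export
aoi_de <- function(normalized, group_a, group_b) {
  normalized <- as.matrix(normalized)
  m <- t(normalized)   # AOIs in rows, genes in columns
  meta <- data.frame(cell_id = rownames(m), x = 0, y = 0, fov = "aoi",
                     region = "aoi", stringsAsFactors = FALSE)
  es <- expr_set(matrix(0L, nrow(m), ncol(m),
                        dimnames = dimnames(m)), meta)
  es$norm <- m
  es$counts <- round(m)   # totals only feed the fold-change epsilon
  out <- de_wilcoxon(es, group_a, group_b)
  attr(out, "method") <- "wilcoxon_rank_sum"
  out
}
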