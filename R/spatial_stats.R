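#' Reference-derived positivity threshold
#'
#' Threshold = mean + k * SD (sample SD) of a reference intensity
#' distribution, typically the young marker-negative population. At least 20
#' reference cells are required.
#'
#' @param reference numeric vector of reference intensities (>= 20 finite).
#' @param k SD multiplier (> 0; default 2).
#' @param channel,group optional labels recorded in the result.
#' @return list of class `threshold_spec`: threshold, mean, sd, k, n,
#'   channel, group.
#' @export
derive_threshold <- function(reference, k = 2, channel = NA, group = NA) {
  reference <- reference[is.finite(reference)]
  if (length(reference) < 20) stop("insufficient reference (< 20 values)")
  if (k <= 0) stop("k must be > 0")
  m <- mean(reference); s <- stats::sd(reference)
  structure(list(threshold = m + k * s, mean = m, sd = s, k = k,
                 n = length(reference), channel = channel, group = group),
            class = "threshold_spec")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum over the pooled sorted support of the absolute ECDF
#' difference. The p-value is exact (conditional on ties) when
#' |x| * |y| <= `exact_max`, otherwise from the asymptotic Kolmogorov
#' distribution.
#'
#' @param x,y numeric samples, each of length >= 2, no NaN/NA.
#' @param exact_max product-of-sizes bound for the exact p-value.
#' @return list of class `ks_result`: statistic D, p.value, n.x, n.y,
#'   method.
#' @export
ks_two_sample <- function(x, y, exact_max = 10000) {
  if (anyNA(x) || anyNA(y)) stop("NA/NaN in input samples")
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each sample needs >= 2 values")
  support <- sort(unique(c(x, y)))
  fx <- stats::ecdf(x)(support)
  fy <- stats::ecdf(y)(support)
  d <- max(abs(fx - fy))
  if (nx * ny <= exact_max) {
    p <- stats::psmirnov(d, sizes = c(nx, ny), z = c(x, y),
                         two.sided = TRUE, lower.tail = FALSE, exact = TRUE)
    method <- "exact"
  } else {
    lambda <- sqrt(nx * ny / (nx + ny)) * d
    j <- 1:100
    p <- min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))))
    method <- "asymptotic"
  }
  structure(list(statistic = d, p.value = p, n.x = nx, n.y = ny,
                 method = method), class = "ks_result")
}

#' PCA composite phenotyping index over per-mouse features
#'
#' Builds the composite index used to separate experimental groups from
#' per-mouse mean morphometric features: features are z-scored, the
#' covariance (= correlation) matrix is eigendecomposed, and per-mouse PC
#' scores are returned. The sign of each component is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param features numeric data.frame/matrix, one row per mouse, one column
#'   per feature; >= 3 rows, >= 2 columns, no missing values.
#' @return list of class `composite_index`: scores, loadings,
#'   var_explained, feature names, center/scale used.
#' @export
composite_pca_index <- function(features) {
  x <- as.matrix(features)
  if (nrow(x) < 3 || ncol(x) < 2) stop("need >= 3 mice and >= 2 features")
  if (anyNA(x)) stop("missing values in feature table")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant feature(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  z <- scale(x)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2, flip, "*")
  scores <- sweep(pc$x, 2, flip, "*")
  structure(list(scores = scores, loadings = rot,
                 var_explained = pc$sdev^2 / sum(pc$sdev^2),
                 features = colnames(x),
                 center = attr(z, "scaled:center"),
                 scale = attr(z, "scaled:scale")),
            class = "composite_index")
}

#' One-way ANOVA with comparisons against a reference group
#'
#' Overall one-way ANOVA F and p, plus per-group Welch t-tests versus the
#' reference group with Holm correction (a documented stand-in for
#' Dunnett's procedure). When all values are identical the F statistic is
#' reported as 0 with p = 1.
#'
#' @param values numeric vector.
#' @param groups group label per value (>= 2 groups, each n >= 2).
#' @param reference reference group label.
#' @return list of class `group_compare`: F, p, df, and a `comparisons`
#'   data.frame (group, estimate, p, p_adj).
#' @export
group_compare <- function(values, groups, reference) {
  groups <- as.character(groups)
  if (!reference %in% groups) stop("reference group absent")
  tab <- table(groups)
  if (length(tab) < 2) stop("need >= 2 groups")
  if (any(tab < 2)) stop("group with n < 2: ",
                         paste(names(tab)[tab < 2], collapse = ", "))
  if (stats::var(values) == 0) {
    others <- setdiff(names(tab), reference)
    return(structure(list(F = 0, p = 1, df = c(length(tab) - 1,
                                               length(values) - length(tab)),
                          comparisons = data.frame(group = others, estimate = 0,
                                                   p = 1, p_adj = 1)),
                     class = "group_compare"))
  }
  fit <- stats::aov(values ~ factor(groups))
  s <- summary(fit)[[1]]
  others <- setdiff(names(tab), reference)
  comp <- lapply(others, function(g) {
    tt <- stats::t.test(values[groups == g], values[groups == reference])
    data.frame(group = g, estimate = diff(rev(tt$estimate)), p = tt$p.value)
  })
  comp <- do.call(rbind, comp); rownames(comp) <- NULL
  comp$p_adj <- stats::p.adjust(comp$p, method = "holm")
  structure(list(F = s$`F value`[1], p = s$`Pr(>F)`[1],
                 df = s$Df, comparisons = comp),
            class = "group_compare")
}

#' ECDF and histogram report per group
#'
#' Per-group empirical CDF evaluated on the pooled sorted support, plus
#' fixed-width histogram bins over the pooled range (counts per group sum to
#' the group size).
#'
#' @param values numeric vector.
#' @param groups group label per value; every group must be non-empty.
#' @param bins number of fixed-width histogram bins.
#' @return list: `ecdf` (data.frame value, group, cumfrac) and `hist`
#'   (data.frame group, mid, count).
#' @export
ecdf_report <- function(values, groups, bins = 30) {
  groups <- as.character(groups)
  if (any(table(groups) == 0) || length(values) == 0) stop("empty group")
  grid <- sort(unique(values))
  ec <- do.call(rbind, lapply(unique(groups), function(g) {
    data.frame(value = grid, group = g,
               cumfrac = stats::ecdf(values[groups == g])(grid))
  }))
  brk <- seq(min(values), max(values), length.out = bins + 1)
  brk[1] <- brk[1] - 1e-9 * max(1, abs(brk[1]))
  hs <- do.call(rbind, lapply(unique(groups), function(g) {
    h <- graphics::hist(values[groups == g], breaks = brk, plot = FALSE)
    data.frame(group = g, mid = h$mids, count = h$counts)
  }))
  list(ecdf = ec, hist = hs)
}
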