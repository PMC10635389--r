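#' Scene configuration for the synthetic section simulator
#'
#' Encodes the stated world of the synthetic tissue sections: two regions
#' (hippocampus and a fimbria white-matter band) with a fimbria midline and
#' a ventricle edge, fiber tracts, and group-dependent cell density, size,
#' shape, tract alignment, GAL3+ fraction and APOE+ lateralization. Planted
#' effect directions follow the aged-white-matter phenotype: old fimbria has
#' denser, larger, more tract-aligned microglia, a much higher GAL3+
#' fraction, and APOE+ cells displaced toward the ventricle side of the
#' fimbria midline. Effect sizes are free parameters (the source figures are
#' summary plots without numeric effect sizes); defaults are chosen once as
#' biologically plausible values and documented in the methods vignette.
#'
#' Geometry is in micrometres, image convention (origin top-left, y down).
#'
#' @param seed integer RNG seed.
#' @param groups group labels; per-group parameter vectors are recycled by
#'   name with "OLD"-prefixed groups inheriting OLD defaults.
#' @param mice_per_group sections simulated per group (one per mouse).
#' @param density cells per mm^2, named by group.
#' @param area_meanlog,area_sdlog lognormal cell-area parameters (um^2),
#'   named by group.
#' @param spindle_fraction fraction of spindle-shaped (3:1) cells per group;
#'   remaining cells are ramified-like (1.2:1).
#' @param align_sd wrapped-normal SD (degrees) of the cell axis around the
#'   nearest tract axis, per group.
#' @param gal3_fraction fraction of GAL3+ cells per group.
#' @param apoe_fraction fraction of APOE+ cells per group.
#' @param apoe_offset_um lateral displacement of APOE+ cells toward the
#'   ventricle side of the fimbria midline, per group.
#' @param intensity_meanlog,intensity_sdlog lognormal mean-intensity
#'   parameters shared by channels; positive cells are shifted by
#'   `marker_shift_sd` standard deviations on the log scale.
#' @param marker_shift_sd log-scale separation (in sdlog units) of
#'   marker-positive cells; default 3 (a 3-sigma separation).
#' @param background_meanlog,background_sdlog lognormal local-background
#'   parameters (a.u./um^2), one draw per section and channel.
#' @param tracts_per_region,tract_angle_sd fiber-tract count and axial
#'   angle SD (deg, around the midline axis) per region.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(seed = 1L,
                         groups = c("YNG", "OLD"),
                         mice_per_group = 5L,
                         density = c(YNG = 250, OLD = 450),
                         area_meanlog = c(YNG = log(60), OLD = log(90)),
                         area_sdlog = c(YNG = 0.4, OLD = 0.4),
                         spindle_fraction = c(YNG = 0.1, OLD = 0.6),
                         align_sd = c(YNG = 40, OLD = 10),
                         gal3_fraction = c(YNG = 0.02, OLD = 0.35),
                         apoe_fraction = c(YNG = 0.15, OLD = 0.15),
                         apoe_offset_um = c(YNG = 0, OLD = 60),
                         intensity_meanlog = log(50),
                         intensity_sdlog = 0.3,
                         marker_shift_sd = 3,
                         background_meanlog = log(2),
                         background_sdlog = 0.2,
                         tracts_per_region = c(hippocampus = 6, fimbria = 12),
                         tract_angle_sd = c(hippocampus = 30, fimbria = 5)) {
  cfg <- list(seed = as.integer(seed), groups = groups,
              mice_per_group = as.integer(mice_per_group),
              density = density, area_meanlog = area_meanlog,
              area_sdlog = area_sdlog, spindle_fraction = spindle_fraction,
              align_sd = align_sd, gal3_fraction = gal3_fraction,
              apoe_fraction = apoe_fraction, apoe_offset_um = apoe_offset_um,
              intensity_meanlog = intensity_meanlog,
              intensity_sdlog = intensity_sdlog,
              marker_shift_sd = marker_shift_sd,
              background_meanlog = background_meanlog,
              background_sdlog = background_sdlog,
              tracts_per_region = tracts_per_region,
              tract_angle_sd = tract_angle_sd,
              scene = default_scene())
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

# Fixed section geometry: a fimbria band over the lateral ventricle with the
# hippocampus above it. Units are micrometres, y increases downward.
default_scene <- function() {
  list(
    regions = list(
      hippocampus = matrix(c(0, 0, 1000, 0, 1000, 350, 0, 350),
                           ncol = 2, byrow = TRUE),
      fimbria = matrix(c(0, 400, 1000, 400, 1000, 800, 0, 800),
                       ncol = 2, byrow = TRUE)
    ),
    midline = matrix(c(0, 600, 1000, 600), ncol = 2, byrow = TRUE),
    ventricle_edge = matrix(c(0, 830, 1000, 830), ncol = 2, byrow = TRUE),
    um_per_unit = 1
  )
}

validate_scene_config <- function(cfg) {
  grp_par <- function(p, g) {
    if (g %in% names(p)) return(p[[g]])
    if (startsWith(g, "OLD") && "OLD" %in% names(p)) return(p[["OLD"]])
    stop("no parameter value for group ", g)
  }
  for (g in cfg$groups) {
    if (grp_par(cfg$density, g) <= 0) stop("densities must be > 0")
    for (f in c("spindle_fraction", "gal3_fraction", "apoe_fraction")) {
      v <- grp_par(cfg[[f]], g)
      if (v < 0 || v > 1) stop(f, " must lie in [0, 1]")
    }
    if (grp_par(cfg$area_sdlog, g) <= 0) stop("area_sdlog must be > 0")
  }
  for (r in names(cfg$scene$regions))
    if (polygon_area(cfg$scene$regions[[r]]) <= 0) stop("degenerate region: ", r)
  invisible(cfg)
}

grp_par <- function(p, g) {
  if (g %in% names(p)) return(p[[g]])
  if (startsWith(g, "OLD") && "OLD" %in% names(p)) return(p[["OLD"]])
  stop("no parameter value for group ", g)
}

# Uniform points in a polygon by bounding-box rejection.
runif_in_polygon <- function(n, poly, max_tries = 1000L) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  bb <- apply(poly, 2, range)
  out <- matrix(NA_real_, n, 2)
  filled <- 0L
  for (try in seq_len(max_tries)) {
    m <- max(2L * (n - filled), 16L)
    x <- stats::runif(m, bb[1, 1], bb[2, 1])
    y <- stats::runif(m, bb[1, 2], bb[2, 2])
    keep <- point_in_polygon(x, y, poly)
    k <- min(sum(keep), n - filled)
    if (k > 0) {
      out[(filled + 1):(filled + k), ] <- cbind(x[keep][1:k], y[keep][1:k])
      filled <- filled + k
    }
    if (filled == n) return(out)
  }
  stop("cell placement failed after bounded retries")
}

# 16-vertex ellipse polygon with given area, aspect ratio and axial angle.
# The inscribed n-gon of an ellipse has area (n/(2*pi))*sin(2*pi/n) times the
# ellipse's; the axes are inflated so the polygon's shoelace area equals the
# requested area exactly (the recorded per-cell area must match the polygon).
ellipse_polygon <- function(cx, cy, area, aspect, angle_deg, n_vertices = 16L) {
  area <- area / (n_vertices / (2 * pi) * sin(2 * pi / n_vertices))
  b <- sqrt(area / (pi * aspect))
  a <- aspect * b
  t <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  th <- angle_deg * pi / 180
  x <- a * cos(t); y <- b * sin(t)
  cbind(cx + x * cos(th) - y * sin(th),
        cy + x * sin(th) + y * cos(th))
}

#' Simulate a set of tissue sections with planted group effects
#'
#' Places cells by a homogeneous Poisson process within each region of each
#' section, draws per-cell size/shape/orientation/marker status from the
#' group-dependent generative model in [scene_config()], and emits the
#' segmentation-level tables the morphometric pipeline consumes together
#' with a ground-truth table used only by tests.
#'
#' Determinism: one RNG stream seeded from `config$seed`, consumed in fixed
#' order (group, then mouse, then region, then cells), so identical configs
#' and seeds give byte-identical tables and appending a group does not
#' perturb earlier draws.
#'
#' @param config a [scene_config()].
#' @return list with `scene` (region/midline geometry), `cells`, `tracts`,
#'   `truth` data.frames.
#' @export
simulate_section <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  validate_scene_config(config)
  set.seed(config$seed)
  scene <- config$scene
  channels <- c("IBA1", "GAL3", "APOE")

  # tracts first: shared across groups, drawn per region
  tracts <- list()
  tid <- 0L
  for (rg in names(scene$regions)) {
    poly <- scene$regions[[rg]]
    k <- config$tracts_per_region[[rg]]
    centers <- runif_in_polygon(k, poly)
    ang <- stats::rnorm(k, 0, config$tract_angle_sd[[rg]]) %% 180
    len <- stats::runif(k, 150, 350)
    th <- ang * pi / 180
    tracts[[rg]] <- data.frame(
      tract_id = tid + seq_len(k), region = rg,
      x1 = centers[, 1] - len / 2 * cos(th), y1 = centers[, 2] - len / 2 * sin(th),
      x2 = centers[, 1] + len / 2 * cos(th), y2 = centers[, 2] + len / 2 * sin(th),
      angle = ang, stringsAsFactors = FALSE)
    tid <- tid + k
  }
  tracts <- do.call(rbind, tracts)
  rownames(tracts) <- NULL

  cells <- list(); truth <- list()
  cid <- 0L
  for (g in config$groups) {
    for (m in seq_len(config$mice_per_group)) {
      mouse <- sprintf("%s_m%02d", g, m)
      # per-section background per channel, shared within the section
      bg <- stats::rlnorm(length(channels), config$background_meanlog,
                          config$background_sdlog)
      names(bg) <- channels
      for (rg in names(scene$regions)) {
        poly <- scene$regions[[rg]]
        area_mm2 <- polygon_area(poly) / 1e6
        n <- stats::rpois(1, grp_par(config$density, g) * area_mm2)
        if (n == 0) next
        pos <- runif_in_polygon(n, poly)
        apoe <- stats::runif(n) < grp_par(config$apoe_fraction, g)
        # APOE+ cells are displaced toward the ventricle side of the midline
        off <- grp_par(config$apoe_offset_um, g)
        if (off != 0 && any(apoe)) {
          cand <- pos[apoe, , drop = FALSE]
          cand[, 2] <- cand[, 2] + off      # +y is the ventricle side
          ok <- point_in_polygon(cand[, 1], cand[, 2], poly)
          pos[apoe, ][ok, ] <- cand[ok, , drop = FALSE]
        }
        gal3 <- stats::runif(n) < grp_par(config$gal3_fraction, g)
        spindle <- stats::runif(n) < grp_par(config$spindle_fraction, g)
        area <- stats::rlnorm(n, grp_par(config$area_meanlog, g),
                              grp_par(config$area_sdlog, g))
        # axial orientation: wrapped normal around the nearest tract axis
        rtr <- tracts[tracts$region == rg, , drop = FALSE]
        near_ang <- vapply(seq_len(n), function(i) {
          d <- point_segment_distance(pos[i, 1], pos[i, 2],
                                      rtr$x1, rtr$y1, rtr$x2, rtr$y2)
          rtr$angle[which.min(d)]
        }, numeric(1))
        ori <- (near_ang + stats::rnorm(n, 0, grp_par(config$align_sd, g))) %% 180
        aspect <- ifelse(spindle, 3, 1.2)
        polys <- vapply(seq_len(n), function(i) {
          format_polygon(ellipse_polygon(pos[i, 1], pos[i, 2], area[i],
                                         aspect[i], ori[i]))
        }, character(1))
        # channel mean intensities; positive cells shifted on the log scale
        ml <- config$intensity_meanlog; sl <- config$intensity_sdlog
        shift <- config$marker_shift_sd * sl
        mi <- list(
          IBA1 = stats::rlnorm(n, ml, sl),
          GAL3 = stats::rlnorm(n, ml + ifelse(gal3, shift, 0), sl),
          APOE = stats::rlnorm(n, ml + ifelse(apoe, shift, 0), sl))
        df <- data.frame(cell_id = cid + seq_len(n), mouse = mouse, group = g,
                         region = rg, x = pos[, 1], y = pos[, 2],
                         area_um2 = area, polygon = polys,
                         stringsAsFactors = FALSE)
        for (ch in channels) {
          df[[paste0("intden_", ch)]] <- mi[[ch]] * area
          df[[paste0("bg_", ch)]] <- rep(bg[[ch]], n)
        }
        cells[[length(cells) + 1L]] <- df
        truth[[length(truth) + 1L]] <- data.frame(
          cell_id = cid + seq_len(n),
          subtype = ifelse(spindle, "spindle", "ramified"),
          gal3_pos = gal3, apoe_pos = apoe, stringsAsFactors = FALSE)
        cid <- cid + n
      }
    }
  }
  cells <- do.call(rbind, cells); rownames(cells) <- NULL
  truth <- do.call(rbind, truth); rownames(truth) <- NULL
  list(scene = scene, cells = cells, tracts = tracts, truth = truth)
}
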