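# Per-cell morphometric and intensity features.

test_that("feret_axis matches enumeration oracle on fixed and random polygons", {
  sq <- feret_axis(matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE))
  expect_equal(sq$length, sqrt(2))
  expect_equal(sq$angle, 45)  # tie between the diagonals broken to 45

  needle <- matrix(c(0, 0, 2, 0, 2, 0.01, 0, 0.01), ncol = 2, byrow = TRUE)
  fn <- feret_axis(needle)
  expect_equal(fn$length, sqrt(4 + 1e-4))
  expect_equal(fn$angle, atan2(0.01, 2) * 180 / pi, tolerance = 1e-10)

  set.seed(11)
  for (i in 1:50) {
    poly <- random_polygon()
    got <- feret_axis(poly)
    want <- feret_oracle(poly)
    expect_identical(got$length, want$length)
  }
})

test_that("feret_axis is rotation-equivariant and rejects degenerate input", {
  set.seed(4)
  poly <- random_polygon(8)
  base <- feret_axis(poly)
  th <- 30 * pi / 180
  rot <- poly %*% matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  r <- feret_axis(rot)
  expect_equal(r$length, base$length, tolerance = 1e-12)
  expect_equal(r$angle %% 180, (base$angle + 30) %% 180, tolerance = 1e-9)
  expect_error(feret_axis(matrix(c(0, 0, 1, 1), 2, byrow = TRUE)), "3 rows")
})

test_that("tract_angle_offset follows axial arithmetic and tie rules", {
  tr <- data.frame(tract_id = 1L, region = "fimbria",
                   x1 = 0, y1 = 0, x2 = 10, y2 = 0)
  mk <- function(angle) {
    th <- angle * pi / 180
    data.frame(tract_id = 1L, x1 = 0, y1 = 0,
               x2 = 10 * cos(th), y2 = 10 * sin(th))
  }
  expect_equal(tract_angle_offset(30, c(1, 1), mk(30))$offset, 0)
  expect_equal(tract_angle_offset(0, c(1, 1), mk(90))$offset, 90)
  expect_equal(tract_angle_offset(10, c(1, 1), mk(170))$offset, 20)

  # nearest tract by point-to-segment distance; equal distances -> lowest id
  two <- data.frame(tract_id = c(2L, 1L),
                    x1 = c(0, 0), y1 = c(2, -2), x2 = c(10, 10), y2 = c(2, -2))
  res <- tract_angle_offset(0, c(5, 0), two)
  expect_identical(res$tract_id, 1L)
  expect_equal(res$distance, 2)
  expect_error(tract_angle_offset(0, c(0, 0), two[0, ]), "no reference tract")
})

test_that("angle offset is invariant under 180-degree flips of either axis", {
  set.seed(21)
  for (i in 1:200) {
    a <- runif(1, 0, 180); b <- runif(1, 0, 180)
    tr <- function(ang) {
      th <- ang * pi / 180
      data.frame(tract_id = 1L, x1 = 0, y1 = 0,
                 x2 = cos(th), y2 = sin(th))
    }
    base <- tract_angle_offset(a, c(0, 0.1), tr(b))$offset
    expect_equal(tract_angle_offset((a + 180) %% 360 %% 180, c(0, 0.1),
                                    tr(b))$offset, base, tolerance = 1e-9)
    expect_equal(tract_angle_offset(a, c(0, 0.1), tr(b + 180))$offset, base,
                 tolerance = 1e-9)
    expect_lte(base, 90)
    expect_gte(base, 0)
  }
})

test_that("corrected_fluorescence implements ID - B*A, linearly, with flags", {
  expect_equal(as.numeric(corrected_fluorescence(1000, 2, 100)), 800)
  expect_equal(as.numeric(corrected_fluorescence(123.4, 0, 10)), 123.4)
  neg <- corrected_fluorescence(100, 2, 100)
  expect_equal(as.numeric(neg), -100)
  expect_true(attr(neg, "negative"))
  # linear in ID and in B
  set.seed(2)
  id <- runif(20, 0, 1000); b <- runif(20, 0, 5); a <- runif(20, 10, 200)
  expect_equal(as.numeric(corrected_fluorescence(2 * id, b, a)),
               2 * as.numeric(corrected_fluorescence(id, b, a)) + b * a)
  expect_error(corrected_fluorescence(10, 1, 0), "positive")
})

test_that("cell_density uses shoelace area and scales as 1/s^2", {
  half_mm <- sqrt(0.5e6)  # square of 0.5 mm^2 in um
  sq <- matrix(c(0, 0, half_mm, 0, half_mm, half_mm, 0, half_mm),
               ncol = 2, byrow = TRUE)
  expect_equal(cell_density(50, sq), 100)
  expect_equal(cell_density(0, sq), 0)
  set.seed(9)
  poly <- random_polygon(10, radius = 500)
  # Monte-Carlo area oracle within 1%
  bb <- apply(poly, 2, range)
  n <- 4e5
  px <- runif(n, bb[1, 1], bb[2, 1]); py <- runif(n, bb[1, 2], bb[2, 2])
  mc_area <- mean(point_in_polygon(px, py, poly)) * diff(bb[, 1]) * diff(bb[, 2])
  expect_equal(polygon_area(poly), mc_area, tolerance = 0.01)
  # uniform scaling by s divides density by s^2
  s <- 3
  expect_equal(cell_density(50, poly * s), cell_density(50, poly) / s^2)
  expect_error(cell_density(1, matrix(c(0, 0, 1, 1, 2, 2), ncol = 2,
                                      byrow = TRUE)), "zero area")
})

test_that("circularity matches closed forms", {
  t <- seq(0, 2 * pi, length.out = 65)[-65]
  circle64 <- cbind(cos(t), sin(t))
  expect_gte(circularity(circle64), 0.996)
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  expect_equal(circularity(sq), 4 * pi / 16)
  needle <- matrix(c(0, 0, 10, 0, 10, 0.05, 0, 0.05), ncol = 2, byrow = TRUE)
  expect_lt(circularity(needle), 0.1)
})

test_that("marker_calls uses a strict threshold and a derived threshold
           separates a planted lognormal mixture as the oracle predicts", {
  expect_identical(marker_calls(c(1, 2, 3), 2), c(FALSE, FALSE, TRUE))
  expect_identical(marker_calls(rep(0, 5), 0), rep(FALSE, 5))
  expect_error(marker_calls(1, NA), "finite")

  # planted 20% positive mixture, 3-sigma log-scale separation; threshold
  # from a marker-negative reference sample (mean + 2 SD)
  set.seed(31)
  s <- 0.3; shift <- 3 * s
  ref <- rlnorm(1000, 0, s)
  pos <- rlnorm(1000, shift, s)
  thr <- derive_threshold(ref, k = 2)
  recall <- mean(marker_calls(pos, thr$threshold))
  fpr <- mean(marker_calls(ref, thr$threshold))
  # closed-form oracle with the population threshold
  pop_thr <- exp(s^2 / 2) * (1 + 2 * sqrt(exp(s^2) - 1))
  oracle_recall <- pnorm((shift - log(pop_thr)) / s)
  expect_equal(recall, oracle_recall, tolerance = 0.04)
  expect_gte(recall, 0.85)   # analytic recall at exactly 3 sigma is 0.895
  expect_lte(fpr, 0.05)
})

test_that("colocalization_fraction matches counting and the binomial oracle", {
  a <- rep(c(TRUE, FALSE), c(10, 10))
  b <- rep(c(TRUE, FALSE, TRUE), c(4, 10, 6))[1:20]
  expect_equal(colocalization_fraction(a, b), 40)
  expect_equal(colocalization_fraction(a, a), 100)
  set.seed(5)
  ca <- runif(10000) < 0.5; cb <- runif(10000) < 0.5
  expect_equal(colocalization_fraction(ca, cb), 50, tolerance = 0.03)
  expect_error(colocalization_fraction(rep(FALSE, 3), rep(TRUE, 3)),
               "no positive")
})

test_that("compute_morphometrics emits a full record per cell", {
  set.seed(13)
  sc <- simulate_section(scene_config(seed = 13, mice_per_group = 1))
  m <- compute_morphometrics(sc$cells, sc$tracts)
  expect_equal(nrow(m), nrow(sc$cells))
  expect_true(all(m$angle_offset >= 0 & m$angle_offset <= 90))
  expect_true(all(m$circularity <= 1 + 1e-9))
  expect_true(all(m$feret_length > 0))
  # feret length bounds every polygon edge length
  i <- which.max(m$area)
  poly <- parse_polygon(sc$cells$polygon[i])
  edges <- sqrt(rowSums((rbind(poly[-1, ], poly[1, ]) - poly)^2))
  expect_gte(m$feret_length[i], max(edges))
  # normalized channels live in [0, 1]
  for (ch in c("IBA1", "GAL3", "APOE")) {
    v <- m[[paste0("norm_", ch)]]
    expect_true(all(v >= 0 & v <= 1))
  }
})
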