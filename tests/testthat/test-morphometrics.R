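test_that("semilandmarks sit at equal arc lengths starting at the anchor", {
  # unit circle at 360 points: semilandmarks every 36 degrees
  ang <- seq(0, 2 * pi, length.out = 361)[-361]
  circ <- pore_curve(cbind(cos(ang), sin(ang)))
  slm <- resample_semilandmarks(circ)
  expect_equal(nrow(slm$points), 10)
  expect_equal(slm$points[10, ], slm$points[1, ])
  got_ang <- atan2(slm$points[1:9, 2], slm$points[1:9, 1]) %% (2 * pi)
  expect_equal(got_ang, (0:8) * 2 * pi / 9, tolerance = 1e-4)

  # square with the anchor at a corner: 9 gaps of perimeter / 9
  s1 <- seq(0, 0.9, by = 0.1)
  s2 <- rev(seq(0.1, 1, by = 0.1))
  sq <- pore_curve(rbind(cbind(s1, 0), cbind(1, s1),
                         cbind(s2, 1), cbind(0, s2)))
  slm_sq <- resample_semilandmarks(sq)
  gaps <- sqrt(rowSums((slm_sq$points[-1, ] - slm_sq$points[-10, ])^2))
  # on a straight edge chord length equals arc length
  expect_equal(gaps[1], 4 / 9, tolerance = 1e-12)
})

test_that("arc-length gaps are equal within 1e-6 relative on any curve", {
  for (s in 1:20) {
    pc <- generate_pore_curve(runif(1, 0.3, 3), n_points = 150,
                              irregularity = 0.08, seed = s)
    slm <- resample_semilandmarks(pc)
    # recompute arc length along the original polyline between landmarks
    pts <- rbind(pc$points, pc$points[1, ])
    seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
    s_cum <- c(0, cumsum(seg))
    pos_of <- function(q) { # arc position via projection onto each segment
      ax <- pts[-nrow(pts), 1]; ay <- pts[-nrow(pts), 2]
      bx <- pts[-1, 1]; by <- pts[-1, 2]
      tt <- pmin(pmax(((q[1] - ax) * (bx - ax) + (q[2] - ay) * (by - ay)) /
                        pmax(seg^2, 1e-300), 0), 1)
      px <- ax + tt * (bx - ax); py <- ay + tt * (by - ay)
      j <- which.min((q[1] - px)^2 + (q[2] - py)^2)
      s_cum[j] + tt[j] * seg[j]
    }
    arcs <- apply(slm$points, 1, pos_of)
    gaps <- diff(arcs[1:9])
    expect_lt(max(abs(gaps - mean(gaps))) / mean(gaps), 1e-6)
  }
})

test_that("the pore polygon drops the closing duplicate and uses 9 vertices", {
  pc <- generate_pore_curve(1.5, seed = 4)
  slm <- resample_semilandmarks(pc)
  expect_equal(nrow(slm$points), 10)
  expect_equal(slm$points[10, ], slm$points[1, ])
  expect_equal(nrow(unique(slm$points)), 9)
})

test_that("pore area matches the closed-form inscribed 9-gon on a circle", {
  ang <- 2 * pi * (0:8) / 9
  ninegon <- rbind(cbind(cos(ang), sin(ang)), c(1, 0))
  expect_equal(pore_area(ninegon), 4.5 * sin(2 * pi / 9), tolerance = 1e-12)
  # resampling a digitized circle gives the same inscribed area
  circ <- generate_pore_curve(pi, n_points = 720, irregularity = 0, seed = 1)
  expect_equal(pore_area(resample_semilandmarks(circ)),
               4.5 * sin(2 * pi / 9), tolerance = 1e-4)
})

test_that("polygon areas underestimate the outline they are inscribed in", {
  side <- seq(0, 1, length.out = 26)[-26]
  sq <- pore_curve(rbind(cbind(side, 0), cbind(1, side),
                         cbind(rev(side), 1), cbind(0, rev(side))))
  expect_lt(pore_area(resample_semilandmarks(sq)), 1)
  # near-circular pores: ratio ~ (9 / 2 pi) sin(2 pi / 9)
  ratio <- 9 * sin(2 * pi / 9) / (2 * pi)
  for (s in 1:5) {
    a <- runif(1, 0.5, 3)
    pc <- generate_pore_curve(a, n_points = 720, irregularity = 0, seed = s)
    expect_equal(pore_area(resample_semilandmarks(pc)) / a, ratio,
                 tolerance = 1e-3)
  }
})

test_that("degenerate and self-intersecting polygons are handled", {
  line <- cbind(seq(0, 1, length.out = 10), 0)
  expect_equal(pore_area(line), 0)
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1),
                  c(0, 0.5), c(0.2, 0.5), c(0.4, 0.5), c(0.6, 0.5),
                  c(0.8, 0.5), c(0, 0))
  expect_warning(a <- pore_area(bowtie), "self-intersects")
  expect_gte(a, 0)
})

test_that("pore area is invariant to rigid motion and scales quadratically", {
  pc <- generate_pore_curve(2, seed = 11)
  slm <- resample_semilandmarks(pc)$points
  a0 <- pore_area(slm)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- slm %*% rot + matrix(c(12, -3), nrow(slm), 2, byrow = TRUE)
  expect_equal(pore_area(moved), a0, tolerance = 1e-12)
  expect_equal(pore_area(2 * slm), 4 * a0, tolerance = 1e-12)
})

test_that("canal means pool the right pore inventories and flag gaps", {
  otic <- tibble::tibble(specimen = "s1", canal = "otic", pore = 1:2,
                         area = c(0.5, 1.5))
  expect_equal(mean_canal_areas(otic)$mean_area, 1)
  preop <- tibble::tibble(specimen = "s1", canal = "preopercular",
                          pore = 1:7, area = c(1, 1, 1, 1, 4, 4, 4))
  got <- mean_canal_areas(preop)
  expect_equal(got$mean_area, 16 / 7)
  expect_true(got$complete)
  dentary <- tibble::tibble(specimen = "s1", canal = "dentary",
                            pore = c(2, 4, 5), area = c(1, 2, 3))
  got2 <- mean_canal_areas(dentary) # pore 3 missing
  expect_equal(got2$mean_area, 2)
  expect_false(got2$complete)
})

test_that("Procrustes alignment is invariant to similarity transforms", {
  set.seed(5)
  base <- matrix(rnorm(20), 10, 2)
  th <- 1.1
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  copy <- 3.2 * base %*% rot + matrix(c(5, -2), 10, 2, byrow = TRUE)
  expect_lt(procrustes_distance(base, copy), 1e-8)
  fit <- gpa_pca(list(base, copy))
  expect_lt(max(abs(fit$aligned[[1]] - fit$aligned[[2]])), 1e-8)
  expect_lt(max(fit$sdev), 1e-8)
  # two identical shapes: zero distance, zero shape variance
  fit2 <- gpa_pca(list(base, base))
  expect_equal(procrustes_distance(base, base), 0)
  expect_lt(max(fit2$sdev), 1e-12)
})

test_that("PC1 variance fraction matches a direct eigendecomposition", {
  set.seed(6)
  base <- generate_pore_curve(1, n_points = 12, seed = 1)$points
  shapes <- lapply(1:20, function(i) base + matrix(rnorm(24, 0, 0.03), 12, 2))
  fit <- gpa_pca(shapes)
  flat <- t(vapply(fit$aligned, as.vector, numeric(24)))
  ev <- eigen(stats::cov(flat), symmetric = TRUE)$values
  expect_equal(fit$variance_explained[1], ev[1] / sum(ev), tolerance = 1e-8)
  expect_equal(sum(fit$variance_explained), 1, tolerance = 1e-8)
})

test_that("alignment does not depend on the order of configurations", {
  set.seed(7)
  shapes <- lapply(1:6, function(i) matrix(rnorm(16, sd = 1), 8, 2))
  f1 <- gpa_pca(shapes)
  f2 <- gpa_pca(rev(shapes))
  expect_equal(f1$variance_explained, f2$variance_explained,
               tolerance = 1e-6)
  expect_lt(max(abs(f1$aligned[[1]] - f2$aligned[[6]])), 1e-6)
})

test_that("pairwise alignment agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(8)
  a <- matrix(rnorm(20), 10, 2)
  b <- a + matrix(rnorm(20, 0, 0.1), 10, 2)
  ours <- procrustes_distance(a, b)
  norm_shape <- function(m) {
    m <- sweep(m, 2, colMeans(m)); m / sqrt(sum(m^2))
  }
  veg <- vegan::procrustes(norm_shape(a), norm_shape(b), scale = FALSE)
  expect_equal(ours, sqrt(sum((veg$X - veg$Yrot)^2)), tolerance = 1e-6)
})

test_that("digitization ANOVA reproduces the two-way F decomposition", {
  set.seed(9)
  n <- 20
  # no event effect at all: F_event exactly 0
  a0 <- rep(rnorm(n, 1, 0.3), 2)
  tab0 <- tibble::tibble(individual = rep(1:n, 2),
                         event = rep(c("original", "repeat"), each = n),
                         area = a0)
  res0 <- digitization_anova(tab0)
  expect_equal(res0$statistic[res0$term == "event"], 0, tolerance = 1e-12)
  expect_equal(res0$df, c(1, n - 1))
  expect_equal(unique(res0$df_residual), n - 1)

  # hand-computed sums of squares on a perturbed table
  tab <- tab0
  tab$area <- tab$area + rnorm(2 * n, 0, 0.05) +
    rep(c(0, 0.04), each = n)
  gm <- mean(tab$area)
  ev_means <- tapply(tab$area, tab$event, mean)
  id_means <- tapply(tab$area, tab$individual, mean)
  ss_event <- n * sum((ev_means - gm)^2)
  ss_id <- 2 * sum((id_means - gm)^2)
  ss_tot <- sum((tab$area - gm)^2)
  ss_res <- ss_tot - ss_event - ss_id
  res <- digitization_anova(tab)
  expect_equal(res$statistic[res$term == "event"],
               (ss_event / 1) / (ss_res / (n - 1)), tolerance = 1e-10)
  expect_equal(res$statistic[res$term == "individual"],
               (ss_id / (n - 1)) / (ss_res / (n - 1)), tolerance = 1e-10)
  expect_true(all(res$p.value >= 0 & res$p.value <= 1))

  # incomplete designs are rejected
  expect_error(digitization_anova(tab[-1, ]), "incomplete")
})
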