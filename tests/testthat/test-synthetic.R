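test_that("the full design has 232 trial rows, two per fish, counterbalanced", {
  d <- generate_design(seed = 1)
  expect_equal(nrow(d), 232)
  expect_equal(length(unique(d$fish_id)), 116)
  per_fish <- dplyr::count(d, .data$fish_id)
  expect_true(all(per_fish$n == 2))
  both <- dplyr::summarise(dplyr::group_by(d, .data$fish_id),
                           ok = setequal(treatment, c("laminar", "turbulent")))
  expect_true(all(both$ok))
  expect_true(all(d$body_length > 0))
})

test_that("treatment order is counterbalanced within half a fish of parity", {
  for (s in 1:5) {
    d <- generate_design(seed = s)
    firsts <- dplyr::filter(d, .data$order == "first")
    n_lam <- sum(firsts$treatment == "laminar")
    expect_lte(abs(n_lam - nrow(firsts) / 2), 1.5)
  }
})

test_that("a single-fish design gives both treatments for that fish", {
  d <- generate_design(1, 0, 0, seed = 3)
  expect_equal(nrow(d), 2)
  expect_equal(length(unique(d$fish_id)), 1)
  expect_setequal(d$treatment, c("laminar", "turbulent"))
})

test_that("design generation is deterministic under a fixed seed", {
  expect_identical(generate_design(seed = 42), generate_design(seed = 42))
})

test_that("morphology collapses to the species centroid when noise vanishes", {
  d <- generate_design(4, 4, 0, seed = 1)
  pars <- morphology_params(sdlog_area = 0, allometry_area = 0,
                            allometry_count = 0)
  m <- generate_morphology(d, pars, seed = 2)
  pa <- dplyr::filter(m, .data$species == "parentA")
  expect_true(all(pa$otic_area == 2.0))
  expect_true(all(pa$dentary_area == 1.2))
  pb <- dplyr::filter(m, .data$species == "parentB")
  expect_true(all(pb$otic_area == 0.5))
})

test_that("hybrid mean pore areas fall between the parental means", {
  d <- generate_design(2000, 2000, 10000, seed = 5)
  m <- generate_morphology(d, seed = 6)
  means <- dplyr::summarise(
    dplyr::group_by(m, .data$species),
    otic = mean(.data$otic_area),
    preop = mean(.data$preopercular_area)
  )
  get <- function(sp, v) means[[v]][means$species == sp]
  for (v in c("otic", "preop")) {
    lo <- min(get("parentA", v), get("parentB", v))
    hi <- max(get("parentA", v), get("parentB", v))
    expect_gt(get("hybrid", v), lo)
    expect_lt(get("hybrid", v), hi)
  }
  # hybrids span the parents: wider spread than either parent
  spreads <- dplyr::summarise(dplyr::group_by(m, .data$species),
                              s = sd(log(.data$otic_area)))
  expect_gt(spreads$s[spreads$species == "hybrid"],
            max(spreads$s[spreads$species != "hybrid"]))
})

test_that("morphology is deterministic and validates its parameters", {
  d <- generate_design(3, 3, 3, seed = 1)
  expect_identical(generate_morphology(d, seed = 9),
                   generate_morphology(d, seed = 9))
  expect_error(morphology_params(sdlog_area = -1), "non-negative")
  expect_error(morphology_params(count_dispersion = 0), ">")
})

test_that("pore curves have prescribed area and a most-anterior anchor", {
  # irregularity 0, area pi: vertices on the unit circle
  pc <- generate_pore_curve(pi, n_points = 360, irregularity = 0, seed = 1)
  expect_equal(max(abs(sqrt(rowSums(pc$points^2)) - 1)), 0, tolerance = 1e-12)
  # dense shoelace oracle within 0.5% for irregular curves
  for (s in 1:5) {
    area <- runif(1, 0.5, 4)
    pc <- generate_pore_curve(area, n_points = 2000, irregularity = 0.08,
                              seed = s)
    expect_lt(abs(shoelace(pc$points) - area) / area, 0.005)
    # anchor is the most anterior (minimum x) vertex
    expect_equal(which.min(pc$points[, 1]), 1)
  }
  expect_identical(generate_pore_curve(2, seed = 7),
                   generate_pore_curve(2, seed = 7))
  expect_error(generate_pore_curve(2, irregularity = 50, seed = 1),
               "radius collapses")
})

test_that("behaviour responses follow the configured generative model", {
  d <- generate_design(50, 50, 400, seed = 2)
  m <- generate_morphology(d, seed = 3)
  # null model: slopes 0, sigma_b 0, huge theta -> Poisson around exp(b0)
  eff <- effect_spec(intercept = log(150), slopes = numeric(),
                     species_offsets = c(parentB = 0, hybrid = 0),
                     body_length_slope = 0, treatment_offset = 0,
                     order_offset = 0, sigma_b = 0, theta = 1e8)
  sim <- generate_behaviour_summaries(d, m, eff, seed = 4)
  expect_equal(mean(sim$trials$mean_nn), 150, tolerance = 0.02)
  expect_equal(var(sim$trials$mean_nn), 150, tolerance = 0.1)

  # negative pore-size slope -> negative rank correlation at study size
  d2 <- generate_design(seed = 5)
  m2 <- generate_morphology(d2, seed = 6)
  eff2 <- effect_spec(slopes = c(otic_area = -0.4), sigma_b = 0.1)
  sim2 <- generate_behaviour_summaries(d2, m2, eff2, seed = 7)
  expect_lt(cor(sim2$trials$otic_area, sim2$trials$mean_nn,
                method = "spearman"), 0)
  expect_identical(
    generate_behaviour_summaries(d2, m2, eff2, seed = 8)$trials,
    generate_behaviour_summaries(d2, m2, eff2, seed = 8)$trials
  )
})

test_that("behaviour generator reports overflow with the offending row", {
  d <- generate_design(1, 1, 0, seed = 1)
  m <- generate_morphology(d, seed = 2)
  eff <- effect_spec(intercept = 800)
  expect_error(generate_behaviour_summaries(d, m, eff, seed = 3),
               "overflow at trial row")
})

test_that("a noise-free shoal on the preferred polygon holds its spacing", {
  par <- swimmer_params(spacing = 100, noise_sd = 0)
  fs <- generate_trajectories(200, par, seed = 1)
  fm <- frame_metrics(fs)
  expect_equal(max(fm$nn) - min(fm$nn), 0, tolerance = 1e-9)
  expect_equal(fm$radius[1], 100, tolerance = 1e-9)
})

test_that("mean nearest-neighbour distance rises with preferred spacing", {
  nn <- vapply(c(50, 100, 150), function(sp) {
    fs <- generate_trajectories(5000, swimmer_params(spacing = sp),
                                seed = 99)
    summarize_trial(fs)$mean_nn
  }, numeric(1))
  expect_true(all(diff(nn) > 0))
})

test_that("trajectories stay in the arena and are seed-reproducible", {
  fs <- generate_trajectories(500, swimmer_params(noise_sd = 40), seed = 3)
  expect_true(all(fs$positions$x >= 0 & fs$positions$x <= fs$arena[1]))
  expect_true(all(fs$positions$y >= 0 & fs$positions$y <= fs$arena[2]))
  fs2 <- generate_trajectories(500, swimmer_params(noise_sd = 40), seed = 3)
  expect_identical(fs$positions, fs2$positions)
})
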