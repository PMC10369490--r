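# Synthetic-data generators: ground-truth recovery hooks, determinism,
# and the statistical contracts of each channel.

test_that("bilayer generator places leaflets at +/- half-thickness", {
  b <- generate_bilayer(64, 19, seed = 3)
  expect_lt(abs(mean(b$upper[, 3]) - 19), 0.3)
  expect_lt(abs(mean(b$lower[, 3]) + 19), 0.3)
  expect_true(all(abs(b$upper[, 3] - 19) < 2.5))
  expect_error(generate_bilayer(64, -1), "half_thickness")
  expect_error(generate_bilayer(4, 19), "n_lipids_per_leaflet")
})

test_that("a Gaussian dimple shifts leaflet heights by the field value", {
  field <- gaussian_deformation(-3, 8, center = c(128, 128))
  b <- generate_bilayer(1024, 19, field, seed = 5, jitter_sd = 0.1)
  # every upper-leaflet point sits at 19 + f(x, y) up to lattice jitter
  expected <- 19 + field(b$upper[, 1], b$upper[, 2])
  expect_lt(max(abs(b$upper[, 3] - expected)), 0.5)
  # near the center the dimple floor approaches 19 - 3 = 16
  r <- sqrt((b$upper[, 1] - 128)^2 + (b$upper[, 2] - 128)^2)
  near <- r < 7
  expect_true(any(near))
  expect_lt(min(b$upper[near, 3]), 16.8)
  expect_gt(min(b$upper[near, 3]), 15.4)
  # the lower leaflet mirrors it: thinning on both sides
  low_expected <- -19 - field(b$lower[, 1], b$lower[, 2])
  expect_lt(max(abs(b$lower[, 3] - low_expected)), 0.5)
})

test_that("generators are pure functions of (parameters, seed)", {
  b1 <- generate_bilayer(64, 19, seed = 11)
  b2 <- generate_bilayer(64, 19, seed = 11)
  expect_identical(b1, b2)
  tr <- ground_truth_profile(c(-7, 1), c(6.5, 6.0))
  cfg <- synthetic_config(n_replicates = 2, n_frames = 300, seed = 9)
  expect_identical(generate_phre_frames(tr, cfg),
                   generate_phre_frames(tr, cfg))
  k1 <- generate_kinetic_trace(1, 0.1, noise_sd = 0.01,
                               t_grid = seq(0.01, 1, 0.01), seed = 2)
  expect_identical(k1, generate_kinetic_trace(1, 0.1, noise_sd = 0.01,
                                              t_grid = seq(0.01, 1, 0.01),
                                              seed = 2))
})

test_that("protonation sampling follows the Hill model at each ladder pH", {
  flat <- ground_truth_profile(c(-7, 1), c(6, 6))
  cfg <- synthetic_config(n_replicates = 1, ph_ladder = c(5, 7),
                          n_frames = 10000, seed = 21)
  fr <- generate_phre_frames(flat, cfg)
  for (ph in c(5, 7)) {
    f_obs <- mean(fr$prot_asp[fr$pH == ph])
    f_true <- hill_protonation(ph, 6, 1)            # 0.909 / 0.091
    n <- sum(fr$pH == ph)
    expect_lt(abs(f_obs - f_true), 4 * sqrt(f_true * (1 - f_true) / n))
  }
  # midpoint: long-run protonated fraction 0.5
  cfg2 <- synthetic_config(n_replicates = 1, ph_ladder = 6.0,
                           n_frames = 10000, seed = 22)
  fr2 <- generate_phre_frames(flat, cfg2)
  expect_lt(abs(mean(fr2$prot_asp) - 0.5), 4 * 0.5 / sqrt(nrow(fr2)))
})

test_that("frame generation handles edge cases per contract", {
  flat <- ground_truth_profile(c(-7, 1), c(6, 6))
  cfg0 <- synthetic_config(n_replicates = 1, n_frames = 0, seed = 1)
  expect_identical(nrow(generate_phre_frames(flat, cfg0)), 0L)
  expect_error(synthetic_config(ph_ladder = c(7, 5)), "ascending")
  expect_error(synthetic_config(n_replicates = 0), "n_replicates")
  expect_error(synthetic_config(noise = list(a = -1)), "noise")
  cfg <- synthetic_config(n_frames = 10, seed = 1)
  narrow <- ground_truth_profile(c(-2, 0), c(6, 6))
  expect_error(generate_phre_frames(narrow, cfg), "cover")
  cfg$ph_ladder <- numeric(0)
  expect_error(generate_phre_frames(flat, cfg), "ladder")
})

test_that("exchange mixing lets each replica visit the whole ladder", {
  tr <- ground_truth_profile(c(-7, 1), 6 + pmin(pmax(-c(-7, 1) / 6, 0), 1))
  cfg <- synthetic_config(n_replicates = 1, n_frames = 2000, seed = 13)
  fr <- generate_phre_frames(tr, cfg)
  visits <- table(fr$replica, fr$pH)
  expect_true(all(visits > 0))
  # marginal protonation at a given pH is still the Hill value
  sub <- fr[fr$insertion_A > -0.75 & fr$pH == 5, ]
  expect_lt(abs(mean(sub$prot_asp) - hill_protonation(5, 6.06, 1)), 0.05)
})

test_that("contact counts track their mean functions", {
  z <- rep(c(-4, -2, 0), each = 100)
  cst <- generate_contact_profiles(z, list(a = function(x) rep(3, length(x))),
                                   dispersion = 0)
  expect_true(all(cst$a == 3L))
  pois <- generate_contact_profiles(rep(0, 10000),
                                    list(a = function(x) rep(5, length(x))),
                                    dispersion = 1, seed = 4)
  expect_lt(abs(mean(pois$a) - 5), 4 * sqrt(5 / 10000))
  expect_true(all(pois$a >= 0))
  expect_error(generate_contact_profiles(z, list(a = function(x) rep(1, 3)),
                                         dispersion = -1), "dispersion")
  expect_error(generate_contact_profiles(
    z, list(a = function(x) ifelse(x < -3, NA, 1))), "undefined")
})

test_that("titration generator hits the Hill midpoint and refits exactly", {
  t1 <- generate_titration_experiment(6.2, 1.8, baseline = 0.3, span = 0.4,
                                      ph_grid = 6.2)
  expect_equal(t1$response, 0.3 + 0.4 / 2)
  # generate-then-refit oracle on a published-scale (pK, n) pair
  tt <- generate_titration_experiment(6.2, 1.8, ph_grid = seq(4, 8, 0.25))
  est <- fit_hill_transition(data.frame(pH = tt$pH, response = tt$response))
  expect_lt(abs(est$pK - 6.2), 1e-6)
  expect_lt(abs(est$n - 1.8), 1e-5)
  # large n approaches a step at pK
  st <- generate_titration_experiment(6, 80, ph_grid = c(5.9, 6.1))
  expect_gt(st$response[1], 0.99)
  expect_lt(st$response[2], 0.01)
  expect_error(generate_titration_experiment(6, 1, ph_grid = numeric(0)),
               "ph_grid")
  expect_error(generate_titration_experiment(6, 1, span = 0), "span")
})

test_that("kinetic traces decay from offset + sum(a) to the offset", {
  k <- generate_kinetic_trace(1, 0.1, offset = 0.25, t_grid = c(0, 5))
  expect_equal(k$intensity[1], 1.25)
  expect_lt(abs(k$intensity[2] - 0.25), 1e-10)
  expect_error(generate_kinetic_trace(1, -0.1, t_grid = 1), "taus")
  expect_error(generate_kinetic_trace(c(1, 1), 0.1, t_grid = 1), "length")
})
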