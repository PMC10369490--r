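# Insertion-binned pKa profiles: slicing, the three QC criteria, Hill
# fitting, Bayesian-bootstrap errors, and the deep-region summary.

test_that("slicing uses half-open 0.5 A bins anchored at multiples of 0.5", {
  fr <- data.frame(insertion_A = c(-2.3, -2.0, -1.99, 0.0, 0.49),
                   pH = 6, replicate = 1, replica = 1, time_ps = 1:5,
                   prot_asp = 0L)
  bins <- slice_by_insertion(fr)
  expect_named(bins, c("[-2.5,-2)", "[-2,-1.5)", "[0,0.5)"))
  expect_equal(attr(bins[["[-2.5,-2)"]], "bin_low"), -2.5)
  expect_equal(nrow(bins[["[-2,-1.5)"]]), 2L)   # -2.0 and -1.99
  expect_equal(nrow(bins[["[0,0.5)"]]), 2L)
  # partition: sizes sum to the input size on random data
  set.seed(3)
  fr2 <- data.frame(insertion_A = runif(500, -7, 1), pH = 6, replicate = 1,
                    replica = 1, time_ps = 1:500, prot_asp = 0L)
  expect_equal(sum(vapply(slice_by_insertion(fr2), nrow, integer(1))), 500L)
})

test_that("criterion 1 demands 10 points of each state per replicate and pH", {
  ladder <- c(5.0, 5.75, 6.5)
  good <- make_balanced_bin(ladder, n_replicates = 3, n_replicas = 2,
                            n = 30, frac = function(p) 0.5)
  led <- check_criteria(good, ladder)
  expect_true(led$criterion1 && led$criterion2 && led$criterion3 && led$pass)
  # 9 protonated points at one pH in one replicate: criterion 1 fails
  spec <- expand.grid(pH = ladder, replicate = 1:3, replica = 1:2)
  spec$n <- 30; spec$n_prot <- 15
  spec$n_prot[spec$pH == 5.0 & spec$replicate == 2 & spec$replica == 1] <- 4
  spec$n_prot[spec$pH == 5.0 & spec$replicate == 2 & spec$replica == 2] <- 5
  bad <- make_bin_frames(spec)
  led2 <- check_criteria(bad, ladder)
  expect_false(led2$criterion1)
  expect_match(paste(led2$violations, collapse = " "), "criterion1")
})

test_that("criterion 2 demands 3 replicates spanning 2 replicas each", {
  ladder <- c(5.0, 5.75, 6.5)
  two_reps <- make_balanced_bin(ladder, n_replicates = 2, n_replicas = 2,
                                n = 30, frac = function(p) 0.5)
  expect_false(check_criteria(two_reps, ladder)$criterion2)
  one_replica <- make_balanced_bin(ladder, n_replicates = 3, n_replicas = 1,
                                   n = 40, frac = function(p) 0.5)
  expect_false(check_criteria(one_replica, ladder)$criterion2)
})

test_that("criterion 3 flags a 0.06 protonation rise on the pooled curve", {
  ladder <- c(5.0, 5.75, 6.5)
  fr <- make_balanced_bin(ladder, n_replicates = 3, n_replicas = 2, n = 50,
                          frac = function(p)
                            c(`5` = 0.60, `5.75` = 0.40, `6.5` = 0.46)[
                              as.character(p)])
  led <- check_criteria(fr, ladder)
  expect_false(led$criterion3)
  expect_equal(led$mono_violating_ph, 6.5)
  # a 0.04 rise is inside the 0.05 tolerance
  fr_ok <- make_balanced_bin(ladder, n_replicates = 3, n_replicas = 2,
                             n = 50, frac = function(p)
                               c(`5` = 0.60, `5.75` = 0.40, `6.5` = 0.44)[
                                 as.character(p)])
  expect_true(check_criteria(fr_ok, ladder)$criterion3)
})

test_that("criteria screens are order-independent and idempotent", {
  ladder <- c(5.0, 5.75, 6.5)
  fr <- make_balanced_bin(ladder, 3, 2, 30,
                          frac = function(p) hill_protonation(p, 5.9, 1))
  led1 <- check_criteria(fr, ladder)
  set.seed(11)
  led2 <- check_criteria(fr[sample(nrow(fr)), ], ladder)
  expect_equal(led1[c("criterion1", "criterion2", "criterion3", "pass")],
               led2[c("criterion1", "criterion2", "criterion3", "pass")])
  expect_equal(check_criteria(fr, ladder)$pass, led1$pass)
})

test_that("removing frames never turns a failing criterion 1 into a pass", {
  ladder <- c(5.0, 5.75)
  spec <- expand.grid(pH = ladder, replicate = 1:3, replica = 1:2)
  spec$n <- 14; spec$n_prot <- 7
  # replicate 1 at pH 5 totals 8 protonated points, short of 10
  spec$n_prot[spec$pH == 5.0 & spec$replicate == 1] <- 4
  fr <- make_bin_frames(spec)
  expect_false(check_criteria(fr, ladder)$criterion1)
  set.seed(13)
  for (k in 1:10) {
    sub <- fr[sample(nrow(fr), nrow(fr) - sample(5:40, 1)), ]
    expect_false(check_criteria(sub, ladder)$criterion1)
  }
})

test_that("Hill fit recovers exact logistic curves and midpoints", {
  ph <- seq(5, 7.25, by = 0.75)
  curve <- data.frame(pH = ph, protonation = hill_protonation(ph, 6.0, 1))
  fit <- fit_pka(curve)
  expect_lt(abs(fit$pka - 6.0), 1e-8)
  expect_lt(abs(fit$hill_n - 1.0), 1e-8)
  # protonation 0.5 at the middle pH pins the midpoint there
  curve2 <- data.frame(pH = c(5.5, 6.0, 6.5),
                       protonation = c(0.8, 0.5, 0.2))
  expect_lt(abs(fit_pka(curve2)$pka - 6.0), 1e-6)
  expect_error(fit_pka(data.frame(pH = c(5, 6),
                                  protonation = c(0.7, 0.3))), ">= 3")
})

test_that("Bayesian bootstrap is exact on degenerate input, seeded, honest", {
  ph <- seq(5, 7.25, by = 0.75)
  m_same <- matrix(hill_protonation(ph, 6.1, 1), nrow = 4, ncol = 3,
                   dimnames = list(ph, NULL))
  bs <- bayesian_bootstrap_sd(m_same, ph, n_boot = 200, seed = 5)
  expect_equal(bs$sd, 0)
  # determinism
  m <- cbind(hill_protonation(ph, 6.0, 1), hill_protonation(ph, 6.3, 1))
  rownames(m) <- ph
  b1 <- bayesian_bootstrap_sd(m, ph, n_boot = 300, seed = 8)
  b2 <- bayesian_bootstrap_sd(m, ph, n_boot = 300, seed = 8)
  expect_identical(b1$pkas, b2$pkas)
  expect_gt(b1$sd, 0)
  expect_error(bayesian_bootstrap_sd(m[, 1, drop = FALSE], ph), "samples")
})

test_that("two-sample bootstrap sd matches a quadrature oracle", {
  ph <- seq(5, 7.25, by = 0.75)
  m <- cbind(hill_protonation(ph, 5.95, 1.0),
             hill_protonation(ph, 6.35, 1.0))
  rownames(m) <- ph
  # Dirichlet(1,1) weight is Uniform(0,1); integrate pKa(w) on a dense grid
  grid <- (seq_len(2000) - 0.5) / 2000
  pk_w <- vapply(grid, function(w)
    oracle_hill_fit(ph, w * m[, 1] + (1 - w) * m[, 2]), numeric(1))
  oracle_sd <- sqrt(mean(pk_w^2) - mean(pk_w)^2)
  bs <- bayesian_bootstrap_sd(m, ph, n_boot = 1000, seed = 3)
  expect_lt(abs(bs$sd - oracle_sd) / oracle_sd, 0.10)
})

test_that("deep-region summary pKa weights passing bins or is undefined", {
  pr <- data.frame(bin_low = c(-6, -5.5, -2), bin_high = c(-5.5, -5, -1.5),
                   bin_mid = c(-5.75, -5.25, -1.75),
                   n_frames = c(100, 300, 500),
                   pass = c(TRUE, TRUE, TRUE),
                   pka = c(6.2, 6.4, 6.0))
  ins <- pka_ins(pr)
  expect_equal(ins$status, "ok")
  expect_equal(ins$value, (6.2 * 100 + 6.4 * 300) / 400)
  one <- pr[1, ]; one$pka <- 6.3
  expect_equal(pka_ins(one)$value, 6.3)
  shallow <- pr[3, , drop = FALSE]
  und <- pka_ins(shallow)
  expect_equal(und$status, "undefined")
  expect_true(is.na(und$value))
})

test_that("profile builder recovers a depth trend end to end", {
  zc <- seq(-7, 1, 0.5)
  truth <- ground_truth_profile(zc, 6 + pmin(pmax(-zc / 6, 0), 1))
  cfg <- synthetic_config(n_frames = 6000, seed = 17)
  fr <- generate_phre_frames(truth, cfg)
  # a shortened run: relax the per-cell floor so mid-depth bins qualify
  pr <- build_profile(fr, n_boot = 200, seed = 4, min_points = 5)
  ok <- pr$pass & !is.na(pr$pka)
  expect_gt(sum(ok), 3)
  # signed depth trend: deeper bins titrate higher, matching the truth sign
  fitline <- stats::lm(pka ~ bin_mid, data = pr[ok, ])
  expect_lt(unname(stats::coef(fitline)[2]), 0)
  deep <- pr$pka[ok][which.min(pr$bin_mid[ok])]
  shallow <- pr$pka[ok][which.max(pr$bin_mid[ok])]
  expect_gt(deep, shallow)
  # profile table is depth-ordered and carries the criteria ledger
  expect_true(all(diff(pr$bin_low) > 0))
  expect_true(all(c("criterion1", "criterion2", "criterion3") %in%
                    names(pr)))
})

test_that("monotonicity remedy drops violating pH points, not the bin", {
  ladder <- c(5.0, 5.75, 6.5, 7.25)
  fr <- make_balanced_bin(ladder, 3, 2, 60,
                          frac = function(p)
                            c(`5` = 0.8, `5.75` = 0.55, `6.5` = 0.65,
                              `7.25` = 0.25)[as.character(p)])
  fr$insertion_A <- -2.1
  pr <- build_profile(fr, equil_frac = 0, n_boot = 100, seed = 2)
  expect_false(pr$criterion3[1])
  expect_equal(pr$n_dropped_ph[1], 1L)
  expect_true(is.finite(pr$pka[1]))
  pr2 <- build_profile(fr, equil_frac = 0, n_boot = 50, seed = 2,
                       mono_remedy = "drop_bin")
  expect_true(is.na(pr2$pka[1]))
})
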