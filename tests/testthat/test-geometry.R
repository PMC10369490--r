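# Membrane geometry: surface reference, insertion depth, deformation
# scans, tilt. Counting logic is checked against brute-force neighbor
# searches.

test_that("local surface reference averages qualifying phosphates", {
  ph <- cbind(runif(12, -3, 3), runif(12, -3, 3), 20)
  s <- local_surface_z(c(0, 0), ph)
  expect_equal(s$mean_z, 20)
  expect_equal(s$n_support_atoms, 12L)
  expect_error(local_surface_z(c(0, 0), ph[0, , drop = FALSE]), "empty")
})

test_that("radius expansion engages when support is short, then errors", {
  set.seed(42)
  near <- cbind(runif(9, -1, 1), runif(9, -1, 1), 19.5)   # within 6
  ring <- cbind(6.5 * cos(1:3), 6.5 * sin(1:3), 20.5)      # within 7
  s <- local_surface_z(c(0, 0), rbind(near, ring))
  expect_equal(s$n_support_atoms, 12L)
  expect_equal(s$radius_xy, 7)
  expect_equal(s$mean_z, mean(c(rep(19.5, 9), rep(20.5, 3))))
  far <- cbind(20 + runif(12), 20 + runif(12), 19)
  expect_error(local_surface_z(c(0, 0), far), "radius cap")
})

test_that("surface support set equals a brute-force xy neighbor search", {
  set.seed(7)
  for (case in 1:20) {
    box <- c(40, 40)
    n <- sample(30:120, 1)
    ph <- cbind(runif(n, 0, 40), runif(n, 0, 40), rnorm(n, 19, 0.5))
    pt <- c(runif(1, 0, 40), runif(1, 0, 40))
    # brute force with explicit wrap
    d <- numeric(n)
    for (i in seq_len(n)) {
      dx <- ph[i, 1] - pt[1]; dx <- dx - 40 * round(dx / 40)
      dy <- ph[i, 2] - pt[2]; dy <- dy - 40 * round(dy / 40)
      d[i] <- sqrt(dx^2 + dy^2)
    }
    r <- 6
    while (sum(d <= r) < 10 && r < 12) r <- r + 1
    if (sum(d <= r) < 10) next
    s <- local_surface_z(pt, ph, box_xy = box)
    expect_equal(s$n_support_atoms, sum(d <= r))
    expect_equal(s$mean_z, mean(ph[d <= r, 3]))
  }
})

test_that("insertion depth is the signed offset from the local surface", {
  s <- structure(list(mean_z = 20, n_support_atoms = 12, radius_xy = 6),
                 class = "surface_reference")
  expect_equal(insertion_depth(18, s)$value, -2)
  expect_equal(insertion_depth(20, s)$value, 0)
  # constructed flat bilayer: residue planted 4.7 A under the plane.
  # Each lipid contributes a 5-atom phosphate-group cloud, the atom
  # density the 6 A / 10-atom support rule assumes.
  b <- generate_bilayer(256, 19, seed = 8, jitter_sd = 0.2)
  atoms <- expand_group_atoms(b$upper, seed = 8)
  surf <- local_surface_z(c(64, 64), atoms, box_xy = b$box_xy)
  expect_gte(surf$n_support_atoms, 10L)
  d <- insertion_depth(19 - 4.7, surf)$value
  expect_lt(abs(d - (-4.7)), 0.5)
})

test_that("half-thickness scan is flat on an undeformed bilayer", {
  b <- generate_bilayer(1024, 19, seed = 15, jitter_sd = 0.15)
  pr <- half_thickness_scan(b$upper, b$lower, center_xy = c(128, 128),
                            box_xy = b$box_xy)
  expect_lt(abs(attr(pr, "bulk_half_thickness") - 19), 0.2)
  populated <- !is.na(pr$upper_dev) & pr$n_upper >= 5
  expect_true(all(abs(pr$upper_dev[populated]) < 0.5))
  # deviations vanish in the bulk region (radius > 15 A)
  bulk <- populated & pr$radius > 15
  expect_lt(max(abs(pr$upper_dev[bulk])), 0.3)
})

test_that("the scan recovers an imposed Gaussian dimple", {
  field <- gaussian_deformation(-3, 8, center = c(128, 128))
  devs <- NULL; wts <- NULL
  for (s in 1:40) {
    b <- generate_bilayer(1024, 19, field, seed = 100 + s, jitter_sd = 0.15)
    pr <- half_thickness_scan(b$upper, b$lower, c(128, 128),
                              box_xy = b$box_xy)
    if (is.null(devs)) { devs <- matrix(0, nrow(pr), 0); wts <- devs }
    devs <- cbind(devs, pr$upper_dev)
    wts <- cbind(wts, pr$n_upper)
  }
  num <- rowSums(devs * wts, na.rm = TRUE)
  den <- rowSums(wts)
  ok <- den >= 5
  mean_dev <- num[ok] / den[ok]
  r <- (seq_len(nrow(devs)) - 0.5) * 0.5
  g <- exp(-r[ok]^2 / (2 * 8^2))
  amp <- sum(den[ok] * g * mean_dev) / sum(den[ok] * g^2)
  expect_lt(abs(amp - (-3)) / 3, 0.10)
})

test_that("scan demands a populated bulk and non-empty leaflets", {
  b <- generate_bilayer(64, 19, seed = 2)
  expect_error(half_thickness_scan(b$upper[0, , drop = FALSE], b$lower,
                                   c(0, 0)), "non-empty")
  # all atoms inside bulk_min: bulk undefined
  tight <- cbind(runif(20, -5, 5), runif(20, -5, 5), 19)
  tightl <- cbind(runif(20, -5, 5), runif(20, -5, 5), -19)
  expect_error(half_thickness_scan(tight, tightl, c(0, 0), bulk_min = 15),
               "bulk")
})

test_that("insertion depth and scan are translation/rotation invariant", {
  b <- generate_bilayer(256, 19, seed = 31, jitter_sd = 0.2)
  pr0 <- half_thickness_scan(b$upper, b$lower, c(64, 64))
  shift <- c(5, -3, 7)
  up2 <- sweep(b$upper, 2, shift, "+"); lo2 <- sweep(b$lower, 2, shift, "+")
  pr1 <- half_thickness_scan(up2, lo2, c(64, 64) + shift[1:2])
  expect_equal(pr1$upper_dev, pr0$upper_dev, tolerance = 1e-10)
  th <- 0.7; R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0,
                           0, 0, 1), 3, 3)
  ctr <- c(64, 64, 0)
  rot <- function(m) sweep(sweep(m, 2, ctr, "-") %*% R, 2, ctr, "+")
  pr2 <- half_thickness_scan(rot(b$upper), rot(b$lower), c(64, 64))
  expect_equal(pr2$upper_dev, pr0$upper_dev, tolerance = 1e-10)
  atoms <- expand_group_atoms(b$upper, seed = 3)
  s0 <- local_surface_z(c(64, 64), atoms)
  s1 <- local_surface_z(c(64, 64) + shift[1:2],
                        sweep(atoms, 2, shift, "+"))
  expect_equal(insertion_depth(10 + shift[3], s1)$value,
               insertion_depth(10, s0)$value, tolerance = 1e-10)
})

test_that("tilt angle folds into [0, 90] degrees", {
  expect_equal(tilt_angle(c(0, 0, 0), c(0, 0, 5)), 0)
  expect_equal(tilt_angle(c(0, 0, 0), c(3, 0, 0)), 90)
  expect_equal(tilt_angle(c(0, 0, 0), c(1, 0, 1)), 45)
  expect_equal(tilt_angle(c(0, 0, 0), c(0, 0, -5)), 0)  # sign-folded
  expect_error(tilt_angle(c(1, 1, 1), c(1, 1, 1)), "zero length")
})

test_that("GRO round trip preserves coordinates to format precision", {
  b <- generate_bilayer(64, 19, seed = 4)
  path <- tempfile(fileext = ".gro")
  write_gro(rbind(b$upper, b$lower), path, box = c(b$box_xy, 80))
  back <- read_gro(path)
  expect_equal(back$coords, unname(rbind(b$upper, b$lower)),
               tolerance = 0.011)
  expect_equal(back$box[1], b$box_xy[1], tolerance = 1e-6)
  unlink(path)
})
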