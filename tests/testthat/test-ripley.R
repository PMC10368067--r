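# Edge-corrected 3-D Ripley K, envelopes, verdicts, projections.

test_that("cap fraction matches the closed form and its degenerate cases", {
  w <- study_window(c(0, 0, 0), radius = 70)
  expect_identical(cap_fraction(c(0, 0, 10), d = 0, w), 1)
  expect_identical(cap_fraction(c(0, 0, 0), d = 50, w), 1)
  expect_equal(cap_fraction(c(0, 0, 35), d = 70, w), 0.375)
  expect_error(cap_fraction(c(0, 0, 100), d = 1, w), "outside")
  expect_error(cap_fraction(c(0, 0, 0), d = -1, w), "non-negative")
})

test_that("cap fraction agrees with surface-measure sampling", {
  # the fraction depends only on the polar angle towards the window
  # center: sampling cos(theta) on a stratified grid is exact uniform
  # surface sampling with O(1/n) error
  set.seed(12)
  n <- 1e5
  ct <- (seq_len(n) - 0.5) / n * 2 - 1
  for (k in 1:10) {
    rho <- runif(1, 0, 69.5)
    d <- runif(1, 0.5, 120)
    mc <- mean(rho^2 + d^2 + 2 * rho * d * ct <= 70^2)
    expect_equal(cap_fraction(c(rho, 0, 0), d, study_window(c(0, 0, 0), 70)),
                 mc, tolerance = 1e-3)
  }
})

test_that("K estimate matches a plain-loop summation oracle", {
  w <- study_window(c(0, 0, 0), radius = 20)
  set.seed(31)
  pts <- matrix(rnorm(15, sd = 6), ncol = 3)
  pts <- pts[sqrt(rowSums(pts^2)) < 20, , drop = FALSE]
  radii <- c(2, 5, 10, 20, 45)
  est <- ripley_k(point_pattern3d(pts), w, radii)
  expect_equal(est$k_values, ripley_reference(pts, w, radii),
               tolerance = 1e-12)
  # beyond the window diameter every indicator is 1: K is the full
  # corrected pair sum
  n <- nrow(pts)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    acc <- acc + 1 / cap_fraction(pts[i, ],
                                  sqrt(sum((pts[i, ] - pts[j, ])^2)), w)
  }
  expect_equal(est$k_values[5],
               4 / 3 * pi * 20^3 / (n * (n - 1)) * acc, tolerance = 1e-12)
  expect_true(all(diff(est$k_values) >= 0))
  expect_equal(est$csr_reference, 4 / 3 * pi * radii^3)
})

test_that("far-apart points give K = 0 and small n errors", {
  w <- study_window(c(0, 0, 0), radius = 100)
  two <- point_pattern3d(rbind(c(0, 0, -90), c(0, 0, 90)))
  est <- ripley_k(two, w, radii = c(5, 10, 20))
  expect_true(all(est$k_values == 0))
  one <- point_pattern3d(rbind(c(0, 0, 0)))
  expect_error(ripley_k(one, w, c(5, 10)), "at least 2")
  outside <- point_pattern3d(rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 500)))
  expect_warning(ripley_k(outside, w, c(5, 10)), "outside")
})

test_that("K is invariant under joint rigid motion", {
  w <- study_window(c(0, 0, 0), radius = 30)
  pp <- simulate_point_pattern("csr", 40, w, seed = 6L)
  radii <- seq(2, 20, by = 2)
  k0 <- ripley_k(pp, w, radii)$k_values
  # rotate about z and translate
  th <- 0.7
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  shift <- c(100, -50, 3)
  pts2 <- t(R %*% t(as.matrix(pp))) + matrix(shift, nrow(pp), 3, TRUE)
  w2 <- study_window(shift, radius = 30)
  k1 <- ripley_k(point_pattern3d(pts2), w2, radii)$k_values
  expect_equal(k0, k1, tolerance = 1e-9)
})

test_that("mean K under CSR tracks 4/3 pi r^3 and correction removes bias", {
  w <- study_window(c(0, 0, 0), radius = 70)
  radii <- seq(5, 40, by = 5)
  kc <- matrix(0, 15, length(radii))
  ku <- kc
  for (sd in 1:15) {
    pp <- simulate_point_pattern("csr", 200, w, seed = sd)
    kc[sd, ] <- ripley_k(pp, w, radii)$k_values
    ku[sd, ] <- ripley_k(pp, w, radii, correction = "none")$k_values
  }
  csr <- 4 / 3 * pi * radii^3
  expect_lt(max(abs(colMeans(kc) / csr - 1)), 0.08)
  # uncorrected estimator is biased low at the largest radius
  expect_lt(colMeans(ku)[length(radii)] / csr[length(radii)], 0.8)
})

test_that("envelopes are deterministic, ordered and bracket CSR", {
  w <- study_window(c(0, 0, 0), radius = 70)
  radii <- seq(5, 40, by = 5)
  e1 <- csr_envelope(100, w, radii, n_sim = 20L, alpha = 0.05, seed = 3L)
  e2 <- csr_envelope(100, w, radii, n_sim = 20L, alpha = 0.05, seed = 3L)
  expect_identical(e1, e2)
  expect_true(all(e1$envelope_lo <= e1$envelope_hi))
  # with n_sim = 20 and alpha = 0.05 the envelopes are the min/max
  sims <- sapply(1:20, function(i)
    ripley_k(simulate_point_pattern("csr", 100, w, seed = 3L + i),
             w, radii)$k_values)
  expect_equal(e1$envelope_lo, apply(sims, 1, min))
  expect_equal(e1$envelope_hi, apply(sims, 1, max))
  # interior radii bracket the theoretical curve
  csr <- 4 / 3 * pi * radii^3
  mid <- radii >= 10 & radii <= 35
  expect_true(all(e1$envelope_lo[mid] < csr[mid] &
                    csr[mid] < e1$envelope_hi[mid]))
})

test_that("clustering verdict separates Thomas from CSR patterns", {
  w <- study_window(c(0, 0, 0), radius = 70)
  radii <- seq(2, 40, by = 2)
  th_true <- 0L
  csr_true <- 0L
  for (sd in 1:5) {
    th <- simulate_point_pattern(
      "thomas", list(n_parents = 8, mean_offspring = 25, cluster_sd = 6),
      w, seed = 200 + sd)
    est <- ripley_k(th, w, radii)
    est <- csr_envelope(nrow(th), w, radii, n_sim = 40L, seed = 300 + sd,
                        estimate = est)
    th_true <- th_true + clustering_verdict(est, c(5, 30))
    cs <- simulate_point_pattern("csr", 200, w, seed = 400 + sd)
    est2 <- ripley_k(cs, w, radii)
    est2 <- csr_envelope(200, w, radii, n_sim = 40L, seed = 500 + sd,
                         estimate = est2)
    csr_true <- csr_true + clustering_verdict(est2, c(5, 30))
  }
  expect_gte(th_true, 4L)
  expect_lte(csr_true, 1L)
  # identically-zero K is never a clustering call
  two <- point_pattern3d(rbind(c(0, 0, -60), c(0, 0, 60)))
  z <- ripley_k(two, w, radii)
  expect_false(clustering_verdict(z, c(5, 30)))
  expect_error(clustering_verdict(z, c(100, 200)), "no tabulated")
})

test_that("projection density conserves mass and symmetry", {
  pts <- point_pattern3d(rbind(c(0, 10, 10), c(0, 30, 30)))
  dens <- projection_density(pts, "xy", grid_shape = c(80L, 80L),
                             bandwidth = 2)
  mass <- sum(dens) * attr(dens, "cell_area")
  expect_equal(mass, 2, tolerance = 0.01)

  one <- point_pattern3d(rbind(c(0, 17, 23)))
  d1 <- projection_density(one, "xy", grid_shape = c(64L, 64L),
                           bandwidth = 1)
  peak <- which(d1 == max(d1), arr.ind = TRUE)
  expect_equal(attr(d1, "xgrid")[peak[2]], 23, tolerance = 1)
  expect_equal(attr(d1, "ygrid")[peak[1]], 17, tolerance = 1)

  # two identical clusters mirrored about the grid center
  mir <- point_pattern3d(rbind(c(0, 10, 10), c(0, 10, 30),
                               c(0, 30, 30), c(0, 30, 10)))
  dm <- projection_density(mir, "xy", grid_shape = c(40L, 40L),
                           bandwidth = 3, xlim = c(0, 40), ylim = c(0, 40))
  expect_equal(unclass(dm), unclass(dm)[rev(seq_len(40)), rev(seq_len(40))],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(projection_density(point_pattern3d(NULL), "xy",
                                  bandwidth = 1), "no points")
})
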