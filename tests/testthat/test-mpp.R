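# Marked point process detector: contrast statistic, quality function,
# energies, admissibility, and the two minimizers.

test_that("contrast statistic matches direct arithmetic and its guards", {
  img <- contrast_fixture()
  rect <- rectangles(row = 4L, col = 4L, w = 2L, l = 2L)  # footprint [3,5)^2
  expect_equal(contrast_statistic(img, rect, crown_width = 1L), 36 / 5)

  flat <- matrix(0.4, 16, 16)
  expect_identical(contrast_statistic(flat, rectangles(8L, 8L, 3L, 3L)), 0)

  step <- matrix(0, 16, 16)
  step[7:9, 7:9] <- 1   # 0-based footprint [6, 9): center (7, 7)
  expect_identical(
    contrast_statistic(step, rectangles(7L, 7L, 3L, 3L), crown_width = 2L),
    Inf)

  expect_error(
    contrast_statistic(matrix(1, 4, 4), rectangles(2L, 2L, 4L, 4L)),
    "crown")
  expect_error(
    contrast_statistic(matrix(1, 4, 4), rectangles(3L, 3L, 4L, 4L)),
    "outside")
})

test_that("quality function reproduces both branch forms", {
  for (form in c("printed", "corrected"))
    expect_identical(quality(0, x0 = 2, form = form), 1)
  expect_identical(quality(2, x0 = 2, form = "printed"), 1)  # discontinuity
  expect_identical(quality(2, x0 = 2, form = "corrected"), 0)
  expect_equal(quality(4, x0 = 2, form = "corrected"), exp(-1) - 1)
  expect_equal(quality(4, x0 = 2, form = "printed"), exp(-1))
  # corrected form is continuous at x0
  eps <- 1e-9
  expect_equal(quality(2 - eps, 2), quality(2 + eps, 2), tolerance = 1e-8)
  expect_error(quality(1, x0 = 0), "x0")
  expect_error(quality(-1, x0 = 1), "non-negative")
})

test_that("corrected quality is non-increasing in x", {
  xs <- seq(0, 20, by = 0.01)
  q <- quality(xs, x0 = 2.5)
  expect_true(all(diff(q) <= 1e-12))
  expect_true(all(q > -1 & q <= 1))
})

test_that("rectangle energy composes the statistic and the gate", {
  flat <- matrix(0.4, 16, 16)
  p <- mpp_params(x0 = 1)
  expect_identical(rectangle_energy(flat, rectangles(8L, 8L, 3L, 3L), p), 1)

  img <- contrast_fixture()  # x = 7.2; with x0 = 3.6 this is exactly 2 x0
  p2 <- mpp_params(x0 = 3.6, crown_width = 1L)
  expect_equal(rectangle_energy(img, rectangles(4L, 4L, 2L, 2L), p2),
               exp(-1) - 1)

  # dark rectangle on bright crown: gated to 1 under bright_only
  inv <- matrix(1, 16, 16)
  inv[7:9, 7:9] <- 0
  expect_identical(rectangle_energy(inv, rectangles(7L, 7L, 3L, 3L),
                                    mpp_params(x0 = 1)), 1)
  expect_lt(rectangle_energy(inv, rectangles(7L, 7L, 3L, 3L),
                             mpp_params(x0 = 1, bright_only = FALSE)), 0)
})

test_that("overlap uses half-open footprints", {
  a <- rectangles(10L, 12L, 4L, 4L)   # cols [10, 14)
  expect_true(overlaps(a, a))
  b <- rectangles(10L, 16L, 4L, 4L)   # cols [14, 18): shares only an edge
  expect_false(overlaps(a, b))
  c <- rectangles(10L, 15L, 4L, 4L)   # cols [13, 17): one column shared
  expect_true(overlaps(a, c))
  d <- rectangles(40L, 40L, 4L, 4L)
  expect_false(overlaps(a, d))
})

test_that("configuration energy sums data terms and rejects overlaps", {
  p <- mpp_params(x0 = 3.6, crown_width = 1L)
  img <- matrix(5, 24, 24)
  plant <- function(img, r, c) {
    img[r + 0:3, c + 0:3] <- rep(c(3, 7), 8)
    img[r + 1:2, c + 1:2] <- c(10, 10, 12, 12)
    img
  }
  img <- plant(img, 3, 3)
  img <- plant(img, 15, 15)
  cfg0 <- rectangles()
  expect_identical(configuration_energy(img, cfg0, p), 0)
  one <- rectangles(4L, 4L, 2L, 2L)   # footprint = the planted interior
  expect_equal(configuration_energy(img, one, p),
               rectangle_energy(img, one, p))
  two <- rectangles(c(4L, 16L), c(4L, 16L), c(2L, 2L), c(2L, 2L))
  expect_equal(configuration_energy(img, two, p), 2 * (exp(-1) - 1))
  bad <- rectangles(c(4L, 5L), c(4L, 4L), c(2L, 2L), c(2L, 2L))
  expect_error(configuration_energy(img, bad, p), "inadmissible")
})

test_that("brute force enumerates admissible subsets with tie-breaking", {
  img <- matrix(0, 32, 32)  # D values supplied directly
  p <- mpp_params()
  # all positive data terms: the empty configuration wins
  cand <- data.frame(row = c(5L, 15L), col = c(5L, 15L), w = 3L, l = 3L,
                     D = c(0.2, 0.4))
  bf <- brute_force_minimize(img, cand, p)
  expect_identical(nrow(bf), 0L)
  expect_identical(attr(bf, "energy"), 0)
  # two overlapping candidates: the better one alone
  cand2 <- data.frame(row = c(10L, 11L), col = c(10L, 10L), w = 3L, l = 3L,
                      D = c(-0.5, -0.6))
  bf2 <- brute_force_minimize(img, cand2, p)
  expect_identical(nrow(bf2), 1L)
  expect_identical(bf2$row, 11L)
  expect_equal(attr(bf2, "energy"), -0.6)
  # three mutually disjoint negatives: all selected
  cand3 <- data.frame(row = c(5L, 15L, 25L), col = c(5L, 15L, 25L),
                      w = 3L, l = 3L, D = c(-0.3, -0.2, -0.4))
  bf3 <- brute_force_minimize(img, cand3, p)
  expect_identical(nrow(bf3), 3L)
  expect_equal(attr(bf3, "energy"), -0.9)
  # exact energy tie between overlapping candidates: lexicographic winner
  cand4 <- data.frame(row = c(11L, 10L), col = c(10L, 10L), w = 3L, l = 3L,
                      D = c(-0.5, -0.5))
  bf4 <- brute_force_minimize(img, cand4, p)
  expect_identical(bf4$row, 10L)
  expect_error(
    brute_force_minimize(img, cand3[rep(1, 25), ], p), "cap")
})

test_that("stochastic minimizer matches the oracle and the greedy bound", {
  matched <- 0L
  for (sd in 1:12) {
    inst <- mpp_small_instance(sd)
    img <- inst$img
    cand <- inst$cand
    p <- inst$params
    bf <- brute_force_minimize(img, cand, p)
    cand$D <- vapply(seq_len(nrow(cand)), function(i)
      rectangle_energy(img, cand[i, , drop = FALSE], p), numeric(1))
    me <- minimize_energy(img, p, candidates = cand)
    expect_lte(attr(me, "energy"),
               attr(greedy_baseline(cand), "energy") + 1e-12)
    # admissibility: no overlapping pair in the returned configuration
    if (nrow(me) > 1) {
      for (i in seq_len(nrow(me) - 1))
        for (j in (i + 1):nrow(me))
          expect_false(overlaps(me[i, , drop = FALSE],
                                me[j, , drop = FALSE]))
    }
    if (abs(attr(bf, "energy") - attr(me, "energy")) < 1e-9)
      matched <- matched + 1L
  }
  expect_gte(matched, 11L)
})

test_that("detection is translation equivariant and ROI-restricted", {
  base <- matrix(0.05, 48, 48)
  base[20:23, 20:22] <- 0.9
  p <- mpp_params(seed = 7L)
  cfg1 <- minimize_energy(base, p)
  shifted <- matrix(0.05, 48, 48)
  shifted[26:29, 25:27] <- 0.9   # shift by (+6, +5)
  cfg2 <- minimize_energy(shifted, p)
  expect_identical(nrow(cfg1), nrow(cfg2))
  expect_identical(cfg2$row, cfg1$row + 6L)
  expect_identical(cfg2$col, cfg1$col + 5L)

  roi <- matrix(FALSE, 48, 48)
  det <- detect_slice(base, p, roi)
  expect_identical(nrow(det$config), 0L)
  expect_false(any(det$mask))
  expect_error(detect_slice(base, p, matrix(TRUE, 2, 2)), "shape")

  det2 <- detect_slice(base, p)
  expect_identical(sum(det2$mask), sum(det2$config$w * det2$config$l))
})

test_that("constant image yields an empty configuration", {
  cfg <- minimize_energy(matrix(0.3, 40, 40), mpp_params(seed = 1L))
  expect_identical(nrow(cfg), 0L)
  expect_identical(attr(cfg, "energy"), 0)
})
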