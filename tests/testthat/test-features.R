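test_that("pattern bin numbers implement the binary weighting", {
  # unit stats: normalized coefficients equal |d|
  st <- fake_ruleset(data.frame(i = 1, j = 2, delta = 0, score = 1), m = 4)$stats
  rules6 <- data.frame(i = rep(1, 6), j = rep(2, 6), delta = 0, score = 1)

  # all comparisons false -> 0; all true (b = 8) -> 255
  lo <- c(0, 5, 0, 0); hi <- c(5, 0, 0, 0)
  rules8 <- data.frame(i = rep(1, 8), j = rep(2, 8), delta = 0, score = 1)
  expect_equal(compute_pattern(lo, rules8, st), 0)
  expect_equal(compute_pattern(hi, rules8, st), 255)

  # q = (1,0,1,0,0,0) for b = 6 -> y = 1 + 4 = 5
  rules_mix <- data.frame(i = c(1, 2, 1, 2, 2, 2), j = c(2, 1, 2, 1, 1, 1),
                          delta = 0, score = 1)
  expect_equal(compute_pattern(hi, rules_mix, st), 5)
})

test_that("the bin map is a bijection onto 0..2^b-1", {
  b <- 3
  st <- fake_ruleset(data.frame(i = 1, j = 2, delta = 0, score = 1), m = 6)$stats
  # rule x compares coefficient 2x-1 against 2x; craft vectors for all 8
  # boolean patterns
  rules <- data.frame(i = c(1, 3, 5), j = c(2, 4, 6), delta = 0, score = 1)
  bins <- integer(8)
  for (k in 0:7) {
    bits <- as.integer(intToBits(k))[1:3]
    v <- numeric(6)
    v[c(1, 3, 5)] <- ifelse(bits == 1, 2, 0)
    v[c(2, 4, 6)] <- 1
    bins[k + 1] <- compute_pattern(v, rules, st)
  }
  expect_setequal(bins, 0:7)
  expect_equal(bins, 0:7)   # bit x of y is comparison x
})

test_that("describe_image: normalization, point masses and patch counts", {
  img <- sinusoid_image(25, size = 72)
  mask <- matrix(TRUE, 72, 72)
  # force every comparison true / false via extreme deltas
  rs_hi <- fake_ruleset(data.frame(i = 2, j = 3, delta = 1e6, score = 1),
                        m = 81, b = 1)
  rs_lo <- fake_ruleset(data.frame(i = 2, j = 3, delta = -1e6, score = 1),
                        m = 81, b = 1)
  f_hi <- describe_image(img, rs_hi, mask = mask)
  f_lo <- describe_image(img, rs_lo, mask = mask)
  expect_equal(as.vector(f_hi), c(0, 1))   # point mass on bin 1
  expect_equal(as.vector(f_lo), c(1, 0))   # point mass on bin 0
  expect_equal(attr(f_hi, "n_patches"), nrow(ccp:::eligible_centers(mask, 9)))

  # generic ruleset: every histogram sums to 1
  rs <- fake_ruleset(data.frame(i = c(2, 3, 10, 4), j = c(3, 2, 4, 19),
                                delta = c(0.1, -0.2, 0, 0.3), score = 1),
                     m = 81, groups = 2, b = 2)
  f <- describe_image(img, rs, mask = mask)
  expect_length(f, 2 * 4)
  expect_equal(sum(f[1:4]), 1, tolerance = 1e-9)
  expect_equal(sum(f[5:8]), 1, tolerance = 1e-9)

  expect_error(describe_image(img, rs, mask = matrix(FALSE, 72, 72)),
               "eligible")

  # stride subsampling keeps normalization but visits fewer centers
  f_s2 <- describe_image(img, rs, mask = mask, stride = 2)
  expect_lt(attr(f_s2, "n_patches"), attr(f_hi, "n_patches") / 3)
  expect_equal(sum(f_s2[1:4]), 1, tolerance = 1e-9)
})

test_that("the descriptor is invariant to the size of the foreground area", {
  set.seed(31)
  img <- sinusoid_image(40, size = 140) + rnorm(140 * 140, sd = 4)
  of <- estimate_orientation_field(img)
  rs <- fake_ruleset(data.frame(i = c(2, 10, 3, 12), j = c(10, 2, 19, 4),
                                delta = c(0.05, -0.1, 0.2, 0), score = 1),
                     m = 81, groups = 1, b = 4)
  disk <- function(cr, cc, r) {
    x <- matrix(rep(1:140, each = 140), 140, 140)
    y <- matrix(rep(1:140, times = 140), 140, 140)
    (x - cc)^2 + (y - cr)^2 <= r^2
  }
  m1 <- disk(70, 45, 28)
  m2 <- disk(70, 45, 28) | disk(70, 103, 28)   # twice the foreground area
  f1 <- describe_image(img, rs, mask = m1, of = of)
  f2 <- describe_image(img, rs, mask = m2, of = of)
  expect_equal(attr(f2, "n_patches"), 2 * attr(f1, "n_patches"),
               tolerance = 0.01)
  expect_lt(max(abs(f1 - f2)), 1e-2)
  expect_equal(sum(f1), 1, tolerance = 1e-9)
})

test_that("descriptors are stable under a 30-degree rotation of the image", {
  fit <- trained_small_model(b = 8)
  sim <- synth_image(synth_config(size = 160), 1L, seed = 55)
  ctr <- c(80, 80) + 0.5
  img <- extract_patch(sim$img, ctr, 0, 97)    # central crop
  rot <- extract_patch(sim$img, ctr, 30, 97)   # its 30-degree rotation
  x <- matrix(rep(1:97, each = 97), 97, 97)
  mask <- (x - 49)^2 + (t(x) - 49)^2 <= 40^2   # disk, invariant to rotation
  f1 <- describe_image(img, fit, mask = mask)
  f2 <- describe_image(rot, fit, mask = mask)
  expect_lt(sum(abs(f1 - f2)), 0.05)
})

test_that("histogram layout variants have the documented dimensions", {
  expect_equal(feature_length(ccp_variant("1x8")), 256)
  expect_equal(feature_length(ccp_variant("4x6")), 256)
  expect_equal(feature_length(ccp_variant("2x8")), 512)
  expect_equal(feature_length(ccp_variant("8x6")), 512)
  v <- ccp_variant("4x6")
  expect_equal(v$groups * v$b, 24)   # total rules learned
  expect_error(ccp_variant("4by6"), "GxB")
  v2 <- ccp_variant("3x5")
  expect_equal(feature_length(v2), 3 * 32)
})

test_that("feature tables round-trip through CSV", {
  feats <- matrix(runif(12), 3, 4)
  man <- data.frame(path = c("a.png", "b.png", "c.png"), label = c(1, 0, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(feats, man, path)
  back <- read_feature_table(path)
  expect_equal(back$features, feats, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(back$manifest$label, man$label)
})
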