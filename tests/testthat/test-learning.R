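test_that("coefficient statistics: closed forms and degenerate cases", {
  # two patches with a_5 = {0, 2}: mean 1, population variance 1, sd 1
  coeffs <- matrix(1, 2, 9)
  coeffs[, 5] <- c(0, -2)          # signed; statistics use absolute values
  st <- suppressMessages(compute_coefficient_stats(coeffs))
  expect_equal(st$mean[5], 1)
  expect_equal(st$sd[5], 1)
  expect_equal(st$n_patches, 2L)
  expect_true(5 %in% st$valid)     # index 5 has positive sd
  expect_false(1 %in% st$valid)    # constant column excluded

  # all patches identical: no index left
  expect_error(
    suppressMessages(compute_coefficient_stats(matrix(3, 10, 4))),
    "zero variance")
  expect_error(compute_coefficient_stats(matrix(1, 1, 4)), "at least 2")
})

test_that("coefficient statistics match a two-pass oracle on large input", {
  set.seed(9)
  coeffs <- matrix(rnorm(1e4 * 16, 2, 3), 1e4, 16)
  st <- compute_coefficient_stats(coeffs)
  a <- abs(coeffs)
  mu2 <- apply(a, 2, mean)
  sd2 <- sqrt(apply(a, 2, function(x) mean((x - mean(x))^2)))
  expect_equal(st$mean, mu2, tolerance = 1e-9)
  expect_equal(st$sd, sd2, tolerance = 1e-9)
})

test_that("comparison frequencies: bounds, strict ties and enumeration", {
  set.seed(10)
  cn <- matrix(rnorm(50 * 6), 50, 6)
  # delta beyond the spread: frequency 1; far below: 0
  expect_equal(comparison_frequency(cn, 1, 2, 1e6), 1)
  expect_equal(comparison_frequency(cn, 1, 2, -1e6), 0)
  # exact ties with delta = 0 contribute 0 (strict inequality)
  cn_tie <- cbind(cn[, 1], cn[, 1])
  expect_equal(comparison_frequency(cn_tie, 1, 2, 0), 0)
  # direct enumeration
  for (d in c(-0.3, 0, 0.44)) {
    cnt <- sum(vapply(seq_len(50),
                      function(t) (cn[t, 3] + d) > cn[t, 5], logical(1)))
    expect_equal(comparison_frequency(cn, 3, 5, d), cnt / 50)
  }
})

test_that("identical classes give all-zero scores and no usable rules", {
  set.seed(12)
  X <- matrix(rnorm(200 * 9), 200, 9)
  coeffs <- rbind(X, X)
  labels <- rep(c(1, 0), each = 200)
  st <- compute_coefficient_stats(coeffs)
  cn <- normalize_coefficients(coeffs, st)
  res <- ccp:::ccp_pair_search(cn[labels == 1, ], cn[labels == 0, ],
                               as.integer(st$valid), -1, 0.02, 101L)
  expect_equal(max(res[, 4]), 0)
  expect_error(search_comparisons(coeffs, labels, ccp_config(n = 3, b = 2)),
               "positive score")
})

test_that("the search recovers a planted coefficient pair", {
  sim <- synth_patch_coeffs(n_per_class = 400, m = 25, planted = c(2, 5),
                            separation = 1.5, seed = 33)
  rs <- search_comparisons(sim$coeffs, sim$labels,
                           ccp_config(n = 5, b = 4))
  expect_setequal(c(rs$rules$i[1], rs$rules$j[1]), c(2, 5))
  expect_gt(rs$rules$score[1], 0.5)
})

test_that("search equals the brute-force triple-loop oracle on a toy problem", {
  set.seed(14)
  n <- 3
  coeffs <- matrix(rnorm(400 * n^2, 0, 2), 400, n^2)
  labels <- rep(c(1, 0), each = 200)
  coeffs[labels == 1, 4] <- coeffs[labels == 1, 4] * 2.5   # mild signal
  cfg <- ccp_config(n = n, b = 4)
  st <- compute_coefficient_stats(coeffs)
  got <- search_comparisons(coeffs, labels, cfg, st)
  ref <- search_oracle(coeffs, labels, cfg, st)
  # full ranking of all 72 ordered pairs must agree
  full <- ccp:::ccp_pair_search(
    normalize_coefficients(coeffs, st)[labels == 1, ],
    normalize_coefficients(coeffs, st)[labels == 0, ],
    as.integer(st$valid), cfg$delta_lo, cfg$delta_step, 101L)
  ord <- order(-full[, 4], full[, 1], full[, 2])
  full <- full[ord, ]
  expect_equal(nrow(full), 72)
  expect_equal(full[, 1], ref$i, ignore_attr = TRUE)
  expect_equal(full[, 2], ref$j, ignore_attr = TRUE)
  expect_equal(full[, 3], ref$delta, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(full[, 4], ref$score, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(got$rules, ref[seq_len(4), ], ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("scores are symmetric under class swap", {
  set.seed(15)
  coeffs <- matrix(rnorm(300 * 9), 300, 9)
  labels <- rep(c(1, 0), c(120, 180))
  st <- compute_coefficient_stats(coeffs)
  cn <- normalize_coefficients(coeffs, st)
  a <- ccp:::ccp_pair_search(cn[labels == 1, ], cn[labels == 0, ],
                             as.integer(st$valid), -1, 0.02, 101L)
  b <- ccp:::ccp_pair_search(cn[labels == 0, ], cn[labels == 1, ],
                             as.integer(st$valid), -1, 0.02, 101L)
  expect_equal(a[, 4], b[, 4], tolerance = 1e-12)
})

test_that("refining the delta grid never lowers the best pair score", {
  set.seed(16)
  coeffs <- matrix(rnorm(200 * 4), 200, 4)
  labels <- rep(c(1, 0), each = 100)
  coeffs[labels == 1, 2] <- coeffs[labels == 1, 2] + 1
  st <- compute_coefficient_stats(coeffs)
  cn <- normalize_coefficients(coeffs, st)
  coarse <- ccp:::ccp_pair_search(cn[labels == 1, ], cn[labels == 0, ],
                                  as.integer(st$valid), -1, 0.02, 101L)
  fine <- ccp:::ccp_pair_search(cn[labels == 1, ], cn[labels == 0, ],
                                as.integer(st$valid), -1, 0.01, 201L)
  key <- paste(coarse[, 1], coarse[, 2])
  expect_true(all(fine[match(key, paste(fine[, 1], fine[, 2])), 4]
                  >= coarse[, 4] - 1e-12))
})

test_that("selected rules are distinct ordered pairs in rank order", {
  sim <- synth_patch_coeffs(n_per_class = 300, m = 9, planted = c(1, 3),
                            separation = 1, seed = 40)
  rs <- search_comparisons(sim$coeffs, sim$labels, ccp_config(n = 3, b = 6))
  r <- rs$rules
  expect_equal(nrow(r), 6)
  expect_false(any(duplicated(paste(r$i, r$j))))
  expect_true(all(diff(r$score) <= 1e-12))
  expect_true(all(r$i != r$j))
  expect_true(all(r$delta >= -1 & r$delta <= 1))
})
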