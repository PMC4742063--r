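# Fixture builders shared across the test files.  Everything is generated in
# code; nothing is read from disk except files the tests themselves write.

# Plane-wave ridge texture at a given orientation (degrees, raster
# convention: 0 = x-axis, clockwise, y down).  The phase is zero at the
# image center so that textures generated at different angles agree at the
# center up to rotation.
sinusoid_image <- function(theta_deg, size = 96, lambda = 8,
                           amplitude = 100, offset = 127.5) {
  x <- matrix(rep(seq_len(size), each = size), size, size)   # col index
  y <- matrix(rep(seq_len(size), times = size), size, size)  # row index
  cx <- (size + 1) / 2
  psi <- (theta_deg + 90) * pi / 180   # wave direction, across the ridges
  phase <- 2 * pi / lambda * ((x - cx) * cos(psi) + (y - cx) * sin(psi))
  offset + amplitude * sin(phase)
}

# Rotated crop: the n x n block around `center`, resampled so that the
# direction alpha of the source is mapped onto the crop's x-axis.  Built on
# extract_patch, i.e. exactly the package's rotation resampling.
rotate_crop <- function(img, alpha_deg, n, center = NULL) {
  if (is.null(center))
    center <- c((nrow(img) + 1) %/% 2, (ncol(img) + 1) %/% 2)
  extract_patch(img, center, alpha_deg, n)
}

# A hand-built comparison set over m coefficient indices with unit
# normalization (mean 0, sd 1), so normalized coefficients equal |d|.
fake_ruleset <- function(rules, m = 81, groups = 1, b = nrow(rules) / groups,
                         n = 9L) {
  stats <- structure(list(mean = rep(0, m), sd = rep(1, m),
                          n_patches = 2L, valid = seq_len(m)),
                     class = "ccp_stats")
  structure(list(rules = rules, stats = stats,
                 config = ccp_config(n = n, b = as.integer(b),
                                     groups = as.integer(groups)),
                 pairs_searched = m * (m - 1L)),
            class = "ccp_rules")
}

# A small trained model on the default synthetic contrast, cached per test
# run; gives realistic comparison rules and coefficient statistics.
trained_small_model <- local({
  cache <- new.env()
  function(b = 8) {
    key <- paste0("b", b)
    if (is.null(cache[[key]])) {
      dir <- file.path(tempdir(), paste0("ccp_small_fit_", key))
      on.exit(unlink(dir, recursive = TRUE), add = TRUE)
      tr <- synth_dataset(dir, 6, 6, synth_config(size = 64), seed = 101,
                          prefix = "tr")
      cache[[key]] <- ccp_fit(tr, config = ccp_config(b = b, p = 300),
                              seed = 7)
    }
    cache[[key]]
  }
})

# Angular distance between two orientations defined modulo 180 degrees.
angle_dist <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# Brute-force O(n^4) type-II orthonormal DCT used as the independent oracle.
dct2_oracle <- function(patch) {
  n <- nrow(patch)
  lam <- function(u) if (u == 0) sqrt(1 / n) else sqrt(2 / n)
  d <- numeric(n * n)
  for (u in 0:(n - 1)) for (v in 0:(n - 1)) {
    s <- 0
    for (a in 0:(n - 1)) for (b in 0:(n - 1))
      s <- s + patch[a + 1, b + 1] *
        cos(pi * (2 * a + 1) * u / (2 * n)) *
        cos(pi * (2 * b + 1) * v / (2 * n))
    d[u * n + v + 1] <- lam(u) * lam(v) * s
  }
  d
}

# Independent triple-loop reference for the comparison search: for every
# ordered pair of valid indices and every delta on the grid, frequencies are
# counted directly; ties over delta broken toward |delta| nearest 0, then
# the smaller delta; pairs ranked by score, then i, then j.
search_oracle <- function(coeffs, labels, cfg, stats) {
  cn <- normalize_coefficients(coeffs, stats)
  live <- cn[labels == 1, , drop = FALSE]
  spoof <- cn[labels == 0, , drop = FALSE]
  deltas <- seq(cfg$delta_lo, cfg$delta_hi, by = cfg$delta_step)
  out <- NULL
  for (i in stats$valid) for (j in stats$valid) {
    if (i == j) next
    best <- -1; bd <- NA
    for (d in deltas) {
      sc <- abs(mean((live[, i] + d) > live[, j]) -
                  mean((spoof[, i] + d) > spoof[, j]))
      if (sc > best + 1e-12 ||
          (sc > best - 1e-12 && !is.na(bd) &&
           (abs(d) < abs(bd) - 1e-12 ||
            (abs(d) < abs(bd) + 1e-12 && d < bd)))) {
        best <- max(best, sc); bd <- d
      }
    }
    out <- rbind(out, data.frame(i = i, j = j, delta = bd, score = best))
  }
  out[order(-out$score, out$i, out$j), ]
}
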