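#' Pooled DCT-coefficient statistics
#'
#' Computes the per-index mean and standard deviation of the absolute DCT
#' coefficient values `a_i = |d_i|` over all training patches, pooled over
#' both classes.  These statistics define the normalized coefficients
#' `c_i = (a_i - mean_i) / sd_i` used by every comparison.  The variance is
#' the population variance (divisor N), matching the definition of the
#' learning stage.
#'
#' @param coeffs Numeric matrix, patches in rows, the `n^2` DCT coefficients
#'   in columns (raw signed values; absolute values are taken internally).
#' @return List of class `ccp_stats`: `mean`, `sd` (length `n^2`),
#'   `n_patches`, and `valid` (indices with positive sd; zero-variance
#'   indices are excluded from the comparison search).
#' @export
compute_coefficient_stats <- function(coeffs) {
  if (nrow(coeffs) < 2L) stop("need at least 2 patches to compute statistics")
  a <- abs(coeffs)
  mu <- colMeans(a)
  v <- colMeans(a * a) - mu^2          # population (1/N) variance
  v[v < 0] <- 0
  s <- sqrt(v)
  valid <- which(s > 0)
  if (length(valid) == 0L)
    stop("all coefficient indices have zero variance (identical patches?)")
  if (length(valid) < length(s))
    message(length(s) - length(valid),
            " zero-variance coefficient index(es) excluded from the search")
  structure(list(mean = mu, sd = s, n_patches = nrow(coeffs), valid = valid),
            class = "ccp_stats")
}

#' Normalize coefficients by pooled statistics
#'
#' @param coeffs Raw coefficient matrix (patches x `n^2`).
#' @param stats A `ccp_stats` object from [compute_coefficient_stats()].
#' @return Matrix of normalized coefficients `c_i`; zero-variance columns are
#'   set to 0.
#' @export
normalize_coefficients <- function(coeffs, stats) {
  a <- sweep(abs(coeffs), 2L, stats$mean, "-")
  s <- stats$sd
  s[s == 0] <- 1
  sweep(a, 2L, s, "/")
}

#' Class frequency of a coefficient comparison
#'
#' Fraction of patches for which `(c_i + delta) > c_j` holds (strict
#' inequality; ties contribute 0).
#'
#' @param cn Normalized-coefficient matrix of one class (patches x `n^2`).
#' @param i,j Coefficient indices (1-based), `i != j`.
#' @param delta Offset.
#' @return Frequency in \[0, 1\].
#' @export
comparison_frequency <- function(cn, i, j, delta) {
  stopifnot(i != j)
  mean((cn[, i] + delta) > cn[, j])
}

delta_grid <- function(cfg) {
  seq(cfg$delta_lo, cfg$delta_hi, by = cfg$delta_step)
}

#' Learn the most discriminative coefficient comparisons
#'
#' Exhaustive search over all ordered pairs of distinct DCT coefficient
#' indices (i, j) and all offsets delta on the configured grid for the
#' comparisons `(c_i + delta) > c_j` whose occurrence frequency differs most
#' between the two classes.  For each ordered pair the best delta is
#' retained; pairs are then ranked by descending score
#' `|freq_live - freq_spoof|` and the top `groups * b` distinct pairs are
#' returned in rank order.
#'
#' Ties are broken deterministically: over delta by the offset closest to 0
#' (the negative one first when both signs tie), over pairs by smaller i,
#' then smaller j.
#'
#' @param coeffs Raw DCT coefficient matrix of all training patches
#'   (patches x `n^2`), both classes pooled.
#' @param labels Vector of image class labels per patch: 1 = live, 0 = spoof.
#' @param cfg A [ccp_config()]; `groups * b` rules are selected.
#' @param stats Optional precomputed `ccp_stats`; defaults to pooled
#'   statistics of `coeffs`.
#' @return List of class `ccp_rules`: `rules` (data.frame with columns
#'   `i, j, delta, score`, `groups * b` rows, rank order), `stats`, `config`,
#'   and `pairs_searched`.
#' @export
search_comparisons <- function(coeffs, labels, cfg = ccp_config(),
                               stats = NULL) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be 1 (live) or 0 (spoof)")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in the training patches")
  if (is.null(stats)) stats <- compute_coefficient_stats(coeffs)
  cn <- normalize_coefficients(coeffs, stats)
  M <- length(delta_grid(cfg))
  res <- ccp_pair_search(cn[labels == 1L, , drop = FALSE],
                         cn[labels == 0L, , drop = FALSE],
                         as.integer(stats$valid),
                         cfg$delta_lo, cfg$delta_step, M)
  df <- data.frame(i = as.integer(res[, 1]), j = as.integer(res[, 2]),
                   delta = res[, 3], score = res[, 4])
  df <- df[order(-df$score, df$i, df$j), , drop = FALSE]
  need <- cfg$groups * cfg$b
  pos <- df[df$score > 0, , drop = FALSE]
  if (nrow(pos) < need)
    stop("only ", nrow(pos), " comparisons with positive score, but ",
         need, " are required; provide more training data")
  rules <- pos[seq_len(need), , drop = FALSE]
  rownames(rules) <- NULL
  structure(list(rules = rules, stats = stats, config = cfg,
                 pairs_searched = nrow(df)),
            class = "ccp_rules")
}

#' @export
print.ccp_rules <- function(x, ...) {
  cat("CCP comparison set: ", nrow(x$rules), " rules (",
      x$config$groups, " group(s) x ", x$config$b, " bit), ",
      x$pairs_searched, " ordered pairs searched\n", sep = "")
  print(utils::head(x$rules, 12L))
  if (nrow(x$rules) > 12L) cat("...\n")
  invisible(x)
}
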