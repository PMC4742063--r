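#' Fit a CCP liveness-detection model
#'
#' Trains the full pipeline on a manifest of labeled fingerprint images:
#' (1) per image, estimate (or read) the foreground mask and orientation
#' field and sample `p` patch centers uniformly at random from the eligible
#' foreground; (2) compute DCT coefficients of the rotation-invariant
#' patches, pool their statistics and learn the `groups * b` most
#' discriminative coefficient comparisons by exhaustive search; (3) compute
#' the histogram descriptor of every training image, rescale each feature to
#' \[-1, 1\] on the training range, and train a linear SVM (live = 1,
#' spoof = 0).
#'
#' @param manifest Data frame with columns `path` and `label` (1 = live,
#'   0 = spoof) and optional `mask` and `orientation` file columns, or the
#'   path of such a CSV file.
#' @param variant Histogram layout string like `"1x8"` or `"4x6"`; ignored
#'   when `config` is given.
#' @param config Optional [ccp_config()] overriding `variant`.
#' @param seed Integer seed controlling patch sampling (default 1).
#' @param progress Print progress messages (default `FALSE`).
#' @return An object of class `ccp_model`; see [predict.ccp_model()],
#'   [write_ccp_model()].
#' @examples
#' \donttest{
#' dir <- tempfile()
#' ds <- synth_dataset(dir, n_live = 8, n_spoof = 8,
#'                     cfg = synth_config(size = 96), seed = 1)
#' fit <- ccp_fit(ds, config = ccp_config(b = 4, p = 300), seed = 1)
#' print(fit)
#' }
#' @export
ccp_fit <- function(manifest, variant = "1x8", config = NULL, seed = 1,
                    progress = FALSE) {
  manifest <- as_manifest(manifest)
  cfg <- if (is.null(config)) ccp_variant(variant) else config
  if (length(unique(manifest$label)) < 2L)
    stop("training manifest must contain both classes (labels 0 and 1)")
  set.seed(as.integer(seed))
  # per-image sampling seeds drawn up-front so sampling is reproducible and
  # independent of per-image patch counts
  img_seeds <- sample.int(.Machine$integer.max, nrow(manifest))

  coeffs <- vector("list", nrow(manifest))
  for (k in seq_len(nrow(manifest))) {
    inp <- load_manifest_row(manifest, k, cfg)
    set.seed(img_seeds[k])
    centers <- sample_patch_centers(inp$mask, cfg$p, cfg$n)
    theta <- if (inherits(inp$of, "orientation_field")) inp$of$theta else inp$of
    coeffs[[k]] <- extract_patch_coeffs(inp$img, centers, theta[centers],
                                        cfg$n)
    if (progress && k %% 25L == 0L)
      message("sampled patches from ", k, "/", nrow(manifest), " images")
  }
  patch_labels <- rep(manifest$label, each = cfg$p)
  ruleset <- search_comparisons(do.call(rbind, coeffs), patch_labels, cfg)
  rm(coeffs)

  if (progress) message("computing training descriptors")
  feats <- describe_manifest(manifest, ruleset, progress)
  scaler <- fit_feature_scaler(feats)
  sc <- apply_feature_scaler(feats, scaler)
  svm_par <- train_linear_svm(sc, manifest$label, cost = cfg$cost)

  model <- structure(list(ruleset = ruleset, scaler = scaler,
                          weights = svm_par$w, bias = svm_par$b,
                          config = cfg, seed = as.integer(seed),
                          index_layout = "row-major (i = u*n + v + 1, DC = 1)",
                          n_train = nrow(manifest)),
                     class = "ccp_model")
  model$train_accuracy <- liveness_metrics(predict(model, feats,
                                                   type = "class"),
                                           manifest$label)$accuracy
  model
}

as_manifest <- function(manifest) {
  if (is.character(manifest) && length(manifest) == 1L)
    manifest <- read.csv(manifest, check.names = FALSE)
  manifest <- as.data.frame(manifest)
  if (!all(c("path", "label") %in% names(manifest)))
    stop("manifest needs columns 'path' and 'label'")
  manifest$label <- as.integer(manifest$label)
  if (!all(manifest$label %in% c(0L, 1L)))
    stop("labels must be 1 (live) or 0 (spoof)")
  manifest
}

#' Rescale features to the \[-1, 1\] training range
#'
#' Per-feature affine map sending the training minimum to -1 and the training
#' maximum to +1.  Constant features map to 0.  Test-set values outside the
#' training range pass through unclipped.
#'
#' @param features Training feature matrix (images x features).
#' @return A list of class `ccp_scaler` with `min` and `max` vectors.
#' @export
fit_feature_scaler <- function(features) {
  structure(list(min = apply(features, 2L, min),
                 max = apply(features, 2L, max)),
            class = "ccp_scaler")
}

#' @rdname fit_feature_scaler
#' @param scaler A `ccp_scaler`.
#' @export
apply_feature_scaler <- function(features, scaler) {
  features <- rbind(features)
  rng <- scaler$max - scaler$min
  out <- sweep(features, 2L, scaler$min, "-")
  out <- sweep(out, 2L, ifelse(rng > 0, rng, 1), "/") * 2 - 1
  out[, rng == 0] <- 0
  out
}

# Linear SVM (C-classification, LIBSVM backend) reduced to its primal form:
# returns w, b with  w . x + b > 0  <=>  predicted live (label 1).
train_linear_svm <- function(x, labels, cost = 1) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to train the SVM")
  fit <- e1071::svm(x, factor(labels, levels = c(0L, 1L)),
                    kernel = "linear", cost = cost, scale = FALSE)
  w <- as.vector(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # orient (w, b) so that  w . x + b > 0  predicts 'live', by agreement with
  # the SVM's own training predictions (LIBSVM's internal sign convention
  # depends on the class order it saw)
  dec <- as.vector(x %*% w) + b
  agree <- mean((dec > 0) == (predict(fit, x) == "1"))
  if (agree < 0.5) { w <- -w; b <- -b }
  list(w = w, b = b, svm = fit)
}

#' Predict liveness for new images or feature vectors
#'
#' @param object A fitted `ccp_model`.
#' @param newdata A manifest data frame (or CSV path) of images, or a numeric
#'   matrix of raw (unscaled) descriptor vectors as produced by
#'   [describe_image()].
#' @param type `"class"` for hard 0/1 labels (1 = live), `"decision"` for
#'   linear decision values `w . x + b`, `"feature"` for the raw descriptor
#'   matrix.
#' @param ... Unused.
#' @return Vector of labels or decision values, or the feature matrix.
#' @export
predict.ccp_model <- function(object, newdata,
                              type = c("class", "decision", "feature"), ...) {
  type <- match.arg(type)
  feats <- if (is.matrix(newdata)) newdata
           else describe_manifest(as_manifest(newdata), object$ruleset)
  if (type == "feature") return(feats)
  dec <- as.vector(apply_feature_scaler(feats, object$scaler) %*%
                     object$weights) + object$bias
  if (type == "decision") dec else as.integer(dec > 0)
}

#' Liveness-detection evaluation metrics
#'
#' Computes the standard presentation-attack detection metrics: accuracy
#' `a = D/N` (D correct decisions out of N), NPCER (FerrLive; proportion of
#' live samples misclassified as spoof), APCER (FerrFake; proportion of spoof
#' samples misclassified as live) and `HTER = (NPCER + APCER)/2`.  On a
#' balanced test set `a = 1 - HTER` holds exactly.
#'
#' @param pred Predicted labels (1 = live, 0 = spoof).
#' @param truth True labels.
#' @return List of class `ccp_metrics`: `D`, `N`, `accuracy`, `npcer`,
#'   `apcer`, `hter`.
#' @export
liveness_metrics <- function(pred, truth) {
  pred <- as.integer(pred); truth <- as.integer(truth)
  if (length(pred) != length(truth)) stop("pred and truth differ in length")
  if (length(pred) == 0L) stop("empty prediction set")
  n_live <- sum(truth == 1L); n_spoof <- sum(truth == 0L)
  out <- list(
    D = sum(pred == truth), N = length(truth),
    accuracy = mean(pred == truth),
    npcer = if (n_live > 0L) sum(truth == 1L & pred == 0L) / n_live else NA_real_,
    apcer = if (n_spoof > 0L) sum(truth == 0L & pred == 1L) / n_spoof else NA_real_
  )
  out$hter <- (out$npcer + out$apcer) / 2
  structure(out, class = "ccp_metrics")
}

#' @export
print.ccp_metrics <- function(x, ...) {
  cat(sprintf(
    "liveness metrics: accuracy %.4f (%d/%d)\n  NPCER (FerrLive) %.4f  APCER (FerrFake) %.4f  HTER %.4f\n",
    x$accuracy, x$D, x$N, x$npcer, x$apcer, x$hter))
  invisible(x)
}

#' @export
print.ccp_model <- function(x, ...) {
  cfg <- x$config
  cat("CCP liveness model (", cfg$groups, "x", cfg$b, " bit, n = ", cfg$n,
      ", ", feature_length(cfg), " features)\n", sep = "")
  cat("  trained on ", x$n_train, " images, p = ", cfg$p,
      " patches/image, seed ", x$seed, "\n", sep = "")
  if (!is.null(x$train_accuracy))
    cat(sprintf("  training accuracy %.3f\n", x$train_accuracy))
  cat("  top rule: (i = ", x$ruleset$rules$i[1], ", j = ",
      x$ruleset$rules$j[1], ", delta = ",
      format(x$ruleset$rules$delta[1]), "), score ",
      sprintf("%.3f", x$ruleset$rules$score[1]), "\n", sep = "")
  invisible(x)
}

#' @export
summary.ccp_model <- function(object, ...) {
  print(object)
  cat("\ncomparison rules (rank order):\n")
  print(object$ruleset$rules)
  invisible(object)
}

#' @export
coef.ccp_model <- function(object, ...) {
  list(rules = object$ruleset$rules,
       svm_weights = object$weights, svm_bias = object$bias)
}

#' @export
plot.ccp_model <- function(x, ...) {
  graphics::barplot(x$ruleset$rules$score,
                    names.arg = paste0(x$ruleset$rules$i, ">",
                                       x$ruleset$rules$j),
                    las = 2, ylab = "|freq_live - freq_spoof|",
                    main = "learned comparison scores", ...)
  invisible(x)
}

#' Serialize a CCP model to a portable JSON file
#'
#' The model file records the configuration, the DCT index-layout tag, the
#' pooled coefficient statistics, the ordered rule list, the feature-scaling
#' range and the linear SVM weights, with full floating-point precision, so
#' that a reloaded model reproduces predictions exactly.
#'
#' @param model A `ccp_model`.
#' @param path Output path.
#' @return `path` (writer) or the restored `ccp_model` (reader).
#' @export
write_ccp_model <- function(model, path) {
  # doubles are written as %.17g strings: 17 significant digits round-trip
  # IEEE doubles exactly, which plain JSON number formatting does not
  num <- function(x) sprintf("%.17g", x)
  obj <- list(
    format = "ccp-model-1",
    index_layout = model$index_layout,
    config = unclass(model$config),
    seed = model$seed, n_train = model$n_train,
    train_accuracy = model$train_accuracy,
    stats = list(mean = num(model$ruleset$stats$mean),
                 sd = num(model$ruleset$stats$sd),
                 n_patches = model$ruleset$stats$n_patches,
                 valid = model$ruleset$stats$valid),
    rules = list(i = model$ruleset$rules$i, j = model$ruleset$rules$j,
                 delta = num(model$ruleset$rules$delta),
                 score = num(model$ruleset$rules$score)),
    pairs_searched = model$ruleset$pairs_searched,
    scaler = list(min = num(model$scaler$min), max = num(model$scaler$max)),
    svm = list(weights = num(model$weights), bias = num(model$bias))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ccp_model
#' @export
read_ccp_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("not a CCP model file: ", path, call. = FALSE))
  if (is.null(obj$format) || obj$format != "ccp-model-1")
    stop("not a CCP model file: ", path)
  cfg <- do.call(ccp_config, obj$config)
  stats <- structure(list(mean = as.numeric(obj$stats$mean),
                          sd = as.numeric(obj$stats$sd),
                          n_patches = obj$stats$n_patches,
                          valid = as.integer(obj$stats$valid)),
                     class = "ccp_stats")
  rules <- data.frame(i = as.integer(obj$rules$i),
                      j = as.integer(obj$rules$j),
                      delta = as.numeric(obj$rules$delta),
                      score = as.numeric(obj$rules$score))
  ruleset <- structure(list(rules = rules,
                            stats = stats, config = cfg,
                            pairs_searched = obj$pairs_searched),
                       class = "ccp_rules")
  structure(list(ruleset = ruleset,
                 scaler = structure(list(min = as.numeric(obj$scaler$min),
                                         max = as.numeric(obj$scaler$max)),
                                    class = "ccp_scaler"),
                 weights = as.numeric(obj$svm$weights),
                 bias = as.numeric(obj$svm$bias),
                 config = cfg, seed = obj$seed,
                 index_layout = obj$index_layout,
                 n_train = obj$n_train,
                 train_accuracy = obj$train_accuracy),
            class = "ccp_model")
}
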