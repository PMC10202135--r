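# Sim-to-real domain gap: feature extraction, 2-D embedding, and a
# centroid-to-centroid Euclidean dataset distance on standardized features.

#' Handcrafted image features
#'
#' The default extractor concatenates per-channel 16-bin colour histograms
#' (48), an 8-bin gradient-orientation histogram weighted by gradient
#' magnitude (8), and 5 texture-energy statistics (mean gradient magnitude,
#' grey-level standard deviation, grey histogram entropy, grey histogram
#' energy, mean local variance), giving a fixed d = 61 vector per image. Any
#' external extractor satisfying the plug-in contract (image -> fixed-length
#' numeric vector) can be supplied instead.
#'
#' @param images List of H x W x 3 arrays in \[0, 1\] (or `rendered_frame`s).
#' @param extractor `"handcrafted"` or a `function(image)` returning a
#'   fixed-length numeric vector.
#' @return A `feature_matrix`: numeric matrix (one row per image) with
#'   attributes `extractor`.
#' @export
extract_features <- function(images, extractor = "handcrafted") {
  if (length(images) == 0)
    abort("`images` must be non-empty.", class = "wheattips_invalid_parameter")
  images <- map(images, function(im)
    if (inherits(im, "rendered_frame")) im$rgb else im)
  chans <- map_int(images, function(im) dim(im)[3])
  if (length(unique(chans)) != 1)
    abort("All images must have the same channel count.",
          class = "wheattips_invalid_parameter")
  fun <- if (is.function(extractor)) extractor else handcrafted_features
  rows <- map(images, fun)
  d <- unique(map_int(rows, length))
  if (length(d) != 1)
    abort("Extractor returned vectors of differing length.",
          class = "wheattips_invalid_parameter")
  M <- do.call(rbind, rows)
  attr(M, "extractor") <- if (is.function(extractor)) "custom" else extractor
  class(M) <- c("feature_matrix", class(M))
  M
}

handcrafted_features <- function(im) {
  breaks <- seq(0, 1, length.out = 17)
  clamp01 <- function(x) pmin(pmax(x, 0), 1 - 1e-9)
  hists <- unlist(lapply(1:3, function(k) {
    h <- tabulate(findInterval(clamp01(as.vector(im[, , k])), breaks,
                               rightmost.closed = TRUE), nbins = 16)
    h / sum(h)
  }))
  g <- 0.299 * im[, , 1] + 0.587 * im[, , 2] + 0.114 * im[, , 3]
  H <- nrow(g); W <- ncol(g)
  gx <- cbind(g[, 2:W], g[, W]) - cbind(g[, 1], g[, 1:(W - 1)])
  gy <- rbind(g[2:H, ], g[H, ]) - rbind(g[1, ], g[1:(H - 1), ])
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)  # (-pi, pi]
  bin <- pmin(floor((ang + pi) / (2 * pi) * 8) + 1, 8)
  ghist <- vapply(1:8, function(b) sum(mag[bin == b]), 0)
  tot <- sum(ghist)
  ghist <- if (tot > 0) ghist / tot else rep(0, 8)
  gh <- tabulate(findInterval(clamp01(as.vector(g)), breaks,
                              rightmost.closed = TRUE), nbins = 16)
  p <- gh / sum(gh)
  entropy <- -sum(ifelse(p > 0, p * log(p), 0))
  # mean local variance over 8x8 blocks
  bh <- floor(H / 8); bw <- floor(W / 8)
  lv <- 0
  if (bh > 0 && bw > 0) {
    sub <- g[1:(8 * bh), 1:(8 * bw)]
    dim(sub) <- c(8, bh, 8, bw)
    lv <- mean(apply(sub, c(2, 4), stats::var))
  }
  c(hists, ghist, mean(mag), sd(as.vector(g)), entropy, sum(p^2), lv)
}

#' 2-D embedding of a feature matrix (t-SNE)
#'
#' t-distributed stochastic neighbour embedding of the image features,
#' deterministic given `seed`. The final KL divergence of the embedding is
#' attached as an attribute.
#'
#' @param features A `feature_matrix` (>= 5 rows).
#' @param perplexity t-SNE perplexity; clamped below `(rows - 1) / 3`.
#' @param seed Integer seed.
#' @return A tibble with columns `dim1`, `dim2` (attributes `kl_divergence`,
#'   `seed`).
#' @export
embed_2d <- function(features, perplexity = 30, seed = 1L) {
  n <- nrow(features)
  if (n < 5)
    abort("t-SNE embedding needs at least 5 rows.",
          class = "wheattips_invalid_parameter")
  perp <- min(perplexity, (n - 1) / 3 - 1e-9)
  set.seed(seed)
  fit <- Rtsne::Rtsne(as.matrix(unclass(features)), dims = 2,
                      perplexity = perp, check_duplicates = FALSE,
                      pca = FALSE, verbose = FALSE, max_iter = 500)
  out <- tibble(dim1 = fit$Y[, 1], dim2 = fit$Y[, 2])
  attr(out, "kl_divergence") <- utils::tail(fit$itercosts, 1)
  attr(out, "seed") <- seed
  out
}

#' Euclidean distance between two image datasets
#'
#' Each feature dimension is standardized over the union of both sets (zero
#' s.d. dimensions contribute nothing), then the Euclidean distance between
#' the two set centroids is returned: sqrt(sum_i (xbar_i - ybar_i)^2). With
#' `space = "embedding"` the same is computed on jointly embedded 2-D t-SNE
#' coordinates instead of raw features.
#'
#' @param A,B `feature_matrix` objects from the same extractor.
#' @param space `"feature"` (default) or `"embedding"`.
#' @param standardize Standardize dimensions before taking centroids.
#' @param seed Seed for the embedding variant.
#' @return A non-negative scalar distance.
#' @export
dataset_distance <- function(A, B, space = c("feature", "embedding"),
                             standardize = TRUE, seed = 1L) {
  space <- match.arg(space)
  if (ncol(A) != ncol(B))
    abort("Feature dimensions differ between datasets.",
          class = "wheattips_invalid_parameter")
  X <- rbind(as.matrix(unclass(A)), as.matrix(unclass(B)))
  nA <- nrow(A)
  if (space == "embedding") {
    emb <- embed_2d(structure(X, class = c("feature_matrix", "matrix")),
                    seed = seed)
    X <- cbind(emb$dim1, emb$dim2)
  }
  if (standardize) {
    mu <- colMeans(X)
    sdev <- apply(X, 2, sd)
    sdev[sdev < 1e-12] <- Inf  # constant dims contribute 0
    X <- sweep(sweep(X, 2, mu, "-"), 2, sdev, "/")
  }
  ca <- colMeans(X[seq_len(nA), , drop = FALSE])
  cb <- colMeans(X[-seq_len(nA), , drop = FALSE])
  sqrt(sum((ca - cb)^2))
}
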