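#' Feature extractor specification
#'
#' Describes how gray-level recurrence-plot images are turned into fixed
#' length feature vectors. Three backends exist:
#' \describe{
#'   \item{`tiny-cnn-test`}{a small fixed random convolutional network:
#'     one valid convolution with seeded Gaussian filters, ReLU, then mean
#'     pooling over a `pool_grid x pool_grid` spatial grid. Deterministic
#'     given the seed; requires no downloads. Feature length is
#'     `n_filters * pool_grid^2`.}
#'   \item{`random-projection-test`}{flattened pixels times a seeded
#'     Gaussian projection matrix; deterministic, length `output_dim`.}
#'   \item{`alexnet-fc7`}{activations of the penultimate fully connected
#'     layer (4096-d) of a pretrained AlexNet. Pretrained weights are not
#'     bundled and no deep-learning runtime is assumed, so this backend
#'     raises an actionable error; the test backends are the offline
#'     substitutes.}
#' }
#'
#' @param backend one of `"tiny-cnn-test"`, `"random-projection-test"`,
#'   `"alexnet-fc7"`.
#' @param input_size expected image side length in pixels (images of a
#'   different size are resampled by [prepare_input()]).
#' @param seed seed from which deterministic backend weights are drawn.
#' @param n_filters,kernel_size,pool_grid tiny-cnn architecture knobs.
#' @param output_dim random-projection feature length.
#' @return object of class `feature_extractor_spec`.
#' @export
feature_extractor <- function(backend = c("tiny-cnn-test",
                                          "random-projection-test",
                                          "alexnet-fc7"),
                              input_size = 227, seed = 42L,
                              n_filters = 8L, kernel_size = 5L,
                              pool_grid = 4L, output_dim = 64L) {
  backend <- match.arg(backend)
  if (!is_count(input_size) || input_size < kernel_size)
    stop_invalid("input_size must be an integer >= kernel_size")
  spec <- list(backend = backend, input_size = as.integer(input_size),
               seed = as.integer(seed), deterministic = TRUE,
               normalization = "none", weights_source = "seeded-rng")
  if (backend == "tiny-cnn-test") {
    spec$n_filters <- as.integer(n_filters)
    spec$kernel_size <- as.integer(kernel_size)
    spec$pool_grid <- as.integer(pool_grid)
    spec$output_dim <- as.integer(n_filters * pool_grid^2)
    spec$filters <- local_seed_eval(seed, {
      array(stats::rnorm(kernel_size^2 * n_filters),
            dim = c(kernel_size, kernel_size, n_filters))
    })
  } else if (backend == "random-projection-test") {
    spec$output_dim <- as.integer(output_dim)
    spec$projection <- local_seed_eval(seed, {
      matrix(stats::rnorm(input_size^2 * output_dim),
             input_size^2, output_dim)
    })
  } else {
    spec$output_dim <- 4096L
    spec$deterministic <- TRUE
    spec$normalization <- "imagenet"
    spec$weights_source <- "pretrained-download"
  }
  structure(spec, class = "feature_extractor_spec")
}

#' @export
print.feature_extractor_spec <- function(x, ...) {
  cat(sprintf("<feature_extractor %s> input %dx%d, %d features, seed %d\n",
              x$backend, x$input_size, x$input_size, x$output_dim, x$seed))
  invisible(x)
}

#' Prepare an image for a feature extractor
#'
#' Resamples the gray-level image to the extractor's input size if needed
#' and replicates it over three channels (convolutional backbones expect RGB
#' input; the recurrence-plot images are single channel). The tiny test
#' backends apply no further normalization; the AlexNet backend records the
#' standard ImageNet channel normalization.
#'
#' @param image matrix in `[0, 1]`.
#' @param spec a [feature_extractor()].
#' @return array of dimension `c(input_size, input_size, 3)`.
#' @export
prepare_input <- function(image, spec) {
  stopifnot(inherits(spec, "feature_extractor_spec"))
  if (!is.matrix(image) || length(image) == 0)
    stop_invalid("image must be a nonempty matrix")
  if (min(image) < -1e-12 || max(image) > 1 + 1e-12)
    stop_invalid("image values must lie in [0, 1]")
  s <- spec$input_size
  if (nrow(image) != s || ncol(image) != s)
    image <- unclass(rp_to_image(image, s))
  arr <- array(rep(as.numeric(image), 3), dim = c(s, s, 3))
  if (spec$normalization == "imagenet") {
    mu <- c(0.485, 0.456, 0.406); sdv <- c(0.229, 0.224, 0.225)
    for (c in 1:3) arr[, , c] <- (arr[, , c] - mu[c]) / sdv[c]
  }
  arr
}

#' Extract deep features from a list of images
#'
#' One feature row per image, with labels and subject groups carried along.
#' Deterministic backends produce bit-identical output on identical input.
#'
#' @param images list of gray-level matrices in `[0, 1]`.
#' @param spec a [feature_extractor()].
#' @param labels,groups optional vectors aligned with `images`.
#' @return a [feature_matrix()].
#' @export
extract_features <- function(images, spec, labels = NULL, groups = NULL) {
  stopifnot(inherits(spec, "feature_extractor_spec"))
  if (length(images) == 0) stop_invalid("images must be a nonempty list")
  if (spec$backend == "alexnet-fc7")
    stop_invalid(paste0(
      "backend 'alexnet-fc7' needs pretrained weights and a CNN runtime, ",
      "neither of which is bundled; use backend 'tiny-cnn-test' or ",
      "'random-projection-test' for fully offline feature extraction"))
  F <- t(vapply(images, function(im) {
    arr <- prepare_input(if (is.matrix(im)) im else as.matrix(im), spec)
    gray <- (arr[, , 1] + arr[, , 2] + arr[, , 3]) / 3
    switch(spec$backend,
           "tiny-cnn-test" = tiny_cnn_features(gray, spec),
           "random-projection-test" = as.numeric(
             matrix(as.vector(t(gray)), 1) %*% spec$projection))
  }, numeric(spec$output_dim)))
  if (spec$output_dim == 1) F <- matrix(F, ncol = 1)
  feature_matrix(F, labels = labels, groups = groups, meta = spec)
}

# conv (valid, seeded filters) -> ReLU -> grid mean pooling
tiny_cnn_features <- function(gray, spec) {
  k <- spec$kernel_size
  patches <- im2col(gray, k)
  Wf <- matrix(spec$filters, k * k, spec$n_filters)
  resp <- pmax(patches %*% Wf, 0)
  oh <- nrow(gray) - k + 1
  ow <- ncol(gray) - k + 1
  Gr <- grid_pool_matrix(oh, spec$pool_grid)
  Gc <- grid_pool_matrix(ow, spec$pool_grid)
  out <- numeric(0)
  for (f in seq_len(spec$n_filters)) {
    R <- matrix(resp[, f], oh, ow)
    out <- c(out, as.vector(Gr %*% R %*% t(Gc)))
  }
  out
}

# All k x k patches of m as rows (column-major scan of valid positions).
im2col <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  oh <- h - k + 1; ow <- w - k + 1
  base <- as.vector(outer(seq_len(oh), (seq_len(ow) - 1) * h, "+"))
  off <- as.vector(outer(seq_len(k) - 1, (seq_len(k) - 1) * h, "+"))
  patches <- matrix(0, oh * ow, k * k)
  for (j in seq_along(off)) patches[, j] <- m[base + off[j]]
  patches
}

# g x n averaging matrix partitioning n positions into g contiguous bins.
grid_pool_matrix <- function(n, g) {
  edges <- floor(seq(0, n, length.out = g + 1))
  W <- matrix(0, g, n)
  for (i in seq_len(g)) {
    a <- edges[i] + 1; b <- max(edges[i + 1], a)
    W[i, a:b] <- 1 / (b - a + 1)
  }
  W
}

#' Feature matrix with aligned labels and groups
#'
#' @param F numeric matrix, samples x features, finite.
#' @param labels optional class labels (coerced to factor), one per row.
#' @param groups optional subject ids, one per row.
#' @param meta optional provenance (e.g. the extractor spec).
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(F, labels = NULL, groups = NULL, meta = NULL) {
  if (!is.matrix(F)) F <- as.matrix(F)
  if (!all(is.finite(F))) stop_invalid("features must be finite")
  if (!is.null(labels) && length(labels) != nrow(F))
    stop_invalid("labels length %d != %d rows", length(labels), nrow(F))
  if (!is.null(groups) && length(groups) != nrow(F))
    stop_invalid("groups length %d != %d rows", length(groups), nrow(F))
  structure(list(F = F,
                 labels = if (!is.null(labels)) factor(labels),
                 groups = groups, meta = meta),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d samples x %d features%s\n",
              nrow(x$F), ncol(x$F),
              if (!is.null(x$labels))
                sprintf(", %d class(es)", nlevels(x$labels)) else ""))
  invisible(x)
}
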