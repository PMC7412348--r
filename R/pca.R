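#' Full-principal-component model of a pixel matrix
#'
#' Fits the eigenvectors of `C = t(X) %*% X` (the uncentered scatter of the
#' flattened gray-level images; one image per row of `X`). All components of
#' the nonzero spectrum are retained -- the transform is an isometry of the
#' row space, used downstream as feature enhancement rather than dimension
#' reduction. Numerically the thin SVD of `X` is used, which solves the
#' small dual problem instead of materializing the m x m matrix `C`
#' (m = resolution^2 can exceed 50,000); the result provably agrees with the
#' direct eigendecomposition of `C` on its nonzero spectrum.
#'
#' No mean is subtracted by default: the scatter matrix is literally
#' `t(X) %*% X`. Set `center = TRUE` for conventional covariance PCA.
#'
#' @param X numeric matrix, images x pixels, at least 2 rows.
#' @param center subtract column means first (default `FALSE`).
#' @return object of class `pixel_pca`: list with `W` (m x r orthonormal
#'   eigenvector matrix), `eigenvalues` (descending, length r), `rank`,
#'   `center`, `means`, `m`.
#' @export
fit_pixel_pca <- function(X, center = FALSE) {
  if (!is.matrix(X) || nrow(X) < 2 || ncol(X) < 1)
    stop_invalid("X must be a matrix with >= 2 rows")
  if (!all(is.finite(X))) stop_invalid("X must be finite")
  means <- if (center) colMeans(X) else numeric(ncol(X))
  Xc <- if (center) sweep(X, 2, means) else X
  sv <- svd(Xc)
  ev <- sv$d^2
  tol <- max(sv$d) * max(dim(Xc)) * .Machine$double.eps
  r <- sum(sv$d > tol)
  structure(list(W = sv$v, eigenvalues = ev, rank = r,
                 center = center, means = means, m = ncol(X)),
            class = "pixel_pca")
}

#' @export
print.pixel_pca <- function(x, ...) {
  cat(sprintf("<pixel_pca> m = %d pixels, %d component(s), rank %d, %s\n",
              x$m, length(x$eigenvalues), x$rank,
              if (x$center) "centered" else "uncentered"))
  invisible(x)
}

#' Project a pixel matrix onto its principal components
#'
#' `F = X %*% W`. With the full nonzero spectrum retained the projection is
#' information preserving: `F %*% t(W)` recovers `X` to numerical precision
#' and row norms are unchanged.
#'
#' @param model a [fit_pixel_pca()] result.
#' @param X matrix with `model$m` columns.
#' @return samples x components score matrix.
#' @export
apply_pixel_pca <- function(model, X) {
  stopifnot(inherits(model, "pixel_pca"))
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != model$m)
    stop_invalid("X has %d columns but the model expects %d", ncol(X), model$m)
  Xc <- if (model$center) sweep(X, 2, model$means) else X
  Xc %*% model$W
}

#' Fold principal-component scores back into images
#'
#' Each score row is folded row-major into a `resolution x resolution`
#' matrix, zero-padded on the right when the score length is below
#' `resolution^2` (rank-deficient spectra), then min--max rescaled to
#' `[0, 1]` per image so downstream feature extractors receive bounded
#' inputs. An all-constant row rescales to the all-zero image by convention.
#'
#' @param F score matrix (one sample per row).
#' @param resolution image side length; `ncol(F)` must not exceed
#'   `resolution^2`.
#' @param rescale apply the per-image min--max rescale (default `TRUE`).
#' @return list of `rp_image` matrices.
#' @export
scores_to_images <- function(F, resolution, rescale = TRUE) {
  if (!is.matrix(F)) F <- matrix(F, nrow = 1)
  m <- resolution^2
  if (ncol(F) > m)
    stop_invalid("score length %d exceeds resolution^2 = %d", ncol(F), m)
  lapply(seq_len(nrow(F)), function(i) {
    v <- c(F[i, ], numeric(m - ncol(F)))
    img <- matrix(v, nrow = resolution, byrow = TRUE)
    if (rescale) {
      rng <- range(img)
      img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1])
             else matrix(0, resolution, resolution)
    }
    structure(img, class = c("rp_image", "matrix"),
              resolution = as.integer(resolution))
  })
}

#' Flatten images into a pixel matrix
#'
#' Row-major flattening, the inverse of [scores_to_images()] with rescaling
#' disabled.
#'
#' @param images list of equally sized matrices in `[0, 1]`.
#' @return images x pixels matrix.
#' @export
images_to_matrix <- function(images) {
  stopifnot(length(images) >= 1)
  rows <- lapply(images, function(im) as.vector(t(unclass(im))))
  do.call(rbind, rows)
}
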