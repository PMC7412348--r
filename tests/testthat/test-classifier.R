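make_clusters <- function(n = 20, sep = 4, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n), n, 2),
             matrix(rnorm(2 * n) + sep, n, 2))
  list(x = x, y = factor(rep(c("a", "b"), each = n)))
}

test_that("prepare_input replicates gray images across three channels", {
  spec <- feature_extractor("tiny-cnn-test", input_size = 16)
  img <- matrix(runif(16 * 16), 16, 16)
  arr <- prepare_input(img, spec)
  expect_equal(dim(arr), c(16, 16, 3))
  expect_identical(arr[, , 1], arr[, , 2])
  expect_identical(arr[, , 2], arr[, , 3])
  expect_equal(arr[, , 1], img, ignore_attr = TRUE)
  # all-black image stays all-minimum under the test backends (no norm)
  expect_true(all(prepare_input(matrix(0, 16, 16), spec) == 0))
  # resize path agrees with rp_to_image on a shared matrix
  big <- matrix(runif(32 * 32), 32, 32)
  expect_equal(prepare_input(big, spec)[, , 1],
               unclass(rp_to_image(big, 16)), ignore_attr = TRUE)
  expect_error(prepare_input(matrix(2, 4, 4), spec), "\\[0, 1\\]")
})

test_that("deterministic backends satisfy their shape and identity contracts", {
  spec <- feature_extractor("tiny-cnn-test", input_size = 16,
                            n_filters = 4, pool_grid = 2)
  imgs <- lapply(1:3, function(i) matrix(runif(256, 0, 1), 16, 16))
  fm <- extract_features(imgs, spec)
  expect_equal(dim(fm$F), c(3, 4 * 4))
  fm2 <- extract_features(imgs, spec)
  expect_identical(fm$F, fm2$F)
  # duplicated images give duplicated rows
  fm3 <- extract_features(list(imgs[[1]], imgs[[1]]), spec)
  expect_identical(fm3$F[1, ], fm3$F[2, ])
})

test_that("random projection equals the explicit seeded matrix product", {
  spec <- feature_extractor("random-projection-test", input_size = 8,
                            seed = 123, output_dim = 5)
  img <- matrix(runif(64), 8, 8)
  fm <- extract_features(list(img), spec)
  # rebuild the projection independently from the seed
  P <- local({
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(123)
    M <- matrix(rnorm(64 * 5), 64, 5)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    M
  })
  expect_equal(fm$F[1, ], as.numeric(matrix(as.vector(t(img)), 1) %*% P),
               tolerance = 1e-12)
})

test_that("the alexnet backend fails with an actionable offline message", {
  spec <- feature_extractor("alexnet-fc7")
  expect_equal(spec$output_dim, 4096L)
  expect_error(extract_features(list(matrix(0.5, 227, 227)), spec),
               "tiny-cnn-test")
})

test_that("linearly separable clusters are fit perfectly", {
  d <- make_clusters()
  model <- train_svm(d$x, d$y)
  expect_equal(as.character(predict(model, d$x)), as.character(d$y))
  # decision scores are signed toward the first level
  sc <- predict(model, d$x, type = "score")
  expect_true(all(sc[d$y == "a"] > 0) && all(sc[d$y == "b"] < 0))
})

test_that("label permutation permutes predictions identically", {
  d <- make_clusters(seed = 7)
  m1 <- train_svm(d$x, d$y)
  swapped <- factor(ifelse(d$y == "a", "b", "a"), levels = c("a", "b"))
  m2 <- train_svm(d$x, swapped)
  p1 <- as.character(predict(m1, d$x))
  p2 <- as.character(predict(m2, d$x))
  expect_identical(p1, ifelse(p2 == "a", "b", "a"))
})

test_that("a linear kernel cannot solve XOR beyond 3 of 4 points", {
  x <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  y <- factor(c("a", "b", "b", "a"))
  model <- train_svm(x, y, svm_spec(C = 100))
  acc <- mean(predict(model, x) == y)
  expect_lte(acc, 0.75)
})

test_that("training and prediction contracts hold", {
  d <- make_clusters()
  expect_error(train_svm(d$x, factor(rep("a", nrow(d$x)))), "single class")
  model <- train_svm(d$x, d$y)
  expect_error(predict(model, matrix(0, 2, 5)), "features")
  expect_length(predict(model, d$x[0, , drop = FALSE]), 0)
  # repeated prediction is identical (deterministic end to end)
  expect_identical(predict(model, d$x), predict(model, d$x))
  # multiclass one-vs-one voting
  set.seed(3)
  x3 <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20) + 5, 10),
              matrix(cbind(rnorm(10), rnorm(10) + 5), 10))
  y3 <- factor(rep(c("a", "b", "c"), each = 10))
  m3 <- train_svm(x3, y3)
  expect_equal(mean(predict(m3, x3) == y3), 1)
  expect_error(predict(m3, x3, type = "score"), "binary")
})
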