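# The window classifier: architecture validation, training behavior,
# inference contracts, and persistence.

test_that("architecture construction matches the search-space rules", {
  a <- cnn_arch()
  expect_equal(a$n_conv, 3L)
  expect_equal(a$filters, rep(32L, 3))
  expect_equal(a$dense, 32L)
  b <- cnn_arch(n_conv = 2, filters = 8, form = "increasing")
  expect_equal(b$filters, c(8L, 16L))
  expect_gt(b$filters[2], b$filters[1])
  d <- cnn_arch(n_conv = 3, filters = 64, form = "decreasing")
  expect_equal(d$filters, c(64L, 32L, 16L))
  expect_error(cnn_arch(n_conv = 0), "at least one")
  expect_warning(cnn_arch(n_conv = 6), "search space")
  expect_error(cnn_arch(dense = c(16, 16, 16)), "dense")
  expect_error(cnn_arch(n_classes = 1), "classes")
})

test_that("the layer stack matches the architecture and rejects
          over-pooling", {
  p <- sweepcnn:::init_params(cnn_arch(), c(20, 50))
  expect_length(p$conv, 3)
  expect_equal(dim(p$conv[[1]]$K), c(3, 3, 1, 32))
  expect_equal(dim(p$conv[[2]]$K), c(3, 3, 32, 32))
  # widths 50 -> 25 -> 12 -> 6; flattened feature size 20 * 6 * 32
  expect_equal(dim(p$dense[[1]]$W), c(32, 20 * 6 * 32))
  expect_equal(dim(p$dense[[2]]$W), c(2, 32))
  expect_error(sweepcnn:::init_params(cnn_arch(n_conv = 5), c(20, 20)),
               "pooling layer 5")
})

test_that("separable toy classes reach ceiling accuracy (brute-force
          pixel-mean oracle first)", {
  tv <- toy_images(200)
  # oracle: a pixel-mean threshold classifier is perfect on this data
  mu <- apply(tv$images, 3, mean)
  oracle <- ifelse(mu > 60, "selection", "neutral")
  expect_equal(mean(oracle == tv$labels), 1.0)
  m <- get_toy_model()
  expect_gte(max(m$history$val_acc), 0.99)
})

test_that("training validates its inputs", {
  tv <- toy_images(40)
  expect_error(fit_sweep_cnn(tv$images, rep("neutral", 40)),
               "at least 2 classes")
  expect_error(fit_sweep_cnn(tv$images, tv$labels, epochs = 0), "epochs")
  expect_error(fit_sweep_cnn(tv$images, tv$labels, val_fraction = 1.5),
               "val_fraction")
  expect_error(fit_sweep_cnn(tv$images, tv$labels[-1]), "one label per")
})

test_that("checkpointing returns the earliest epoch with maximal validation
          accuracy", {
  expect_equal(sweepcnn:::select_checkpoint(c(0.6, 0.9, 0.8)), 2)
  expect_equal(sweepcnn:::select_checkpoint(c(0.5, 0.9, 0.9)), 2)
  expect_equal(sweepcnn:::select_checkpoint(c(0.7)), 1)
  m <- get_toy_model()
  expect_equal(m$best_epoch, sweepcnn:::select_checkpoint(m$history$val_acc))
})

test_that("inference returns a c x L column-stochastic matrix,
          deterministically", {
  m <- get_toy_model()
  imgs <- toy_images(31)$images
  p <- predict(m, imgs)
  expect_equal(dim(p), c(2, 31))
  expect_equal(rownames(p), c("neutral", "selection"))
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(max(abs(colSums(p) - 1)), 1e-6)
  expect_identical(unclass(p), unclass(predict(m, imgs)))
  expect_error(predict(m, array(0, c(10, 50, 3))), "shape mismatch")
  expect_error(predict(m, array(0, c(20, 40, 3))), "shape mismatch")
})

test_that("a saved model reproduces probabilities bit-for-bit after loading", {
  m <- get_toy_model()
  dir <- withr::local_tempdir()
  save_sweep_cnn(m, dir)
  m2 <- load_sweep_cnn(dir)
  imgs <- toy_images(17)$images
  expect_identical(unclass(predict(m, imgs)), unclass(predict(m2, imgs)))
  expect_equal(m2$best_epoch, m$best_epoch)
})

test_that("label-shuffled training stays at chance level", {
  set.seed(77)
  # windows from one neutral scenario, labels assigned at random
  reps <- simulate_ms(eq_neutral(), 40, seed = 501)
  tr <- sweepcnn:::training_images(list(a = reps[1:20], b = reps[21:40]),
                                  width = 50, per_rep = 5)
  m <- fit_sweep_cnn(tr$images, sample(tr$labels), epochs = 3,
                     val_fraction = 0.25, seed = 502)
  acc <- max(m$history$val_acc)
  n_val <- round(0.25 * length(tr$labels))
  expect_lt(abs(acc - 0.5), 3 * sqrt(0.25 / n_val) + 0.05)
})

test_that("the architecture search ranks candidates by validation
          accuracy", {
  tv <- toy_images(60)
  grid <- data.frame(n_conv = c(2, 2), filters = c(4, 8),
                     form = "constant", dense = 8,
                     stringsAsFactors = FALSE)
  res <- search_sweep_cnn(tv$images, tv$labels, grid = grid, epochs = 1,
                          seed = 13)
  expect_equal(nrow(res), 2)
  expect_true(all(!is.na(res$val_acc)))
  expect_true(!is.unsorted(rev(res$val_acc)))
})

test_that("training reproduces exactly under a fixed seed", {
  tv <- toy_images(60)
  m1 <- fit_sweep_cnn(tv$images, tv$labels, epochs = 2, seed = 9)
  m2 <- fit_sweep_cnn(tv$images, tv$labels, epochs = 2, seed = 9)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})
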