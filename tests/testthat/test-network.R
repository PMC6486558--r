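test_that("output width is the known-type count plus one", {
  gs <- gene_space(sprintf("G%d", 1:100))
  m37 <- init_model(cell_type_catalog(sprintf("T%d", 1:37)), gs, seed = 1)
  expect_equal(ncol(m37$weights[[3]]$W), 38L)
  m30 <- init_model(cell_type_catalog(sprintf("T%d", 1:30)), gs, seed = 1)
  expect_equal(ncol(m30$weights[[3]]$W), 31L)
})

test_that("initialization is seed-deterministic and fan-in scaled", {
  gs <- gene_space(sprintf("G%d", 1:64))
  cat3 <- cell_type_catalog(c("A", "B", "C"))
  a <- init_model(cat3, gs, seed = 11)
  b <- init_model(cat3, gs, seed = 11)
  expect_identical(a$weights, b$weights)
  # bounds of the scaled-uniform draw
  lim1 <- sqrt(6 / 64)
  expect_lte(max(abs(a$weights[[1]]$W)), lim1)
  expect_true(all(a$weights[[1]]$b == 0))
})

test_that("degenerate and malformed training inputs are rejected", {
  gs <- gene_space(sprintf("G%d", 1:20))
  cat2 <- cell_type_catalog(c("A", "B"))
  model <- init_model(cat2, gs, hidden_sizes = c(4, 3), seed = 1)
  x <- matrix(rbinom(200, 1, 0.3), nrow = 10,
              dimnames = list(NULL, unclass(gs)))
  expect_error(train_classifier(model, x, rep("A", 10)), "single class")
  expect_error(train_classifier(model, x * 2.5, rep(c("A", "B"), 5)),
               "binary")
})

test_that("an untrained uniform model scores cross-entropy ln(K)", {
  gs <- gene_space(sprintf("G%d", 1:30))
  cat5 <- cell_type_catalog(sprintf("T%d", 1:5))
  model <- init_model(cat5, gs, hidden_sizes = c(8, 4), seed = 2)
  model$weights[[3]]$W[] <- 0
  model$weights[[3]]$b[] <- 0
  x <- matrix(rbinom(300, 1, 0.3), nrow = 10,
              dimnames = list(NULL, unclass(gs)))
  probs <- predict(model, x, type = "prob")
  expect_equal(unname(probs), matrix(1 / 6, 10, 6), tolerance = 1e-12)
  expect_equal(-mean(log(probs[cbind(1:10, rep(1, 10))])), log(6),
               tolerance = 1e-12)
})

test_that("probability rows sum to one and ties break to the first class", {
  gs <- gene_space(sprintf("G%d", 1:25))
  cat4 <- cell_type_catalog(c("A", "B", "C"))
  model <- init_model(cat4, gs, hidden_sizes = c(6, 4), seed = 3)
  x <- matrix(rbinom(250, 1, 0.4), nrow = 10,
              dimnames = list(NULL, unclass(gs)))
  probs <- predict(model, x, type = "prob")
  expect_equal(rowSums(probs), rep(1, 10), tolerance = 1e-6)
  # zeroed final layer -> exact tie -> lowest catalog index wins
  model$weights[[3]]$W[] <- 0
  model$weights[[3]]$b[] <- 0
  zero_profile <- matrix(0, 1, 25, dimnames = list("z", unclass(gs)))
  expect_equal(predict(model, zero_profile, type = "label"), "A")
})

test_that("prediction is a pure function of weights and input", {
  ds <- generate_labeled_dataset(small_synth(21, n_types = 3L,
                                             cells_per_type = 50L))
  model <- init_model(ds$catalog, gene_space(colnames(ds$x)),
                      hidden_sizes = c(16, 8), seed = 21)
  model <- train_classifier(model, ds$x, ds$labels$label,
                            config = fast_train(21, max_epochs = 5L))
  dup <- ds$x[c(1, 1, 1), , drop = FALSE]
  p <- predict(model, dup, type = "prob")
  expect_identical(p[1, ], p[2, ])
  expect_identical(predict(model, ds$x[1:10, ], type = "label"),
                   predict(model, ds$x[1:10, ], type = "label"))
})

test_that("training is reproducible from the seed", {
  ds <- generate_labeled_dataset(small_synth(33, n_types = 3L,
                                             cells_per_type = 60L))
  run <- function() {
    m <- init_model(ds$catalog, gene_space(colnames(ds$x)),
                    hidden_sizes = c(16, 8), seed = 33)
    train_classifier(m, ds$x, ds$labels$label,
                     config = fast_train(33, max_epochs = 6L))
  }
  a <- run(); b <- run()
  expect_identical(a$weights, b$weights)
  expect_identical(a$history, b$history)
})

test_that("the validation split is stratified and class-covering", {
  # 3 classes with very different sizes; a 20% stratified split must keep
  # every class in both partitions
  labels <- c(rep("A", 200), rep("B", 40), rep("C", 10))
  y <- as.integer(factor(labels))
  val <- withr::with_seed(9, scident:::stratified_split(y, 0.2))
  expect_equal(length(intersect(val, which(y == 1))), 40L)
  expect_equal(length(intersect(val, which(y == 2))), 8L)
  expect_equal(length(intersect(val, which(y == 3))), 2L)
  expect_true(all(1:3 %in% y[-val]))
})

test_that("early stopping restores the best-epoch weights", {
  ds <- generate_labeled_dataset(small_synth(41, n_types = 3L,
                                             cells_per_type = 60L))
  model <- init_model(ds$catalog, gene_space(colnames(ds$x)),
                      hidden_sizes = c(16, 8), seed = 41)
  cfg <- train_config(batch_size = 128L, max_epochs = 40L, patience = 2L,
                      learning_rate = 0.05, seed = 41)
  fit <- train_classifier(model, ds$x, ds$labels$label, config = cfg)
  h <- fit$history
  if (nrow(h) < cfg$max_epochs) {
    # stopped early: the last `patience` epochs show no improvement over
    # the restored best epoch
    best <- which.min(h$val_loss)
    expect_lte(best, nrow(h) - 1L)
    expect_true(all(h$val_loss[(best + 1):nrow(h)] >= h$val_loss[best] - 1e-9))
  }
  expect_true(all(is.finite(h$loss)))
})

test_that("class weighting lifts minority-class recall under 50:1 imbalance", {
  # two types sharing overlapping markers, 50:1 imbalance
  cfg <- synthetic_config(n_types = 2L, markers_per_type = 20L,
                          n_background_genes = 300L,
                          p_marker_on = 0.6, p_marker_off = 0.35,
                          cells_per_type = c(1500L, 30L), seed = 42)
  ds <- generate_labeled_dataset(cfg)
  cw <- compute_class_weights(ds$labels$label, ds$catalog, missing = "drop")
  gs <- gene_space(colnames(ds$x))
  tc <- train_config(batch_size = 256L, max_epochs = 15L, patience = 15L,
                     seed = 42)
  fit_w <- train_classifier(init_model(ds$catalog, gs, hidden_sizes = c(32, 16),
                                       seed = 42),
                            ds$x, ds$labels$label, config = tc,
                            class_weights = cw)
  fit_u <- train_classifier(init_model(ds$catalog, gs, hidden_sizes = c(32, 16),
                                       seed = 42),
                            ds$x, ds$labels$label, config = tc)
  test_ds <- generate_labeled_dataset(
    synthetic_config(n_types = 2L, markers_per_type = 20L,
                     n_background_genes = 300L,
                     p_marker_on = 0.6, p_marker_off = 0.35,
                     cells_per_type = 200L, seed = 142))
  minority <- test_ds$labels$label == "Type2"
  recall <- function(fit) {
    mean(predict(fit, test_ds$x[minority, ], type = "label") == "Type2")
  }
  expect_gt(recall(fit_w), recall(fit_u))
})
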