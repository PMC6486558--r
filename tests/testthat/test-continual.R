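# Shared fixture: a small trained base model plus upgrade data, built once.
upgrade_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    bench <- generate_upgrade_benchmark(small_synth(11), n_new_types = 2L,
                                        n_unknown = 150L, seed = 11)
    gs <- bench$gene_space
    model <- init_model(bench$base$catalog, gs, hidden_sizes = c(32, 16),
                        seed = 11)
    cw <- compute_class_weights(bench$base$labels, bench$base$catalog,
                                missing = "drop")
    model <- train_classifier(model, bench$base$x, bench$base$labels,
                              config = fast_train(11, max_epochs = 20L),
                              class_weights = cw)
    cache <<- list(bench = bench, model = model)
    cache
  }
})

test_that("zero-epoch updates leave the weights untouched", {
  fx <- upgrade_fixture()
  out <- online_update(fx$model, fx$bench$new$x, fx$bench$new$labels_phase1,
                       config = train_config(max_epochs = 0L, seed = 1),
                       policy = review_policy(review_size = 0L))
  expect_identical(out$weights, fx$model$weights)
})

test_that("labels outside the catalog direct the user to expand_catalog", {
  fx <- upgrade_fixture()
  expect_error(
    online_update(fx$model, fx$bench$new$x, fx$bench$new$labels_phase2,
                  config = train_config(max_epochs = 1L, seed = 1)),
    "expand_catalog"
  )
})

test_that("review training protects old-domain accuracy during online updates", {
  fx <- upgrade_fixture()
  tc <- train_config(batch_size = 64L, max_epochs = 8L,
                     learning_rate = 0.05, seed = 11)
  pool_n <- nrow(fx$model$replay$x)
  with_review <- online_update(fx$model, fx$bench$new$x,
                               fx$bench$new$labels_phase1, config = tc,
                               policy = review_policy(min(4000L, pool_n),
                                                      seed = 11))
  without <- online_update(fx$model, fx$bench$new$x,
                           fx$bench$new$labels_phase1, config = tc,
                           policy = review_policy(0L))
  old_acc <- function(m) {
    concordance(predict(m, fx$bench$base_test$x, type = "label"),
                fx$bench$base_test$labels)
  }
  expect_gte(old_acc(with_review), old_acc(without))
  # review history tracks replay-pool performance
  expect_true(all(is.finite(with_review$history$replay_accuracy)))
})

test_that("review draws are reproducible and without replacement", {
  fx <- upgrade_fixture()
  tc <- train_config(batch_size = 256L, max_epochs = 2L, seed = 11)
  a <- online_update(fx$model, fx$bench$new$x, fx$bench$new$labels_phase1,
                     config = tc, policy = review_policy(500L, seed = 3))
  b <- online_update(fx$model, fx$bench$new$x, fx$bench$new$labels_phase1,
                     config = tc, policy = review_policy(500L, seed = 3))
  expect_identical(a$weights, b$weights)
})

test_that("a model without a replay pool warns and skips review", {
  fx <- upgrade_fixture()
  bare <- fx$model
  bare$replay <- NULL
  expect_warning(
    online_update(bare, fx$bench$new$x[1:50, ],
                  fx$bench$new$labels_phase1[1:50],
                  config = train_config(batch_size = 64L, max_epochs = 1L,
                                        seed = 1),
                  policy = review_policy(100L)),
    "replay pool"
  )
})

test_that("catalog expansion widens the output before Unknown and freezes layer 1", {
  fx <- upgrade_fixture()
  x_all <- rbind(fx$bench$base$x, fx$bench$new$x)
  lab_all <- c(fx$bench$base$labels, fx$bench$new$labels_phase2)
  expanded <- expand_catalog(fx$model, fx$bench$new_types, x_all, lab_all,
                             config = train_config(batch_size = 256L,
                                                   max_epochs = 6L,
                                                   seed = 12),
                             policy = review_policy(500L, seed = 12),
                             init_seed = 12)
  expect_equal(expanded$catalog$classes,
               c(fx$model$catalog$known, fx$bench$new_types, "Unknown"))
  expect_equal(ncol(expanded$weights[[3]]$W),
               ncol(fx$model$weights[[3]]$W) + 2L)
  # frozen-layer contract: bit-identical first hidden layer
  expect_identical(expanded$weights[[1]]$W, fx$model$weights[[1]]$W)
  expect_identical(expanded$weights[[1]]$b, fx$model$weights[[1]]$b)
  # the later layers did train
  expect_false(identical(expanded$weights[[2]]$W, fx$model$weights[[2]]$W))
  expect_equal(expanded$version, "v2")
})

test_that("expansion guards against duplicates and missing examples", {
  fx <- upgrade_fixture()
  expect_error(expand_catalog(fx$model, "Type1", fx$bench$new$x,
                              fx$bench$new$labels_phase2),
               "already in catalog")
  expect_error(expand_catalog(fx$model, c("NewA", "NewA"), fx$bench$new$x,
                              fx$bench$new$labels_phase2),
               "duplicate")
  expect_error(expand_catalog(fx$model, "NeverSeen", fx$bench$new$x,
                              fx$bench$new$labels_phase2),
               "no training example")
})

test_that("expanding by zero types behaves as an online update", {
  fx <- upgrade_fixture()
  tc <- train_config(batch_size = 256L, max_epochs = 2L, seed = 5)
  pol <- review_policy(200L, seed = 5)
  expanded <- expand_catalog(fx$model, character(0), fx$bench$new$x,
                             fx$bench$new$labels_phase1, config = tc,
                             policy = pol)
  updated <- online_update(fx$model, fx$bench$new$x,
                           fx$bench$new$labels_phase1, config = tc,
                           policy = pol)
  expect_equal(ncol(expanded$weights[[3]]$W), ncol(fx$model$weights[[3]]$W))
  expect_identical(expanded$catalog$classes, updated$catalog$classes)
})
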