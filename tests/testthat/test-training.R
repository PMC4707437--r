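test_that("label error is observed minus expected", {
  set.seed(2)
  pot <- random_potentials(5, 3)
  post <- crf_posteriors(pot)
  y <- c(1L, 3L, 2L, 2L, 1L)
  E <- label_error(post, y)
  em <- enum_marginals(pot)
  onehot <- matrix(0, 5, 3); onehot[cbind(1:5, y)] <- 1
  expect_equal(E, onehot - em$singleton, tolerance = 1e-9)
  # uniform posterior: truth entries 1 - 1/S, others -1/S
  upot <- structure(list(node = matrix(0, 4, 4), pair = matrix(0, 4, 4)),
                    class = "potential_table")
  Eu <- label_error(crf_posteriors(upot), rep(2L, 4))
  expect_equal(unique(Eu[, 2]), 0.75)
  expect_equal(unique(as.numeric(Eu[, -2])), -0.25)
})

test_that("analytic gradients match central finite differences", {
  # 2 hidden layers, window 3, <= 4 neurons: every parameter class checked
  res <- gradient_check(n_points = 8, seed = 42)
  expect_lt(res$max_relative_error, 1e-5)
  # and with sigmoid activations / zero regularization
  spec <- deepcnf_spec(4, 3, c(3, 4), 3, activation = "sigmoid")
  res2 <- gradient_check(spec, n_points = 4, lambda = 0, seed = 7)
  expect_lt(res2$max_relative_error, 1e-5)
})

test_that("structural zero-gradient cases hold", {
  spec <- deepcnf_spec(4, 3, c(3, 3), 3)
  params <- init_params(spec, seed = 5)
  # all-zero input features: first-layer gradient carries a factor X = 0
  X <- matrix(0, 6, 4)
  sg <- sequence_gradient(params, X, rep(1L, 6), spec)
  expect_equal(sg$grad$W[[1]], array(0, dim = dim(params$W[[1]])))
})

test_that("the penalized objective has the documented form", {
  spec <- deepcnf_spec(42, 3, 3, 3)
  ds <- toy_labelled_dataset(n = 3, L = 15, seed = 2)
  train_set <- deepcnf:::as_training_set(ds, spec)
  theta <- flatten_params(init_params(spec, seed = 3))
  # lambda = 0: negative sum of per-sequence log-likelihoods
  obj0 <- deepcnf_objective(theta, train_set, spec, lambda = 0)
  params <- unflatten_params(theta, spec)
  ll <- sum(vapply(train_set, function(rec) {
    pot <- make_potentials(params, dcnn_forward(params, rec$features, spec))
    crf_loglik(pot, rec$labels)
  }, numeric(1)))
  expect_equal(obj0$value, -ll, tolerance = 1e-10)
  # lambda > 0 adds lambda * sum(theta^2)
  obj2 <- deepcnf_objective(theta, train_set, spec, lambda = 2)
  expect_equal(obj2$value, obj0$value + 2 * sum(theta^2), tolerance = 1e-10)
  expect_equal(obj2$gradient, obj0$gradient + 4 * theta, tolerance = 1e-10)
  # theta = 0: uniform model, objective is total length * log(S)
  zero <- deepcnf_objective(0 * theta, train_set, spec, lambda = 0)
  total_len <- sum(vapply(train_set, function(r) nrow(r$features), numeric(1)))
  expect_equal(zero$value, total_len * log(3), tolerance = 1e-10)
})

test_that("training is deterministic and decreases the objective", {
  ds <- toy_labelled_dataset(n = 5, L = 25, seed = 6)
  spec <- deepcnf_spec(42, 3, 5, 3)
  cfg <- train_config(lambda = 1, max_iterations = 25, seed = 3)
  m1 <- train_deepcnf(ds, spec, cfg)
  m2 <- train_deepcnf(ds, spec, cfg)
  expect_identical(flatten_params(m1$params), flatten_params(m2$params))
  expect_lt(m1$objective, m1$initial_objective)
  expect_error(train_deepcnf(list(), spec, cfg), "empty")
})

test_that("training log-likelihood does not degrade with more iterations", {
  ds <- toy_labelled_dataset(n = 4, L = 20, seed = 8)
  spec <- deepcnf_spec(42, 3, 4, 3)
  obj_at <- vapply(c(5L, 15L, 40L), function(it) {
    train_deepcnf(ds, spec,
                  train_config(lambda = 0, max_iterations = it,
                               seed = 4))$objective
  }, numeric(1))
  expect_true(all(diff(obj_at) <= 1e-6))
})

test_that("depth-1 training reduces to the independently coded CNF", {
  spec <- deepcnf_spec(5, 3, 4, 3)
  ds <- list(list(features = matrix(runif(40), 8, 5),
                  labels = sample.int(3, 8, replace = TRUE)),
             list(features = matrix(runif(30), 6, 5),
                  labels = sample.int(3, 6, replace = TRUE)))
  set.seed(10)
  theta <- runif(count_parameters(spec), -0.6, 0.6)
  mine <- deepcnf_objective(theta, ds, spec, lambda = 0.5)
  ref <- cnf_reference_objective(theta, ds, spec, lambda = 0.5)
  expect_equal(mine$value, ref$value, tolerance = 1e-10)
  expect_equal(mine$gradient, ref$gradient, tolerance = 1e-10)
})

test_that("layer-wise pretraining degenerates to plain training at depth 1", {
  ds <- toy_labelled_dataset(n = 4, L = 20, seed = 12)
  spec <- deepcnf_spec(42, 3, 5, 3)
  cfg <- train_config(lambda = 1, max_iterations = 20, seed = 2)
  plain <- train_deepcnf(ds, spec, cfg)
  pre <- pretrain_layerwise(ds, spec, cfg)
  expect_identical(flatten_params(plain$params), flatten_params(pre$params))
})

test_that("fine-tuning improves on the stacked initialization", {
  ds <- toy_labelled_dataset(n = 5, L = 25, seed = 14)
  spec <- deepcnf_spec(42, 3, c(5, 5), 3)
  cfg <- train_config(lambda = 1, max_iterations = 30, seed = 2,
                      pretrain_layerwise = TRUE)
  model <- train_deepcnf(ds, spec, cfg)
  expect_true(model$metadata$pretrained_layerwise)
  expect_lte(model$objective, model$metadata$stacked_objective + 1e-8)
})

test_that("cross-validation folds partition the data and are seeded", {
  ds <- toy_labelled_dataset(n = 8, L = 15, seed = 16)
  spec <- deepcnf_spec(42, 3, 3, 3)
  cfg <- train_config(lambda = 1, max_iterations = 8, seed = 1)
  tab <- cross_validate(ds, spec, lambdas = c(1, 100), k = 4,
                        config = cfg, seed = 9)
  folds <- attr(tab, "folds")
  expect_equal(sort(unique(folds)), 1:4)
  expect_length(folds, 8)
  expect_equal(tab$lambda, c(1, 100))
  expect_true(all(tab$mean_accuracy >= 0 & tab$mean_accuracy <= 1))
  tab2 <- cross_validate(ds, spec, lambdas = c(1, 100), k = 4,
                         config = cfg, seed = 9)
  expect_identical(attr(tab2, "folds"), folds)
  expect_error(cross_validate(ds, spec, 1, k = 20, config = cfg), "exceeds")
})
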