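test_that("potentials are the documented linear scores", {
  spec <- deepcnf_spec(3, 4, 2, 3)
  params <- init_params(spec, seed = 2)
  Htop <- matrix(rnorm(10), 5, 2)
  pot <- make_potentials(params, Htop)
  # independent double-loop evaluation
  direct <- matrix(0, 5, 4)
  for (i in 1:5) for (a in 1:4) {
    direct[i, a] <- sum(params$U[, a] * Htop[i, ])
  }
  expect_equal(pot$node, direct)
  expect_identical(pot$pair, params$T)
  # zero parameters / constant activation special cases
  params$U[] <- 0
  expect_equal(make_potentials(params, Htop)$node, matrix(0, 5, 4))
  params$U <- matrix(c(1, 2, 3, 4), 1, 4)
  expect_equal(make_potentials(params, matrix(1, 5, 1))$node,
               matrix(rep(c(1, 2, 3, 4), each = 5), 5, 4))
  expect_error(make_potentials(init_params(spec, 1), matrix(0, 5, 3)),
               "width")
})

test_that("uniform and single-position chains have closed-form values", {
  pot <- structure(list(node = matrix(0, 4, 8), pair = matrix(0, 8, 8)),
                   class = "potential_table")
  expect_equal(crf_log_partition(pot), 4 * log(8))
  post <- crf_posteriors(pot)
  expect_equal(post$singleton, matrix(1 / 8, 4, 8))
  expect_equal(crf_loglik(structure(list(node = matrix(0, 1, 8),
                                         pair = matrix(0, 8, 8)),
                                    class = "potential_table"), 3L),
               log(1 / 8))
  # L = 1: log-sum-exp of the node row, no pair terms
  pot1 <- random_potentials(1, 5)
  expect_equal(crf_log_partition(pot1),
               log(sum(exp(pot1$node[1, ]))))
})

test_that("inference matches brute-force enumeration on random chains", {
  set.seed(21)
  for (rep in 1:25) {
    L <- sample(1:6, 1); S <- sample(2:4, 1)
    pot <- random_potentials(L, S, scale = 1.5)
    expect_equal(crf_log_partition(pot), enum_log_partition(pot),
                 tolerance = 1e-10)
    post <- crf_posteriors(pot)
    em <- enum_marginals(pot)
    expect_equal(post$singleton, em$singleton, tolerance = 1e-9)
    if (L > 1) expect_equal(post$pairwise, em$pairwise, tolerance = 1e-9)
    y <- sample.int(S, L, replace = TRUE)
    expect_equal(crf_loglik(pot, y),
                 enum_sequence_score(pot, y) - enum_log_partition(pot),
                 tolerance = 1e-10)
    expect_lte(crf_loglik(pot, y), 0)
  }
})

test_that("posteriors normalize and are mutually consistent", {
  set.seed(33)
  for (rep in 1:10) {
    L <- sample(2:12, 1); S <- sample(2:5, 1)
    pot <- random_potentials(L, S, scale = 2)
    post <- crf_posteriors(pot)
    expect_equal(rowSums(post$singleton), rep(1, L), tolerance = 1e-9)
    for (i in seq_len(L - 1)) {
      slice <- post$pairwise[i, , ]
      expect_equal(sum(slice), 1, tolerance = 1e-9)
      expect_equal(rowSums(matrix(slice, S, S)), post$singleton[i, ],
                   tolerance = 1e-9)
      expect_equal(colSums(matrix(slice, S, S)), post$singleton[i + 1, ],
                   tolerance = 1e-9)
    }
  }
})

test_that("probabilities over all label sequences sum to one", {
  set.seed(8)
  for (rep in 1:5) {
    L <- sample(2:6, 1); S <- sample(2:4, 1)
    pot <- random_potentials(L, S)
    seqs <- all_label_sequences(L, S)
    total <- sum(exp(apply(seqs, 1, function(y) crf_loglik(pot, y))))
    expect_equal(total, 1, tolerance = 1e-9)
  }
})

test_that("log-partition shifts by exactly c under a node-row shift", {
  set.seed(13)
  pot <- random_potentials(5, 3)
  shifted <- pot
  shifted$node[3, ] <- shifted$node[3, ] + 7.25
  expect_equal(crf_log_partition(shifted), crf_log_partition(pot) + 7.25,
               tolerance = 1e-10)
})

test_that("inference stays finite for potentials scaled by 1000", {
  set.seed(3)
  pot <- random_potentials(20, 4)
  pot$node <- pot$node * 1000
  pot$pair <- pot$pair * 1000
  expect_true(is.finite(crf_log_partition(pot)))
  post <- crf_posteriors(pot)
  expect_true(all(is.finite(post$singleton)))
  expect_equal(rowSums(post$singleton), rep(1, 20), tolerance = 1e-9)
})

test_that("Viterbi decoding is exact and breaks ties to the lower index", {
  set.seed(17)
  for (rep in 1:15) {
    L <- sample(1:4, 1) + 3; S <- 3
    pot <- random_potentials(L, S)
    expect_equal(crf_viterbi(pot), enum_viterbi(pot))
  }
  # all potentials equal: the tie rule gives the all-first-label path
  pot <- structure(list(node = matrix(1, 5, 3), pair = matrix(2, 3, 3)),
                   class = "potential_table")
  expect_equal(crf_viterbi(pot), rep(1L, 5))
  expect_equal(crf_posterior_decode(crf_posteriors(pot)), rep(1L, 5))
})

test_that("the two decoders coincide when the chain decouples", {
  set.seed(29)
  pot <- random_potentials(8, 4)
  pot$pair[] <- 0
  post <- crf_posteriors(pot)
  v <- crf_viterbi(pot)
  expect_equal(v, crf_posterior_decode(post))
  expect_equal(v, apply(pot$node, 1, which.max))
  # marginal decode matches the enumeration-oracle marginals' argmax
  em <- enum_marginals(random_potentials(4, 3))
  expect_equal(crf_posterior_decode(structure(list(singleton = em$singleton),
                                              class = "chain_posteriors")),
               apply(em$singleton, 1, which.max))
})

test_that("the Viterbi path scores at least as high as the marginal path", {
  set.seed(41)
  for (rep in 1:10) {
    pot <- random_potentials(6, 3, scale = 1.5)
    v <- crf_viterbi(pot)
    p <- crf_posterior_decode(crf_posteriors(pot))
    expect_gte(enum_sequence_score(pot, v), enum_sequence_score(pot, p) - 1e-12)
  }
})
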