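#' Per-position label error (observed minus expected)
#'
#' E_i(a) = delta(y_i = a) - P(Y_i = a | X), the quantity that seeds the
#' back-propagation through the convolutional stack.
#'
#' @param post `chain_posteriors`.
#' @param labels integer label indices, length L.
#' @return L x S matrix.
#' @export
label_error <- function(post, labels) {
  L <- nrow(post$singleton); S <- ncol(post$singleton)
  if (length(labels) != L) stop("label sequence length mismatch")
  onehot <- matrix(0, L, S)
  onehot[cbind(seq_len(L), labels)] <- 1
  onehot - post$singleton
}

#' Gradient of the log-likelihood for one sequence
#'
#' Exact analytic gradient of log P(Y | X) with respect to every parameter:
#' \itemize{
#'   \item dT(a,b) = sum_i [delta(y_{i-1}=a, y_i=b) - P(Y_{i-1}=a, Y_i=b | X)]
#'   \item dU(m,a) = sum_i E_i(a) H^top_i(m)
#'   \item dW^k_n(m',m) = sum_i D^{k+1}_i(m) H^k_{i+n}(m'), where
#'     D^{k+1} = (back-propagated error at layer k+1) * g(H^{k+1}) and g is
#'     the activation derivative expressed in activation values.
#' }
#' Out-of-range window positions contribute zero, mirroring the forward pass.
#'
#' @param params `deepcnf_params`.
#' @param features L x input_width matrix.
#' @param labels integer label indices.
#' @param spec `deepcnf_spec`.
#' @return list with `grad` (a `deepcnf_params`-shaped list dW/dU/dT under
#'   names W/U/T) and `loglik`.
#' @export
sequence_gradient <- function(params, features, labels, spec) {
  H <- dcnn_forward(params, features, spec)
  pot <- make_potentials(params, H)
  post <- crf_posteriors(pot)
  L <- nrow(pot$node); S <- ncol(pot$node)

  score <- sum(pot$node[cbind(seq_len(L), labels)])
  if (L > 1L) score <- score + sum(pot$pair[cbind(labels[-L], labels[-1L])])
  loglik <- score - post$log_z

  E <- label_error(post, labels)
  K <- length(spec$hidden_sizes)
  Htop <- H[[K + 1L]]
  dU <- crossprod(Htop, E)

  dT <- matrix(0, S, S)
  if (L > 1L) {
    obs <- matrix(0, S, S)
    for (i in 2:L) obs[labels[i - 1L], labels[i]] <- obs[labels[i - 1L], labels[i]] + 1
    dT <- obs - apply(post$pairwise, c(2L, 3L), sum)
  }

  # back-propagate through the convolutional stack
  dW <- vector("list", K)
  dH <- E %*% t(params$U)                 # dL/dH^{K+1}
  for (k in K:1L) {
    Dk <- dH * activation_deriv(H[[k + 1L]], spec$activation[k])
    W <- params$W[[k]]
    N <- spec$half_window[k]
    dWk <- array(0, dim = dim(W))
    if (k > 1L) dH <- matrix(0, L, ncol(H[[k]]))
    for (j in seq_len(2L * N + 1L)) {
      n <- j - N - 1L
      dWk[j, , ] <- crossprod(shift_rows(H[[k]], n), Dk)
      if (k > 1L) {
        Wj <- matrix(W[j, , ], dim(W)[2], dim(W)[3])
        dH <- dH + shift_rows(Dk, -n) %*% t(Wj)
      }
    }
    dW[[k]] <- dWk
  }
  list(grad = list(W = dW, U = dU, T = dT), loglik = loglik)
}

#' Training configuration
#'
#' @param lambda non-negative L2 regularization factor; the penalty is
#'   lambda * sum(theta^2) over all of W, U and T (no 1/2 factor), and the
#'   data term is summed (not averaged) over sequences, so lambda scales with
#'   dataset size.  The cross-validation optimum for the full-scale secondary
#'   structure task is around 50.
#' @param max_iterations L-BFGS iteration cap.
#' @param gradient_tolerance projected-gradient stopping tolerance.
#' @param seed seed for parameter initialization.
#' @param init_scale half-width of the uniform initialization interval.
#' @param pretrain_layerwise logical; if TRUE [train_deepcnf()] stacks
#'   layer-by-layer supervised pretraining before the simultaneous fine-tune.
#' @param memory L-BFGS history size.
#' @param verbose print an iteration log.
#' @return list of class `train_config`.
#' @export
train_config <- function(lambda = 50, max_iterations = 200L,
                         gradient_tolerance = 1e-4, seed = 1L,
                         init_scale = 0.05, pretrain_layerwise = FALSE,
                         memory = 10L, verbose = FALSE) {
  stopifnot(lambda >= 0, gradient_tolerance > 0, max_iterations >= 1L)
  structure(list(lambda = lambda, max_iterations = as.integer(max_iterations),
                 gradient_tolerance = gradient_tolerance,
                 seed = as.integer(seed), init_scale = init_scale,
                 pretrain_layerwise = isTRUE(pretrain_layerwise),
                 memory = as.integer(memory), verbose = isTRUE(verbose)),
            class = "train_config")
}

# dataset as the objective consumes it: list of (features, label indices)
as_training_set <- function(dataset, spec) {
  alph <- label_alphabet(spec$num_labels)
  lapply(dataset, function(rec) {
    labs <- rec$labels
    if (spec$num_labels == 3L && !all(strsplit(labs, "")[[1]] %in% SS3_ALPHABET)) {
      labs <- ss8_to_ss3(labs)
    }
    list(features = unclass(rec$features),
         labels = labels_to_indices(labs, alph))
  })
}

#' Penalized negative log-likelihood and its gradient
#'
#' objective(theta) = -sum_seq log P(Y | X) + lambda * ||theta||_2^2, with
#' gradient -sum_seq d(log-lik) + 2 * lambda * theta.
#'
#' @param theta flat parameter vector.
#' @param train_set list of records with `features` and integer `labels`
#'   (see [as_training_set()] internals; [deepcnf_objective()] is exported
#'   mainly for gradient checking).
#' @param spec `deepcnf_spec`.
#' @param lambda L2 factor.
#' @return list with `value` and `gradient` (flat vector).
#' @export
deepcnf_objective <- function(theta, train_set, spec, lambda = 0) {
  params <- unflatten_params(theta, spec)
  total <- 0
  gW <- lapply(params$W, function(w) array(0, dim = dim(w)))
  gU <- matrix(0, nrow(params$U), ncol(params$U))
  gT <- matrix(0, nrow(params$T), ncol(params$T))
  for (rec in train_set) {
    sg <- sequence_gradient(params, rec$features, rec$labels, spec)
    total <- total + sg$loglik
    for (k in seq_along(gW)) gW[[k]] <- gW[[k]] + sg$grad$W[[k]]
    gU <- gU + sg$grad$U
    gT <- gT + sg$grad$T
  }
  g <- -c(unlist(lapply(gW, as.numeric)), as.numeric(gU), as.numeric(gT))
  value <- -total
  if (lambda > 0) {
    value <- value + lambda * sum(theta^2)
    g <- g + 2 * lambda * theta
  }
  list(value = value, gradient = g)
}

# optim calls fn and gr separately at the same point; compute both once
make_objective_cache <- function(train_set, spec, lambda, log_env = NULL) {
  cache <- new.env(parent = emptyenv())
  cache$theta <- NULL
  ensure <- function(theta) {
    if (is.null(cache$theta) || !identical(theta, cache$theta)) {
      obj <- deepcnf_objective(theta, train_set, spec, lambda)
      cache$theta <- theta
      cache$obj <- obj
      if (!is.null(log_env)) {
        log_env$trace <- rbind(
          log_env$trace,
          data.frame(evaluation = nrow(log_env$trace) + 1L,
                     objective = obj$value,
                     grad_norm = sqrt(sum(obj$gradient^2))))
      }
    }
    cache$obj
  }
  list(fn = function(theta) ensure(theta)$value,
       gr = function(theta) ensure(theta)$gradient)
}

run_lbfgs <- function(theta0, train_set, spec, config) {
  log_env <- new.env(parent = emptyenv())
  log_env$trace <- data.frame(evaluation = integer(0), objective = numeric(0),
                              grad_norm = numeric(0))
  obj <- make_objective_cache(train_set, spec, config$lambda, log_env)
  f0 <- obj$fn(theta0)
  if (!is.finite(f0)) stop("objective is not finite at initialization")
  fit <- stats::optim(theta0, obj$fn, obj$gr, method = "L-BFGS-B",
                      control = list(maxit = config$max_iterations,
                                     lmm = config$memory,
                                     pgtol = config$gradient_tolerance,
                                     factr = 0))
  if (!is.finite(fit$value)) {
    stop("L-BFGS produced a non-finite objective (", fit$value,
         ") after ", nrow(log_env$trace), " evaluations")
  }
  if (config$verbose) {
    message(sprintf("L-BFGS: %d evaluations, objective %.6f -> %.6f",
                    nrow(log_env$trace), f0, fit$value))
  }
  list(theta = fit$par, value = fit$value, initial_value = f0,
       trace = log_env$trace, convergence = fit$convergence)
}

#' Train a deep convolutional neural field by maximum likelihood
#'
#' Full-batch L-BFGS on the L2-penalized negative log-likelihood.  Training
#' is deterministic given `config$seed` (which controls only the parameter
#' initialization; the optimizer itself is deterministic).  With
#' `config$pretrain_layerwise = TRUE` the stack is first trained one layer at
#' a time in a supervised mode and then fine-tuned simultaneously.
#'
#' @param dataset list of records with `features` (L x input_width matrix)
#'   and `labels` (label string), e.g. from [load_dataset()] or
#'   [simulate_dataset()].
#' @param spec `deepcnf_spec`.
#' @param config `train_config`.
#' @return object of class `deepcnf_model`: `params`, `spec`, `config`,
#'   `objective` (final value), `initial_objective`, `trace` (per-evaluation
#'   log) and `metadata`.
#' @export
train_deepcnf <- function(dataset, spec, config = train_config()) {
  if (length(dataset) == 0L) stop("empty training set")
  train_set <- as_training_set(dataset, spec)
  if (config$pretrain_layerwise) {
    return(pretrain_layerwise(dataset, spec, config))
  }
  theta0 <- flatten_params(init_params(spec, config$seed, config$init_scale))
  fit <- run_lbfgs(theta0, train_set, spec, config)
  new_deepcnf_model(fit, spec, config)
}

new_deepcnf_model <- function(fit, spec, config, pretrained = FALSE) {
  structure(
    list(params = unflatten_params(fit$theta, spec), spec = spec,
         config = config, objective = fit$value,
         initial_objective = fit$initial_value, trace = fit$trace,
         metadata = list(lambda = config$lambda, seed = config$seed,
                         evaluations = nrow(fit$trace),
                         final_objective = fit$value,
                         pretrained_layerwise = pretrained)),
    class = "deepcnf_model"
  )
}

#' @export
print.deepcnf_model <- function(x, ...) {
  cat("deep convolutional neural field model\n")
  print(x$spec)
  cat(sprintf("  objective   : %.4f (lambda = %g)\n", x$objective,
              x$config$lambda))
  invisible(x)
}

#' Layer-wise supervised pretraining
#'
#' Trains the first window layer inside a one-hidden-layer model, freezes its
#' activations as input to a one-hidden-layer model for the next layer, and
#' so on to the top; the stacked window weights (plus the last stage's U and
#' T) then initialize a simultaneous fine-tune of all parameters.  With a
#' single hidden layer this reduces exactly to [train_deepcnf()].
#'
#' @inheritParams train_deepcnf
#' @return `deepcnf_model`; `$metadata$stacked_objective` records the
#'   objective at the stacked initialization, which the fine-tune can only
#'   improve.
#' @export
pretrain_layerwise <- function(dataset, spec, config = train_config()) {
  if (length(dataset) == 0L) stop("empty training set")
  base_config <- config
  base_config$pretrain_layerwise <- FALSE
  K <- length(spec$hidden_sizes)
  if (K == 1L) return(train_deepcnf(dataset, spec, base_config))

  train_set <- as_training_set(dataset, spec)
  m <- layer_widths(spec)
  W_stack <- vector("list", K)
  current <- lapply(train_set, `[[`, "features")
  U <- NULL; Tm <- NULL
  for (k in seq_len(K)) {
    sub_spec <- deepcnf_spec(
      input_width = m[k], num_labels = spec$num_labels,
      hidden_sizes = spec$hidden_sizes[k],
      window = 2L * spec$half_window[k] + 1L,
      activation = spec$activation[k])
    sub_set <- Map(function(x, rec) list(features = x, labels = rec$labels),
                   current, train_set)
    theta0 <- flatten_params(init_params(sub_spec, base_config$seed + k - 1L,
                                         base_config$init_scale))
    fit <- run_lbfgs(theta0, sub_set, sub_spec, base_config)
    sub_params <- unflatten_params(fit$theta, sub_spec)
    W_stack[[k]] <- sub_params$W[[1L]]
    U <- sub_params$U; Tm <- sub_params$T
    if (k < K) {
      current <- lapply(sub_set, function(rec) {
        dcnn_forward(sub_params, rec$features, sub_spec)[[2L]]
      })
    }
  }
  stacked <- structure(list(W = W_stack, U = U, T = Tm),
                       class = "deepcnf_params")
  theta_stacked <- flatten_params(stacked)
  fit <- run_lbfgs(theta_stacked, train_set, spec, base_config)
  model <- new_deepcnf_model(fit, spec, base_config, pretrained = TRUE)
  model$metadata$stacked_objective <- fit$initial_value
  model$config$pretrain_layerwise <- TRUE
  model
}

#' Choose the regularization factor by k-fold cross-validation
#'
#' Randomly partitions the dataset into k folds (seeded), trains on k-1 folds
#' for each candidate lambda and scores per-residue Q accuracy on the held-out
#' fold.
#'
#' @param dataset labelled dataset (as for [train_deepcnf()]).
#' @param spec `deepcnf_spec`.
#' @param lambdas numeric vector of candidate regularization factors.
#' @param k number of folds (>= 2; the full-scale protocol uses 5).
#' @param config base `train_config`; its lambda is overridden per candidate.
#' @param seed seed for the fold assignment.
#' @return data.frame with columns `lambda`, `mean_accuracy` and one
#'   `fold<i>_accuracy` column per fold; attribute `folds` records the
#'   assignment.
#' @export
cross_validate <- function(dataset, spec, lambdas, k = 5L,
                           config = train_config(), seed = 1L) {
  n <- length(dataset)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k (", k, ") exceeds dataset size (", n, ")")
  set.seed(seed)
  folds <- sample(rep_len(seq_len(k), n))
  alph <- label_alphabet(spec$num_labels)
  rows <- lapply(lambdas, function(lam) {
    cfg <- config
    cfg$lambda <- lam
    acc <- vapply(seq_len(k), function(f) {
      model <- train_deepcnf(dataset[folds != f], spec, cfg)
      held <- dataset[folds == f]
      correct <- 0L; total <- 0L
      for (rec in held) {
        pred <- predict_labels(model, rec$features)
        truth <- rec$labels
        if (spec$num_labels == 3L &&
            !all(strsplit(truth, "")[[1]] %in% SS3_ALPHABET)) {
          truth <- ss8_to_ss3(truth)
        }
        y <- labels_to_indices(truth, alph)
        correct <- correct + sum(pred == y)
        total <- total + length(y)
      }
      correct / total
    }, numeric(1))
    c(lambda = lam, mean_accuracy = mean(acc),
      stats::setNames(acc, paste0("fold", seq_len(k), "_accuracy")))
  })
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "folds") <- folds
  out
}

# Viterbi label indices for one feature matrix under a trained model
predict_labels <- function(model, features) {
  H <- dcnn_forward(model$params, features, model$spec)
  crf_viterbi(make_potentials(model$params, H))
}
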