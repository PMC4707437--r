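# Independent oracles kept deliberately naive: brute-force enumeration for
# the chain model, triple-loop evaluation for the convolution, and a directly
# coded one-hidden-layer conditional neural field.  None of them share code
# with the package's vectorized/dynamic-programming paths.

random_potentials <- function(L, S, scale = 1) {
  structure(list(node = matrix(stats::rnorm(L * S, sd = scale), L, S),
                 pair = matrix(stats::rnorm(S * S, sd = scale), S, S)),
            class = "potential_table")
}

all_label_sequences <- function(L, S) {
  as.matrix(expand.grid(rep(list(seq_len(S)), L)))
}

enum_sequence_score <- function(pot, y) {
  L <- nrow(pot$node)
  s <- sum(pot$node[cbind(seq_len(L), y)])
  if (L > 1) s <- s + sum(pot$pair[cbind(y[-L], y[-1])])
  s
}

enum_log_partition <- function(pot) {
  seqs <- all_label_sequences(nrow(pot$node), ncol(pot$node))
  log(sum(exp(apply(seqs, 1, enum_sequence_score, pot = pot))))
}

enum_marginals <- function(pot) {
  L <- nrow(pot$node); S <- ncol(pot$node)
  seqs <- all_label_sequences(L, S)
  w <- exp(apply(seqs, 1, enum_sequence_score, pot = pot))
  w <- w / sum(w)
  singleton <- sapply(seq_len(S), function(a) {
    sapply(seq_len(L), function(i) sum(w[seqs[, i] == a]))
  })
  pairwise <- NULL
  if (L > 1) {
    pairwise <- array(0, dim = c(L - 1, S, S))
    for (i in 2:L) for (a in seq_len(S)) for (b in seq_len(S)) {
      pairwise[i - 1, a, b] <- sum(w[seqs[, i - 1] == a & seqs[, i] == b])
    }
  }
  list(singleton = matrix(singleton, L, S), pairwise = pairwise)
}

enum_viterbi <- function(pot) {
  seqs <- all_label_sequences(nrow(pot$node), ncol(pot$node))
  scores <- apply(seqs, 1, enum_sequence_score, pot = pot)
  unname(seqs[which.max(scores), ])
}

# position-by-position triple-loop evaluation of the windowed recurrence
direct_conv_forward <- function(params, features, spec) {
  H <- unclass(features)
  for (k in seq_along(spec$hidden_sizes)) {
    W <- params$W[[k]]
    N <- spec$half_window[k]
    L <- nrow(H)
    Mout <- dim(W)[3]
    out <- matrix(0, L, Mout)
    for (i in seq_len(L)) for (m in seq_len(Mout)) {
      acc <- 0
      for (n in -N:N) {
        if (i + n >= 1 && i + n <= L) {
          for (mp in seq_len(dim(W)[2])) {
            acc <- acc + W[n + N + 1, mp, m] * H[i + n, mp]
          }
        }
      }
      out[i, m] <- if (spec$activation[k] == "tanh") tanh(acc)
                   else 1 / (1 + exp(-acc))
    }
    H <- out
  }
  H
}

# independently coded single-hidden-layer conditional neural field:
# objective and gradient via its own loops + enumeration-free forward-backward
# written from scratch (scaled, not log-space, fine at toy size)
cnf_reference_objective <- function(theta, train_set, spec, lambda) {
  stopifnot(length(spec$hidden_sizes) == 1)
  Min <- spec$input_width; Mh <- spec$hidden_sizes[1]
  S <- spec$num_labels; N <- spec$half_window[1]
  Wlen <- (2 * N + 1) * Min * Mh
  W <- array(theta[1:Wlen], dim = c(2 * N + 1, Min, Mh))
  U <- matrix(theta[(Wlen + 1):(Wlen + Mh * S)], Mh, S)
  Tm <- matrix(theta[(Wlen + Mh * S + 1):length(theta)], S, S)
  act <- spec$activation[1]
  total <- 0
  grad <- numeric(length(theta))
  for (rec in train_set) {
    X <- rec$features; y <- rec$labels; L <- nrow(X)
    Hh <- matrix(0, L, Mh)
    for (i in 1:L) for (m in 1:Mh) {
      a <- 0
      for (n in -N:N) if (i + n >= 1 && i + n <= L) {
        a <- a + sum(W[n + N + 1, , m] * X[i + n, ])
      }
      Hh[i, m] <- if (act == "tanh") tanh(a) else 1 / (1 + exp(-a))
    }
    node <- Hh %*% U
    # plain (scaled) forward-backward
    alpha <- matrix(0, L, S); beta <- matrix(0, L, S)
    eT <- exp(Tm); en <- exp(node)
    alpha[1, ] <- en[1, ]
    ca <- numeric(L); ca[1] <- sum(alpha[1, ]); alpha[1, ] <- alpha[1, ] / ca[1]
    if (L > 1) for (i in 2:L) {
      alpha[i, ] <- (alpha[i - 1, ] %*% eT) * en[i, ]
      ca[i] <- sum(alpha[i, ]); alpha[i, ] <- alpha[i, ] / ca[i]
    }
    logz <- sum(log(ca))
    beta[L, ] <- 1
    if (L > 1) for (i in (L - 1):1) {
      beta[i, ] <- (eT %*% (en[i + 1, ] * beta[i + 1, ])) / ca[i + 1]
    }
    post <- alpha * beta
    post <- post / rowSums(post)
    sc <- sum(node[cbind(1:L, y)])
    if (L > 1) sc <- sc + sum(Tm[cbind(y[-L], y[-1])])
    total <- total + sc - logz
    E <- matrix(0, L, S); E[cbind(1:L, y)] <- 1; E <- E - post
    dU <- t(Hh) %*% E
    dT <- matrix(0, S, S)
    if (L > 1) for (i in 2:L) {
      pp <- outer(alpha[i - 1, ], en[i, ] * beta[i, ]) * eT / ca[i]
      dT <- dT - pp / sum(pp) * 1  # expected counts
      dT[y[i - 1], y[i]] <- dT[y[i - 1], y[i]] + 1
    }
    D <- (E %*% t(U)) * (if (act == "tanh") 1 - Hh^2 else Hh * (1 - Hh))
    dW <- array(0, dim = dim(W))
    for (i in 1:L) for (n in -N:N) if (i + n >= 1 && i + n <= L) {
      dW[n + N + 1, , ] <- dW[n + N + 1, , ] + outer(X[i + n, ], D[i, ])
    }
    grad <- grad + c(as.numeric(dW), as.numeric(dU), as.numeric(dT))
  }
  value <- -total + lambda * sum(theta^2)
  gradient <- -grad + 2 * lambda * theta
  list(value = value, gradient = gradient)
}

# small random labelled dataset in the shape train_deepcnf consumes
toy_labelled_dataset <- function(n = 6, L = 25, seed = 1) {
  simulate_dataset(generator_config(num_sequences = n, mean_length = L,
                                    seed = seed))
}
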