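# log-sum-exp of a numeric vector, guarded against -Inf rows
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Build CRF log-potentials from top-layer activations
#'
#' The node potential for position i and label a is the linear score
#' sum_m U(m, a) * H^top_i(m); the pair potential for adjacent labels (a, b)
#' is the shared entry T(a, b).  Pair potentials apply between positions
#' (i-1, i) for i = 2..L; there are no separate start/end parameters.
#'
#' @param params `deepcnf_params` (uses `U` and `T`).
#' @param activations activation stack from [dcnn_forward()], or a plain
#'   L x M_top matrix of top-layer activations.
#' @return list of class `potential_table` with `node` (L x S) and
#'   `pair` (S x S).
#' @export
make_potentials <- function(params, activations) {
  Htop <- if (is.list(activations)) activations[[length(activations)]]
          else activations
  if (ncol(Htop) != nrow(params$U)) {
    stop("top layer width ", ncol(Htop), " does not match U (",
         nrow(params$U), " rows)")
  }
  structure(list(node = Htop %*% params$U, pair = params$T),
            class = "potential_table")
}

#' Log partition function of the chain
#'
#' Forward recursion in log space:
#' alpha_1 = node_1;  alpha_i(b) = node_i(b) + lse_a(alpha_{i-1}(a) + T(a,b)).
#'
#' @param pot `potential_table`.
#' @return log Z(X), a finite scalar for finite potentials.
#' @export
crf_log_partition <- function(pot) {
  a <- forward_messages(pot)
  logsumexp(a[nrow(a), ])
}

forward_messages <- function(pot) {
  node <- pot$node
  L <- nrow(node); S <- ncol(node)
  alpha <- matrix(0, L, S)
  alpha[1L, ] <- node[1L, ]
  if (L > 1L) {
    for (i in 2:L) {
      prev <- alpha[i - 1L, ]
      alpha[i, ] <- node[i, ] +
        apply(prev + pot$pair, 2L, logsumexp)
    }
  }
  alpha
}

backward_messages <- function(pot) {
  node <- pot$node
  L <- nrow(node); S <- ncol(node)
  beta <- matrix(0, L, S)
  if (L > 1L) {
    for (i in (L - 1L):1L) {
      nxt <- node[i + 1L, ] + beta[i + 1L, ]
      beta[i, ] <- apply(sweep(pot$pair, 2L, nxt, `+`), 1L, logsumexp)
    }
  }
  beta
}

#' Exact posterior marginals by forward-backward
#'
#' One forward-backward pass in log space yields the per-position label
#' posteriors P(Y_i = a | X), the adjacent-pair posteriors
#' P(Y_{i-1} = a, Y_i = b | X) and log Z(X).
#'
#' @param pot `potential_table`.
#' @return list of class `chain_posteriors` with `singleton` (L x S, rows sum
#'   to 1), `pairwise` ((L-1) x S x S array, slices sum to 1; NULL when L = 1)
#'   and `log_z`.
#' @export
crf_posteriors <- function(pot) {
  node <- pot$node
  L <- nrow(node); S <- ncol(node)
  alpha <- forward_messages(pot)
  beta <- backward_messages(pot)
  log_z <- logsumexp(alpha[L, ])
  singleton <- exp(alpha + beta - log_z)
  singleton <- singleton / rowSums(singleton)  # scrub rounding residue
  pairwise <- NULL
  if (L > 1L) {
    pairwise <- array(0, dim = c(L - 1L, S, S))
    for (i in 2:L) {
      lp <- outer(alpha[i - 1L, ], node[i, ] + beta[i, ], `+`) + pot$pair -
        log_z
      p <- exp(lp)
      pairwise[i - 1L, , ] <- p / sum(p)
    }
  }
  structure(list(singleton = singleton, pairwise = pairwise, log_z = log_z),
            class = "chain_posteriors")
}

#' Conditional log-likelihood of a label sequence
#'
#' log P(Y | X) = sum_i node(i, y_i) + sum_{i>=2} T(y_{i-1}, y_i) - log Z(X).
#'
#' @param pot `potential_table`.
#' @param labels integer vector of 1-based label indices, length L.
#' @return log-probability (always <= 0).
#' @export
crf_loglik <- function(pot, labels) {
  node <- pot$node
  L <- nrow(node); S <- ncol(node)
  if (length(labels) != L) stop("label sequence length mismatch")
  if (any(labels < 1L | labels > S)) stop("label index out of range")
  score <- sum(node[cbind(seq_len(L), labels)])
  if (L > 1L) {
    score <- score + sum(pot$pair[cbind(labels[-L], labels[-1L])])
  }
  score - crf_log_partition(pot)
}

#' Viterbi decoding
#'
#' Returns a maximum-probability label sequence; ties are broken toward the
#' lower label index at every backtracking step, so the output is
#' deterministic.
#'
#' @param pot `potential_table`.
#' @return integer vector of 1-based label indices.
#' @export
crf_viterbi <- function(pot) {
  node <- pot$node
  L <- nrow(node); S <- ncol(node)
  delta <- matrix(-Inf, L, S)
  back <- matrix(1L, L, S)
  delta[1L, ] <- node[1L, ]
  if (L > 1L) {
    for (i in 2:L) {
      sc <- delta[i - 1L, ] + pot$pair        # S x S: rows = previous label
      best <- apply(sc, 2L, which.max)        # first max = lowest index
      delta[i, ] <- node[i, ] + sc[cbind(best, seq_len(S))]
      back[i, ] <- best
    }
  }
  path <- integer(L)
  path[L] <- which.max(delta[L, ])
  if (L > 1L) {
    for (i in L:2L) path[i - 1L] <- back[i, path[i]]
  }
  path
}

#' Posterior (marginal) decoding
#'
#' Per-position argmax of the singleton posteriors; ties break toward the
#' lower label index.
#'
#' @param post `chain_posteriors` from [crf_posteriors()].
#' @return integer vector of 1-based label indices.
#' @export
crf_posterior_decode <- function(post) {
  apply(post$singleton, 1L, which.max)
}
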