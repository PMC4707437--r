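# rows shifted by n with zero padding: row i of the result is H[i + n, ]
# when 1 <= i + n <= L and zero otherwise.  Window positions that fall off
# either end of the sequence therefore contribute nothing.
shift_rows <- function(H, n) {
  L <- nrow(H)
  out <- matrix(0, L, ncol(H))
  if (n >= 0L) {
    if (n < L) out[1:(L - n), ] <- H[(1L + n):L, , drop = FALSE]
  } else {
    if (-n < L) out[(1L - n):L, ] <- H[1:(L + n), , drop = FALSE]
  }
  out
}

apply_activation <- function(x, kind) {
  if (kind == "tanh") tanh(x) else 1 / (1 + exp(-x))
}

# derivative of the activation expressed in the activation value a
activation_deriv <- function(a, kind) {
  if (kind == "tanh") 1 - a^2 else a * (1 - a)
}

#' Forward pass through the convolutional stack
#'
#' Computes all layer activations H^1 .. H^{K+1} where H^1 is the input
#' feature matrix and, for each layer,
#' H^{k+1}_i(m) = h( sum_{n=-N_k}^{N_k} sum_{m'} W^k_n(m', m) H^k_{i+n}(m') )
#' with h the layer's activation function.  Positions i+n outside 1..L
#' contribute zero (zero padding).
#'
#' @param params `deepcnf_params` (only `W` is used).
#' @param features L x input_width numeric matrix (H^1).
#' @param spec matching `deepcnf_spec`.
#' @return list of matrices, element k being H^k; the last element is the
#'   top-layer activation consumed by the CRF.
#' @export
dcnn_forward <- function(params, features, spec) {
  features <- unclass(features)
  if (ncol(features) != spec$input_width) {
    stop("features have ", ncol(features), " columns; spec expects ",
         spec$input_width)
  }
  H <- vector("list", length(spec$hidden_sizes) + 1L)
  H[[1L]] <- features
  for (k in seq_along(spec$hidden_sizes)) {
    W <- params$W[[k]]
    N <- spec$half_window[k]
    pre <- matrix(0, nrow(features), dim(W)[3])
    for (j in seq_len(2L * N + 1L)) {
      n <- j - N - 1L
      Wj <- matrix(W[j, , ], dim(W)[2], dim(W)[3])
      pre <- pre + shift_rows(H[[k]], n) %*% Wj
    }
    H[[k + 1L]] <- apply_activation(pre, spec$activation[k])
  }
  H
}
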