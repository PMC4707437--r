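#' Describe a deep convolutional neural field architecture
#'
#' A model is a stack of windowed (convolutional) hidden layers over the
#' per-residue input features, topped by a linear-chain conditional random
#' field.  Layer k maps an L x M_k matrix of activations to an L x M_{k+1}
#' matrix through a window of 2*N+1 positions; weights are shared across
#' positions.  The default mirrors the architecture used for the secondary
#' structure task: 5 hidden layers of 100 neurons with window size 11.
#'
#' @param input_width number of input features per residue (42 for the
#'   secondary-structure task).
#' @param num_labels number of CRF states (8 or 3 for this task; any >= 2).
#' @param hidden_sizes integer vector, neurons per hidden layer.
#' @param window odd window size(s), recycled across layers (2*N+1).
#' @param activation "tanh" (default) or "sigmoid", recycled across layers.
#' @return object of class `deepcnf_spec`.
#' @examples
#' spec <- deepcnf_spec(42, 8)                    # the default architecture
#' count_parameters(spec)
#' @export
deepcnf_spec <- function(input_width = 42L, num_labels = 8L,
                         hidden_sizes = rep(100L, 5L), window = 11L,
                         activation = "tanh") {
  stopifnot(input_width >= 1L, num_labels >= 2L, length(hidden_sizes) >= 1L,
            all(hidden_sizes >= 1L))
  window <- rep_len(as.integer(window), length(hidden_sizes))
  if (any(window %% 2L != 1L)) stop("window sizes must be odd (2N+1)")
  activation <- rep_len(activation, length(hidden_sizes))
  if (!all(activation %in% c("tanh", "sigmoid"))) {
    stop("activation must be 'tanh' or 'sigmoid'")
  }
  structure(
    list(input_width = as.integer(input_width),
         num_labels = as.integer(num_labels),
         hidden_sizes = as.integer(hidden_sizes),
         half_window = (window - 1L) %/% 2L,
         activation = activation),
    class = "deepcnf_spec"
  )
}

#' @export
print.deepcnf_spec <- function(x, ...) {
  cat("deep convolutional neural field spec\n")
  cat("  input width :", x$input_width, "\n")
  cat("  labels      :", x$num_labels, "\n")
  for (k in seq_along(x$hidden_sizes)) {
    cat(sprintf("  layer %d     : %d neurons, window %d, %s\n", k,
                x$hidden_sizes[k], 2L * x$half_window[k] + 1L,
                x$activation[k]))
  }
  cat("  parameters  :", count_parameters(x), "\n")
  invisible(x)
}

# per-layer widths including the input layer: M_1 = input, M_{K+1} = top
layer_widths <- function(spec) c(spec$input_width, spec$hidden_sizes)

#' Count trainable parameters
#'
#' Sum over layers of (2N_k+1) * M_k * M_{k+1} for the window weights, plus
#' M_top * num_labels for the top-to-label matrix U and num_labels^2 for the
#' label-pair matrix T.  There are no bias terms.
#'
#' @param spec a `deepcnf_spec`.
#' @return integer parameter count.
#' @export
count_parameters <- function(spec) {
  m <- layer_widths(spec)
  w <- sum((2L * spec$half_window + 1L) * m[-length(m)] * m[-1L])
  w + m[length(m)] * spec$num_labels + spec$num_labels^2
}

#' Initialize model parameters
#'
#' Draws every weight uniformly from [-init_scale, init_scale] with a seeded
#' generator.  Small symmetric initialization keeps the squashing activations
#' away from saturation at the start of training.
#'
#' @param spec a `deepcnf_spec`.
#' @param seed integer seed.
#' @param init_scale half-width of the uniform initialization interval.
#' @return parameter list of class `deepcnf_params`: `W` (list of
#'   (2N+1) x M_k x M_{k+1} arrays), `U` (M_top x num_labels), `T`
#'   (num_labels x num_labels).
#' @export
init_params <- function(spec, seed = 1L, init_scale = 0.05) {
  set.seed(seed)
  m <- layer_widths(spec)
  W <- lapply(seq_along(spec$hidden_sizes), function(k) {
    d <- c(2L * spec$half_window[k] + 1L, m[k], m[k + 1L])
    array(stats::runif(prod(d), -init_scale, init_scale), dim = d)
  })
  U <- matrix(stats::runif(m[length(m)] * spec$num_labels,
                           -init_scale, init_scale),
              m[length(m)], spec$num_labels)
  Tm <- matrix(stats::runif(spec$num_labels^2, -init_scale, init_scale),
               spec$num_labels, spec$num_labels)
  structure(list(W = W, U = U, T = Tm), class = "deepcnf_params")
}

#' Flatten parameters to a numeric vector (optimizer order)
#' @param params `deepcnf_params`.
#' @return numeric vector.
#' @export
flatten_params <- function(params) {
  c(unlist(lapply(params$W, as.numeric)), as.numeric(params$U),
    as.numeric(params$T))
}

#' Rebuild structured parameters from a flat vector
#' @param theta numeric vector from [flatten_params()].
#' @param spec matching `deepcnf_spec`.
#' @return `deepcnf_params`.
#' @export
unflatten_params <- function(theta, spec) {
  m <- layer_widths(spec)
  S <- spec$num_labels
  pos <- 0L
  take <- function(n) {
    out <- theta[(pos + 1L):(pos + n)]
    pos <<- pos + n
    out
  }
  W <- lapply(seq_along(spec$hidden_sizes), function(k) {
    d <- c(2L * spec$half_window[k] + 1L, m[k], m[k + 1L])
    array(take(prod(d)), dim = d)
  })
  U <- matrix(take(m[length(m)] * S), m[length(m)], S)
  Tm <- matrix(take(S * S), S, S)
  if (pos != length(theta)) stop("parameter vector length mismatch")
  structure(list(W = W, U = U, T = Tm), class = "deepcnf_params")
}

check_param_shapes <- function(params, spec) {
  m <- layer_widths(spec)
  for (k in seq_along(spec$hidden_sizes)) {
    d <- dim(params$W[[k]])
    if (!identical(as.integer(d),
                   c(2L * spec$half_window[k] + 1L, m[k], m[k + 1L]))) {
      stop("layer ", k, " weight tensor has wrong shape")
    }
  }
  if (!identical(as.integer(dim(params$U)),
                 c(m[length(m)], spec$num_labels))) {
    stop("U has wrong shape")
  }
  if (!identical(as.integer(dim(params$T)),
                 c(spec$num_labels, spec$num_labels))) {
    stop("T has wrong shape")
  }
  invisible(TRUE)
}
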