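#' Check analytic gradients against central finite differences
#'
#' Draws random small instances (features, labels, parameters), computes the
#' analytic gradient of the penalized objective and compares every component
#' with a central finite difference of the objective value.  This is the
#' package's central correctness check for the training equations.
#'
#' @param spec `deepcnf_spec` (defaults to a 2-hidden-layer toy model).
#' @param n_points number of random parameter/data points to test.
#' @param seq_length sequence length of each instance.
#' @param lambda regularization factor used in the checked objective.
#' @param step finite-difference step.
#' @param seed seed.
#' @return list with `max_relative_error`, `n_components` (total components
#'   compared) and `passed` (max relative error < `tol`).
#' @param tol pass threshold on the relative error (default 1e-5).
#' @export
gradient_check <- function(spec = deepcnf_spec(input_width = 5L,
                                               num_labels = 3L,
                                               hidden_sizes = c(4L, 3L),
                                               window = 3L),
                           n_points = 10L, seq_length = 6L, lambda = 0.1,
                           step = 1e-5, seed = 1L, tol = 1e-5) {
  set.seed(seed)
  worst <- 0
  n_comp <- 0L
  for (p in seq_len(n_points)) {
    L <- seq_length
    feats <- matrix(stats::runif(L * spec$input_width), L, spec$input_width)
    labels <- sample.int(spec$num_labels, L, replace = TRUE)
    theta <- stats::runif(count_parameters(spec), -0.5, 0.5)
    train_set <- list(list(features = feats, labels = labels))
    obj <- deepcnf_objective(theta, train_set, spec, lambda)
    fd <- vapply(seq_along(theta), function(j) {
      up <- theta; up[j] <- up[j] + step
      dn <- theta; dn[j] <- dn[j] - step
      (deepcnf_objective(up, train_set, spec, lambda)$value -
       deepcnf_objective(dn, train_set, spec, lambda)$value) / (2 * step)
    }, numeric(1))
    rel <- abs(obj$gradient - fd) / pmax(abs(obj$gradient), abs(fd), 1)
    worst <- max(worst, rel)
    n_comp <- n_comp + length(theta)
  }
  list(max_relative_error = worst, n_components = n_comp,
       passed = worst < tol)
}
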