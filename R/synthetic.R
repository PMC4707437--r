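#' Configuration for the synthetic sequence generator
#'
#' The generator emulates labelled protein sequences: a hidden state process
#' with secondary-structure-like segment lengths, and pseudo-profile
#' emissions that encode the hidden state.  Segment durations are geometric
#' with the configured means (helix 11, strand 6, coil 5 by default, matching
#' the field's average helix/strand lengths); between-segment jumps follow a
#' row-stochastic matrix over distinct states.  Each residue's 20 profile
#' scores are drawn as `emission_signal * mu_state + Normal(0, noise_sd)`,
#' rounded to integers and clipped to [-9, 13] to mimic the printed range of
#' real PSI-BLAST matrices, so the standard parser and featurization apply
#' unchanged.  The per-state mean patterns `mu` are fixed disjoint blocks of
#' +1, so `emission_signal = 0` removes all label information and large
#' values make the states separable.
#'
#' @param num_sequences number of sequences.
#' @param mean_length mean sequence length (lengths are Poisson around it,
#'   floored at 10).
#' @param states "ss3" (default) or "ss8"; the hidden alphabet.
#' @param mean_segment_length named numeric vector of per-state mean segment
#'   lengths.
#' @param jump row-stochastic matrix of between-state transition
#'   probabilities given that a segment ends (diagonal 0); default uniform
#'   over the other states.
#' @param emission_signal non-negative signal strength (default 1).
#' @param noise_sd emission noise standard deviation (default 2, roughly the
#'   spread of real log-odds scores).
#' @param seed integer seed; all randomness flows from it.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(num_sequences = 200L, mean_length = 100L,
                             states = c("ss3", "ss8"),
                             mean_segment_length = NULL, jump = NULL,
                             emission_signal = 1, noise_sd = 2,
                             seed = 1L) {
  states <- match.arg(states)
  alphabet <- if (states == "ss3") SS3_ALPHABET else SS8_ALPHABET
  S <- length(alphabet)
  if (is.null(mean_segment_length)) {
    mean_segment_length <- if (states == "ss3") {
      c(H = 11, E = 6, C = 5)
    } else {
      # helix family around 11, strand family around 6, coil family around 5
      c(H = 11, G = 4, I = 4, E = 6, B = 2, T = 4, S = 4, L = 5)
    }
  }
  stopifnot(all(alphabet %in% names(mean_segment_length)),
            all(mean_segment_length >= 1))
  if (is.null(jump)) {
    jump <- matrix(1 / (S - 1), S, S, dimnames = list(alphabet, alphabet))
    diag(jump) <- 0
  }
  if (any(abs(rowSums(jump) - 1) > 1e-12)) {
    stop("jump matrix rows must sum to 1")
  }
  stopifnot(emission_signal >= 0, noise_sd > 0)
  structure(
    list(num_sequences = as.integer(num_sequences),
         mean_length = as.integer(mean_length), states = states,
         alphabet = alphabet,
         mean_segment_length = mean_segment_length[alphabet],
         jump = jump, emission_signal = emission_signal,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "generator_config"
  )
}

# fixed per-state mean patterns over the 20 profile columns: disjoint +1
# blocks (states beyond the 3rd reuse shifted blocks for the 8-state case)
state_mean_profiles <- function(config) {
  S <- length(config$alphabet)
  mu <- matrix(0, S, 20L)
  block <- max(2L, 20L %/% S)
  for (s in seq_len(S)) {
    idx <- (((s - 1L) * block):((s * block) - 1L)) %% 20L + 1L
    mu[s, idx] <- 1
  }
  config$emission_signal * mu
}

# full per-position Markov chain including self-loops: staying probability
# 1 - 1/mean gives geometric segment lengths with the configured mean
full_transition_matrix <- function(config) {
  S <- length(config$alphabet)
  stay <- 1 - 1 / config$mean_segment_length
  P <- config$jump * (1 - stay)      # rows scaled by the leave probability
  diag(P) <- stay
  P
}

stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- abs(Re(e$vectors[, which.max(Re(e$values))]))
  v / sum(v)
}

#' Generate a synthetic labelled dataset
#'
#' Deterministic given `config$seed`.  Residue identities are drawn uniformly
#' from the 20 standard amino acids (they carry no label signal; the signal
#' lives in the pseudo-profile), so the indicator block of the feature matrix
#' is exercised but uninformative.
#'
#' @param config `generator_config`.
#' @return list of class `synthetic_dataset`: records each with `id`,
#'   `residues`, `labels`, `features`, `profile` (integer score matrix) plus
#'   a `truth_model` attribute holding the generating parameters.
#' @export
simulate_dataset <- function(config = generator_config()) {
  set.seed(config$seed)
  S <- length(config$alphabet)
  P <- full_transition_matrix(config)
  pi0 <- stationary_distribution(P)
  mu <- state_mean_profiles(config)
  records <- lapply(seq_len(config$num_sequences), function(i) {
    L <- max(10L, stats::rpois(1L, config$mean_length))
    y <- integer(L)
    y[1L] <- sample.int(S, 1L, prob = pi0)
    for (t in seq_len(L - 1L)) {
      y[t + 1L] <- sample.int(S, 1L, prob = P[y[t], ])
    }
    scores <- mu[y, , drop = FALSE] +
      matrix(stats::rnorm(L * 20L, 0, config$noise_sd), L, 20L)
    scores <- pmin(pmax(round(scores), -9), 13)
    residues <- paste(sample(AA_ALPHABET[1:20], L, replace = TRUE),
                      collapse = "")
    profile <- structure(
      list(scores = {
        m <- scores
        colnames(m) <- PSIBLAST_AA_ORDER
        m
      },
      residues = residues, residue_order = PSIBLAST_AA_ORDER),
      class = "profile_matrix")
    list(id = sprintf("synth%04d", i), residues = residues,
         labels = paste(config$alphabet[y], collapse = ""),
         features = build_features(residues, profile),
         profile = profile)
  })
  structure(records, class = "synthetic_dataset",
            truth_model = list(config = config, transition = P,
                               initial = pi0, means = mu,
                               noise_sd = config$noise_sd))
}

#' Write a synthetic dataset to disk in the standard input formats
#'
#' One FASTA, one PSI-BLAST-style ASCII PSSM and one label file per sequence,
#' plus a tab-separated manifest, exactly the formats [load_dataset()]
#' consumes; parsing the files back reproduces the in-memory matrices.
#'
#' @param dataset `synthetic_dataset`.
#' @param dir output directory (created if missing).
#' @return path of the manifest file.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(dataset, function(rec) {
    fa <- file.path(dir, paste0(rec$id, ".fasta"))
    ps <- file.path(dir, paste0(rec$id, ".pssm"))
    lb <- file.path(dir, paste0(rec$id, ".labels"))
    write_fasta(stats::setNames(rec$residues, rec$id), fa)
    write_pssm(rec$profile, ps)
    write_labels(stats::setNames(rec$labels, rec$id), lb)
    data.frame(id = rec$id, fasta = basename(fa), pssm = basename(ps),
               labels = basename(lb))
  })
  man <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), man, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  man
}

# node log-potentials of the true generative model at the stored (integer)
# profile scores: Gaussian log-density per column, initial distribution
# folded into position 1
truth_potentials <- function(rec, truth) {
  scores <- rec$profile$scores
  S <- nrow(truth$means)
  node <- vapply(seq_len(S), function(s) {
    rowSums(stats::dnorm(scores,
                         matrix(truth$means[s, ], nrow(scores), 20L,
                                byrow = TRUE),
                         truth$noise_sd, log = TRUE))
  }, numeric(nrow(scores)))
  node <- matrix(node, nrow(scores), S)
  node[1L, ] <- node[1L, ] + log(truth$initial)
  structure(list(node = node, pair = log(truth$transition)),
            class = "potential_table")
}

#' Bayes-oracle accuracy of a synthetic dataset
#'
#' Per-residue accuracy of posterior decoding under the true generative
#' model, computed with the same forward-backward machinery the CRF uses but
#' on the true-model potentials (Gaussian emission log-densities evaluated at
#' the stored integer scores, plus the true chain transitions).  This is the
#' ceiling no trained model should beat by more than sampling noise.
#'
#' @param dataset `synthetic_dataset` carrying its `truth_model` attribute.
#' @return list with `accuracy` (fraction), `n_residues` and `se` (binomial
#'   standard error).
#' @export
bayes_accuracy <- function(dataset) {
  truth <- attr(dataset, "truth_model")
  if (is.null(truth)) stop("dataset carries no truth_model attribute")
  alphabet <- truth$config$alphabet
  correct <- 0L; total <- 0L
  for (rec in dataset) {
    pot <- truth_potentials(rec, truth)
    decoded <- crf_posterior_decode(crf_posteriors(pot))
    y <- match(strsplit(rec$labels, "")[[1]], alphabet)
    correct <- correct + sum(decoded == y)
    total <- total + length(y)
  }
  acc <- correct / total
  list(accuracy = acc, n_residues = total,
       se = sqrt(acc * (1 - acc) / total))
}
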