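#' Build the 42-column per-residue feature matrix
#'
#' Each residue gets 42 features: columns 1-20 are the sigmoid transform
#' 1/(1+exp(-x)) of its profile log-odds scores, reordered into the package's
#' alphabetical amino-acid ordering; column 21 is an unknown-residue profile
#' slot (1 where the residue is non-standard, 0 elsewhere -- at such positions
#' the 20 profile features are neutralised to sigmoid(0) = 0.5); columns 22-42
#' are a 21-way one-hot indicator of the residue identity (20 standard amino
#' acids plus 'X').
#'
#' @param residues amino-acid string.
#' @param profile `profile_matrix` from [parse_pssm()], or a plain L x 20
#'   numeric matrix already in alphabetical column order.
#' @return L x 42 numeric matrix of class `feature_matrix`.
#' @examples
#' prof <- matrix(0, 3, 20)
#' f <- build_features("ACD", prof)
#' stopifnot(all(f[, 1:20] == 0.5), all(rowSums(f[, 22:42]) == 1))
#' @export
build_features <- function(residues, profile) {
  res <- strsplit(toupper(residues), "")[[1]]
  L <- length(res)
  if (inherits(profile, "profile_matrix")) {
    scores <- profile$scores
    # reorder the file's columns into the package's alphabetical ordering
    ord <- match(AA_ALPHABET[1:20], profile$residue_order)
    if (anyNA(ord)) stop("profile residue order is not the standard 20 letters")
    scores <- scores[, ord, drop = FALSE]
  } else {
    scores <- as.matrix(profile)
  }
  if (nrow(scores) != L) {
    stop("profile has ", nrow(scores), " rows but sequence has ", L,
         " residues")
  }
  if (ncol(scores) != 20L) stop("profile must have 20 columns")
  if (any(!is.finite(scores))) stop("profile contains non-finite entries")

  aa_idx <- match(res, AA_ALPHABET)
  aa_idx[is.na(aa_idx)] <- 21L  # non-standard residues -> 'X'

  x <- matrix(0, L, 42L)
  x[, 1:20] <- 1 / (1 + exp(-scores))
  unknown <- aa_idx == 21L
  if (any(unknown)) {
    x[unknown, 1:20] <- 0.5   # neutral profile for degenerate residues
    x[unknown, 21L] <- 1
  }
  x[cbind(seq_len(L), 21L + aa_idx)] <- 1
  class(x) <- c("feature_matrix", class(x))
  x
}
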