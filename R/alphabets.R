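#' Label and amino-acid alphabets
#'
#' Fixed alphabet orderings used throughout the package.  The eight-state
#' secondary-structure alphabet follows DSSP: three helix types (H alpha
#' helix, G 3-10 helix, I pi helix), two strand types (E beta strand, B beta
#' bridge) and three coil types (T turn, S high-curvature loop, L irregular).
#' The three-state alphabet is helix (H), strand (E), coil (C).  The
#' amino-acid alphabet is the twenty standard residues in alphabetical
#' one-letter order followed by 'X' for anything non-standard.  The orderings
#' are frozen constants: indices into them are used in serialized models.
#'
#' @name alphabets
#' @keywords internal
NULL

SS8_ALPHABET <- c("H", "G", "I", "E", "B", "T", "S", "L")
SS3_ALPHABET <- c("H", "E", "C")
AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

# DSSP grouping: G,H,I -> helix; E,B -> strand; T,S,L -> coil
SS8_TO_SS3 <- c(H = "H", G = "H", I = "H",
                E = "E", B = "E",
                T = "C", S = "C", L = "C")

#' Map eight-state labels to three states
#'
#' Collapses the DSSP eight-state alphabet onto helix/strand/coil: G, H and I
#' become helix (H); E and B become strand (E); T, S and L become coil (C).
#' Blank and '-' coil symbols emitted by some DSSP dialects are normalised to
#' 'L' first.
#'
#' @param labels character vector of label strings (each string is one
#'   sequence of per-residue symbols), or a single vector of single symbols.
#' @return character vector of the same shape with three-state symbols.
#' @examples
#' ss8_to_ss3("HGIEBTSL")   # "HHHEECCC"
#' @export
ss8_to_ss3 <- function(labels) {
  vapply(labels, function(s) {
    sym <- strsplit(s, "")[[1]]
    sym <- normalize_ss8_symbols(sym)
    bad <- !(sym %in% SS8_ALPHABET)
    if (any(bad)) {
      stop("invalid 8-state label symbol(s): ",
           paste(unique(sym[bad]), collapse = " "))
    }
    paste(SS8_TO_SS3[sym], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# DSSP dialects write ' ' or '-' for the irregular coil state.
normalize_ss8_symbols <- function(sym) {
  sym[sym %in% c(" ", "-", ".")] <- "L"
  sym
}

#' Convert a label string to 1-based alphabet indices
#'
#' @param labels single label string.
#' @param alphabet the alphabet the symbols are drawn from
#'   (default the eight-state alphabet).
#' @return integer vector of indices into `alphabet`.
#' @export
labels_to_indices <- function(labels, alphabet = SS8_ALPHABET) {
  stopifnot(length(labels) == 1L)
  sym <- strsplit(labels, "")[[1]]
  if (identical(alphabet, SS8_ALPHABET)) sym <- normalize_ss8_symbols(sym)
  idx <- match(sym, alphabet)
  if (anyNA(idx)) {
    stop("invalid label symbol(s): ",
         paste(unique(sym[is.na(idx)]), collapse = " "))
  }
  idx
}

#' Convert alphabet indices back to a label string
#'
#' @param idx integer vector of 1-based indices.
#' @param alphabet target alphabet.
#' @return single label string.
#' @export
indices_to_labels <- function(idx, alphabet = SS8_ALPHABET) {
  if (any(idx < 1L | idx > length(alphabet))) stop("label index out of range")
  paste(alphabet[idx], collapse = "")
}

#' Pick the label alphabet for a model's number of states
#' @param num_labels 3 or 8.
#' @return character vector alphabet.
#' @keywords internal
label_alphabet <- function(num_labels) {
  if (num_labels == 8L) SS8_ALPHABET
  else if (num_labels == 3L) SS3_ALPHABET
  else stop("no named alphabet for ", num_labels, " labels")
}
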