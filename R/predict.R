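#' Predict secondary structure for feature matrices or input files
#'
#' Runs the convolutional forward pass, builds the CRF potentials, and
#' decodes each sequence (Viterbi by default, or per-position posterior
#' argmax).  Accepts either an in-memory dataset (records with `features`)
#' or a manifest path.
#'
#' @param object trained `deepcnf_model`.
#' @param newdata dataset list (records with `id`, `residues`, `features`) or
#'   a manifest path understood by [load_dataset()].
#' @param decoder "viterbi" (default) or "posterior".
#' @param ... unused.
#' @return list of `prediction_record`s: `id`, `residues`, `ss8` (NA for a
#'   three-state model), `ss3`, `posterior` (L x S matrix, rows sum to 1) and
#'   `labels_idx`.  Sequences whose record errors (e.g. a missing profile)
#'   are skipped with a warning; the run continues.
#' @export
predict.deepcnf_model <- function(object, newdata,
                                  decoder = c("viterbi", "posterior"), ...) {
  decoder <- match.arg(decoder)
  man <- NULL
  if (is.character(newdata)) {
    man <- read_manifest(newdata)
    newdata <- seq_len(nrow(man))
  }
  out <- list()
  for (j in seq_along(newdata)) {
    id <- if (is.null(man)) newdata[[j]]$id %||% "?" else man$id[j]
    res <- tryCatch({
      rec <- if (is.null(man)) newdata[[j]] else load_record(man, j)
      predict_one(object, rec, decoder)
    }, error = function(e) {
      warning("skipping record ", id, ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(res)) out[[length(out) + 1L]] <- res
  }
  out
}

predict_one <- function(model, rec, decoder) {
  H <- dcnn_forward(model$params, rec$features, model$spec)
  pot <- make_potentials(model$params, H)
  post <- crf_posteriors(pot)
  idx <- if (decoder == "viterbi") crf_viterbi(pot)
         else crf_posterior_decode(post)
  alph <- label_alphabet(model$spec$num_labels)
  pred <- indices_to_labels(idx, alph)
  structure(
    list(id = rec$id, residues = rec$residues,
         ss8 = if (model$spec$num_labels == 8L) pred else NA_character_,
         ss3 = if (model$spec$num_labels == 8L) ss8_to_ss3(pred) else pred,
         posterior = post$singleton, labels_idx = idx),
    class = "prediction_record"
  )
}

#' Write prediction records
#'
#' For each record writes a per-residue tab-separated table (position,
#' residue, predicted 8-state and 3-state labels, per-label posteriors) into
#' `<dir>/<id>.ss.tsv`, and appends the predicted label strings to a
#' FASTA-like summary file `<dir>/predictions.ss`.
#'
#' @param records list of `prediction_record`s.
#' @param dir output directory (created if missing).
#' @return the summary file path.
#' @export
write_predictions <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summary_path <- file.path(dir, "predictions.ss")
  summary_lines <- character(0)
  for (rec in records) {
    res <- strsplit(rec$residues, "")[[1]]
    L <- length(res)
    alph <- colnames(rec$posterior)
    if (is.null(alph)) {
      alph <- label_alphabet(ncol(rec$posterior))
    }
    header <- c("pos", "residue", "ss8", "ss3", paste0("p_", alph))
    ss8 <- if (is.na(rec$ss8)) rep(".", L) else strsplit(rec$ss8, "")[[1]]
    ss3 <- strsplit(rec$ss3, "")[[1]]
    rows <- vapply(seq_len(L), function(i) {
      paste(c(i, res[i], ss8[i], ss3[i],
              sprintf("%.6f", rec$posterior[i, ])), collapse = "\t")
    }, character(1))
    writeLines(c(paste(header, collapse = "\t"), rows),
               file.path(dir, paste0(rec$id, ".ss.tsv")))
    best <- if (is.na(rec$ss8)) rec$ss3 else rec$ss8
    summary_lines <- c(summary_lines, paste0(">", rec$id), best)
  }
  writeLines(summary_lines, summary_path)
  summary_path
}
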