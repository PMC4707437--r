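split1 <- function(s) strsplit(s, "")[[1]]

check_same_length <- function(pred, truth) {
  if (nchar(pred) != nchar(truth)) {
    stop("prediction and reference have different lengths (",
         nchar(pred), " vs ", nchar(truth), ")")
  }
}

#' Per-residue accuracy (Q3 / Q8)
#'
#' Percentage of positions whose predicted label equals the reference label.
#' Called on three-state strings this is Q3; on eight-state strings, Q8.
#'
#' @param pred,truth label strings of equal length (or equal-length vectors
#'   of strings, pooled position-wise).
#' @return accuracy in percent.
#' @export
q_accuracy <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  match_n <- 0L; total <- 0L
  for (i in seq_along(pred)) {
    check_same_length(pred[i], truth[i])
    p <- split1(pred[i]); t <- split1(truth[i])
    match_n <- match_n + sum(p == t)
    total <- total + length(t)
  }
  100 * match_n / total
}

#' Per-state recall and precision
#'
#' Recall is TP over the state's support in the reference; precision is TP
#' over its count in the prediction.  A state absent from the reference gets
#' recall 0 and one absent from the prediction gets precision 0, keeping
#' report aggregation free of NaN.
#'
#' @param pred,truth equal-length label strings (or vectors, pooled).
#' @param alphabet states to report (default: union of observed symbols in
#'   alphabet order if they match a known alphabet).
#' @return data.frame with columns `state`, `recall`, `precision`, `support`.
#' @export
per_state_scores <- function(pred, truth, alphabet = NULL) {
  stopifnot(length(pred) == length(truth))
  p <- character(0); t <- character(0)
  for (i in seq_along(pred)) {
    check_same_length(pred[i], truth[i])
    p <- c(p, split1(pred[i])); t <- c(t, split1(truth[i]))
  }
  if (is.null(alphabet)) {
    seen <- union(t, p)
    alphabet <- if (all(seen %in% SS3_ALPHABET)) SS3_ALPHABET
                else if (all(seen %in% SS8_ALPHABET)) SS8_ALPHABET
                else sort(seen)
  }
  rows <- lapply(alphabet, function(s) {
    tp <- sum(p == s & t == s)
    support <- sum(t == s)
    predicted <- sum(p == s)
    data.frame(state = s,
               recall = if (support > 0) tp / support else 0,
               precision = if (predicted > 0) tp / predicted else 0,
               support = support)
  })
  do.call(rbind, rows)
}

#' Run-length segments of a label string
#'
#' Maximal constant runs in order, with 0-based half-open coordinates, the
#' representation the segment-overlap score works on.
#'
#' @param labels non-empty label string.
#' @return data.frame with columns `state`, `start`, `end` ([start, end)).
#' @export
ss_segments <- function(labels) {
  sym <- split1(labels)
  if (length(sym) == 0L) stop("empty label string")
  r <- rle(sym)
  end <- cumsum(r$lengths)
  data.frame(state = r$values, start = c(0L, end[-length(end)]), end = end,
             stringsAsFactors = FALSE)
}

#' Segment overlap score (SOV'99)
#'
#' Segment-level accuracy for three-state secondary structure.  For each
#' reference segment s1 of state v and each predicted segment s2 of the same
#' state that overlaps it, the pair contributes
#' len(s1) * (minov + delta) / maxov, where minov is the overlap length,
#' maxov the span of the union, and
#' delta = min(maxov - minov, minov, floor(len(s1)/2), floor(len(s2)/2)).
#' Reference segments with no same-state overlap contribute 0.  The
#' normalizer counts len(s1) once per overlapping pair, or once for an
#' unpaired reference segment.  The delta allowance forgives small boundary
#' shifts while errors in the middle of a segment split it and are punished.
#'
#' Eight-state inputs are mapped to three states first; the score is defined
#' (and reported in the field) on helix/strand/coil.
#'
#' @param pred,truth equal-length label strings (or vectors of strings;
#'   sequences are scored jointly with a shared normalizer).
#' @return SOV score in percent.
#' @export
sov <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  total_num <- 0; total_den <- 0
  for (i in seq_along(pred)) {
    check_same_length(pred[i], truth[i])
    p <- pred[i]; t <- truth[i]
    if (!all(split1(t) %in% SS3_ALPHABET)) t <- ss8_to_ss3(t)
    if (!all(split1(p) %in% SS3_ALPHABET)) p <- ss8_to_ss3(p)
    seg_t <- ss_segments(t)
    seg_p <- ss_segments(p)
    for (a in seq_len(nrow(seg_t))) {
      s1 <- seg_t[a, ]
      len1 <- s1$end - s1$start
      mates <- seg_p[seg_p$state == s1$state &
                     seg_p$start < s1$end & seg_p$end > s1$start, ,
                     drop = FALSE]
      if (nrow(mates) == 0L) {
        total_den <- total_den + len1
        next
      }
      for (b in seq_len(nrow(mates))) {
        s2 <- mates[b, ]
        len2 <- s2$end - s2$start
        minov <- min(s1$end, s2$end) - max(s1$start, s2$start)
        maxov <- max(s1$end, s2$end) - min(s1$start, s2$start)
        delta <- min(maxov - minov, minov, len1 %/% 2, len2 %/% 2)
        ratio <- min(1, (minov + delta) / maxov)
        total_num <- total_num + len1 * ratio
        total_den <- total_den + len1
      }
    }
  }
  if (total_den == 0) return(0)
  100 * total_num / total_den
}

#' Evaluate predictions against reference labels
#'
#' Bundles the per-residue accuracy (Q8 and/or Q3), the SOV'99 score on the
#' three-state mapping, and per-state recall/precision.
#'
#' @param pred,truth equal-length vectors of label strings.
#' @param states 8 or 3: the alphabet the strings are in.
#' @return list of class `eval_report` with `q8` (NA for three-state input),
#'   `q3`, `sov`, `per_state` and `per_state3`.
#' @export
evaluate_predictions <- function(pred, truth, states = 8L) {
  if (states == 8L) {
    q8 <- q_accuracy(pred, truth)
    pred3 <- ss8_to_ss3(pred); truth3 <- ss8_to_ss3(truth)
    per8 <- per_state_scores(pred, truth, SS8_ALPHABET)
  } else {
    q8 <- NA_real_
    pred3 <- pred; truth3 <- truth
    per8 <- NULL
  }
  structure(
    list(q8 = q8, q3 = q_accuracy(pred3, truth3), sov = sov(pred3, truth3),
         per_state = per8,
         per_state3 = per_state_scores(pred3, truth3, SS3_ALPHABET)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  if (!is.na(x$q8)) cat(sprintf("Q8  : %6.2f %%\n", x$q8))
  cat(sprintf("Q3  : %6.2f %%\n", x$q3))
  cat(sprintf("SOV : %6.2f %%\n", x$sov))
  cat("per-state (3-class):\n")
  print(x$per_state3, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report
#'
#' Emits a tab-separated summary and, alongside it, a JSON mirror with the
#' same numbers for machine consumption.
#'
#' @param report `eval_report`.
#' @param path output TSV path; the JSON twin gets extension `.json`.
#' @export
write_eval_report <- function(report, path) {
  lines <- c("metric\tvalue")
  if (!is.na(report$q8)) lines <- c(lines, sprintf("Q8\t%.4f", report$q8))
  lines <- c(lines, sprintf("Q3\t%.4f", report$q3),
             sprintf("SOV\t%.4f", report$sov))
  for (i in seq_len(nrow(report$per_state3))) {
    r <- report$per_state3[i, ]
    lines <- c(lines, sprintf("recall_%s\t%.4f", r$state, r$recall),
               sprintf("precision_%s\t%.4f", r$state, r$precision))
  }
  writeLines(lines, path)
  jsonlite::write_json(unclass(report), sub("\\.[^.]*$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
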