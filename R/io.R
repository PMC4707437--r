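#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning a plain named
#' character vector of upper-case residue strings, which is the representation
#' the rest of the package works with.
#'
#' @param path FASTA file (possibly multi-record).
#' @return named character vector; names are the first whitespace-delimited
#'   token of each header.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of residue strings.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# PSI-BLAST prints residue scores in this column order.
PSIBLAST_AA_ORDER <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Parse a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Reads the classic `-out_ascii_pssm` layout: a title line, a header line
#' whose first 20 tokens name the amino-acid columns of the log-odds block,
#' one row per residue (index, residue letter, 20 log-odds integers, then
#' optional weighted-percentage and information columns which are ignored),
#' and trailing statistics.  Only the first 20-column log-odds block is kept.
#'
#' @param path file path, or a character vector of lines.
#' @return object of class `profile_matrix`: a list with `scores` (L x 20
#'   numeric matrix, columns named by the file's residue order), `residues`
#'   (the per-row residue string from the file) and `residue_order`.
#' @export
parse_pssm <- function(path) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    readLines(path)
  } else {
    unlist(strsplit(path, "\n"))
  }
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    stop("PSSM parse error: empty input")
  }
  # header = first line whose leading tokens are single letters (column names)
  header_at <- NA_integer_
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) >= 20L && all(nchar(tok[1:20]) == 1L) &&
        all(tok[1:20] %in% c(LETTERS))) {
      header_at <- i
      break
    }
  }
  if (is.na(header_at)) stop("PSSM parse error: no column header line found")
  residue_order <- strsplit(trimws(lines[header_at]), "\\s+")[[1]][1:20]

  rows <- list()
  residues <- character(0)
  for (i in seq(header_at + 1L, length(lines))) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) break  # blank line ends the matrix block
    tok <- strsplit(ln, "\\s+")[[1]]
    # data rows start with a position index and a residue letter
    if (is.na(suppressWarnings(as.integer(tok[1])))) break
    if (length(tok) < 22L) {
      stop("PSSM parse error at line ", i, ": expected at least 22 fields")
    }
    vals <- suppressWarnings(as.numeric(tok[3:22]))
    if (anyNA(vals)) {
      stop("PSSM parse error at line ", i, ": non-numeric score cell")
    }
    rows[[length(rows) + 1L]] <- vals
    residues <- c(residues, tok[2])
  }
  if (length(rows) == 0L) stop("PSSM parse error: no data rows found")
  scores <- do.call(rbind, rows)
  colnames(scores) <- residue_order
  structure(
    list(scores = scores,
         residues = paste(residues, collapse = ""),
         residue_order = residue_order),
    class = "profile_matrix"
  )
}

#' Write a profile matrix in PSI-BLAST ASCII layout
#'
#' Emits the dialect [parse_pssm()] consumes, so the pair round-trips the
#' 20-column log-odds block exactly (scores are written with enough digits to
#' be re-read bit-identically when integral, as real PSSM entries are).
#'
#' @param profile `profile_matrix` object.
#' @param path output file.
#' @export
write_pssm <- function(profile, path) {
  stopifnot(inherits(profile, "profile_matrix"))
  scores <- profile$scores
  res <- strsplit(profile$residues, "")[[1]]
  stopifnot(nrow(scores) == length(res))
  lines <- c(
    "",
    "Last position-specific scoring matrix computed, weighted, and scaled",
    paste0("            ", paste(sprintf("%3s", profile$residue_order),
                                 collapse = " "))
  )
  for (i in seq_len(nrow(scores))) {
    lines <- c(lines, paste0(
      sprintf("%5d %s ", i, res[i]),
      paste(sprintf("%3.0f", scores[i, ]), collapse = " ")
    ))
  }
  lines <- c(lines, "", "                      K         Lambda")
  writeLines(lines, path)
  invisible(path)
}

#' Read secondary-structure label strings
#'
#' Label files are FASTA-like two-line records: a `>id` line followed by one
#' per-residue label string over the eight-state alphabet (blank/'-' coil
#' symbols are normalised to 'L').
#'
#' @param path label file.
#' @return named character vector of label strings.
#' @export
read_labels <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || hdr[1] == FALSE) stop("label file must start with a '>' id line")
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1L)
  labs <- character(length(ids))
  j <- 0L
  for (ln in lines) {
    if (grepl("^>", ln)) {
      j <- j + 1L
    } else {
      labs[j] <- paste0(labs[j], gsub("\\s", "", ln))
    }
  }
  labs <- vapply(labs, function(s) {
    paste(normalize_ss8_symbols(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  names(labs) <- ids
  labs
}

#' Write secondary-structure label strings
#' @param labels named character vector of label strings.
#' @param path output file.
#' @export
write_labels <- function(labels, path) {
  writeLines(as.vector(rbind(paste0(">", names(labels)), labels)), path)
  invisible(path)
}

#' Read a dataset manifest
#'
#' The manifest is tab-separated with columns `id`, `fasta`, `pssm`,
#' `labels`; relative paths are resolved against the manifest's directory.
#' The `labels` column may be empty for prediction-only inputs.
#'
#' @param path manifest file.
#' @return data.frame with absolute paths.
#' @export
read_manifest <- function(path) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "fasta", "pssm")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns id, fasta, pssm (and optionally labels)")
  }
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(is.na(p) | p == "", p,
                            ifelse(grepl("^/", p), p, file.path(base, p)))
  for (col in intersect(c("fasta", "pssm", "labels"), names(man))) {
    man[[col]] <- fix(man[[col]])
  }
  man
}

#' Load a labelled dataset from a manifest
#'
#' Reads each record's sequence, profile and (if present) labels, builds the
#' 42-column feature matrix, and cross-checks that sequence, profile and
#' label lengths agree.
#'
#' @param manifest path to a manifest file or a data.frame as returned by
#'   [read_manifest()].
#' @return list of records, each a list with `id`, `residues`, `labels`
#'   (NA if absent), `features` (L x 42 matrix) and `profile`.
#' @export
load_dataset <- function(manifest) {
  man <- if (is.character(manifest)) read_manifest(manifest) else manifest
  lapply(seq_len(nrow(man)), function(i) load_record(man, i))
}

# one manifest row -> one record; errors name the record
load_record <- function(man, i) {
  {
    seqs <- read_fasta(man$fasta[i])
    id <- man$id[i]
    residues <- if (id %in% names(seqs)) seqs[[id]] else seqs[[1]]
    profile <- parse_pssm(man$pssm[i])
    if (nchar(profile$residues) != nchar(residues)) {
      stop("record ", id, ": PSSM has ", nchar(profile$residues),
           " rows but sequence has ", nchar(residues), " residues")
    }
    labels <- NA_character_
    if ("labels" %in% names(man) && !is.na(man$labels[i]) &&
        nzchar(man$labels[i])) {
      labs <- read_labels(man$labels[i])
      labels <- if (id %in% names(labs)) labs[[id]] else labs[[1]]
      if (nchar(labels) != nchar(residues)) {
        stop("record ", id, ": label string length differs from sequence")
      }
    }
    list(id = id, residues = residues, labels = labels,
         features = build_features(residues, profile), profile = profile)
  }
}
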