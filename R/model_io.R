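MODEL_FORMAT_VERSION <- 1L

#' Save a trained model to a JSON file
#'
#' The file records the format version, the architecture, the frozen label
#' and amino-acid alphabet orderings, every parameter tensor (flattened, with
#' its shape) at full floating-point precision, and training metadata, so
#' [load_model()] reproduces the parameters bit-exactly.
#'
#' @param model `deepcnf_model`.
#' @param path output path.
#' @export
save_model <- function(model, path) {
  spec <- model$spec
  tensors <- c(
    lapply(seq_along(model$params$W), function(k) {
      w <- model$params$W[[k]]
      list(name = paste0("W", k), shape = dim(w), values = as.numeric(w))
    }),
    list(list(name = "U", shape = dim(model$params$U),
              values = as.numeric(model$params$U)),
         list(name = "T", shape = dim(model$params$T),
              values = as.numeric(model$params$T)))
  )
  payload <- list(
    format_version = MODEL_FORMAT_VERSION,
    spec = list(input_width = spec$input_width,
                num_labels = spec$num_labels,
                hidden_sizes = spec$hidden_sizes,
                window = 2L * spec$half_window + 1L,
                activation = spec$activation),
    alphabets = list(labels = label_alphabet(spec$num_labels),
                     amino_acids = AA_ALPHABET),
    parameters = tensors,
    training_metadata = model$metadata
  )
  # digits = I(17): doubles round-trip bit-exactly through decimal text
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' Refuses files with a different format version, a truncated/garbled body,
#' or tensors whose shapes disagree with the recorded architecture.
#'
#' @param path model file.
#' @return `deepcnf_model` (without the training trace).
#' @export
load_model <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        stop("model file integrity error: ",
                             conditionMessage(e))
                      })
  if (is.null(payload$format_version) ||
      payload$format_version != MODEL_FORMAT_VERSION) {
    stop("model format version mismatch: file has ",
         payload$format_version %||% "none", ", expected ",
         MODEL_FORMAT_VERSION)
  }
  ps <- payload$spec
  spec <- deepcnf_spec(ps$input_width, ps$num_labels, ps$hidden_sizes,
                       ps$window, ps$activation)
  tensors <- payload$parameters
  get_tensor <- function(name, shape) {
    row <- which(tensors$name == name)
    if (length(row) != 1L) stop("model file is missing tensor ", name)
    vals <- tensors$values[[row]]
    got <- unlist(tensors$shape[[row]])
    if (!identical(as.integer(got), as.integer(shape)) ||
        length(vals) != prod(shape)) {
      stop("tensor ", name, " has shape ", paste(got, collapse = "x"),
           " with ", length(vals), " values; expected ",
           paste(shape, collapse = "x"))
    }
    array(as.numeric(vals), dim = shape)
  }
  m <- layer_widths(spec)
  W <- lapply(seq_along(spec$hidden_sizes), function(k) {
    get_tensor(paste0("W", k),
               c(2L * spec$half_window[k] + 1L, m[k], m[k + 1L]))
  })
  U <- get_tensor("U", c(m[length(m)], spec$num_labels))
  Tm <- get_tensor("T", c(spec$num_labels, spec$num_labels))
  if (!identical(unlist(payload$alphabets$labels),
                 label_alphabet(spec$num_labels))) {
    stop("model file label alphabet disagrees with the package's ordering")
  }
  structure(
    list(params = structure(list(W = W, U = matrix(U, m[length(m)]),
                                 T = matrix(Tm, spec$num_labels)),
                            class = "deepcnf_params"),
         spec = spec, config = NULL,
         objective = payload$training_metadata$final_objective,
         metadata = payload$training_metadata),
    class = "deepcnf_model"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
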