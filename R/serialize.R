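## Model serialization: human-readable JSON documents with an explicit
## schema version. Matrices are stored as named lists of numeric rows so a
## round trip is lossless (full double precision) for every field,
## including the covariance family code and the block partition.

DAMDA_SCHEMA <- "damda-model/1"

mat_to_list <- function(m) apply(unname(as.matrix(m)), 1L, as.numeric, simplify = FALSE)

list_to_mat <- function(l, path) {
  rows <- lapply(l, as.numeric)
  n <- lengths(rows)
  if (length(rows) == 0L || length(unique(n)) != 1L)
    stop(sprintf("model parse error at '%s': ragged or empty matrix", path),
         call. = FALSE)
  do.call(rbind, rows)
}

model_to_document <- function(model) {
  if (inherits(model, "edda")) {
    list(
      schema = DAMDA_SCHEMA, type = "edda",
      var_names = model$var_names, class_names = model$class_names,
      family = model$family, props = as.numeric(model$props),
      means = mat_to_list(model$means),
      sigmas = lapply(seq_along(model$class_names),
                      function(k) mat_to_list(model$sigmas[, , k])),
      bic = model$bic, loglik = model$loglik, df = model$df
    )
  } else if (inherits(model, "damda")) {
    list(
      schema = DAMDA_SCHEMA, type = "damda",
      var_names = model$var_names, class_names = model$class_names,
      K = model$K, H = model$H, p = model$p,
      props = as.numeric(model$props),
      means = mat_to_list(model$means),
      sigmas = lapply(seq_along(model$class_names),
                      function(k) mat_to_list(model$sigmas[, , k])),
      learned = model_to_document(model$learned),
      bic = model$bic, loglik = model$loglik
    )
  } else stop("unsupported model class", call. = FALSE)
}

require_field <- function(doc, field, path) {
  if (is.null(doc[[field]]))
    stop(sprintf("model parse error: missing field '%s%s'", path, field),
         call. = FALSE)
  doc[[field]]
}

document_to_model <- function(doc, path = "") {
  schema <- require_field(doc, "schema", path)
  if (!identical(schema, DAMDA_SCHEMA))
    stop(sprintf("model parse error: unsupported schema '%s'", schema),
         call. = FALSE)
  type <- require_field(doc, "type", path)
  vn <- as.character(require_field(doc, "var_names", path))
  cn <- as.character(require_field(doc, "class_names", path))
  means <- list_to_mat(require_field(doc, "means", path), paste0(path, "means"))
  sig_l <- require_field(doc, "sigmas", path)
  R <- length(vn)
  sigmas <- array(NA_real_, c(R, R, length(cn)))
  for (k in seq_along(cn))
    sigmas[, , k] <- list_to_mat(sig_l[[k]], sprintf("%ssigmas[%d]", path, k))
  rownames(means) <- vn
  props <- as.numeric(require_field(doc, "props", path))
  if (identical(type, "edda")) {
    new_edda(means = means, sigmas = sigmas, props = props,
             family = as.character(require_field(doc, "family", path)),
             var_names = vn, class_names = cn,
             bic = as.numeric(doc$bic), loglik = as.numeric(doc$loglik),
             df = as.numeric(doc$df))
  } else if (identical(type, "damda")) {
    learned <- document_to_model(require_field(doc, "learned", path),
                                 paste0(path, "learned."))
    m <- new_damda_model(means = means, sigmas = sigmas, props = props,
                         var_names = vn, class_names = cn,
                         K = as.integer(require_field(doc, "K", path)),
                         H = as.integer(require_field(doc, "H", path)),
                         p = as.integer(require_field(doc, "p", path)),
                         learned = learned)
    m$bic <- as.numeric(doc$bic)
    m$loglik <- as.numeric(doc$loglik)
    m
  } else stop(sprintf("model parse error: unknown type '%s'", type), call. = FALSE)
}

#' Write a fitted model to a JSON document
#'
#' @param model An `edda` or `damda` model object.
#' @param file Path of the JSON file to write.
#' @return `file`, invisibly.
#' @seealso [read_damda_model()]
#' @export
write_damda_model <- function(model, file) {
  doc <- model_to_document(model)
  ## 17 significant digits: doubles survive the text round trip bit-exactly
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), null = "null")
  writeLines(json, file)
  invisible(file)
}

#' Read a model written by [write_damda_model()]
#'
#' The round trip is lossless: all numeric fields are stored at full double
#' precision. A malformed or truncated document raises a parse error naming
#' the offending field; no partial model is returned.
#'
#' @param file Path of the JSON model document.
#' @return The restored `edda` or `damda` model object.
#' @export
read_damda_model <- function(file) {
  doc <- tryCatch(
    jsonlite::fromJSON(file, simplifyVector = FALSE),
    error = function(e)
      stop(sprintf("model parse error: %s", conditionMessage(e)), call. = FALSE)
  )
  document_to_model(doc)
}
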