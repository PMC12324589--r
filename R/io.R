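## Reading and writing delimited tables and the serialized model.

#' Read a delimited participant table
#'
#' TSV or CSV, autodetected by file extension; a header row is required
#' and `participant_id` is read as character. Lines starting with `#`
#' (provenance headers) are ignored.
#'
#' @param path file path ending in `.tsv` or `.csv`.
#' @return tibble.
#' @export
read_participant_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("input file not found: %s", path))
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else readr::read_tsv
  out <- reader(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  if ("participant_id" %in% names(out)) {
    out$participant_id <- as.character(out$participant_id)
  }
  out
}

## write a tibble as TSV with provenance comment headers
write_table_prov <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(sprintf("# %s: %s", names(provenance), unlist(provenance)), con)
  }
  cat(readr::format_tsv(df), file = con)
  invisible(path)
}

#' Serialize a fitted PLS model to JSON
#'
#' Writes weights, loadings, rotation, centering/scaling parameters,
#' feature names and block labels to a single structured JSON file from
#' which [read_pls_model()] reconstructs a model usable for
#' [pls_transform()] and [restrict_model()]. The training scores and
#' trait are not serialized.
#'
#' @param model a fitted `pls_model`.
#' @param path output path.
#' @param provenance optional named list stored alongside the arrays.
#' @return invisibly, `path`.
#' @export
write_pls_model <- function(model, path, provenance = NULL) {
  stopifnot(inherits(model, "pls_model"))
  obj <- list(
    format = "plsmodes/pls_model/1",
    n = model$n, n_components = model$n_components,
    feature_names = model$feature_names,
    block_labels = model$block_labels,
    weights = model$weights, loadings = model$loadings,
    y_loadings = model$y_loadings, rotation = model$rotation,
    x_mean = model$x_mean, x_scale = model$x_scale,
    y_mean = model$y_mean, y_scale = model$y_scale,
    scaled = model$scaled, blockwise = model$blockwise,
    ptw_condition = model$ptw_condition,
    provenance = provenance
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialized PLS model
#'
#' @param path a JSON file written by [write_pls_model()].
#' @return a `pls_model` (without training scores/trait; transform and
#'   restriction work as usual).
#' @export
read_pls_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("model file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "plsmodes/pls_model/1")) {
    abort("not a serialized plsmodes PLS model.")
  }
  fn <- obj$feature_names
  K <- obj$n_components
  dn <- list(fn, paste0("mode_", seq_len(K)))
  shape <- function(m) {
    m <- matrix(as.numeric(unlist(m)), nrow = length(fn), ncol = K)
    dimnames(m) <- dn
    m
  }
  structure(list(
    weights = shape(obj$weights), loadings = shape(obj$loadings),
    y_loadings = as.numeric(obj$y_loadings), scores = NULL,
    rotation = shape(obj$rotation),
    x_mean = setNames(as.numeric(obj$x_mean), fn),
    x_scale = setNames(as.numeric(obj$x_scale), fn),
    y_mean = obj$y_mean, y_scale = obj$y_scale,
    feature_names = fn, block_labels = obj$block_labels,
    trait = NULL, n = obj$n, n_components = K,
    scaled = obj$scaled, blockwise = obj$blockwise,
    ptw_condition = obj$ptw_condition
  ), class = "pls_model")
}
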