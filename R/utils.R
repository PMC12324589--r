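## Shared internal helpers: feature-table <-> matrix conversion, block
## bookkeeping, seed fan-out, and small validators.

#' Convert a feature table to a numeric matrix
#'
#' Feature tables are tibbles with a `participant_id` column followed by
#' numeric feature columns. This strips the id into rownames.
#' @param data a data frame with a `participant_id` column.
#' @return numeric matrix with participant ids as rownames.
#' @keywords internal
#' @noRd
as_feature_matrix <- function(data) {
  if (!is.data.frame(data)) {
    if (is.matrix(data)) return(data)
    abort("`data` must be a data frame or matrix.")
  }
  if (!"participant_id" %in% names(data)) {
    abort("feature tables must carry a `participant_id` column.")
  }
  ids <- as.character(data[["participant_id"]])
  X <- as.matrix(data[setdiff(names(data), "participant_id")])
  if (!is.numeric(X)) abort("feature columns must all be numeric.")
  if (anyNA(X)) abort("feature matrix contains missing values; apply complete-case filtering first.")
  rownames(X) <- ids
  X
}

## matrix -> tibble with participant_id first
matrix_to_table <- function(X, ids = rownames(X)) {
  out <- tibble::as_tibble(X, .name_repair = "minimal")
  tibble::add_column(out, participant_id = as.character(ids), .before = 1)
}

#' Infer modality block labels from feature names
#'
#' Feature names follow the `BLOCK_name` convention (e.g. `GMV_017`); the
#' block is the token before the first underscore.
#' @param feature_names character vector.
#' @return character vector of block labels.
#' @export
infer_blocks <- function(feature_names) {
  sub("_.*$", "", feature_names)
}

## deterministic per-stage child seeds derived from one master seed,
## kept below 2^31 so they remain valid R integers
child_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1)
  offs <- c(synth = 1L, phenome = 2L, transfer = 3L, permute = 4L,
            boot = 5L, participants = 6L, scan = 7L)
  k <- if (is.character(stage)) offs[[stage]] else as.integer(stage)
  as.integer((as.numeric(master) * 48271 + k * 10007) %% 2147483647)
}

## run code under a temporary RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must lie in [%s, %s].", name, lower, upper))
  }
  if (integer && x != round(x)) abort(sprintf("`%s` must be an integer.", name))
  invisible(x)
}

## Pearson correlation with two-sided p from the t transform (n-2 df)
cor_test_fast <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) return(list(r = NA_real_, p = NA_real_, n = n))
  xs <- x[ok]; ys <- y[ok]
  if (sd(xs) == 0 || sd(ys) == 0) return(list(r = NA_real_, p = NA_real_, n = n))
  r <- cor(xs, ys)
  r2 <- min(r^2, 1 - 1e-15)
  tval <- r * sqrt((n - 2) / (1 - r2))
  p <- 2 * pt(-abs(tval), df = n - 2)
  list(r = r, p = p, n = n)
}
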