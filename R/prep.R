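## Cohort preparation: trait recoding, exclusion filters, confound
## residualization.

#' Declared questionnaire levels for the diurnal-preference item
#'
#' The six self-report answers, in morning-to-evening order followed by
#' the two non-informative answers.
#' @return character vector of length 6.
#' @export
trait_levels <- function() {
  c("definitely a morning person",
    "more a morning than an evening person",
    "more an evening than a morning person",
    "definitely an evening person",
    "do not know",
    "prefer not to answer")
}

#' Declared levels for the shift-work flag fields
#' @return character vector; the first level means no shift work.
#' @export
shift_work_levels <- function() {
  c("Never/rarely", "Sometimes", "Usually", "Always")
}

#' Recode the 6-level diurnal-preference answer to -1/+1
#'
#' Morning answers ("definitely a morning person", "more a morning than an
#' evening person") code to -1 (early bird); evening answers code to +1
#' (night owl); "do not know" and "prefer not to answer" become `NA`.
#'
#' @param raw character vector of questionnaire answers.
#' @return numeric vector in \{-1, +1, NA\}.
#' @export
#' @examples
#' recode_chronotype(c("definitely a morning person", "definitely an evening person"))
recode_chronotype <- function(raw) {
  lv <- trait_levels()
  raw_chr <- as.character(raw)
  bad <- !is.na(raw_chr) & !raw_chr %in% lv
  if (any(bad)) {
    abort(sprintf("undeclared trait level(s): %s",
                  paste(sQuote(unique(raw_chr[bad])), collapse = ", ")))
  }
  out <- rep(NA_real_, length(raw_chr))
  out[raw_chr %in% lv[1:2]] <- -1
  out[raw_chr %in% lv[3:4]] <- 1
  out
}

#' Retain participants with concordant trait answers across instances
#'
#' Keeps only rows whose recoded trait is non-missing and identical at
#' both assessment instances, excluding participants whose coded answer
#' flipped between the initial and the imaging visit. Row order is
#' preserved.
#'
#' @param data data frame with the two instance columns.
#' @param instance_cols names of the two raw trait columns.
#' @return the retained rows of `data`, as a tibble, with a `trait`
#'   column holding the agreed -1/+1 code.
#' @export
filter_concordant <- function(data,
                              instance_cols = c("chronotype_0", "chronotype_2")) {
  stopifnot(length(instance_cols) == 2)
  missing_cols <- setdiff(instance_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing instance column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  c0 <- recode_chronotype(data[[instance_cols[1]]])
  c2 <- recode_chronotype(data[[instance_cols[2]]])
  keep <- !is.na(c0) & !is.na(c2) & c0 == c2
  out <- tibble::as_tibble(data[keep, , drop = FALSE])
  out$trait <- c0[keep]
  out
}

#' Exclude participants with any positive shift-work flag
#'
#' A participant is excluded when any listed flag column takes a level in
#' `positive_levels` at any instance. Missing flag values are treated as
#' no evidence of shift work (the participant is retained): exclusion
#' requires positive evidence.
#'
#' @param data data frame with the flag columns.
#' @param flag_cols names of the shift-work flag columns.
#' @param positive_levels levels counting as shift work.
#' @return the retained rows of `data`, as a tibble.
#' @export
filter_shift_workers <- function(data,
                                 flag_cols = c("shift_work_0", "shift_work_2",
                                               "night_shift_0", "night_shift_2"),
                                 positive_levels = shift_work_levels()[-1]) {
  missing_cols <- setdiff(flag_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing shift-work flag column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  exposed <- rep(FALSE, nrow(data))
  for (col in flag_cols) {
    v <- as.character(data[[col]])
    exposed <- exposed | (!is.na(v) & v %in% positive_levels)
  }
  tibble::as_tibble(data[!exposed, , drop = FALSE])
}

#' Residualize features on confound covariates
#'
#' Replaces every feature column by its least-squares residual on an
#' intercept plus the confound columns. Residual columns have zero mean
#' and zero sample correlation with every confound. Confounds are
#' z-scored before regression for numerical conditioning (residuals are
#' invariant to this). The operation is idempotent.
#'
#' @param features feature table (`participant_id` + numeric columns) or
#'   numeric matrix.
#' @param confounds confound table (`participant_id` optional) or numeric
#'   matrix, same row order as `features`.
#' @return residualized features in the same form as the input.
#' @export
residualize <- function(features, confounds) {
  X <- as_feature_matrix(features)
  C <- if (is.data.frame(confounds)) {
    as.matrix(confounds[setdiff(names(confounds), "participant_id")])
  } else as.matrix(confounds)
  if (nrow(C) != nrow(X)) {
    abort(sprintf("row mismatch: %d feature rows vs %d confound rows.",
                  nrow(X), nrow(C)))
  }
  if (anyNA(C)) abort("confound table contains missing values.")
  keep <- apply(C, 2, sd) > 0
  Cz <- scale(C[, keep, drop = FALSE])
  D <- cbind(`(Intercept)` = 1, Cz)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    abort("confound design is rank-deficient after z-scoring; drop duplicated or collinear confound columns.")
  }
  R <- qr.resid(qrD, X)
  colnames(R) <- colnames(X)
  if (is.data.frame(features)) matrix_to_table(R, rownames(X)) else R
}

#' Prepare a raw cohort for model fitting
#'
#' Applies, in order: trait recoding with the cross-instance concordance
#' filter, the shift-work exclusion, complete-case filtering of features
#' and confounds, and confound residualization of the feature matrix
#' (the trait is left untouched by default). The two exclusion filters
#' commute, so the order does not affect the retained set.
#'
#' @param participants raw participant table (see
#'   [simulate_participants()] for the expected columns).
#' @param features feature table keyed by `participant_id`.
#' @param confounds confound table keyed by `participant_id`.
#' @param residualize_trait also residualize the -1/+1 trait on the
#'   confounds (off by default; the imaging features are the object of
#'   confound removal).
#' @param instance_cols,flag_cols passed to the filters.
#' @return list of class `prepped_cohort`: `features` (residualized),
#'   `trait` (tibble: participant_id, trait), `confounds`, and `report`
#'   (counts removed by each step).
#' @export
prep_cohort <- function(participants, features, confounds,
                        residualize_trait = FALSE,
                        instance_cols = c("chronotype_0", "chronotype_2"),
                        flag_cols = c("shift_work_0", "shift_work_2",
                                      "night_shift_0", "night_shift_2")) {
  n0 <- nrow(participants)
  concordant <- filter_concordant(participants, instance_cols)
  n1 <- nrow(concordant)
  retained <- filter_shift_workers(concordant, flag_cols)
  n2 <- nrow(retained)

  ids <- intersect(retained$participant_id, features$participant_id)
  ids <- intersect(ids, confounds$participant_id)
  feat <- features[match(ids, features$participant_id), , drop = FALSE]
  conf <- confounds[match(ids, confounds$participant_id), , drop = FALSE]
  complete <- stats::complete.cases(feat) & stats::complete.cases(conf)
  ids <- ids[complete]
  feat <- feat[complete, , drop = FALSE]
  conf <- conf[complete, , drop = FALSE]
  n3 <- length(ids)
  if (n3 == 0) abort("no participants survive preparation.")

  trait <- retained$trait[match(ids, retained$participant_id)]
  feat_res <- residualize(feat, conf)
  if (residualize_trait) {
    trait <- as.numeric(residualize(matrix(trait, ncol = 1), conf))
  }
  structure(list(
    features = feat_res,
    trait = tibble::tibble(participant_id = ids, trait = trait),
    confounds = tibble::as_tibble(conf),
    report = list(
      n_input = n0,
      removed_discordant_or_missing = n0 - n1,
      removed_shift_work = n1 - n2,
      removed_incomplete = n2 - n3,
      n_retained = n3,
      n_positive = sum(trait > 0),
      n_negative = sum(trait < 0)
    )
  ), class = "prepped_cohort")
}

#' @export
print.prepped_cohort <- function(x, ...) {
  r <- x$report
  cat("<prepped_cohort> ", r$n_retained, " participants retained of ",
      r$n_input, "\n", sep = "")
  cat("  removed: ", r$removed_discordant_or_missing, " discordant/missing trait, ",
      r$removed_shift_work, " shift work, ", r$removed_incomplete,
      " incomplete\n", sep = "")
  cat("  trait split: ", r$n_positive, " coded +1, ", r$n_negative,
      " coded -1\n", sep = "")
  invisible(x)
}
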