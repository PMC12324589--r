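## Phenome-wide profiling of latent mode scores: mass-univariate Pearson
## scans with per-family Bonferroni correction (PheWAS / DiaWAS / MedWAS
## style), group-difference t-tests, and age-bracket stratification.

## coerce a scores input (pls_transform tibble, pls_model, or matrix)
as_score_matrix <- function(scores) {
  if (inherits(scores, "pls_model")) return(scores$scores)
  if (is.matrix(scores)) return(scores)
  if (is.data.frame(scores)) {
    cols <- grep("^mode_", names(scores), value = TRUE)
    if (length(cols) == 0) cols <- setdiff(names(scores), "participant_id")
    S <- as.matrix(scores[cols])
    if ("participant_id" %in% names(scores)) {
      rownames(S) <- as.character(scores$participant_id)
    }
    return(S)
  }
  abort("`scores` must be a pls_model, a scores tibble, or a matrix.")
}

#' Phenome-wide association scan of mode scores
#'
#' Correlates every component's x-scores with every phenotype column:
#' pairwise-complete Pearson correlation with a two-sided p-value from
#' the t transform on `n_used - 2` degrees of freedom. Binary 0/1
#' phenotypes are handled as numeric (the point-biserial correlation is
#' the Pearson correlation on the indicator). Family-wise correction is
#' Bonferroni at `alpha / family_size`, where the family size defaults to
#' the declared family total (e.g. 977 behavioral phenotypes), not the
#' per-test complete count. p-values are floored at the smallest positive
#' double before the `-log10` transform; floored records are flagged.
#'
#' @param scores a `pls_model`, a scores tibble from [pls_transform()],
#'   or a matrix.
#' @param phenome phenome table (`participant_id` + phenotype columns), a
#'   [simulate_phenome()] result, or a matrix. Participants are aligned
#'   by id when both sides carry ids, positionally otherwise.
#' @param categories optional tibble (`phenotype`, `category`) or named
#'   vector of per-column category labels.
#' @param family family label recorded on every record.
#' @param family_size Bonferroni denominator; defaults to the number of
#'   phenotype columns supplied.
#' @param alpha family-wise significance level.
#' @param constant_policy `"keep"`: constant phenotypes yield a record
#'   with `r = NA` and stay in the denominator; `"drop"`: they are
#'   removed and the denominator shrinks to the tested-column count
#'   (only when `family_size` is not given explicitly).
#' @return tibble of class `phewas_scan`, one row per component x
#'   phenotype: `component`, `phenotype`, `category`, `family`,
#'   `n_used`, `r`, `p`, `neg_log10_p`, `p_floored`,
#'   `passes_bonferroni`; the threshold and family size are attributes.
#' @export
phenome_scan <- function(scores, phenome, categories = NULL,
                         family = "behavior", family_size = NULL,
                         alpha = 0.05,
                         constant_policy = c("keep", "drop")) {
  constant_policy <- match.arg(constant_policy)
  check_scalar(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  S <- as_score_matrix(scores)
  family_size_given <- !is.null(family_size)

  meta <- NULL
  if (inherits(phenome, "synthetic_phenome")) {
    meta <- phenome$meta
    phenome <- phenome$values
  }
  P <- if (is.data.frame(phenome)) {
    M <- as.matrix(phenome[setdiff(names(phenome), "participant_id")])
    if ("participant_id" %in% names(phenome)) {
      rownames(M) <- as.character(phenome$participant_id)
    }
    M
  } else as.matrix(phenome)

  if (!is.null(rownames(S)) && !is.null(rownames(P))) {
    ids <- intersect(rownames(S), rownames(P))
    if (length(ids) == 0) abort("no shared participant ids between scores and phenome.")
    S <- S[ids, , drop = FALSE]
    P <- P[ids, , drop = FALSE]
  } else if (nrow(S) != nrow(P)) {
    abort("scores and phenome have different row counts and no shared ids.")
  }

  cat_lookup <- NULL
  if (!is.null(categories)) {
    cat_lookup <- if (is.data.frame(categories)) {
      setNames(categories$category, categories$phenotype)
    } else setNames(as.character(categories), names(categories) %||% colnames(P))
  } else if (!is.null(meta)) {
    cat_lookup <- setNames(meta$category, meta$phenotype)
  }

  constant <- apply(P, 2, function(v) sd(v, na.rm = TRUE) %in% c(0, NA) ||
                      is.na(sd(v, na.rm = TRUE)))
  if (constant_policy == "drop") {
    P <- P[, !constant, drop = FALSE]
    constant <- constant[!constant]
  }
  if (is.null(family_size)) family_size <- ncol(P)
  if (family_size < ncol(P)) {
    abort("`family_size` must be at least the number of tested phenotypes.")
  }
  threshold <- alpha / family_size

  K <- ncol(S)
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    sk <- S[, k]
    stats_list <- lapply(seq_len(ncol(P)), function(j) cor_test_fast(sk, P[, j]))
    r <- vapply(stats_list, `[[`, numeric(1), "r")
    p <- vapply(stats_list, `[[`, numeric(1), "p")
    n_used <- vapply(stats_list, `[[`, numeric(1), "n")
    p_floored <- !is.na(p) & p < .Machine$double.xmin
    p_eff <- pmax(p, .Machine$double.xmin)
    rows[[k]] <- tibble::tibble(
      component = colnames(S)[k] %||% paste0("mode_", k),
      phenotype = colnames(P),
      category = if (is.null(cat_lookup)) NA_character_ else
        unname(cat_lookup[colnames(P)]),
      family = family,
      n_used = as.integer(n_used),
      r = r,
      p = p_eff,
      neg_log10_p = -log10(p_eff),
      p_floored = p_floored,
      passes_bonferroni = !is.na(p_eff) & p_eff < threshold
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "alpha") <- alpha
  attr(out, "family_size") <- family_size
  attr(out, "threshold") <- threshold
  class(out) <- c("phewas_scan", class(out))
  out
}

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha family-wise level.
#' @param family_size number of tests in the family.
#' @return `alpha / family_size`.
#' @export
bonferroni_threshold <- function(alpha, family_size) {
  check_scalar(alpha, "alpha", lower = 1e-300, upper = 1)
  check_scalar(family_size, "family_size", lower = 1, integer = TRUE)
  alpha / family_size
}

#' Per-component two-sample t-test on mode scores
#'
#' Compares mode scores between two groups (e.g. female vs male).
#' Student's pooled-variance t-test by default; Welch optional. The sign
#' convention is mean(group coded 1) minus mean(group coded 0).
#'
#' @param scores a `pls_model`, scores tibble, or matrix.
#' @param group binary vector (0/1, logical, or two-level factor; the
#'   second level codes 1).
#' @param variant `"student"` (pooled) or `"welch"`.
#' @return tibble: `component`, `n0`, `n1`, `mean_diff`, `t`, `p`.
#' @export
group_difference <- function(scores, group, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  S <- as_score_matrix(scores)
  if (is.factor(group) || is.character(group)) {
    group <- as.integer(factor(group)) - 1L
  }
  g <- as.numeric(group)
  if (length(g) != nrow(S)) abort("`group` length must match the score rows.")
  if (!all(g %in% c(0, 1))) abort("`group` must be binary 0/1.")
  n0 <- sum(g == 0); n1 <- sum(g == 1)
  if (n0 < 2 || n1 < 2) abort("both groups must have at least 2 members.")
  res <- lapply(seq_len(ncol(S)), function(k) {
    x1 <- S[g == 1, k]; x0 <- S[g == 0, k]
    ht <- stats::t.test(x1, x0, var.equal = (variant == "student"))
    tibble::tibble(component = colnames(S)[k] %||% paste0("mode_", k),
                   n0 = n0, n1 = n1,
                   mean_diff = mean(x1) - mean(x0),
                   t = unname(ht$statistic), p = ht$p.value)
  })
  dplyr::bind_rows(res)
}

#' Age-bracket summary of mode scores
#'
#' Splits participants into ordered half-open age brackets
#' `[low, high)` -- an age on a shared printed endpoint (e.g. exactly 50
#' for brackets 40-50 and 50-55) goes to the upper bracket -- and
#' reports per bracket and component the count, mean and sample standard
#' deviation of the scores. Participants outside every bracket are
#' counted in the `unassigned` attribute.
#'
#' @param scores a `pls_model`, scores tibble, or matrix.
#' @param age numeric age vector (years or months), aligned with scores.
#' @param brackets either a numeric vector of ordered breakpoints
#'   (`c(40, 50, 55, 60, 65, 70)` gives 5 brackets) or a two-column
#'   data frame / matrix of (low, high) pairs, non-overlapping.
#' @return tibble: `bracket`, `low`, `high`, `component`, `n`,
#'   `mean_score`, `sd_score`; attribute `unassigned` holds the
#'   out-of-range count.
#' @export
stratify_age <- function(scores, age,
                         brackets = c(40, 50, 55, 60, 65, 70)) {
  S <- as_score_matrix(scores)
  age <- as.numeric(age)
  if (length(age) != nrow(S)) abort("`age` length must match the score rows.")
  if (is.data.frame(brackets) || is.matrix(brackets)) {
    B <- as.matrix(brackets)[, 1:2, drop = FALSE]
  } else {
    if (length(brackets) < 2 || is.unsorted(brackets, strictly = TRUE)) {
      abort("breakpoints must be strictly increasing.")
    }
    B <- cbind(brackets[-length(brackets)], brackets[-1])
  }
  o <- order(B[, 1])
  B <- B[o, , drop = FALSE]
  if (any(B[, 1] >= B[, 2])) abort("each bracket must have low < high.")
  if (nrow(B) > 1 && any(B[-1, 1] < B[-nrow(B), 2])) {
    abort("brackets overlap; they must be disjoint [low, high) intervals.")
  }
  lab <- sprintf("[%g,%g)", B[, 1], B[, 2])
  assign_idx <- rep(NA_integer_, length(age))
  for (b in seq_len(nrow(B))) {
    assign_idx[age >= B[b, 1] & age < B[b, 2]] <- b
  }
  rows <- list()
  for (b in seq_len(nrow(B))) {
    in_b <- which(assign_idx == b)
    for (k in seq_len(ncol(S))) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        bracket = lab[b], low = B[b, 1], high = B[b, 2],
        component = colnames(S)[k] %||% paste0("mode_", k),
        n = length(in_b),
        mean_score = if (length(in_b) > 0) mean(S[in_b, k]) else NA_real_,
        sd_score = if (length(in_b) > 1) sd(S[in_b, k]) else NA_real_
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "unassigned") <- sum(is.na(assign_idx))
  out
}

#' Manhattan-style plot of a phenome scan
#'
#' @param scan a [phenome_scan()] result.
#' @param components components to show (default all).
#' @return ggplot: phenotypes grouped by category on x, `-log10(p)` on
#'   y, the Bonferroni threshold as a dashed line.
#' @export
plot_manhattan <- function(scan, components = NULL) {
  stopifnot(inherits(scan, "phewas_scan"))
  d <- scan
  if (!is.null(components)) d <- dplyr::filter(d, .data$component %in% components)
  d <- dplyr::arrange(d, .data$category, .data$phenotype)
  d$idx <- stats::ave(seq_len(nrow(d)), d$component, FUN = seq_along)
  thr <- attr(scan, "threshold")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$idx, y = .data$neg_log10_p,
                                  color = .data$category)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = 2) +
    ggplot2::facet_wrap(~component, ncol = 1) +
    ggplot2::labs(x = "phenotype", y = expression(-log[10](p)),
                  color = "category") +
    ggplot2::theme_minimal()
}
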