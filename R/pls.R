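## Single-response partial least squares (NIPALS PLS1) between a
## participants x brain-features matrix and a -1/+1 trait, with the
## rotation R = W (P'W)^-1 that maps standardized features to x-scores
## and makes the model transferable to unseen cohorts.

## NIPALS PLS1 core on pre-standardized matrices. y is not deflated:
## after X-deflation the scores are orthogonal to the deflated columns,
## so X_d'(y - t c) = X_d'y and the two variants coincide for a single
## response.
pls_core <- function(Xs, ys, K, tol = 1e-10) {
  n <- nrow(Xs); p <- ncol(Xs)
  W <- matrix(0, p, K); P <- matrix(0, p, K)
  Tm <- matrix(0, n, K); cvec <- numeric(K)
  Xd <- Xs
  k_eff <- 0L
  x_norm0 <- sqrt(sum(Xs^2))
  for (k in seq_len(K)) {
    w <- crossprod(Xd, ys)
    wn <- sqrt(sum(w^2))
    if (wn <= tol * max(x_norm0, 1)) break
    w <- w / wn
    tk <- Xd %*% w
    tt <- sum(tk^2)
    if (tt <= tol^2 * n) break
    pk <- crossprod(Xd, tk) / tt
    ck <- sum(ys * tk) / tt
    Xd <- Xd - tcrossprod(tk, pk)
    k_eff <- k
    W[, k] <- w; P[, k] <- pk; Tm[, k] <- tk; cvec[k] <- ck
  }
  idx <- seq_len(k_eff)
  list(W = W[, idx, drop = FALSE], P = P[, idx, drop = FALSE],
       scores = Tm[, idx, drop = FALSE], y_loadings = cvec[idx],
       k = k_eff)
}

## extract a -1/+1 numeric trait vector from the accepted input forms
as_trait_vector <- function(trait, n = NULL) {
  y <- if (is.data.frame(trait)) {
    if (!"trait" %in% names(trait)) abort("trait table must have a `trait` column.")
    trait[["trait"]]
  } else trait
  y <- as.numeric(y)
  if (!is.null(n) && length(y) != n) {
    abort(sprintf("trait length %d does not match %d participants.", length(y), n))
  }
  if (anyNA(y)) abort("trait contains missing values; drop them before fitting.")
  y
}

#' Fit a supervised PLS covariation model
#'
#' Fits single-response NIPALS partial least squares between the feature
#' matrix and the trait: components are extracted sequentially, each
#' maximizing covariance with the trait and orthogonal (in score space)
#' to the previous ones via X-deflation. Features are centered and, by
#' default, scaled to unit variance inside the fit; the centering and
#' scaling parameters are stored so unseen data can be projected with
#' [pls_transform()] through the rotation `R = W (P'W)^-1`.
#'
#' @param features feature table (`participant_id` + numeric columns) or
#'   numeric matrix, no missing values.
#' @param trait -1/+1 numeric vector or a tibble with a `trait` column,
#'   aligned with the feature rows.
#' @param n_components number of latent components requested; reduced
#'   with a warning if the data rank is lower.
#' @param scale scale features to unit variance (default) in addition to
#'   centering; a center-only fit is obtained with `scale = FALSE`.
#' @param blockwise additionally divide each feature by the square root
#'   of its block size, giving every modality block equal total variance.
#'   Blocks are inferred from feature-name prefixes.
#' @return an object of class `pls_model` with elements `weights` (W,
#'   unit-norm columns), `loadings` (P), `y_loadings`, `scores` (T),
#'   `rotation` (R), `x_mean`, `x_scale`, `y_mean`, `y_scale`,
#'   `feature_names`, `block_labels`, `trait`, `n`, `n_components`.
#' @export
#' @examples
#' coh <- simulate_cohort(n = 100, truth = mode_truth(block_sizes = c(GMV = 8, FA = 4)))
#' fit <- pls_fit(coh$features, coh$trait, n_components = 2)
#' fit
pls_fit <- function(features, trait, n_components = 10, scale = TRUE,
                    blockwise = FALSE) {
  X <- as_feature_matrix(features)
  n <- nrow(X); p <- ncol(X)
  y <- as_trait_vector(trait, n)
  check_scalar(n_components, "n_components", lower = 1, integer = TRUE)
  if (n <= n_components) abort("need more participants than components.")
  if (sd(y) == 0) abort("trait is constant; a degenerate target cannot be fitted.")

  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, sd)
  x_scale <- if (scale) ifelse(x_sd > 0, x_sd, 1) else rep(1, p)
  block_labels <- infer_blocks(colnames(X))
  if (blockwise) {
    bsize <- table(block_labels)
    x_scale <- x_scale * sqrt(as.numeric(bsize[block_labels]))
  }
  Xs <- sweep(sweep(X, 2, x_mean, "-"), 2, x_scale, "/")
  y_mean <- mean(y); y_scale <- sd(y)
  ys <- (y - y_mean) / y_scale

  core <- pls_core(Xs, ys, n_components)
  if (core$k == 0) abort("no PLS component could be extracted (rank-deficient input).")
  if (core$k < n_components) {
    warn(sprintf("requested %d components but the data support only %d; reducing.",
                 n_components, core$k))
  }
  PtW <- crossprod(core$P, core$W)
  rotation <- core$W %*% solve(PtW)
  dn <- list(colnames(X), paste0("mode_", seq_len(core$k)))
  dimnames(core$W) <- dn; dimnames(core$P) <- dn; dimnames(rotation) <- dn
  colnames(core$scores) <- dn[[2]]
  rownames(core$scores) <- rownames(X)

  structure(list(
    weights = core$W, loadings = core$P, y_loadings = core$y_loadings,
    scores = core$scores, rotation = rotation,
    x_mean = x_mean, x_scale = x_scale, y_mean = y_mean, y_scale = y_scale,
    feature_names = colnames(X), block_labels = block_labels,
    trait = y, n = n, n_components = core$k,
    scaled = scale, blockwise = blockwise,
    ptw_condition = kappa(PtW, exact = TRUE)
  ), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", x$n_components, " component(s), ",
      length(x$feature_names), " features, n = ", x$n, "\n", sep = "")
  if (!is.null(x$scores) && !is.null(x$trait)) {
    r <- latent_correlation(x)
    cat("  latent trait correlations: ",
        paste(sprintf("%s r=%.3f", r$component, r$r), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Per-component Pearson correlation between x-scores and the trait
#'
#' The per-mode latent correlation `rho_k = cor(T[, k], y)` is the
#' statistic carried through permutation testing and reported per
#' subtype, with a two-sided p-value from the t transform on n - 2
#' degrees of freedom.
#'
#' @param model a fitted `pls_model`.
#' @param trait optional trait vector/tibble; defaults to the training
#'   trait stored in the model.
#' @return tibble with `component`, `r`, `p`, `n`.
#' @export
latent_correlation <- function(model, trait = NULL) {
  stopifnot(inherits(model, "pls_model"))
  y <- if (is.null(trait)) model$trait else as_trait_vector(trait, nrow(model$scores))
  if (length(y) < 3) abort("need at least 3 participants for a correlation.")
  res <- purrr::map(seq_len(model$n_components), function(k) {
    ct <- cor_test_fast(model$scores[, k], y)
    tibble::tibble(component = colnames(model$scores)[k], r = ct$r,
                   p = ct$p, n = ct$n)
  })
  dplyr::bind_rows(res)
}

#' Project data through a fitted model's rotation
#'
#' Computes `scores = ((X_new - x_mean) / x_scale) %*% R`; on the
#' training data this reproduces the stored x-scores (the defining
#' identity of the rotation). Columns are matched to the model by feature
#' name, not position.
#'
#' @param model a fitted `pls_model`.
#' @param features feature table or matrix whose columns cover the
#'   model's features.
#' @return tibble of scores: `participant_id` plus one `mode_k` column
#'   per component.
#' @export
pls_transform <- function(model, features) {
  stopifnot(inherits(model, "pls_model"))
  X <- as_feature_matrix(features)
  missing_f <- setdiff(model$feature_names, colnames(X))
  extra_f <- setdiff(colnames(X), model$feature_names)
  if (length(missing_f) > 0) {
    abort(sprintf("new data lacks %d model feature(s), e.g. %s",
                  length(missing_f), paste(head(missing_f, 3), collapse = ", ")))
  }
  if (length(extra_f) > 0) {
    warn(sprintf("ignoring %d feature(s) unknown to the model.", length(extra_f)))
  }
  X <- X[, model$feature_names, drop = FALSE]
  Xs <- sweep(sweep(X, 2, model$x_mean, "-"), 2, model$x_scale, "/")
  S <- Xs %*% model$rotation
  matrix_to_table(S, rownames(X) %||% seq_len(nrow(X)))
}

#' Fix the arbitrary signs of PLS components
#'
#' PLS component signs are arbitrary: flipping a column of W, P, c, T and
#' R jointly leaves the model equivalent. `trait_positive` flips each
#' component so its latent trait correlation is non-negative;
#' `loading_max_positive` so the largest-magnitude x-loading is positive.
#' Correlation magnitudes and the `T P'` reconstruction are unchanged.
#'
#' @param model a fitted `pls_model`.
#' @param convention sign convention.
#' @return the model with aligned signs; idempotent.
#' @export
align_signs <- function(model,
                        convention = c("trait_positive", "loading_max_positive")) {
  stopifnot(inherits(model, "pls_model"))
  convention <- match.arg(convention)
  flip <- vapply(seq_len(model$n_components), function(k) {
    if (convention == "trait_positive") {
      r <- cor(model$scores[, k], model$trait)
      r < 0
    } else {
      pk <- model$loadings[, k]
      pk[which.max(abs(pk))] < 0
    }
  }, logical(1))
  s <- ifelse(flip, -1, 1)
  model$weights <- sweep(model$weights, 2, s, "*")
  model$loadings <- sweep(model$loadings, 2, s, "*")
  model$rotation <- sweep(model$rotation, 2, s, "*")
  model$scores <- sweep(model$scores, 2, s, "*")
  model$y_loadings <- model$y_loadings * s
  model
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted PLS model into a long feature table
#'
#' @param x a `pls_model`.
#' @param ... unused.
#' @return tibble with one row per feature x component: `feature`,
#'   `block`, `component`, `weight`, `loading`.
#' @exportS3Method
tidy.pls_model <- function(x, ...) {
  K <- x$n_components
  tibble::tibble(
    feature = rep(x$feature_names, K),
    block = rep(x$block_labels, K),
    component = rep(colnames(x$scores), each = length(x$feature_names)),
    weight = as.numeric(x$weights),
    loading = as.numeric(x$loadings)
  )
}

#' One-row model summary
#'
#' @param x a `pls_model`.
#' @param ... unused.
#' @return tibble with `n`, `n_features`, `n_components`, `r_mode_1`
#'   (leading latent trait correlation), and the condition number of
#'   `P'W`.
#' @exportS3Method
glance.pls_model <- function(x, ...) {
  r <- latent_correlation(x)
  tibble::tibble(
    n = x$n, n_features = length(x$feature_names),
    n_components = x$n_components,
    r_mode_1 = r$r[1],
    ptw_condition = x$ptw_condition
  )
}

#' Plot per-block loadings of a fitted PLS model
#'
#' @param object a `pls_model`.
#' @param components components to display (default all).
#' @param ... unused.
#' @return a ggplot object: features on x, loadings on y, faceted by
#'   component, colored by modality block.
#' @exportS3Method
autoplot.pls_model <- function(object, components = NULL, ...) {
  d <- tidy(object)
  if (!is.null(components)) d <- dplyr::filter(d, .data$component %in% components)
  d$idx <- rep(seq_along(object$feature_names), length.out = nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$idx, y = .data$loading,
                                  fill = .data$block)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_wrap(~component, ncol = 1) +
    ggplot2::labs(x = "feature", y = "x-loading", fill = "block") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
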