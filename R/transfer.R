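## Cross-cohort transfer: restrict a trained model to a feature block and
## project an unseen cohort into the source latent space through the
## recomputed rotation R_sub = W_sub (P_sub' W_sub)^-1.

#' Restrict a trained PLS model to a feature block
#'
#' Subsets the x-weights and x-loadings to the kept features and
#' recomputes the rotation from the restricted matrices,
#' `R_sub = W_sub (P_sub' W_sub)^-1`. The rotation is recomputed, not
#' sliced from the parent rotation: the inverse must apply to the
#' restricted `P'W`, which is what makes projection from a feature
#' subset well defined.
#'
#' @param model a fitted `pls_model`.
#' @param block a block name (e.g. `"GMV"`), several block names, or an
#'   explicit character vector of feature names.
#' @param max_condition error when the condition number of `P_sub' W_sub`
#'   exceeds this bound (near-singularity).
#' @return object of class `pls_model_restricted` with `kept_features`,
#'   `weights`, `loadings`, `rotation`, `x_mean`, `x_scale`,
#'   `n_components`, `ptw_condition`, and parent provenance.
#' @export
restrict_model <- function(model, block, max_condition = 1e8) {
  stopifnot(inherits(model, "pls_model"))
  if (length(block) == 0) abort("`block` must be non-empty.")
  if (all(block %in% model$block_labels)) {
    keep <- model$block_labels %in% block
  } else if (all(block %in% model$feature_names)) {
    keep <- model$feature_names %in% block
  } else {
    abort(sprintf("unknown block or feature names: %s; available blocks: %s",
                  paste(head(setdiff(block, c(model$block_labels, model$feature_names)), 3),
                        collapse = ", "),
                  paste(unique(model$block_labels), collapse = ", ")))
  }
  K <- model$n_components
  if (sum(keep) < K) {
    abort(sprintf("restriction keeps %d feature(s) but the model has %d components; P_sub'W_sub is singular.",
                  sum(keep), K))
  }
  W_sub <- model$weights[keep, , drop = FALSE]
  P_sub <- model$loadings[keep, , drop = FALSE]
  PtW <- crossprod(P_sub, W_sub)
  cond <- tryCatch(kappa(PtW, exact = TRUE), error = function(e) Inf)
  if (!is.finite(cond) || cond > max_condition) {
    abort(sprintf("P_sub'W_sub is near-singular (condition %.3g); use fewer components or a larger block.", cond))
  }
  R_sub <- W_sub %*% solve(PtW)
  structure(list(
    kept_features = model$feature_names[keep],
    block_labels = model$block_labels[keep],
    weights = W_sub, loadings = P_sub, rotation = R_sub,
    x_mean = model$x_mean[keep], x_scale = model$x_scale[keep],
    n_components = K, ptw_condition = cond,
    parent = list(n = model$n, n_features = length(model$feature_names),
                  n_components = model$n_components,
                  fingerprint = signif(sum(model$weights^2 *
                                             seq_along(model$weights)), 12))
  ), class = "pls_model_restricted")
}

#' @export
print.pls_model_restricted <- function(x, ...) {
  cat("<pls_model_restricted> ", length(x$kept_features), " feature(s) (",
      paste(unique(x$block_labels), collapse = ", "), "), ",
      x$n_components, " component(s)\n", sep = "")
  cat("  P'W condition number:", format(x$ptw_condition, digits = 4), "\n")
  invisible(x)
}

#' Project an unseen cohort into the source latent space
#'
#' Applies `scores = standardized(X_target) %*% R_sub`, the
#' block-restricted rotation of the trained source model. By default the
#' target cohort is standardized with its own column means and standard
#' deviations (`centering = "target"`), since source and target cohorts
#' typically come from different scanners, age ranges and preprocessing
#' and their raw feature scales are not comparable;
#' `centering = "source"` reuses the source model's stored parameters for
#' strict formula replication, and `centering = "none"` applies the
#' rotation to the raw values (the projection is then exactly linear).
#'
#' @param rmodel a `pls_model_restricted` (or a full `pls_model`, which
#'   is treated as restricted to all features).
#' @param features target-cohort feature table or matrix covering the
#'   kept features.
#' @param centering `"target"`, `"source"`, or `"none"`.
#' @return tibble of projected scores: `participant_id` plus `mode_k`
#'   columns.
#' @export
project_cohort <- function(rmodel, features,
                           centering = c("target", "source", "none")) {
  centering <- match.arg(centering)
  if (inherits(rmodel, "pls_model")) {
    rmodel <- restrict_model(rmodel, unique(rmodel$block_labels))
  }
  stopifnot(inherits(rmodel, "pls_model_restricted"))
  X <- as_feature_matrix(features)
  missing_f <- setdiff(rmodel$kept_features, colnames(X))
  if (length(missing_f) > 0) {
    abort(sprintf("target data lacks %d kept feature(s), e.g. %s",
                  length(missing_f), paste(head(missing_f, 3), collapse = ", ")))
  }
  X <- X[, rmodel$kept_features, drop = FALSE]
  Xs <- switch(centering,
    target = {
      mu <- colMeans(X)
      sds <- apply(X, 2, sd)
      sds[sds == 0] <- 1
      sweep(sweep(X, 2, mu, "-"), 2, sds, "/")
    },
    source = sweep(sweep(X, 2, rmodel$x_mean, "-"), 2, rmodel$x_scale, "/"),
    none = X
  )
  S <- Xs %*% rmodel$rotation
  colnames(S) <- paste0("mode_", seq_len(ncol(S)))
  matrix_to_table(S, rownames(X) %||% seq_len(nrow(X)))
}
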