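## Permutation significance of latent modes and bootstrap stability of
## x-loadings with Hungarian component matching.

## standardize once; shared by the resampling loops
standardize_for_pls <- function(features, trait, scale = TRUE) {
  X <- as_feature_matrix(features)
  y <- as_trait_vector(trait, nrow(X))
  if (sd(y) == 0) abort("trait is constant; a degenerate target cannot be permuted.")
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, sd)
  x_scale <- if (scale) ifelse(x_sd > 0, x_sd, 1) else rep(1, ncol(X))
  Xs <- sweep(sweep(X, 2, x_mean, "-"), 2, x_scale, "/")
  ys <- (y - mean(y)) / sd(y)
  list(Xs = Xs, ys = ys, y = y, feature_names = colnames(X))
}

#' Permutation test of latent-mode significance
#'
#' Holds the brain features fixed while the trait vector is randomly
#' shuffled across participants, refits the complete PLS on each
#' permutation, and records the absolute latent correlation `|rho_k|`
#' between each component's x-scores and the permuted trait. This builds
#' an empirical null distribution of the latent correlation per
#' component under no brain-trait association. The p-value uses the
#' add-one estimator `p_k = (1 + #(|rho_null| >= |rho_obs|)) / (1 + n_perm)`,
#' whose lower bound `1/(n_perm + 1)` corresponds to the observed
#' correlation exceeding every null model; a component is declared
#' significant when `p_k <= alpha`, so that an observed correlation
#' beating all 999 of 999 permutations rejects at alpha = 0.001.
#' Comparison is two-sided on `|rho|` because component signs are
#' arbitrary.
#'
#' @param features feature table or matrix.
#' @param trait -1/+1 trait vector or tibble with a `trait` column.
#' @param n_components components to extract and test simultaneously.
#' @param n_perm number of permutation iterations (>= 1; 1000 is the
#'   conventional default).
#' @param alpha component-wise significance threshold (default 0.001).
#' @param seed integer seed; identical seeds reproduce the null draws.
#' @param scale passed to the PLS standardization.
#' @return object of class `pls_permutation`: a result tibble
#'   (`component`, `observed_rho`, `p_value`, `significant`) plus the
#'   `null_rhos` matrix (n_perm x K), `alpha`, `n_perm`, `seed`.
#' @export
pls_permutation_test <- function(features, trait, n_components = 10,
                                 n_perm = 1000, alpha = 0.001, seed = 1,
                                 scale = TRUE) {
  check_scalar(n_perm, "n_perm", lower = 1, integer = TRUE)
  check_scalar(alpha, "alpha", lower = 1e-12, upper = 1)
  st <- standardize_for_pls(features, trait, scale)
  obs <- pls_core(st$Xs, st$ys, n_components)
  K <- obs$k
  obs_rho <- as.numeric(cor(obs$scores, st$ys))

  null_rhos <- with_seed(child_seed(seed, "permute"), {
    out <- matrix(NA_real_, n_perm, K)
    for (b in seq_len(n_perm)) {
      yp <- st$ys[sample.int(length(st$ys))]
      fit <- pls_core(st$Xs, yp, K)
      rho <- rep(0, K)
      if (fit$k > 0) rho[seq_len(fit$k)] <- as.numeric(cor(fit$scores, yp))
      out[b, ] <- rho
    }
    out
  })
  colnames(null_rhos) <- paste0("mode_", seq_len(K))
  p_value <- vapply(seq_len(K), function(k) {
    (1 + sum(abs(null_rhos[, k]) >= abs(obs_rho[k]))) / (1 + n_perm)
  }, numeric(1))
  structure(list(
    result = tibble::tibble(
      component = paste0("mode_", seq_len(K)),
      observed_rho = obs_rho,
      p_value = p_value,
      significant = p_value <= alpha
    ),
    null_rhos = null_rhos,
    alpha = alpha, n_perm = as.integer(n_perm), seed = as.integer(seed)
  ), class = "pls_permutation")
}

#' @export
print.pls_permutation <- function(x, ...) {
  cat("<pls_permutation> ", x$n_perm, " permutations, alpha = ", x$alpha,
      "\n", sep = "")
  print(x$result)
  invisible(x)
}

#' @exportS3Method
tidy.pls_permutation <- function(x, ...) x$result

#' @exportS3Method
glance.pls_permutation <- function(x, ...) {
  tibble::tibble(n_perm = x$n_perm, alpha = x$alpha,
                 n_significant = sum(x$result$significant))
}

#' Bootstrap stability of PLS x-loadings
#'
#' Refits the complete PLS on resamples of the participants drawn with
#' replacement at the original sample size. Each bootstrapped loading
#' matrix is matched to the full-sample reference model's components by
#' Hungarian assignment on the absolute column-correlation similarity
#' matrix and sign-aligned before being recorded, so component order and
#' orientation are comparable across resamples. Per-entry percentile
#' confidence intervals (default the 5th-95th band) are computed across
#' the matched loadings; an entry is flagged stable ("significant") when
#' its interval excludes zero.
#'
#' Resamples with a constant trait are redrawn (and counted); more than
#' 10 percent redraws raises an error.
#'
#' @param features feature table or matrix.
#' @param trait -1/+1 trait vector or tibble with a `trait` column.
#' @param n_components components fitted and matched.
#' @param n_boot number of bootstrap iterations (>= 2; 1000 is the
#'   conventional default).
#' @param percentiles lower/upper percentile bounds (in percent).
#' @param seed integer seed.
#' @param scale passed to the PLS standardization.
#' @return object of class `loading_stability`: `ci` tibble (`feature`,
#'   `block`, `component`, `loading`, `ci_low`, `ci_high`,
#'   `significant`), the matched `boot_loadings` array
#'   (n_boot x p x K), `percentiles`, `n_boot`, `n_redraws`.
#' @export
pls_bootstrap_loadings <- function(features, trait, n_components = 5,
                                   n_boot = 1000, percentiles = c(5, 95),
                                   seed = 1, scale = TRUE) {
  check_scalar(n_boot, "n_boot", lower = 2, integer = TRUE)
  if (length(percentiles) != 2 || percentiles[1] >= percentiles[2]) {
    abort("`percentiles` must be an increasing pair, in percent.")
  }
  X <- as_feature_matrix(features)
  y <- as_trait_vector(trait, nrow(X))
  ref <- pls_fit(X, y, n_components = n_components, scale = scale)
  K <- ref$n_components
  n <- nrow(X); p <- ncol(X)

  boot <- array(NA_real_, dim = c(n_boot, p, K))
  n_redraws <- 0L
  max_redraws <- ceiling(0.1 * n_boot)
  with_seed(child_seed(seed, "boot"), {
    b <- 1L
    while (b <= n_boot) {
      idx <- sample.int(n, n, replace = TRUE)
      yb <- y[idx]
      if (sd(yb) == 0) {
        n_redraws <- n_redraws + 1L
        if (n_redraws > max_redraws) {
          abort("more than 10% of bootstrap resamples had a constant trait; the split is too unbalanced for stable resampling.")
        }
        next
      }
      Xb <- X[idx, , drop = FALSE]
      x_mean <- colMeans(Xb)
      x_sd <- apply(Xb, 2, sd)
      x_scale <- if (scale) ifelse(x_sd > 0, x_sd, 1) else rep(1, p)
      Xs <- sweep(sweep(Xb, 2, x_mean, "-"), 2, x_scale, "/")
      ys <- (yb - mean(yb)) / sd(yb)
      fit <- pls_core(Xs, ys, K)
      if (fit$k < K) {
        n_redraws <- n_redraws + 1L
        if (n_redraws > max_redraws) {
          abort("more than 10% of bootstrap resamples were rank-deficient.")
        }
        next
      }
      m <- match_components(fit$P, ref$loadings, warn_degenerate = FALSE)
      boot[b, , ] <- sweep(fit$P[, m$order, drop = FALSE], 2, m$signs, "*")
      b <- b + 1L
    }
  })

  probs <- percentiles / 100
  ci_low <- apply(boot, c(2, 3), quantile, probs = probs[1])
  ci_high <- apply(boot, c(2, 3), quantile, probs = probs[2])
  significant <- ci_low > 0 | ci_high < 0
  structure(list(
    ci = tibble::tibble(
      feature = rep(ref$feature_names, K),
      block = rep(ref$block_labels, K),
      component = rep(paste0("mode_", seq_len(K)), each = p),
      loading = as.numeric(ref$loadings),
      ci_low = as.numeric(ci_low),
      ci_high = as.numeric(ci_high),
      significant = as.logical(significant)
    ),
    boot_loadings = boot,
    reference = ref,
    percentiles = percentiles,
    n_boot = as.integer(n_boot),
    n_redraws = n_redraws,
    seed = as.integer(seed)
  ), class = "loading_stability")
}

#' @export
print.loading_stability <- function(x, ...) {
  cat("<loading_stability> ", x$n_boot, " bootstrap iterations, ",
      paste(x$percentiles, collapse = "-"), "% interval\n", sep = "")
  tab <- dplyr::count(x$ci, .data$component, stable = .data$significant)
  print(tidyr::pivot_wider(tab, names_from = "stable", values_from = "n"))
  invisible(x)
}

#' @exportS3Method
tidy.loading_stability <- function(x, ...) x$ci

#' Plot bootstrap loading stability
#'
#' @param object a `loading_stability` result.
#' @param component which component to display.
#' @param ... unused.
#' @return ggplot: per-feature reference loading with its percentile
#'   interval; entries whose interval excludes zero are highlighted.
#' @exportS3Method
autoplot.loading_stability <- function(object, component = "mode_1", ...) {
  d <- dplyr::filter(object$ci, .data$component == !!component)
  d$idx <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$idx, y = .data$loading,
                                  color = .data$significant)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "feature", y = "x-loading",
                  color = "CI excludes 0", title = component) +
    ggplot2::theme_minimal()
}
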