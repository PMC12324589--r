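test_that("single-feature fit collapses to the standardized column", {
  set.seed(1)
  x <- rnorm(40)
  y <- rep(c(-1, 1), 20)
  X <- matrix(x, dimnames = list(NULL, "GMV_001"))
  fit <- pls_fit(X, y, n_components = 1)
  expect_equal(abs(unname(fit$weights[1, 1])), 1, tolerance = 1e-12)
  expect_equal(unname(fit$scores[, 1] * sign(fit$weights[1, 1])),
               as.numeric(scale(x)), tolerance = 1e-10)
  expect_equal(latent_correlation(fit)$r[1] * sign(fit$weights[1, 1]),
               cor(x, y), tolerance = 1e-12)
})

test_that("degenerate inputs are rejected or reduced", {
  X <- rand_features(30, 5)
  expect_error(pls_fit(X, rep(1, 30)), "constant")
  Xna <- X; Xna[2, 3] <- NA
  expect_error(pls_fit(Xna, rep(c(-1, 1), 15)), "missing")
  ## K above the data rank is reduced with a warning
  Xlow <- cbind(X[, 1:2], X[, 1:2] %*% matrix(rnorm(6), 2, 3))
  colnames(Xlow) <- sprintf("F_%03d", 1:5)
  expect_warning(fit <- pls_fit(Xlow, rep(c(-1, 1), 15), n_components = 5),
                 "reduc")
  expect_lte(fit$n_components, 2L)
})

test_that("planted rank-1 structure is recovered exactly without noise", {
  tr <- mode_truth(block_sizes = c(GMV = 10, FA = 4, FC = 6), k_modes = 1,
                   mode_strengths = 1, trait_weights = 1, trait_noise_sd = 0.5,
                   noise_sd = 0, sex_effect = 0, age_slope = 0,
                   confound_strength = 0, seed = 2)
  coh <- simulate_cohort(n = 200, truth = tr, seed = 3)
  fit <- pls_fit(coh$features, coh$trait, n_components = 1, scale = FALSE)
  cosine <- abs(sum(fit$weights[, 1] * tr$planted_loadings[, 1]))
  expect_gt(cosine, 0.999)
})

test_that("scores are orthogonal and the rotation identity holds on training data", {
  coh <- simulate_cohort(n = 150, truth = tiny_truth(9), seed = 5)
  fit <- pls_fit(coh$features, coh$trait, n_components = 4)
  G <- crossprod(fit$scores)
  offdiag <- max(abs(G[upper.tri(G)])) / max(diag(G))
  expect_lt(offdiag, 1e-6)
  ## T = X_std R
  X <- as.matrix(coh$features[, -1])
  Xs <- sweep(sweep(X, 2, fit$x_mean, "-"), 2, fit$x_scale, "/")
  expect_lt(max(abs(fit$scores - Xs %*% fit$rotation)), 1e-8)
  ## transform() reproduces the stored scores, under shuffled column order
  shuffled <- coh$features[, c(1, sample(2:ncol(coh$features)))]
  sc <- pls_transform(fit, shuffled)
  expect_equal(unname(as.matrix(sc[, -1])), unname(fit$scores),
               tolerance = 1e-8, ignore_attr = TRUE)
  ## rows equal to the training mean map to zero scores
  Xm <- matrix(fit$x_mean, 3, length(fit$x_mean), byrow = TRUE,
               dimnames = list(NULL, fit$feature_names))
  expect_lt(max(abs(as.matrix(pls_transform(fit, Xm)[, -1]))), 1e-10)
  ## missing features are a schema error
  expect_error(pls_transform(fit, X[, -3]), "lacks")
})

test_that("new-data transform equals the explicit rotation solve", {
  coh <- simulate_cohort(n = 120, truth = tiny_truth(12), seed = 6)
  fit <- pls_fit(coh$features, coh$trait, n_components = 3)
  Xnew <- rand_features(15, length(fit$feature_names), seed = 7)
  colnames(Xnew) <- fit$feature_names
  got <- as.matrix(pls_transform(fit, Xnew)[, -1])
  Xs <- sweep(sweep(Xnew, 2, fit$x_mean, "-"), 2, fit$x_scale, "/")
  want <- Xs %*% fit$weights %*% solve(crossprod(fit$loadings, fit$weights))
  expect_equal(unname(got), unname(want), tolerance = 1e-10)
})

test_that("fitted scores match the reference NIPALS implementation up to sign", {
  for (seed in 1:3) {
    X <- rand_features(50, 20, seed = seed)
    set.seed(seed + 100)
    y <- sample(c(-1, 1), 50, replace = TRUE, prob = c(2, 1) / 3)
    fit <- pls_fit(X, y, n_components = 4)
    ref <- mixOmics::pls(X, matrix(y), ncomp = 4, mode = "regression",
                         scale = TRUE)
    for (k in 1:4) {
      a <- fit$scores[, k]; b <- ref$variates$X[, k]
      s <- sign(sum(a * b))
      expect_lt(max(abs(a - s * b)), 1e-6)
    }
  }
})

test_that("sign alignment is idempotent and preserves the model", {
  coh <- simulate_cohort(n = 100, truth = tiny_truth(2), seed = 9)
  fit <- pls_fit(coh$features, coh$trait, n_components = 3)
  al <- align_signs(fit, "trait_positive")
  expect_true(all(latent_correlation(al)$r >= 0))
  expect_equal(abs(latent_correlation(al)$r), abs(latent_correlation(fit)$r),
               tolerance = 1e-12)
  expect_equal(align_signs(al, "trait_positive"), al)
  ## X reconstruction T P' is invariant under any sign convention
  expect_equal(al$scores %*% t(al$loadings), fit$scores %*% t(fit$loadings),
               tolerance = 1e-10)
  al2 <- align_signs(fit, "loading_max_positive")
  picks <- apply(al2$loadings, 2, function(p) p[which.max(abs(p))])
  expect_true(all(picks > 0))
})

test_that("latent correlations match the hand Pearson formula on a printed toy", {
  xs <- c(1.2, -0.4, 0.8, 2.1, -1.5, 0.3, -0.9, 1.7, -2.2, 0.6)
  y <- c(1, -1, 1, 1, -1, -1, -1, 1, -1, 1)
  fit <- pls_fit(matrix(xs, dimnames = list(NULL, "GMV_001")), y, 1)
  want <- pearson_oracle(xs, y)
  got <- latent_correlation(fit)
  expect_equal(abs(got$r), abs(want$r), tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  ## a score orthogonalized against y correlates at 0
  set.seed(3)
  z <- rnorm(10)
  z_perp <- residuals(lm(z ~ y))
  expect_lt(abs(cor(z_perp, y)), 1e-12)
})

test_that("tidy, glance and serialization round-trip the model", {
  coh <- simulate_cohort(n = 80, truth = tiny_truth(8), seed = 4)
  fit <- pls_fit(coh$features, coh$trait, n_components = 2)
  td <- tidy(fit)
  expect_identical(nrow(td), 2L * length(fit$feature_names))
  expect_named(td, c("feature", "block", "component", "weight", "loading"))
  gl <- glance(fit)
  expect_identical(gl$n_components, 2L)

  path <- withr::local_tempfile(fileext = ".json")
  write_pls_model(fit, path)
  back <- read_pls_model(path)
  expect_equal(back$rotation, fit$rotation, tolerance = 1e-12)
  sc <- pls_transform(back, coh$features)
  expect_equal(unname(as.matrix(sc[, -1])), unname(fit$scores),
               tolerance = 1e-8)
})

test_that("blockwise scaling equalizes block variance shares", {
  coh <- simulate_cohort(n = 100, truth = tiny_truth(3), seed = 7)
  fit <- pls_fit(coh$features, coh$trait, n_components = 2, blockwise = TRUE)
  X <- as.matrix(coh$features[, -1])
  Xs <- sweep(sweep(X, 2, fit$x_mean, "-"), 2, fit$x_scale, "/")
  v <- tapply(apply(Xs, 2, stats::var), fit$block_labels, sum)
  expect_lt(diff(range(v)), 1e-6)
})
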