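test_that("identical seeds reproduce every output bit-exactly", {
  a <- simulate_cohort(n = 60, truth = tiny_truth(3), seed = 11)
  b <- simulate_cohort(n = 60, truth = tiny_truth(3), seed = 11)
  expect_identical(a$features, b$features)
  expect_identical(a$trait, b$trait)
  expect_identical(a$confounds, b$confounds)
  expect_identical(a$truth$latent_scores, b$truth$latent_scores)
  d <- simulate_cohort(n = 60, truth = tiny_truth(3), seed = 12)
  expect_false(identical(a$features, d$features))

  pa <- simulate_phenome(a, n_pheno = 30, seed = 5)
  pb <- simulate_phenome(b, n_pheno = 30, seed = 5)
  expect_identical(pa$values, pb$values)
  ta <- simulate_transfer_cohort(a$truth, n2 = 40, seed = 9)
  tb <- simulate_transfer_cohort(b$truth, n2 = 40, seed = 9)
  expect_identical(ta$features, tb$features)
})

test_that("planted loadings are orthonormal and the noiseless matrix has rank k_modes", {
  tr <- tiny_truth(2, k_modes = 3, mode_strengths = c(5, 3, 2),
                   trait_weights = c(1, 0.5, 0.25), sex_effect = c(0, 0, 0),
                   age_slope = c(0, 0, 0), noise_sd = 0, confound_strength = 0)
  G <- crossprod(tr$planted_loadings)
  expect_equal(G, diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  coh <- simulate_cohort(n = 50, truth = tr, seed = 4)
  X <- as.matrix(coh$features[, -1])
  expect_equal(qr(X)$rank, 3L)
})

test_that("trait coding splits at the exact prevalence quantile", {
  ## the 2:1 imbalance at the study's headcount: round(0.334 * 27030) = 9028
  tr <- mode_truth(block_sizes = c(GMV = 4, FA = 2), k_modes = 1,
                   mode_strengths = 3, trait_weights = 1,
                   sex_effect = 0, age_slope = 0, seed = 1)
  coh <- simulate_cohort(n = 27030, truth = tr, seed = 2)
  expect_identical(sum(coh$trait$trait == 1), 9028L)
  expect_identical(sum(coh$trait$trait == -1), 27030L - 9028L)

  ## noiseless single mode: +1 participants sit strictly above every -1
  tr0 <- mode_truth(block_sizes = c(GMV = 4), k_modes = 1, mode_strengths = 2,
                    trait_weights = 1, trait_noise_sd = 0, noise_sd = 0,
                    sex_effect = 0, age_slope = 0, confound_strength = 0,
                    seed = 5)
  coh0 <- simulate_cohort(n = 90, truth = tr0, seed = 6)
  t1 <- coh0$truth$latent_scores[, 1]
  expect_gt(min(t1[coh0$trait$trait == 1]), max(t1[coh0$trait$trait == -1]))
})

test_that("generator rejects invalid parameters", {
  expect_error(mode_truth(block_sizes = c(GMV = -1)), "positive")
  expect_error(mode_truth(block_sizes = c(GMV = 2), k_modes = 5), "exceeds")
  expect_error(mode_truth(trait_prevalence = 1.2), "trait_prevalence")
  expect_error(simulate_cohort(n = 5, truth = tiny_truth()), "n")
})

test_that("linked phenotypes carry the target correlation and labels", {
  coh <- simulate_cohort(n = 2000, truth = tiny_truth(7), seed = 3)
  ph <- simulate_phenome(coh, n_pheno = 40, n_linked_per_mode = 3,
                         effect_r = 0.9, binary_fraction = 0, seed = 8)
  V <- as.matrix(ph$values[, -1])
  linked <- which(ph$meta$linked_mode == 1)
  for (j in linked) {
    expect_gt(cor(V[, j], coh$truth$latent_scores[, 1]), 0.85)
  }
  expect_true(all(ph$meta$category %in% c("lifestyle", "cognition",
                                          "mental_health", "physical")))
  phb <- simulate_phenome(coh, n_pheno = 40, binary_fraction = 1, seed = 8)
  expect_true(all(as.matrix(phb$values[, -1]) %in% c(0, 1)))
  expect_error(simulate_phenome(coh, n_pheno = 4, n_linked_per_mode = 3),
               "exceeds")
  expect_error(simulate_phenome(coh, effect_r = 1.5), "effect_r")
})

test_that("transfer cohort keeps only the shared block and reverses age trends", {
  tr <- tiny_truth(4, age_slope = c(-0.8, 0.8), sex_effect = c(0, 0))
  coh <- simulate_cohort(n = 400, truth = tr, seed = 2)
  tc <- simulate_transfer_cohort(coh$truth, n2 = 400, shared_block = "GMV",
                                 seed = 3)
  expect_identical(setdiff(names(tc$features), "participant_id"),
                   tr$feature_names[tr$block_labels == "GMV"])
  ## reversed slope flips the sign of the latent score/age trend
  src_trend <- cor(coh$truth$latent_scores[, 1], coh$trait$age)
  tgt_trend <- cor(tc$truth$latent_scores[, 1], tc$covariates$age)
  expect_lt(src_trend * tgt_trend, 0)

  empty <- simulate_transfer_cohort(coh$truth, n2 = 0, seed = 1)
  expect_identical(nrow(empty$features), 0L)
  expect_identical(nrow(empty$covariates), 0L)
  expect_error(simulate_transfer_cohort(coh$truth, shared_block = "PET"),
               "not found")
})

test_that("cohorts round-trip through delimited files and the truth sidecar", {
  coh <- simulate_cohort(n = 30, truth = tiny_truth(6), seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  feat <- read_participant_table(paths[["features"]])
  expect_equal(as.matrix(feat[, -1]), as.matrix(coh$features[, -1]),
               tolerance = 1e-12, ignore_attr = TRUE)
  truth_json <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth_json$mode_strengths, coh$truth$mode_strengths)
  regen <- mode_truth(block_sizes = unlist(truth_json$block_sizes),
                      k_modes = truth_json$k_modes,
                      mode_strengths = truth_json$mode_strengths,
                      trait_weights = truth_json$trait_weights,
                      seed = truth_json$seed)
  expect_equal(unname(regen$planted_loadings),
               unname(as.matrix(coh$truth$planted_loadings)),
               tolerance = 1e-12)
})
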