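toy_scores <- function(n = 8, K = 2, seed = 1) {
  set.seed(seed)
  S <- matrix(rnorm(n * K), n, K, dimnames = list(NULL, paste0("mode_", 1:K)))
  S
}

test_that("scan statistics match the hand Pearson oracle on a toy table", {
  S <- matrix(c(0.5, -1.2, 0.3, 2.0, -0.7, 1.1, -0.4, 0.9), 8, 1,
              dimnames = list(NULL, "mode_1"))
  P <- cbind(ph_a = c(1.0, -0.8, 0.2, 1.9, -1.1, 0.7, -0.2, 1.2),
             ph_b = c(0, 1, 0, 1, 1, 0, 0, 1))
  scan <- phenome_scan(S, P, family = "behavior")
  for (j in 1:2) {
    want <- pearson_oracle(S[, 1], P[, j])
    row <- scan[scan$phenotype == colnames(P)[j], ]
    expect_equal(row$r, want$r, tolerance = 1e-12)
    expect_equal(row$p, want$p, tolerance = 1e-12)
    expect_equal(row$neg_log10_p, -log10(want$p), tolerance = 1e-10)
  }
  ## binary phenotypes go through the same Pearson path (point-biserial)
  expect_equal(scan$r[scan$phenotype == "ph_b"],
               cor(S[, 1], P[, 2]), tolerance = 1e-12)
})

test_that("a phenotype identical to the score is a maximal hit", {
  S <- toy_scores(50, 1)
  scan <- phenome_scan(S, cbind(self = S[, 1]), family_size = 977)
  expect_equal(scan$r, 1, tolerance = 1e-12)
  expect_true(scan$passes_bonferroni)
})

test_that("the per-family Bonferroni rule reproduces the printed thresholds", {
  expect_equal(bonferroni_threshold(0.05, 977), 0.05 / 977, tolerance = 1e-15)
  ## 0.05/977 = 5.117...e-5: a p of 6e-5 fails, 4e-5 passes
  expect_false(6e-5 < bonferroni_threshold(0.05, 977))
  expect_true(4e-5 < bonferroni_threshold(0.05, 977))
  for (fs in c(977, 1396, 133, 5859)) {
    thr <- bonferroni_threshold(0.05, fs)
    expect_equal(thr, 0.05 / fs, tolerance = 1e-15)
  }
  ## the scan applies exactly the declared-family denominator
  S <- toy_scores(60, 1, seed = 4)
  set.seed(5)
  P <- matrix(rnorm(60 * 10), 60, 10,
              dimnames = list(NULL, sprintf("ph_%02d", 1:10)))
  scan <- phenome_scan(S, P, family_size = 977, alpha = 0.05)
  expect_identical(attr(scan, "threshold"), 0.05 / 977)
  expect_identical(scan$passes_bonferroni, scan$p < 0.05 / 977)
})

test_that("missing values are handled pairwise-complete and constants per policy", {
  S <- toy_scores(30, 1, seed = 2)
  set.seed(3)
  P <- cbind(ok = rnorm(30), holey = rnorm(30), flat = rep(1, 30))
  P[1:5, "holey"] <- NA
  scan <- phenome_scan(S, P)
  expect_identical(scan$n_used[scan$phenotype == "holey"], 25L)
  expect_identical(scan$n_used[scan$phenotype == "ok"], 30L)
  flat_row <- scan[scan$phenotype == "flat", ]
  expect_true(is.na(flat_row$r))
  expect_identical(attr(scan, "family_size"), 3L)
  dropped <- phenome_scan(S, P, constant_policy = "drop")
  expect_identical(attr(dropped, "family_size"), 2L)
  expect_false("flat" %in% dropped$phenotype)
  expect_error(phenome_scan(S, P, family_size = 2), "at least")
})

test_that("neg_log10_p ordering matches p ordering", {
  S <- toy_scores(40, 2, seed = 6)
  set.seed(7)
  P <- matrix(rnorm(40 * 15), 40, 15,
              dimnames = list(NULL, sprintf("ph_%02d", 1:15)))
  scan <- phenome_scan(S, P)
  expect_identical(order(scan$p), order(-scan$neg_log10_p))
})

test_that("group differences match the pooled-t hand calculation", {
  x1 <- c(2.1, 1.8, 2.5, 1.9, 2.2)
  x0 <- c(1.2, 0.9, 1.5, 1.1, 1.4)
  S <- matrix(c(x1, x0), ncol = 1, dimnames = list(NULL, "mode_1"))
  g <- c(rep(1, 5), rep(0, 5))
  got <- group_difference(S, g, variant = "student")
  want <- pooled_t_oracle(x1, x0)
  expect_equal(got$t, want$t, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_gt(got$t, 0)  # group 1 minus group 0
  ## identical groups: t exactly 0, p = 1
  S2 <- matrix(rep(c(1, 2, 3), 2), ncol = 1, dimnames = list(NULL, "mode_1"))
  same <- group_difference(S2, c(1, 1, 1, 0, 0, 0))
  expect_equal(same$t, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  ## welch variant agrees with stats::t.test
  got_w <- group_difference(S, g, variant = "welch")
  ref_w <- t.test(x1, x0)
  expect_equal(got_w$t, unname(ref_w$statistic), tolerance = 1e-12)
  expect_error(group_difference(S, rep(1, 10)), "at least 2")
})

test_that("a large planted mean shift yields a large correctly signed t", {
  set.seed(9)
  S <- matrix(c(rnorm(2000, 1), rnorm(2000, 0)), ncol = 1,
              dimnames = list(NULL, "mode_1"))
  g <- c(rep(1, 2000), rep(0, 2000))
  got <- group_difference(S, g)
  expect_gt(got$t, 10)
})

test_that("age stratification uses half-open brackets and conserves counts", {
  S <- matrix(seq_len(12), ncol = 1, dimnames = list(NULL, "mode_1"))
  age <- c(45, 50, 52, 49.9, 55, 61, 66, 69.9, 70, 39, 58, 63)
  br <- c(40, 50, 55, 60, 65, 70)
  out <- stratify_age(S, age, br)
  ## oracle by direct enumeration
  lows <- br[-length(br)]; highs <- br[-1]
  for (b in seq_along(lows)) {
    idx <- which(age >= lows[b] & age < highs[b])
    row <- out[out$low == lows[b], ]
    expect_identical(row$n, length(idx))
    if (length(idx) > 0) expect_equal(row$mean_score, mean(S[idx, 1]))
    if (length(idx) > 1) expect_equal(row$sd_score, sd(S[idx, 1]))
  }
  ## age exactly 50 goes to [50,55), not [40,50)
  expect_identical(out$n[out$low == 40], sum(age >= 40 & age < 50))
  expect_true(2 %in% which(age == 50))
  ## ages 70 and 39 fall outside all brackets
  expect_identical(attr(out, "unassigned"), 2L)
  expect_identical(sum(out$n[out$component == "mode_1"]) +
                     attr(out, "unassigned"), 12L)
  ## one bracket covering everything reduces to the global mean
  all_in <- stratify_age(S, age, c(0, 100))
  expect_equal(all_in$mean_score, mean(S[, 1]))
  expect_error(stratify_age(S, age, data.frame(low = c(40, 45), high = c(50, 55))),
               "overlap")
  expect_error(stratify_age(S, age, c(50, 40)), "increasing")
})

test_that("scan and manhattan plot integrate with simulated phenomes", {
  coh <- simulate_cohort(n = 300, truth = tiny_truth(13), seed = 13)
  fit <- pls_fit(coh$features, coh$trait, n_components = 2)
  ph <- simulate_phenome(coh, n_pheno = 60, n_linked_per_mode = 4,
                         effect_r = 0.5, seed = 14)
  scan <- phenome_scan(fit, ph, alpha = 0.05)
  expect_s3_class(scan, "phewas_scan")
  expect_identical(nrow(scan), 2L * 60L)
  expect_true(all(c("category", "neg_log10_p") %in% names(scan)))
  pl <- plot_manhattan(scan, components = "mode_1")
  expect_s3_class(pl, "ggplot")
  pl2 <- autoplot(fit)
  expect_s3_class(pl2, "ggplot")
})
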