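## Synthetic cohorts with planted low-rank trait-linked latent modes.
##
## The generator is the ground-truth stand-in for an access-controlled
## population cohort: participants x brain-feature matrices with named
## modality blocks (GMV / FA / FC), a dichotomized trait driven by the
## planted latent modes, sex- and age-structured mode expression, additive
## confound effects with known coefficients, a sparse linked phenome, and
## a transfer cohort that shares only one block and reverses age trends.

#' Ground-truth parameters for a planted-mode synthetic cohort
#'
#' Defines `k_modes` orthonormal planted loading vectors over the
#' concatenated feature blocks, the per-mode signal scales, and the
#' parameters linking latent mode scores to the dichotomized trait and to
#' the covariates (sex, age).
#'
#' The trait is generated as `y* = sum_k beta_k t_k + trait_noise_sd * eps`
#' and dichotomized at the `trait_prevalence` upper quantile, so
#' `trait_prevalence` participants are coded +1 ("night owl" pole) and the
#' rest -1. The default prevalence 0.334 mirrors a roughly 2:1
#' morning/evening imbalance observed in large adult cohorts.
#'
#' @param block_sizes named integer vector of features per modality block;
#'   default `c(GMV = 139, FA = 48, FC = 210)`.
#' @param k_modes number of planted latent modes.
#' @param mode_strengths per-mode signal scale `sigma_k > 0` on the feature
#'   matrix.
#' @param trait_weights per-mode contribution `beta_k` to the latent trait.
#' @param trait_noise_sd standard deviation of the trait noise term.
#' @param noise_sd i.i.d. feature noise standard deviation.
#' @param trait_prevalence fraction of participants coded +1, in (0, 1).
#' @param sex_effect per-mode mean shift in latent score between sexes.
#' @param age_slope per-mode linear trend of latent score versus
#'   standardized age.
#' @param signal_fraction fraction of features (from the start of the
#'   concatenated layout) allowed to carry planted loading mass; the
#'   remaining features are pure noise. Default 1 (all features).
#' @param confound_strength scale of the additive linear confound effects
#'   on the features; 0 disables them.
#' @param seed integer seed controlling the planted loading directions.
#' @return an object of class `mode_truth`.
#' @export
mode_truth <- function(block_sizes = c(GMV = 139, FA = 48, FC = 210),
                       k_modes = 2,
                       mode_strengths = c(5, 3),
                       trait_weights = c(1, 0.75),
                       trait_noise_sd = 1.2,
                       noise_sd = 1,
                       trait_prevalence = 0.334,
                       sex_effect = c(0, 0.4),
                       age_slope = c(-0.3, 0.3),
                       signal_fraction = 1,
                       confound_strength = 0.5,
                       seed = 1) {
  check_scalar(k_modes, "k_modes", lower = 1, integer = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(trait_noise_sd, "trait_noise_sd", lower = 0)
  check_scalar(trait_prevalence, "trait_prevalence", lower = 1e-9, upper = 1 - 1e-9)
  check_scalar(signal_fraction, "signal_fraction", lower = 0, upper = 1)
  if (any(block_sizes <= 0)) abort("all `block_sizes` must be positive.")
  if (is.null(names(block_sizes))) names(block_sizes) <- paste0("B", seq_along(block_sizes))
  p <- sum(block_sizes)
  if (k_modes > p) abort("`k_modes` exceeds the total number of features.")
  for (nm in c("mode_strengths", "trait_weights", "sex_effect", "age_slope")) {
    v <- get(nm)
    if (length(v) == 1) assign(nm, rep(v, k_modes))
    if (length(get(nm)) != k_modes) abort(sprintf("`%s` must have length %d.", nm, k_modes))
  }
  if (any(mode_strengths <= 0)) abort("all `mode_strengths` must be positive.")

  feature_names <- unlist(lapply(names(block_sizes), function(b) {
    sprintf("%s_%03d", b, seq_len(block_sizes[[b]]))
  }), use.names = FALSE)
  n_signal <- max(k_modes, round(signal_fraction * p))

  loadings <- with_seed(child_seed(seed, 1L), {
    L <- matrix(0, p, k_modes)
    raw <- matrix(rnorm(n_signal * k_modes), n_signal, k_modes)
    L[seq_len(n_signal), ] <- qr.Q(qr(raw))[, seq_len(k_modes), drop = FALSE]
    L
  })
  rownames(loadings) <- feature_names

  structure(list(
    block_sizes = block_sizes,
    feature_names = feature_names,
    block_labels = rep(names(block_sizes), block_sizes),
    k_modes = as.integer(k_modes),
    planted_loadings = loadings,
    mode_strengths = mode_strengths,
    trait_weights = trait_weights,
    trait_noise_sd = trait_noise_sd,
    noise_sd = noise_sd,
    trait_prevalence = trait_prevalence,
    sex_effect = sex_effect,
    age_slope = age_slope,
    signal_fraction = signal_fraction,
    confound_strength = confound_strength,
    seed = as.integer(seed)
  ), class = "mode_truth")
}

#' @export
print.mode_truth <- function(x, ...) {
  cat("<mode_truth> ", x$k_modes, " planted mode(s) over ",
      length(x$feature_names), " features (",
      paste(sprintf("%s=%d", names(x$block_sizes), x$block_sizes), collapse = ", "),
      ")\n", sep = "")
  cat("  mode_strengths:", format(x$mode_strengths), "| noise_sd:", x$noise_sd,
      "| trait_prevalence:", x$trait_prevalence, "\n")
  invisible(x)
}

## latent mode scores with sex/age structure; z is the i.i.d. part
latent_scores_for <- function(truth, n, sex, age_z, slopes = truth$age_slope) {
  Z <- matrix(rnorm(n * truth$k_modes), n, truth$k_modes)
  sex_c <- sex - 0.5
  for (k in seq_len(truth$k_modes)) {
    Z[, k] <- Z[, k] + truth$sex_effect[k] * sex_c + slopes[k] * age_z
  }
  Z
}

#' Simulate a participant cohort with planted brain-trait modes
#'
#' Draws latent mode scores `t_k` per participant (standard normal plus
#' sex- and age-structured shifts), builds the feature matrix as
#' `X = sum_k sigma_k t_k l_k' + noise_sd * E` plus additive linear
#' confound effects with known coefficients, and dichotomizes the latent
#' trait `y* = sum_k beta_k t_k + eps` at the configured prevalence
#' quantile (+1 for the top `trait_prevalence` fraction, -1 otherwise).
#'
#' @param n number of participants (>= 10).
#' @param truth a [mode_truth()] parameter object.
#' @param seed integer seed; identical seeds reproduce the cohort exactly.
#' @param age_range sampled uniform age range in years.
#' @return a list of class `synthetic_cohort` with elements
#'   `features` (tibble: participant_id + feature columns),
#'   `trait` (tibble: participant_id, trait in -1/+1, sex, age),
#'   `confounds` (tibble of numeric confound columns), and
#'   `truth` (the input `mode_truth` augmented with the realized
#'   `latent_scores` and confound coefficients).
#' @export
simulate_cohort <- function(n = 1000, truth = mode_truth(), seed = 1,
                            age_range = c(40, 70)) {
  check_scalar(n, "n", lower = 10, integer = TRUE)
  if (!inherits(truth, "mode_truth")) abort("`truth` must be a `mode_truth` object.")
  K <- truth$k_modes
  p <- length(truth$feature_names)

  with_seed(child_seed(seed, "synth"), {
    ids <- sprintf("P%06d", seq_len(n))
    sex <- as.numeric(runif(n) < 0.544)        # 1 = female
    age <- runif(n, age_range[1], age_range[2])
    age_z <- as.numeric(scale(age))

    Tlat <- latent_scores_for(truth, n, sex, age_z)
    X <- Tlat %*% (truth$mode_strengths * t(truth$planted_loadings))
    if (truth$noise_sd > 0) X <- X + truth$noise_sd * matrix(rnorm(n * p), n, p)

    confound_coef <- NULL
    confounds <- tibble::tibble(
      participant_id = ids,
      bmi = rnorm(n), head_size = rnorm(n),
      motion = rnorm(n), sleep_duration = rnorm(n)
    )
    if (truth$confound_strength > 0) {
      C <- as.matrix(confounds[, -1])
      confound_coef <- truth$confound_strength *
        matrix(rnorm(ncol(C) * p), ncol(C), p)
      X <- X + C %*% confound_coef
    }
    colnames(X) <- truth$feature_names
    rownames(X) <- ids

    y_star <- as.numeric(Tlat %*% truth$trait_weights) +
      truth$trait_noise_sd * rnorm(n)
    n_pos <- round(truth$trait_prevalence * n)
    trait <- rep(-1, n)
    trait[order(y_star, decreasing = TRUE)[seq_len(n_pos)]] <- 1

    truth$latent_scores <- Tlat
    truth$confound_coef <- confound_coef
    truth$latent_trait <- y_star

    structure(list(
      features = matrix_to_table(X),
      trait = tibble::tibble(participant_id = ids, trait = trait,
                             sex = sex, age = age),
      confounds = confounds,
      truth = truth
    ), class = "synthetic_cohort")
  })
}

#' Simulate a raw participant table for the preparation filters
#'
#' Expands a simulated cohort's -1/+1 trait back into the raw 6-level
#' questionnaire answers at two assessment instances plus shift-work flag
#' fields, planting a configurable fraction of discordant answers,
#' missing answers, and shift workers so the exclusion filters have work
#' to do.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param discord_frac fraction with opposite answers across instances.
#' @param missing_frac fraction answering "do not know" / "prefer not to
#'   answer" at the first instance.
#' @param shift_frac fraction flagged as shift workers.
#' @param seed integer seed.
#' @return tibble with columns `participant_id`, `chronotype_0`,
#'   `chronotype_2`, four shift-work flag columns, `sex`, `age`.
#' @export
simulate_participants <- function(cohort, discord_frac = 0.05,
                                  missing_frac = 0.03, shift_frac = 0.05,
                                  seed = 1) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  n <- nrow(cohort$trait)
  morning <- trait_levels()[1:2]
  evening <- trait_levels()[3:4]
  missing_lv <- trait_levels()[5:6]
  with_seed(child_seed(seed, "participants"), {
    pick <- function(pool, m) pool[sample.int(length(pool), m, replace = TRUE)]
    level_of <- function(code) ifelse(code > 0, pick(evening, length(code)),
                                      pick(morning, length(code)))
    base <- cohort$trait$trait
    chron2 <- level_of(base)
    chron0 <- level_of(base)
    flip <- runif(n) < discord_frac
    chron0[flip] <- level_of(-base[flip])
    miss <- runif(n) < missing_frac
    chron0[miss] <- pick(missing_lv, sum(miss))

    flag_levels <- shift_work_levels()
    flags <- replicate(4, rep(flag_levels[1], n), simplify = FALSE)
    names(flags) <- c("shift_work_0", "shift_work_2",
                      "night_shift_0", "night_shift_2")
    shifty <- which(runif(n) < shift_frac)
    for (i in shifty) {
      j <- sample.int(4, 1)
      flags[[j]][i] <- pick(flag_levels[-1], 1)
    }
    tibble::tibble(
      participant_id = cohort$trait$participant_id,
      chronotype_0 = chron0, chronotype_2 = chron2,
      !!!flags,
      sex = cohort$trait$sex, age = cohort$trait$age
    )
  })
}

#' Simulate a phenome matrix linked to latent mode scores
#'
#' For each planted mode, `n_linked_per_mode` phenotypes are constructed
#' as `effect_r * z(t_k) + sqrt(1 - effect_r^2) * noise`; a
#' `binary_fraction` of the linked columns (and of the noise columns) are
#' dichotomized at the 70th percentile into 0/1 indicators. All remaining
#' phenotypes are pure noise. Every column carries a category label.
#'
#' @param cohort a [simulate_cohort()] result (supplies latent scores and
#'   participant ids).
#' @param n_pheno total number of phenotype columns.
#' @param n_linked_per_mode linked phenotypes per planted mode.
#' @param effect_r target Pearson correlation of a linked phenotype with
#'   its mode score, in (0, 1).
#' @param binary_fraction fraction of columns dichotomized to 0/1.
#' @param category_labels labels cycled across columns.
#' @param family family tag used for Bonferroni bookkeeping downstream.
#' @param seed integer seed.
#' @return list of class `synthetic_phenome`: `values` (tibble,
#'   participant_id + phenotype columns) and `meta` (tibble: phenotype,
#'   category, family, linked_mode, type).
#' @export
simulate_phenome <- function(cohort, n_pheno = 200, n_linked_per_mode = 5,
                             effect_r = 0.3, binary_fraction = 0.3,
                             category_labels = c("lifestyle", "cognition",
                                                 "mental_health", "physical"),
                             family = "behavior", seed = 1) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (effect_r <= 0 || effect_r >= 1) abort("`effect_r` must lie strictly in (0, 1).")
  K <- cohort$truth$k_modes
  if (n_linked_per_mode * K > n_pheno) {
    abort("n_linked_per_mode * k_modes exceeds n_pheno.")
  }
  n <- nrow(cohort$trait)
  Tlat <- cohort$truth$latent_scores
  with_seed(child_seed(seed, "phenome"), {
    V <- matrix(rnorm(n * n_pheno), n, n_pheno)
    linked_mode <- rep(NA_integer_, n_pheno)
    idx <- 1
    for (k in seq_len(K)) {
      zk <- as.numeric(scale(Tlat[, k]))
      for (j in seq_len(n_linked_per_mode)) {
        V[, idx] <- effect_r * zk + sqrt(1 - effect_r^2) * V[, idx]
        linked_mode[idx] <- k
        idx <- idx + 1
      }
    }
    is_binary <- runif(n_pheno) < binary_fraction
    for (j in which(is_binary)) {
      V[, j] <- as.numeric(V[, j] > quantile(V[, j], 0.7))
    }
    pheno_names <- sprintf("pheno_%04d", seq_len(n_pheno))
    colnames(V) <- pheno_names
    rownames(V) <- cohort$trait$participant_id
    structure(list(
      values = matrix_to_table(V),
      meta = tibble::tibble(
        phenotype = pheno_names,
        category = rep_len(category_labels, n_pheno),
        family = family,
        linked_mode = linked_mode,
        type = ifelse(is_binary, "binary", "continuous")
      )
    ), class = "synthetic_phenome")
  })
}

#' Simulate a transfer cohort sharing one modality block
#'
#' Emulates carrying a trained model to a second, younger cohort observed
#' only on one block (structural grey matter by default). The planted
#' loadings are the same truth restricted to the shared block's rows; the
#' per-mode age trends are replaced (by default reversed), mirroring the
#' inverted age distribution of mode expression between an adult and a
#' youth cohort.
#'
#' @param truth the source cohort's `mode_truth`.
#' @param n2 number of transfer-cohort participants (0 gives empty output).
#' @param shared_block block name retained (must exist in `truth`).
#' @param age_range age range of the transfer cohort, in months.
#' @param reversed_age_slope per-mode age trend; default `-age_slope`.
#' @param seed integer seed.
#' @return list of class `synthetic_transfer`: `features` (tibble with the
#'   shared block's columns only), `covariates` (tibble: participant_id,
#'   sex, age), and `truth` (restricted truth with realized latent scores).
#' @export
simulate_transfer_cohort <- function(truth, n2 = 1000, shared_block = "GMV",
                                     age_range = c(100, 140),
                                     reversed_age_slope = -truth$age_slope,
                                     seed = 1) {
  stopifnot(inherits(truth, "mode_truth"))
  if (!shared_block %in% names(truth$block_sizes)) {
    abort(sprintf("block `%s` not found; available: %s", shared_block,
                  paste(names(truth$block_sizes), collapse = ", ")))
  }
  check_scalar(n2, "n2", lower = 0, integer = TRUE)
  keep <- truth$block_labels == shared_block
  L_sub <- truth$planted_loadings[keep, , drop = FALSE]
  p_sub <- sum(keep)

  with_seed(child_seed(seed, "transfer"), {
    ids <- sprintf("T%06d", seq_len(n2))
    sex <- as.numeric(runif(n2) < 0.48)
    age <- runif(n2, age_range[1], age_range[2])
    age_z <- if (n2 > 1) as.numeric(scale(age)) else rep(0, n2)
    Tlat <- latent_scores_for(truth, n2, sex, age_z, slopes = reversed_age_slope)
    X <- Tlat %*% (truth$mode_strengths * t(L_sub))
    if (truth$noise_sd > 0 && n2 > 0) {
      X <- X + truth$noise_sd * matrix(rnorm(n2 * p_sub), n2, p_sub)
    }
    colnames(X) <- truth$feature_names[keep]
    rownames(X) <- ids

    truth2 <- truth
    truth2$planted_loadings <- L_sub
    truth2$block_sizes <- truth$block_sizes[shared_block]
    truth2$feature_names <- truth$feature_names[keep]
    truth2$block_labels <- truth$block_labels[keep]
    truth2$age_slope <- reversed_age_slope
    truth2$latent_scores <- Tlat

    structure(list(
      features = matrix_to_table(X),
      covariates = tibble::tibble(participant_id = ids, sex = sex, age = age),
      truth = truth2
    ), class = "synthetic_transfer")
  })
}

#' Write a synthetic cohort to delimited files
#'
#' Writes `features.tsv`, `trait.tsv`, `confounds.tsv` (TSV, header row,
#' `participant_id` first column) and a `truth.json` sidecar holding the
#' generative parameters and planted loadings.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    features = file.path(dir, "features.tsv"),
    trait = file.path(dir, "trait.tsv"),
    confounds = file.path(dir, "confounds.tsv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_tsv(cohort$features, paths[["features"]])
  readr::write_tsv(cohort$trait, paths[["trait"]])
  readr::write_tsv(cohort$confounds, paths[["confounds"]])
  tr <- cohort$truth
  jsonlite::write_json(list(
    block_sizes = as.list(tr$block_sizes),
    k_modes = tr$k_modes,
    mode_strengths = tr$mode_strengths,
    trait_weights = tr$trait_weights,
    trait_noise_sd = tr$trait_noise_sd,
    noise_sd = tr$noise_sd,
    trait_prevalence = tr$trait_prevalence,
    sex_effect = tr$sex_effect,
    age_slope = tr$age_slope,
    signal_fraction = tr$signal_fraction,
    confound_strength = tr$confound_strength,
    seed = tr$seed,
    planted_loadings = tr$planted_loadings
  ), paths[["truth"]], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
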