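test_that("probe AUC equals the brute-force pairwise count", {
  expect_equal(probe_auc(c(2.5, 3.5, 1, 2, 3), c(TRUE, TRUE, FALSE, FALSE, FALSE)),
               5 / 6)
  expect_identical(probe_auc(c(10, 9, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_identical(probe_auc(rep(1, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  set.seed(13)
  for (i in 1:20) {
    n1 <- sample(2:8, 1); n0 <- sample(2:15, 1)
    v <- c(sample(1:6, n1, TRUE) + 0.5 * sample(0:1, n1, TRUE),
           sample(1:6, n0, TRUE))
    lab <- rep(c(TRUE, FALSE), c(n1, n0))
    expect_equal(probe_auc(v, lab), oracle_auc(v[lab], v[!lab]),
                 tolerance = 1e-12)
  }
  expect_error(probe_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("feature selection keeps AUC-1 probes and prunes by correlation blocks", {
  # fixture: 10 probes in 3 correlation blocks across 8 patients, 12 controls
  set.seed(7)
  n1 <- 8; n0 <- 12; n <- n1 + n0
  grp <- rep(c("patient", "control"), c(n1, n0))
  sheet <- data.frame(sample_id = sprintf("s%02d", 1:n), labeled_sex = "M",
                      group = grp, role = "discovery")
  block <- rep(1:3, c(4, 3, 3))
  latent <- sapply(1:3, function(b) ifelse(grp == "patient", 0.8, 0.2))
  v <- sapply(1:10, function(j)
    latent[, block[j]] + rnorm(n, 0, 0.015) * j)
  v <- t(pmin(pmax(v, 0.01), 0.99))
  dimnames(v) <- list(sprintf("cg%02d", 1:10), sheet$sample_id)
  bm <- beta_matrix(v)
  sel <- select_features(bm, sheet, rownames(v), r2_cut = 0.8)
  expect_true(all(sel$auc[sel$retained_after_auc] >= 1 - 1e-9))
  expect_identical(sel$retained_after_pruning,
                   oracle_prune(v[sel$retained_after_auc, , drop = FALSE],
                                sel$retained_after_auc, sqrt(0.8)))
  expect_true(all(sel$retained_after_pruning %in% sel$retained_after_auc))
  expect_equal(sel$pruning_threshold, sqrt(0.8))

  # two perfectly correlated AUC-1 probes collapse to one
  v2 <- v[c(1, 1), ]
  rownames(v2) <- c("p1", "p2")
  sel2 <- select_features(beta_matrix(v2), sheet, c("p1", "p2"))
  expect_length(sel2$retained_after_pruning, 1L)

  # probes with r^2 = 0.5 both survive
  set.seed(8)
  a <- ifelse(grp == "patient", 0.8, 0.2) + rnorm(n, 0, 0.02)
  b <- 0.5 * scale(a)[, 1] * 0.1 + 0.5 +
    sqrt(0.5) * 0.1 * scale(ifelse(grp == "patient", 1, -1) + rnorm(n, 0, 0.3))[, 1]
  v3 <- rbind(p1 = pmin(pmax(a, 0.01), 0.99), p2 = pmin(pmax(b, 0.01), 0.99))
  colnames(v3) <- sheet$sample_id
  if (abs(cor(v3[1, ], v3[2, ])) < sqrt(0.8)) {
    sel3 <- select_features(beta_matrix(v3), sheet, c("p1", "p2"),
                            auc_tol = 1)  # keep both regardless of AUC
    expect_length(sel3$retained_after_pruning, 2L)
  }

  # nothing separating -> explicit error
  set.seed(9)
  noise <- matrix(runif(3 * n), 3, n,
                  dimnames = list(c("n1", "n2", "n3"), sheet$sample_id))
  expect_error(select_features(beta_matrix(noise), sheet, rownames(noise)),
               "AUC")
})

test_that("feature selection is invariant to sample order", {
  fix <- classifier_cohort()
  eff <- fix$config$planted_probe_effects
  sel1 <- select_features(fix$beta, fix$sheet, eff$probe_id)
  perm <- beta_matrix(fix$beta$values[, sample(ncol(fix$beta$values))])
  sel2 <- select_features(perm, fix$sheet, eff$probe_id)
  expect_identical(sel2$retained_after_pruning, sel1$retained_after_pruning)
})

test_that("SVM training is deterministic and perfectly separates the cohort", {
  fix <- classifier_cohort()
  eff <- fix$config$planted_probe_effects
  sel <- select_features(fix$beta, fix$sheet, eff$probe_id)
  m1 <- suppressWarnings(train_svm(fix$beta, fix$sheet,
                                   sel$retained_after_pruning, seed = 17))
  m2 <- suppressWarnings(train_svm(fix$beta, fix$sheet,
                                   sel$retained_after_pruning, seed = 17))
  expect_identical(m1$cost, m2$cost)
  expect_identical(m1$svm_core$gamma, m2$svm_core$gamma)
  expect_equal(predict_scores(m1, fix$beta), predict_scores(m2, fix$beta),
               tolerance = 1e-12)
  expect_equal(m1$cv_accuracy, 1.0)
  pr <- predict_scores(m1, fix$beta)
  expect_identical(pr$predicted_class, fix$sheet$group)
  expect_equal(pr$score_patient + pr$score_carrier + pr$score_control,
               rep(1, nrow(pr)), tolerance = 1e-6)
  expect_true(all(pr$score_patient >= 0 & pr$score_patient <= 1))
  expect_false(any(pr$ambiguous))
})

test_that("permuted labels drop CV accuracy to chance level", {
  fix <- classifier_cohort()
  eff <- fix$config$planted_probe_effects
  sel <- select_features(fix$beta, fix$sheet, eff$probe_id)
  shuf <- fix$sheet
  set.seed(3)
  shuf$group <- sample(shuf$group)
  m <- suppressWarnings(train_svm(fix$beta, shuf, sel$retained_after_pruning,
                                  seed = 17))
  maj <- max(table(fix$sheet$group)) / nrow(fix$sheet)
  expect_lt(m$cv_accuracy, 1)
  expect_lt(abs(m$cv_accuracy - maj), 0.2)
})

test_that("prediction contract: missing probes error, ambiguous flag on flat input", {
  fix <- classifier_cohort()
  eff <- fix$config$planted_probe_effects
  sel <- select_features(fix$beta, fix$sheet, eff$probe_id)
  model <- suppressWarnings(train_svm(fix$beta, fix$sheet,
                                      sel$retained_after_pruning, seed = 1))
  expect_error(predict_scores(model, tiny_beta(4, 2)), "missing")
  flat <- matrix(0.5, length(model$probes), 2,
                 dimnames = list(model$probes, c("f1", "f2")))
  pr <- predict_scores(model, beta_matrix(flat))
  expect_equal(pr$score_patient + pr$score_carrier + pr$score_control,
               rep(1, 2), tolerance = 1e-6)
  expect_identical(pr$ambiguous,
                   (pmax(pr$score_patient, pr$score_carrier, pr$score_control) < 0.5))
})

test_that("specificity evaluation classifies disjoint-signature cohorts as control", {
  fix <- classifier_cohort()
  eff <- fix$config$planted_probe_effects
  sel <- select_features(fix$beta, fix$sheet, eff$probe_id)
  model <- suppressWarnings(train_svm(fix$beta, fix$sheet,
                                      sel$retained_after_pruning, seed = 1))
  ext <- simulate_external_cohorts(fix$config, fix$manifest,
                                   avoid_probes = model$probes,
                                   n_controls = 60, n_other = 50,
                                   n_other_probes = 40)
  res <- evaluate_specificity(model, ext$beta, ext$sheet)
  expect_equal(res$specificity, 1.0)
  expect_identical(res$n, 110L)
  empty <- fix$beta$values[, 0, drop = FALSE]
  colnames(empty) <- character(0)
  expect_error(evaluate_specificity(model, beta_matrix(empty), fix$sheet),
               "empty")
})

test_that("increasing noise never improves CV accuracy on average", {
  acc <- sapply(c(0.12, 0.6, 1.2), function(ns) {
    accs <- sapply(1:3, function(r) {
      cfg <- sim_config(n_background_probes = 60, noise_sd = ns,
                        n_patients = 6, n_carriers = 4, n_controls = 12,
                        n_chrx_probes = 0, seed = 300 + r)
      man <- generate_manifest(cfg)
      cfg$planted_probe_effects <-
        sample_probe_effects(cfg, man, 12, delta_min = 0.15, delta_max = 0.3)
      cohort <- simulate_cohort(cfg, man)
      m <- suppressWarnings(train_svm(cohort$beta, cohort$sheet,
                                      cfg$planted_probe_effects$probe_id,
                                      folds = 4, cost_grid = c(1, 10),
                                      gamma_grid = c(0.05), seed = 5))
      m$cv_accuracy
    })
    mean(accs)
  })
  expect_true(acc[1] >= acc[2] - 1e-9 && acc[2] >= acc[3] - 1e-9)
})
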