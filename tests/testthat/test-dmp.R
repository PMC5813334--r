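make_design_fixture <- function(p = 10, n = 20, seed = 11) {
  set.seed(seed)
  grp <- rep(c("patient", "control"), c(n / 2, n / 2))
  ids <- sprintf("s%02d", 1:n)
  sheet <- data.frame(sample_id = ids, labeled_sex = "M", group = grp,
                      role = "discovery")
  M <- matrix(rnorm(p * n), p, n, dimnames = list(sprintf("cg%03d", 1:p), ids))
  fr <- matrix(runif(n * 3, 0.2, 0.5), n, 3,
               dimnames = list(ids, c("A", "B", "C")))
  fr <- fr / rowSums(fr)
  list(M = M, sheet = sheet, fractions = fr, ids = ids)
}

test_that("per-probe OLS equals the normal-equations oracle", {
  fx <- make_design_fixture()
  X <- build_design_matrix(fx$sheet, fx$ids, fx$fractions)
  fit <- fit_probe_models(fx$M, X)
  orc <- oracle_ols(fx$M, X)
  expect_lt(max(abs(fit$coefficients - orc$coefficients[, "group"])), 1e-10)
  expect_lt(max(abs(fit$sigma - orc$sigma)), 1e-10)
  expect_identical(fit$df_residual[1], nrow(X) - ncol(X))
  expect_equal(fit$stdev_unscaled, sqrt(orc$xtx_inv["group", "group"]),
               tolerance = 1e-12)
})

test_that("with no covariates the group coefficient is the difference of group means", {
  fx <- make_design_fixture()
  X <- build_design_matrix(fx$sheet, fx$ids)
  fit <- fit_probe_models(fx$M, X)
  pat <- fx$sheet$group == "patient"
  dm <- rowMeans(fx$M[, pat]) - rowMeans(fx$M[, !pat])
  expect_equal(unname(fit$coefficients), unname(dm), tolerance = 1e-12)
  # constant probe: zero residual variance, finite coefficient
  M2 <- fx$M; M2[1, ] <- 3
  fit2 <- fit_probe_models(M2, X)
  expect_lt(fit2$sigma[1], 1e-12)
})

test_that("a rank-deficient design is rejected naming the collinear column", {
  fx <- make_design_fixture()
  X <- build_design_matrix(fx$sheet, fx$ids)
  X2 <- cbind(X, dup = X[, "group"])
  expect_error(fit_probe_models(fx$M, X2), "rank deficient.*dup")
  fr_bad <- cbind(fx$fractions[, 1:2], C = 0.5)  # constant column
  fr_bad <- fr_bad / rowSums(fr_bad)
  expect_silent(build_design_matrix(fx$sheet, fx$ids, fr_bad))
})

test_that("moderated statistics agree with the limma oracle", {
  skip_if_not_installed("limma")
  set.seed(42)
  p <- 400; n <- 24
  grp <- rep(c(1, 0), each = n / 2)
  # heteroskedastic probes so the prior is informative
  sds <- sqrt(1 / rgamma(p, shape = 4, rate = 4))
  M <- matrix(rnorm(p * n, sd = rep(sds, n)), p, n,
              dimnames = list(sprintf("cg%04d", 1:p), sprintf("s%02d", 1:n)))
  M[1:30, grp == 1] <- M[1:30, grp == 1] + 2
  X <- cbind(intercept = 1, group = grp)
  fit <- fit_probe_models(M, X)
  mod <- ebayes_moderate(fit)
  lfit <- limma::eBayes(limma::lmFit(M, X))
  expect_equal(mod$params$d0, lfit$df.prior, tolerance = 1e-6)
  expect_equal(mod$params$s0_sq, lfit$s2.prior, tolerance = 1e-6)
  expect_equal(unname(mod$t_mod), unname(lfit$t[, "group"]), tolerance = 1e-8)
  expect_equal(unname(mod$p), unname(lfit$p.value[, "group"]), tolerance = 1e-8)
})

test_that("equal variances drive the prior to infinity and the posterior to s0", {
  fx <- make_design_fixture(p = 50)
  X <- build_design_matrix(fx$sheet, fx$ids)
  fit <- fit_probe_models(fx$M, X)
  fit$sigma <- rep(1.3, 50)   # identical residual sds
  mod <- ebayes_moderate(fit)
  expect_identical(mod$params$d0, Inf)
  expect_equal(unique(mod$s_post_sq), mod$params$s0_sq)
  expect_lte(max(mod$df_total), 1e6)
  # few usable variances is an error
  fit$sigma <- c(rep(0, 45), rep(1, 5))
  expect_error(ebayes_moderate(fit), "at least 10")
})

test_that("null p-values are uniform and BH matches the step-up oracle", {
  set.seed(9)
  p <- 10000; n <- 30
  X <- cbind(intercept = 1, group = rep(c(1, 0), each = n / 2))
  M <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("cg%05d", 1:p), sprintf("s%02d", 1:n)))
  fit <- fit_probe_models(M, X)
  mod <- ebayes_moderate(fit)
  ks <- suppressWarnings(stats::ks.test(mod$p, "punif"))
  expect_gt(ks$p.value, 0.01)

  for (i in 1:5) {
    pv <- runif(sample(5:60, 1))
    expect_equal(bh_adjust(pv), oracle_bh(pv), tolerance = 1e-12)
  }
  expect_identical(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  pv <- runif(100)
  expect_true(all(diff(bh_adjust(pv)[order(pv)]) >= -1e-15))
  expect_true(all(bh_adjust(pv) >= pv))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the dual gate excludes probes failing either criterion", {
  fix <- small_cohort()
  res <- run_dmp(fix$beta, fix$sheet,
                 fractions = estimate_cell_fractions(fix$beta,
                                                     fix$config$cell_reference))
  full <- res$full
  expect_true(all(full$p_adj >= full$p))
  expect_identical(full$direction, ifelse(full$delta_beta < 0, "hypo", "hyper"))
  called <- res$table
  expect_true(all(called$p_adj < 0.01 & abs(called$delta_beta) > 0.10))
  excluded <- full[!full$significant, ]
  expect_true(all(excluded$p_adj >= 0.01 | abs(excluded$delta_beta) <= 0.10))
  # planted singleton probes are recovered
  eff <- fix$config$planted_probe_effects
  expect_gte(mean(eff$probe_id %in% called$probe_id), 0.95)
})

test_that("planted direction split is preserved in the calls", {
  fix <- small_cohort()
  res <- run_dmp(fix$beta, fix$sheet)
  eff <- fix$config$planted_probe_effects
  called <- res$table[res$table$probe_id %in% eff$probe_id, ]
  planted_dir <- ifelse(eff$delta[match(called$probe_id, eff$probe_id)] < 0,
                        "hypo", "hyper")
  expect_identical(called$direction, planted_dir)
})

test_that("DMP calls are invariant to sample and probe order", {
  fix <- small_cohort()
  res1 <- run_dmp(fix$beta, fix$sheet)
  perm <- beta_matrix(fix$beta$values[rev(seq_len(nrow(fix$beta$values))),
                                      sample(ncol(fix$beta$values))])
  res2 <- run_dmp(perm, fix$sheet)
  expect_identical(res2$table$probe_id, res1$table$probe_id)
  expect_equal(res2$table$delta_beta, res1$table$delta_beta, tolerance = 1e-12)
})

test_that("a global null simulation yields almost no calls", {
  cfg <- sim_config(n_background_probes = 50000, n_patients = 7,
                    n_carriers = 0, n_controls = 56, n_chrx_probes = 0,
                    seed = 88)
  man <- generate_manifest(cfg)
  cohort <- simulate_cohort(cfg, man)
  res <- run_dmp(cohort$beta, cohort$sheet)
  expect_lt(nrow(res$table), 5)
})

test_that("signature clustering fully separates patients from controls", {
  fix <- small_cohort()
  sig <- run_dmp(fix$beta, fix$sheet)$table$probe_id
  purity <- signature_cluster_purity(fix$beta, fix$sheet, sig)
  expect_equal(as.numeric(purity), 1.0)
  carriers <- attr(purity, "carriers")
  expect_length(carriers, sum(fix$sheet$group == "carrier"))

  # shuffled labels give purity near the majority-class fraction
  set.seed(5)
  shuf <- fix$sheet
  pc <- shuf$group %in% c("patient", "control")
  shuf$group[pc] <- sample(shuf$group[pc])
  maj <- max(table(fix$sheet$group[pc])) / sum(pc)
  shuffled <- as.numeric(signature_cluster_purity(fix$beta, shuf, sig))
  expect_lt(shuffled, 1)
  # expectation for a random 7/56 relabelling of a 7/56 cluster split
  expect_lt(abs(shuffled - (maj^2 + (1 - maj)^2)), 0.15)

  expect_error(signature_cluster_purity(fix$beta, fix$sheet, sig[1]),
               "at least 2")
})
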