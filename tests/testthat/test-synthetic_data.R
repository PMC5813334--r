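test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_background_probes = 300, n_patients = 4, n_carriers = 3,
                    n_controls = 6, n_chrx_probes = 10, seed = 7)
  man1 <- generate_manifest(cfg)
  man2 <- generate_manifest(cfg)
  expect_identical(man1, man2)
  c1 <- simulate_cohort(cfg, man1)
  c2 <- simulate_cohort(cfg, man1)
  expect_identical(c1$beta$values, c2$beta$values)
  expect_identical(c1$beta$detection_p, c2$beta$detection_p)
  cfg2 <- cfg; cfg2$seed <- 8L
  expect_false(identical(simulate_cohort(cfg2, man1)$beta$values,
                         c1$beta$values))
})

test_that("region probes land inside the requested span with gaps under 500 bp", {
  cfg <- sim_config(n_background_probes = 200, n_chrx_probes = 0,
                    planted_regions = data.frame(
                      chrom = "chr17", start = 7486551L, end = 7486874L,
                      n_probes = 3L, delta = -0.297), seed = 3)
  man <- generate_manifest(cfg)
  rows <- man$chrom == "chr17" & man$pos >= 7486551 & man$pos <= 7486874
  expect_identical(sum(rows), 3L)
  expect_lt(max(diff(man$pos[rows])), 500)
  expect_identical(range(man$pos[rows]), c(7486551L, 7486874L))
  # an impossible probe count for the span errors out
  cfg_bad <- sim_config(n_background_probes = 200,
                        planted_regions = data.frame(
                          chrom = "chr1", start = 1000L, end = 9000L,
                          n_probes = 3L, delta = 0.2), seed = 3)
  expect_error(generate_manifest(cfg_bad), "gaps < 500")
})

test_that("a config without planted regions yields background-only geometry", {
  cfg <- sim_config(n_background_probes = 250, n_chrx_probes = 0, seed = 2)
  man <- generate_manifest(cfg)
  expect_false(any(grepl("^sim_dmr", man$probe_id)))
  # mixed gap structure: both sub-500 and super-500 gaps occur
  gaps <- unlist(tapply(man$pos, man$chrom, diff))
  expect_gt(sum(gaps <= 500), 0)
  expect_gt(sum(gaps > 500), 0)
})

test_that("probes more than 500 bp apart fall into different clusters", {
  man <- validate_manifest(data.frame(
    probe_id = c("a", "b", "c"), chrom = "chr1",
    pos = c(100L, 700L, 1100L), island_relation = "open_sea",
    flag_xy = FALSE, flag_snp = FALSE, flag_crossreactive = FALSE))
  cl <- cluster_probes(man)
  expect_identical(unname(cl), c(1L, 2L, 2L))
})

test_that("zero noise reproduces the planted means exactly, carriers at half effect", {
  cfg <- sim_config(n_background_probes = 200, noise_sd = 0,
                    n_patients = 2, n_carriers = 2, n_controls = 2,
                    n_chrx_probes = 0, seed = 5)
  man <- generate_manifest(cfg)
  cfg$planted_probe_effects <- data.frame(index = c(5L, 10L),
                                          delta = c(-0.30, 0.20))
  cohort <- simulate_cohort(cfg, man)
  truth <- cohort$truth
  pid <- names(truth$patient_delta)[truth$patient_delta == -0.30]
  ctl_mean <- truth$control_mean[pid]
  v <- cohort$beta$values[pid, ]
  grp <- cohort$sheet$group
  expect_equal(unname(v[grp == "control"][1]), unname(ctl_mean), tolerance = 1e-12)
  expect_equal(unname(v[grp == "patient"][1]), unname(ctl_mean - 0.30),
               tolerance = 1e-12)
  expect_equal(unname(v[grp == "carrier"][1]), unname(ctl_mean - 0.15),
               tolerance = 1e-12)
})

test_that("group-wise empirical effects track the planted truth", {
  fix <- small_cohort()
  eff <- fix$config$planted_probe_effects
  grp <- fix$sheet$group
  v <- fix$beta$values[eff$probe_id, ]
  db <- rowMeans(v[, grp == "patient"]) - rowMeans(v[, grp == "control"])
  # mean across planted probes of the estimation error is tightly centred
  expect_lt(abs(mean(db - eff$delta)), 0.02)
  expect_gt(cor(db, eff$delta), 0.98)
})

test_that("carrier-to-patient effect ratio converges to the carrier factor", {
  cfg <- sim_config(n_background_probes = 400, n_patients = 50,
                    n_carriers = 50, n_controls = 50, n_chrx_probes = 0,
                    seed = 21)
  man <- generate_manifest(cfg)
  cfg$planted_probe_effects <- sample_probe_effects(cfg, man, 60,
                                                    delta_min = 0.15,
                                                    delta_max = 0.35)
  cohort <- simulate_cohort(cfg, man)
  grp <- cohort$sheet$group
  v <- cohort$beta$values[cfg$planted_probe_effects$probe_id, ]
  d_pat <- rowMeans(v[, grp == "patient"]) - rowMeans(v[, grp == "control"])
  d_car <- rowMeans(v[, grp == "carrier"]) - rowMeans(v[, grp == "control"])
  ratio <- sum(d_car * d_pat) / sum(d_pat^2)
  expect_lt(abs(ratio - 0.5), 0.05)
})

test_that("pooled control betas pass the bimodality check at default thresholds", {
  fix <- small_cohort()
  ctl <- fix$sheet$sample_id[fix$sheet$group == "control"]
  dens <- check_density_bimodality(
    beta_matrix(fix$beta$values[, ctl, drop = FALSE]))
  expect_false(any(dens$flagged))
  expect_true(all(fix$beta$values > 0 & fix$beta$values < 1))
})

test_that("external cohorts avoid the signature and carry their own effects", {
  fix <- classifier_cohort()
  sig <- fix$config$planted_probe_effects$probe_id
  ext <- simulate_external_cohorts(fix$config, fix$manifest,
                                   avoid_probes = sig,
                                   n_controls = 40, n_other = 30,
                                   n_other_probes = 50)
  expect_identical(sum(ext$sheet$group == "control"), 40L)
  expect_identical(unique(ext$sheet$role), "external")
  expect_length(intersect(ext$truth$other_probes, sig), 0L)
  expect_error(
    simulate_external_cohorts(fix$config, fix$manifest, avoid_probes = sig,
                              other_probes = sig[1:3]),
    "overlap")
  # other-disorder samples express their own planted signature
  oth <- ext$sheet$sample_id[ext$sheet$group == "unknown"]
  ctl <- ext$sheet$sample_id[ext$sheet$group == "control"]
  db <- rowMeans(ext$beta$values[ext$truth$other_probes, oth]) -
    rowMeans(ext$beta$values[ext$truth$other_probes, ctl])
  expect_gte(mean(abs(db) > 0.10), 0.90)
  # and their baselines agree with the training cohort at signature probes
  db_sig <- rowMeans(ext$beta$values[sig, ctl]) -
    rowMeans(fix$beta$values[sig, fix$sheet$group == "control"])
  expect_lt(max(abs(db_sig)), 0.15)
})
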