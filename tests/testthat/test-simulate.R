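test_that("configuration invariants are enforced", {
  expect_error(simConfig(n_patients = 5), "quartiles")
  expect_error(simConfig(n_genes = 100, module_sizes = c(80, 50)), "exceed")
  expect_error(simConfig(pten_loss_fraction = 1.4), "proportions")
  expect_error(simulateTwoGroup(simConfig(), n_per_group = 1), "at least 2")
  # zero-inflation defaults to the loss fraction
  cfg <- simConfig(pten_loss_fraction = 0.3)
  expect_equal(cfg$hscore_zero_inflation, 0.3)
})

test_that("identical config and seed reproduce bit-identical cohorts", {
  cfg <- simConfig(n_patients = 30, n_genes = 300, seed = 5)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$cores, b$cores)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  # different seed changes the draws
  c_ <- simulateCohort(simConfig(n_patients = 30, n_genes = 300, seed = 6))
  expect_false(identical(a$counts, c_$counts))
  # two-group generator is reproducible too
  t1 <- simulateTwoGroup(cfg, 4)
  t2 <- simulateTwoGroup(cfg, 4)
  expect_identical(t1$counts, t2$counts)
})

test_that("H-scores are zero-inflated, bounded, and loss = H-score 0", {
  cfg <- simConfig(n_patients = 200, n_genes = 200,
                   module_sizes = c(30, 20), n_pi3k = 20,
                   hscore_zero_inflation = 0.5, seed = 8)
  sim <- simulateCohort(cfg)
  pat <- scorePatients(sim$cores)
  inc <- pat[pat$included, ]
  expect_true(all(inc$h_score >= 0 & inc$h_score <= 300))
  # ~100 of 200 patients carry an exact-zero H-score (binomial noise)
  h_all <- sim$truth$loss_status
  expect_equal(sum(h_all), 100, tolerance = 3 * sqrt(200 * 0.25) / 1)
  expect_gt(sum(h_all), 100 - 3 * sqrt(200 * 0.25))
  expect_lt(sum(h_all), 100 + 3 * sqrt(200 * 0.25))
  # loss status is exactly the zero-H-score set
  zero_pat <- names(sim$truth$loss_status)[sim$truth$loss_status]
  obs_zero <- inc$patient_id[inc$h_score == 0]
  expect_true(all(obs_zero %in% zero_pat))
  # non-zero scores are right-skewed (mean > median)
  nz <- inc$h_score[inc$h_score > 0]
  expect_gt(mean(nz), median(nz))
})

test_that("about a quarter of patients fail QC on both cores at the default rate", {
  excl <- vapply(1:6, function(s) {
    sim <- simulateCohort(simConfig(n_patients = 150, n_genes = 150,
                                    module_sizes = c(30), n_pi3k = 20,
                                    seed = 50 + s))
    pat <- scorePatients(sim$cores)
    mean(!pat$included)
  }, numeric(1))
  expect_equal(mean(excl), 0.25, tolerance = 0.05)
})

test_that("count matrix has planted module correlation and stable library sizes", {
  cfg <- simConfig(n_patients = 60, n_genes = 400, module_sizes = c(50, 40),
                   n_pi3k = 30, seed = 12)
  sim <- simulateCohort(cfg)
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == round(sim$counts)))
  # column sums concentrate around mean_libsize (CV of lognormal = 0.2)
  cs <- colSums(sim$counts)
  expect_lt(max(abs(cs - cfg$mean_libsize) / cfg$mean_libsize), 3 * 0.2 * 1.5)
  expect_equal(median(cs) / cfg$mean_libsize, 1, tolerance = 0.15)
  # within-module correlation beats between-module correlation
  lc <- logCPM(sim$counts)
  mm <- sim$truth$module_membership
  m1 <- names(mm)[mm == "planted1"][1:25]
  m2 <- names(mm)[mm == "planted2"][1:25]
  r11 <- cor(t(lc[m1, ]))
  r12 <- cor(t(lc[m1, ]), t(lc[m2, ]))
  expect_gt(mean(r11[upper.tri(r11)]), mean(r12) + 0.2)
  # clinical outcomes well-formed
  expect_true(all(sim$clinical$dfs_time > 0))
  expect_true(all(sim$clinical$dfs_event %in% 0:1))
})

test_that("loss samples have elevated PI3K and stromal-module expression", {
  cfg <- simConfig(n_patients = 80, n_genes = 400, module_sizes = c(50, 40),
                   n_pi3k = 40, pi3k_effect = 1, stromal_effect = 1, seed = 3)
  sim <- simulateCohort(cfg)
  lc <- logCPM(sim$counts)
  loss <- sim$truth$loss_status[colnames(lc)]
  for (set in list(sim$truth$pi3k_genes, sim$truth$signature_genes)) {
    delta <- mean(lc[set, loss]) - mean(lc[set, !loss])
    expect_gt(delta, 0.4)
  }
})

test_that("two-group generator plants the effect only when asked", {
  # null effect: group log-fold-changes centered on 0
  cfg0 <- simConfig(n_patients = 20, n_genes = 300, pi3k_effect = 0,
                    stromal_effect = 0, seed = 9)
  tg0 <- simulateTwoGroup(cfg0, n_per_group = 10)
  lc0 <- logCPM(tg0$counts)
  lfc0 <- rowMeans(lc0[, tg0$group == "KO"]) -
    rowMeans(lc0[, tg0$group == "WT"])
  expect_lt(abs(mean(lfc0)), 0.1)
  # large planted effect: module genes dominate the top of the DE ranking
  cfg1 <- simConfig(n_patients = 20, n_genes = 300, module_sizes = c(50),
                    n_pi3k = 10, pi3k_effect = 0, stromal_effect = 3,
                    seed = 10)
  tg1 <- simulateTwoGroup(cfg1, n_per_group = 10)
  de <- runDE(filterGenes(tg1$counts), tg1$group, profile = "mouse")
  top50 <- de$gene[order(de$p_value)][1:50]
  expect_gte(mean(top50 %in% tg1$truth$signature_genes), 0.8)
})

test_that("survival block responds to the planted signature hazard", {
  # null planted log-HR: quartile log-rank rejects at ~ nominal rate
  pvals <- vapply(1:20, function(s) {
    cfg <- simConfig(n_patients = 120, n_genes = 60, module_sizes = c(20),
                     n_pi3k = 10, planted_log_hr = 0, seed = 200 + s)
    sim <- simulateCohort(cfg)
    z <- sim$truth$z_signature[sim$clinical$patient_id]
    q <- quartileStratify(z)
    ex <- q$labels %in% c("Q1", "Q4")
    logrankTest(sim$clinical$dfs_time[ex], sim$clinical$dfs_event[ex],
                droplevels(q$labels[ex]))$p_value
  }, numeric(1))
  expect_lte(sum(pvals < 0.05), 4)  # ~1 expected of 20 at the null
  expect_gt(min(pvals), 0.001)
})

test_that("cohort writer emits the plain-text artifact set", {
  sim <- simulateCohort(simConfig(n_patients = 12, n_genes = 60,
                                  module_sizes = c(15), n_pi3k = 10,
                                  seed = 2))
  dir <- withr::local_tempdir()
  paths <- writeCohort(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- as.matrix(read.delim(paths["counts"], row.names = 1,
                               check.names = FALSE))
  expect_equal(back, sim$counts, ignore_attr = TRUE)
  truth <- jsonlite::read_json(paths["truth"])
  expect_equal(truth$true_threshold, 0)
  se <- cohortSE(sim$counts, sim$clinical)
  expect_s4_class(se, "SummarizedExperiment")
  expect_equal(ncol(se), nrow(sim$clinical))
})
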