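test_that("cell reference is in range, full rank, and deterministic", {
  ref <- simulate_cell_reference(K = 2, m = 10, seed = 1)
  expect_equal(dim(ref), c(2, 10))
  expect_true(all(ref >= 0 & ref <= 1))

  ref6 <- simulate_cell_reference(K = 6, m = 500, seed = 7)
  expect_equal(qr(unclass(ref6))$rank, 6)
  expect_identical(ref6, simulate_cell_reference(K = 6, m = 500, seed = 7))

  expect_error(simulate_cell_reference(K = 5, m = 3), "invalid")
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_causal = 100, m_probes = 50), "n_causal")
  expect_error(sim_config(ctp_case_shift = c(0.1, rep(0, 5))), "sum to 0")
  expect_error(sim_config(probe_overlap = 1.2), "probe_overlap")
  expect_error(sim_config(frac_low_variance = 1), "frac_low_variance")
})

test_that("simulated cohorts respect composition and range invariants", {
  cfg <- sim_config(n_cases = 60, n_controls = 60, m_probes = 300,
                    n_causal = 10, seed = 11)
  co <- simulate_cohort(cfg)
  expect_true(all(co$methyl$values >= 0 & co$methyl$values <= 1))
  ctp <- as.matrix(co$truth$true_ctp[, -1])
  expect_lt(max(abs(rowSums(ctp) - 1)), 1e-12)
  expect_true(all(ctp >= 0))
  expect_true(co$truth$true_rho2 >= 0 && co$truth$true_rho2 <= 1)
  expect_setequal(names(co$samples),
                  c("sample_id", "status", "age", "sex", "smoking_score",
                    "batch", "chip_position"))
  # deterministic given seed
  co2 <- simulate_cohort(cfg)
  expect_identical(co$methyl$values, co2$methyl$values)
})

test_that("low-variance probe fraction is honoured", {
  cfg <- sim_config(n_cases = 150, n_controls = 150, m_probes = 2000,
                    n_causal = 0, effect_sd = 0, frac_low_variance = 0.05,
                    seed = 5)
  co <- simulate_cohort(cfg)
  n_low <- sum(apply(co$methyl$values, 2, sd) < 0.02)
  expect_gt(n_low, 70)
  expect_lt(n_low, 130)
})

test_that("global-null cohorts give uniform linear MWAS p-values", {
  ks_p <- vapply(1:5, function(s) {
    cfg <- sim_config(n_cases = 60, n_controls = 60, m_probes = 400,
                      n_causal = 0, effect_sd = 0,
                      ctp_case_shift = rep(0, 6), batch_sd = 0,
                      batch_confounding = 0, seed = 20 + s)
    co <- simulate_cohort(cfg)
    std <- standardize_probes(filter_probes(co$methyl))
    tab <- mwas_linear(std, co$samples$status)
    suppressWarnings(stats::ks.test(tab$p, "punif")$p.value)
  }, numeric(1))
  # combined over replicates: uniformity not rejected at alpha = 0.01
  expect_gt(min(p.adjust(ks_p, "bonferroni")), 0.01)
})

test_that("realized case-control difference matches the configured effect", {
  diffs <- c()
  for (s in 1:8) {
    cfg <- sim_config(n_cases = 500, n_controls = 500, m_probes = 120,
                      n_causal = 10, effect_sd = 0.3, frac_low_variance = 0,
                      ctp_case_shift = rep(0, 6), batch_sd = 0,
                      batch_confounding = 0, seed = 40 + s)
    co <- simulate_cohort(cfg)
    st <- co$samples$status
    for (pid in co$truth$causal_probe_ids) {
      w <- co$methyl$values[, pid]
      d <- (mean(w[st == 1]) - mean(w[st == 0])) / sd(w[st == 0])
      diffs <- c(diffs, d * sign(co$truth$true_effects[pid]))
    }
  }
  expect_lt(abs(mean(diffs) - 0.3), 0.02)
})

test_that("cohort pairs share effects and overlap the right probe count", {
  cfg <- sim_config(n_cases = 50, n_controls = 50, m_probes = 101,
                    n_causal = 10, probe_overlap = 94 / 101, seed = 3)
  pair <- simulate_cohort_pair(cfg)
  expect_equal(n_probes(pair$target$methyl), 94)
  expect_true(all(pair$target$methyl$probe_annot$probe_id %in%
                    pair$discovery$methyl$probe_annot$probe_id))
  shared_causal <- intersect(names(pair$target$truth$true_effects),
                             names(pair$discovery$truth$true_effects))
  expect_identical(pair$target$truth$true_effects[shared_causal],
                   pair$discovery$truth$true_effects[shared_causal])
  # full overlap -> identical probe sets
  cfg1 <- sim_config(n_cases = 30, n_controls = 30, m_probes = 50,
                     n_causal = 5, probe_overlap = 1, seed = 4)
  pair1 <- simulate_cohort_pair(cfg1)
  expect_identical(pair1$target$methyl$probe_annot$probe_id,
                   pair1$discovery$methyl$probe_annot$probe_id)
  # independent individuals
  expect_length(intersect(sample_ids(pair$target$methyl),
                          sample_ids(pair$discovery$methyl)), 0)
})

test_that("discovery and target effect estimates correlate under shared effects", {
  cfg <- sim_config(n_cases = 250, n_controls = 250, m_probes = 300,
                    n_causal = 40, effect_sd = 0.3, seed = 8,
                    frac_low_variance = 0)
  pair <- simulate_cohort_pair(cfg)
  est <- lapply(pair, function(co) {
    std <- standardize_probes(co$methyl)
    mwas_linear(std, co$samples$status)
  })
  causal <- intersect(pair$discovery$truth$causal_probe_ids,
                      est$target$probe_id)
  b1 <- est$discovery$b[match(causal, est$discovery$probe_id)]
  b2 <- est$target$b[match(causal, est$target$probe_id)]
  expect_gt(cor(b1, b2), 0.5)
})

test_that("trait simulated from the random-probe-effect model hits its variance share", {
  ms <- make_white_methyl(300, 400, seed = 2)
  y <- simulate_oreml_trait(ms, rho2 = 0.5, seed = 3)
  expect_length(y, 300)
  # variance of the probe component across many draws brackets the target
  vars <- vapply(1:30, function(s) {
    var(simulate_oreml_trait(ms, rho2 = 0.5, seed = s))
  }, numeric(1))
  expect_lt(abs(mean(vars) - 1), 0.1)
  expect_error(simulate_oreml_trait(ms, rho2 = 1.2), "rho2")
})
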