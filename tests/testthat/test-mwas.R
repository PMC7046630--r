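test_that("linear engine matches per-probe regression oracle exactly", {
  ms <- make_white_methyl(40, 25, seed = 1)
  set.seed(2)
  y <- rnorm(40)
  C <- cbind(age = rnorm(40), sex = rbinom(40, 1, 0.5))
  tab <- mwas_linear(ms, y, C)
  for (i in sample(25, 8)) {
    pid <- colnames(ms$values)[i]
    fit <- summary(lm(y ~ ms$values[, i] + C))$coefficients[2, ]
    row <- tab[tab$probe_id == pid, ]
    expect_equal(row$b, unname(fit[1]), tolerance = 1e-10)
    expect_equal(row$se, unname(fit[2]), tolerance = 1e-10)
    expect_equal(row$p, unname(fit[4]), tolerance = 1e-10)
  }
})

test_that("a probe identical to the trait gets slope one and tiny p", {
  ms <- make_white_methyl(60, 10, seed = 3)
  y <- ms$values[, 4]
  tab <- mwas_linear(ms, y)
  row <- tab[tab$probe_id == colnames(ms$values)[4], ]
  expect_equal(row$b, 1, tolerance = 1e-10)
  expect_lt(row$p, 1e-50)
})

test_that("flipping a probe's sign flips its effect and keeps its p-value", {
  ms <- make_white_methyl(50, 15, seed = 4)
  y <- simulate_oreml_trait(ms, 0.3, seed = 5)
  flip <- ms
  flip$values[, 7] <- -flip$values[, 7]
  for (f in list(mwas_linear, mwas_moa)) {
    t1 <- f(ms, y); t2 <- f(flip, y)
    pid <- colnames(ms$values)[7]
    expect_equal(t2$b[t2$probe_id == pid], -t1$b[t1$probe_id == pid],
                 tolerance = 1e-10)
    expect_equal(t2$p[t2$probe_id == pid], t1$p[t1$probe_id == pid],
                 tolerance = 1e-10)
    other <- setdiff(t1$probe_id, pid)
    expect_equal(t2$p[match(other, t2$probe_id)],
                 t1$p[match(other, t1$probe_id)], tolerance = 1e-8)
  }
})

test_that("PC adjustment with k = 0 or uninformative PCs reduces to linear", {
  ms <- make_white_methyl(50, 30, seed = 6)
  set.seed(7)
  y <- rnorm(50)
  t0 <- mwas_pc_adjusted(ms, y, k = 0)
  tl <- mwas_linear(ms, y)
  expect_equal(t0$p, tl$p, tolerance = 1e-12)
  expect_identical(attr(t0, "method"), "linear_pc")
})

test_that("MOA reduces to linear regression when the omics variance vanishes", {
  ms <- make_white_methyl(60, 40, seed = 8)
  set.seed(9)
  y <- rnorm(60)
  fake <- methylmlm:::new_oreml_fit(
    sigma2 = c(orm1 = 1e-12, residual = 1), rho2 = 0, se_rho2 = 0,
    sigma_P2 = 1, se_sigma_P2 = 0,
    beta_hat = c(`(Intercept)` = mean(y)), beta_cov = matrix(1 / 60),
    loglik = 0, n_iter = 1L, converged = TRUE, n = 60)
  moa <- mwas_moa(ms, y, reml = fake)
  lin <- mwas_linear(ms, y)
  expect_lt(max(abs(moa$b - lin$b[match(moa$probe_id, lin$probe_id)])), 1e-6)
})

test_that("MOA equals the explicit GLS oracle at the fitted variances", {
  ms <- make_white_methyl(50, 120, seed = 10)
  y <- simulate_oreml_trait(ms, 0.4, seed = 11)
  orm <- compute_orm(ms)
  fit <- reml_fit(y, NULL, list(orm))
  moa <- mwas_moa(ms, y, reml = fit)
  V <- fit$sigma2[["orm1"]] * orm$A + diag(fit$sigma2[["residual"]], 50)
  Vinv <- solve(V)
  resid <- y - fit$beta_hat[["(Intercept)"]]
  for (i in sample(120, 20)) {
    w <- ms$values[, i]
    b_o <- drop(crossprod(w, Vinv %*% resid) / crossprod(w, Vinv %*% w))
    se_o <- drop(crossprod(w, Vinv %*% w))^-0.5
    pid <- colnames(ms$values)[i]
    expect_equal(moa$b[moa$probe_id == pid], b_o, tolerance = 1e-8)
    expect_equal(moa$se[moa$probe_id == pid], se_o, tolerance = 1e-8)
  }
})

test_that("MOA two-step approximates the joint fixed-effect REML oracle", {
  ms <- make_white_methyl(70, 50, seed = 12)
  y <- simulate_oreml_trait(ms, 0.3, seed = 13) + 0.2 * ms$values[, 1]
  orm <- compute_orm(ms)
  moa <- mwas_moa(ms, y)
  chi_moa <- (moa$b / moa$se)^2
  chi_joint <- vapply(seq_len(50), function(i) {
    fit <- reml_fit(y, ms$values[, i, drop = FALSE], list(orm))
    unname(fit$beta_hat[2]^2 / fit$beta_cov[2, 2])
  }, numeric(1))
  chi_moa <- chi_moa[match(colnames(ms$values), moa$probe_id)]
  rel <- abs(chi_moa - chi_joint) / pmax(chi_joint, 0.5)
  expect_lt(median(rel), 0.02)
  expect_lt(unname(quantile(rel, 0.9)), 0.10)
})

test_that("MOMENT tracks linear ranks on independent probes without confounding", {
  ms <- make_white_methyl(120, 150, seed = 14, bp_gap = 2e5)
  set.seed(15)
  beta <- c(rnorm(8, 0, 0.15), rep(0, 142))
  y <- drop(ms$values %*% beta) + rnorm(120)
  lin <- mwas_linear(ms, y)
  mom <- mwas_moment(ms, y)
  shared <- lin$probe_id
  expect_gt(cor(rank(lin$p), rank(mom$p[match(shared, mom$probe_id)])), 0.9)
})

test_that("fast MOMENT path matches the per-probe refit path closely", {
  ms <- make_white_methyl(50, 40, seed = 16, bp_gap = 4e4)
  y <- simulate_oreml_trait(ms, 0.3, seed = 17)
  fast <- mwas_moment(ms, y)
  slow <- mwas_moment(ms, y, cfg = moment_config(refit_variance_per_probe = TRUE))
  # same parametrization up to re-estimated variances: effects agree closely
  expect_gt(cor(fast$b, slow$b[match(fast$probe_id, slow$probe_id)]), 0.99)
})

test_that("window exclusion recovers a causal probe masked by proximal contamination", {
  # a causal probe and a correlated neighbour 30 kb away: MOMENT keeps the
  # causal probe's signal while MOA shrinks it against itself
  set.seed(18)
  n <- 150
  causal <- rnorm(n)
  neighbour <- 0.95 * causal + rnorm(n, 0, sqrt(1 - 0.95^2))
  rest <- matrix(rnorm(n * 60), n, 60)
  vals <- cbind(causal, neighbour, rest)
  vals <- sweep(sweep(vals, 2, colMeans(vals)), 2,
                sqrt(colMeans(sweep(vals, 2, colMeans(vals))^2)), `/`)
  colnames(vals) <- sprintf("cg%05d", seq_len(ncol(vals)))
  rownames(vals) <- sprintf("s%03d", seq_len(n))
  bp <- as.integer(c(1e6, 1e6 + 3e4, seq(5e6, by = 2e5, length.out = 60)))
  annot <- tibble::tibble(probe_id = colnames(vals), chr = "1", bp = bp,
                          gene = "g", orientation = "F")
  ms <- methyl_set(vals, annot, scale_state = "standardized")
  y <- 0.5 * vals[, 1] + rnorm(n)
  moa <- mwas_moa(ms, y)
  mom <- mwas_moment(ms, y, cfg = moment_config(group_p_threshold = 1e-3))
  pid <- colnames(vals)[1]
  chi_moa <- (moa$b / moa$se)[moa$probe_id == pid]^2
  chi_mom <- (mom$b / mom$se)[mom$probe_id == pid]^2
  expect_gt(chi_mom, chi_moa)
})

test_that("genomic inflation factor has its defining properties", {
  expect_equal(genomic_lambda(chi2 = rep(0.4549364, 5)), 1, tolerance = 1e-6)
  set.seed(19)
  chi <- rchisq(5000, 1)
  expect_equal(genomic_lambda(chi2 = 2 * chi), 2 * genomic_lambda(chi2 = chi),
               tolerance = 1e-12)
  p <- runif(20000)
  expect_equal(genomic_lambda(p = p), 1, tolerance = 0.05)
  expect_error(genomic_lambda(), "supply")
})

test_that("Bonferroni thresholds reproduce the printed significance cutoffs", {
  expect_equal(signif(bonferroni_threshold(160304), 2), 3.1e-7)
  expect_equal(signif(bonferroni_threshold(94), 2), 5.3e-4)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_error(bonferroni_threshold(0), "m must be")
})

test_that("all engines are calibrated on the global null", {
  lam <- matrix(NA_real_, 5, 4)
  for (s in 1:5) {
    cfg <- sim_config(n_cases = 200, n_controls = 200, m_probes = 2000,
                      n_causal = 0, effect_sd = 0, ctp_case_shift = rep(0, 6),
                      batch_sd = 0, batch_confounding = 0, seed = 900 + s)
    co <- simulate_cohort(cfg)
    std <- standardize_probes(filter_probes(co$methyl))
    y <- co$samples$status
    orm <- compute_orm(std)
    lam[s, ] <- c(attr(mwas_linear(std, y), "lambda_gc"),
                  attr(mwas_pc_adjusted(std, y, orm = orm, k = 10), "lambda_gc"),
                  attr(mwas_moa(std, y), "lambda_gc"),
                  attr(mwas_moment(std, y), "lambda_gc"))
  }
  expect_true(all(colMeans(lam) > 0.9))
  expect_true(all(colMeans(lam) < 1.1))
})
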