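test_that("BLUP equals the ridge closed form and shrinks to zero with the variance", {
  ms <- make_white_methyl(60, 150, seed = 1)
  y <- simulate_oreml_trait(ms, 0.4, seed = 2)
  fit <- reml_fit(y, NULL, list(compute_orm(ms)))
  wt <- blup_effects(ms, y, reml = fit)
  W <- ms$values
  lambda <- fit$sigma2[["residual"]] / (fit$sigma2[["orm1"]] / ncol(W))
  resid <- y - fit$beta_hat[["(Intercept)"]]
  u_ridge <- drop(crossprod(W, solve(tcrossprod(W) + diag(lambda, 60), resid)))
  expect_lt(max(abs(wt$weight - u_ridge)), 1e-8)
  expect_equal(attr(wt, "m_used"), 150)

  fake <- methylmlm:::new_oreml_fit(
    sigma2 = c(orm1 = 1e-14, residual = 1), rho2 = 0, se_rho2 = 0,
    sigma_P2 = 1, se_sigma_P2 = 0,
    beta_hat = c(`(Intercept)` = mean(y)), beta_cov = matrix(1 / 60),
    loglik = 0, n_iter = 1L, converged = TRUE, n = 60)
  wt0 <- blup_effects(ms, y, reml = fake)
  expect_lt(max(abs(wt0$weight)), 1e-10)
})

test_that("BLUP weights shrink relative to OLS slopes on orthogonal probes", {
  # columns mutually orthogonal and orthogonal to the intercept
  n <- 40
  set.seed(30)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 20), n))))[, 2:21]
  W <- Q * sqrt(n)
  dimnames(W) <- list(sprintf("s%03d", 1:n), sprintf("cg%05d", 1:20))
  annot <- tibble::tibble(probe_id = colnames(W), chr = "1",
                          bp = as.integer(1:20 * 2e5), gene = "g",
                          orientation = "F")
  ms <- methyl_set(W, annot, scale_state = "standardized")
  set.seed(3)
  y <- drop(W %*% rnorm(20, 0, 0.3)) + rnorm(n)
  fit <- reml_fit(y, NULL, list(compute_orm(ms)))
  wt <- blup_effects(ms, y, reml = fit)
  b_ols <- mwas_linear(ms, y)
  b_ols <- b_ols$b[match(wt$probe_id, b_ols$probe_id)]
  expect_true(all(abs(wt$weight) <= abs(b_ols) + 1e-8))
})

test_that("profile scores behave under matching, missing probes and zero weights", {
  ms <- make_white_methyl(30, 25, seed = 4)
  wt <- tibble::tibble(probe_id = colnames(ms$values)[1:10],
                       weight = rep(0, 10), source = "blup")
  sc <- mps_score(ms, wt)
  expect_true(all(sc$score == 0))

  wt2 <- tibble::tibble(probe_id = c(colnames(ms$values)[1:10], "cg_absent"),
                        weight = c(rnorm(10), 5), source = "moa")
  sc2 <- mps_score(ms, wt2)
  sc3 <- mps_score(ms, wt2[1:10, ])
  expect_equal(sc2$score, sc3$score)
  expect_equal(attr(sc2, "n_missing"), 1)
  expect_equal(attr(sc2, "n_matched"), 10)

  expect_error(mps_score(ms, tibble::tibble(probe_id = "nope", weight = 1)),
               "no weight probes")
})

test_that("in-sample BLUP scores correlate with the trait", {
  ms <- make_white_methyl(80, 100, seed = 5)
  y <- simulate_oreml_trait(ms, 0.5, seed = 6)
  wt <- blup_effects(ms, y)
  sc <- mps_score(ms, wt)
  expect_gt(cor(sc$score, y), 0.3)
})

test_that("threshold grids produce monotone, well-labelled weight tables", {
  ms <- make_white_methyl(60, 80, seed = 7)
  y <- simulate_oreml_trait(ms, 0.3, seed = 8)
  tab <- mwas_linear(ms, y)
  wts <- suppressWarnings(threshold_weights(tab, c(1e-4, 0.01, 0.5, 1)))
  m_used <- vapply(wts, function(w) attr(w, "m_used"), numeric(1))
  expect_true(all(diff(m_used) >= 0))
  expect_equal(unname(m_used[4]), 80)
  expect_warning(threshold_weights(tab, min(tab$p) / 10), "no probes")
})

test_that("cell-composition scores are linear in the effects", {
  ctp <- tibble::tibble(sample_id = c("a", "b"), neutrophils = c(0.5, 0.7),
                        CD4T = c(0.3, 0.2))
  eff <- tibble::tibble(cell_type = c("neutrophils", "CD4T"), estimate = c(0, 0))
  expect_true(all(ctp_score(ctp, eff)$score == 0))
  eff2 <- tibble::tibble(cell_type = "neutrophils", estimate = 2)
  expect_equal(ctp_score(ctp, eff2)$score, c(1.0, 1.4))
  eff3 <- tibble::tibble(cell_type = "basophils", estimate = 1)
  expect_error(ctp_score(ctp, eff3), "absent")

  ms <- make_white_methyl(2, 5, seed = 9)
  rownames(ms$values) <- c("a", "b")
  comb <- profile_score(ms, weights = tibble::tibble(
    probe_id = colnames(ms$values)[1], weight = 1), ctp = ctp,
    ctp_effects = eff2)
  expect_equal(comb$mps_total, comb$mps_probe + comb$mps_ctp)
})

test_that("AUC estimator has its exact boundary and symmetry properties", {
  status <- c(rep(1, 30), rep(0, 40))
  expect_equal(classify_scores(rep(1, 70), status)$auc, 0.5)
  expect_equal(classify_scores(status, status)$auc, 1)
  set.seed(10)
  s <- rnorm(70)
  expect_equal(classify_scores(s, status)$auc +
                 classify_scores(-s, status)$auc, 1)
})

test_that("AUC approaches the binormal closed form on large samples", {
  set.seed(11)
  n <- 8000
  d <- 1
  scores <- c(rnorm(n, d), rnorm(n, 0))
  status <- rep(c(1, 0), each = n)
  res <- classify_scores(scores, status)
  expect_equal(res$auc, pnorm(d / sqrt(2)), tolerance = 0.015)
  expect_lt(res$p_logistic, 1e-10)
  expect_gt(res$or_per_sd, 1)
})

test_that("AUC and DeLong variance match the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  status <- rbinom(120, 1, 0.45)
  scores <- rnorm(120) + 0.6 * status
  mine <- methylmlm:::auc_delong(scores, status)
  ref <- pROC::roc(status, scores, quiet = TRUE, direction = "<")
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_equal(mine$var, as.numeric(pROC::var(ref)), tolerance = 1e-10)
})

test_that("classification demands both classes", {
  expect_error(classify_scores(rnorm(10), rep(1, 10)), "both classes")
})
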