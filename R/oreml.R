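#' REML variance components for omics relationship matrices
#'
#' Fits `y = C beta + sum_j g_j + e`, `var(y) = sum_j A_j sigma_j^2 +
#' I sigma_e^2`, by average-information REML and reports the fraction of
#' phenotypic variance captured by the omics components,
#' `rho^2 = sum_j sigma_j^2 / (sum_j sigma_j^2 + sigma_e^2)`. For a
#' case-control trait the estimate is on the observed 0/1 scale; no
#' liability-scale transformation is offered, because for methylation the
#' captured variance can reflect both causes and consequences of disease
#' and the observed-scale estimate is the interpretable quantity (reported
#' together with the phenotypic variance `sigma_P^2`, which for a
#' covariate-free model approaches the binomial variance `P(1 - P)`).
#'
#' With a single relationship matrix the solver works in the eigenbasis of
#' `A`, where `V` is diagonal and each iteration costs `O(n p^2)`; with
#' several components it uses dense solves. Average-information updates are
#' step-halved whenever they would decrease the restricted likelihood or
#' push a variance below its floor (`1e-6 * var(y)`), so the restricted
#' log-likelihood is non-decreasing across accepted iterations.
#'
#' @param y Numeric response (e.g. 0/1 case-control status).
#' @param C Covariate matrix (columns are covariates) or `NULL`; an
#'   intercept is always included.
#' @param orms List of `orm` objects (or n x n matrices); may be empty,
#'   in which case only the residual variance is estimated.
#' @param max_iter,tol Iteration cap (default 100) and convergence
#'   tolerance on the change in restricted log-likelihood (default 1e-8).
#' @param engine `"auto"` (eigendecomposition fast path for a single
#'   relationship matrix, dense solves otherwise) or `"dense"` to force
#'   the generic path.
#' @return An object of class `oreml_fit` with variance components
#'   (`sigma2`, named, residual last), `rho2`, `se_rho2`, `sigma_P2`,
#'   `se_sigma_P2`, fixed effects `beta_hat` with covariance `beta_cov`,
#'   restricted log-likelihood `loglik`, `n_iter`, and `converged`.
#' @export
reml_fit <- function(y, C = NULL, orms = list(), max_iter = 100, tol = 1e-8,
                     engine = c("auto", "dense")) {
  engine <- match.arg(engine)
  y <- as.numeric(y)
  n <- length(y)
  C <- build_fixed_design(C, n)
  p <- ncol(C)
  if (n < p + 2) abort("need n >= p + 2 observations.")
  if (inherits(orms, "orm")) orms <- list(orms)
  A_list <- lapply(orms, function(a) if (inherits(a, "orm")) a$A else a)
  q <- length(A_list)
  vy <- var(y)
  floor_v <- 1e-6 * vy

  if (q == 0) {
    fit <- lm.fit(C, y)
    df <- n - p
    s2 <- sum(fit$residuals^2) / df
    XtXinv <- chol2inv(chol(crossprod(C)))
    out <- new_oreml_fit(
      sigma2 = c(residual = s2), rho2 = 0, se_rho2 = 0,
      sigma_P2 = s2, se_sigma_P2 = s2 * sqrt(2 / df),
      beta_hat = setNames(fit$coefficients, colnames(C)),
      beta_cov = XtXinv * s2,
      loglik = -0.5 * (df * log(s2) + df + determinant(crossprod(C))$modulus),
      n_iter = 0L, converged = TRUE, n = n)
    return(out)
  }

  engine <- if (q == 1 && engine == "auto") reml_engine_eigen(y, C, A_list[[1]])
            else reml_engine_dense(y, C, A_list)

  theta <- rep(vy / (q + 1), q + 1)
  state <- engine$evaluate(theta)
  n_iter <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    n_iter <- it
    # active-set AI step: components pinned at the floor with a negative
    # score stay frozen, the AI system is solved for the free ones
    free <- !(theta <= floor_v * (1 + 1e-8) & state$score < 0)
    step <- rep(0, q + 1)
    if (any(free)) {
      ai_step <- tryCatch(
        solve(state$AI[free, free, drop = FALSE], state$score[free]),
        error = function(e) NULL)
      if (is.null(ai_step) || any(!is.finite(ai_step))) {
        ai_step <- (theta^2 * (state$yPAPy - state$trPA) / n)[free]  # EM fallback
      }
      step[free] <- ai_step
    }
    accepted <- FALSE
    for (h in 0:30) {
      cand <- pmax(theta + step / 2^h, floor_v)
      cand_state <- tryCatch(engine$evaluate(cand), error = function(e) NULL)
      if (!is.null(cand_state) && is.finite(cand_state$loglik) &&
          cand_state$loglik >= state$loglik - 1e-8 * (1 + abs(state$loglik))) {
        accepted <- TRUE
        break
      }
    }
    if (!accepted) {
      # no step-halved move improves the restricted likelihood: we are at
      # a (possibly boundary) optimum to numerical precision
      converged <- TRUE
      break
    }
    delta_ll <- cand_state$loglik - state$loglik
    theta <- cand
    state <- cand_state
    if (abs(delta_ll) < tol) {
      converged <- TRUE
      break
    }
  }

  names(theta) <- c(paste0("orm", seq_len(q)), "residual")
  sigma_o2 <- sum(theta[seq_len(q)])
  sigma_P2 <- sum(theta)
  rho2 <- sigma_o2 / sigma_P2

  theta_cov <- tryCatch(solve(state$AI), error = function(e) {
    matrix(NA_real_, q + 1, q + 1)
  })
  grad <- c(rep(theta[q + 1], q), -sigma_o2) / sigma_P2^2  # d rho2 / d theta
  se_rho2 <- sqrt(max(0, drop(grad %*% theta_cov %*% grad)))
  se_sigma_P2 <- sqrt(max(0, sum(theta_cov)))

  new_oreml_fit(
    sigma2 = theta, rho2 = rho2, se_rho2 = se_rho2,
    sigma_P2 = sigma_P2, se_sigma_P2 = se_sigma_P2,
    beta_hat = state$beta_hat, beta_cov = state$beta_cov,
    loglik = state$loglik, n_iter = n_iter, converged = converged, n = n)
}

build_fixed_design <- function(C, n) {
  if (is.null(C)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  C <- as.matrix(C)
  if (nrow(C) != n) abort("covariate matrix rows must match length(y).")
  has_const <- any(apply(C, 2, function(col) sd(col) == 0 & col[1] != 0))
  if (!has_const) {
    C <- cbind(`(Intercept)` = 1, C)
  }
  if (is.null(colnames(C))) colnames(C) <- paste0("x", seq_len(ncol(C)))
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    dropped <- colnames(C)[qrC$pivot[(qrC$rank + 1):ncol(C)]]
    abort(paste0("rank-deficient fixed-effect design: ",
                 paste(dropped, collapse = ", ")))
  }
  C
}

# Shared iteration quantities for a parameter vector theta:
# loglik, score, AI matrix, beta_hat/beta_cov, and the EM ingredients.
# Eigen engine: single ORM, V diagonal in the eigenbasis of A.
reml_engine_eigen <- function(y, C, A) {
  eg <- eigen(A, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  Q <- eg$vectors
  ys <- drop(crossprod(Q, y))
  Cs <- crossprod(Q, C)
  p <- ncol(C)
  list(evaluate = function(theta) {
    d <- theta[1] * lam + theta[2]
    if (any(d <= 0)) abort("non-positive-definite V.")
    Cd <- Cs / d
    M <- crossprod(Cs, Cd)
    Mc <- chol(M)
    Minv <- chol2inv(Mc)
    Pv <- function(v, av = v / d) av - Cd %*% (Minv %*% crossprod(Cs, av))
    Py <- drop(Pv(ys))
    beta_hat <- drop(Minv %*% crossprod(Cd, ys))
    # tr(P D_a) for A rotated to diag(a): sum(a/d) - tr(Minv Cs' diag(a/d^2) Cs)
    trPD <- function(a) {
      sum(a / d) - sum(Minv * crossprod(Cs * (a / d^2), Cs))
    }
    PAPy <- list(drop(Pv(lam * Py)), drop(Pv(Py)))
    yPAPy <- c(sum(Py * lam * Py), sum(Py * Py))  # (Py)' A (Py) in rotated basis
    score <- -0.5 * (c(trPD(lam), trPD(rep(1, length(d)))) - yPAPy)
    AI <- matrix(0, 2, 2)
    basis <- list(lam, rep(1, length(d)))
    for (j in 1:2) for (k in j:2) {
      AI[j, k] <- 0.5 * sum((basis[[j]] * Py) * PAPy[[k]])
      AI[k, j] <- AI[j, k]
    }
    loglik <- -0.5 * (sum(log(d)) + 2 * sum(log(diag(Mc))) + sum(ys * Py))
    list(loglik = loglik, score = score, AI = AI,
         yPAPy = yPAPy, trPA = c(trPD(lam), trPD(rep(1, length(d)))),
         beta_hat = setNames(beta_hat, colnames(C)), beta_cov = Minv)
  })
}

# Dense engine: any number of ORMs.
reml_engine_dense <- function(y, C, A_list) {
  n <- length(y)
  q <- length(A_list)
  I_n <- diag(n)
  list(evaluate = function(theta) {
    V <- theta[q + 1] * I_n
    for (j in seq_len(q)) V <- V + theta[j] * A_list[[j]]
    Vc <- tryCatch(chol(V), error = function(e) abort("non-positive-definite V."))
    Vinv <- chol2inv(Vc)
    VC <- Vinv %*% C
    M <- crossprod(C, VC)
    Mc <- chol(M)
    Minv <- chol2inv(Mc)
    P <- Vinv - VC %*% Minv %*% t(VC)
    Py <- drop(P %*% y)
    mats <- c(A_list, list(I_n))
    APy <- lapply(mats, function(A) drop(A %*% Py))
    PAPy <- lapply(APy, function(v) drop(P %*% v))
    yPAPy <- vapply(APy, function(v) sum(Py * v), numeric(1))
    trPA <- vapply(mats, function(A) sum(P * A), numeric(1))
    score <- -0.5 * (trPA - yPAPy)
    AI <- matrix(0, q + 1, q + 1)
    for (j in seq_len(q + 1)) for (k in j:(q + 1)) {
      AI[j, k] <- 0.5 * sum(APy[[j]] * PAPy[[k]])
      AI[k, j] <- AI[j, k]
    }
    beta_hat <- drop(Minv %*% crossprod(VC, y))
    loglik <- -0.5 * (2 * sum(log(diag(Vc))) + 2 * sum(log(diag(Mc))) +
                        sum(y * Py))
    list(loglik = loglik, score = score, AI = AI,
         yPAPy = yPAPy, trPA = trPA,
         beta_hat = setNames(beta_hat, colnames(C)), beta_cov = Minv)
  })
}

new_oreml_fit <- function(sigma2, rho2, se_rho2, sigma_P2, se_sigma_P2,
                          beta_hat, beta_cov, loglik, n_iter, converged, n) {
  structure(list(sigma2 = sigma2, rho2 = rho2, se_rho2 = se_rho2,
                 sigma_P2 = sigma_P2, se_sigma_P2 = se_sigma_P2,
                 beta_hat = beta_hat, beta_cov = beta_cov,
                 loglik = as.numeric(loglik), n_iter = n_iter,
                 converged = converged, n = n),
            class = "oreml_fit")
}

#' @export
print.oreml_fit <- function(x, ...) {
  cat(sprintf(
    "<oreml_fit> n = %d | rho2 = %.3f (s.e. %.3f) | sigma_P2 = %.3f | %s in %d iter\n",
    x$n, x$rho2, x$se_rho2, x$sigma_P2,
    if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Tidy an OREML fit
#'
#' @param x An `oreml_fit`.
#' @param effects `"variance"` for variance components or `"fixed"` for
#'   fixed-effect estimates.
#' @param ... Unused.
#' @return A tibble with one row per term.
#' @export
tidy.oreml_fit <- function(x, effects = c("variance", "fixed"), ...) {
  effects <- match.arg(effects)
  if (effects == "variance") {
    tibble(term = names(x$sigma2), estimate = unname(x$sigma2))
  } else {
    tibble(term = names(x$beta_hat), estimate = unname(x$beta_hat),
           std.error = sqrt(pmax(0, diag(x$beta_cov))))
  }
}

#' @rdname tidy.oreml_fit
#' @export
glance.oreml_fit <- function(x, ...) {
  tibble(rho2 = x$rho2, se_rho2 = x$se_rho2, sigma_P2 = x$sigma_P2,
         se_sigma_P2 = x$se_sigma_P2, logLik = x$loglik,
         n_iter = x$n_iter, converged = x$converged, nobs = x$n)
}

#' Cell-type-proportion fixed effects from an OREML model
#'
#' Appends the estimated cell proportions (minus one reference cell type,
#' dropped for compositional collinearity) to the base covariates and
#' returns their fixed-effect estimates from [reml_fit()]. These effects
#' weight the cell proportions in the cell-composition component of a
#' methylation profile score.
#'
#' @param y Case-control status (0/1).
#' @param C_base Base covariate matrix or `NULL`.
#' @param ctp Tibble from [estimate_ctp()] (`sample_id` + proportions).
#' @param orm An `orm` object (genome-wide relationship matrix).
#' @param drop_cell Cell type excluded from the design; defaults to
#'   `"eosinophils"` when present, else the last column.
#' @return A list: `effects` (tibble cell_type/estimate/std.error) and
#'   `fit` (the full `oreml_fit`).
#' @export
ctp_fixed_effects <- function(y, C_base = NULL, ctp, orm, drop_cell = NULL) {
  ctp_mat <- as.matrix(ctp[, setdiff(names(ctp), "sample_id")])
  if (is.null(drop_cell)) {
    drop_cell <- if ("eosinophils" %in% colnames(ctp_mat)) "eosinophils"
                 else colnames(ctp_mat)[ncol(ctp_mat)]
  }
  keep <- setdiff(colnames(ctp_mat), drop_cell)
  design <- cbind(C_base, ctp_mat[, keep, drop = FALSE])
  fit <- reml_fit(y, design, list(orm))
  idx <- match(keep, names(fit$beta_hat))
  effects <- tibble(
    cell_type = keep,
    estimate = unname(fit$beta_hat[idx]),
    std.error = sqrt(pmax(0, diag(fit$beta_cov)[idx]))
  )
  list(effects = effects, fit = fit)
}
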