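# PRS-phenotype association machinery: OLS with incremental R-squared,
# baseline-category multinomial logistic regression via Newton-Raphson with
# step-halving, 1-df Wald odds-ratio equality contrasts, and
# GENSUB-adjusted reruns.

#' Expand covariates into a reference-coded numeric design block
#'
#' Builds the standard covariate set: sex, within-sample age quartiles
#' (rank-based, ties broken by first occurrence so bins are deterministic
#' and near-equal), three ancestry principal components, and study of
#' origin. Categorical variables are expanded to indicator columns against
#' their first observed level.
#'
#' @param covars data.frame with columns sex, age, pc1..pc3, study.
#' @return Numeric matrix (no intercept column), one row per sample.
#' @export
build_covariates <- function(covars) {
  stopifnot(all(c("sex", "age", "pc1", "pc2", "pc3", "study") %in%
                  names(covars)))
  n <- nrow(covars)
  rk <- rank(covars$age, ties.method = "first")
  q <- cut(rk, breaks = stats::quantile(rk, probs = seq(0, 1, 0.25)),
           include.lowest = TRUE, labels = paste0("q", 1:4))
  study <- factor(covars$study)
  out <- cbind(sex = as.numeric(covars$sex),
               stats::model.matrix(~q)[, -1, drop = FALSE],
               pc1 = covars$pc1, pc2 = covars$pc2, pc3 = covars$pc3,
               stats::model.matrix(~study)[, -1, drop = FALSE])
  colnames(out) <- sub("^qq", "age_q", colnames(out))
  out
}

check_full_rank <- function(x) {
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("design matrix is rank deficient; aliased columns: ",
         paste(bad, collapse = ", "))
  }
  qx
}

#' OLS association with incremental R-squared
#'
#' Regresses the outcome on the standardized PRS plus covariates, reporting
#' the standardized coefficient (per SD of PRS, per SD of outcome), the
#' incremental R-squared over the covariate-only model, and the t-test
#' p-value for the PRS term.
#'
#' @param y Outcome vector (e.g. standardized GENSUB scores).
#' @param prs PRS vector; z-scored internally.
#' @param covars Optional numeric covariate matrix (see
#'   [build_covariates()]); may be NULL.
#' @return List: beta_std, r2_inc, r2_full, r2_cov, tstat, pvalue, n.
#' @export
ols_incremental <- function(y, prs, covars = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  prs_std <- as.numeric(scale(prs))
  x0 <- cbind(`(Intercept)` = rep(1, n), covars)
  x1 <- cbind(x0, prs = prs_std)
  if (n <= ncol(x1)) stop("need more observations than predictors")
  q1 <- check_full_rank(x1)
  fit1 <- stats::lm.fit(x1, y)
  fit0 <- stats::lm.fit(x0, y)
  tss <- sum((y - mean(y))^2)
  r2_full <- 1 - sum(fit1$residuals^2) / tss
  r2_cov <- 1 - sum(fit0$residuals^2) / tss
  dfres <- n - ncol(x1)
  sigma2 <- sum(fit1$residuals^2) / dfres
  xtxi <- chol2inv(qr.R(q1))
  se <- sqrt(sigma2 * xtxi[ncol(x1), ncol(x1)])
  b <- fit1$coefficients["prs"]
  tstat <- b / se
  list(beta_std = unname(b / stats::sd(y)),
       r2_inc = r2_full - r2_cov, r2_full = r2_full, r2_cov = r2_cov,
       tstat = unname(tstat),
       pvalue = unname(2 * stats::pt(-abs(tstat), dfres)), n = n)
}

#' Baseline-category multinomial logistic regression
#'
#' Fits the 5-level involvement outcome against the standardized PRS and
#' covariates by full Newton-Raphson on the multinomial log-likelihood with
#' baseline-category logits (reference = lowest level). The step is halved
#' until the log-likelihood does not decrease; convergence requires the
#' score max-norm below `tol`. The coefficient covariance is the inverse
#' observed information (equal to expected information under this canonical
#' parameterization).
#'
#' @param level Integer outcome vector with levels 0..K-1 (reference 0);
#'   every level must be observed.
#' @param prs PRS vector, z-scored internally (pass `standardize = FALSE`
#'   to use as-is).
#' @param covars Optional numeric covariate matrix; may be NULL.
#' @param tol Convergence tolerance on the score max-norm.
#' @param max_iter Iteration cap.
#' @param standardize Standardize the PRS column first? Default TRUE.
#' @return A `multinom_fit`: coefficient matrix (predictors x K-1 levels),
#'   per-level PRS summaries (b, se, z, or), the (K-1)x(K-1) covariance of
#'   the PRS coefficients, full vcov, log-likelihood, iterations, n.
#' @export
multinomial_fit <- function(level, prs, covars = NULL, tol = 1e-8,
                            max_iter = 100, standardize = TRUE) {
  level <- as.integer(level)
  lvls <- sort(unique(level))
  k <- length(lvls)
  if (k < 2) stop("outcome has a single level")
  if (!identical(lvls, seq(min(lvls), max(lvls)))) {
    # relabel to consecutive codes, reference stays the lowest
    level <- match(level, lvls) - 1L
  } else {
    level <- level - min(lvls)
  }
  n <- length(level)
  prs_col <- if (standardize) as.numeric(scale(prs)) else as.numeric(prs)
  x <- cbind(`(Intercept)` = rep(1, n), covars, prs = prs_col)
  check_full_rank(x)
  p <- ncol(x)
  km1 <- k - 1L
  y <- matrix(0, n, km1)
  for (j in seq_len(km1)) y[, j] <- as.numeric(level == j)

  beta <- matrix(0, p, km1,
                 dimnames = list(colnames(x), paste0("level", seq_len(km1))))
  loglik <- function(b) {
    eta <- x %*% b
    denom <- log1p(rowSums(exp(eta)))
    sum(eta * y) - sum(denom)
  }
  ll <- loglik(beta)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- x %*% beta
    expeta <- exp(eta)
    denom <- 1 + rowSums(expeta)
    pr <- expeta / denom                 # n x km1 non-reference probabilities
    score <- crossprod(x, y - pr)        # p x km1
    if (max(abs(score)) < tol) break
    if (iter > max_iter)
      stop("multinomial fit did not converge in ", max_iter, " iterations")
    # observed information, (p*km1) x (p*km1), blocks W_jl = diag(p_j (1{j=l} - p_l))
    info <- matrix(0, p * km1, p * km1)
    for (j in seq_len(km1)) {
      for (l in j:km1) {
        w <- if (j == l) pr[, j] * (1 - pr[, j]) else -pr[, j] * pr[, l]
        blk <- crossprod(x, x * w)
        rj <- (j - 1) * p + seq_len(p)
        rl <- (l - 1) * p + seq_len(p)
        info[rj, rl] <- blk
        info[rl, rj] <- blk
      }
    }
    step <- tryCatch(solve(info, as.vector(score)), error = function(e)
      stop("singular information matrix (possible separation or empty cell)"))
    step <- matrix(step, p, km1)
    sz <- 1
    repeat {
      cand <- beta + sz * step
      llc <- loglik(cand)
      if (is.finite(llc) && llc >= ll - 1e-12) break
      sz <- sz / 2
      if (sz < 1e-10) stop("step-halving failed; likelihood not improvable")
    }
    beta <- beta + sz * step
    ll <- loglik(beta)
    if (max(abs(beta)) > 30)
      stop("diverging coefficients; possible perfect separation in '",
           rownames(beta)[which.max(apply(abs(beta), 1, max))], "'")
  }
  # final information and covariance at the optimum
  eta <- x %*% beta
  expeta <- exp(eta)
  pr <- expeta / (1 + rowSums(expeta))
  info <- matrix(0, p * km1, p * km1)
  for (j in seq_len(km1)) {
    for (l in j:km1) {
      w <- if (j == l) pr[, j] * (1 - pr[, j]) else -pr[, j] * pr[, l]
      blk <- crossprod(x, x * w)
      rj <- (j - 1) * p + seq_len(p)
      rl <- (l - 1) * p + seq_len(p)
      info[rj, rl] <- blk
      info[rl, rj] <- blk
    }
  }
  vcov_full <- solve(info)
  prs_pos <- p * seq_len(km1)            # prs row is the last predictor
  prs_vcov <- vcov_full[prs_pos, prs_pos, drop = FALSE]
  b <- beta[p, ]
  se <- sqrt(diag(prs_vcov))
  structure(list(coefficients = beta,
                 prs = data.frame(level = seq_len(km1), b = b, se = se,
                                  z = b / se, or = exp(b), row.names = NULL),
                 prs_vcov = prs_vcov, vcov = vcov_full,
                 loglik = ll, iterations = iter, n = n,
                 fitted = cbind(ref = 1 - rowSums(pr), pr)),
            class = "multinom_fit")
}

#' 1-df Wald test of odds-ratio equality between two involvement levels
#'
#' Tests `b_k = b_k'` for the PRS coefficients of two non-reference levels:
#' `W = (b_k - b_k')^2 / (var_k + var_k' - 2 cov)`, chi-square with 1 df.
#'
#' @param fit A [multinomial_fit()] result.
#' @param k,kp Non-reference level indices (1-based among non-reference
#'   levels), distinct.
#' @return List: levels, statistic, pvalue.
#' @export
wald_pair <- function(fit, k, kp) {
  stopifnot(k != kp)
  km1 <- nrow(fit$prs)
  if (k < 1 || kp < 1 || k > km1 || kp > km1)
    stop("levels must be non-reference levels of the fit")
  d <- fit$prs$b[k] - fit$prs$b[kp]
  v <- fit$prs_vcov[k, k] + fit$prs_vcov[kp, kp] - 2 * fit$prs_vcov[k, kp]
  if (v <= 0) stop("non-positive variance of the contrast")
  stat <- d^2 / v
  list(levels = c(k, kp), statistic = stat,
       pvalue = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' All pairwise odds-ratio equality contrasts
#'
#' @param fit A [multinomial_fit()] result.
#' @return data.frame with one row per unordered pair of non-reference
#'   levels: level_a, level_b, statistic, pvalue.
#' @export
wald_all_pairs <- function(fit) {
  km1 <- nrow(fit$prs)
  pairs <- utils::combn(km1, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    w <- wald_pair(fit, pairs[1, i], pairs[2, i])
    data.frame(level_a = pairs[1, i], level_b = pairs[2, i],
               statistic = w$statistic, pvalue = w$pvalue)
  }))
  out
}

#' GENSUB-adjusted multinomial rerun
#'
#' Repeats [multinomial_fit()] with the GENSUB factor score appended to the
#' covariate block, to ask whether a disorder-substance association is
#' explained by general substance-involvement liability.
#'
#' @inheritParams multinomial_fit
#' @param gensub Standardized GENSUB score vector.
#' @return A `multinom_fit` (see [multinomial_fit()]).
#' @export
adjusted_rerun <- function(level, prs, covars, gensub, ...) {
  gensub <- as.numeric(gensub)
  if (stats::sd(gensub) == 0) {
    warning("gensub has zero variance; returning the unadjusted fit")
    return(multinomial_fit(level, prs, covars = covars, ...))
  }
  multinomial_fit(level, prs, covars = cbind(covars, gensub = gensub), ...)
}

#' @export
print.multinom_fit <- function(x, ...) {
  cat("Baseline-category multinomial fit: n =", x$n,
      "; logLik =", format(x$loglik), "; iterations =", x$iterations, "\n")
  print(transform(x$prs, or = round(or, 4), z = round(z, 3)))
  invisible(x)
}
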